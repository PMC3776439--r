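# The iterative feedback loop.
#
# Each iteration: (1) select high-confidence peptides; (2) collect their
# parent proteins into the putative list; (3) update experimental peptide
# counts and shared-peptide weights; (4) score each putative protein with
# the length-normalized noisy-OR model; (5) replenish previously
# low-confidence peptides through high-confidence proteins; (6) recompute
# peptide probabilities from the protein probabilities; (7) permanently
# eliminate proteins that oscillate in and out of the putative list; stop
# when the protein and peptide lists and the protein probabilities are
# steady.

#' Inference configuration
#'
#' @param peptide_threshold Probability above which a peptide is selected as
#'   high-confidence (default 0.95).
#' @param protein_threshold Probability above which a protein is considered
#'   positive and replenishes its peptides (default 0.95).
#' @param q_tolerance Convergence tolerance on the largest protein
#'   probability change between iterations (default 1e-6).
#' @param max_iterations Iteration cap (default 100).
#' @param elimination_cycles Number of complete in-out-in oscillations of
#'   the putative-list membership before a protein is permanently
#'   eliminated (default 1).
#' @param log_base Base of the logarithm in the protein-model exponent
#'   (default `exp(1)`, the natural log; the base only rescales the
#'   length-normalization exponent).
#' @return A list of class `infer_config`.
#' @export
infer_config <- function(peptide_threshold = 0.95,
                         protein_threshold = 0.95,
                         q_tolerance = 1e-6,
                         max_iterations = 100L,
                         elimination_cycles = 1L,
                         log_base = exp(1)) {
  stopifnot(peptide_threshold > 0, peptide_threshold <= 1,
            protein_threshold > 0, protein_threshold <= 1,
            q_tolerance > 0, max_iterations >= 1,
            elimination_cycles >= 1, log_base > 1)
  structure(list(peptide_threshold = peptide_threshold,
                 protein_threshold = protein_threshold,
                 q_tolerance = q_tolerance,
                 max_iterations = as.integer(max_iterations),
                 elimination_cycles = as.integer(elimination_cycles),
                 log_base = log_base),
            class = "infer_config")
}

#' Protein presence probability
#'
#' The probability that a protein is present given its currently selected
#' constituent peptides:
#' \deqn{q = \left[1 - \prod_i (1 - x_i w_{ik} q_{prev})\right]^{-\log(n_k / N_k)}}
#' The bracket is a noisy-OR over the peptide evidence, discounted by the
#' previous iteration's protein probability; the exponent normalizes for
#' protein length through the ratio of experimental to theoretical peptide
#' counts. Conventions: `n_k = 0` gives `q = 0`; when `n_k = N_k` the
#' exponent is 0 and `q = 1` if the bracket is positive, `0` otherwise
#' (zero evidence never yields presence).
#'
#' @param x Peptide probabilities (length `n_k`).
#' @param w Peptide-to-protein weights (length `n_k`).
#' @param q_prev Protein probability from the previous iteration.
#' @param n_k Number of selected experimental peptides.
#' @param N_k Number of theoretical peptides, `>= max(n_k, 1)`.
#' @param log_base Logarithm base for the exponent (default natural).
#' @return Probability in `[0, 1]`.
#' @examples
#' protein_probability(c(0.9, 0.8), c(1, 1), 1, 2, 20)  # ~0.95455
#' @export
protein_probability <- function(x, w, q_prev, n_k, N_k, log_base = exp(1)) {
  if (length(x) != length(w))
    stop("x and w must have equal length", call. = FALSE)
  if (length(x) != n_k)
    stop("length(x) must equal n_k", call. = FALSE)
  if (n_k == 0L) return(0)
  if (N_k < max(n_k, 1L))
    stop("N_k must be at least max(n_k, 1)", call. = FALSE)
  bracket <- 1 - prod(1 - x * w * q_prev)
  expo <- -log(n_k / N_k, base = log_base)
  if (expo == 0) return(if (bracket > 0) 1 else 0)
  min(max(bracket^expo, 0), 1)
}

#' Select high-confidence peptides
#'
#' Peptides whose current probability meets the threshold and that retain at
#' least one non-eliminated parent protein.
#'
#' @param x Named vector of current peptide probabilities.
#' @param index A `pp_index`.
#' @param eliminated Accessions permanently eliminated.
#' @param threshold Selection threshold in `(0, 1]`.
#' @return Sorted character vector of selected peptide sequences.
#' @export
select_peptides <- function(x, index, eliminated = character(), threshold) {
  cand <- names(x)[x >= threshold]
  keep <- vapply(cand, function(p) {
    length(setdiff(index$peptide_to_proteins[[p]], eliminated)) > 0L
  }, logical(1))
  sort(cand[keep])
}

#' Putative protein list
#'
#' Union of the selected peptides' parents, minus eliminated accessions.
#'
#' @param selected Selected peptide sequences.
#' @param index A `pp_index`.
#' @param eliminated Eliminated accessions.
#' @return Sorted character vector of active accessions.
#' @export
putative_proteins <- function(selected, index, eliminated = character()) {
  par <- unlist(index$peptide_to_proteins[selected], use.names = FALSE)
  sort(setdiff(unique(as.character(par)), eliminated))
}

#' Replenish peptides through high-confidence proteins
#'
#' Previously unselected peptides mapping to at least one high-confidence
#' protein are added to the selected set regardless of their current
#' probability; already selected peptides are retained.
#'
#' @param selected Currently selected peptide sequences.
#' @param high_conf Accessions with probability at or above the protein
#'   threshold.
#' @param peptides All peptide sequences under consideration.
#' @param index A `pp_index`.
#' @return Sorted augmented selected set.
#' @export
replenish_peptides <- function(selected, high_conf, peptides, index) {
  if (!length(high_conf)) return(sort(selected))
  cand <- setdiff(peptides, selected)
  add <- cand[vapply(cand, function(p) {
    length(intersect(index$peptide_to_proteins[[p]], high_conf)) > 0L
  }, logical(1))]
  sort(union(selected, add))
}

#' Recompute peptide probabilities from protein probabilities
#'
#' \deqn{x_i = \sum_k w_{ik} q_k} over the peptide's active parents. Since
#' the weights sum to 1 and each `q` is in `[0, 1]`, so is the result.
#'
#' @param weights Named list of per-peptide weight vectors (from
#'   [assign_weights()]).
#' @param q Named vector of active-protein probabilities.
#' @return Named vector of updated peptide probabilities.
#' @export
recompute_peptide_probabilities <- function(weights, q) {
  vapply(weights, function(w) sum(w * q[names(w)]), numeric(1))
}

#' Detect proteins to eliminate from their membership history
#'
#' A protein whose putative-list membership history (recorded from its first
#' appearance) shows at least `elimination_cycles` complete in-out-in
#' oscillations is permanently eliminated: such proteins are repeatedly
#' dropped for low probability yet re-admitted through peptides shared with
#' positive proteins.
#'
#' @param histories Named list of character vectors over `{"in", "out"}`.
#' @param elimination_cycles Required number of completed oscillations.
#' @return Character vector of accessions to eliminate.
#' @export
apply_elimination <- function(histories, elimination_cycles = 1L) {
  cycles <- vapply(histories, function(h) {
    if (length(h) < 3L) return(0L)
    sum(h[-1L] == "in" & h[-length(h)] == "out")
  }, integer(1))
  sort(names(cycles)[cycles >= elimination_cycles])
}

#' Convergence check between two iteration snapshots
#'
#' Converged when the active protein set and the selected peptide set are
#' unchanged and the largest protein-probability change is below tolerance.
#'
#' @param previous,current Snapshots: lists with `active`, `q`, `selected`.
#' @param q_tolerance Tolerance on `max |q - q_prev|`.
#' @return Logical flag.
#' @export
check_convergence <- function(previous, current, q_tolerance = 1e-6) {
  if (is.null(previous)) return(FALSE)
  if (!identical(previous$active, current$active)) return(FALSE)
  if (!identical(previous$selected, current$selected)) return(FALSE)
  if (!length(current$active)) return(TRUE)
  max(abs(current$q[current$active] - previous$q[previous$active])) <
    q_tolerance
}

#' Fit the feedback protein-inference model
#'
#' Runs the iterative feedback loop on a PSM report and a protein database.
#' Peptide probabilities are initialized from the report (the maximum
#' PSM-level probability per distinct peptide), protein probabilities start
#' at 1 (every protein with identified constituent peptides is given the
#' same prior chance of presence), and the loop alternates protein scoring
#' and peptide re-scoring until both lists and the protein probabilities are
#' steady.
#'
#' @param psms PSM data frame from [read_psm_table()] or
#'   [read_pepxml_subset()].
#' @param proteins Protein database data frame from [read_fasta()].
#' @param config An [infer_config()].
#' @param settings A [digestion_settings()]; a `NULL` mass window is filled
#'   in from the report via [infer_mass_window()].
#' @param map_by_fasta Also map peptides to database proteins by substring
#'   matching (see [build_index()]).
#' @param equate_il Treat isoleucine and leucine as indistinguishable by
#'   rewriting I to L in peptides and database sequences.
#' @param verbose Emit a per-iteration progress line.
#' @return An object of class `feedprot_fit`: a list with `proteins` and
#'   `peptides` result tables, the per-iteration `log`, `snapshots`,
#'   `converged`, `n_iterations`, and the configuration used.
#' @examples
#' syn <- generate_proteome(synthetic_config(seed = 1, n_present = 4,
#'                                           n_absent = 6))
#' rep <- simulate_report(syn)
#' fit <- feedback_infer(rep$psms, syn$proteins)
#' coef(fit)
#' @export
feedback_infer <- function(psms, proteins, config = infer_config(),
                           settings = digestion_settings(),
                           map_by_fasta = FALSE, equate_il = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "infer_config"),
            inherits(settings, "digestion_settings"))
  if (!nrow(psms)) stop("empty PSM table", call. = FALSE)
  validate_psms(psms)
  if (equate_il) {
    psms$peptide <- gsub("I", "L", psms$peptide, fixed = TRUE)
    proteins$sequence <- gsub("I", "L", proteins$sequence, fixed = TRUE)
  }

  if (is.null(settings$mass_min) || is.null(settings$mass_max)) {
    win <- infer_mass_window(psms)
    settings$mass_min <- win[["mass_min"]]
    settings$mass_max <- win[["mass_max"]]
  }

  index <- build_index(psms, proteins, map_by_fasta = map_by_fasta)
  dropped_acc <- setdiff(unique(unlist(psm_proteins(psms))),
                         proteins$accession)
  if (length(dropped_acc))
    warning("report accession(s) absent from the database were ignored: ",
            paste(dropped_acc, collapse = ", "), call. = FALSE)

  intensities <- peptide_intensity(psms)
  all_peps <- intensities$peptide
  initial_x <- vapply(split(psms$probability, psms$peptide), max, numeric(1))
  initial_x <- initial_x[all_peps]
  x <- initial_x

  # theoretical peptide counts, computed once per database protein in play
  universe <- names(index$protein_to_peptides)
  N_theo <- stats::setNames(integer(length(universe)), universe)
  for (k in universe)
    N_theo[k] <- count_theoretical_peptides(
      proteins$sequence[match(k, proteins$accession)], settings)

  eliminated <- character()
  elim_iter <- stats::setNames(integer(0), character(0))
  histories <- list()      # membership per protein, from first appearance
  status <- stats::setNames(rep("unseen", length(universe)), universe)
  q_state <- stats::setNames(numeric(0), character(0))
  last_q <- stats::setNames(numeric(length(universe)), universe)  # last computed
  prev_snapshot <- NULL
  selected_final <- character()
  weights_final <- list()
  snapshots <- list()
  log_rows <- list()
  converged <- FALSE
  n_k_final <- stats::setNames(integer(length(universe)), universe)

  for (iter in seq_len(config$max_iterations)) {
    sel <- select_peptides(x, index, eliminated, config$peptide_threshold)
    active <- putative_proteins(sel, index, eliminated)

    for (k in setdiff(union(names(histories), active), eliminated)) {
      if (is.null(histories[[k]]) && !(k %in% active)) next
      histories[[k]] <- c(histories[[k]],
                          if (k %in% active) "in" else "out")
    }
    status[active] <- "active"
    status[setdiff(names(histories), c(active, eliminated))] <- "dropped"

    # experimental counts and weights over the pre-replenishment selection
    n_k <- vapply(active, function(k) {
      length(intersect(index$protein_to_peptides[[k]], sel))
    }, integer(1))
    W <- assign_weights(sel, active, index, intensities)

    q_new <- stats::setNames(numeric(length(active)), active)
    for (k in active) {
      peps <- intersect(index$protein_to_peptides[[k]], sel)
      wk <- vapply(peps, function(p) W[[p]][[k]], numeric(1))
      q_prev <- if (k %in% names(q_state)) q_state[[k]] else 1
      q_new[k] <- protein_probability(x[peps], wk, q_prev,
                                      n_k[k],
                                      max(N_theo[k], n_k[k], 1L),
                                      config$log_base)
    }

    high_conf <- active[q_new >= config$protein_threshold]
    sel2 <- replenish_peptides(sel, high_conf, all_peps, index)
    W2 <- assign_weights(sel2, active, index, intensities)
    sel2 <- intersect(sel2, names(W2))  # drop peptides with no active parent
    x[sel2] <- recompute_peptide_probabilities(W2[sel2], q_new)

    to_elim <- apply_elimination(histories, config$elimination_cycles)
    if (length(to_elim)) {
      eliminated <- sort(union(eliminated, to_elim))
      elim_iter[to_elim] <- iter
      status[to_elim] <- "eliminated"
      histories[to_elim] <- NULL
      active <- setdiff(active, to_elim)
      q_new <- q_new[active]
      # shared peptides of the eliminated renormalize among survivors;
      # their unique peptides leave the selected set
      W2 <- assign_weights(sel2, active, index, intensities)
      sel2 <- intersect(sel2, names(W2))
      x[sel2] <- recompute_peptide_probabilities(W2[sel2], q_new)
    }

    snap <- list(active = active, q = q_new, selected = sel2)
    snapshots[[iter]] <- snap
    max_dq <- if (!is.null(prev_snapshot) &&
                  identical(prev_snapshot$active, active) && length(active))
      max(abs(q_new - prev_snapshot$q[active])) else NA_real_
    log_rows[[iter]] <- data.frame(
      iteration = iter, n_active = length(active),
      n_selected = length(sel2), max_dq = max_dq,
      n_eliminated = length(to_elim))
    if (verbose)
      message(sprintf(
        "iter %d: %d active proteins, %d selected peptides, max|dq|=%s, %d eliminated",
        iter, length(active), length(sel2),
        if (is.na(max_dq)) "NA" else format(max_dq, digits = 3),
        length(to_elim)))

    conv <- check_convergence(prev_snapshot, snap, config$q_tolerance)
    q_state <- q_new
    last_q[active] <- q_new
    n_k_final[] <- 0L
    n_k_final[active] <- vapply(active, function(k) {
      length(intersect(index$protein_to_peptides[[k]], sel))
    }, integer(1))
    selected_final <- sel2
    weights_final <- W2[sel2]
    prev_snapshot <- snap
    if (conv) { converged <- TRUE; break }
  }
  if (!converged)
    warning("inference stopped at max_iterations (", config$max_iterations,
            ") without converging", call. = FALSE)

  fit <- .finalize_fit(index, status, last_q, n_k_final, N_theo, x,
                       initial_x, selected_final, weights_final, eliminated,
                       snapshots, do.call(rbind, log_rows), converged,
                       config, settings, map_by_fasta)
  fit$elimination_log <- data.frame(accession = names(elim_iter),
                                    iteration = unname(elim_iter),
                                    row.names = NULL,
                                    stringsAsFactors = FALSE)
  fit
}

.finalize_fit <- function(index, status, last_q, n_k, N_theo, x, initial_x,
                          selected, weights, eliminated, snapshots, log,
                          converged, config, settings, map_by_fasta) {
  seen <- names(status)[status != "unseen"]
  prot_tab <- data.frame(
    accession = seen,
    q = unname(last_q[seen]),
    n_peptides = n_k[seen],
    n_theoretical = pmax(N_theo[seen], n_k[seen], 1L),
    status = status[seen],
    peptides = vapply(seen, function(k) {
      paste(intersect(index$protein_to_peptides[[k]], selected),
            collapse = ";")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  all_peps <- names(index$peptide_to_proteins)
  orphan <- attr(index, "orphans")
  pep_status <- ifelse(all_peps %in% selected, "selected",
                       ifelse(all_peps %in% orphan, "orphan", "unselected"))
  live_parents <- lapply(index$peptide_to_proteins[all_peps],
                         setdiff, y = eliminated)
  pep_tab <- data.frame(
    peptide = all_peps,
    probability = ifelse(all_peps %in% selected, x[all_peps],
                         initial_x[all_peps]),
    initial_probability = initial_x[all_peps],
    status = pep_status,
    shared = lengths(live_parents) >= 2L,
    parents = vapply(all_peps, function(p) {
      if (p %in% selected) paste(names(weights[[p]]), collapse = ";")
      else paste(live_parents[[p]], collapse = ";")
    }, character(1)),
    weights = vapply(all_peps, function(p) {
      if (p %in% selected)
        paste(sprintf("%.8g", weights[[p]]), collapse = ";")
      else ""
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(proteins = prot_tab, peptides = pep_tab,
                 weights = weights, eliminated = eliminated,
                 snapshots = snapshots, log = log,
                 converged = converged,
                 n_iterations = nrow(log),
                 config = config, settings = settings,
                 map_by_fasta = map_by_fasta, index = index),
            class = "feedprot_fit")
}
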