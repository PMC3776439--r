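# MS/MS intensity-based apportioning of shared peptides.
#
# A peptide's intensity is the sum of its matched spectra's Sequest
# preliminary (Sp) scores after dataset-wide normalization. A shared peptide
# is assigned to each parent protein in proportion to how close its intensity
# lies to that parent's sibling-peptide average: the parent whose own
# siblings are nearer the shared peptide's intensity receives the larger
# weight. Unique peptides take weight 1.

#' Normalize Sp scores by the dataset maximum
#'
#' @param sp_scores Non-negative numeric vector of Sp scores.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_sp <- function(sp_scores) {
  if (!length(sp_scores)) stop("no Sp scores to normalize", call. = FALSE)
  if (any(is.na(sp_scores) | sp_scores < 0))
    stop("Sp scores must be non-negative", call. = FALSE)
  m <- max(sp_scores)
  if (m <= 0)
    stop("all Sp scores are zero; dataset carries no intensity information",
         call. = FALSE)
  sp_scores / m
}

#' Per-peptide intensity table
#'
#' Sums each distinct peptide's normalized Sp scores over its matched
#' spectra and counts the spectra.
#'
#' @param psms PSM data frame.
#' @return Data frame with `peptide`, `intensity`, `n_spectra`, one row per
#'   distinct peptide, sorted by sequence.
#' @export
peptide_intensity <- function(psms) {
  if (!nrow(psms)) stop("empty PSM table", call. = FALSE)
  sp <- normalize_sp(psms$sp_score)
  f <- factor(psms$peptide, levels = sort(unique(psms$peptide)))
  data.frame(peptide = levels(f),
             intensity = as.numeric(tapply(sp, f, sum)),
             n_spectra = as.integer(table(f)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sibling average intensity
#'
#' Mean intensity of a protein's other currently selected peptides (all
#' selected peptides of that protein except the query peptide, shared ones
#' included). `NA` when the protein has no other selected peptide.
#'
#' @param peptide Query peptide sequence.
#' @param protein Parent accession.
#' @param selected Character vector of currently selected peptide sequences.
#' @param intensities Intensity table from [peptide_intensity()].
#' @param index A `pp_index` from [build_index()].
#' @return Mean sibling intensity, or `NA` if there are no siblings.
#' @export
sibling_intensity <- function(peptide, protein, selected, intensities, index) {
  sibs <- setdiff(intersect(index$protein_to_peptides[[protein]], selected),
                  peptide)
  if (!length(sibs)) return(NA_real_)
  mean(intensities$intensity[match(sibs, intensities$peptide)])
}

#' Shared-peptide weights from sibling-intensity closeness
#'
#' For each parent k the normalized distance d_k = |I_p - I_b(k)| / I_p is
#' computed against that parent's own sibling average I_b(k) (d_k = 1 when
#' the parent has no siblings). The raw weight of parent k is the mean of the
#' d_j of the *other* parents, so a parent whose siblings sit close to the
#' peptide's intensity receives the larger weight; raw weights are then
#' normalized to sum to 1. With two parents this reduces exactly to the
#' pairwise proportions of the closeness model. Degenerate cases (I_p = 0 or
#' all distances zero) fall back to uniform weights.
#'
#' @param intensity The shared peptide's intensity I_p.
#' @param sibling_means Named numeric vector of sibling averages per parent
#'   accession; `NA` marks a parent with no siblings.
#' @return Named numeric weights over the parents, summing to 1.
#' @export
shared_weights <- function(intensity, sibling_means) {
  if (length(sibling_means) < 2L)
    stop("shared_weights requires at least two parents", call. = FALSE)
  k <- length(sibling_means)
  if (intensity <= 0)
    return(stats::setNames(rep(1 / k, k), names(sibling_means)))
  d <- ifelse(is.na(sibling_means), 1,
              abs(intensity - sibling_means) / intensity)
  raw <- vapply(seq_len(k), function(i) mean(d[-i]), numeric(1))
  s <- sum(raw)
  w <- if (s == 0) rep(1 / k, k) else raw / s
  stats::setNames(w, names(sibling_means))
}

#' Assign peptide-to-protein weights over the active proteins
#'
#' Weight 1 for peptides unique among the active parents, sibling-closeness
#' weights otherwise. Recomputed from scratch at each iteration of the
#' feedback loop. Peptides with no active parent are excluded.
#'
#' @param selected Character vector of selected peptide sequences.
#' @param active Character vector of active protein accessions.
#' @param index A `pp_index`.
#' @param intensities Intensity table from [peptide_intensity()].
#' @return Named list (by peptide) of named weight vectors over the
#'   peptide's active parents.
#' @export
assign_weights <- function(selected, active, index, intensities) {
  selected <- sort(selected)
  # per-protein sums over selected peptides make sibling means O(1) each
  sel_int <- intensities$intensity[match(selected, intensities$peptide)]
  names(sel_int) <- selected
  prot_sum <- prot_cnt <- stats::setNames(numeric(length(active)), active)
  for (k in active) {
    peps <- intersect(index$protein_to_peptides[[k]], selected)
    prot_sum[k] <- sum(sel_int[peps])
    prot_cnt[k] <- length(peps)
  }
  out <- vector("list", length(selected))
  names(out) <- selected
  for (p in selected) {
    par <- intersect(index$peptide_to_proteins[[p]], active)
    if (!length(par)) next
    if (length(par) == 1L) {
      out[[p]] <- stats::setNames(1, par)
    } else {
      ip <- sel_int[[p]]
      sib <- vapply(par, function(k) {
        nb <- prot_cnt[k] - 1L  # the peptide itself is selected and of k
        if (nb <= 0L) NA_real_ else (prot_sum[k] - ip) / nb
      }, numeric(1))
      out[[p]] <- shared_weights(ip, sib)
    }
  }
  out[!vapply(out, is.null, logical(1))]
}
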