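# Independent oracles. These deliberately share no code with the package:
# brute-force digestion enumerating every cleavage-site pair, a second copy
# of the standard residue masses, and a straight-line re-implementation of
# the feedback loop written directly from the model definitions.

oracle_residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_mass <- function(pep)
  sum(oracle_residue_mass[strsplit(pep, "")[[1]]]) + 18.010565

# every fragment between two cleavage boundaries with <= missed internal
# sites, by exhaustive enumeration over boundary pairs
oracle_digest <- function(seq, missed = 2L, proline = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sites <- integer(0)
  for (i in seq_len(max(n - 1L, 0L)))
    if (ch[i] %in% c("K", "R") && !(proline && ch[i + 1L] == "P"))
      sites <- c(sites, i)
  bounds <- c(0L, sites, n)
  out <- character(0)
  for (a in seq_along(bounds)) for (b in seq_along(bounds))
    if (b > a && (b - a - 1L) <= missed)
      out <- c(out, substr(seq, bounds[a] + 1L, bounds[b]))
  unique(out)
}

oracle_count_theoretical <- function(seq, missed, mmin, mmax,
                                     proline = TRUE) {
  peps <- oracle_digest(seq, missed, proline)
  sum(vapply(peps, oracle_mass, numeric(1)) >= mmin &
        vapply(peps, oracle_mass, numeric(1)) <= mmax)
}

# Straight-line re-implementation of the feedback loop on raw inputs.
# Returns final active set, q, selected set, eliminated set, iterations.
oracle_infer <- function(psms, proteins, pep_thr = 0.95, prot_thr = 0.95,
                         tol = 1e-6, max_iter = 100L, cycles = 1L,
                         map_by_fasta = FALSE) {
  acc <- proteins$accession
  # peptide -> parents
  peps <- sort(unique(psms$peptide))
  parents <- list()
  for (p in peps) {
    from_report <- character(0)
    for (i in which(psms$peptide == p))
      from_report <- c(from_report,
                       strsplit(psms$proteins[i], ";")[[1]])
    from_report <- intersect(unique(from_report), acc)
    if (map_by_fasta)
      for (k in seq_along(acc))
        if (grepl(p, proteins$sequence[k], fixed = TRUE))
          from_report <- union(from_report, acc[k])
    parents[[p]] <- sort(from_report)
  }
  children <- lapply(acc, function(k)
    sort(peps[vapply(peps, function(p) k %in% parents[[p]], logical(1))]))
  names(children) <- acc

  nsp <- psms$sp_score / max(psms$sp_score)
  intensity <- vapply(peps, function(p) sum(nsp[psms$peptide == p]),
                      numeric(1))
  x <- vapply(peps, function(p) max(psms$probability[psms$peptide == p]),
              numeric(1))
  mmin <- min(psms$peptide_mass); mmax <- max(psms$peptide_mass)
  Nk <- vapply(acc, function(k)
    oracle_count_theoretical(proteins$sequence[acc == k], 2L, mmin, mmax),
    numeric(1))

  weights_for <- function(sel, active) {
    W <- list()
    for (p in sel) {
      par <- intersect(parents[[p]], active)
      if (!length(par)) next
      if (length(par) == 1L) { W[[p]] <- setNames(1, par); next }
      d <- numeric(length(par)); names(d) <- par
      for (k in par) {
        sibs <- setdiff(intersect(children[[k]], sel), p)
        d[k] <- if (!length(sibs)) 1 else
          abs(intensity[p] - mean(intensity[sibs])) / intensity[p]
      }
      raw <- vapply(par, function(k) mean(d[setdiff(par, k)]), numeric(1))
      W[[p]] <- if (sum(raw) == 0 || intensity[p] == 0)
        setNames(rep(1 / length(par), length(par)), par)
      else raw / sum(raw)
    }
    W
  }

  eliminated <- character(0)
  hist <- list()
  q_state <- setNames(numeric(0), character(0))
  prev <- NULL
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    sel <- sort(peps[x[peps] >= pep_thr &
      vapply(peps, function(p)
        length(setdiff(parents[[p]], eliminated)) > 0L, logical(1))])
    active <- sort(setdiff(unique(as.character(
      unlist(parents[sel], use.names = FALSE))), eliminated))
    for (k in setdiff(union(names(hist), active), eliminated)) {
      if (is.null(hist[[k]]) && !(k %in% active)) next
      hist[[k]] <- c(hist[[k]], if (k %in% active) "in" else "out")
    }
    W <- weights_for(sel, active)
    q <- setNames(numeric(length(active)), active)
    for (k in active) {
      mine <- intersect(children[[k]], sel)
      qp <- if (k %in% names(q_state)) q_state[[k]] else 1
      nk <- length(mine)
      NN <- max(Nk[[k]], nk, 1)
      if (nk == 0L) { q[k] <- 0; next }
      br <- 1 - prod(1 - x[mine] *
                       vapply(mine, function(p) W[[p]][[k]], numeric(1)) * qp)
      ex <- -log(nk / NN)
      q[k] <- if (ex == 0) { if (br > 0) 1 else 0 } else
        min(max(br^ex, 0), 1)
    }
    high <- active[q >= prot_thr]
    add <- setdiff(peps, sel)
    add <- add[vapply(add, function(p)
      length(intersect(parents[[p]], high)) > 0L, logical(1))]
    sel2 <- sort(union(sel, add))
    W2 <- weights_for(sel2, active)
    sel2 <- intersect(sel2, names(W2))
    for (p in sel2) x[p] <- sum(W2[[p]] * q[names(W2[[p]])])
    elim <- character(0)
    for (k in names(hist)) {
      h <- hist[[k]]
      if (length(h) >= 3L &&
          sum(h[-1] == "in" & h[-length(h)] == "out") >= cycles)
        elim <- c(elim, k)
    }
    if (length(elim)) {
      eliminated <- sort(union(eliminated, elim))
      hist[elim] <- NULL
      active <- setdiff(active, elim)
      q <- q[active]
      W2 <- weights_for(sel2, active)
      sel2 <- intersect(sel2, names(W2))
      for (p in sel2) x[p] <- sum(W2[[p]] * q[names(W2[[p]])])
    }
    snap <- list(active = active, q = q, selected = sel2)
    if (!is.null(prev) && identical(prev$active, active) &&
        identical(prev$selected, sel2) &&
        (!length(active) ||
           max(abs(q - prev$q[active])) < tol)) {
      converged <- TRUE
      prev <- snap
      break
    }
    q_state <- q
    prev <- snap
  }
  list(active = as.character(prev$active), q = prev$q,
       selected = as.character(prev$selected),
       x = x, eliminated = eliminated, converged = converged,
       iterations = iters)
}

# Tiny random instance (<=5 proteins, <=10 peptides) for the fixed-point
# cross-check.
random_tiny_instance <- function(seed) {
  set.seed(seed)
  n_prot <- sample(2:5, 1)
  blocks <- list()
  residues <- c("A","C","D","E","F","G","H","L","M","N","Q","S","T","V","W","Y")
  for (i in seq_len(n_prot)) {
    nb <- sample(2:4, 1)
    blocks[[i]] <- vapply(seq_len(nb), function(j)
      paste0(paste(sample(residues, sample(5:9, 1), replace = TRUE),
                   collapse = ""), sample(c("K", "R"), 1)), character(1))
  }
  # induce sharing: copy one block across proteins half the time
  if (n_prot >= 2 && runif(1) < 0.6) {
    from <- sample(n_prot, 1); to <- sample(setdiff(seq_len(n_prot), from), 1)
    blocks[[to]] <- append(blocks[[to]], sample(blocks[[from]], 1),
                           after = sample(0:length(blocks[[to]]), 1))
  }
  proteins <- make_proteins(sprintf("T%02d", seq_len(n_prot)),
                            vapply(blocks, paste, character(1), collapse = ""))
  all_peps <- unique(unlist(blocks))
  obs <- sample(all_peps, min(length(all_peps), sample(3:10, 1)))
  rows <- lapply(obs, function(p) {
    par <- proteins$accession[grepl(p, proteins$sequence, fixed = TRUE)]
    n_psm <- sample(1:2, 1)
    data.frame(spectrum_id = paste0("s", p, seq_len(n_psm)),
               peptide = p, sp_score = round(runif(n_psm, 0.5, 10), 3),
               probability = round(runif(n_psm)^0.25, 3),
               proteins = paste(sort(par), collapse = ";"),
               peptide_mass = round(oracle_mass(p), 4),
               stringsAsFactors = FALSE)
  })
  list(proteins = proteins, psms = do.call(rbind, rows))
}
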