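# Truth-based evaluation: true/false positive proteins and peptides, with
# the unique/shared breakdown, and threshold sweeps.

#' Evaluate an inference result against ground truth
#'
#' A protein counts as identified iff it is active with probability at or
#' above `protein_threshold`; it is a true positive iff it is in the truth's
#' present set. A peptide counts as identified iff it is selected with
#' probability at or above `peptide_threshold`; it is a true positive iff
#' labeled true, and unique/shared is determined by its final active-parent
#' count.
#'
#' @param fit A `feedprot_fit`.
#' @param truth Truth list (`present_proteins`, `all_proteins`,
#'   `peptide_labels`) from [simulate_report()] or [read_truth()].
#' @param protein_threshold,peptide_threshold Identification thresholds.
#' @return A list of class `feedprot_eval` with counts `tp_proteins`,
#'   `fp_proteins`, `tp_peptides`, `fp_peptides`, `true_unique`,
#'   `false_unique`, `true_shared`, `false_shared` and the thresholds used.
#' @export
evaluate_inference <- function(fit, truth, protein_threshold = 0.95,
                               peptide_threshold = 0.95) {
  stopifnot(inherits(fit, "feedprot_fit"))
  pr <- fit$proteins
  ident_prot <- pr$accession[pr$status == "active" &
                               pr$q >= protein_threshold]
  missing_acc <- setdiff(ident_prot, truth$all_proteins)
  if (length(missing_acc))
    stop("accession(s) missing from the truth set: ",
         paste(missing_acc, collapse = ", "), call. = FALSE)
  pe <- fit$peptides
  ident <- pe[pe$status == "selected" &
                pe$probability >= peptide_threshold, , drop = FALSE]
  missing_pep <- setdiff(ident$peptide, truth$peptide_labels$peptide)
  if (length(missing_pep))
    stop("peptide(s) missing from the truth labels: ",
         paste(missing_pep, collapse = ", "), call. = FALSE)
  lab <- truth$peptide_labels[
    match(ident$peptide, truth$peptide_labels$peptide), , drop = FALSE]
  n_parents <- lengths(strsplit(ident$parents, ";", fixed = TRUE))
  shared <- n_parents >= 2L
  structure(list(
    tp_proteins = sum(ident_prot %in% truth$present_proteins),
    fp_proteins = sum(!ident_prot %in% truth$present_proteins),
    tp_peptides = sum(lab$true),
    fp_peptides = sum(!lab$true),
    true_unique = sum(lab$true & !shared),
    false_unique = sum(!lab$true & !shared),
    true_shared = sum(lab$true & shared),
    false_shared = sum(!lab$true & shared),
    protein_threshold = protein_threshold,
    peptide_threshold = peptide_threshold),
    class = "feedprot_eval")
}

#' @export
print.feedprot_eval <- function(x, ...) {
  cat("Protein/peptide identification vs ground truth",
      sprintf("(thresholds: protein %.2f, peptide %.2f)\n",
              x$protein_threshold, x$peptide_threshold))
  cat(sprintf("  proteins: %d TP, %d FP\n", x$tp_proteins, x$fp_proteins))
  cat(sprintf("  peptides: %d TP (%d unique, %d shared), %d FP (%d unique, %d shared)\n",
              x$tp_peptides, x$true_unique, x$true_shared,
              x$fp_peptides, x$false_unique, x$false_shared))
  invisible(x)
}

#' Threshold sweep
#'
#' Re-runs the inference for each peptide selection threshold and evaluates
#' the result at each protein identification threshold, one row per
#' threshold pair.
#'
#' @param psms,proteins Inputs as for [feedback_infer()].
#' @param truth Truth list.
#' @param peptide_thresholds,protein_thresholds Threshold grids.
#' @param config Base [infer_config()]; its peptide threshold is overridden
#'   by each grid value.
#' @param ... Further arguments passed to [feedback_infer()].
#' @return Data frame with one row per (peptide_threshold,
#'   protein_threshold) pair and the evaluation counts as columns.
#' @export
sweep_thresholds <- function(psms, proteins, truth,
                             peptide_thresholds = c(0.9, 0.95, 1),
                             protein_thresholds = 0.95,
                             config = infer_config(), ...) {
  if (!length(peptide_thresholds) || !length(protein_thresholds))
    stop("threshold grids must be non-empty", call. = FALSE)
  rows <- list()
  for (pt in peptide_thresholds) {
    cfg <- config
    cfg$peptide_threshold <- pt
    fit <- feedback_infer(psms, proteins, config = cfg, ...)
    for (qt in protein_thresholds) {
      ev <- evaluate_inference(fit, truth, protein_threshold = qt,
                               peptide_threshold = pt)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_threshold = pt, protein_threshold = qt,
        tp_proteins = ev$tp_proteins, fp_proteins = ev$fp_proteins,
        tp_peptides = ev$tp_peptides, fp_peptides = ev$fp_peptides,
        true_unique = ev$true_unique, false_unique = ev$false_unique,
        true_shared = ev$true_shared, false_shared = ev$false_shared)
    }
  }
  do.call(rbind, rows)
}
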