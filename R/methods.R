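# S3 methods for fitted inference objects.

#' @export
print.feedprot_fit <- function(x, ...) {
  act <- x$proteins[x$proteins$status == "active", , drop = FALSE]
  cat("Feedback protein inference fit\n")
  cat(sprintf("  %d iterations (%s)\n", x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  %d active proteins (%d eliminated, %d dropped)\n",
              nrow(act), length(x$eliminated),
              sum(x$proteins$status == "dropped")))
  cat(sprintf("  %d selected peptides of %d in the report\n",
              sum(x$peptides$status == "selected"), nrow(x$peptides)))
  invisible(x)
}

#' @export
summary.feedprot_fit <- function(object, ...) {
  act <- object$proteins[object$proteins$status == "active", , drop = FALSE]
  sel <- object$peptides[object$peptides$status == "selected", , drop = FALSE]
  out <- list(
    n_iterations = object$n_iterations,
    converged = object$converged,
    n_active = nrow(act),
    n_eliminated = length(object$eliminated),
    n_dropped = sum(object$proteins$status == "dropped"),
    n_selected = nrow(sel),
    n_shared_selected = sum(sel$shared),
    q_summary = if (nrow(act)) summary(act$q) else NULL,
    x_summary = if (nrow(sel)) summary(sel$probability) else NULL,
    top_proteins = utils::head(act[order(-act$q, act$accession),
                                   c("accession", "q", "n_peptides",
                                     "n_theoretical")], 10L))
  class(out) <- "summary.feedprot_fit"
  out
}

#' @export
print.summary.feedprot_fit <- function(x, ...) {
  cat(sprintf("Feedback protein inference: %d iterations (%s)\n",
              x$n_iterations, if (x$converged) "converged" else "not converged"))
  cat(sprintf("Proteins: %d active, %d dropped, %d eliminated\n",
              x$n_active, x$n_dropped, x$n_eliminated))
  cat(sprintf("Peptides: %d selected (%d shared)\n",
              x$n_selected, x$n_shared_selected))
  if (!is.null(x$q_summary)) {
    cat("Active protein probabilities:\n")
    print(x$q_summary)
  }
  cat("Top proteins:\n")
  print(x$top_proteins, row.names = FALSE)
  invisible(x)
}

#' Protein probabilities of a fit
#'
#' @param object A `feedprot_fit`.
#' @param all Include dropped and eliminated proteins (default only active).
#' @param ... Ignored.
#' @return Named vector of protein probabilities.
#' @export
coef.feedprot_fit <- function(object, all = FALSE, ...) {
  pr <- object$proteins
  if (!all) pr <- pr[pr$status == "active", , drop = FALSE]
  stats::setNames(pr$q, pr$accession)
}

#' Final peptide probabilities of a fit
#'
#' @param object A `feedprot_fit`.
#' @param ... Ignored.
#' @return Named vector over all report peptides (selected peptides carry
#'   their recomputed probability, others their initial one).
#' @export
fitted.feedprot_fit <- function(object, ...) {
  stats::setNames(object$peptides$probability, object$peptides$peptide)
}

#' Convergence diagnostics plot
#'
#' Plots the active protein and selected peptide counts per iteration and
#' the largest protein-probability change (log scale) against the
#' convergence tolerance.
#'
#' @param x A `feedprot_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.feedprot_fit <- function(x, ...) {
  log <- x$log
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(log$iteration, log$n_active, type = "b", pch = 16,
                 xlab = "iteration", ylab = "count",
                 ylim = range(0, log$n_active, log$n_selected),
                 main = "list sizes", ...)
  graphics::lines(log$iteration, log$n_selected, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("right", legend = c("active proteins", "selected peptides"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  ok <- !is.na(log$max_dq) & log$max_dq > 0
  if (any(ok)) {
    graphics::plot(log$iteration[ok], log$max_dq[ok], type = "b", pch = 16,
                   log = "y", xlab = "iteration", ylab = "max |dq|",
                   main = "probability change")
    graphics::abline(h = x$config$q_tolerance, lty = 3)
  }
  invisible(x)
}
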