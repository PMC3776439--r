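# In-silico tryptic digestion and peptide masses.
#
# The protein model normalizes the experimental peptide count n_k by the
# number of theoretical peptides N_k a protein could have produced: distinct
# fully tryptic fragments with at most `max_missed` internal missed cleavage
# sites whose neutral mass falls inside the mass window observed in the
# identification report.

# Monoisotopic and average residue masses (Da) for the 20 standard residues.
.residue_masses <- list(
  monoisotopic = c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931),
  average = c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
)

.water_mass <- c(monoisotopic = 18.010565, average = 18.01528)

.valid_residues <- names(.residue_masses$monoisotopic)

.check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a single non-empty amino-acid string", call. = FALSE)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), .valid_residues)
  if (length(bad))
    stop("invalid residue(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  ch
}

#' Digestion settings
#'
#' Parameters controlling the theoretical tryptic digest used to compute a
#' protein's theoretical peptide count.
#'
#' @param max_missed_cleavages Maximum number of internal missed cleavage
#'   sites allowed in a fragment (default 2).
#' @param mass_min,mass_max Neutral peptide mass window in Daltons. `NULL`
#'   (the default) means the window is inferred from the identification
#'   report with [infer_mass_window()].
#' @param mass_kind `"monoisotopic"` (default) or `"average"` residue masses.
#' @param proline_rule If `TRUE` (default), K/R followed by proline is not a
#'   cleavage site, matching common search-engine practice.
#' @return A list of class `digestion_settings`.
#' @export
digestion_settings <- function(max_missed_cleavages = 2L,
                               mass_min = NULL, mass_max = NULL,
                               mass_kind = c("monoisotopic", "average"),
                               proline_rule = TRUE) {
  mass_kind <- match.arg(mass_kind)
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  if (is.na(max_missed_cleavages) || max_missed_cleavages < 0L)
    stop("max_missed_cleavages must be a non-negative integer", call. = FALSE)
  if (!is.null(mass_min) && !is.null(mass_max) && !(mass_min < mass_max))
    stop("mass_min must be smaller than mass_max", call. = FALSE)
  structure(list(max_missed_cleavages = max_missed_cleavages,
                 mass_min = mass_min, mass_max = mass_max,
                 mass_kind = mass_kind,
                 proline_rule = isTRUE(proline_rule)),
            class = "digestion_settings")
}

#' Tryptic peptides of a protein sequence
#'
#' Cleaves after K or R (not before P when the proline rule is on) and
#' returns every contiguous fragment spanning at most
#' `settings$max_missed_cleavages` internal cleavage sites, as a set of
#' distinct sequences. No mass filter is applied here.
#'
#' @param sequence Amino-acid string (uppercase, 20 standard residues).
#' @param settings A [digestion_settings()] object.
#' @return Character vector of distinct peptide sequences.
#' @examples
#' tryptic_peptides("AKRPC", digestion_settings())  # "AK" "RPC" "AKRPC"
#' @export
tryptic_peptides <- function(sequence, settings = digestion_settings()) {
  ch <- .check_sequence(sequence)
  n <- length(ch)
  sites <- integer(0)
  if (n > 1L) {
    sites <- which(ch[-n] %in% c("K", "R"))
    if (settings$proline_rule)
      sites <- sites[ch[sites + 1L] != "P"]
  }
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  # consecutive-bound fragments, then join runs of up to max_missed+1 of them
  base_frags <- substring(sequence, bounds[-nb] + 1L, bounds[-1L])
  out <- character(0)
  for (span in seq_len(min(settings$max_missed_cleavages + 1L, nb - 1L))) {
    first <- seq_len(nb - span)
    out <- c(out, substring(sequence, bounds[first] + 1L, bounds[first + span]))
  }
  unique(out)
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, in Daltons.
#'
#' @param sequence Amino-acid string.
#' @param mass_kind `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Daltons.
#' @examples
#' peptide_mass("G")  # 75.032025
#' @export
peptide_mass <- function(sequence, mass_kind = c("monoisotopic", "average")) {
  mass_kind <- match.arg(mass_kind)
  ch <- .check_sequence(sequence, "peptide")
  sum(.residue_masses[[mass_kind]][ch]) + .water_mass[[mass_kind]]
}

#' Theoretical peptide count of a protein
#'
#' Number of distinct tryptic peptides (per [tryptic_peptides()]) whose
#' neutral mass lies inside the settings' mass window. This is the N_k that
#' normalizes protein length in the inference model.
#'
#' @inheritParams tryptic_peptides
#' @return Integer count.
#' @export
count_theoretical_peptides <- function(sequence,
                                       settings = digestion_settings()) {
  if (is.null(settings$mass_min) || is.null(settings$mass_max))
    stop("settings must carry an explicit mass window; ",
         "use infer_mass_window() on the report first", call. = FALSE)
  peps <- tryptic_peptides(sequence, settings)
  m <- vapply(peps, peptide_mass, numeric(1), mass_kind = settings$mass_kind)
  sum(m >= settings$mass_min & m <= settings$mass_max)
}

#' Mass window observed in a PSM report
#'
#' The minimum and maximum reported neutral peptide mass; used as the
#' theoretical-digest mass window when none is configured.
#'
#' @param psms A PSM data frame from [read_psm_table()].
#' @return Numeric `c(mass_min, mass_max)`.
#' @export
infer_mass_window <- function(psms) {
  m <- psms$peptide_mass
  m <- m[!is.na(m)]
  if (!length(m))
    stop("no peptide masses in the report; configure the mass window ",
         "explicitly via digestion_settings(mass_min=, mass_max=)",
         call. = FALSE)
  c(mass_min = min(m), mass_max = max(m))
}
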