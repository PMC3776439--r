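# Readers and writers for the peptide identification report dialects, the
# protein database, and the bipartite peptide-protein index.

.psm_columns <- c("spectrum_id", "peptide", "sp_score", "probability",
                  "proteins", "peptide_mass")

#' Read a tab-separated PSM report
#'
#' The canonical input dialect: a header row with columns `spectrum_id`,
#' `peptide`, `sp_score`, `probability`, `proteins` (";"-separated accessions)
#' and `peptide_mass` (calculated neutral mass, Da). One row per
#' peptide-spectrum match; row order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A data frame with the columns above (`proteins` kept as the
#'   ";"-joined string; split with [psm_proteins()]).
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  psms <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.psm_columns, names(psms))
  if (length(missing_cols))
    stop("PSM report is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  psms <- psms[.psm_columns]
  psms$sp_score <- as.numeric(psms$sp_score)
  psms$probability <- as.numeric(psms$probability)
  psms$peptide_mass <- as.numeric(psms$peptide_mass)
  psms$peptide <- toupper(psms$peptide)
  validate_psms(psms, line_offset = 1L)
  psms
}

#' @keywords internal
validate_psms <- function(psms, line_offset = 0L) {
  line <- seq_len(nrow(psms)) + line_offset
  bad <- function(ok, what) {
    if (any(!ok))
      stop("invalid PSM row(s): ", what, " at line(s) ",
           paste(line[!ok], collapse = ", "), call. = FALSE)
  }
  bad(!is.na(psms$probability) & psms$probability >= 0 &
        psms$probability <= 1, "probability outside [0,1]")
  bad(!is.na(psms$sp_score) & psms$sp_score >= 0, "negative or missing sp_score")
  bad(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", psms$peptide),
      "peptide with invalid residues")
  bad(nzchar(psms$proteins), "empty protein assignment")
  bad(is.na(psms$peptide_mass) | psms$peptide_mass > 0,
      "non-positive peptide_mass")
  invisible(psms)
}

#' Split the protein assignments of a PSM table
#'
#' @param psms PSM data frame.
#' @return List (one element per row) of accession character vectors.
#' @export
psm_proteins <- function(psms) {
  strsplit(psms$proteins, ";", fixed = TRUE)
}

#' Read a pepXML subset
#'
#' Best-effort reader for PeptideProphet-processed pepXML: walks
#' `spectrum_query` / `search_hit` elements, takes the rank-1 hit, merges
#' `alternative_protein` entries into the assignment list, reads the Sequest
#' preliminary score from a `search_score` named `sp`/`spscore`, and the
#' PeptideProphet probability from `peptideprophet_result`. Hits without a
#' probability are skipped with a warning and counted in the `n_skipped`
#' attribute.
#'
#' @param path Path to the pepXML file.
#' @return A PSM data frame with the same columns as [read_psm_table()].
#' @export
read_pepxml_subset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  rows <- list()
  n_skipped <- 0L
  for (q in queries) {
    hit <- xml2::xml_find_first(q, ".//search_hit")
    if (inherits(hit, "xml_missing")) next
    prob_node <- xml2::xml_find_first(hit, ".//peptideprophet_result")
    if (inherits(prob_node, "xml_missing")) {
      n_skipped <- n_skipped + 1L
      next
    }
    scores <- xml2::xml_find_all(hit, ".//search_score")
    score_names <- tolower(xml2::xml_attr(scores, "name"))
    sp_i <- match(TRUE, score_names %in% c("sp", "spscore", "sprank_sp"))
    sp <- if (is.na(sp_i)) NA_real_ else
      as.numeric(xml2::xml_attr(scores[[sp_i]], "value"))
    alts <- xml2::xml_attr(xml2::xml_find_all(hit, ".//alternative_protein"),
                           "protein")
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = xml2::xml_attr(q, "spectrum"),
      peptide = toupper(xml2::xml_attr(hit, "peptide")),
      sp_score = sp,
      probability = as.numeric(xml2::xml_attr(prob_node, "probability")),
      proteins = paste(unique(c(xml2::xml_attr(hit, "protein"), alts)),
                       collapse = ";"),
      peptide_mass = as.numeric(xml2::xml_attr(hit, "calc_neutral_pep_mass")),
      stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " search hit(s) without a PeptideProphet probability ",
            "were skipped", call. = FALSE)
  psms <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(), peptide = character(),
               sp_score = numeric(), probability = numeric(),
               proteins = character(), peptide_mass = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(psms)) validate_psms(psms)
  attr(psms, "n_skipped") <- n_skipped
  psms
}

#' Read a protein FASTA database
#'
#' The accession is the first whitespace-delimited token of the defline;
#' the remainder is kept as the description. Sequences are uppercased and
#' trailing "*" stop characters stripped.
#'
#' @param path Path to the FASTA file.
#' @return Data frame with columns `accession`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  deflines <- names(aa)
  accession <- sub("\\s.*$", "", deflines)
  description <- ifelse(grepl("\\s", deflines),
                        sub("^\\S+\\s+", "", deflines), "")
  sequence <- toupper(gsub("\\*+$", "", as.character(aa)))
  dup <- accession[duplicated(accession)]
  if (length(dup))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!nzchar(sequence)))
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  data.frame(accession = accession, sequence = sequence,
             description = description, stringsAsFactors = FALSE)
}

#' Build the peptide-protein index
#'
#' Two transposed maps over the bipartite peptide-protein graph. With
#' `map_by_fasta = TRUE` a peptide additionally maps to every database
#' protein containing it as a substring (union with the report assignments);
#' otherwise only the search engine's assignments are used. Peptides mapping
#' to no database protein are retained and flagged as orphans.
#'
#' @param psms PSM data frame.
#' @param proteins Protein data frame from [read_fasta()].
#' @param map_by_fasta Use substring matching against the database in
#'   addition to the report's assignments.
#' @return A list of class `pp_index` with `peptide_to_proteins` and
#'   `protein_to_peptides` (named lists of sorted character vectors) and an
#'   `orphans` attribute naming unmapped peptides.
#' @export
build_index <- function(psms, proteins, map_by_fasta = FALSE) {
  peptides <- sort(unique(psms$peptide))
  known <- proteins$accession
  assigned <- psm_proteins(psms)
  p2p <- lapply(peptides, function(p) {
    acc <- unique(unlist(assigned[psms$peptide == p], use.names = FALSE))
    acc <- intersect(acc, known)
    if (map_by_fasta)
      acc <- union(acc, known[grepl(p, proteins$sequence, fixed = TRUE)])
    sort(acc)
  })
  names(p2p) <- peptides
  orphans <- peptides[lengths(p2p) == 0L]
  if (length(orphans))
    message(length(orphans),
            " peptide(s) map to no database protein (kept as orphans)")
  pairs_pep <- rep(peptides, lengths(p2p))
  pairs_acc <- unlist(p2p, use.names = FALSE)
  t2p <- split(pairs_pep, factor(pairs_acc, levels = sort(unique(pairs_acc))))
  t2p <- lapply(t2p, function(x) sort(unique(x)))
  structure(list(peptide_to_proteins = p2p,
                 protein_to_peptides = t2p),
            orphans = orphans, class = "pp_index")
}

#' Write the final protein and peptide reports
#'
#' Writes `proteins.tsv` (accession, probability, experimental and
#' theoretical peptide counts, lifecycle status, constituent peptides) and
#' `peptides.tsv` (sequence, probability, initial probability, status, shared
#' flag, parents with weights). Probabilities are printed with 8 significant
#' digits; rows are ordered by descending probability with an
#' accession/sequence tiebreak so identical runs are byte-identical.
#'
#' @param fit A `feedprot_fit` object from [feedback_infer()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(fit, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fmt <- function(x) sprintf("%.8g", x)

  pr <- fit$proteins
  pr <- pr[order(-pr$q, pr$accession), , drop = FALSE]
  pr_out <- data.frame(accession = pr$accession, q = fmt(pr$q),
                       n_peptides = pr$n_peptides,
                       n_theoretical = pr$n_theoretical,
                       status = pr$status, peptides = pr$peptides,
                       stringsAsFactors = FALSE)
  pe <- fit$peptides
  pe <- pe[order(-pe$probability, pe$peptide), , drop = FALSE]
  pe_out <- data.frame(peptide = pe$peptide,
                       probability = fmt(pe$probability),
                       initial_probability = fmt(pe$initial_probability),
                       status = pe$status,
                       shared = pe$shared,
                       parents = pe$parents,
                       weights = pe$weights,
                       stringsAsFactors = FALSE)
  paths <- file.path(out_dir, c("proteins.tsv", "peptides.tsv"))
  utils::write.table(pr_out, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pe_out, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write a PSM table in the canonical TSV dialect
#'
#' Inverse of [read_psm_table()]; used by the synthetic generator and for
#' round-trip checks.
#'
#' @param psms PSM data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms[.psm_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a protein data frame as FASTA
#'
#' @param proteins Data frame with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  desc <- proteins$description
  names(aa) <- if (!is.null(desc) && any(nzchar(desc)))
    trimws(paste(proteins$accession, desc)) else proteins$accession
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
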