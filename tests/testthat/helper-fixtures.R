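# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from stored binary data.

# A minimal PSM data frame in the canonical column layout.
make_psms <- function(peptide, probability, sp_score = NULL, proteins = NULL,
                      peptide_mass = NULL) {
  n <- length(peptide)
  data.frame(
    spectrum_id = sprintf("spec_%03d", seq_len(n)),
    peptide = peptide,
    sp_score = if (is.null(sp_score)) rep(1, n) else sp_score,
    probability = probability,
    proteins = if (is.null(proteins)) rep("P1", n) else proteins,
    peptide_mass = if (is.null(peptide_mass))
      vapply(peptide, feedprot::peptide_mass, numeric(1)) else peptide_mass,
    stringsAsFactors = FALSE)
}

make_proteins <- function(accession, sequence) {
  data.frame(accession = accession, sequence = sequence,
             description = "", stringsAsFactors = FALSE)
}

# Random PSM table for round-trip tests.
random_psm_table <- function(n, seed) {
  set.seed(seed)
  peps <- vapply(seq_len(n), function(i) {
    paste0(paste(sample(LETTERS[LETTERS %in%
      c("A","C","D","E","F","G","H","I","L","M","N","P","Q","S","T","V","W","Y")],
      sample(5:12, 1), replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1))
  }, character(1))
  make_psms(
    peptide = peps,
    probability = round(runif(n), 4),
    sp_score = round(runif(n, 0.1, 500), 3),
    proteins = vapply(seq_len(n), function(i)
      paste(sample(sprintf("P%02d", 1:8), sample(1:3, 1)), collapse = ";"),
      character(1)),
    peptide_mass = round(runif(n, 500, 3000), 4))
}

random_fasta <- function(n, seed) {
  set.seed(seed)
  make_proteins(
    accession = sprintf("RND%04d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                     "Q","R","S","T","V","W","Y"), sample(30:120, 1),
                   replace = TRUE), collapse = ""), character(1)))
}

# The constructed elimination scenario: present protein A with four strong
# unique peptides and one peptide shared with absent protein B, whose own
# unique peptides are weak. B oscillates in and out of the putative list
# through the shared peptide and must be permanently eliminated.
elimination_fixture <- function() {
  U <- c("GASVTCLDEK", "MNQEFHWYLK", "DDEEFFGGHR", "SSTTVVWWYK")
  S <- "LMNQSTVWYR"
  V <- c("ACDEFGHLMK", "TTSSAAGGVR")
  proteins <- make_proteins(c("A", "B"),
                            c(paste(c(U, S), collapse = ""),
                              paste(c(V[1], S, V[2]), collapse = "")))
  psms <- make_psms(
    peptide = c(U, S, V),
    probability = c(rep(0.99, 4), 0.97, 0.30, 0.30),
    sp_score = c(rep(10, 4), 8, 2, 2),
    proteins = c(rep("A", 4), "A;B", "B", "B"))
  list(proteins = proteins, psms = psms, U = U, S = S, V = V)
}

# Writer for a minimal pepXML fixture (text only, built in code).
write_pepxml_fixture <- function(path, hits) {
  # hits: list of lists with spectrum, peptide, proteins (chr vec), sp,
  # mass, probability (NULL = omit the PeptideProphet element)
  q <- vapply(hits, function(h) {
    alt <- if (length(h$proteins) > 1L)
      paste(sprintf('        <alternative_protein protein="%s"/>',
                    h$proteins[-1]), collapse = "\n") else ""
    prob <- if (!is.null(h$probability)) sprintf(
      paste0('        <analysis_result analysis="peptideprophet">\n',
             '          <peptideprophet_result probability="%s"/>\n',
             '        </analysis_result>'), h$probability) else ""
    paste0(
      sprintf('  <spectrum_query spectrum="%s" start_scan="1" end_scan="1">\n',
              h$spectrum),
      '    <search_result>\n',
      sprintf('      <search_hit hit_rank="1" peptide="%s" protein="%s" calc_neutral_pep_mass="%s">\n',
              h$peptide, h$proteins[1], h$mass),
      if (nzchar(alt)) paste0(alt, "\n") else "",
      sprintf('        <search_score name="spscore" value="%s"/>\n', h$sp),
      if (nzchar(prob)) paste0(prob, "\n") else "",
      '      </search_hit>\n',
      '    </search_result>\n',
      '  </spectrum_query>')
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<msms_pipeline_analysis xmlns="http://regis-web.systemsbiology.net/pepXML">',
    '<msms_run_summary base_name="fixture" search_engine="SEQUEST">',
    q,
    '</msms_run_summary>',
    '</msms_pipeline_analysis>'), path)
  invisible(path)
}
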