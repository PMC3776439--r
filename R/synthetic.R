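# Fully synthetic proteome + identification-report generator with known
# ground truth. It emulates the design of the standard-protein-mix style
# benchmark: a database of present and absent proteins with engineered
# sequence sharing, PSMs whose Sp intensities scale with parent-protein
# abundance (shared peptides summing the contributions of all present
# parents), and initial probabilities drawn from separated high/low
# distributions for true/false identifications.

#' Synthetic study configuration
#'
#' Defaults define the package's reference study conditions: 20 present and
#' 80 absent proteins, 30% of present proteins donating a tryptic block to
#' another protein to induce shared peptides, Beta(9,1) vs Beta(1,9) initial
#' probabilities for true vs false identifications (medians about 0.93 and
#' 0.07), log-uniform protein abundance over 1-100, log-normal multiplicative
#' Sp noise with sd 0.3, and a 5% chance for each absent-protein tryptic
#' peptide to appear as a false identification.
#'
#' @param seed Integer RNG seed; fixes every downstream draw.
#' @param n_present,n_absent Numbers of present/absent database proteins.
#' @param protein_length_range Target protein length range (residues).
#' @param shared_block_fraction Fraction of present proteins that donate one
#'   tryptic block to another randomly chosen protein.
#' @param psm_per_true_peptide_range Range of PSM counts per observed peptide.
#' @param true_prob_params,false_prob_params Beta shape pairs for initial
#'   probabilities of true/false identifications.
#' @param abundance_range Protein abundance range (log-uniform draw).
#' @param noise_sd Log-normal sd of the multiplicative Sp noise.
#' @param false_psm_rate Probability that an absent protein's tryptic
#'   peptide is emitted as a false identification.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L,
                             n_present = 20L, n_absent = 80L,
                             protein_length_range = c(150L, 300L),
                             shared_block_fraction = 0.3,
                             psm_per_true_peptide_range = c(1L, 5L),
                             true_prob_params = c(9, 1),
                             false_prob_params = c(1, 9),
                             abundance_range = c(1, 100),
                             noise_sd = 0.3,
                             false_psm_rate = 0.05) {
  stopifnot(n_present >= 1, n_absent >= 0,
            protein_length_range[1] <= protein_length_range[2],
            shared_block_fraction >= 0, shared_block_fraction <= 1,
            psm_per_true_peptide_range[1] >= 1,
            psm_per_true_peptide_range[1] <= psm_per_true_peptide_range[2],
            all(true_prob_params > 0), all(false_prob_params > 0),
            abundance_range[1] > 0, abundance_range[1] <= abundance_range[2],
            noise_sd >= 0, false_psm_rate >= 0, false_psm_rate <= 1)
  structure(list(seed = as.integer(seed), n_present = as.integer(n_present),
                 n_absent = as.integer(n_absent),
                 protein_length_range = as.integer(protein_length_range),
                 shared_block_fraction = shared_block_fraction,
                 psm_per_true_peptide_range =
                   as.integer(psm_per_true_peptide_range),
                 true_prob_params = true_prob_params,
                 false_prob_params = false_prob_params,
                 abundance_range = abundance_range,
                 noise_sd = noise_sd,
                 false_psm_rate = false_psm_rate),
            class = "synthetic_config")
}

# one fully tryptic block: interior residues avoid K/R/P (P also avoided at
# the start so the preceding block's K/R remains a cleavage site), with a
# K or R terminus
.random_block <- function(min_len = 6L, max_len = 14L) {
  interior <- setdiff(c("G", "A", "S", "V", "T", "C", "L", "I", "N", "D",
                        "Q", "E", "M", "H", "F", "Y", "W"), character(0))
  len <- sample(min_len:max_len, 1L)
  paste0(paste(sample(interior, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a synthetic proteome with engineered peptide sharing
#'
#' Proteins are concatenations of fully tryptic blocks (each ending in K/R,
#' never followed by P), so every block is a zero-missed-cleavage tryptic
#' peptide of usable mass. For `shared_block_fraction` of the present
#' proteins, one block is copied into another randomly chosen protein
#' (present or absent), creating shared peptides; copies land at block
#' boundaries so the shared peptide stays fully tryptic in both parents.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_proteome`: `proteins` (data frame for
#'   [write_fasta()]), `present` (accession set), `blocks` (named list of
#'   per-protein tryptic blocks) and the `config`.
#' @export
generate_proteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_present + config$n_absent
  accession <- c(sprintf("PRES%03d", seq_len(config$n_present)),
                 sprintf("ABS%03d", seq_len(config$n_absent)))
  blocks <- vector("list", n)
  names(blocks) <- accession
  for (i in seq_len(n)) {
    target <- sample(config$protein_length_range[1]:
                       config$protein_length_range[2], 1L)
    b <- character(0)
    while (sum(nchar(b)) < target) b <- c(b, .random_block())
    blocks[[i]] <- b
  }
  n_donors <- round(config$shared_block_fraction * config$n_present)
  if (n_donors > 0 && n >= 2) {
    donors <- sample(accession[seq_len(config$n_present)], n_donors)
    for (d in donors) {
      blk <- sample(blocks[[d]], 1L)
      recipient <- sample(setdiff(accession, d), 1L)
      at <- sample(0:length(blocks[[recipient]]), 1L)
      blocks[[recipient]] <- append(blocks[[recipient]], blk, after = at)
    }
  }
  proteins <- data.frame(
    accession = accession,
    sequence = vapply(blocks, paste, character(1), collapse = ""),
    description = ifelse(accession %in% accession[seq_len(config$n_present)],
                         "synthetic present protein",
                         "synthetic absent protein"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(proteins = proteins,
                 present = accession[seq_len(config$n_present)],
                 blocks = blocks, config = config),
            class = "synthetic_proteome")
}

#' Simulate a PSM identification report from a synthetic proteome
#'
#' Each present protein draws a log-uniform abundance; each of its tryptic
#' block peptides is observed with 1 to k PSMs whose Sp scores are
#' proportional to the summed abundance of all present parents (shared
#' peptides accumulate every parent's contribution) times log-normal noise.
#' Initial probabilities come from the high Beta distribution for true
#' peptides and the low one for false peptides, which are drawn from absent
#' proteins' tryptic sets at `false_psm_rate`. Assigned proteins are all
#' database proteins containing the peptide.
#'
#' @param proteome A `synthetic_proteome` from [generate_proteome()].
#' @return A list of class `synthetic_report`: `psms` (canonical PSM data
#'   frame) and `truth` (list with `present_proteins`, `all_proteins`, and
#'   `peptide_labels` with true/shared flags).
#' @export
simulate_report <- function(proteome) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  config <- proteome$config
  set.seed(config$seed + 1L)
  prot <- proteome$proteins
  present <- proteome$present

  abundance <- stats::setNames(
    exp(stats::runif(length(present), log(config$abundance_range[1]),
                     log(config$abundance_range[2]))), present)

  parents_of <- function(p) prot$accession[grepl(p, prot$sequence,
                                                 fixed = TRUE)]
  true_peps <- sort(unique(unlist(proteome$blocks[present],
                                  use.names = FALSE)))
  absent <- setdiff(prot$accession, present)
  absent_peps <- setdiff(sort(unique(unlist(proteome$blocks[absent],
                                            use.names = FALSE))), true_peps)
  false_peps <- absent_peps[stats::runif(length(absent_peps)) <
                              config$false_psm_rate]

  rows <- list()
  spec_no <- 0L
  emit <- function(pep, base_sp, prob_params) {
    n_psm <- sample(config$psm_per_true_peptide_range[1]:
                      config$psm_per_true_peptide_range[2], 1L)
    par <- paste(sort(parents_of(pep)), collapse = ";")
    mass <- peptide_mass(pep)
    for (j in seq_len(n_psm)) {
      spec_no <<- spec_no + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        spectrum_id = sprintf("spec_%05d", spec_no),
        peptide = pep,
        sp_score = base_sp * stats::rlnorm(1, 0, config$noise_sd),
        probability = stats::rbeta(1, prob_params[1], prob_params[2]),
        proteins = par,
        peptide_mass = mass,
        stringsAsFactors = FALSE)
    }
  }
  for (pep in true_peps)
    emit(pep, sum(abundance[intersect(parents_of(pep), present)]),
         config$true_prob_params)
  for (pep in false_peps)
    emit(pep, exp(stats::runif(1, log(config$abundance_range[1]),
                               log(config$abundance_range[2]))),
         config$false_prob_params)
  psms <- do.call(rbind, rows)

  all_obs <- c(true_peps, false_peps)
  labels <- data.frame(
    peptide = all_obs,
    true = all_obs %in% true_peps,
    shared = vapply(all_obs, function(p) length(parents_of(p)) >= 2L,
                    logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  labels <- labels[order(labels$peptide), , drop = FALSE]

  structure(list(psms = psms,
                 truth = list(present_proteins = present,
                              all_proteins = prot$accession,
                              peptide_labels = labels),
                 abundance = abundance),
            class = "synthetic_report")
}

#' Write a synthetic fixture to disk
#'
#' Emits `db.fasta`, `psms.tsv`, `truth_proteins.txt` (accession + present
#' flag for every database protein) and `truth_peptides.tsv`; all re-readable
#' with [read_fasta()], [read_psm_table()] and [read_truth()].
#'
#' @param proteome A `synthetic_proteome`.
#' @param report A `synthetic_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
emit_fixture <- function(proteome, report, out_dir) {
  stopifnot(inherits(proteome, "synthetic_proteome"),
            inherits(report, "synthetic_report"))
  if (!length(report$truth$present_proteins))
    stop("empty ground-truth protein set", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("db.fasta", "psms.tsv",
                                "truth_proteins.txt", "truth_peptides.tsv"))
  write_fasta(proteome$proteins, paths[1])
  write_psm_table(report$psms, paths[2])
  utils::write.table(
    data.frame(accession = report$truth$all_proteins,
               present = as.integer(report$truth$all_proteins %in%
                                      report$truth$present_proteins)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$truth$peptide_labels, paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a ground-truth fixture back
#'
#' @param dir Directory holding `truth_proteins.txt` and
#'   `truth_peptides.tsv` as written by [emit_fixture()].
#' @return Truth list as in [simulate_report()].
#' @export
read_truth <- function(dir) {
  pr <- utils::read.delim(file.path(dir, "truth_proteins.txt"),
                          stringsAsFactors = FALSE)
  pe <- utils::read.delim(file.path(dir, "truth_peptides.tsv"),
                          stringsAsFactors = FALSE)
  list(present_proteins = pr$accession[pr$present == 1L],
       all_proteins = pr$accession,
       peptide_labels = pe)
}
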