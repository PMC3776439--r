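# The protein probability model and the feedback loop.

test_that("protein probability obeys its closed-form limits", {
  # certain evidence with n_k = N_k: exponent 0, bracket positive
  expect_equal(protein_probability(1, 1, 1, 1, 1), 1)
  # zero evidence: bracket 0 regardless of counts
  expect_equal(protein_probability(c(0, 0), c(1, 1), 1, 2, 20), 0)
  # bracket 0 with exponent 0 resolves to 0, not 1
  expect_equal(protein_probability(0, 1, 1, 1, 1), 0)
  # no experimental peptides
  expect_equal(protein_probability(numeric(0), numeric(0), 1, 0, 5), 0)
  # hand-derived value
  expect_equal(protein_probability(c(0.9, 0.8), c(1, 1), 1, 2, 20),
               (1 - 0.1 * 0.2)^(-log(2 / 20)), tolerance = 1e-12)
  expect_equal(protein_probability(c(0.9, 0.8), c(1, 1), 1, 2, 20),
               0.9545469, tolerance = 1e-6)
  # a different log base only rescales the exponent
  expect_equal(protein_probability(c(0.9, 0.8), c(1, 1), 1, 2, 20,
                                   log_base = 10),
               (1 - 0.1 * 0.2)^(-log10(0.1)), tolerance = 1e-12)
  expect_error(protein_probability(c(0.5), c(1, 1), 1, 1, 5), "equal length")
  expect_error(protein_probability(c(0.5, 0.5), c(1, 1), 1, 2, 1), "N_k")
})

test_that("protein probability is monotone in evidence", {
  set.seed(55)
  for (i in 1:300) {
    n <- sample(1:6, 1)
    N <- n + sample(0:20, 1)
    x <- runif(n); w <- runif(n); qp <- runif(1)
    q0 <- protein_probability(x, w, qp, n, N)
    expect_gte(q0, 0); expect_lte(q0, 1)
    # raising any x_i, w_i, or q_prev never decreases q
    j <- sample(n, 1)
    x_up <- x; x_up[j] <- min(1, x[j] + runif(1, 0, 1 - x[j]))
    expect_gte(protein_probability(x_up, w, qp, n, N) + 1e-12, q0)
    w_up <- w; w_up[j] <- min(1, w[j] + runif(1, 0, 1 - w[j]))
    expect_gte(protein_probability(x, w_up, qp, n, N) + 1e-12, q0)
    qp_up <- min(1, qp + runif(1, 0, 1 - qp))
    expect_gte(protein_probability(x, w, qp_up, n, N) + 1e-12, q0)
    # appending a positive-evidence peptide (N fixed) never decreases q
    if (N > n) {
      q1 <- protein_probability(c(x, runif(1, 0.05, 1)),
                                c(w, runif(1, 0.05, 1)), qp, n + 1L, N)
      expect_gte(q1 + 1e-12, q0)
    }
  }
})

test_that("selection, putative search and replenishment follow their rules", {
  db <- make_proteins(c("P1", "P2"), c("AAAKCCCKSSSHHK", "DDDKSSSHHK"))
  psms <- make_psms(c("AAAK", "CCCK", "SSSHHK", "DDDK"),
                    c(0.99, 0.95, 0.90, 0.2),
                    proteins = c("P1", "P1", "P1;P2", "P2"))
  idx <- build_index(psms, db)
  x <- c(AAAK = 0.99, CCCK = 0.95, SSSHHK = 0.90, DDDK = 0.2)
  expect_equal(select_peptides(x, idx, character(), 0.95),
               c("AAAK", "CCCK"))
  # threshold 1 admits only probability-1 peptides
  expect_equal(select_peptides(c(x, EEEK = 1), idx, character(), 1), character(0))
  expect_equal(select_peptides(x, idx, character(), 0.90),
               c("AAAK", "CCCK", "SSSHHK"))
  # all parents eliminated: never selected regardless of x
  expect_equal(select_peptides(x, idx, c("P1", "P2"), 0.5), character(0))

  expect_equal(putative_proteins(c("AAAK", "SSSHHK"), idx), c("P1", "P2"))
  expect_equal(putative_proteins(c("AAAK", "SSSHHK"), idx, "P2"), "P1")

  # replenishment pulls unselected peptides of high-confidence proteins
  expect_equal(replenish_peptides(c("AAAK", "CCCK"), "P2", names(x), idx),
               sort(c("AAAK", "CCCK", "SSSHHK", "DDDK")))
  expect_equal(replenish_peptides(c("AAAK", "CCCK"), character(), names(x),
                                  idx),
               c("AAAK", "CCCK"))
  # a low-x peptide of a low-confidence protein is not added
  expect_equal(replenish_peptides("AAAK", "P1", names(x), idx),
               sort(c("AAAK", "CCCK", "SSSHHK")))
})

test_that("peptide probabilities recombine weights and protein probabilities", {
  q <- c(P1 = 1.0, P2 = 0.5, P3 = 0.97)
  W <- list(unique_pep = c(P3 = 1),
            shared_pep = c(P1 = 0.3, P2 = 0.7),
            sums_pep = c(P1 = 0.4, P3 = 0.6))
  x <- recompute_peptide_probabilities(W, q)
  expect_equal(unname(x["unique_pep"]), 0.97)
  expect_equal(unname(x["shared_pep"]), 0.3 + 0.35)
  expect_true(all(x >= 0 & x <= 1))
  # all parents at probability 1: x equals the weight sum, i.e. 1
  expect_equal(unname(recompute_peptide_probabilities(
    list(p = c(P1 = 0.25, P2 = 0.75)), c(P1 = 1, P2 = 1))["p"]), 1)
})

test_that("the elimination rule fires on in-out-in membership patterns", {
  expect_equal(apply_elimination(list(B = c("in", "out", "in")), 1L), "B")
  expect_equal(apply_elimination(list(B = c("in", "in", "in")), 1L),
               character(0))
  expect_equal(apply_elimination(list(B = c("in", "out", "out")), 1L),
               character(0))
  # two completed cycles required
  expect_equal(apply_elimination(list(B = c("in", "out", "in")), 2L),
               character(0))
  expect_equal(apply_elimination(
    list(B = c("in", "out", "in", "out", "in")), 2L), "B")
})

test_that("convergence requires identical lists and stable probabilities", {
  a <- list(active = c("P1", "P2"), q = c(P1 = 0.99, P2 = 0.5),
            selected = c("x", "y"))
  expect_true(check_convergence(a, a, 1e-6))
  b <- a; b$q["P1"] <- 0.99 + 1e-3
  expect_false(check_convergence(a, b, 1e-6))
  expect_true(check_convergence(a, b, 1e-2))
  c2 <- a; c2$active <- "P1"; c2$q <- a$q["P1"]
  expect_false(check_convergence(a, c2, 1))
  d <- a; d$selected <- "x"
  expect_false(check_convergence(a, d, 1))
  expect_false(check_convergence(NULL, a, 1))
})

test_that("a single protein with strong unique peptides reaches the fixed point", {
  db <- make_proteins("P1", "AAAGGGCCKSSSTTTHHK")
  psms <- make_psms(c("AAAGGGCCK", "SSSTTTHHK"), c(0.99, 0.98),
                    proteins = c("P1", "P1"))
  fit <- feedback_infer(psms, db)
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2L)
  expect_equal(unname(coef(fit)["P1"]), 1)
  sel <- fit$peptides[fit$peptides$status == "selected", ]
  expect_equal(sel$probability, c(1, 1))
  # mass window from the report keeps only the two observed peptides: n = N
  expect_equal(fit$proteins$n_peptides, 2L)
  expect_equal(fit$proteins$n_theoretical, 2L)
})

test_that("no peptide above threshold yields an immediate empty fixed point", {
  db <- make_proteins("P1", "AAAGGGCCKSSSTTTHHK")
  psms <- make_psms(c("AAAGGGCCK", "SSSTTTHHK"), c(0.5, 0.4),
                    proteins = c("P1", "P1"))
  fit <- feedback_infer(psms, db)
  expect_true(fit$converged)
  expect_equal(sum(fit$proteins$status == "active"), 0L)
  expect_equal(sum(fit$peptides$status == "selected"), 0L)
  expect_equal(fit$peptides$probability, fit$peptides$initial_probability)
})

test_that("an oscillating absent protein is permanently eliminated", {
  fx <- elimination_fixture()
  fit <- feedback_infer(fx$psms, fx$proteins)
  expect_true(fit$converged)
  expect_equal(fit$eliminated, "B")
  expect_equal(fit$proteins$status[fit$proteins$accession == "B"],
               "eliminated")
  # the survivor holds the shared peptide with weight 1
  expect_equal(fit$weights[[fx$S]], c(A = 1))
  pe <- fit$peptides
  expect_true(pe$status[pe$peptide == fx$S] == "selected")
  expect_false(pe$shared[pe$peptide == fx$S])
  # B's weak unique peptides never enter
  expect_true(all(pe$status[pe$peptide %in% fx$V] == "unselected"))
  expect_equal(unname(coef(fit)["A"]), 1)
  # eliminated proteins never reappear in later snapshots
  elim_iter <- fit$elimination_log$iteration[
    fit$elimination_log$accession == "B"]
  for (s in fit$snapshots[seq(elim_iter, length(fit$snapshots))])
    expect_false("B" %in% s$active)
})

test_that("runs are deterministic and reproducible end-to-end", {
  syn <- generate_proteome(synthetic_config(seed = 8, n_present = 5,
                                            n_absent = 10))
  rep <- simulate_report(syn)
  f1 <- feedback_infer(rep$psms, syn$proteins)
  f2 <- feedback_infer(rep$psms, syn$proteins)
  expect_identical(f1$proteins, f2$proteins)
  expect_identical(f1$peptides, f2$peptides)
  expect_identical(f1$log, f2$log)
})

test_that("final states match the straight-line oracle on tiny instances", {
  for (seed in 1:40) {
    inst <- random_tiny_instance(seed)
    fit <- feedback_infer(inst$psms, inst$proteins)
    orc <- oracle_infer(inst$psms, inst$proteins)
    expect_equal(sort(fit$proteins$accession[fit$proteins$status == "active"]),
                 orc$active, info = paste("seed", seed))
    expect_equal(sort(fit$peptides$peptide[fit$peptides$status == "selected"]),
                 orc$selected, info = paste("seed", seed))
    act <- fit$proteins$accession[fit$proteins$status == "active"]
    expect_equal(coef(fit)[orc$active], orc$q[orc$active],
                 tolerance = 1e-10, info = paste("seed", seed))
    expect_equal(sort(fit$eliminated), orc$eliminated,
                 info = paste("seed", seed))
  }
})

test_that("probabilities stay in the unit interval at every iteration", {
  syn <- generate_proteome(synthetic_config(seed = 17, n_present = 6,
                                            n_absent = 12,
                                            shared_block_fraction = 0.5))
  rep <- simulate_report(syn)
  fit <- feedback_infer(rep$psms, syn$proteins)
  for (s in fit$snapshots) {
    expect_true(all(s$q >= 0 & s$q <= 1))
    expect_equal(sort(names(s$q)), s$active)
  }
  expect_true(all(fit$peptides$probability >= 0 &
                    fit$peptides$probability <= 1))
})

test_that("I/L equivalence collapses isobaric peptides when requested", {
  db <- make_proteins("P1", "AAIIGGKSSTTVVKDDDEEFK")
  psms <- make_psms(c("AALLGGK", "SSTTVVK", "DDDEEFK"), rep(0.99, 3),
                    proteins = c("X1", "P1", "P1"))
  # without equivalence the L-form peptide cannot be located in the database
  fit_plain <- suppressWarnings(suppressMessages(
    feedback_infer(psms, db, map_by_fasta = TRUE)))
  expect_equal(sum(fit_plain$peptides$status == "selected"), 2L)
  expect_equal(fit_plain$peptides$status[
    fit_plain$peptides$peptide == "AALLGGK"], "orphan")
  # with equivalence all three peptides map and n_k reaches N_k
  fit_il <- suppressWarnings(
    feedback_infer(psms, db, map_by_fasta = TRUE, equate_il = TRUE))
  expect_equal(sum(fit_il$peptides$status == "selected"), 3L)
  expect_equal(unname(coef(fit_il)["P1"]), 1)
})
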