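test_that("pruning likelihood matches brute-force enumeration", {
  aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAAG", c = "ACGAAA"))
  ltr <- read_foreground_tree(text = tree3_newick())
  pi <- rep(1 / 61, 61)
  pars <- list(kappa = 2.3, omega0 = 0.2, omega2 = 3.5, p0 = 0.6,
               p1 = 0.3, frequencies = "equal")
  seqs <- as.list(alignment_strings(aln))
  for (model in c("alt", "null")) {
    eng <- bs_loglik(aln, ltr, pars, model = model)
    ora <- oracle_bs_loglik(seqs, ltr$phy, "a", 2.3, 0.2, 3.5, 0.6, 0.3,
                            pi, model)
    expect_equal(eng, ora, tolerance = 1e-10)
  }
})

test_that("alt likelihood at omega2 = 1 equals the null (nesting)", {
  aln <- sim_fixture(n_codons = 40, seed = 21)$alignment
  ltr <- read_foreground_tree(text = tree6_newick())
  pars <- list(kappa = 1.8, omega0 = 0.15, omega2 = 1, p0 = 0.7,
               p1 = 0.2, frequencies = "equal")
  expect_identical(bs_loglik(aln, ltr, pars, "alt"),
                   bs_loglik(aln, ltr, pars, "null"))
})

test_that("likelihood is invariant to inserting a gapped codon column", {
  sim <- sim_fixture(n_codons = 30, seed = 22)
  ltr <- sim$tree
  pars <- list(kappa = 2, omega0 = 0.1, omega2 = 3, p0 = 0.6, p1 = 0.3,
               frequencies = "equal")
  base <- bs_loglik(sim$alignment, ltr, pars)
  seqs <- alignment_strings(sim$alignment)
  seqs2 <- paste0(substr(seqs, 1, 30), "---", substring(seqs, 31))
  seqs2["human"] <- paste0(substr(seqs["human"], 1, 30), "AAA",
                           substring(seqs["human"], 31))
  names(seqs2) <- names(seqs)
  expect_equal(bs_loglik(codon_alignment(seqs2), ltr, pars), base,
               tolerance = 1e-12)
})

test_that("LRT statistic and chi-squared tail behave as specified", {
  expect_identical(lrt_pvalue(-100, -100), list(stat = 0, p = 1))
  expect_equal(lrt_pvalue(-100 + 6.635 / 2, -100)$p, 0.0100,
               tolerance = 1e-3)
  expect_equal(lrt_pvalue(-50 + 3.841 / 2, -50)$p, 0.0500,
               tolerance = 1e-3)
  # agreement with an independent normal-CDF route
  for (s in c(0.5, 2, 6.635, 10)) {
    expect_equal(lrt_pvalue(s / 2, 0)$p, oracle_chisq1_tail(s),
                 tolerance = 1e-12)
  }
  expect_warning(lrt_pvalue(-10, -9.9), "beyond tolerance")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 0.0266666666666667, 0.04))
  expect_identical(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("fitting is deterministic given a seed and respects nesting", {
  sim <- sim_fixture(n_codons = 150, seed = 23, omega2 = 4)
  f1 <- branch_site_fit(sim$alignment, sim$tree, n_starts = 2, seed = 5)
  f2 <- branch_site_fit(sim$alignment, sim$tree, n_starts = 2, seed = 5)
  expect_identical(f1$lnL_alt, f2$lnL_alt)
  expect_identical(f1$params_alt, f2$params_alt)
  expect_gte(f1$lnL_alt, f1$lnL_null)
  expect_gte(f1$lrt_stat, 0)
  expect_true(f1$converged)
  # different seed: same optimum within multi-start stability tolerance
  f3 <- branch_site_fit(sim$alignment, sim$tree, n_starts = 2, seed = 99)
  expect_equal(f3$lnL_alt, f1$lnL_alt, tolerance = 1e-4)
})

test_that("BEB posteriors are probabilities mapped to original columns", {
  sim <- sim_fixture(n_codons = 150, seed = 23, omega2 = 4)
  f <- branch_site_fit(sim$alignment, sim$tree, n_starts = 2, seed = 5)
  beb <- beb_posteriors(f)
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
  expect_identical(beb$column, f$column_map)
  bad <- f
  bad$converged <- FALSE
  expect_error(beb_posteriors(bad), "unconverged")
})

test_that("gene screening applies the conjunction rule and maps sites", {
  # toy batch on the 3-taxon tree: one strongly selected gene among nulls
  ltr <- read_foreground_tree(text = "(a#1:0.4,b:0.3,c:0.3);")
  mk <- function(seed, w2) simulate_alignment(simulation_config(
    "(a#1:0.4,b:0.3,c:0.3);", 200, omega2 = w2, p0 = 0.5, p1 = 0.3,
    seed = seed))$alignment
  alns <- list(g1 = mk(1, 8), g2 = mk(2, 1), g3 = mk(3, 1))
  res <- screen_genes(alns, ltr, seed = 11)
  expect_identical(nrow(res$genes), 3L)
  expect_true(all(res$genes$converged))
  expect_identical(res$genes$pass,
                   res$genes$pass_p & res$genes$q_value < 0.05)
  if (nrow(res$sites) > 0) {
    expect_true(all(res$sites$posterior > 0.95))
    expect_true(all(res$sites$gene %in% res$genes$gene[res$genes$pass]))
  }
})
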