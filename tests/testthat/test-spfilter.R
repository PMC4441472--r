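# Small protein alignment builder: each argument is one sequence string
# with '-' gaps; rows named A, B, C...
pmat <- function(...) {
  seqs <- c(...)
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- if (is.null(names(seqs)))
    LETTERS[seq_along(seqs)] else names(seqs)
  m
}

test_that("window extraction counts focal residues, not columns", {
  # focal A has a gap inside the upstream window: it spans extra columns
  m <- pmat(A = "MKVLWAALL-VTFLAGCQAKVEQAVETEPEPELRQQTEW",
            B = "MKVLWAALLQVTFLAGCQAKVEQAVETEPEPELRQQTEW")
  w <- extract_window(m, "A", 20, 15)
  expect_identical(w$n_up, 15L)
  expect_identical(w$n_down, 15L)
  expect_identical(length(w$up), 16L)  # 15 residues + 1 gap column
  expect_identical(length(w$down), 15L)
  expect_identical(w$down, 21:35)

  # site at focal residue 5: n_up = 4 -> S = 15/4
  w2 <- extract_window(m[, 1:12], "B", 5, 15)
  expect_identical(w2$n_up, 4L)
  sc <- score_site(pmat(A = "MKVLWAALLVTF", B = "MKVLWAALLVTF"), "A", 5)
  expect_equal(sc$S_up, 15 / 4)

  # site at residue 1: empty upstream stream
  w3 <- extract_window(m, "B", 1, 15)
  expect_identical(w3$n_up, 0L)
  expect_identical(length(w3$up), 0L)
  expect_error(extract_window(m, "A", 10, 15), "gapped")
})

test_that("pairwise penalties follow the 0 / -S / -2S rule", {
  expect_identical(pairwise_penalty(rep("A", 15), rep("A", 15), 1), 0)
  # 3 mismatches + 2 one-sided gaps at S = 1
  a <- c("A", "A", "A", "C", "C", "C", "-", "A", rep("G", 7))
  b <- c("A", "A", "A", "D", "D", "D", "A", "-", rep("G", 7))
  expect_identical(pairwise_penalty(a, b, 1), -7)
  # all one-sided gaps across a full 15-column window
  expect_identical(pairwise_penalty(rep("A", 15), rep("-", 15), 1), -30)
  # gap/gap columns are silent
  expect_identical(pairwise_penalty(c("-", "A"), c("-", "A"), 2), 0)
  expect_error(pairwise_penalty(c("A"), c("A", "A"), 1), "mismatch")
})

test_that("perfectly conserved windows score zero and pass", {
  m <- pmat(A = strrep("MKVLWAALLVT", 3), B = strrep("MKVLWAALLVT", 3),
            C = strrep("MKVLWAALLVT", 3), D = strrep("MKVLWAALLVT", 3))
  sc <- score_site(m, "B", 17)
  expect_identical(sc$general_score, 0)
  expect_identical(sc$individual_score, 0)
  expect_true(sc$pass)
  expect_equal(sc$S_up, 1)
})

test_that("thresholds are strict inequalities", {
  m <- pmat(A = strrep("MKVLWAALLVT", 3), B = strrep("MKVLWAALLVT", 3))
  sc <- score_site(m, "A", 17)
  cfg_eq <- sp_config(general_threshold = sc$general_score,
                      individual_threshold = -15)
  expect_false(score_site(m, "A", 17, cfg_eq)$pass)
  cfg_ind <- sp_config(general_threshold = -50,
                       individual_threshold = sc$individual_score)
  expect_false(score_site(m, "A", 17, cfg_ind)$pass)
})

test_that("score_site equals the naive oracle on random fixtures", {
  set.seed(77)
  aas <- c("A", "C", "D", "E", "F", "G", "-")
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    L <- sample(35:80, 1)
    m <- matrix(sample(aas, n * L, replace = TRUE,
                       prob = c(rep(0.15, 6), 0.1)), n, L,
                dimnames = list(paste0("t", 1:n), NULL))
    focal <- sample(rownames(m), 1)
    ok <- which(m[focal, ] != "-")
    col <- sample(ok, 1)
    sc <- score_site(m, focal, col)
    ora <- oracle_sp_score(m, focal, col)
    expect_equal(sc$general_score, ora$general, tolerance = 1e-9)
    expect_equal(sc$individual_score, ora$individual, tolerance = 1e-9)
  }
})

test_that("adding mismatches or gaps never raises a score", {
  set.seed(42)
  base <- strrep("MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQTE", 2)
  m <- pmat(A = base, B = base, C = base)
  col <- 37
  sc0 <- score_site(m, "A", col)
  for (k in 1:20) {
    m2 <- m
    j <- sample(setdiff(22:52, col), 1)
    m2["B", j] <- if (k %% 2) "-" else "W"
    sc <- score_site(m2, "A", col)
    expect_lte(sc$general_score, sc0$general_score)
    expect_lte(sc$individual_score, sc0$individual_score)
    expect_lte(sc$general_score, 0)
    expect_lte(sc$individual_score, 0)
  }
})

test_that("shuffle corruption strictly lowers the SP score of inside sites", {
  sim <- simulate_alignment(simulation_config(tree_close_newick(), 200,
                                              omega2 = 1, seed = 44))
  spec <- corruption_spec(misalignment_windows = list(
    list(taxon = "human", start = 80, width = 40, mode = "shuffle")),
    seed = 9)
  cor <- corrupt_alignment(sim$alignment, spec)
  p0 <- translate_alignment(sim$alignment)
  p1 <- translate_alignment(cor$alignment)
  col <- 100
  s_before <- score_site(p0, "human", col)
  s_after <- score_site(p1, "human", col)
  expect_lt(s_after$general_score, s_before$general_score)
  expect_lt(s_after$individual_score, s_before$individual_score)
})

test_that("filter_sites reports per-species retention and FPR", {
  sim <- simulate_alignment(simulation_config(tree_close_newick(), 150,
                                              omega2 = 1, seed = 45))
  cor <- corrupt_alignment(sim$alignment, corruption_spec(
    misalignment_windows = list(list(taxon = "human", start = 60,
                                     width = 40, mode = "shuffle")),
    seed = 2))
  alns <- list(geneA = cor$alignment)
  sites <- data.frame(gene = "geneA", foreground = "human",
                      column = c(20, 30, 75, 80, 130))
  out <- filter_sites(sites, alns)
  expect_identical(nrow(out$sites), 5L)
  expect_identical(out$summary$species, "human")
  expect_identical(out$summary$total, 5L)
  expect_equal(out$summary$fpr_pct,
               misalignment_fpr(5, out$summary$retained))
  # orphan sites are reported but not summarized
  sites2 <- rbind(sites, data.frame(gene = "missing",
                                    foreground = "human", column = 1))
  out2 <- filter_sites(sites2, alns)
  expect_true(is.na(out2$sites$pass[6]))
  expect_identical(out2$summary$total, 5L)
})

test_that("misalignment FPR arithmetic matches the reporting convention", {
  expect_equal(misalignment_fpr(26, 16), 38.46)
  expect_equal(misalignment_fpr(92, 54), 41.30)
  expect_equal(misalignment_fpr(10, 10), 0)
})
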