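test_that("cDNA mapping recovers exact substring coordinates", {
  sim <- simulate_alignment(simulation_config(tree_close_newick(), 120,
                                              seed = 51))
  cds <- gsub("-", "", alignment_strings(sim$alignment)[["human"]])
  frag <- substr(cds, 61, 180)
  m <- map_cdna(cds, frag)
  expect_identical(m$start, 61L)
  expect_identical(m$end, 180L)
  expect_identical(m$strand, "+")
  expect_true(all(m$aligned$cds_base == m$aligned$cdna_base))

  # reverse-complement fragments map on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag)))
  m2 <- map_cdna(cds, rc)
  expect_identical(m2$strand, "-")
  expect_identical(c(m2$start, m2$end), c(61L, 180L))

  # unrelated sequence is rejected
  set.seed(1)
  junk <- paste0(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                 collapse = "")
  expect_null(map_cdna(cds, junk))
})

test_that("a single internal mismatch is mapped and recorded", {
  sim <- simulate_alignment(simulation_config(tree_close_newick(), 100,
                                              seed = 52))
  cds <- gsub("-", "", alignment_strings(sim$alignment)[["chimp"]])
  frag <- substr(cds, 31, 150)
  at <- 60  # fragment-local position
  ch <- substr(frag, at, at)
  sub <- setdiff(c("A", "C", "G", "T"), ch)[1]
  fragm <- paste0(substr(frag, 1, at - 1), sub, substring(frag, at + 1))
  m <- map_cdna(cds, fragm)
  expect_false(is.null(m))
  mm <- m$aligned[m$aligned$cds_base != m$aligned$cdna_base &
                    m$aligned$cds_base != "-" &
                    m$aligned$cdna_base != "-", ]
  expect_equal(mm$cds_position, 30 + at)
})

test_that("site validation distinguishes valid/invalid/unmapped", {
  sim <- simulate_alignment(simulation_config(tree_close_newick(), 100,
                                              seed = 53))
  cds <- gsub("-", "", alignment_strings(sim$alignment)[["human"]])
  codon <- 20
  nt <- (3 * (codon - 1) + 1):(3 * codon)
  good <- substr(cds, 31, 120)          # covers codon 20 (nt 58-60)
  miss <- substr(cds, 121, 240)         # does not cover
  bad <- good
  off <- nt[2] - 31 + 1
  ch <- substr(bad, off, off)
  substr(bad, off, off) <- setdiff(c("A", "C", "G", "T"), ch)[1]

  v1 <- validate_site(codon, cds, c(f1 = good, f2 = miss))
  expect_identical(v1$verdict, "valid")
  expect_identical(v1$n_covering, 1L)

  v2 <- validate_site(codon, cds, c(f1 = bad, f2 = miss))
  expect_identical(v2$verdict, "invalid")

  v3 <- validate_site(codon, cds, c(f2 = miss))
  expect_identical(v3$verdict, "unmapped")

  # monotonicity: adding cDNAs can only improve the verdict
  v4 <- validate_site(codon, cds, c(f1 = bad, f2 = miss, f3 = good))
  expect_identical(v4$verdict, "valid")
  expect_identical(validate_site(codon, cds, c(f1 = good, f2 = bad))$verdict,
                   "valid")
})

test_that("validation summary reports coverage, FPR and gene roll-up", {
  verdicts <- c(rep("valid", 73), rep("invalid", 120),
                rep("unmapped", 2009 - 193))
  s <- validation_summary(verdicts)
  expect_identical(s$n_total, 2009L)
  expect_identical(s$n_mapped, 193L)
  expect_equal(s$coverage_pct, 9.61)
  expect_equal(s$fpr_pct, round(100 * 120 / 193, 2))

  s0 <- validation_summary(c("valid", "valid", "unmapped"),
                           genes = c("g1", "g1", "g2"))
  expect_identical(s0$n_invalid, 0L)
  expect_equal(s0$fpr_pct, 0)
  expect_identical(s0$genes_surviving, 1L)
  expect_error(validation_summary("maybe"))
})
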