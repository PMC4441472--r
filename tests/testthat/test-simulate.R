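test_that("identical seeds give byte-identical alignments", {
  a <- simulate_alignment(simulation_config(tree6_newick(), 50, seed = 9))
  b <- simulate_alignment(simulation_config(tree6_newick(), 50, seed = 9))
  expect_identical(alignment_strings(a$alignment),
                   alignment_strings(b$alignment))
  expect_identical(a$truth, b$truth)
  c <- simulate_alignment(simulation_config(tree6_newick(), 50, seed = 10))
  expect_false(identical(alignment_strings(a$alignment),
                         alignment_strings(c$alignment)))
})

test_that("zero divergence copies the root draw to every tip", {
  tr <- "((a#1:0,b:0):0,c:0,d:0);"
  sim <- simulate_alignment(simulation_config(tr, 40, seed = 2))
  seqs <- alignment_strings(sim$alignment)
  expect_true(all(seqs == seqs[1]))
})

test_that("site classes follow the Model A proportions", {
  # omega2 = 1, p0 + p1 = 1: classes 0/1 only, binomial sampling check
  cfg <- simulation_config(tree6_newick(), 5000, p0 = 0.6, p1 = 0.4,
                           omega2 = 1, seed = 31)
  sim <- simulate_alignment(cfg)
  tab <- table(sim$truth$class)
  expect_setequal(names(tab), c("0", "1"))
  se <- sqrt(0.6 * 0.4 / 5000)
  expect_lt(abs(tab[["0"]] / 5000 - 0.6), 3 * se)
  # full model: all four classes present at the configured split
  cfg2 <- simulation_config(tree6_newick(), 5000, p0 = 0.5, p1 = 0.3,
                            seed = 8)
  pr <- modelA_proportions(0.5, 0.3)
  tab2 <- table(simulate_alignment(cfg2)$truth$class) / 5000
  for (k in 1:4) {
    se <- sqrt(pr[k] * (1 - pr[k]) / 5000)
    expect_lt(abs(tab2[[k]] - pr[k]), 3.5 * se)
  }
})

test_that("simulated codons match the stationary distribution", {
  # long total tree length; pooled tip codons vs equal frequencies
  tr <- "((a#1:0.5,b:0.5):0.3,(c:0.5,d:0.5):0.3,e:0.6);"
  sim <- simulate_alignment(simulation_config(tr, 10000, seed = 12))
  # one tip only: sites are i.i.d., tips are not (shared ancestry)
  counts <- table(factor(sim$alignment$codons["e", ],
                         levels = sense_codons()))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(counts),
                                            p = rep(1 / 61, 61)))
  expect_gt(gof$p.value, 0.01)
})

test_that("corruption is local, logged, and an empty spec is identity", {
  sim <- sim_fixture(n_codons = 100, seed = 5)
  id <- corrupt_alignment(sim$alignment, corruption_spec())
  expect_identical(id$alignment$codons, sim$alignment$codons)
  expect_identical(nrow(id$truth), 0L)

  spec <- corruption_spec(misalignment_windows = list(
    list(taxon = "mouse", start = 11, width = 8, mode = "gap_burst"),
    list(taxon = "rat", start = 41, width = 10, mode = "shuffle")),
    seed = 4)
  out <- corrupt_alignment(sim$alignment, spec)
  # exactly w gap codons for the named taxon in the window
  expect_identical(unname(out$alignment$codons["mouse", 11:18]),
                   rep("---", 8))
  # untouched columns byte-identical for every taxon
  touched <- out$truth
  for (tx in sim$alignment$taxa) {
    cols <- setdiff(seq_len(100), touched$column[touched$taxon == tx])
    expect_identical(out$alignment$codons[tx, cols],
                     sim$alignment$codons[tx, cols])
  }
  # shuffle permutes the window content (multiset preserved)
  expect_setequal(out$alignment$codons["rat", 41:50],
                  sim$alignment$codons["rat", 41:50])
  # shift rotates the window by one codon
  sh <- corrupt_alignment(sim$alignment, corruption_spec(
    misalignment_windows = list(list(taxon = "dog", start = 30,
                                     width = 6, mode = "shift"))))
  expect_identical(unname(sh$alignment$codons["dog", 30:35]),
                   unname(sim$alignment$codons["dog", c(31:35, 30)]))
  expect_error(corrupt_alignment(sim$alignment, corruption_spec(
    misalignment_windows = list(list(taxon = "rat", start = 98,
                                     width = 10, mode = "shuffle")))),
    "outside")
})

test_that("frameshift corruption reframes downstream codons", {
  sim <- sim_fixture(n_codons = 60, seed = 6)
  spec <- corruption_spec(frameshift = list(taxon = "dog", position = 20,
                                            length = 2), seed = 1)
  out <- corrupt_alignment(sim$alignment, spec)
  expect_identical(out$alignment$codons["dog", 1:19],
                   sim$alignment$codons["dog", 1:19])
  expect_false(identical(out$alignment$codons["dog", 20:60],
                         sim$alignment$codons["dog", 20:60]))
  expect_error(corruption_spec(frameshift = list(taxon = "dog",
                                                 position = 2,
                                                 length = 3)),
               "divisible")
})

test_that("error-free cDNA fragments are exact CDS substrings", {
  sim <- sim_fixture(n_codons = 120, seed = 7)
  cds <- gsub("-", "", alignment_strings(sim$alignment)[["human"]])
  out <- emit_cdnas(sim$alignment, "human", 12, c(15, 40), seed = 3)
  expect_identical(nrow(out$cdnas), 12L)
  expect_identical(nrow(out$errors), 0L)
  for (i in seq_len(12)) {
    a <- 3 * (out$cdnas$start_codon[i] - 1) + 1
    b <- 3 * out$cdnas$end_codon[i]
    expect_identical(out$cdnas$sequence[i], substr(cds, a, b))
  }
  again <- emit_cdnas(sim$alignment, "human", 12, c(15, 40), seed = 3)
  expect_identical(again$cdnas, out$cdnas)
  expect_error(emit_cdnas(sim$alignment, "human", 3, c(10, 500)),
               "exceeds")
})

test_that("cDNA error injection is recorded with codon coordinates", {
  sim <- sim_fixture(n_codons = 100, seed = 8)
  out <- emit_cdnas(sim$alignment, "chimp", 20, c(30, 60),
                    error_rate = 0.02, seed = 5)
  expect_gt(nrow(out$errors), 0)
  cds <- gsub("-", "", alignment_strings(sim$alignment)[["chimp"]])
  for (k in seq_len(nrow(out$errors))) {
    i <- match(out$errors$cdna_id[k], out$cdnas$cdna_id)
    off <- out$errors$cds_position[k] -
      (3 * (out$cdnas$start_codon[i] - 1) + 1) + 1
    expect_false(substr(out$cdnas$sequence[i], off, off) ==
                   substr(cds, out$errors$cds_position[k],
                          out$errors$cds_position[k]))
    expect_identical(out$errors$codon[k],
                     (out$errors$cds_position[k] - 1L) %/% 3L + 1L)
  }
})

test_that("proteome generator honours its truth table", {
  clean <- emit_proteomes(3, 8, paralog_rate = 0, identity_decay = 0,
                          seed = 2)
  expect_identical(nrow(clean$proteins), 24L)
  # zero decay: orthologs are identical across species
  for (g in 1:8) {
    seqs <- clean$proteins$sequence[clean$truth$ancestor_gene == g]
    expect_true(all(seqs == seqs[1]))
  }
  # heavy decay pushes a pair below the 60% identity floor
  far <- emit_proteomes(2, 4, identity_decay = 0.35, seed = 3)
  s1 <- far$proteins$sequence[far$proteins$species == "sp1"][1]
  s2 <- far$proteins$sequence[far$proteins$species == "sp2"][1]
  ident <- mean(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]])
  expect_lt(ident, 0.60)
  # reproducible
  expect_identical(emit_proteomes(2, 4, identity_decay = 0.35, seed = 3),
                   far)
})
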