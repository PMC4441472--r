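recs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(species = r[[1]], gene_id = r[[2]], transcript_id = r[[3]],
               sequence = r[[4]])))
}

test_that("longest transcript is kept with a lexicographic tie rule", {
  r <- recs(list("sp1", "g1", "t_b", strrep("MKLV", 25)),
            list("sp1", "g1", "t_a", strrep("MK", 50)),
            list("sp1", "g1", "t_short", "MKLV"),
            list("sp1", "g2", "only", "MMMM"))
  out <- select_longest_transcript(r)
  expect_identical(nrow(out), 2L)
  # both 100-residue transcripts tie: t_a wins lexicographically
  expect_identical(out$transcript_id[out$gene_id == "g1"], "t_a")
  expect_identical(out$transcript_id[out$gene_id == "g2"], "only")
  expect_identical(nrow(select_longest_transcript(r[0, ])), 0L)
})

test_that("best hit ranks by score with the identity floor", {
  q <- data.frame(species = "sp1", gene_id = "q", transcript_id = "q_t",
                  sequence = "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQTEW")
  tg <- recs(list("sp2", "exact", "t", q$sequence),
             list("sp2", "near", "t",
                  sub("KVEQ", "KVDQ", q$sequence)),
             list("sp2", "far", "t", strrep("PGHR", 10)))
  h <- best_hit(q, tg)
  expect_identical(h$gene_id, "exact")
  expect_equal(h$identity, 100)
  # all targets dissimilar -> no hit
  expect_null(best_hit(q, tg[tg$gene_id == "far", , drop = FALSE]))
  # equal-score duplicate targets break ties lexicographically
  dup <- recs(list("sp2", "zz_copy", "t", q$sequence),
              list("sp2", "aa_copy", "t", q$sequence))
  expect_identical(best_hit(q, dup)$gene_id, "aa_copy")
})

test_that("RBH recovers true pairs and rejects paralog decoys", {
  pp <- emit_proteomes(2, 10, paralog_rate = 0, identity_decay = 0.05,
                       seed = 4)
  ref <- select_longest_transcript(
    pp$proteins[pp$proteins$species == "sp1", ])
  oth <- select_longest_transcript(
    pp$proteins[pp$proteins$species == "sp2", ])
  pairs <- reciprocal_best_hits(ref, oth)
  expect_identical(nrow(pairs), 10L)
  expect_true(all(pairs$identity >= 60))
  expect_identical(sub("sp1", "sp2", pairs$reference_gene),
                   pairs$other_gene)

  # hand-built decoy: b is closer to a2 than to a1
  base <- strrep("MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQTEWQSGQRWELALGRFWDYLRWVQ", 2)
  a2 <- sub("QSGQ", "QAGQ", base)
  b <- sub("QSGQ", "QAGQ", sub("WELA", "WDLA", base))
  reference <- recs(list("r", "a1", "t", base), list("r", "a2", "t", a2))
  other <- recs(list("o", "b", "t", b))
  pairs <- reciprocal_best_hits(reference, other)
  expect_false(any(pairs$reference_gene == "a1"))
  expect_identical(pairs$reference_gene, "a2")

  # empty other proteome
  expect_identical(nrow(reciprocal_best_hits(reference, other[0, ])), 0L)
})

test_that("RBH is symmetric between the two proteomes", {
  pp <- emit_proteomes(2, 8, paralog_rate = 0.5, identity_decay = 0.08,
                       seed = 9)
  A <- select_longest_transcript(
    pp$proteins[pp$proteins$species == "sp1", ])
  B <- select_longest_transcript(
    pp$proteins[pp$proteins$species == "sp2", ])
  ab <- reciprocal_best_hits(A, B)
  ba <- reciprocal_best_hits(B, A)
  expect_setequal(paste(ab$reference_gene, ab$other_gene),
                  paste(ba$other_gene, ba$reference_gene))
})
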