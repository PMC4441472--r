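#!/usr/bin/env Rscript
# Stage 5 — cDNA validation.
#
# Maps each reference-species cDNA fragment onto its gene's CDS and checks
# whether the codon at each SP-surviving site matches at least one
# covering fragment exactly. Outputs under results/cdna/.

suppressMessages(library(posscreen))

data_dir <- "results/data"
out <- "results/cdna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cdnas <- read.delim(file.path(data_dir, "cdnas.tsv"))
files <- list.files(file.path(data_dir, "alignments"), full.names = TRUE)
alns <- setNames(lapply(files, read_codon_fasta),
                 sub("\\.fa$", "", basename(files)))
scored <- read.delim("results/spfilter/sites_scored.tsv")
surv <- scored[scored$pass %in% TRUE, ]
if (nrow(surv) == 0) {
  message("no SP-surviving sites to validate")
  quit(status = 0)
}

rows <- list()
for (k in seq_len(nrow(surv))) {
  fg <- surv$foreground[k]
  g <- surv$gene[k]
  pool <- cdnas[cdnas$taxon == fg & cdnas$gene == g, ]
  aln <- alns[[g]]
  cds <- gsub("-", "", paste0(aln$codons[fg, ], collapse = ""))
  upto <- aln$codons[fg, seq_len(surv$column[k])]
  ci <- sum(upto != "---")
  verdict <- if (nrow(pool) == 0) "unmapped" else
    validate_site(ci, cds, setNames(pool$sequence, pool$cdna_id))$verdict
  rows[[k]] <- data.frame(gene = g, foreground = fg,
                          column = surv$column[k], codon_index = ci,
                          verdict = verdict)
}
validations <- do.call(rbind, rows)
write.table(validations, file.path(out, "validations.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
vs <- validation_summary(validations$verdict, validations$gene)
write.table(as.data.frame(vs), file.path(out, "validation_summary.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message(vs$n_valid, " valid / ", vs$n_invalid, " invalid / ",
        vs$n_total - vs$n_mapped, " without covering cDNA; ",
        "coverage ", vs$coverage_pct, "%, genes surviving ",
        vs$genes_surviving, " -> ", out)
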