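#!/usr/bin/env Rscript
# Stage 4 — SP penalty filtering.
#
# Scores the +/-15-residue windows around every candidate site (general
# threshold -50, individual threshold -15) and writes the per-site scores
# plus the per-species retention summary (candidate sites, retained sites,
# misalignment FPR). Outputs under results/spfilter/.

suppressMessages(library(posscreen))

data_dir <- "results/data"
out <- "results/spfilter"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design_tab <- read.delim(file.path(data_dir, "design.tsv"))
design <- species_group_design(design_tab$species, design_tab$group)
files <- list.files(file.path(data_dir, "alignments"), full.names = TRUE)
alns <- setNames(lapply(files, read_codon_fasta),
                 sub("\\.fa$", "", basename(files)))
sites <- read.delim("results/screen/sites.tsv")
if (nrow(sites) == 0) stop("no candidate sites; run stage 3 first")

scored <- list(); summaries <- list()
for (fg in unique(sites$foreground)) {
  i <- match(fg, design$tests$foreground)
  taxa <- c(fg, design$tests$background[[i]])
  sub <- lapply(alns, function(a) {
    a$codons <- a$codons[taxa, , drop = FALSE]; a$taxa <- taxa; a
  })
  part <- filter_sites(sites[sites$foreground == fg, ], sub)
  scored[[fg]] <- part$sites
  summaries[[fg]] <- part$summary
}
scored <- do.call(rbind, scored)
summary <- do.call(rbind, summaries)
write.table(scored, file.path(out, "sites_scored.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(summary, file.path(out, "retention_by_species.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
message(sum(scored$pass, na.rm = TRUE), "/", nrow(scored),
        " sites retained (",
        retention_overall(summary$total, summary$retained),
        "% overall) -> ", out)
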