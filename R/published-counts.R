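# Reported per-species counts from the genome-wide branch-site screen of
# seasonal versus non-seasonal breeding mammals. These printed tables are
# inputs to the reporting arithmetic (group means, fold changes, retention,
# misalignment FPR); the screen itself required Ensembl-scale genome data.

#' Reported per-species gene counts under successive filters
#'
#' Numbers of positively selected genes per foreground species in the
#' Distant- and Close-Species sets, at three filtering stages: chi-squared
#' p <= 0.01, FDR < 0.05, and SP-score filtering.
#'
#' @return Data frame with `set` (Distant/Close), `group`
#'   (non-seasonal/seasonal), `species`, `n_p001`, `n_fdr`, `n_sp`.
#' @export
published_gene_counts <- function() {
  rbind(
    data.frame(set = "Distant", group = "non-seasonal",
               species = c("Human", "Chimpanzee", "Cynomolgus", "Mouse",
                           "Rat"),
               n_p001 = c(88, 207, 113, 228, 274),
               n_fdr = c(16, 68, 62, 15, 43),
               n_sp = c(4, 27, 27, 4, 18)),
    data.frame(set = "Distant", group = "seasonal",
               species = c("Indian rhesus", "Chinese rhesus", "Dog",
                           "Horse", "Rabbit"),
               n_p001 = c(453, 203, 499, 463, 444),
               n_fdr = c(361, 110, 158, 157, 129),
               n_sp = c(131, 51, 54, 55, 58)),
    data.frame(set = "Close", group = "non-seasonal",
               species = c("Human", "Gorilla", "Chimpanzee", "Cynomolgus"),
               n_p001 = c(116, 274, 289, 266),
               n_fdr = c(20, 163, 117, 159),
               n_sp = c(4, 34, 48, 69)),
    data.frame(set = "Close", group = "seasonal",
               species = c("Orangutan", "Indian rhesus", "Chinese rhesus",
                           "Marmoset"),
               n_p001 = c(446, 603, 229, 688),
               n_fdr = c(303, 464, 130, 314),
               n_sp = c(147, 157, 57, 107)))
}

#' Reported per-species positive-site counts before/after SP filtering
#'
#' Sites with BEB posterior > 0.95 per foreground species, and the subset
#' retained by SP-score filtering.
#'
#' @return Data frame with `set`, `group`, `species`, `sites_beb`,
#'   `sites_sp`.
#' @export
published_site_counts <- function() {
  rbind(
    data.frame(set = "Distant", group = "non-seasonal",
               species = c("Human", "Chimpanzee", "Cynomolgus", "Mouse",
                           "Rat"),
               sites_beb = c(26, 103, 92, 10, 66),
               sites_sp = c(16, 65, 54, 5, 42)),
    data.frame(set = "Distant", group = "seasonal",
               species = c("Indian rhesus", "Chinese rhesus", "Dog",
                           "Horse", "Rabbit"),
               sites_beb = c(532, 153, 261, 262, 241),
               sites_sp = c(206, 77, 106, 134, 127)),
    data.frame(set = "Close", group = "non-seasonal",
               species = c("Human", "Gorilla", "Chimpanzee", "Cynomolgus"),
               sites_beb = c(9, 158, 132, 237),
               sites_sp = c(6, 84, 90, 131)),
    data.frame(set = "Close", group = "seasonal",
               species = c("Orangutan", "Indian rhesus", "Chinese rhesus",
                           "Marmoset"),
               sites_beb = c(444, 531, 189, 364),
               sites_sp = c(246, 299, 89, 232)))
}

#' Reported genes surviving SP filtering plus cDNA validation
#'
#' Final gene lists (non-seasonal and seasonal foregrounds) after both
#' false-positive filters. One row per validated gene.
#'
#' @return Data frame with `group`, `species`, `gene`.
#' @export
published_validated_genes <- function() {
  rbind(
    data.frame(group = "non-seasonal",
               species = c(rep("Human", 6), rep("Cynomolgus", 3),
                           rep("Mouse", 4), rep("Rat", 2)),
               gene = c("CGA", "TOMM6", "CD151", "RRP8", "ACCN4",
                        "CHRNA1", "SNX5", "NCAPG", "VPS33A", "SWI5",
                        "NID2", "DHDH", "DNAH1", "INVS", "GALK2")),
    data.frame(group = "seasonal",
               species = c(rep("Orangutan", 18), rep("Rabbit", 2), "Dog",
                           rep("Horse", 3)),
               gene = c("TADA1", "LGALS3BP", "ZFR", "THRAP3", "MTMR12",
                        "TMCC2", "SLC44A2", "MIPEP", "XRN2", "RBM47",
                        "MBTPS1", "FAM69A", "SLC43A2", "RAB1B", "CMTM6",
                        "DARS2", "AARS", "TH1L",
                        "PLEK", "SNX25", "ALB", "SMC4", "ANO6",
                        "GLIPR1")))
}
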