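# Shared fixtures: small trees and hand-built alignments.

tree6_newick <- function(fg = "human") {
  tpl <- "((human:0.1,chimp:0.1):0.05,(mouse:0.25,rat:0.25):0.1,(dog:0.2,horse:0.2):0.08);"
  sub(fg, paste0(fg, "#1"), tpl, fixed = TRUE)
}

tree3_newick <- function() "(a#1:0.2,b:0.3,c:0.4);"

# Close-set-like primate tree (branch lengths in expected substitutions
# per codon, literature scale).
tree_close_newick <- function(fg = "human") {
  tpl <- "((human:0.008,chimp:0.008):0.006,(gorilla:0.012,orangutan:0.025):0.008,(rhesus:0.04,marmoset:0.055):0.015);"
  sub(fg, paste0(fg, "#1"), tpl, fixed = TRUE)
}

# A tiny hand-made gap-free alignment (5 codons, 3 taxa).
toy_alignment <- function() {
  codon_alignment(c(
    a = "ATGAAACCCGGGTTT",
    b = "ATGAAACCTGGGTTT",
    c = "ATGAAGCCCGGATTT"))
}

sim_fixture <- function(n_codons = 200, omega2 = 4, seed = 1,
                        fg = "human", ...) {
  cfg <- simulation_config(tree6_newick(fg), n_codons = n_codons,
                           omega2 = omega2, seed = seed, ...)
  c(simulate_alignment(cfg), list(tree = read_foreground_tree(
    text = tree6_newick(fg))))
}
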