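#' Phylogeny with a designated foreground branch
#'
#' Wraps an [ape::phylo] tree together with the identity of the single
#' branch to be tested for positive selection. The foreground branch is the
#' edge subtending the named tip (or internal node).
#'
#' @param phy An `ape::phylo` object with branch lengths.
#' @param foreground Tip or node label whose subtending edge is foreground.
#' @return Object of class `labeled_tree`: list with `phy`, `foreground`,
#'   and `fg_edge` (row index into `phy$edge`).
#' @export
labeled_tree <- function(phy, foreground) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  node <- match(foreground, phy$tip.label)
  if (is.na(node) && !is.null(phy$node.label)) {
    hit <- match(foreground, phy$node.label)
    if (!is.na(hit)) node <- ape::Ntip(phy) + hit
  }
  if (is.na(node))
    stop("foreground label '", foreground, "' not found in tree")
  fg_edge <- which(phy$edge[, 2] == node)
  if (length(fg_edge) != 1L)
    stop("foreground node has no subtending edge (is it the root?)")
  structure(list(phy = phy, foreground = foreground, fg_edge = fg_edge),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("labeled_tree:", ape::Ntip(x$phy), "tips, foreground =",
      x$foreground, "\n")
  invisible(x)
}

#' Read a Newick tree with a `#1` foreground tag
#'
#' Follows the codeml convention: exactly one tip or internal-node label
#' carries the suffix `#1`, marking its subtending branch as foreground.
#'
#' @param text Newick string (or use `file`).
#' @param file Path to a Newick file.
#' @return A [labeled_tree].
#' @export
read_foreground_tree <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text)
         else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input")
  labs <- c(phy$tip.label, phy$node.label)
  tagged <- grepl("#1$", labs)
  if (sum(tagged) != 1L)
    stop("expected exactly one '#1' foreground tag, found ", sum(tagged))
  phy$tip.label <- sub("#1$", "", phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- sub("#1$", "", phy$node.label)
  fg <- sub("#1$", "", labs[tagged])
  if (fg == "") stop("foreground tag must be attached to a named node")
  labeled_tree(phy, fg)
}

#' Write a labeled tree as Newick with the `#1` tag
#' @param tree A [labeled_tree].
#' @param file Optional path; if omitted the Newick string is returned.
#' @return Newick string, invisibly when written to file.
#' @export
write_foreground_tree <- function(tree, file = NULL) {
  phy <- tree$phy
  tip <- match(tree$foreground, phy$tip.label)
  if (!is.na(tip)) {
    phy$tip.label[tip] <- paste0(phy$tip.label[tip], "#1")
  } else {
    idx <- match(tree$foreground, phy$node.label)
    phy$node.label[idx] <- paste0(phy$node.label[idx], "#1")
  }
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Neighbour-joining fallback tree from a codon alignment
#'
#' Builds an unrooted NJ tree from raw nucleotide distances when no
#' per-gene tree is supplied. This is a deliberate simplification of a
#' full maximum-likelihood tree search.
#'
#' @param aln A [codon_alignment].
#' @param foreground Taxon to flag as foreground.
#' @return A [labeled_tree].
#' @export
nj_codon_tree <- function(aln, foreground) {
  seqs <- alignment_strings(aln)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  d <- ape::dist.dna(as.matrix(bin), model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.5)
  phy <- ape::nj(d)
  phy$edge.length[phy$edge.length < 0] <- 0
  labeled_tree(phy, foreground)
}

# Postorder edge structure consumed by the pruning core.
tree_structure <- function(tree) {
  phy <- ape::reorder.phylo(tree$phy, "postorder")
  fg_node <- tree$phy$edge[tree$fg_edge, 2]
  list(edge = phy$edge,
       lengths = phy$edge.length,
       fg = phy$edge[, 2] == fg_node,
       ntip = ape::Ntip(phy),
       nnode = ape::Ntip(phy) + phy$Nnode,
       root = ape::Ntip(phy) + 1L,
       tips = phy$tip.label)
}
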