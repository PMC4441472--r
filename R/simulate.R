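# Synthetic-data generators: codon alignments evolved under the branch-site
# Model A process, corruption operators emulating misalignment / sequencing
# / annotation error, cDNA fragments, and proteome sets with known
# orthology. These define the study conditions every downstream stage is
# tested against.

#' Simulation configuration for the Model A codon process
#'
#' @param tree Newick string with branch lengths (expected substitutions
#'   per codon) and a `#1` foreground tag, or a [labeled_tree].
#' @param n_codons Number of codon sites (>= 1).
#' @param p0,p1 Model A class proportions (`p0, p1 >= 0`, `p0 + p1 <= 1`);
#'   the remainder is split between classes 2a/2b as in Model A.
#' @param omega0 Purifying ratio in (0, 1).
#' @param omega2 Foreground ratio (>= 1).
#' @param kappa Transition/transversion ratio (> 0).
#' @param codon_frequencies `"equal"` or a 61-vector.
#' @param seed Integer seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_codons, p0 = 0.7, p1 = 0.2,
                              omega0 = 0.1, omega2 = 4, kappa = 2,
                              codon_frequencies = "equal", seed = 1L) {
  if (is.character(tree)) tree <- read_foreground_tree(text = tree)
  stopifnot(inherits(tree, "labeled_tree"),
            n_codons >= 1, p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12,
            p0 + p1 > 0, omega0 > 0, omega0 < 1, omega2 >= 1, kappa > 0)
  if (ape::Ntip(tree$phy) < 3) stop("tree must have at least 3 leaves")
  pi <- resolve_codon_frequencies(codon_frequencies)
  structure(list(tree = tree, n_codons = as.integer(n_codons), p0 = p0,
                 p1 = p1, omega0 = omega0, omega2 = omega2, kappa = kappa,
                 pi = pi, seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw categorical samples, one per row of `prob_rows` (rows of a cumsum'd
# probability matrix selected by parent state).
sample_states <- function(cumP, parents, u) {
  1L + rowSums(cumP[parents, , drop = FALSE] < u)
}

#' Simulate a codon alignment under branch-site Model A
#'
#' Site classes are drawn i.i.d. with the Model A proportions; sequences
#' evolve along the tree under the GY94 process with the class's background
#' omega, switching to `omega2` on the foreground branch for classes 2a/2b.
#' Branch lengths are expected substitutions per codon under the background
#' mixture at the configured parameters.
#'
#' @param config A [simulation_config()].
#' @return List with `alignment` (gap-free [codon_alignment] over the tree
#'   tips) and `truth` (data frame: `site`, `class` in `0/1/2a/2b`,
#'   `corrupted = FALSE`).
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng(config$seed, {
    n <- config$n_codons
    pi <- config$pi
    pr <- modelA_proportions(config$p0, config$p1)
    classes <- sample.int(4L, n, replace = TRUE, prob = pr)
    beta <- modelA_rate_normalizer(config$kappa, config$omega0,
                                   config$p0, config$p1, pi)
    om <- modelA_class_omegas(config$omega0, config$omega2)
    egs <- list(w0 = codon_eigen(config$kappa, config$omega0, pi),
                w1 = codon_eigen(config$kappa, 1, pi),
                w2 = codon_eigen(config$kappa, config$omega2, pi))
    pick_eg <- function(w) {
      if (w == config$omega0) egs$w0 else if (w == 1) egs$w1 else egs$w2
    }
    ts <- tree_structure(config$tree)
    states <- matrix(0L, ts$nnode, n)
    states[ts$root, ] <- sample.int(61L, n, replace = TRUE, prob = pi)
    # reverse postorder = parents before children
    for (e in rev(seq_len(nrow(ts$edge)))) {
      par <- ts$edge[e, 1]; chl <- ts$edge[e, 2]
      t_eff <- ts$lengths[e] / beta
      for (c in 1:4) {
        idx <- which(classes == c)
        if (!length(idx)) next
        w <- if (ts$fg[e]) om$foreground[c] else om$background[c]
        P <- codon_pmat(pick_eg(w), t_eff)
        cumP <- t(apply(P, 1, cumsum))
        cumP[, 61] <- 1
        states[chl, idx] <- sample_states(cumP, states[par, idx],
                                          stats::runif(length(idx)))
      }
    }
    codons <- sense_codons()
    seqs <- apply(states[seq_len(ts$ntip), , drop = FALSE], 1,
                  function(s) paste0(codons[s], collapse = ""))
    names(seqs) <- ts$tips
    out <- codon_alignment(seqs)
    if (!all(out$codons %in% codons))
      stop("internal error: stop codon generated")  # state space excludes stops
    list(alignment = out,
         truth = data.frame(site = seq_len(n),
                            class = c("0", "1", "2a", "2b")[classes],
                            corrupted = FALSE))
  })
}

#' Corruption specification
#'
#' Named operators emulating the three failure classes of real data:
#' misalignment (`gap_burst`, `shuffle`, `shift` windows), per-nucleotide
#' sequencing error on one taxon, and an annotation-style frameshift.
#'
#' @param misalignment_windows List of lists with `taxon`, `start`
#'   (codon column), `width`, `mode` in `gap_burst/shuffle/shift`.
#' @param substitution_error_rate Per-nucleotide error probability.
#' @param error_taxon Taxon receiving substitution errors.
#' @param frameshift Optional list with `taxon`, `position` (codon
#'   column), `length` (nucleotides, not divisible by 3).
#' @param seed Integer seed.
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(misalignment_windows = list(),
                            substitution_error_rate = 0,
                            error_taxon = NULL, frameshift = NULL,
                            seed = 1L) {
  stopifnot(substitution_error_rate >= 0, substitution_error_rate <= 1)
  if (!is.null(frameshift) && frameshift$length %% 3 == 0)
    stop("frameshift length must not be divisible by 3")
  structure(list(windows = misalignment_windows,
                 sub_rate = substitution_error_rate,
                 error_taxon = error_taxon, frameshift = frameshift,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a codon alignment
#'
#' Applies the operators of a [corruption_spec()] and records every touched
#' (taxon, codon column) in a truth table. Columns outside the declared
#' windows (and untouched taxa) are byte-identical before and after.
#'
#' @param aln A [codon_alignment].
#' @param spec A [corruption_spec()].
#' @return List with `alignment` and `truth` (data frame `taxon`,
#'   `column`, `type`).
#' @export
corrupt_alignment <- function(aln, spec) {
  stopifnot(inherits(spec, "corruption_spec"))
  m <- aln$codons
  nc <- ncol(m)
  events <- list()
  log_event <- function(taxon, cols, type) {
    events[[length(events) + 1]] <<- data.frame(taxon = taxon,
                                                column = cols, type = type)
  }
  with_rng(spec$seed, {
    for (w in spec$windows) {
      cols <- seq(w$start, w$start + w$width - 1L)
      if (w$start < 1 || max(cols) > nc)
        stop("corruption window outside alignment bounds")
      tx <- w$taxon
      if (!tx %in% aln$taxa) stop("unknown taxon in window: ", tx)
      if (w$mode == "gap_burst") {
        m[tx, cols] <- "---"
      } else if (w$mode == "shuffle") {
        m[tx, cols] <- m[tx, sample(cols)]
      } else if (w$mode == "shift") {
        m[tx, cols] <- m[tx, c(cols[-1], cols[1])]
      } else stop("unknown corruption mode: ", w$mode)
      log_event(tx, cols, w$mode)
    }
    if (spec$sub_rate > 0 && !is.null(spec$error_taxon)) {
      tx <- spec$error_taxon
      seq_chars <- strsplit(paste0(m[tx, ], collapse = ""), "")[[1]]
      eligible <- which(seq_chars %in% .nucs)
      hit <- eligible[stats::runif(length(eligible)) < spec$sub_rate]
      for (i in hit)
        seq_chars[i] <- sample(setdiff(.nucs, seq_chars[i]), 1)
      if (length(hit)) {
        newseq <- paste0(seq_chars, collapse = "")
        m[tx, ] <- substring(newseq, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
        log_event(tx, unique((hit - 1L) %/% 3L + 1L), "substitution")
      }
    }
    if (!is.null(spec$frameshift)) {
      fs <- spec$frameshift
      tx <- fs$taxon
      chars <- strsplit(paste0(m[tx, ], collapse = ""), "")[[1]]
      at <- 3L * (fs$position - 1L) + 1L
      if (at + fs$length - 1L > length(chars))
        stop("frameshift outside alignment bounds")
      chars <- c(chars[seq_len(at - 1L)],
                 chars[seq(at + fs$length, length(chars))],
                 sample(.nucs, fs$length, replace = TRUE))
      newseq <- paste0(chars, collapse = "")
      m[tx, ] <- substring(newseq, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
      log_event(tx, seq(fs$position, nc), "frameshift")
    }
  })
  out <- aln
  out$codons <- m
  truth <- if (length(events)) do.call(rbind, events)
           else data.frame(taxon = character(), column = integer(),
                           type = character())
  list(alignment = out, truth = truth)
}

#' Emit cDNA fragments for one taxon
#'
#' Fragments are contiguous codon-range substrings of the taxon's ungapped
#' CDS, optionally carrying injected per-nucleotide substitution errors,
#' with recorded CDS coordinates — the synthetic analogue of transcript
#' evidence used to validate candidate sites.
#'
#' @param aln A [codon_alignment] (the corrupted alignment if errors in
#'   the genome sequence are being emulated upstream).
#' @param taxon Taxon whose CDS is fragmented.
#' @param n_fragments Number of fragments.
#' @param span_range Length-2 integer vector: min/max fragment span in
#'   codons.
#' @param error_rate Per-nucleotide substitution probability inside
#'   fragments (0 = faithful fragments).
#' @param seed Integer seed.
#' @return List with `cdnas` (data frame: `cdna_id`, `taxon`,
#'   `start_codon`, `end_codon`, `sequence`) and `errors` (data frame:
#'   `cdna_id`, `cds_position` in nucleotides, `codon`).
#' @export
emit_cdnas <- function(aln, taxon, n_fragments, span_range = c(20, 60),
                       error_rate = 0, seed = 1L) {
  stopifnot(taxon %in% aln$taxa, span_range[1] >= 1,
            span_range[1] <= span_range[2])
  cds <- gsub("-", "", paste0(aln$codons[taxon, ], collapse = ""))
  ncod <- nchar(cds) %/% 3L
  if (span_range[2] > ncod) stop("fragment span exceeds CDS length")
  with_rng(seed, {
    spans <- sample(seq(span_range[1], span_range[2]), n_fragments,
                    replace = TRUE)
    starts <- vapply(spans, function(s)
      sample.int(ncod - s + 1L, 1L), 1L)
    err_rows <- list()
    seqs <- character(n_fragments)
    for (i in seq_len(n_fragments)) {
      a <- 3L * (starts[i] - 1L) + 1L
      b <- 3L * (starts[i] + spans[i] - 1L)
      frag <- strsplit(substr(cds, a, b), "")[[1]]
      if (error_rate > 0) {
        hit <- which(stats::runif(length(frag)) < error_rate)
        for (j in hit) frag[j] <- sample(setdiff(.nucs, frag[j]), 1)
        if (length(hit))
          err_rows[[length(err_rows) + 1]] <- data.frame(
            cdna_id = paste0(taxon, "_cdna", i),
            cds_position = a + hit - 1L,
            codon = (a + hit - 2L) %/% 3L + 1L)
      }
      seqs[i] <- paste0(frag, collapse = "")
    }
    list(cdnas = data.frame(cdna_id = paste0(taxon, "_cdna",
                                             seq_len(n_fragments)),
                            taxon = taxon, start_codon = starts,
                            end_codon = starts + spans - 1L,
                            sequence = seqs),
         errors = if (length(err_rows)) do.call(rbind, err_rows)
                  else data.frame(cdna_id = character(),
                                  cds_position = integer(),
                                  codon = integer()))
  })
}

.amino_acids <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")

#' Emit synthetic proteomes with known orthology
#'
#' Generates ancestral protein sequences and per-species derived copies
#' (1:1 orthologs by descent), plus optional paralogous duplicates at
#' higher divergence, with a truth table of the correct pairing.
#'
#' @param n_species Number of species (species 1 is the reference).
#' @param n_genes Ancestral gene count (>= 1).
#' @param paralog_rate Probability a (species, gene) also carries a
#'   diverged duplicate.
#' @param identity_decay Per-residue substitution probability applied to
#'   each species copy.
#' @param paralog_extra_decay Additional per-residue substitution
#'   probability for paralogs (default 0.3).
#' @param len_range Min/max protein length.
#' @param seed Integer seed.
#' @return List with `proteins` (data frame: `species`, `gene_id`,
#'   `transcript_id`, `sequence`) and `truth` (data frame:
#'   `ancestor_gene`, `species`, `gene_id`, `is_paralog`).
#' @export
emit_proteomes <- function(n_species, n_genes, paralog_rate = 0,
                           identity_decay = 0.05,
                           paralog_extra_decay = 0.3,
                           len_range = c(120, 300), seed = 1L) {
  stopifnot(n_genes >= 1, n_species >= 2,
            paralog_rate >= 0, paralog_rate <= 1,
            identity_decay >= 0, identity_decay <= 1)
  aas <- .amino_acids
  mutate <- function(s, rate) {
    if (rate <= 0) return(s)
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit) v[i] <- sample(setdiff(aas, v[i]), 1)
    paste0(v, collapse = "")
  }
  with_rng(seed, {
    lens <- sample(seq(len_range[1], len_range[2]), n_genes, replace = TRUE)
    anc <- vapply(lens, function(L)
      paste0(sample(aas, L, replace = TRUE), collapse = ""), "")
    rows <- list()
    truth <- list()
    for (s in seq_len(n_species)) {
      sp <- paste0("sp", s)
      for (g in seq_len(n_genes)) {
        gid <- sprintf("%s_g%03d", sp, g)
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, gene_id = gid,
          transcript_id = paste0(gid, "_t1"),
          sequence = mutate(anc[g], identity_decay))
        truth[[length(truth) + 1]] <- data.frame(
          ancestor_gene = g, species = sp, gene_id = gid,
          is_paralog = FALSE)
        if (stats::runif(1) < paralog_rate) {
          pid <- sprintf("%s_g%03d_par", sp, g)
          rows[[length(rows) + 1]] <- data.frame(
            species = sp, gene_id = pid,
            transcript_id = paste0(pid, "_t1"),
            sequence = mutate(anc[g],
                              identity_decay + paralog_extra_decay))
          truth[[length(truth) + 1]] <- data.frame(
            ancestor_gene = g, species = sp, gene_id = pid,
            is_paralog = TRUE)
        }
      }
    }
    list(proteins = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
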