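# Independent oracles, deliberately written from first principles and
# sharing no code with the package internals.

# --- GY94 rate matrix by explicit looping -------------------------------
oracle_codons <- function() {
  nt <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(nt, nt, nt), 1, paste0, collapse = ""))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

oracle_Q <- function(kappa, omega, pi) {
  codons <- oracle_codons()
  gc <- Biostrings::GENETIC_CODE
  n <- length(codons)
  Q <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    ci <- strsplit(codons[i], "")[[1]]
    cj <- strsplit(codons[j], "")[[1]]
    d <- which(ci != cj)
    if (length(d) != 1) next
    r <- pi[j]
    pair <- sort(c(ci[d], cj[d]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
      r <- r * kappa
    if (gc[[codons[i]]] != gc[[codons[j]]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q
}

oracle_mean_rate <- function(kappa, omega, pi) {
  -sum(pi * diag(oracle_Q(kappa, omega, pi)))
}

# --- brute-force branch-site likelihood ---------------------------------
# Explicit summation over all internal-node state assignments, with dense
# matrix exponentials (Matrix::expm). Tree given as an ape phylo plus the
# foreground tip label. Only usable at toy scale.
oracle_bs_loglik <- function(seqs, phy, foreground, kappa, omega0, omega2,
                             p0, p1, pi, model = "alt") {
  if (model == "null") omega2 <- 1
  codons <- oracle_codons()
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  rest <- 1 - p0 - p1
  props <- c(p0, p1, rest * p0 / (p0 + p1), rest * p1 / (p0 + p1))
  om_bg <- c(omega0, 1, omega0, 1)
  om_fg <- c(omega0, 1, omega2, omega2)
  beta <- (props[1] + props[3]) * oracle_mean_rate(kappa, omega0, pi) +
          (props[2] + props[4]) * oracle_mean_rate(kappa, 1, pi)
  fg_node <- match(foreground, phy$tip.label)
  ncod <- nchar(seqs[1]) / 3
  obs <- sapply(phy$tip.label, function(tx) {
    s <- seqs[[tx]]
    match(substring(s, 3 * (1:ncod) - 2, 3 * (1:ncod)), codons)
  })
  obs <- matrix(obs, ncol = ntip)  # site x tip
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  Ps_by_class <- lapply(1:4, function(cls)
    lapply(seq_len(nrow(phy$edge)), function(e) {
      w <- if (phy$edge[e, 2] == fg_node) om_fg[cls] else om_bg[cls]
      as.matrix(Matrix::expm(oracle_Q(kappa, w, pi) *
                               phy$edge.length[e] / beta))
    }))
  total <- 0
  for (site in seq_len(ncod)) {
    site_lik <- 0
    for (cls in 1:4) {
      Ps <- Ps_by_class[[cls]]
      # enumerate internal states
      grid <- do.call(expand.grid, rep(list(seq_along(codons)),
                                       length(internal)))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- integer(nnode)
        assign_state[seq_len(ntip)] <- obs[site, ]
        assign_state[internal] <- as.integer(grid[g, ])
        root <- ntip + 1
        pr <- pi[assign_state[root]]
        for (e in seq_len(nrow(phy$edge))) {
          pr <- pr * Ps[[e]][assign_state[phy$edge[e, 1]],
                             assign_state[phy$edge[e, 2]]]
        }
        lik <- lik + pr
      }
      site_lik <- site_lik + props[cls] * lik
    }
    total <- total + log(site_lik)
  }
  total
}

# --- naive SP scorer -----------------------------------------------------
# Direct transcription of the scoring rules, operating on a character
# matrix and recomputing everything per pair with plain loops.
oracle_sp_score <- function(prot, focal, site_col, window = 15) {
  taxa <- rownames(prot)
  collect <- function(dirn) {
    cols <- integer(0)
    n <- 0
    j <- site_col + dirn
    while (j >= 1 && j <= ncol(prot) && n < window) {
      cols <- c(cols, j)
      if (prot[focal, j] != "-") n <- n + 1
      j <- j + dirn
    }
    list(cols = cols, n = n)
  }
  up <- collect(-1L)
  dn <- collect(1L)
  pen_pair <- function(t1, t2, cols, S) {
    tot <- 0
    for (j in cols) {
      a <- prot[t1, j]; b <- prot[t2, j]
      if (a == "-" && b == "-") next
      if (a == "-" || b == "-") tot <- tot - 2 * S
      else if (a != b) tot <- tot - S
    }
    tot
  }
  S_up <- if (up$n > 0) window / up$n else 0
  S_dn <- if (dn$n > 0) window / dn$n else 0
  gen <- 0; ind <- 0
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i >= j) next
    p <- 0
    if (up$n > 0) p <- p + pen_pair(taxa[i], taxa[j], up$cols, S_up)
    if (dn$n > 0) p <- p + pen_pair(taxa[i], taxa[j], dn$cols, S_dn)
    gen <- gen + p
    if (taxa[i] == focal || taxa[j] == focal) ind <- ind + p
  }
  list(general = gen / length(taxa), individual = ind)
}

# --- chi-squared df=1 upper tail via the normal CDF ----------------------
oracle_chisq1_tail <- function(stat) 2 * stats::pnorm(-sqrt(stat))
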