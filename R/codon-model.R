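#' @useDynLib posscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cache for codon-space structure shared by the simulator and the
# likelihood engine (built once per session).
.posscreen_cache <- new.env(parent = emptyenv())

.nucs <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' The 61 non-stop codons, in lexicographic (A < C < G < T) order. This
#' ordering fixes the state space of the GY94 substitution process used
#' throughout the package.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  if (!is.null(.posscreen_cache$codons)) return(.posscreen_cache$codons)
  all64 <- as.vector(outer(outer(.nucs, .nucs, paste0), .nucs, paste0))
  all64 <- sort(all64)
  codons <- all64[!all64 %in% c("TAA", "TAG", "TGA")]
  .posscreen_cache$codons <- codons
  codons
}

#' Amino-acid translation of the sense codons
#' @return Named character vector (codon -> one-letter amino acid).
#' @export
codon_aa <- function() {
  if (!is.null(.posscreen_cache$aa)) return(.posscreen_cache$aa)
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[sense_codons()]
  names(aa) <- sense_codons()
  .posscreen_cache$aa <- aa
  aa
}

# Pairwise structure of the codon space: which ordered pairs differ at a
# single nucleotide, whether the change is a transition, and whether it is
# nonsynonymous. Returned as 61 x 61 logical matrices.
codon_structure <- function() {
  if (!is.null(.posscreen_cache$struct)) return(.posscreen_cache$struct)
  codons <- sense_codons()
  n <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  aa <- codon_aa()
  diffs <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    d <- outer(cmat[, p], cmat[, p], "!=")
    diffs <- diffs + d
    pur <- cmat[, p] %in% c("A", "G")
    ts <- ts | (d & !outer(pur, pur, "!="))
  }
  single <- diffs == 1L
  nonsyn <- outer(aa, aa, "!=")
  .posscreen_cache$struct <- list(single = single, ts = ts & single,
                                  nonsyn = nonsyn)
  .posscreen_cache$struct
}

#' GY94 codon rate matrix
#'
#' Instantaneous rate matrix of the Goldman-Yang codon process restricted to
#' single-nucleotide changes: `q_ij = pi_j * kappa^[transition] *
#' omega^[nonsynonymous]` for codons differing at one position, zero
#' otherwise. Stop codons are excluded from the state space entirely.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Stationary codon frequencies, length 61, summing to 1.
#' @param normalize If `TRUE`, scale so the expected substitution rate at
#'   stationarity is 1 per codon per unit time.
#' @return 61 x 61 rate matrix with rows summing to zero.
#' @export
codon_rate_matrix <- function(kappa, omega, pi, normalize = FALSE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L,
            abs(sum(pi) - 1) < 1e-8)
  st <- codon_structure()
  Q <- matrix(0, 61, 61)
  rate <- matrix(1, 61, 61)
  rate[st$ts] <- kappa
  rate[st$nonsyn] <- rate[st$nonsyn] * omega
  Q[st$single] <- (rep(pi, each = 61) * rate)[st$single]
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Mean substitution rate (per codon, per unit time) of the unnormalized
# GY94 process at stationarity.
codon_mean_rate <- function(kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi)
  -sum(pi * diag(Q))
}

# Eigendecomposition of the (reversible) GY94 generator via the symmetric
# similarity transform B = D^1/2 Q D^-1/2. Returns factors such that
# P(t) = U diag(exp(lambda * t)) W.
codon_eigen <- function(kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi)
  sp <- sqrt(pi)
  B <- Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp, W = t(e$vectors * sp), lambda = e$values)
}

# Transition probability matrix from a codon_eigen() decomposition.
codon_pmat <- function(eg, t) {
  if (t <= 0) return(diag(61))
  P <- (eg$U * rep(exp(eg$lambda * t), each = 61)) %*% eg$W
  P[P < 0] <- 0
  P
}

#' Model A site-class proportions
#'
#' The four site classes of the modified branch-site Model A: class 0
#' (omega0 on all branches), class 1 (neutral everywhere), and classes
#' 2a/2b (omega2 on the foreground branch; omega0 resp. 1 on background),
#' with `p2a = (1 - p0 - p1) p0 / (p0 + p1)` and
#' `p2b = (1 - p0 - p1) p1 / (p0 + p1)`.
#'
#' @param p0,p1 Proportions of classes 0 and 1 (`p0, p1 >= 0`,
#'   `p0 + p1 <= 1`, `p0 + p1 > 0`).
#' @return Numeric vector `c(p0, p1, p2a, p2b)` summing to 1.
#' @export
modelA_proportions <- function(p0, p1) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12, p0 + p1 > 0)
  rest <- max(0, 1 - p0 - p1)
  c(p0 = p0, p1 = p1,
    p2a = rest * p0 / (p0 + p1),
    p2b = rest * p1 / (p0 + p1))
}

# Background/foreground omega of each Model A class, in class order
# (0, 1, 2a, 2b).
modelA_class_omegas <- function(omega0, omega2) {
  list(background = c(omega0, 1, omega0, 1),
       foreground = c(omega0, 1, omega2, omega2))
}

# Normalization factor shared by all class matrices: expected substitutions
# per codon per unit branch length under the background mixture, so that
# branch lengths read as expected substitutions per codon.
modelA_rate_normalizer <- function(kappa, omega0, p0, p1, pi) {
  pr <- modelA_proportions(p0, p1)
  mu0 <- codon_mean_rate(kappa, omega0, pi)
  mu1 <- codon_mean_rate(kappa, 1, pi)
  (pr[1] + pr[3]) * mu0 + (pr[2] + pr[4]) * mu1
}

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies estimated from the codon columns
#' of an alignment, multiplied across the three positions and renormalized
#' over the 61 sense codons.
#'
#' @param aln A [codon_alignment].
#' @return Numeric vector of length 61 summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  m <- aln$codons
  chars <- do.call(rbind, strsplit(as.vector(m), ""))
  keep <- !apply(chars, 1, function(x) any(!x %in% .nucs))
  chars <- chars[keep, , drop = FALSE]
  if (nrow(chars) == 0) return(rep(1 / 61, 61))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(chars[, p], levels = .nucs))
    (as.numeric(tab) + 0.5) / (sum(tab) + 2)  # light smoothing
  })
  codons <- sense_codons()
  cm <- do.call(rbind, strsplit(codons, ""))
  pi <- f[match(cm[, 1], .nucs), 1] *
        f[match(cm[, 2], .nucs), 2] *
        f[match(cm[, 3], .nucs), 3]
  pi / sum(pi)
}

# Uniform frequencies over sense codons.
equal_codon_frequencies <- function() rep(1 / 61, 61)

# Resolve a codon-frequency spec ("equal", "f3x4", or a 61-vector).
resolve_codon_frequencies <- function(freq, aln = NULL) {
  if (is.character(freq)) {
    freq <- match.arg(freq, c("equal", "f3x4"))
    if (freq == "equal") return(equal_codon_frequencies())
    stopifnot(!is.null(aln))
    return(f3x4_frequencies(aln))
  }
  stopifnot(is.numeric(freq), length(freq) == 61L, all(freq >= 0))
  freq / sum(freq)
}
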