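# Branch-site Model A inference: likelihood evaluation, ML fitting,
# LRT/FDR, and Bayes Empirical Bayes site posteriors.

# Per-pattern log-likelihood for one site class, i.e. one assignment of
# (background omega, foreground omega) to edges.
class_pattern_loglik <- function(states, ts, eg_bg, eg_fg, t_eff, pi) {
  P <- array(0, c(61, 61, length(t_eff)))
  for (e in seq_along(t_eff)) {
    eg <- if (ts$fg[e]) eg_fg else eg_bg
    P[, , e] <- codon_pmat(eg, t_eff[e])
  }
  as.numeric(prune_loglik_cpp(states, ts$edge, P, pi, ts$nnode, ts$root))
}

# n x 4 matrix of per-pattern log-likelihoods for the four Model A classes
# (0, 1, 2a, 2b). `beta` converts branch lengths into rate-matrix time.
bs_class_logliks <- function(states, ts, kappa, omega0, omega2, pi,
                             beta, scale = 1) {
  eg0 <- codon_eigen(kappa, omega0, pi)
  eg1 <- codon_eigen(kappa, 1, pi)
  eg2 <- if (omega2 == omega0) eg0 else if (omega2 == 1) eg1
         else codon_eigen(kappa, omega2, pi)
  t_eff <- ts$lengths * scale / beta
  cbind(class_pattern_loglik(states, ts, eg0, eg0, t_eff, pi),
        class_pattern_loglik(states, ts, eg1, eg1, t_eff, pi),
        class_pattern_loglik(states, ts, eg0, eg2, t_eff, pi),
        class_pattern_loglik(states, ts, eg1, eg2, t_eff, pi))
}

# log(sum(exp(.))) across the columns of a matrix, numerically safe.
row_logsumexp <- function(m, weights = NULL) {
  mx <- do.call(pmax, as.data.frame(m))
  em <- exp(m - mx)
  if (is.null(weights)) mx + log(rowSums(em))
  else mx + log(as.numeric(em %*% weights))
}

# Mixture log-likelihood given per-pattern class log-likelihoods.
mixture_loglik <- function(L, wts, p0, p1) {
  pr <- modelA_proportions(p0, p1)
  sum(wts * row_logsumexp(L, pr))
}

# EM over the Model A proportions with the class log-likelihoods held
# fixed. Exploits the factorization of the four class weights into two
# independent Bernoulli draws: t1 = p0 + p1, t2 = p0 / (p0 + p1).
em_proportions <- function(L, wts, t1 = 0.8, t2 = 0.7,
                           tol = 1e-9, maxit = 400) {
  eps <- 1e-8
  n <- sum(wts)
  mx <- pmax(L[, 1], L[, 2], L[, 3], L[, 4])
  eL <- exp(L - mx)
  last <- -Inf
  ll <- -Inf
  for (it in seq_len(maxit)) {
    pr <- c(t1 * t2, t1 * (1 - t2), (1 - t1) * t2, (1 - t1) * (1 - t2))
    num <- eL * rep(pr, each = nrow(eL))
    den <- rowSums(num)
    ll <- sum(wts * (mx + log(den)))
    cs <- colSums(num / den * wts)
    t1 <- min(max((cs[1] + cs[2]) / n, eps), 1 - eps)
    t2 <- min(max((cs[1] + cs[3]) / n, eps), 1 - eps)
    if (is.finite(ll) && ll - last < tol && it > 2) break
    last <- ll
  }
  list(p0 = t1 * t2, p1 = t1 * (1 - t2), loglik = ll)
}

#' Branch-site Model A log-likelihood
#'
#' Evaluates the log-likelihood of a codon alignment under the modified
#' branch-site Model A (or its \eqn{\omega_2 = 1} null) at fixed parameter
#' values. Codon columns containing gaps or ambiguity are removed first, so
#' the value is invariant to inserting gapped columns.
#'
#' @param aln A [codon_alignment].
#' @param tree A [labeled_tree]; leaf names must cover the alignment taxa.
#' @param params List with `kappa`, `omega0`, `omega2` (ignored under the
#'   null), `p0`, `p1`, and optionally `scale` (branch-length multiplier,
#'   default 1) and `frequencies` ("equal", "f3x4", or a 61-vector;
#'   default "f3x4").
#' @param model `"alt"` or `"null"`.
#' @return Log-likelihood (numeric scalar).
#' @export
bs_loglik <- function(aln, tree, params, model = c("alt", "null")) {
  model <- match.arg(model)
  stripped <- strip_gap_columns(aln)
  ts <- tree_structure(tree)
  if (!all(ts$tips %in% stripped$alignment$taxa))
    stop("tree tips missing from alignment")
  states <- codon_states(stripped$alignment)[ts$tips, , drop = FALSE]
  pat <- site_patterns(states)
  freq <- if (is.null(params$frequencies)) "f3x4" else params$frequencies
  pi <- resolve_codon_frequencies(freq, stripped$alignment)
  omega2 <- if (model == "null") 1 else params$omega2
  scale <- if (is.null(params$scale)) 1 else params$scale
  beta <- modelA_rate_normalizer(params$kappa, params$omega0,
                                 params$p0, params$p1, pi)
  L <- bs_class_logliks(pat$states, ts, params$kappa, params$omega0,
                        omega2, pi, beta, scale)
  ll <- mixture_loglik(L, pat$weights, params$p0, params$p1)
  if (!is.finite(ll)) {
    bad <- which(!is.finite(row_logsumexp(L)))[1]
    stop("non-finite likelihood at site pattern ", bad)
  }
  ll
}

# One ML fit (alt or null) on pre-digested data. Outer quasi-Newton search
# over (kappa, omega0 [, omega2] [, scale]) in unconstrained space with the
# mixture proportions profiled out by EM at every evaluation. Branch
# lengths are interpreted under a neutral-rate normalization; the free
# scale multiplier absorbs the convention.
fit_one <- function(pat, ts, pi, model, start, estimate_scale, scale_fixed,
                    maxit = 200) {
  state <- new.env()
  state$t1 <- min(max(start$p0 + start$p1, 1e-4), 1 - 1e-4)
  state$t2 <- min(max(start$p0 / (start$p0 + start$p1), 1e-4), 1 - 1e-4)
  alt <- model == "alt"

  par <- c(log(start$kappa), stats::qlogis(start$omega0))
  if (alt) par <- c(par, log(max(start$omega2 - 1, 1e-4)))
  if (estimate_scale) par <- c(par, log(start$scale))

  unpack <- function(par) {
    kappa <- exp(min(max(par[1], -5), 7))
    omega0 <- 1e-6 + (1 - 2e-6) * stats::plogis(par[2])
    i <- 3
    omega2 <- 1
    if (alt) { omega2 <- min(1 + exp(min(par[i], 12)), 999); i <- i + 1 }
    scale <- if (estimate_scale) exp(min(max(par[i], -8), 8)) else scale_fixed
    list(kappa = kappa, omega0 = omega0, omega2 = omega2, scale = scale)
  }

  negll <- function(par) {
    p <- unpack(par)
    beta <- codon_mean_rate(p$kappa, 1, pi)
    L <- bs_class_logliks(pat$states, ts, p$kappa, p$omega0, p$omega2,
                          pi, beta, p$scale)
    em <- em_proportions(L, pat$weights, state$t1, state$t2)
    state$t1 <- min(max(em$p0 + em$p1, 1e-8), 1 - 1e-8)
    state$t2 <- min(max(em$p0 / (em$p0 + em$p1), 1e-8), 1 - 1e-8)
    if (!is.finite(em$loglik)) return(1e10)
    -em$loglik
  }

  opt <- stats::optim(par, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  p <- unpack(opt$par)
  # one final EM at the optimum to report the proportions
  beta <- codon_mean_rate(p$kappa, 1, pi)
  L <- bs_class_logliks(pat$states, ts, p$kappa, p$omega0, p$omega2,
                        pi, beta, p$scale)
  em <- em_proportions(L, pat$weights, state$t1, state$t2)
  list(loglik = em$loglik,
       params = list(kappa = p$kappa, omega0 = p$omega0,
                     omega2 = p$omega2, p0 = em$p0, p1 = em$p1,
                     scale = p$scale),
       convergence = opt$convergence)
}

default_start <- function() {
  list(kappa = 2, omega0 = 0.3, omega2 = 2.5, p0 = 0.65, p1 = 0.25,
       scale = 1)
}

jitter_start <- function(start, rng_state) {
  f <- function(x, s) x * exp(stats::rnorm(1, 0, s))
  with_rng(rng_state, {
    start$kappa <- f(start$kappa, 0.4)
    start$omega0 <- stats::plogis(stats::qlogis(start$omega0) +
                                    stats::rnorm(1, 0, 0.7))
    start$omega2 <- 1 + f(start$omega2 - 1, 0.6)
    start$scale <- f(start$scale, 0.3)
    start
  })
}

#' Fit the branch-site model to one gene
#'
#' Maximum-likelihood fit of the modified branch-site Model A and its
#' \eqn{\omega_2 = 1} null to a codon alignment with one foreground branch,
#' followed by the one-degree-of-freedom likelihood-ratio test. The search
#' runs in unconstrained (log/logit) space with the site-class proportions
#' profiled out by EM; the null is fitted first (including a tree-scale
#' multiplier) and seeds the alternative, which is restarted from several
#' \eqn{\omega_2} values plus seeded jitter.
#'
#' @param aln A [codon_alignment].
#' @param tree A [labeled_tree].
#' @param frequencies Codon frequency model: `"f3x4"` (default), `"equal"`,
#'   or a 61-vector.
#' @param n_starts Number of optimization starts per model (>= 1).
#' @param seed Integer seed controlling start jitter.
#' @param estimate_scale Estimate a single branch-length multiplier under
#'   the null (fixed for the alternative)?
#' @return Object of class `branch_site_fit`: log-likelihoods and MLEs for
#'   both models, `lrt_stat`, `p_value`, convergence flags, and cached
#'   alignment digests reused by [beb_posteriors()].
#' @export
branch_site_fit <- function(aln, tree, frequencies = "f3x4", n_starts = 3,
                            seed = 1L, estimate_scale = TRUE) {
  stripped <- strip_gap_columns(aln)
  if (length(stripped$alignment$taxa) < 3)
    stop("need at least 3 taxa")
  ts <- tree_structure(tree)
  if (!all(ts$tips %in% stripped$alignment$taxa))
    stop("tree tips missing from alignment")
  states <- codon_states(stripped$alignment)[ts$tips, , drop = FALSE]
  pat <- site_patterns(states)
  pi <- resolve_codon_frequencies(frequencies, stripped$alignment)

  starts <- list(default_start())
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- jitter_start(default_start(),
                                      derive_seed(seed, 101 + k))
  }
  null_fits <- lapply(starts, function(s)
    fit_one(pat, ts, pi, "null", s, estimate_scale, 1))
  null <- null_fits[[which.max(vapply(null_fits, `[[`, 0, "loglik"))]]

  # alternative: start at the null optimum with a ladder of omega2 values
  w2_ladder <- c(1.001, 2.5, 6)[seq_len(max(1, n_starts))]
  alt_fits <- lapply(seq_along(w2_ladder), function(k) {
    s <- null$params
    s$omega2 <- w2_ladder[k]
    if (k > 2) s <- jitter_start(s, derive_seed(seed, 202 + k))
    fit_one(pat, ts, pi, "alt", s, FALSE, null$params$scale)
  })
  alt <- alt_fits[[which.max(vapply(alt_fits, `[[`, 0, "loglik"))]]
  if (alt$loglik < null$loglik) {
    # the null is a boundary point (omega2 = 1) of the alternative space
    alt <- list(loglik = null$loglik,
                params = utils::modifyList(null$params, list(omega2 = 1)),
                convergence = null$convergence)
  }

  lrt <- lrt_pvalue(alt$loglik, null$loglik)
  structure(list(
    lnL_alt = alt$loglik, lnL_null = null$loglik,
    params_alt = alt$params, params_null = null$params,
    lrt_stat = lrt$stat, p_value = lrt$p,
    converged = alt$convergence == 0 && null$convergence == 0,
    n_codons_clean = ncol(states), n_patterns = ncol(pat$states),
    column_map = stripped$column_map,
    cache = list(pat = pat, ts = ts, pi = pi)),
    class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf(
    "branch_site_fit: lnL_alt = %.4f, lnL_null = %.4f\n  2*dlnL = %.4f, p = %.4g\n  omega2-hat = %.3f (kappa %.2f, omega0 %.3f, p0 %.3f, p1 %.3f)\n",
    x$lnL_alt, x$lnL_null, x$lrt_stat, x$p_value, x$params_alt$omega2,
    x$params_alt$kappa, x$params_alt$omega0, x$params_alt$p0,
    x$params_alt$p1))
  invisible(x)
}

#' Likelihood-ratio test for the branch-site comparison
#'
#' Computes `2 * (lnL_alt - lnL_null)` (clamped at zero; small negative
#' values are optimizer noise in a nested comparison) and the upper tail of
#' the chi-squared distribution with one degree of freedom.
#'
#' @param lnL_alt,lnL_null Log-likelihoods of the alternative and null fits.
#' @param tol Tolerance below which a negative statistic is an error.
#' @return List with `stat` and `p`.
#' @export
lrt_pvalue <- function(lnL_alt, lnL_null, tol = 0.01) {
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -tol)
    warning("lnL_alt below lnL_null beyond tolerance (", stat, ")")
  stat <- max(stat, 0)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment across a family of p-values (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Bayes Empirical Bayes site posteriors
#'
#' Per-site posterior probability that a codon column belongs to the
#' positively selected classes (2a + 2b) on the foreground branch,
#' integrating over a uniform prior on a discretized parameter grid:
#' a triangular d x d grid on `(p0, p1)` and d-point grids on `omega0`
#' (midpoints of (0, 1)) and `omega2` (midpoints of (1, 11)), with
#' `kappa`, frequencies, and branch lengths fixed at their MLEs.
#'
#' @param fit A converged [branch_site_fit()].
#' @param d Grid density per dimension (default 10).
#' @return Data frame with `column` (original codon column, 1-based),
#'   `clean_column` (post gap-stripping), and `posterior`.
#' @export
beb_posteriors <- function(fit, d = 10) {
  if (!inherits(fit, "branch_site_fit")) stop("need a branch_site_fit")
  if (!fit$converged) stop("refusing BEB on an unconverged fit")
  pat <- fit$cache$pat
  ts <- fit$cache$ts
  pi <- fit$cache$pi
  kappa <- fit$params_alt$kappa
  scale <- fit$params_alt$scale
  beta <- codon_mean_rate(kappa, 1, pi)
  t_eff <- ts$lengths * scale / beta
  npat <- ncol(pat$states)

  w0_grid <- (seq_len(d) - 0.5) / d
  w2_grid <- 1 + 10 * (seq_len(d) - 0.5) / d
  eg1 <- codon_eigen(kappa, 1, pi)
  l1 <- class_pattern_loglik(pat$states, ts, eg1, eg1, t_eff, pi)
  eg0s <- lapply(w0_grid, function(w) codon_eigen(kappa, w, pi))
  eg2s <- lapply(w2_grid, function(w) codon_eigen(kappa, w, pi))
  l0 <- vapply(eg0s, function(eg)
    class_pattern_loglik(pat$states, ts, eg, eg, t_eff, pi),
    numeric(npat))
  l2b <- vapply(eg2s, function(eg)
    class_pattern_loglik(pat$states, ts, eg1, eg, t_eff, pi),
    numeric(npat))
  l2a <- array(0, c(npat, d, d))  # [pattern, w0, w2]
  for (i in seq_len(d)) for (j in seq_len(d))
    l2a[, i, j] <- class_pattern_loglik(pat$states, ts, eg0s[[i]],
                                        eg2s[[j]], t_eff, pi)

  # triangular proportion grid
  pp <- expand.grid(i = seq_len(d), j = seq_len(d))
  pp <- pp[(pp$i - 0.5) / d + (pp$j - 0.5) / d <= 1, ]
  p0g <- (pp$i - 0.5) / d
  p1g <- (pp$j - 0.5) / d

  ngrid <- d * d * length(p0g)
  post_num <- matrix(0, npat, ngrid)  # per-grid-point P(class 2 | site)
  logw <- numeric(ngrid)
  g <- 0L
  prmat <- vapply(seq_along(p0g), function(k)
    modelA_proportions(p0g[k], p1g[k]), numeric(4))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    L <- cbind(l0[, i], l1, l2a[, i, j], l2b[, j])
    mx <- pmax(L[, 1], L[, 2], L[, 3], L[, 4])
    eL <- exp(L - mx)
    fall <- eL %*% prmat           # npat x npairs mixture likelihoods
    p2all <- eL[, 3:4] %*% prmat[3:4, ]
    for (k in seq_along(p0g)) {
      g <- g + 1L
      logw[g] <- sum(pat$weights * (mx + log(fall[, k])))
      post_num[, g] <- p2all[, k] / fall[, k]
    }
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  post_pat <- as.numeric(post_num %*% w)
  post <- post_pat[pat$index]
  data.frame(column = fit$column_map,
             clean_column = seq_along(fit$column_map),
             posterior = post)
}

#' Screen a set of genes for foreground positive selection
#'
#' Fits the branch-site test to every gene with the given foreground,
#' adjusts p-values by Benjamini-Hochberg across the gene family, and for
#' genes passing both thresholds reports sites with BEB posterior above the
#' site threshold (coordinates in original, pre-cleaning codon columns).
#'
#' @param alignments Named list of [codon_alignment] objects.
#' @param trees A single [labeled_tree] shared by all genes, or a named
#'   list of per-gene trees.
#' @param p_threshold Gene-level chi-squared p-value cutoff (default 0.01;
#'   genes pass at `p <= p_threshold`).
#' @param q_threshold FDR cutoff (default 0.05; genes pass at
#'   `q < q_threshold`).
#' @param beb_threshold Site posterior cutoff (default 0.95, strict `>`).
#' @param frequencies,n_starts,seed Passed to [branch_site_fit()].
#' @return List with `genes` (one row per gene: lnL values, LRT, p, q,
#'   MLEs, pass flags) and `sites` (one row per reported site).
#' @export
screen_genes <- function(alignments, trees, p_threshold = 0.01,
                         q_threshold = 0.05, beb_threshold = 0.95,
                         frequencies = "f3x4", n_starts = 2, seed = 1L) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  genes <- names(alignments)
  get_tree <- function(g) if (inherits(trees, "labeled_tree")) trees
                          else trees[[g]]
  fits <- vector("list", length(genes))
  names(fits) <- genes
  rows <- lapply(seq_along(genes), function(k) {
    g <- genes[k]
    f <- tryCatch(
      branch_site_fit(alignments[[g]], get_tree(g),
                      frequencies = frequencies, n_starts = n_starts,
                      seed = derive_seed(seed, k)),
      error = function(e) e)
    if (inherits(f, "error")) {
      return(data.frame(gene = g, lnL_null = NA, lnL_alt = NA,
                        lrt_stat = NA, p_value = NA, omega2 = NA,
                        kappa = NA, omega0 = NA, p0 = NA, p1 = NA,
                        converged = FALSE, error = conditionMessage(f)))
    }
    fits[[g]] <<- f
    data.frame(gene = g, lnL_null = f$lnL_null, lnL_alt = f$lnL_alt,
               lrt_stat = f$lrt_stat, p_value = f$p_value,
               omega2 = f$params_alt$omega2, kappa = f$params_alt$kappa,
               omega0 = f$params_alt$omega0, p0 = f$params_alt$p0,
               p1 = f$params_alt$p1, converged = f$converged, error = "")
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & !is.na(tab$p_value)
  tab$q_value <- NA_real_
  tab$q_value[ok] <- bh_fdr(tab$p_value[ok])
  tab$pass_p <- ok & tab$p_value <= p_threshold
  tab$pass <- tab$pass_p & tab$q_value < q_threshold

  site_rows <- list()
  for (g in tab$gene[tab$pass %in% TRUE]) {
    f <- fits[[g]]
    beb <- beb_posteriors(f)
    hit <- beb[beb$posterior > beb_threshold, , drop = FALSE]
    if (nrow(hit) == 0) next
    aln <- alignments[[g]]
    fg <- get_tree(g)$foreground
    res <- rep(NA_character_, nrow(hit))
    if (fg %in% aln$taxa) {
      prot <- translate_alignment(aln)
      res <- prot[fg, hit$column]
    }
    site_rows[[g]] <- data.frame(gene = g, foreground = fg,
                                 column = hit$column, residue = res,
                                 posterior = hit$posterior)
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows)
           else data.frame(gene = character(), foreground = character(),
                           column = integer(), residue = character(),
                           posterior = numeric())
  rownames(sites) <- NULL
  list(genes = tab, sites = sites)
}
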