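#' Exact window time-point count
#'
#' Number of samples in the closed analysis window `[t0_h, t1_h]` at
#' sampling interval `dt_h`; the default 12-20 h window at 30-min sampling
#' holds 17 time points.
#'
#' @param t0_h,t1_h window bounds in hours, `t1_h > t0_h`.
#' @param dt_h sampling interval in hours; the window span must be an
#'   integer multiple of it.
#' @return integer count.
#' @examples
#' window_timepoint_count(12, 20, 0.5)  # 17
#' @export
window_timepoint_count <- function(t0_h, t1_h, dt_h) {
  if (!(t1_h > t0_h) || !(dt_h > 0))
    stop_bimodyn("need t1_h > t0_h and dt_h > 0", "bimodyn_invalid_window")
  k <- (t1_h - t0_h) / dt_h
  if (abs(k - round(k)) > 1e-8)
    stop_bimodyn("window span is not an integer multiple of dt_h",
                 "bimodyn_invalid_window")
  as.integer(round(k)) + 1L
}

#' Three-test consensus for two slope samples
#'
#' Two-sided Welch t-test, two-sample Kolmogorov-Smirnov test and
#' Mann-Whitney (Wilcoxon rank-sum) test of the null hypothesis that the
#' two samples come from one distribution. When both samples are constant
#' with equal values the t p-value is defined as 1 (and 0 when the two
#' constants differ).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a one-row tibble with columns `p_t`, `p_ks`, `p_mw`.
#' @export
three_sample_tests <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_bimodyn("both samples need at least 2 values", "bimodyn_invalid_input")
  p_t <- tryCatch(t.test(a, b)$p.value, error = function(e) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  })
  if (is.nan(p_t)) p_t <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  p_ks <- suppressWarnings(ks.test(a, b)$p.value)
  p_mw <- tryCatch(suppressWarnings(wilcox.test(a, b)$p.value),
                   error = function(e) 1)
  if (is.nan(p_mw)) p_mw <- 1
  tibble(p_t = p_t, p_ks = p_ks, p_mw = p_mw)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up procedure controlling the false-discovery rate at `q`: reject
#' all p-values up to the largest order statistic `p_(k)` with
#' `p_(k) <= k q / m`. Flags are returned in the input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q target false-discovery rate in (0, 1).
#' @return logical vector of rejection flags, same length/order as `pvals`.
#' @export
benjamini_hochberg <- function(pvals, q = 0.1) {
  if (length(pvals) == 0) return(logical(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_bimodyn("p-values must lie in [0, 1]", "bimodyn_invalid_input")
  p.adjust(pvals, method = "BH") <= q
}

#' Permutation reference p-values for the three tests
#'
#' Monte-Carlo permutation p-values for the absolute Welch t statistic, the
#' Kolmogorov-Smirnov D statistic and the centred Mann-Whitney U statistic,
#' computed by random reassignment of the pooled sample. Intended as an
#' independent reference for calibrating [three_sample_tests()]; it shares
#' no code with the parametric/exact implementations.
#'
#' @param a,b numeric samples.
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @return one-row tibble with `p_t`, `p_ks`, `p_mw` (each at resolution
#'   `1/n_perm`).
#' @export
permutation_test_triple <- function(a, b, n_perm = 1e5, seed = 1L) {
  local_rng(seed)
  x <- c(a, b); n1 <- length(a); n2 <- length(b); n <- n1 + n2
  welch <- function(g1, g2) {
    (mean(g1) - mean(g2)) / sqrt(var(g1) / length(g1) + var(g2) / length(g2))
  }
  ks_stat <- function(g1, g2) {
    pooled <- sort(unique(x))
    max(abs(ecdf_at(g1, pooled) - ecdf_at(g2, pooled)))
  }
  u_stat <- function(idx) abs(sum(rank(x)[idx]) - n1 * (n + 1) / 2)

  t_obs <- abs(welch(a, b))
  d_obs <- ks_stat(a, b)
  u_obs <- u_stat(seq_len(n1))

  # permutation assignment matrix: n x n_perm, TRUE = group a
  idx <- replicate(n_perm, sample.int(n, n1))
  Z <- matrix(0, n, n_perm)
  Z[cbind(as.vector(idx), rep(seq_len(n_perm), each = n1))] <- 1

  s1 <- crossprod(Z, x)[, 1]
  q1 <- crossprod(Z, x^2)[, 1]
  s2 <- sum(x) - s1
  q2 <- sum(x^2) - q1
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- pmax(q1 - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(q2 - n2 * m2^2, 0) / (n2 - 1)
  t_perm <- abs(m1 - m2) / sqrt(v1 / n1 + v2 / n2)

  r <- rank(x)
  u_perm <- abs(crossprod(Z, r)[, 1] - n1 * (n + 1) / 2)

  o <- order(x)
  Zs <- Z[o, , drop = FALSE]
  xs <- x[o]
  L <- matrix(0, n, n); L[lower.tri(L, diag = TRUE)] <- 1
  cum1 <- L %*% Zs
  ks_rows <- which(xs != c(xs[-1], Inf))  # last index of each tie run
  k_idx <- matrix(rep(seq_len(n), n_perm), n)[ks_rows, , drop = FALSE]
  diff_mat <- abs(cum1[ks_rows, , drop = FALSE] / n1 -
                    (k_idx - cum1[ks_rows, , drop = FALSE]) / n2)
  d_perm <- apply(diff_mat, 2, max)

  eps <- 1e-12
  tibble(p_t = mean(t_perm >= t_obs - eps),
         p_ks = mean(d_perm >= d_obs - eps),
         p_mw = mean(u_perm >= u_obs - eps))
}

ecdf_at <- function(g, at) vapply(at, function(v) mean(g <= v), numeric(1))
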