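#' Change/variability decomposition (CVD) of climate time series
#'
#' The CVD splits a univariate series into an autocorrelated "change"
#' component and a white-noise-like "variability" component. The series is
#' detrended and z-scored, embedded with window length `M` (23 slices =
#' 23,000 years, one precession cycle, by default) and decomposed by
#' singular spectrum analysis (SSA) into `M` reconstructed components (RCs)
#' ordered by eigenvalue. The smallest `w` is sought for which the sum of
#' RCs `w+1..M` is consistent with white noise, judged in the frequency
#' domain against the pointwise confidence band of the flat theoretical
#' white-noise spectrum. With eigenvalues normalised to sum to 100, the sum
#' of the first `w` gives the percentage of variance in the change
#' component; the remainder is the variability percentage, used as the
#' unpredictability proxy (higher = less predictable).
#'
#' @name cvd
NULL

#' Remove a linear trend and scale to unit variance
#'
#' Ordinary-least-squares linear detrend followed by division by the sample
#' standard deviation; output has mean 0 and sd 1. Variance removed by the
#' trend is excluded from all downstream percentages.
#'
#' @param series numeric vector, finite values.
#' @return list with `series` (preprocessed), `slope`, `intercept`, `scale`.
#' @export
detrend_zscore <- function(series) {
  x <- as.numeric(series)
  if (anyNA(x) || any(!is.finite(x))) stop("series must be finite", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("series too short to detrend", call. = FALSE)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  intercept <- mean(x) - slope * mean(t)
  r <- x - (intercept + slope * t)
  v <- stats::var(r)
  if (v < 1e-12)
    stop("constant series after detrending: CVD undefined", call. = FALSE)
  list(series = r / sqrt(v), slope = slope, intercept = intercept,
       scale = sqrt(v))
}

#' Singular spectrum analysis of a univariate series
#'
#' SVD of the Broomhead-King trajectory matrix of `K = N - M + 1` lagged
#' windows; eigenvalues are squared singular values normalised to sum to
#' 100; reconstructed components are obtained by diagonal averaging
#' (Hankelisation), so that the RCs sum exactly to the input series.
#'
#' @param series numeric vector of length `N > M`.
#' @param M embedding dimension (window length, in slices).
#' @return list of class `ssa_decomposition`: `M`, `N`, `eigenvalues`
#'   (normalised, length M, non-increasing), `raw_eigenvalues`, `eofs`
#'   (M x M, columns are EOFs; zero-padded beyond the rank), `rcs`
#'   (N x M matrix of reconstructed components).
#' @export
ssa <- function(series, M) {
  x <- as.numeric(series)
  N <- length(x)
  M <- as.integer(M)
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  if (N <= M) stop("series length N must exceed the embedding dimension M",
                   call. = FALSE)
  K <- N - M + 1L
  X <- matrix(0, M, K)
  for (m in seq_len(M)) X[m, ] <- x[m:(m + K - 1L)]
  sv <- svd(X)
  r <- length(sv$d)                       # rank bound = min(M, K)
  lam_raw <- numeric(M)
  lam_raw[seq_len(r)] <- sv$d^2
  tot <- sum(lam_raw)
  lam <- if (tot > 0) 100 * lam_raw / tot else lam_raw
  eofs <- matrix(0, M, M)
  eofs[, seq_len(r)] <- sv$u[, seq_len(r), drop = FALSE]
  counts <- pmin(seq_len(N), M, K, N - seq_len(N) + 1L)
  rcs <- matrix(0, N, M)
  for (i in seq_len(r)) {
    if (sv$d[i] == 0) next
    u <- sv$u[, i]; v <- sv$v[, i]
    # antidiagonal sums of d * u v^T are the polynomial convolution of u and v
    s <- stats::convolve(u, rev(v), type = "open")
    rcs[, i] <- sv$d[i] * s / counts
  }
  structure(list(M = M, N = N, eigenvalues = lam, raw_eigenvalues = lam_raw,
                 eofs = eofs, rcs = rcs),
            class = "ssa_decomposition")
}

#' Raw periodogram at positive Fourier frequencies
#'
#' Frequencies `k/N` for `k = 1 .. floor((N-1)/2)`: the zero frequency is
#' excluded, and for even `N` so is the Nyquist ordinate. Powers are
#' `|FFT_k|^2 / N` of the demeaned series, so that the mean power of a
#' white-noise series estimates its variance and each ordinate is
#' asymptotically Exp(mean = sigma^2) under white noise.
#'
#' @param series numeric vector, length >= 8.
#' @return list with `frequencies` (cycles per slice) and `powers`.
#' @export
periodogram <- function(series) {
  x <- as.numeric(series)
  N <- length(x)
  if (N < 8L) stop("series too short for a periodogram (need >= 8)", call. = FALSE)
  f <- stats::fft(x - mean(x))
  k <- seq_len(floor((N - 1) / 2))
  list(frequencies = k / N, powers = Mod(f[k + 1L])^2 / N)
}

#' White-noise consistency test in the frequency domain
#'
#' Each periodogram ordinate of a white-noise series is exponentially
#' distributed around the flat theoretical spectrum (mean `s2`, the series
#' variance estimated by the mean ordinate). Two concrete acceptance rules
#' are provided:
#'
#' * `"fw_max"` (default): the series is white noise iff its largest
#'   ordinate stays below the family-wise `1 - alpha` envelope of the flat
#'   spectrum, `-s2 * log(1 - (1 - alpha)^(1/n))`; exact level `alpha`
#'   against the null and sensitive to any concentrated spectral line —
#'   which is exactly what a leftover periodic component looks like.
#' * `"binomial_count"`: count ordinates outside the pointwise central
#'   `1 - alpha` band `[s2 * (-log(1 - alpha/2)), s2 * (-log(alpha/2))]`
#'   and accept iff the count does not exceed the `1 - alpha` quantile of
#'   Binomial(n, alpha). This rule has little power against a narrow line
#'   carrying much variance in few ordinates, so it is not the default;
#'   see the methods vignette.
#'
#' A (near-)zero-variance series counts as a noise-free remainder and
#' returns `TRUE`, which guarantees termination of the CVD search at
#' `w = M`.
#'
#' @param series numeric vector.
#' @param alpha test level (default 0.05).
#' @param rule acceptance rule, `"fw_max"` or `"binomial_count"`.
#' @return logical scalar.
#' @export
is_white_noise <- function(series, alpha = 0.05,
                           rule = c("fw_max", "binomial_count")) {
  rule <- match.arg(rule)
  x <- as.numeric(series)
  if (stats::var(x) < 1e-12) return(TRUE)
  pg <- periodogram(x)
  s2 <- mean(pg$powers)
  n <- length(pg$powers)
  if (rule == "fw_max") {
    crit <- -s2 * log(1 - (1 - alpha)^(1 / n))
    max(pg$powers) <= crit
  } else {
    lo <- s2 * (-log(1 - alpha / 2))
    hi <- s2 * (-log(alpha / 2))
    n_out <- sum(pg$powers < lo | pg$powers > hi)
    n_out <= stats::qbinom(1 - alpha, n, alpha)
  }
}

#' Change/variability decomposition
#'
#' @param series numeric vector (a climate series at 1 ka steps; orientation
#'   irrelevant — the result is invariant to time reversal).
#' @param M embedding dimension in slices (default 23 = one precession
#'   cycle at 1 ka resolution).
#' @param alpha level of the white-noise consistency test.
#' @param rule white-noise acceptance rule; see [is_white_noise()].
#' @param quiet suppress the short-series warning emitted when `N < 2M`.
#' @return object of class `cvd_result`: `w`, `pct_change`,
#'   `pct_variability`, `change` and `variability` component series (on the
#'   preprocessed scale), `eigenvalues`, `M`, `N`, `alpha`, `preprocessing`
#'   (trend slope/intercept/scale).
#' @export
cvd_decompose <- function(series, M = 23, alpha = 0.05,
                          rule = c("fw_max", "binomial_count"),
                          quiet = FALSE) {
  rule <- match.arg(rule)
  pre <- detrend_zscore(series)
  x <- pre$series
  N <- length(x)
  if (N <= M) stop("need N > M (series of ", N, " slices, M = ", M, ")",
                   call. = FALSE)
  if (!quiet && N < 2 * M)
    warning("series length ", N, " is below 2*M = ", 2 * M,
            "; eigen-spectrum estimates will be coarse", call. = FALSE)
  dec <- ssa(x, M)
  # residual after removing RCs 1..w, built by successive subtraction
  resid <- x
  w <- M
  for (k in 0:M) {
    if (k > 0) resid <- resid - dec$rcs[, k]
    if (is_white_noise(resid, alpha = alpha, rule = rule)) { w <- k; break }
  }
  change <- if (w == 0) rep(0, N) else rowSums(dec$rcs[, seq_len(w), drop = FALSE])
  variability <- x - change
  pct_change <- if (w == 0) 0 else sum(dec$eigenvalues[seq_len(w)])
  structure(list(w = w, pct_change = pct_change,
                 pct_variability = 100 - pct_change,
                 change = change, variability = variability,
                 preprocessed = x, eigenvalues = dec$eigenvalues,
                 M = M, N = N, alpha = alpha,
                 preprocessing = pre[c("slope", "intercept", "scale")]),
            class = "cvd_result")
}

#' @export
print.cvd_result <- function(x, ...) {
  cat(sprintf("<cvd_result> N = %d, M = %d, w = %d: change %.1f%% / variability %.1f%%\n",
              x$N, x$M, x$w, x$pct_change, x$pct_variability))
  invisible(x)
}

#' Unpredictability proxy of a CVD result
#'
#' Returns the percentage of variance in the variability component; higher
#' values mean a less predictable climate series.
#'
#' @param result a `cvd_result`.
#' @return numeric percentage in [0, 100].
#' @export
unpredictability <- function(result) {
  stopifnot(inherits(result, "cvd_result"))
  result$pct_variability
}
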