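#' Sample autocorrelation function
#'
#' Classical biased-denominator estimator: r(k) = sum_t (x_t - xbar)
#' (x_{t+k} - xbar) / sum_t (x_t - xbar)^2 with the full-series mean, so
#' r(0) = 1 and the sequence is positive semi-definite (the form the
#' Durbin-Levinson recursion requires).
#'
#' @param x numeric series, non-constant.
#' @param max_lag largest lag (>= 1); `n >= max_lag + 2` required.
#' @return numeric vector of r(1), ..., r(max_lag).
#' @export
serial_acf <- function(x, max_lag) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(max_lag >= 1, n >= max_lag + 2)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("series is constant; autocorrelation undefined")
  vapply(seq_len(max_lag), function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / denom
  }, numeric(1))
}

#' Partial autocorrelation with large-sample significance
#'
#' The partial autocorrelation at lag k — the correlation between the series
#' and its lag-k values after removing the linear effect of the intervening
#' lags — computed by the Durbin-Levinson recursion on [serial_acf()]. Each
#' value is equipped with the large-sample standard error 1/sqrt(n), the t
#' statistic pacf * sqrt(n), and the one-sided (upper-tail) normal p-value,
#' matching how a significant positive periodic dependence is reported.
#'
#' @param x numeric series, non-constant.
#' @param max_lag largest lag; must satisfy `max_lag <= n/2`.
#' @return a data frame of class `pacf_result` with columns `lag`, `pacf`,
#'   `se`, `t_stat`, `p_one_sided`; attribute `n` holds the series length.
#' @seealso [pacf_significance()] for the bare arithmetic.
#' @export
serial_pacf <- function(x, max_lag) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(max_lag >= 1)
  if (max_lag > n / 2) stop("max_lag must not exceed n/2")
  r <- serial_acf(x, max_lag)
  phi <- durbin_levinson(r)
  sig <- pacf_significance(phi, n)
  structure(data.frame(lag = seq_len(max_lag), pacf = phi,
                       se = rep(1 / sqrt(n), max_lag),
                       t_stat = sig$t_stat, p_one_sided = sig$p_one_sided),
            class = c("pacf_result", "data.frame"), n = n)
}

## Durbin-Levinson: partial autocorrelations from r(1..K)
durbin_levinson <- function(r) {
  K <- length(r)
  pacf <- numeric(K)
  pacf[1] <- r[1]
  prev <- r[1]                     # AR(k-1) coefficients phi_{k-1, 1..k-1}
  if (K >= 2) {
    for (k in 2:K) {
      j <- seq_len(k - 1)
      num <- r[k] - sum(prev * r[k - j])
      den <- 1 - sum(prev * r[j])
      pacf[k] <- num / den
      prev <- c(prev - pacf[k] * rev(prev), pacf[k])
    }
  }
  pacf
}

#' Significance of a partial autocorrelation
#'
#' Large-sample test of a partial autocorrelation estimated from n
#' observations: t = value * sqrt(n) (standard error 1/sqrt(n)) and the
#' one-sided upper-tail normal probability p = 1 - Phi(t). A partial
#' autocorrelation of 0.39 at n = 25 thus gives t = 1.95 and p ~ 0.026.
#'
#' @param value partial autocorrelation(s), in `[-1, 1]`.
#' @param n series length (>= 2).
#' @return list with numeric `t_stat` and `p_one_sided`.
#' @examples
#' pacf_significance(0.39, 25)
#' @export
pacf_significance <- function(value, n) {
  stopifnot(is.numeric(value), is.numeric(n), length(n) == 1L, n >= 2)
  if (any(abs(value) > 1)) stop("a partial autocorrelation must lie in [-1, 1]")
  t_stat <- value * sqrt(n)
  list(t_stat = t_stat, p_one_sided = stats::pnorm(t_stat, lower.tail = FALSE))
}

#' Fourier coefficients at a single frequency
#'
#' Harmonic-regression coefficients of the mean-detrended series at frequency
#' f (cycles per bin): a = (2/N) sum_t x(t) cos(2 pi f t) and
#' b = (2/N) sum_t x(t) sin(2 pi f t), with t = 0, ..., N-1 counted from the
#' youngest bin. At a Fourier frequency k/N these are the DFT cosine/sine
#' amplitudes, so a unit cosine at f returns (1, 0).
#'
#' @param x numeric series (length >= 4); mean-detrended internally.
#' @param frequency cycles per bin, in (0, 0.5].
#' @return named numeric vector `c(cosine = a, sine = b)`.
#' @export
fourier_coefficients <- function(x, frequency) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 4)
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      frequency <= 0 || frequency > 0.5) {
    stop("frequency must lie in (0, 0.5] cycles per bin")
  }
  xc <- x - mean(x)
  t <- seq_len(n) - 1
  w <- 2 * pi * frequency * t
  c(cosine = 2 / n * sum(xc * cos(w)), sine = 2 / n * sum(xc * sin(w)))
}

#' Periodogram over the Fourier frequency grid
#'
#' Cosine/sine coefficients (see [fourier_coefficients()]) and intensities
#' I(f) = (N/4) (a^2 + b^2) at all Fourier frequencies k/N,
#' k = 1, ..., floor(N/2). For mean-detrended input and odd N the intensities
#' satisfy Parseval's identity: sum_k (a_k^2 + b_k^2)/2 equals the (biased)
#' sample variance.
#'
#' @param x numeric series (length >= 4), non-constant; mean-detrended
#'   internally.
#' @param bin_width optional bin width in My; if given, a `period` column in
#'   My is added (period = bin_width / frequency).
#' @return a data frame of class `periodogram` with columns `frequency`,
#'   `cosine`, `sine`, `intensity` (and `period` if `bin_width` given);
#'   attributes `n` and `bin_width`.
#' @export
periodogram <- function(x, bin_width = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 4)
  if (stats::var(x) == 0) stop("series is constant; periodogram undefined")
  xc <- x - mean(x)
  k <- seq_len(n %/% 2)
  freq <- k / n
  t <- seq_len(n) - 1
  cosine <- vapply(freq, function(f) 2 / n * sum(xc * cos(2 * pi * f * t)), numeric(1))
  sine <- vapply(freq, function(f) 2 / n * sum(xc * sin(2 * pi * f * t)), numeric(1))
  out <- data.frame(frequency = freq, cosine = cosine, sine = sine,
                    intensity = n / 4 * (cosine^2 + sine^2))
  if (!is.null(bin_width)) out$period <- bin_width / out$frequency
  structure(out, class = c("periodogram", "data.frame"),
            n = n, bin_width = bin_width)
}

#' Fisher's exact g-test for the largest periodogram ordinate
#'
#' Tests the largest periodogram intensity against a white-noise null.
#' g = max intensity / total intensity over the m ordinates (the Nyquist
#' ordinate at frequency 0.5 is excluded for even N, where its distribution
#' differs), with the exact null tail probability
#' P = sum_j (-1)^(j-1) C(m, j) (1 - j g)^(m-1) over j with j g < 1.
#' Ties in the maximum are broken toward the lowest frequency.
#'
#' @param p a `periodogram` (or numeric vector of intensities, taken to be
#'   ordered by increasing frequency).
#' @return list of class `g_test`: `g`, `m`, `p_value`, `peak_frequency`
#'   (`NA` for bare intensity input), `peak_period` (My, if the periodogram
#'   carried a bin width).
#' @export
fisher_g_test <- function(p) {
  if (inherits(p, "periodogram")) {
    keep <- p$frequency < 0.5 - 1e-12
    intens <- p$intensity[keep]
    freq <- p$frequency[keep]
    bw <- attr(p, "bin_width")
  } else {
    intens <- as.numeric(p)
    freq <- rep(NA_real_, length(intens))
    bw <- NULL
  }
  m <- length(intens)
  if (m < 3L) stop("Fisher's g-test needs at least 3 periodogram ordinates")
  total <- sum(intens)
  if (total <= 0) stop("all periodogram intensities are zero")
  i_max <- which.max(intens)      # which.max takes the first = lowest frequency
  g <- intens[i_max] / total
  structure(list(g = g, m = m, p_value = fisher_g_pvalue(g, m),
                 peak_frequency = freq[i_max],
                 peak_period = if (!is.null(bw) && !is.na(freq[i_max])) bw / freq[i_max] else NA_real_),
            class = "g_test")
}

## exact upper-tail probability of Fisher's g under white noise
fisher_g_pvalue <- function(g, m) {
  stopifnot(g > 0, g <= 1, m >= 2)
  jmax <- floor(1 / g - 1e-12)
  if (jmax < 1) return(0)
  j <- seq_len(min(jmax, m))
  terms <- (-1)^(j - 1) * exp(lchoose(m, j) + (m - 1) * log1p(-j * g))
  min(max(sum(terms), 0), 1)
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("Fisher's g-test: g = %.4f over m = %d ordinates, P = %.4g\n",
              x$g, x$m, x$p_value))
  if (!is.na(x$peak_frequency)) {
    cat(sprintf("  peak at frequency %.4g cycles/bin", x$peak_frequency))
    if (!is.na(x$peak_period)) cat(sprintf(" (period %.4g My)", x$peak_period))
    cat("\n")
  }
  invisible(x)
}

#' Convert between frequency (cycles per bin) and period
#'
#' With bins of width `bin_width` My, a frequency f in cycles per bin
#' corresponds to a period `bin_width / f` My; e.g. f = 0.25 at 0.1-My bins
#' is a 0.4-My (400-kyr) period.
#'
#' @param frequency cycles per bin.
#' @param bin_width bin width in My.
#' @return period in My.
#' @export
frequency_to_period <- function(frequency, bin_width) bin_width / frequency

#' @rdname frequency_to_period
#' @param period period in My.
#' @export
period_to_frequency <- function(period, bin_width) bin_width / period

#' Plot a periodogram
#'
#' Needle plot of intensity against frequency, the conventional display for
#' count-series periodograms.
#'
#' @param x a `periodogram`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.periodogram <- function(x, ...) {
  graphics::plot(x$frequency, x$intensity, type = "h",
                 xlab = "frequency (cycles per bin)", ylab = "intensity", ...)
  invisible(x)
}
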