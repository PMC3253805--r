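## Independent oracles used by the unit and acceptance tests. These are kept
## deliberately naive (double loops, direct linear solves) so they share no
## code path with the package implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

## autocorrelation by direct double summation
acf_brute <- function(x, k) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (t in 1:(n - k)) num <- num + xc[t] * xc[t + k]
  num / sum(xc^2)
}

## partial autocorrelation as the last coefficient of the least-squares
## (Yule-Walker) normal equations built from the sample autocorrelations,
## solved directly -- independent of the Durbin-Levinson recursion
pacf_yw_solve <- function(x, k) {
  r <- serial_acf(x, k)
  if (k == 1) return(r[1])
  solve(toeplitz(c(1, r[seq_len(k - 1)])), r[seq_len(k)])[k]
}

## Fourier coefficients by naive term-by-term summation
fourier_brute <- function(x, f) {
  x <- x - mean(x)
  n <- length(x)
  a <- 0; b <- 0
  for (t in 0:(n - 1)) {
    a <- a + x[t + 1] * cos(2 * pi * f * t)
    b <- b + x[t + 1] * sin(2 * pi * f * t)
  }
  c(2 * a / n, 2 * b / n)
}
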