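#' Bin branching events into a discrete time series
#'
#' Counts events in fixed-width, half-open age bins `[lo, hi)`, youngest bin
#' first (index 1 covers `[t_min, t_min + bin_width)`). This binned count
#' series is what all spectral statistics in the package consume. Events at
#' or beyond `t_max`, or older than the last complete bin, are excluded and
#' their number recorded; a trailing partial bin is dropped with a warning
#' rather than padded.
#'
#' @param ages event ages: a numeric vector (Ma) or a `node_ages` table
#'   (mean ages are used).
#' @param bin_width bin width in My (> 0). Default 0.1 My, the 100-kyr band.
#' @param t_min youngest edge of the grid, Ma (default 0 = present).
#' @param t_max oldest edge; default the smallest multiple of `bin_width`
#'   covering the oldest event.
#' @return an object of class `binned_series`: list with `counts` (integer
#'   vector), `origin`, `bin_width`, `n_bins`, `n_excluded`.
#' @examples
#' bin_events(c(0.05, 0.15, 0.15, 0.35), bin_width = 0.1, t_max = 0.4)$counts
#' @export
bin_events <- function(ages, bin_width = 0.1, t_min = 0, t_max = NULL) {
  a <- event_ages(ages)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a single positive number")
  }
  if (is.null(t_max)) {
    t_max <- ceiling(max(a) / bin_width) * bin_width
    if (t_max <= max(a)) t_max <- t_max + bin_width   # keep the oldest event inside the half-open grid
  }
  if (t_max <= t_min) stop("t_max must exceed t_min")
  span <- t_max - t_min
  n_bins <- floor(span / bin_width + 1e-9)
  if (n_bins < 1L) stop("span shorter than one bin")
  if (span - n_bins * bin_width > 1e-9 * bin_width) {
    warning(sprintf("span %.6g is not a multiple of bin_width %.6g; dropping trailing partial bin",
                    span, bin_width))
  }
  idx <- floor((a - t_min) / bin_width + 1e-9)
  inside <- idx >= 0 & idx < n_bins & a >= t_min
  counts <- tabulate(idx[inside] + 1L, nbins = n_bins)
  n_excluded <- sum(!inside)
  if (sum(counts) == 0L) stop("no events fall inside the binning grid")
  structure(list(counts = as.integer(counts), origin = t_min,
                 bin_width = bin_width, n_bins = as.integer(n_bins),
                 n_excluded = as.integer(n_excluded)),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("Binned branching-event series: %d bins of %g My from %g Ma (%d events, %d excluded)\n",
              x$n_bins, x$bin_width, x$origin, sum(x$counts), x$n_excluded))
  print(x$counts)
  invisible(x)
}

#' Export a binned series to CSV
#'
#' Columns `bin_start,bin_end,count` (ages in Ma, youngest bin first).
#'
#' @param series a `binned_series`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "binned_series"))
  i <- seq_len(series$n_bins) - 1L
  utils::write.csv(data.frame(bin_start = series$origin + i * series$bin_width,
                              bin_end = series$origin + (i + 1L) * series$bin_width,
                              count = series$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Waiting times between consecutive branching events
#'
#' Ages are sorted ascending and differenced; duplicated ages yield zero
#' gaps, which are retained.
#'
#' @param ages event ages (numeric or `node_ages`); at least two.
#' @return numeric vector of `n - 1` non-negative gaps in My.
#' @export
waiting_times <- function(ages) {
  a <- sort(event_ages(ages))
  if (length(a) < 2L) stop("waiting times need at least 2 events")
  diff(a)
}

#' Detrend a count series
#'
#' `"none"` casts counts to reals; `"mean"` removes the sample mean (the
#' default preprocessing for all spectral statistics here); `"linear"`
#' removes an ordinary-least-squares straight line in bin index, useful when
#' the event intensity carries a secular trend (e.g. the growth of a birth
#' process).
#'
#' @param series a `binned_series` or numeric vector.
#' @param method one of `"none"`, `"mean"`, `"linear"`.
#' @return a numeric vector of the same length.
#' @export
detrend <- function(series, method = c("mean", "none", "linear")) {
  method <- match.arg(method)
  x <- if (inherits(series, "binned_series")) as.numeric(series$counts) else as.numeric(series)
  n <- length(x)
  if (n < 2L) stop("series too short to detrend")
  switch(method,
    none = x,
    mean = x - mean(x),
    linear = {
      if (n < 3L) stop("linear detrending needs at least 3 points")
      t <- seq_len(n)
      stats::lm.fit(cbind(1, t), x)$residuals
    }
  )
}
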