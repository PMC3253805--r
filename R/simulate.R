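#' Sinusoidally forced speciation-rate model
#'
#' A "Court Jester" rate law: the instantaneous speciation rate is a base
#' rate modulated log-linearly by one or more sinusoids,
#' lambda(t) = lambda0 * exp(sum_i A_i cos(2 pi t / P_i + phi_i)).
#' The exponential form keeps the rate strictly positive for any amplitude;
#' with all amplitudes zero the rate is constant at `base_rate`.
#'
#' @param base_rate events per My per lineage, lambda0 > 0.
#' @param periods sinusoid periods P_i in My (e.g. 0.4 and 0.1 for the
#'   eccentricity bands).
#' @param amplitudes dimensionless amplitudes A_i >= 0 (same length as
#'   `periods`).
#' @param phases phases phi_i in radians (recycled; default 0).
#' @return an object of class `forcing_model`.
#' @seealso [eccentricity_preset()], [rate_at()], [simulate_events()]
#' @export
forcing_model <- function(base_rate, periods = numeric(0),
                          amplitudes = numeric(0), phases = 0) {
  stopifnot(is.numeric(base_rate), length(base_rate) == 1L, base_rate > 0,
            length(periods) == length(amplitudes))
  if (length(periods)) {
    stopifnot(all(periods > 0), all(amplitudes >= 0))
    phases <- rep_len(phases, length(periods))
  } else {
    phases <- numeric(0)
  }
  structure(list(base_rate = base_rate, periods = as.numeric(periods),
                 amplitudes = as.numeric(amplitudes),
                 phases = as.numeric(phases)),
            class = "forcing_model")
}

#' @export
print.forcing_model <- function(x, ...) {
  cat(sprintf("Forcing model: base rate %.4g events/My", x$base_rate))
  if (length(x$periods)) {
    cat(", components:\n")
    for (i in seq_along(x$periods)) {
      cat(sprintf("  period %.4g My, amplitude %.4g, phase %.4g rad\n",
                  x$periods[i], x$amplitudes[i], x$phases[i]))
    }
  } else cat(" (constant rate)\n")
  invisible(x)
}

#' Evaluate the forced speciation rate
#'
#' @param model a [forcing_model()].
#' @param t time(s) in Ma (>= 0).
#' @return rate(s) in events per My.
#' @examples
#' rate_at(forcing_model(1, periods = 0.4, amplitudes = 1), c(0, 0.2))  # e, 1/e
#' @export
rate_at <- function(model, t) {
  stopifnot(inherits(model, "forcing_model"), all(t >= 0))
  s <- numeric(length(t))
  for (i in seq_along(model$periods)) {
    s <- s + model$amplitudes[i] * cos(2 * pi * t / model$periods[i] + model$phases[i])
  }
  model$base_rate * exp(s)
}

## majorant of the rate law (all cosines at +1)
rate_max <- function(model) model$base_rate * exp(sum(model$amplitudes))

#' Eccentricity-band forcing preset
#'
#' Sinusoidal forcing at the two dominant orbital-eccentricity periods,
#' 0.4 My (400 kyr, amplitude 1.0) and 0.1 My (100 kyr, amplitude 0.5),
#' phases zero. These amplitudes are package defaults for simulation
#' studies, not empirical estimates.
#'
#' @param base_rate base speciation rate, events per My (default 2.5, ~25
#'   expected events over a 10-My span at zero amplitude).
#' @return a `forcing_model`.
#' @export
eccentricity_preset <- function(base_rate = 2.5) {
  forcing_model(base_rate, periods = c(0.4, 0.1), amplitudes = c(1, 0.5))
}

#' Expected event count of a forcing model over a span
#'
#' Numerical (trapezoid) integral of the rate law over `[0, span]`, on a
#' grid fine relative to the shortest forcing period.
#'
#' @param model a `forcing_model`.
#' @param span span in My.
#' @return expected number of events.
#' @export
expected_events <- function(model, span) {
  stopifnot(span > 0)
  dt <- if (length(model$periods)) min(model$periods) / 400 else span / 1000
  grid <- seq(0, span, by = min(dt, span / 1000))
  if (grid[length(grid)] < span) grid <- c(grid, span)
  y <- rate_at(model, grid)
  sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
}

#' Rescale a forcing model to a target expected event count
#'
#' Adjusts the base rate so that the expected number of events over
#' `[0, span]` (see [expected_events()]) equals `target_events`, leaving the
#' forcing components unchanged.
#'
#' @param model a `forcing_model`.
#' @param target_events desired expected event count (> 0).
#' @param span span in My.
#' @return a rescaled `forcing_model`.
#' @export
tune_base_rate <- function(model, target_events, span) {
  stopifnot(target_events > 0)
  model$base_rate <- model$base_rate * target_events / expected_events(model, span)
  model
}

#' Simulate branching-event ages under a forced Poisson process
#'
#' Inhomogeneous Poisson realization of the rate law by Lewis-Shedler
#' thinning: candidate events are drawn at the constant majorant rate
#' lambda_max = lambda0 * exp(sum A_i) and each accepted with probability
#' lambda(t)/lambda_max. Event times are ages in Ma on `[0, span]`, returned
#' sorted ascending (youngest first).
#'
#' @param model a [forcing_model()].
#' @param span simulate over ages `[0, span]`, My.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream, which is convenient inside replicate loops.
#' @return numeric vector of event ages, Ma.
#' @export
simulate_events <- function(model, span, seed = NULL) {
  stopifnot(inherits(model, "forcing_model"), span > 0)
  if (model$base_rate * span > 1e7) {
    stop("refusing runaway simulation: base_rate * span exceeds 1e7 expected events")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  lmax <- rate_max(model)
  n_cand <- stats::rpois(1, lmax * span)
  if (n_cand == 0L) return(numeric(0))
  cand <- stats::runif(n_cand, 0, span)
  keep <- stats::runif(n_cand) < rate_at(model, cand) / lmax
  sort(cand[keep])
}

#' Simulate a dated pure-birth tree under a forced speciation rate
#'
#' A Yule (pure-birth) tree grown from one lineage at age `span` towards the
#' present, each extant lineage splitting with instantaneous rate lambda(t)
#' (per-lineage Lewis-Shedler thinning). Extinction is not modelled; the
#' empirical trees this emulates are reconstructed from extant taxa only.
#' The returned tree is ultrametric with tips at age 0, and the true
#' branching ages are returned alongside so that downstream age extraction
#' can be validated against ground truth.
#'
#' @inheritParams simulate_events
#' @return list with `tree` (an ultrametric `phylo`) and `ages` (numeric,
#'   true branching ages sorted descending).
#' @export
simulate_tree <- function(model, span, seed = NULL) {
  stopifnot(inherits(model, "forcing_model"), span > 0)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  lmax <- rate_max(model)
  birth <- c(span)              # birth age of each lineage, indexed by id
  children <- list(NULL)        # ids of the two daughters once split
  split_age <- c(NA_real_)
  active <- 1L
  a <- span
  repeat {
    n <- length(active)
    a <- a - stats::rexp(1, rate = n * lmax)
    if (a <= 0) break
    if (stats::runif(1) < rate_at(model, a) / lmax) {
      i <- active[sample.int(n, 1)]
      id1 <- length(birth) + 1L
      id2 <- length(birth) + 2L
      if (id2 > 2e5L) {
        stop("refusing runaway tree simulation (> 1e5 lineages); lower base_rate or span")
      }
      birth[c(id1, id2)] <- a
      children[c(id1, id2)] <- list(NULL)   # extend list; NULL marks a leaf
      split_age[c(id1, id2)] <- NA_real_
      children[[i]] <- c(id1, id2)
      split_age[i] <- a
      active <- c(setdiff(active, i), id1, id2)
    }
  }
  if (length(active) == 1L) {
    stop("no branching events over the span; increase base_rate or span")
  }
  tip_counter <- new.env(parent = emptyenv())
  tip_counter$k <- 0L
  nwk <- function(id, parent_age) {
    if (is.null(children[[id]])) {
      tip_counter$k <- tip_counter$k + 1L
      sprintf("t%d:%.12f", tip_counter$k, parent_age)
    } else {
      s <- split_age[id]
      sprintf("(%s,%s):%.12f", nwk(children[[id]][1], s), nwk(children[[id]][2], s),
              parent_age - s)
    }
  }
  s_root <- split_age[1]
  txt <- sprintf("(%s,%s);", nwk(children[[1]][1], s_root), nwk(children[[1]][2], s_root))
  tree <- ape::read.tree(text = txt)
  true_ages <- sort(split_age[!is.na(split_age)], decreasing = TRUE)
  list(tree = tree, ages = true_ages)
}

#' Add multiplicative lognormal dating noise to node ages
#'
#' Each mean age is multiplied by an independent lognormal factor with
#' median 1 whose coefficient of variation is `cv` (log-sd
#' sqrt(log(1 + cv^2))), mimicking relaxed-clock dating uncertainty whose
#' interval widths scale with the mean. The 95% interval is centred on the
#' noisy mean: low/high are the noisy mean times the 2.5%/97.5% quantiles of
#' the noise factor, so the interval invariant always holds. `cv = 0`
#' returns the input unchanged.
#'
#' @param ages a `node_ages` table (or numeric ages).
#' @param cv coefficient of variation of the noise factor (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `node_ages` table.
#' @export
add_dating_noise <- function(ages, cv, seed = NULL) {
  ages <- as_node_ages(ages)
  stopifnot(is.numeric(cv), length(cv) == 1L, cv >= 0)
  if (cv == 0) return(ages)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  sdlog <- sqrt(log(1 + cv^2))
  f <- stats::rlnorm(nrow(ages), meanlog = 0, sdlog = sdlog)
  m <- ages$mean * f
  node_ages(ages$label, m,
            low = m * stats::qlnorm(0.025, 0, sdlog),
            high = m * stats::qlnorm(0.975, 0, sdlog))
}
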