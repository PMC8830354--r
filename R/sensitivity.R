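#' Probabilistic sensitivity analysis
#'
#' Draws every distributed parameter jointly `n_iterations` times (see
#' [sample_parameter_set()]) and evaluates all strategies on each draw, so
#' the per-iteration expected values are directly comparable across
#' strategies.
#'
#' @param params A `mia_parameters` object.
#' @param table A `mia_life_table`.
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Integer seed; recorded in the result.
#' @return Object of class `mia_psa`: list with `ev` (iterations x strategies
#'   matrix of discounted QALYs), `draws` (sampled parameters), `seed`,
#'   `n_iterations`, `n_renormalised`.
#' @export
#' @examples
#' psa <- run_psa(load_base_parameters(), n_iterations = 100, seed = 1)
#' optimal_frequencies(psa)
run_psa <- function(params, table = build_fixture_table(),
                    n_iterations = 10000, seed = 1) {
  stopifnot(n_iterations >= 1)
  set.seed(seed)
  draws <- sample_parameter_set(params, n_iterations)
  ev <- .ev_matrix(draws, params$settings, table)
  structure(list(ev = ev, draws = draws, seed = seed,
                 n_iterations = n_iterations,
                 n_renormalised = attr(draws, "n_renormalised")),
            class = "mia_psa")
}

#' @export
print.mia_psa <- function(x, ...) {
  cat("<mia_psa>", x$n_iterations, "iterations, seed", x$seed, "\n")
  print(round(optimal_frequencies(x), 2))
  invisible(x)
}

# argmax per iteration with ties broken by the fixed strategy order
.argmax_strategy <- function(ev) {
  colnames(ev)[max.col(ev, ties.method = "first")]
}

#' Percentage of iterations in which each strategy is optimal
#'
#' Ties (numerically equal maxima) are assigned to the earlier strategy in
#' the fixed comparison order.
#'
#' @param psa A `mia_psa`, or a bare iterations-by-strategies EV matrix.
#' @return Named numeric vector of percentages summing to 100.
#' @export
optimal_frequencies <- function(psa) {
  ev <- if (inherits(psa, "mia_psa")) psa$ev else psa
  stopifnot(is.matrix(ev), nrow(ev) >= 1)
  best <- factor(.argmax_strategy(ev), levels = colnames(ev))
  out <- 100 * as.numeric(table(best)) / nrow(ev)
  names(out) <- colnames(ev)
  out
}

#' Percentage of iterations in which one strategy beats another
#'
#' @param psa A `mia_psa`.
#' @param a,b Strategy ids; reports the percentage of iterations with
#'   `EV(a) > EV(b)`.
#' @return A percentage.
#' @export
pairwise_preference <- function(psa, a = "treat_two", b = "treat_one") {
  ev <- if (inherits(psa, "mia_psa")) psa$ev else psa
  if (!all(c(a, b) %in% colnames(ev))) stop("unknown strategy id")
  100 * mean(ev[, a] > ev[, b])
}

#' Stability of the PSA optimal-strategy frequencies across seeds
#'
#' Repeats the PSA with fresh seeds and reports the per-repeat frequency
#' table together with the maximum absolute deviation of the leading
#' strategy's frequency from its across-repeat mean. For a binomial
#' proportion p at n iterations the Monte Carlo standard error is
#' `sqrt(p (1 - p) / n)`, so deviations should stay within a few multiples
#' of that.
#'
#' @inheritParams run_psa
#' @param n_repeats Number of repeated analyses (>= 2).
#' @param seeds Integer seeds, one per repeat; defaults to `seed + 0:(k-1)`.
#' @param seed Base seed used when `seeds` is not given.
#' @return List with `frequencies` (repeats x strategies data frame),
#'   `leading` (strategy id), `max_abs_deviation` (percentage points) and
#'   `binomial_se` (percentage points).
#' @export
psa_stability <- function(params, table = build_fixture_table(),
                          n_iterations = 10000, n_repeats = 10,
                          seeds = NULL, seed = 1) {
  stopifnot(n_repeats >= 2)
  if (is.null(seeds)) seeds <- seed + seq_len(n_repeats) - 1
  stopifnot(length(seeds) == n_repeats)
  freq <- t(vapply(seeds, function(s) {
    optimal_frequencies(run_psa(params, table, n_iterations, seed = s))
  }, numeric(length(list_strategies()$id))))
  freq <- as.data.frame(freq)
  freq$seed <- seeds
  lead <- names(which.max(colMeans(freq[setdiff(names(freq), "seed")])))
  p <- mean(freq[[lead]]) / 100
  list(frequencies = freq,
       leading = lead,
       max_abs_deviation = max(abs(freq[[lead]] - mean(freq[[lead]]))),
       binomial_se = 100 * sqrt(p * (1 - p) / n_iterations))
}

.parameter_row <- function(params, parameter) {
  tab <- rbind(params$clinical, params$utilities)
  i <- match(parameter, tab$name)
  if (is.na(i)) stop("unknown parameter '", parameter, "'")
  tab[i, ]
}

#' One-way sensitivity sweep of a parameter
#'
#' Holds every other parameter at its point estimate and sweeps one parameter
#' over its published range, recording each strategy's expected value and the
#' decision-model expected value (the best strategy's EV) at each point.
#'
#' @param parameter Parameter name (a row of the parameter table with
#'   `low < high`).
#' @param params A `mia_parameters` object.
#' @param table A `mia_life_table`.
#' @param n_points Number of equally spaced sweep points.
#' @return List with `curves` (data frame: `value`, one EV column per
#'   strategy, `optimal`) and `entry` (one-row data frame: `parameter`,
#'   `ev_at_low`, `ev_at_high`, `spread`, `optimal_switches`).
#' @export
one_way_sweep <- function(parameter, params, table = build_fixture_table(),
                          n_points = 101) {
  row <- .parameter_row(params, parameter)
  if (row$low >= row$high) stop("parameter '", parameter, "' has a degenerate range")
  xs <- seq(row$low, row$high, length.out = n_points)
  draws <- .base_values(params)
  draws[[parameter]] <- NULL
  draws <- c(as.list(draws), stats::setNames(list(xs), parameter))
  ev <- .ev_matrix(draws, params$settings, table)
  best <- .argmax_strategy(ev)
  ev_best <- ev[cbind(seq_len(nrow(ev)), match(best, colnames(ev)))]
  curves <- data.frame(value = xs, ev, optimal = best, check.names = FALSE)
  entry <- data.frame(parameter = parameter,
                      ev_at_low = ev_best[1],
                      ev_at_high = ev_best[n_points],
                      spread = max(ev_best) - min(ev_best),
                      optimal_switches = length(unique(best)) > 1)
  list(curves = curves, entry = entry)
}

#' Tornado analysis over all ranged parameters
#'
#' Runs [one_way_sweep()] for every parameter with a non-degenerate range and
#' returns the entries sorted by spread, largest first.
#'
#' @inheritParams one_way_sweep
#' @return Data frame with one row per parameter: `parameter`, `ev_at_low`,
#'   `ev_at_high`, `spread`, `optimal_switches`.
#' @export
tornado_analysis <- function(params, table = build_fixture_table(), n_points = 41) {
  tab <- rbind(params$clinical, params$utilities)
  tab <- tab[tab$low < tab$high, ]
  entries <- do.call(rbind, lapply(tab$name, function(nm) {
    one_way_sweep(nm, params, table, n_points)$entry
  }))
  entries <- entries[order(-entries$spread), ]
  rownames(entries) <- NULL
  entries
}

#' Threshold (switch-point) search for one parameter
#'
#' Locates the parameter value at which the identity of the optimal strategy
#' changes, holding all other parameters at their point estimates. A coarse
#' scan over the published range brackets the first switch from the low end;
#' bisection then narrows the bracket below `tolerance`. If the optimal
#' strategy never changes over the range the threshold is `NA`.
#'
#' @inheritParams one_way_sweep
#' @param tolerance Width to which the switch point is bracketed.
#' @param n_scan Number of coarse-scan points.
#' @return List with `parameter`, `threshold` (or `NA`), `strategy_below`,
#'   `strategy_above`, `tolerance`, `multiple` (TRUE when the coarse scan saw
#'   more than one switch).
#' @export
threshold_search <- function(parameter, params, table = build_fixture_table(),
                             tolerance = 1e-4, n_scan = 64) {
  row <- .parameter_row(params, parameter)
  if (row$low >= row$high) stop("parameter '", parameter, "' has a degenerate range")
  base <- as.list(.base_values(params))
  best_at <- function(x) {
    draws <- base
    draws[[parameter]] <- x
    .argmax_strategy(.ev_matrix(draws, params$settings, table))
  }
  xs <- seq(row$low, row$high, length.out = n_scan)
  best <- best_at(xs)
  sw <- which(best[-1] != best[-n_scan])
  if (!length(sw)) {
    return(list(parameter = parameter, threshold = NA_real_,
                strategy_below = best[1], strategy_above = best[n_scan],
                tolerance = tolerance, multiple = FALSE))
  }
  lo <- xs[sw[1]]; hi <- xs[sw[1] + 1]
  b_lo <- best[sw[1]]
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (best_at(mid) == b_lo) lo <- mid else hi <- mid
  }
  list(parameter = parameter, threshold = (lo + hi) / 2,
       strategy_below = b_lo, strategy_above = best_at(hi),
       tolerance = tolerance, multiple = length(sw) > 1)
}

#' Two-way sensitivity map
#'
#' Evaluates the optimal strategy on a Cartesian grid over the published
#' ranges of two parameters, all others held at their point estimates.
#'
#' @param parameter_x,parameter_y Distinct parameter names with ranges.
#' @param params A `mia_parameters` object.
#' @param table A `mia_life_table`.
#' @param grid_size Number of grid points per axis (inclusive of both range
#'   endpoints).
#' @return Long-format data frame with columns `x`, `y`, `optimal`, and
#'   attributes `parameter_x`, `parameter_y`.
#' @export
two_way_grid <- function(parameter_x, parameter_y, params,
                         table = build_fixture_table(), grid_size = 26) {
  if (identical(parameter_x, parameter_y)) {
    stop("the two parameters of a two-way analysis must differ")
  }
  rx <- .parameter_row(params, parameter_x)
  ry <- .parameter_row(params, parameter_y)
  gx <- seq(rx$low, rx$high, length.out = grid_size)
  gy <- seq(ry$low, ry$high, length.out = grid_size)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  draws <- as.list(.base_values(params))
  draws[[parameter_x]] <- grid$x
  draws[[parameter_y]] <- grid$y
  ev <- .ev_matrix(draws, params$settings, table)
  out <- data.frame(x = grid$x, y = grid$y, optimal = .argmax_strategy(ev))
  attr(out, "parameter_x") <- parameter_x
  attr(out, "parameter_y") <- parameter_y
  out
}
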