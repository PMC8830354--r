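# Report writers: every file carries a `#`-prefixed header echoing the seed
# and settings that produced it, so any table can be traced to its run.

.write_with_header <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.settings_header <- function(settings, seed = NULL) {
  c(sprintf("start_age=%s max_age=%s discount_rate=%s procedure_disutility=%s sah_fraction=%s",
            settings$start_age, settings$max_age, settings$discount_rate,
            settings$procedure_disutility, settings$sah_fraction),
    if (!is.null(seed)) sprintf("seed=%s", seed))
}

#' Write the strategy expected-value table
#'
#' @param ev Data frame from [evaluate_strategies()].
#' @param path Output CSV path.
#' @param settings Model settings echoed in the header.
#' @export
write_ev_table <- function(ev, path, settings = default_settings()) {
  ev <- ev[order(-ev$qalys), ]
  ev$rank <- seq_len(nrow(ev))
  .write_with_header(ev, path, .settings_header(settings))
}

#' Write a cohort trace as CSV
#'
#' One row per cycle: age, the nine state occupancies, the procedure-related
#' utility mass, and the discounted per-cycle utility.
#'
#' @param trace A `mia_trace`.
#' @param params The `mia_parameters` used for the run.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, params, path) {
  v <- .base_values(params)
  u <- unlist(.state_utilities(v))[colnames(trace$occupancy)]
  r <- params$settings$discount_rate
  t <- seq_len(nrow(trace$occupancy)) - 1
  per_cycle <- as.numeric(trace$occupancy %*% u) -
    params$settings$procedure_disutility * trace$proc_utility
  df <- data.frame(cycle = t, age = trace$ages, trace$occupancy,
                   proc_utility = trace$proc_utility,
                   discounted_utility = (1 + r)^(-t) * per_cycle,
                   check.names = FALSE)
  .write_with_header(df, path,
                     c(paste("strategy:", trace$strategy),
                       .settings_header(params$settings)))
}

#' Write PSA iterations as CSV
#'
#' @param psa A `mia_psa`.
#' @param path Output CSV path.
#' @param draws Include the sampled parameter values alongside the EVs.
#' @export
write_psa_csv <- function(psa, path, draws = FALSE) {
  df <- as.data.frame(psa$ev)
  df <- cbind(iteration = seq_len(nrow(df)), df)
  if (draws) df <- cbind(df, psa$draws)
  .write_with_header(df, path,
                     c(sprintf("iterations=%d seed=%d renormalised_draws=%d",
                               psa$n_iterations, psa$seed, psa$n_renormalised)))
}

#' Write the tornado table as CSV
#'
#' @param tornado Data frame from [tornado_analysis()].
#' @param path Output CSV path.
#' @export
write_tornado_csv <- function(tornado, path) {
  .write_with_header(tornado, path, "one-way sweeps over published ranges, others at point estimates")
}

#' Write a threshold result as JSON
#'
#' @param threshold List from [threshold_search()].
#' @param path Output JSON path.
#' @export
write_threshold_json <- function(threshold, path) {
  jsonlite::write_json(threshold, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a two-way sensitivity map as long-format CSV
#'
#' @param map Data frame from [two_way_grid()].
#' @param path Output CSV path.
#' @export
write_twoway_csv <- function(map, path) {
  .write_with_header(map, path,
                     sprintf("x=%s y=%s", attr(map, "parameter_x"),
                             attr(map, "parameter_y")))
}
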