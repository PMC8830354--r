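#' Gompertz life-table fixture
#'
#' Builds an age-indexed table of annual background death probabilities
#' `q(age) = min(1, a * exp(b * age))`. The default shape is anchored at
#' q(57) = 0.005 and q(85) = 0.08, a plausible adult mortality schedule for a
#' recent Chinese census life table (which is not reproduced here); any
#' user-supplied table can be used instead via [read_life_table()].
#'
#' @param a Gompertz level parameter, positive. Default anchors the curve as
#'   described above.
#' @param b Gompertz slope parameter, positive.
#' @param ages Integer ages covered; must span the model horizon.
#' @return An object of class `mia_life_table`: data frame with columns
#'   `age` and `q`.
#' @export
#' @examples
#' lt <- build_fixture_table()
#' lt$q[lt$age == 57] # 0.005
build_fixture_table <- function(a = NULL, b = NULL, ages = 57:99) {
  if (is.null(b)) b <- log(0.08 / 0.005) / (85 - 57)
  if (is.null(a)) a <- 0.005 / exp(57 * b)
  if (!is.finite(a) || a <= 0) stop("Gompertz parameter a must be positive")
  if (!is.finite(b) || b <= 0) stop("Gompertz parameter b must be positive")
  out <- data.frame(age = as.integer(ages), q = pmin(1, a * exp(b * ages)))
  class(out) <- c("mia_life_table", "data.frame")
  out
}

.validate_life_table <- function(table) {
  if (!all(c("age", "q") %in% names(table))) stop("life table needs columns age, q")
  if (any(!is.finite(table$q)) || any(table$q < 0 | table$q > 1)) {
    stop("life-table q must lie in [0, 1]")
  }
  if (any(diff(table$age) != 1L)) stop("life-table ages must be consecutive")
  invisible(table)
}

#' Read a life table from CSV
#'
#' @param path CSV with columns `age,q`; `#`-prefixed comment lines allowed.
#' @return A `mia_life_table`.
#' @export
read_life_table <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .validate_life_table(out)
  class(out) <- c("mia_life_table", "data.frame")
  out
}

#' Write a life table to CSV
#'
#' @param table A `mia_life_table`.
#' @param path Output path.
#' @export
write_life_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("age", "q")], path, row.names = FALSE)
  invisible(path)
}

#' Cause-deleted background mortality
#'
#' Removes the fraction of deaths attributable to aneurysmal SAH from the
#' all-cause probabilities, `q' = q * (1 - sah_fraction)`, so that rupture
#' deaths generated inside the model are not counted twice.
#'
#' @param table A `mia_life_table`.
#' @param sah_fraction Fraction of background deaths attributed to aneurysmal
#'   SAH, in `[0, 1)`.
#' @return The adjusted `mia_life_table`.
#' @export
cause_deleted_adjustment <- function(table, sah_fraction) {
  .validate_life_table(table)
  if (!is.finite(sah_fraction) || sah_fraction < 0 || sah_fraction >= 1) {
    stop("sah_fraction must lie in [0, 1)")
  }
  table$q <- table$q * (1 - sah_fraction)
  table
}

.q_at <- function(table, age) {
  i <- match(age, table$age)
  if (any(is.na(i))) stop("age ", paste(age[is.na(i)], collapse = ", "),
                          " outside the life-table span")
  table$q[i]
}

#' Disability-adjusted annual death probability
#'
#' Multiplies the background probability by the disability-specific mortality
#' risk ratio (none: 1; mild: 2.02; moderate-to-severe: 4.46 at the default
#' point estimates), capped at 1. The multiplicative form on annual
#' probabilities mirrors the published "adjusted by k-fold" wording; setting
#' `hazard_transform = TRUE` in the model settings uses `1 - (1 - q)^RR`
#' instead.
#'
#' @param age Age in years, within the table span.
#' @param level One of `"none"`, `"mild"`, `"moderate_severe"`.
#' @param table A `mia_life_table` (typically already cause-deleted).
#' @param params A `mia_parameters` object supplying the risk ratios.
#' @return Annual death probability in `[0, 1]`.
#' @export
disability_adjusted_mortality <- function(age, level = c("none", "mild", "moderate_severe"),
                                          table, params) {
  level <- match.arg(level)
  q <- .q_at(table, age)
  cl <- params$clinical
  rr <- switch(level,
    none = 1,
    mild = cl$mean[cl$name == "rr_death_mild"],
    moderate_severe = cl$mean[cl$name == "rr_death_modsev"]
  )
  .apply_rr(q, rr, params$settings$hazard_transform)
}

# risk-ratio application on an annual probability
.apply_rr <- function(p, rr, hazard = FALSE) {
  if (isTRUE(hazard)) 1 - (1 - pmin(p, 1))^rr else pmin(1, p * rr)
}
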