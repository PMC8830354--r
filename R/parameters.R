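#' Built-in clinical parameter table
#'
#' Returns the default input-parameter table of the decision model: annual
#' event rates for small intracranial aneurysms, risk ratios for patients
#' with multiple aneurysms (MIAs), outcome proportions of endovascular
#' coiling (elective, one or two aneurysms, and after subarachnoid
#' haemorrhage), disability-specific mortality risk ratios, and health-state
#' utilities. Each row carries a point estimate (`mean`), a plausible range
#' (`low`, `high`) used by the one-way and two-way sweeps, an uncertainty
#' distribution family (`beta`, `lognormal`, `triangular` or `fixed`) used by
#' the probabilistic sensitivity analysis, and, for beta/lognormal rows, the
#' standard deviation on the natural scale.
#'
#' @return A data frame with columns `name`, `mean`, `low`, `high`, `family`,
#'   `sd`. Utility rows are identified by the `utility_` name prefix.
#' @export
#' @examples
#' default_parameter_table()
default_parameter_table <- function() {
  rows <- list(
    # name,                      mean,  low,   high,  family,      sd
    c("growth_rate_small",       0.026, 0.017, 0.04,  "beta",      0.004),
    c("rupture_rate_nongrowing", 0.005, 0.003, 0.009, "beta",      0.001),
    c("rupture_rate_growing",    0.063, 0.01,  0.22,  "beta",      0.035),
    c("rr_growth_mia",           3.47,  1.87,  6.45,  "lognormal", 1.15),
    c("rr_rupture_mia",          2.08,  1.46,  2.96,  "lognormal", 0.25),
    c("de_novo_rate",            0.003, 0.002, 0.004, "beta",      0.0004),
    c("rr_de_novo_mia",          3.92,  1.95,  7.87,  "lognormal", 0.99),
    c("mild_after_treat_one",    0.016, 0,     0.037, "beta",      0.011),
    c("modsev_after_treat_one",  0.047, 0.01,  0.083, "beta",      0.019),
    c("mortality_after_treat_one", 0,   0,     0.005, "beta",      0.001),
    c("mild_after_treat_two",    0.032, 0,     0.067, "beta",      0.018),
    c("modsev_after_treat_two",  0.053, 0.008, 0.098, "beta",      0.023),
    c("mortality_after_treat_two", 0.011, 0,   0.031, "beta",      0.01),
    c("mild_after_sah",          0.15,  0.13,  0.17,  "beta",      0.007),
    c("modsev_after_sah",        0.09,  0.07,  0.11,  "beta",      0.007),
    c("mortality_after_sah",     0.35,  0.25,  0.45,  "beta",      0.033),
    c("rr_death_mild",           2.02,  1.7,   2.4,   "lognormal", 0.109),
    c("rr_death_modsev",         4.46,  4.05,  4.91,  "lognormal", 0.128),
    c("utility_full_recovery",   1,     1,     1,     "fixed",     NA),
    c("utility_mild",            0.72,  0.65,  0.80,  "triangular", NA),
    c("utility_modsev",          0.41,  0.25,  0.65,  "triangular", NA),
    c("utility_sah",             0.64,  0.52,  0.71,  "triangular", NA)
  )
  out <- data.frame(
    name   = vapply(rows, `[`, "", 1),
    mean   = as.numeric(vapply(rows, `[`, "", 2)),
    low    = as.numeric(vapply(rows, `[`, "", 3)),
    high   = as.numeric(vapply(rows, `[`, "", 4)),
    family = vapply(rows, `[`, "", 5),
    sd     = as.numeric(vapply(rows, `[`, "", 6)),
    stringsAsFactors = FALSE
  )
  out
}

.clinical_names <- function() {
  tab <- default_parameter_table()
  tab$name[!startsWith(tab$name, "utility_")]
}

#' Default model settings
#'
#' Cohort entry age, horizon, cycle length, annual discount rate, the
#' temporary disutility of a coiling procedure, and the fraction of background
#' mortality attributed to aneurysmal SAH (removed by cause deletion so that
#' rupture deaths are not double-counted). Model-structure switches:
#' `hazard_transform` applies risk ratios as `1 - (1 - p)^RR` instead of the
#' default multiplicative `min(1, RR * p)`; `rr_on_growing` additionally
#' scales the growing-aneurysm rupture rate by the MIA rupture risk ratio.
#'
#' @param ... Named overrides of individual settings.
#' @return A list of settings.
#' @export
default_settings <- function(...) {
  s <- list(
    start_age = 57,
    max_age = 99,
    cycle_length = 1,
    discount_rate = 0.03,
    procedure_disutility = 0.05,
    sah_fraction = 0.003,
    hazard_transform = FALSE,
    rr_on_growing = FALSE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(s))
  if (length(bad)) stop("unknown setting(s): ", paste(bad, collapse = ", "))
  s[names(dots)] <- dots
  s
}

.validate_parameter_row <- function(row) {
  nm <- row$name
  if (is.na(nm) || !nzchar(nm)) stop("parameter row without a name")
  fam <- row$family
  if (!fam %in% c("beta", "lognormal", "triangular", "fixed")) {
    stop(sprintf("parameter '%s': unknown distribution family '%s'", nm, fam))
  }
  if (any(is.na(c(row$mean, row$low, row$high)))) {
    stop(sprintf("parameter '%s': mean/low/high must all be given", nm))
  }
  if (row$low > row$mean || row$mean > row$high) {
    stop(sprintf("parameter '%s': requires low <= mean <= high (%g, %g, %g)",
                 nm, row$low, row$mean, row$high))
  }
  if (fam %in% c("beta", "lognormal") && (is.na(row$sd) || row$sd <= 0)) {
    stop(sprintf("parameter '%s': family '%s' requires sd > 0", nm, fam))
  }
  if (fam == "beta") {
    if (row$low < 0 || row$high > 1) {
      stop(sprintf("parameter '%s': beta range must lie in [0, 1]", nm))
    }
    # a zero-mean beta is degenerate; it is sampled with a small epsilon mean
    m <- if (row$mean == 0) 5e-4 else row$mean
    if (row$sd^2 >= m * (1 - m)) {
      stop(sprintf("parameter '%s': sd^2 = %g is infeasible for a beta with mean %g",
                   nm, row$sd^2, m))
    }
  }
  if (fam == "lognormal" && row$mean <= 0) {
    stop(sprintf("parameter '%s': lognormal mean must be positive", nm))
  }
  invisible(TRUE)
}

#' Load and validate the model parameter set
#'
#' Builds the full parameter set of the decision model from the built-in
#' default table (reproducing the published point estimates, ranges and
#' distributions) or from a user-supplied CSV file with columns
#' `name,mean,low,high,family,sd`.
#'
#' @param source `NULL` for the built-in defaults, a path to a parameter CSV,
#'   or a data frame with the same columns.
#' @param settings Model settings, see [default_settings()].
#' @return An object of class `mia_parameters`: a list with elements
#'   `clinical` (data frame of the 18 clinical rows), `utilities` (data frame
#'   of the 4 utility rows) and `settings`.
#' @export
#' @examples
#' p <- load_base_parameters()
#' subset(p$clinical, name == "growth_rate_small")
load_base_parameters <- function(source = NULL, settings = default_settings()) {
  tab <- if (is.null(source)) {
    default_parameter_table()
  } else if (is.data.frame(source)) {
    source
  } else {
    utils::read.csv(source, stringsAsFactors = FALSE, comment.char = "#")
  }
  need <- c("name", "mean", "low", "high", "family", "sd")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  tab <- tab[need]
  for (i in seq_len(nrow(tab))) .validate_parameter_row(tab[i, ])
  if (anyDuplicated(tab$name)) {
    stop("duplicated parameter name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  is_util <- startsWith(tab$name, "utility_")
  clinical <- tab[!is_util, , drop = FALSE]
  utilities <- tab[is_util, , drop = FALSE]
  miss <- setdiff(.clinical_names(), clinical$name)
  if (length(miss)) stop("missing clinical parameter(s): ", paste(miss, collapse = ", "))
  if (any(utilities$mean < 0 | utilities$mean > 1)) {
    stop("utilities must lie in [0, 1]")
  }
  fr <- utilities[utilities$name == "utility_full_recovery", ]
  if (nrow(fr) != 1L || fr$mean != 1 || fr$family != "fixed") {
    stop("the full-recovery utility must be present, fixed, and equal to 1")
  }
  # each treatment branch must leave room for the full-recovery complement
  for (k in c("treat_one", "treat_two", "sah")) {
    nms <- paste0(c("mortality_after_", "mild_after_", "modsev_after_"), k)
    tot <- sum(clinical$mean[clinical$name %in% nms])
    if (tot > 1) stop(sprintf("outcome probabilities of the %s branch sum to %g > 1", k, tot))
  }
  rownames(clinical) <- rownames(utilities) <- NULL
  structure(list(clinical = clinical, utilities = utilities, settings = settings),
            class = "mia_parameters")
}

#' @export
print.mia_parameters <- function(x, ...) {
  cat("<mia_parameters>", nrow(x$clinical), "clinical parameters,",
      nrow(x$utilities), "utilities\n")
  cat("  start age", x$settings$start_age, "| horizon to age", x$settings$max_age,
      "| discount", x$settings$discount_rate, "\n")
  invisible(x)
}

#' Method-of-moments beta shapes
#'
#' Converts a (mean, sd) pair into the `(alpha, beta)` shape parameters of the
#' beta distribution having exactly those two moments:
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean nu`, `beta = (1 - mean) nu`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' beta_from_moments(0.5, 0.25) # c(alpha = 1.5, beta = 1.5)
beta_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta_from_moments: mean must lie strictly inside (0, 1)")
  }
  if (!is.finite(sd) || sd <= 0) stop("beta_from_moments: sd must be positive")
  if (sd^2 >= mean * (1 - mean)) {
    stop(sprintf("beta_from_moments: infeasible moments, sd^2 = %g >= mean(1-mean) = %g",
                 sd^2, mean * (1 - mean)))
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Moment-matched lognormal parameters
#'
#' Converts a (mean, sd) pair given on the natural (ratio) scale into the
#' log-scale parameters of the lognormal distribution with those moments:
#' `sigma_log^2 = log(1 + sd^2 / mean^2)`, `mu_log = log(mean) - sigma_log^2 / 2`.
#'
#' @param mean Mean on the natural scale, positive.
#' @param sd Standard deviation on the natural scale, positive.
#' @return Named numeric vector `c(mu_log, sigma_log)`.
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("lognormal_from_moments: mean must be positive")
  if (!is.finite(sd) || sd <= 0) stop("lognormal_from_moments: sd must be positive")
  s2 <- log(1 + sd^2 / mean^2)
  c(mu_log = log(mean) - s2 / 2, sigma_log = sqrt(s2))
}

.rtriangular <- function(n, low, mode, high) {
  if (high == low) return(rep(low, n))
  u <- stats::runif(n)
  f <- (mode - low) / (high - low)
  ifelse(u < f,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' Draw from a parameter's uncertainty distribution
#'
#' Beta and lognormal rows are sampled from their moment-matched shapes;
#' triangular rows use minimum = `low`, mode = `mean`, maximum = `high`;
#' `fixed` rows return the mean. A beta row with mean exactly 0 (possible for
#' an observed zero event count) is sampled with a small epsilon mean of
#' 0.0005 so the distribution is defined; the base case keeps the exact 0.
#' Draws are not truncated to `[low, high]`; probabilities are clamped to
#' `[0, 1]` where they enter the transition model, not here.
#'
#' Uses R's global random stream: call `set.seed()` for reproducibility.
#'
#' @param spec One row of a parameter table (data frame or list with fields
#'   `name`, `mean`, `low`, `high`, `family`, `sd`).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n = 1) {
  spec <- as.list(spec)
  .validate_parameter_row(spec)
  switch(spec$family,
    fixed = rep(spec$mean, n),
    triangular = .rtriangular(n, spec$low, spec$mean, spec$high),
    beta = {
      m <- if (spec$mean == 0) 5e-4 else spec$mean
      sh <- beta_from_moments(m, spec$sd)
      stats::rbeta(n, sh[["alpha"]], sh[["beta"]])
    },
    lognormal = {
      lp <- lognormal_from_moments(spec$mean, spec$sd)
      stats::rlnorm(n, lp[["mu_log"]], lp[["sigma_log"]])
    }
  )
}

#' Joint draw of the full parameter set
#'
#' Draws every distributed parameter `n` times, independently across
#' parameters (the published estimates carry no correlation information).
#' Within each treatment-outcome branch (elective one- or two-aneurysm
#' coiling, post-SAH coiling) any draw whose death/mild/moderate-severe
#' probabilities sum above 1 is renormalised to sum to 1 (full recovery 0)
#' and counted; the count is returned as attribute `n_renormalised`.
#'
#' @param params A `mia_parameters` object.
#' @param n Number of joint draws.
#' @return Data frame with one column per parameter and `n` rows, attribute
#'   `n_renormalised`.
#' @export
sample_parameter_set <- function(params, n) {
  stopifnot(inherits(params, "mia_parameters"), n >= 1)
  tab <- rbind(params$clinical, params$utilities)
  draws <- lapply(seq_len(nrow(tab)), function(i) sample_parameter(tab[i, ], n))
  names(draws) <- tab$name
  draws <- as.data.frame(draws)
  n_fix <- 0L
  for (k in c("treat_one", "treat_two", "sah")) {
    nms <- paste0(c("mortality_after_", "mild_after_", "modsev_after_"), k)
    tot <- rowSums(draws[nms])
    bad <- tot > 1
    if (any(bad)) {
      draws[bad, nms] <- draws[bad, nms] / tot[bad]
      n_fix <- n_fix + sum(bad)
    }
  }
  attr(draws, "n_renormalised") <- n_fix
  draws
}

# point-estimate draw: one row of base-case means
.base_values <- function(params) {
  tab <- rbind(params$clinical, params$utilities)
  vals <- as.list(tab$mean)
  names(vals) <- tab$name
  as.data.frame(vals)
}
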