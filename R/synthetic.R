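#' Generate a synthetic endovascular-treatment cohort
#'
#' Emulates the patient-level records behind the treatment-outcome rows of
#' the parameter table: `n_one` patients with one aneurysm coiled and `n_two`
#' with both coiled, each drawing an mRS-banded outcome (full recovery, mild
#' disability, moderate-to-severe disability, death) independently from the
#' corresponding branch distribution. Ages are normal around 55.98 (SD 9.99)
#' years and follow-up around 31.24 (SD 22.93) months, truncated below at
#' plausible minima; sex and the other covariates carried by such registries
#' do not enter the decision model and only `sex` is generated, as a cosmetic
#' field.
#'
#' @param n_one,n_two Number of one-treated and two-treated patients.
#' @param params A `mia_parameters` supplying the branch outcome
#'   probabilities.
#' @param seed Integer seed.
#' @return Data frame with columns `age`, `sex`, `treated_count`, `outcome`,
#'   `follow_up_months`.
#' @export
#' @examples
#' head(generate_treatment_cohort(129, 95, seed = 7))
generate_treatment_cohort <- function(n_one = 129, n_two = 95,
                                      params = load_base_parameters(),
                                      seed = 1) {
  stopifnot(n_one >= 0, n_two >= 0, n_one + n_two > 0)
  set.seed(seed)
  levs <- c("full_recovery", "mild", "moderate_severe", "death")
  draw_branch <- function(kind, n) {
    p <- treatment_outcome_branch(kind, params)
    sample(levs, n, replace = TRUE, prob = p[levs])
  }
  n <- n_one + n_two
  out <- data.frame(
    age = round(pmax(18, stats::rnorm(n, 55.98, 9.99))),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.656, 0.344)),
    treated_count = rep(c(1L, 2L), c(n_one, n_two)),
    outcome = factor(c(draw_branch("treat_one", n_one),
                       draw_branch("treat_two", n_two)), levels = levs),
    follow_up_months = pmax(1, stats::rnorm(n, 31.24, 22.93)),
    stringsAsFactors = FALSE
  )
  out
}

#' Estimate treatment-outcome proportions from patient records
#'
#' The estimation step that turns a treated cohort into parameter-table rows:
#' per branch (one or two aneurysms treated) the proportion of each
#' non-recovery outcome with its binomial standard deviation
#' `sqrt(p (1 - p) / n)`.
#'
#' @param records Data frame as produced by [generate_treatment_cohort()].
#' @return Data frame with columns `name`, `mean`, `low`, `high`, `family`,
#'   `sd`, `n`, directly consumable as clinical parameter rows (ranges are
#'   the 95% binomial interval clipped to `[0, 1]`).
#' @export
estimate_outcome_proportions <- function(records) {
  stopifnot(all(c("treated_count", "outcome") %in% names(records)))
  map <- c(mild = "mild_after_treat_%s",
           moderate_severe = "modsev_after_treat_%s",
           death = "mortality_after_treat_%s")
  out <- list()
  for (k in c(1L, 2L)) {
    branch <- records[records$treated_count == k, ]
    n <- nrow(branch)
    if (n == 0L) stop("no records with treated_count = ", k)
    for (oc in names(map)) {
      p <- mean(branch$outcome == oc)
      sd <- sqrt(p * (1 - p) / n)
      out[[length(out) + 1L]] <- data.frame(
        name = sprintf(map[[oc]], c("one", "two")[k]),
        mean = p,
        low = max(0, p - 1.96 * sd),
        high = min(1, p + 1.96 * sd),
        family = "beta",
        sd = sd,
        n = n,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Gompertz life-table generator
#'
#' Pipeline-convenience re-export of [build_fixture_table()].
#'
#' @inheritParams build_fixture_table
#' @return A `mia_life_table`.
#' @export
generate_life_table <- function(a = NULL, b = NULL, ages = 57:99) {
  build_fixture_table(a = a, b = b, ages = ages)
}
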