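#' The six compared management strategies
#'
#' Returns the strategy table in the fixed comparison (and tie-breaking)
#' order: treat both aneurysms, treat one aneurysm, annual / biennial /
#' five-yearly imaging follow-up, natural history.
#'
#' `screening_interval` is the MRA schedule (in years) under which growth of
#' an untreated multiple-aneurysm carrier is detected; it is `NA` for the
#' arms without scheduled imaging of the intact carrier state.
#' `entry_procedure` is the elective coiling applied at cycle 0.
#' `single_growing_detected` records whether growth of the remaining
#' untreated aneurysm in a treated, fully recovered patient is itself under
#' surveillance and triggers coiling: this holds in the treat-one arm (the
#' annual follow-up there looks for growth of the untreated aneurysm or de
#' novo formation), whereas after a growth-triggered treatment in the
#' follow-up arms the annual follow-up looks for de novo formation only.
#'
#' @return Data frame with columns `id`, `screening_interval`,
#'   `entry_procedure`, `single_growing_detected`.
#' @export
#' @examples
#' list_strategies()
list_strategies <- function() {
  data.frame(
    id = c("treat_two", "treat_one", "follow_up_1y", "follow_up_2y",
           "follow_up_5y", "natural_history"),
    screening_interval = c(NA, NA, 1L, 2L, 5L, NA),
    entry_procedure = c("treat_two", "treat_one", "none", "none", "none", "none"),
    single_growing_detected = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

.strategy <- function(id) {
  st <- list_strategies()
  i <- match(id, st$id)
  if (is.na(i)) stop("unknown strategy '", id, "'")
  st[i, ]
}

#' Is a screening visit due at a given cycle?
#'
#' Screening never occurs at cycle 0 (the decision point itself); thereafter
#' it fires at every multiple of the interval, so over a 43-cycle horizon an
#' annual schedule fires 42 times, biennial 21, five-yearly 8.
#'
#' @param cycle_index Non-negative integer cycle.
#' @param interval Screening interval in years, >= 1.
#' @return Logical.
#' @export
screening_due <- function(cycle_index, interval) {
  if (any(!is.finite(interval)) || any(interval < 1)) {
    stop("screening interval must be >= 1")
  }
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  cycle_index > 0 & cycle_index %% interval == 0
}
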