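#' The nine health states of the cohort model
#'
#' `well_mia`: intact carrier of two small unruptured aneurysms;
#' `well_growing_mia`: carrier with a growing aneurysm (both untreated);
#' `well_single_growing`: treated patient whose remaining untreated aneurysm
#' is growing; `well_one_treated` / `well_both_treated`: fully recovered after
#' coiling of one / both aneurysms; `sah`: subarachnoid haemorrhage, a
#' one-cycle transient (tunnel) state resolved by coiling of both aneurysms;
#' `mild_disability` / `modsev_disability`: permanent disability (mRS 2 /
#' mRS 3-5); `death` is absorbing.
#'
#' @return Character vector of the nine state names, in fixed order.
#' @export
health_states <- function() {
  c("well_mia", "well_growing_mia", "well_single_growing", "well_one_treated",
    "well_both_treated", "sah", "mild_disability", "modsev_disability", "death")
}

# state utilities for one draw (list of scalars or vectors)
.state_utilities <- function(v) {
  list(
    well_mia = v$utility_full_recovery,
    well_growing_mia = v$utility_full_recovery,
    well_single_growing = v$utility_full_recovery,
    well_one_treated = v$utility_full_recovery,
    well_both_treated = v$utility_full_recovery,
    sah = v$utility_sah,
    mild_disability = v$utility_mild,
    modsev_disability = v$utility_modsev,
    death = 0
  )
}

# derived per-cycle event probabilities and outcome branches from raw values
.derived_values <- function(v, settings) {
  ht <- settings$hazard_transform
  list(
    p_rupt_mia = .apply_rr(v$rupture_rate_nongrowing, v$rr_rupture_mia, ht),
    p_grow_mia = .apply_rr(v$growth_rate_small, v$rr_growth_mia, ht),
    p_rupt_growing = if (isTRUE(settings$rr_on_growing)) {
      .apply_rr(v$rupture_rate_growing, v$rr_rupture_mia, ht)
    } else {
      pmin(1, v$rupture_rate_growing)
    },
    p_rupt_single = pmin(1, v$rupture_rate_nongrowing),
    p_grow_single = pmin(1, v$growth_rate_small),
    p_de_novo = .apply_rr(v$de_novo_rate, v$rr_de_novo_mia, ht),
    b_one = list(death = v$mortality_after_treat_one,
                 mild = v$mild_after_treat_one,
                 modsev = v$modsev_after_treat_one,
                 full = 1 - (v$mortality_after_treat_one + v$mild_after_treat_one +
                               v$modsev_after_treat_one)),
    b_two = list(death = v$mortality_after_treat_two,
                 mild = v$mild_after_treat_two,
                 modsev = v$modsev_after_treat_two,
                 full = 1 - (v$mortality_after_treat_two + v$mild_after_treat_two +
                               v$modsev_after_treat_two)),
    b_sah = list(death = v$mortality_after_sah,
                 mild = v$mild_after_sah,
                 modsev = v$modsev_after_sah,
                 full = 1 - (v$mortality_after_sah + v$mild_after_sah +
                               v$modsev_after_sah)),
    rr_death_mild = v$rr_death_mild,
    rr_death_modsev = v$rr_death_modsev
  )
}

#' Outcome distribution of a coiling procedure
#'
#' Probabilities of the four modified-Rankin-banded outcomes of endovascular
#' coiling, with full recovery as the complement of the death, mild and
#' moderate-to-severe disability point estimates.
#'
#' @param kind `"treat_one"` (elective, one aneurysm), `"treat_two"`
#'   (elective, both aneurysms) or `"sah_coiling"` (coiling after rupture).
#' @param params A `mia_parameters` object.
#' @return Named numeric vector over `full_recovery`, `mild`,
#'   `moderate_severe`, `death`, summing to 1.
#' @export
#' @examples
#' treatment_outcome_branch("treat_two", load_base_parameters())
treatment_outcome_branch <- function(kind = c("treat_one", "treat_two", "sah_coiling"),
                                     params) {
  kind <- match.arg(kind)
  v <- .base_values(params)
  d <- .derived_values(v, params$settings)
  b <- switch(kind, treat_one = d$b_one, treat_two = d$b_two, sah_coiling = d$b_sah)
  if (b$full < 0) {
    stop(sprintf("%s outcome probabilities sum above 1 (full recovery %g)", kind, b$full))
  }
  c(full_recovery = b$full, mild = b$mild, moderate_severe = b$modsev, death = b$death)
}

# flows out of one state for one cycle: list of (dest, prob, procedure)
# qa: annual background death probability at this age (already cause-deleted)
# detect_growing: does scheduled screening fire on well_growing_mia this cycle
.transition_flows <- function(strat, state, qa, detect_growing, d, settings) {
  flow <- function(dest, prob, procedure = FALSE) {
    data.frame(dest = dest, prob = prob, procedure = procedure,
               stringsAsFactors = FALSE)
  }
  branch_to <- function(mass, b, full_dest) {
    rbind(flow("death", mass * b$death),
          flow("mild_disability", mass * b$mild, TRUE),
          flow("modsev_disability", mass * b$modsev, TRUE),
          flow(full_dest, mass * b$full, TRUE))
  }
  ht <- settings$hazard_transform
  switch(state,
    death = flow("death", 1),
    mild_disability = {
      pd <- .apply_rr(qa, d$rr_death_mild, ht)
      rbind(flow("death", pd), flow("mild_disability", 1 - pd))
    },
    modsev_disability = {
      pd <- .apply_rr(qa, d$rr_death_modsev, ht)
      rbind(flow("death", pd), flow("modsev_disability", 1 - pd))
    },
    sah = {
      # tunnel resolution: coiling of both aneurysms at the end of the SAH cycle
      sv <- 1 - qa
      rbind(flow("death", qa), branch_to(sv, d$b_sah, "well_both_treated"))
    },
    well_mia = {
      sv <- 1 - qa
      s2 <- sv * (1 - d$p_rupt_mia)
      rbind(flow("death", qa),
            flow("sah", sv * d$p_rupt_mia),
            flow("well_growing_mia", s2 * d$p_grow_mia),
            flow("well_mia", s2 * (1 - d$p_grow_mia)))
    },
    well_growing_mia = {
      sv <- 1 - qa
      s2 <- sv * (1 - d$p_rupt_growing)
      out <- rbind(flow("death", qa), flow("sah", sv * d$p_rupt_growing))
      if (detect_growing) {
        rbind(out, branch_to(s2, d$b_one, "well_one_treated"))
      } else {
        rbind(out, flow("well_growing_mia", s2))
      }
    },
    well_single_growing = {
      sv <- 1 - qa
      s2 <- sv * (1 - d$p_rupt_growing)
      out <- rbind(flow("death", qa), flow("sah", sv * d$p_rupt_growing))
      if (isTRUE(strat$single_growing_detected)) {
        # treated, fully recovered patients are on annual surveillance
        rbind(out, branch_to(s2, d$b_one, "well_both_treated"))
      } else {
        rbind(out, flow("well_single_growing", s2))
      }
    },
    well_one_treated = {
      sv <- 1 - qa
      s2 <- sv * (1 - d$p_rupt_single)
      s3 <- s2 * (1 - d$p_grow_single)
      dn <- s3 * d$p_de_novo
      out <- rbind(flow("death", qa),
                   flow("sah", sv * d$p_rupt_single),
                   flow("well_single_growing", s2 * d$p_grow_single),
                   branch_to(dn, d$b_one, "well_one_treated"),
                   flow("well_one_treated", s3 * (1 - d$p_de_novo)))
      out
    },
    well_both_treated = {
      sv <- 1 - qa
      dn <- sv * d$p_de_novo
      rbind(flow("death", qa),
            branch_to(dn, d$b_one, "well_both_treated"),
            flow("well_both_treated", sv * (1 - d$p_de_novo)))
    },
    stop("unknown state '", state, "'")
  )
}

#' One-cycle transition row of the cohort model
#'
#' Returns the outgoing probability flows of one health state for one cycle
#' under one strategy, composed in the fixed competing-event order background
#' death, rupture, growth/detection, de novo formation (as conditional
#' sequential probabilities). The `procedure` flag marks arcs on which a
#' coiling procedure occurs, which attracts the temporary procedure
#' disutility in the arrival cycle.
#'
#' Screening detection applies at the end of the cycle: patients occupying a
#' growing state during cycle `t` are detected (and coiled) in the transition
#' into cycle `t + 1` whenever a screening visit is due then.
#'
#' @param strategy Strategy id, see [list_strategies()].
#' @param state One of [health_states()].
#' @param age Age in years at the start of the cycle.
#' @param params A `mia_parameters` object (point estimates are used).
#' @param table A `mia_life_table` of all-cause background mortality; the SAH
#'   cause-deletion from the model settings is applied internally.
#' @param cycle Cycle index, defaulting to `age - start_age`.
#' @return Data frame with columns `origin`, `dest`, `prob`, `procedure`;
#'   probabilities sum to 1 within 1e-12.
#' @export
#' @examples
#' p <- load_base_parameters()
#' transition_row("natural_history", "well_mia", 57, p, build_fixture_table())
transition_row <- function(strategy, state, age, params, table,
                           cycle = age - params$settings$start_age) {
  strat <- .strategy(strategy)
  if (!state %in% health_states()) stop("unknown state '", state, "'")
  settings <- params$settings
  cd <- cause_deleted_adjustment(table, settings$sah_fraction)
  qa <- .q_at(cd, age)
  d <- .derived_values(.base_values(params), settings)
  detect <- !is.na(strat$screening_interval) &&
    screening_due(cycle + 1, strat$screening_interval)
  out <- .transition_flows(strat, state, qa, detect, d, settings)
  out <- cbind(origin = state, out)
  if (any(out$prob < -1e-12 | out$prob > 1 + 1e-12)) {
    stop("transition probabilities escaped [0, 1] for state '", state, "'")
  }
  if (abs(sum(out$prob) - 1) > 1e-12) {
    stop("transition row of state '", state, "' does not sum to 1")
  }
  rownames(out) <- NULL
  out
}

#' Run the annual-cycle cohort simulation for one strategy
#'
#' Starts a cohort of carriers of two small unruptured aneurysms at the entry
#' age, applies the strategy's entry procedure at cycle 0 (elective coiling
#' for the treat arms, none otherwise), and propagates state occupancy one
#' cycle per year of age until the horizon. The trace also records, per
#' cycle, the utility-weighted occupancy that arrived through a coiling
#' procedure, which [discounted_qalys()] uses for the temporary procedure
#' disutility.
#'
#' @inheritParams transition_row
#' @param table A `mia_life_table`; defaults to the bundled Gompertz fixture.
#' @return An object of class `mia_trace`: list with `occupancy` (cycles x
#'   states matrix, rows summing to 1), `proc_utility` (per-cycle vector),
#'   `strategy`, `ages`.
#' @export
run_cohort <- function(strategy, params, table = build_fixture_table()) {
  strat <- .strategy(strategy)
  settings <- params$settings
  states <- health_states()
  ages <- settings$start_age:settings$max_age
  ncyc <- length(ages)
  cd <- cause_deleted_adjustment(table, settings$sah_fraction)
  v <- .base_values(params)
  u <- unlist(.state_utilities(v))[states]

  occ <- matrix(0, ncyc, length(states), dimnames = list(NULL, states))
  proc_u <- numeric(ncyc)
  if (strat$entry_procedure == "none") {
    occ[1, "well_mia"] <- 1
  } else {
    b <- treatment_outcome_branch(strat$entry_procedure, params)
    full_dest <- if (strat$entry_procedure == "treat_two") {
      "well_both_treated"
    } else {
      "well_one_treated"
    }
    occ[1, "death"] <- b[["death"]]
    occ[1, "mild_disability"] <- b[["mild"]]
    occ[1, "modsev_disability"] <- b[["moderate_severe"]]
    occ[1, full_dest] <- b[["full_recovery"]]
    proc_u[1] <- sum(occ[1, ] * u)
  }

  for (t in 0:(ncyc - 2)) {
    nxt <- numeric(length(states))
    names(nxt) <- states
    pu <- 0
    for (s in states) {
      m <- occ[t + 1, s]
      if (m == 0) next
      fl <- transition_row(strategy, s, ages[t + 1], params, table, cycle = t)
      # transition_row re-applies cause deletion internally; table is all-cause
      agg <- tapply(m * fl$prob, fl$dest, sum)
      nxt[names(agg)] <- nxt[names(agg)] + agg
      pu <- pu + sum(m * fl$prob[fl$procedure] * u[fl$dest[fl$procedure]])
    }
    occ[t + 2, ] <- nxt
    proc_u[t + 2] <- pu
    if (abs(sum(nxt) - 1) > 1e-9) stop("occupancy row does not sum to 1 at cycle ", t + 1)
  }
  structure(list(occupancy = occ, proc_utility = proc_u,
                 strategy = strategy, ages = ages),
            class = "mia_trace")
}

#' @export
print.mia_trace <- function(x, ...) {
  cat("<mia_trace>", x$strategy, "-", nrow(x$occupancy), "cycles, ages",
      min(x$ages), "to", max(x$ages), "\n")
  cat("  final death occupancy:", round(x$occupancy[nrow(x$occupancy), "death"], 4), "\n")
  invisible(x)
}

#' Discounted quality-adjusted life-years of a cohort trace
#'
#' Accumulates `sum_t (1 + r)^(-t) * (occupancy(t) . utility - 0.05 *
#' procedure_inflow_utility(t))` with `t = 0` at model entry: each cycle's
#' occupancy earns the state utilities, and occupancy that arrived through a
#' coiling procedure loses the temporary procedure disutility that cycle.
#' No half-cycle correction is applied.
#'
#' @param trace A `mia_trace` from [run_cohort()].
#' @param params The `mia_parameters` used to run the trace.
#' @return One-row data frame with columns `strategy`, `qalys`.
#' @export
discounted_qalys <- function(trace, params) {
  stopifnot(inherits(trace, "mia_trace"))
  v <- .base_values(params)
  u <- unlist(.state_utilities(v))[colnames(trace$occupancy)]
  r <- params$settings$discount_rate
  t <- seq_len(nrow(trace$occupancy)) - 1
  per_cycle <- as.numeric(trace$occupancy %*% u) -
    params$settings$procedure_disutility * trace$proc_utility
  data.frame(strategy = trace$strategy,
             qalys = sum((1 + r)^(-t) * per_cycle))
}

#' Evaluate the discounted QALYs of each strategy
#'
#' Deterministic expected values at the parameter point estimates, in the
#' fixed strategy order. This is the base-case comparison surface; the
#' sensitivity analyses re-evaluate it under perturbed or sampled parameters.
#'
#' @param params A `mia_parameters` object.
#' @param table A `mia_life_table`; defaults to the bundled Gompertz fixture.
#' @param strategies Character vector of strategy ids to evaluate.
#' @return Data frame with columns `strategy`, `qalys`.
#' @export
#' @examples
#' evaluate_strategies(load_base_parameters())
evaluate_strategies <- function(params, table = build_fixture_table(),
                                strategies = list_strategies()$id) {
  ev <- .ev_matrix(.base_values(params), params$settings, table, strategies)
  data.frame(strategy = strategies, qalys = as.numeric(ev[1, ]))
}
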