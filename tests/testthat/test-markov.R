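test_that("treatment outcome branches are the point estimates plus complement", {
  p <- load_base_parameters()
  b2 <- treatment_outcome_branch("treat_two", p)
  expect_equal(b2, c(full_recovery = 0.904, mild = 0.032,
                     moderate_severe = 0.053, death = 0.011))
  bs <- treatment_outcome_branch("sah_coiling", p)
  expect_equal(bs, c(full_recovery = 0.41, mild = 0.15,
                     moderate_severe = 0.09, death = 0.35))
  p0 <- set_means(zero_event_overrides())
  expect_equal(treatment_outcome_branch("treat_one", p0)[["full_recovery"]], 1)
})

test_that("intact-carrier transition composes rupture and growth at MIA-adjusted rates", {
  p <- set_means(list(), default_settings(sah_fraction = 0))
  fl <- transition_row("natural_history", "well_mia", 60, p, constant_q_table(0))
  expect_equal(sum(fl$prob), 1, tolerance = 1e-12)
  expect_equal(fl$prob[fl$dest == "sah"], 0.005 * 2.08, tolerance = 1e-12)
  grow <- fl$prob[fl$dest == "well_growing_mia"]
  # growth arc conditional on no rupture equals the MIA-adjusted growth rate
  expect_equal(grow / (1 - 0.005 * 2.08), 0.026 * 3.47, tolerance = 1e-12)
  expect_false(any(fl$procedure))
})

test_that("death is absorbing and every transition row conserves probability", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  fl <- transition_row("treat_two", "death", 80, p, lt)
  expect_equal(fl$dest, "death")
  expect_equal(fl$prob, 1)
  for (seed in 1:5) {
    pf <- fuzzed_params(seed)
    for (s in list_strategies()$id) {
      for (state in health_states()) {
        for (age in c(57, 58, 61, 98)) {
          fl <- transition_row(s, state, age, pf, lt)
          expect_equal(sum(fl$prob), 1, tolerance = 1e-12)
          expect_true(all(fl$prob >= 0 & fl$prob <= 1))
        }
      }
    }
  }
})

test_that("growing aneurysms are coiled only when screening is due", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  # biennial arm: detection fires entering even cycles
  fl_fire <- transition_row("follow_up_2y", "well_growing_mia", 58, p, lt, cycle = 1)
  expect_true("well_one_treated" %in% fl_fire$dest)
  fl_wait <- transition_row("follow_up_2y", "well_growing_mia", 59, p, lt, cycle = 2)
  expect_false("well_one_treated" %in% fl_wait$dest)
  expect_true("well_growing_mia" %in% fl_wait$dest)
  # natural history never detects
  fl_nh <- transition_row("natural_history", "well_growing_mia", 70, p, lt)
  expect_false("well_one_treated" %in% fl_nh$dest)
  # the treat-one arm treats a growing remaining aneurysm; follow-up arms do not
  fl_t1 <- transition_row("treat_one", "well_single_growing", 70, p, lt)
  expect_true("well_both_treated" %in% fl_t1$dest)
  fl_fu <- transition_row("follow_up_1y", "well_single_growing", 70, p, lt)
  expect_false("well_both_treated" %in% fl_fu$dest)
})

test_that("cohort traces conserve mass and death occupancy never decreases", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  for (s in list_strategies()$id) {
    tr <- run_cohort(s, p, lt)
    expect_equal(nrow(tr$occupancy), 43)
    expect_equal(rowSums(tr$occupancy), rep(1, 43), tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
  }
})

test_that("entry procedures place the cohort per the outcome branch at cycle 0", {
  p <- load_base_parameters()
  tr <- run_cohort("treat_two", p, build_fixture_table())
  expect_equal(unname(tr$occupancy[1, "death"]), 0.011)
  expect_equal(unname(tr$occupancy[1, "modsev_disability"]), 0.053)
  expect_equal(unname(tr$occupancy[1, "mild_disability"]), 0.032)
  expect_equal(unname(tr$occupancy[1, "well_both_treated"]), 0.904)
  tr_nh <- run_cohort("natural_history", p, build_fixture_table())
  expect_equal(unname(tr_nh$occupancy[1, "well_mia"]), 1)
})

test_that("no-event, no-mortality cohort earns the closed-form annuity", {
  p <- set_means(zero_event_overrides(), default_settings(sah_fraction = 0))
  lt <- constant_q_table(0)
  tr <- run_cohort("natural_history", p, lt)
  expect_equal(tr$occupancy[, "well_mia"], rep(1, 43))
  ev <- discounted_qalys(tr, p)$qalys
  annuity <- sum((1 / 1.03)^(0:42))
  expect_equal(ev, annuity, tolerance = 1e-10)
  expect_equal(annuity, 24.70, tolerance = 1e-3) # geometric series, 43 terms at 3%
})

test_that("engine matches the closed-form survival annuity in a collapsed model", {
  # two effective states (alive at utility 1 / dead), constant hazard
  q <- 0.02
  p <- set_means(zero_event_overrides(), default_settings(sah_fraction = 0))
  lt <- constant_q_table(q)
  ev <- discounted_qalys(run_cohort("natural_history", p, lt), p)$qalys
  surv <- (1 - q)^(0:42)
  expect_equal(ev, sum(surv / 1.03^(0:42)), tolerance = 1e-10)
})

test_that("discounting reduces the expected value of any non-degenerate trace", {
  p <- load_base_parameters()
  p0 <- load_base_parameters(settings = default_settings(discount_rate = 0))
  lt <- build_fixture_table()
  for (s in c("treat_two", "natural_history")) {
    tr <- run_cohort(s, p, lt)
    expect_gt(discounted_qalys(tr, p0)$qalys, discounted_qalys(tr, p)$qalys)
  }
})

test_that("whole-cohort death earns zero QALYs", {
  p <- set_means(list(mortality_after_treat_two = 1, mild_after_treat_two = 0,
                      modsev_after_treat_two = 0))
  tr <- run_cohort("treat_two", p, build_fixture_table())
  expect_equal(tr$occupancy[, "death"], rep(1, 43))
  expect_equal(discounted_qalys(tr, p)$qalys, 0)
})

test_that("vectorised engine and audited trace path agree on fuzzed parameters", {
  lt <- build_fixture_table()
  for (seed in 1:4) {
    pf <- fuzzed_params(seed)
    ev_engine <- evaluate_strategies(pf, lt)
    for (i in seq_len(nrow(ev_engine))) {
      tr <- run_cohort(ev_engine$strategy[i], pf, lt)
      expect_equal(discounted_qalys(tr, pf)$qalys, ev_engine$qalys[i],
                   tolerance = 1e-12)
    }
  }
})

test_that("expected values respond monotonically to key risks", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  sw <- one_way_sweep("rupture_rate_nongrowing", p, lt, n_points = 9)
  expect_true(all(diff(sw$curves$natural_history) < 0))
  sw2 <- one_way_sweep("mortality_after_treat_two", p, lt, n_points = 9)
  expect_true(all(diff(sw2$curves$treat_two) < 0))
})

test_that("treatment dominance holds at the risk extremes", {
  lt <- build_fixture_table()
  # harmless treatment: treating both weakly dominates everything
  p_safe <- set_means(list(mild_after_treat_one = 0, modsev_after_treat_one = 0,
                           mortality_after_treat_one = 0, mild_after_treat_two = 0,
                           modsev_after_treat_two = 0, mortality_after_treat_two = 0))
  ev <- evaluate_strategies(p_safe, lt)
  q <- setNames(ev$qalys, ev$strategy)
  expect_true(all(q[["treat_two"]] >= q + -1e-12))
  # lethal treatment: natural history strictly beats treating both
  p_lethal <- set_means(list(mortality_after_treat_two = 1, mild_after_treat_two = 0,
                             modsev_after_treat_two = 0))
  ev2 <- evaluate_strategies(p_lethal, lt)
  q2 <- setNames(ev2$qalys, ev2$strategy)
  expect_gt(q2[["natural_history"]], q2[["treat_two"]])
})

test_that("without disease or treatment harm all strategies coincide up to the procedure disutility", {
  p <- set_means(zero_event_overrides())
  ev <- evaluate_strategies(p, build_fixture_table())
  q <- setNames(ev$qalys, ev$strategy)
  untreated <- q[c("natural_history", "follow_up_1y", "follow_up_2y", "follow_up_5y")]
  expect_true(all(abs(untreated - untreated[1]) < 1e-12))
  # the treat arms differ only by the one-off 5% disutility at entry
  expect_equal(q[["treat_two"]], q[["natural_history"]] - 0.05, tolerance = 1e-12)
  expect_equal(q[["treat_one"]], q[["treat_two"]], tolerance = 1e-12)
})
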