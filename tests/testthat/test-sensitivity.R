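test_that("zero-variance PSA reproduces the base case exactly", {
  p_fixed <- all_fixed_params()
  psa <- run_psa(p_fixed, n_iterations = 25, seed = 3)
  base <- evaluate_strategies(p_fixed)
  for (i in seq_len(25)) {
    expect_equal(as.numeric(psa$ev[i, ]), base$qalys, tolerance = 1e-12)
  }
  freq <- optimal_frequencies(psa)
  expect_equal(unname(freq[names(which.max(setNames(base$qalys, base$strategy)))]), 100)
})

test_that("PSA is reproducible under a seed and counts renormalised draws", {
  p <- load_base_parameters()
  a <- run_psa(p, n_iterations = 300, seed = 7)
  b <- run_psa(p, n_iterations = 300, seed = 7)
  expect_identical(a$ev, b$ev)
  expect_equal(a$n_iterations, 300)
  expect_gte(a$n_renormalised, 0)
  expect_equal(ncol(a$ev), 6)
  expect_false(any(is.na(a$ev)))
})

test_that("optimal frequencies partition the iterations", {
  p <- load_base_parameters()
  psa <- run_psa(p, n_iterations = 500, seed = 21)
  freq <- optimal_frequencies(psa)
  expect_equal(sum(freq), 100)
  expect_true(all(freq >= 0))
  expect_named(freq, list_strategies()$id)
  pct <- pairwise_preference(psa, "treat_two", "treat_one")
  expect_gte(pct, 0); expect_lte(pct, 100)
})

test_that("repeated PSAs with one seed coincide and with many seeds vary as binomial noise", {
  p <- load_base_parameters()
  st_same <- psa_stability(p, n_iterations = 200, n_repeats = 2, seeds = c(5, 5))
  expect_equal(st_same$max_abs_deviation, 0)
  st_small <- psa_stability(p, n_iterations = 100, n_repeats = 4, seed = 5)
  st_large <- psa_stability(p, n_iterations = 2000, n_repeats = 4, seed = 5)
  # variance scaling: the leading frequency is less stable at tiny n
  expect_gt(st_small$binomial_se, st_large$binomial_se)
})

test_that("one-way sweeps leave unaffected strategies constant", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  sw <- one_way_sweep("mortality_after_treat_two", p, lt, n_points = 7)
  curves <- sw$curves
  # the two-aneurysm branch enters only the treat-two arm
  for (s in c("treat_one", "follow_up_1y", "follow_up_2y", "follow_up_5y",
              "natural_history")) {
    expect_equal(diff(range(curves[[s]])), 0, tolerance = 1e-12)
  }
  expect_true(sw$entry$optimal_switches)
  expect_gte(sw$entry$spread, 0)
  expect_error(one_way_sweep("not_a_parameter", p, lt), "unknown parameter")
})

test_that("tornado is sorted by spread and flags the four published switch parameters", {
  p <- load_base_parameters()
  tor <- tornado_analysis(p, n_points = 21)
  expect_true(all(diff(tor$spread) <= 1e-12))
  expect_true(all(tor$spread >= 0))
  switchers <- tor$parameter[tor$optimal_switches]
  expect_true(all(c("modsev_after_treat_two", "mortality_after_treat_two",
                    "modsev_after_treat_one", "rupture_rate_growing") %in% switchers))
})

test_that("threshold bisection brackets the switch and agrees with a dense grid scan", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  th <- threshold_search("modsev_after_treat_two", p, lt, tolerance = 1e-6)
  expect_false(is.na(th$threshold))
  expect_equal(th$strategy_below, "treat_two")
  expect_equal(th$strategy_above, "treat_one")
  row <- subset(p$clinical, name == "modsev_after_treat_two")
  expect_gte(th$threshold, row$low)
  expect_lte(th$threshold, row$high)
  # independent brute-force oracle: dense grid argmax scan
  xs <- seq(row$low, row$high, length.out = 2001)
  draws <- as.list(miamarkov:::.base_values(p))
  draws[["modsev_after_treat_two"]] <- xs
  ev <- miamarkov:::.ev_matrix(draws, p$settings, lt)
  best <- colnames(ev)[max.col(ev, ties.method = "first")]
  i <- which(best[-1] != best[-length(best)])[1]
  grid_threshold <- (xs[i] + xs[i + 1]) / 2
  expect_lt(abs(th$threshold - grid_threshold), diff(xs[1:2]))
})

test_that("parameters that never change the optimal strategy report no threshold", {
  p <- load_base_parameters()
  th <- threshold_search("mild_after_sah", p, tolerance = 1e-3, n_scan = 32)
  expect_true(is.na(th$threshold))
  expect_equal(th$strategy_below, th$strategy_above)
  expect_false(th$multiple)
})

test_that("two-way map covers the grid and is dominated by the two treat arms", {
  p <- load_base_parameters()
  map <- two_way_grid("modsev_after_treat_one", "modsev_after_treat_two", p,
                      grid_size = 9)
  expect_equal(nrow(map), 81)
  rx <- subset(p$clinical, name == "modsev_after_treat_one")
  expect_equal(range(map$x), c(rx$low, rx$high))
  share <- mean(map$optimal %in% c("treat_one", "treat_two"))
  expect_gt(share, 0.7)
  expect_error(two_way_grid("rr_growth_mia", "rr_growth_mia", p), "must differ")
})

test_that("the two-way map restricted to a base-mean line matches the one-way sweep", {
  p <- load_base_parameters()
  lt <- build_fixture_table()
  # the two-treated moderate-severe range (0.008-0.098) has the base mean
  # 0.053 as its midpoint, so an odd grid passes exactly through it
  map <- two_way_grid("modsev_after_treat_one", "modsev_after_treat_two", p, lt,
                      grid_size = 9)
  line <- map[abs(map$y - 0.053) < 1e-12, ]
  expect_equal(nrow(line), 9)
  sw <- one_way_sweep("modsev_after_treat_one", p, lt, n_points = 9)
  expect_equal(line$optimal[order(line$x)],
               sw$curves$optimal[order(sw$curves$value)])
})
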