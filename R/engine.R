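# Vectorised expected-value engine.
#
# Propagates the nine-state occupancy for many parameter draws at once: state
# occupancies are length-n vectors and every flow is elementwise arithmetic,
# so a 10,000-iteration PSA or a dense one-way sweep is a single pass of the
# 42 cycle updates per strategy. run_cohort()/discounted_qalys() implement
# the identical flows one state at a time; the two paths are held together by
# an equality test on fuzzed parameters.

# draws: data.frame/list of parameter vectors (length n or 1), one entry per
# parameter name; returns n x length(strategies) matrix of discounted QALYs
.ev_matrix <- function(draws, settings, table = build_fixture_table(),
                       strategies = list_strategies()$id) {
  cd <- cause_deleted_adjustment(table, settings$sah_fraction)
  ages <- settings$start_age:settings$max_age
  qvec <- .q_at(cd, ages)
  n <- max(vapply(draws, length, 1L))
  out <- matrix(NA_real_, n, length(strategies),
                dimnames = list(NULL, strategies))
  for (s in strategies) out[, s] <- .strategy_ev_vec(s, draws, qvec, settings, n)
  out
}

.strategy_ev_vec <- function(strategy, draws, qvec, settings, n) {
  strat <- .strategy(strategy)
  g <- function(nm) {
    x <- draws[[nm]]
    if (is.null(x)) stop("draws lack parameter '", nm, "'")
    rep_len(x, n)
  }
  v <- lapply(c(.clinical_names(), "utility_full_recovery", "utility_mild",
                "utility_modsev", "utility_sah"), g)
  names(v) <- c(.clinical_names(), "utility_full_recovery", "utility_mild",
                "utility_modsev", "utility_sah")
  d <- .derived_values(v, settings)
  uw <- v$utility_full_recovery
  um <- v$utility_mild; us <- v$utility_modsev; ua <- v$utility_sah
  ht <- settings$hazard_transform
  disut <- settings$procedure_disutility
  r <- settings$discount_rate
  interval <- strat$screening_interval
  sg_detect <- isTRUE(strat$single_growing_detected)

  z <- numeric(n)
  MIA <- z; GRO <- z; SG <- z; OT <- z; BT <- z; SAH <- z; MI <- z; MS <- z; DE <- z
  proc0 <- z
  if (strat$entry_procedure == "treat_one") {
    b <- d$b_one
    if (any(b$full < 0)) stop("treat_one outcome probabilities sum above 1")
    DE <- b$death; MI <- b$mild; MS <- b$modsev; OT <- b$full
    proc0 <- MI * um + MS * us + OT * uw
  } else if (strat$entry_procedure == "treat_two") {
    b <- d$b_two
    if (any(b$full < 0)) stop("treat_two outcome probabilities sum above 1")
    DE <- b$death; MI <- b$mild; MS <- b$modsev; BT <- b$full
    proc0 <- MI * um + MS * us + BT * uw
  } else {
    MIA <- rep(1, n)
  }
  total_u <- function() (MIA + GRO + SG + OT + BT) * uw + SAH * ua + MI * um + MS * us
  ev <- total_u() - disut * proc0

  b1 <- d$b_one; bs <- d$b_sah
  ncyc <- length(qvec)
  for (t in 0:(ncyc - 2)) {
    qa <- qvec[t + 1]
    det <- !is.na(interval) && screening_due(t + 1, interval)
    pdm <- .apply_rr(qa, d$rr_death_mild, ht)
    pds <- .apply_rr(qa, d$rr_death_modsev, ht)
    svMIA <- MIA * (1 - qa); svGRO <- GRO * (1 - qa); svSG <- SG * (1 - qa)
    svOT <- OT * (1 - qa); svBT <- BT * (1 - qa); svSAH <- SAH * (1 - qa)

    nDE <- DE + (MIA + GRO + SG + OT + BT + SAH) * qa + MI * pdm + MS * pds
    nMI <- MI * (1 - pdm); nMS <- MS * (1 - pds)
    proc <- numeric(n)

    # sah tunnel resolves: coiling of both aneurysms
    nDE <- nDE + svSAH * bs$death
    nMI <- nMI + svSAH * bs$mild; nMS <- nMS + svSAH * bs$modsev
    nBT <- svSAH * bs$full
    proc <- proc + svSAH * (bs$mild * um + bs$modsev * us + bs$full * uw)

    # well_mia: rupture then growth
    nSAH <- svMIA * d$p_rupt_mia
    s2 <- svMIA * (1 - d$p_rupt_mia)
    nGRO <- s2 * d$p_grow_mia
    nMIA <- s2 * (1 - d$p_grow_mia)

    # well_growing_mia: rupture then scheduled detection
    nSAH <- nSAH + svGRO * d$p_rupt_growing
    s2 <- svGRO * (1 - d$p_rupt_growing)
    nOT <- numeric(n)
    if (det) {
      nDE <- nDE + s2 * b1$death
      nMI <- nMI + s2 * b1$mild; nMS <- nMS + s2 * b1$modsev
      nOT <- s2 * b1$full
      proc <- proc + s2 * (b1$mild * um + b1$modsev * us + b1$full * uw)
    } else {
      nGRO <- nGRO + s2
    }

    # well_single_growing: rupture, then annual surveillance if the strategy
    # monitors growth of the remaining untreated aneurysm
    nSAH <- nSAH + svSG * d$p_rupt_growing
    s2 <- svSG * (1 - d$p_rupt_growing)
    nSG <- numeric(n)
    if (sg_detect) {
      nDE <- nDE + s2 * b1$death
      nMI <- nMI + s2 * b1$mild; nMS <- nMS + s2 * b1$modsev
      nBT <- nBT + s2 * b1$full
      proc <- proc + s2 * (b1$mild * um + b1$modsev * us + b1$full * uw)
    } else {
      nSG <- s2
    }

    # well_one_treated: rupture of the untreated aneurysm, growth, de novo
    nSAH <- nSAH + svOT * d$p_rupt_single
    s2 <- svOT * (1 - d$p_rupt_single)
    nSG <- nSG + s2 * d$p_grow_single
    s3 <- s2 * (1 - d$p_grow_single)
    dn <- s3 * d$p_de_novo
    nDE <- nDE + dn * b1$death
    nMI <- nMI + dn * b1$mild; nMS <- nMS + dn * b1$modsev
    nOT <- nOT + dn * b1$full + s3 * (1 - d$p_de_novo)
    proc <- proc + dn * (b1$mild * um + b1$modsev * us + b1$full * uw)

    # well_both_treated: de novo only
    dn <- svBT * d$p_de_novo
    nDE <- nDE + dn * b1$death
    nMI <- nMI + dn * b1$mild; nMS <- nMS + dn * b1$modsev
    nBT <- nBT + dn * b1$full + svBT * (1 - d$p_de_novo)
    proc <- proc + dn * (b1$mild * um + b1$modsev * us + b1$full * uw)

    MIA <- nMIA; GRO <- nGRO; SG <- nSG; OT <- nOT; BT <- nBT
    SAH <- nSAH; MI <- nMI; MS <- nMS; DE <- nDE
    ev <- ev + (1 + r)^(-(t + 1)) * (total_u() - disut * proc)
  }
  ev
}
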