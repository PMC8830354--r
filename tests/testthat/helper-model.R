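# shared fixtures for the model tests: all built in code, no files

# parameter set with selected means overridden; overridden rows become
# family "fixed" so distribution feasibility never constrains extreme values
set_means <- function(overrides, settings = default_settings()) {
  tab <- default_parameter_table()
  for (nm in names(overrides)) {
    i <- match(nm, tab$name)
    stopifnot(!is.na(i))
    v <- overrides[[nm]]
    tab$mean[i] <- v
    tab$low[i] <- min(tab$low[i], v)
    tab$high[i] <- max(tab$high[i], v)
    tab$family[i] <- "fixed"
    tab$sd[i] <- NA_real_
  }
  load_base_parameters(tab, settings)
}

# no aneurysm events, no treatment harm: the cohort only ages and dies
zero_event_overrides <- function() {
  list(growth_rate_small = 0, rupture_rate_nongrowing = 0,
       rupture_rate_growing = 0, de_novo_rate = 0,
       mild_after_treat_one = 0, modsev_after_treat_one = 0,
       mortality_after_treat_one = 0,
       mild_after_treat_two = 0, modsev_after_treat_two = 0,
       mortality_after_treat_two = 0,
       mild_after_sah = 0, modsev_after_sah = 0, mortality_after_sah = 0)
}

# life table with one constant annual death probability
constant_q_table <- function(q, ages = 57:99) {
  out <- data.frame(age = as.integer(ages), q = q)
  class(out) <- c("mia_life_table", "data.frame")
  out
}

# parameter table rows fuzzed uniformly within their published ranges
fuzzed_params <- function(seed) {
  set.seed(seed)
  tab <- default_parameter_table()
  pick <- tab$low < tab$high
  tab$mean[pick] <- tab$low[pick] + runif(sum(pick)) * (tab$high[pick] - tab$low[pick])
  tab$family <- "fixed"
  tab$sd <- NA_real_
  # keep each outcome branch feasible
  for (k in c("treat_one", "treat_two", "sah")) {
    nms <- paste0(c("mortality_after_", "mild_after_", "modsev_after_"), k)
    i <- match(nms, tab$name)
    tot <- sum(tab$mean[i])
    if (tot > 1) tab$mean[i] <- tab$mean[i] / tot
  }
  load_base_parameters(tab)
}

all_fixed_params <- function(settings = default_settings()) {
  tab <- default_parameter_table()
  tab$family <- "fixed"
  tab$sd <- NA_real_
  load_base_parameters(tab, settings)
}
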