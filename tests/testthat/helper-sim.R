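# Shared builders for parameter-recovery fixtures.

# A tiny hand-built dataset: one period, two methods, four surveys.
tiny_dataset <- function() {
  resight_data(
    surveys = tibble::tribble(
      ~period_id, ~day, ~diel, ~method, ~marked_seen, ~unmarked_seen,
      "P1", 1L, "AM", "SO",  100L, 900L,
      "P1", 1L, "PM", "SO",  120L, 680L,
      "P1", 1L, "AM", "UAV",  80L, 1000L,
      "P1", 1L, "PM", "UAV",  90L, 1100L),
    markings = tibble::tibble(period_id = "P1", n_marked = 2000L)
  )
}

# Exact detection-probability ratio marked:unmarked for one method — the
# generative quantity the fraction model sees (independent arithmetic, kept
# here so tests do not lean on implied_marked_logit()).
detect_ratio <- function(base_p, kappa) {
  plogis(qlogis(base_p) + log(kappa)) / base_p
}

# Simulation config whose implied marked-fraction model has known
# parameters: period-level variation enters through the marked cohort size
# M_i (as in a real programme, where nesting numbers set how many turtles
# can be painted), so the generating (alpha, beta, sigma_period) are exact
# at zero random effects.
make_recovery_cfg <- function(alpha, sig_p, kappa, base, seed,
                              n_periods = 6, n_true = 20000,
                              sigma_day = 0.05, sigma_diel = 0.02) {
  r_so <- detect_ratio(base[["SO"]], kappa[["SO"]])
  z <- markresight:::with_seed(seed * 1000 + 7, rnorm(n_periods, 0, sig_p))
  odds <- exp(alpha + z) / r_so
  M <- round(n_true * odds / (1 + odds))
  sim_config(n_true = n_true, n_marked = M,
             periods = sprintf("P%02d", seq_len(n_periods)),
             base_detect = base, mark_bias = kappa,
             sigma_period = 0.4, sigma_day = sigma_day,
             sigma_diel = sigma_diel, seed = seed)
}

recovery_truth <- function(alpha, sig_p, kappa, base) {
  r <- vapply(names(kappa), function(m) detect_ratio(base[[m]], kappa[[m]]),
              numeric(1))
  c(alpha = unname(alpha),
    beta_UWV = unname(log(r[["UWV"]] / r[["SO"]])),
    beta_UAV = unname(log(r[["UAV"]] / r[["SO"]])),
    sigma_period = unname(sig_p))
}
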