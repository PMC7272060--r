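test_that("certain detection returns the whole population, split by mark", {
  cfg <- sim_config(n_true = 500, n_marked = 50, periods = "P1",
                    methods = "UAV", base_detect = c(UAV = 1),
                    mark_bias = c(UAV = 1), sigma_period = 0, sigma_day = 0,
                    sigma_diel = 0, days = 1, diel_per_day = 1)
  d <- simulate_surveys(cfg)
  expect_identical(d$surveys$marked_seen, 50L)
  expect_identical(d$surveys$unmarked_seen, 450L)
})

test_that("simulation is deterministic in the seed and stable to adding a method", {
  cfg <- sim_config(seed = 99L)
  expect_identical(simulate_surveys(cfg)$surveys, simulate_surveys(cfg)$surveys)
  expect_false(identical(simulate_surveys(sim_config(seed = 100L))$surveys,
                         simulate_surveys(cfg)$surveys))

  # sub-streams: SO draws unchanged when UAV is added to the design
  base <- sim_config(n_true = 8000, n_marked = 800, periods = c("A", "B"),
                     methods = "SO", base_detect = c(SO = 0.1),
                     mark_bias = c(SO = 1.2), seed = 5L)
  both <- sim_config(n_true = 8000, n_marked = 800, periods = c("A", "B"),
                     methods = c("SO", "UAV"),
                     base_detect = c(SO = 0.1, UAV = 0.1),
                     mark_bias = c(SO = 1.2, UAV = 1), seed = 5L)
  so_only <- simulate_surveys(base)$surveys
  so_in_both <- dplyr::filter(simulate_surveys(both)$surveys, method == "SO")
  expect_equal(as.data.frame(so_only), as.data.frame(so_in_both))
})

test_that("unbiased detection keeps the marked fraction at M over N", {
  # the Lincoln-Petersen equal-detectability assumption, generatively
  cfg <- sim_config(n_true = 10000, n_marked = 1000,
                    periods = sprintf("P%03d", 1:200), days = 1,
                    diel_per_day = 1, methods = "SO",
                    base_detect = c(SO = 0.3), mark_bias = c(SO = 1),
                    sigma_period = 0, sigma_day = 0, sigma_diel = 0,
                    seed = 21L)
  s <- simulate_surveys(cfg)$surveys
  frac <- s$marked_seen / s$total_seen
  mc_se <- sd(frac) / sqrt(nrow(s))
  expect_lt(abs(mean(frac) - 0.1), 3 * mc_se)
})

test_that("surface-observer mark bias raises its marked fraction above the UAV's", {
  cfg <- sim_config(n_true = 20000, n_marked = 2000,
                    periods = sprintf("P%02d", 1:20), days = 1,
                    diel_per_day = 1, methods = c("SO", "UAV"),
                    base_detect = c(SO = 0.05, UAV = 0.08),
                    mark_bias = c(SO = 1.6, UAV = 1),
                    sigma_period = 0.3, seed = 8L)
  s <- simulate_surveys(cfg)$surveys
  frac <- tapply(s$marked_seen / s$total_seen, s$method, mean)
  expect_gt(frac[["SO"]], frac[["UAV"]])
})

test_that("closure holds without departures and erodes geometrically with them", {
  closed <- sim_config(n_true = 20000, n_marked = 2000,
                       periods = sprintf("P%02d", 1:40), methods = "SO",
                       base_detect = c(SO = 0.1), mark_bias = c(SO = 1),
                       sigma_period = 0, sigma_day = 0, sigma_diel = 0,
                       departure_prob = 0, seed = 31L)
  s <- simulate_surveys(closed)$surveys
  by_day <- tapply(s$total_seen, s$day, mean)
  expect_lt(max(abs(by_day / by_day[1] - 1)), 0.02)

  open <- sim_config(n_true = 20000, n_marked = 2000,
                     periods = sprintf("P%02d", 1:40), methods = "SO",
                     base_detect = c(SO = 0.1), mark_bias = c(SO = 1),
                     sigma_period = 0, sigma_day = 0, sigma_diel = 0,
                     departure_prob = 0.25, seed = 32L)
  so <- simulate_surveys(open)$surveys
  by_day_o <- tapply(so$total_seen, so$day, mean)
  ratios <- by_day_o[-1] / by_day_o[-3]
  expect_lt(max(abs(ratios - 0.75)), 0.03)
  # truth sidecar agrees with the decline
  pres <- sim_truth(simulate_surveys(open))$present
  expect_true(all(unlist(tapply(pres$marked_present, pres$period_id, diff)) <= 0))
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(n_true = 100, n_marked = 200, periods = "P1"),
               "n_marked")
  expect_error(sim_config(departure_prob = 1), "departure_prob")
  expect_error(sim_config(base_detect = c(SO = 0, UWV = 0.1, UAV = 0.1)),
               "base_detect")
  expect_error(sim_config(mark_bias = c(SO = 0.5, UWV = 1, UAV = 1)),
               "mark_bias")
})

test_that("detectability trials honour the configured mark gain", {
  # noise-free: marked depth exceeds plain by exactly the gain
  tr <- simulate_detectability_trials(plain_mu = 10, mark_gain = 3,
                                      noise_sd = 0, n_sites = 3, seed = 1)
  wide <- tidyr::pivot_wider(tr, names_from = "treatment",
                             values_from = "loss_depth_m")
  expect_equal(wide$MARKED - wide$PLAIN, rep(3, 3))

  tr0 <- simulate_detectability_trials(mark_gain = 0, noise_sd = 0,
                                       n_sites = 4, seed = 2)
  w0 <- tidyr::pivot_wider(tr0, names_from = "treatment",
                           values_from = "loss_depth_m")
  expect_equal(w0$MARKED, w0$PLAIN)

  # Monte-Carlo: mean difference within 3 SEs of the configured 3 m gain
  trn <- simulate_detectability_trials(plain_mu = 10, mark_gain = 3,
                                       noise_sd = 0.1, n_sites = 200,
                                       seed = 3)
  wn <- tidyr::pivot_wider(trn, names_from = "treatment",
                           values_from = "loss_depth_m")
  dif <- wn$MARKED - wn$PLAIN
  expect_lt(abs(mean(dif) - 3), 3 * sd(dif) / sqrt(length(dif)))

  expect_error(simulate_detectability_trials(n_sites = 1), "n_sites")
})

test_that("implied marked-fraction logits match a brute-force simulation", {
  cfg <- sim_config(n_true = 20000, n_marked = 1500,
                    periods = sprintf("P%03d", 1:300), days = 1,
                    diel_per_day = 1, methods = c("SO", "UAV"),
                    base_detect = c(SO = 0.08, UAV = 0.1),
                    mark_bias = c(SO = 1.7, UAV = 1),
                    sigma_period = 0, sigma_day = 0, sigma_diel = 0,
                    seed = 77L)
  s <- simulate_surveys(cfg)$surveys
  imp <- implied_marked_logit(cfg)
  for (m in c("SO", "UAV")) {
    frac <- with(dplyr::filter(s, method == m), marked_seen / total_seen)
    want <- plogis(imp$logit_fraction[imp$method == m][1])
    expect_lt(abs(mean(frac) - want), 3 * sd(frac) / sqrt(length(frac)))
  }
})
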