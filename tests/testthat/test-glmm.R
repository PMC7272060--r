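# One moderately sized fit at the study design (6 periods x 6 surveys x 3
# methods) is shared across several assertions below.
kappa_fix <- c(SO = 1.55, UWV = 1.2, UAV = 1.0)
base_fix <- c(SO = 0.04, UWV = 0.05, UAV = 0.06)
truth_fix <- recovery_truth(qlogis(0.065), 0.4, kappa_fix, base_fix)
fit_fix <- local({
  d <- simulate_surveys(make_recovery_cfg(truth_fix[["alpha"]], 0.4,
                                          kappa_fix, base_fix, seed = 11))
  fit_detection_model(d, n_iter = 4000, n_burn = 1200, n_chains = 2,
                      seed = 2)
})

test_that("the sampler is deterministic given the seed", {
  d <- simulate_surveys(sim_config(
    n_true = 5000, n_marked = 500, periods = c("A", "B"),
    methods = c("SO", "UAV"), base_detect = c(SO = 0.1, UAV = 0.1),
    mark_bias = c(SO = 1.4, UAV = 1), seed = 3))
  f1 <- fit_detection_model(d, n_iter = 600, n_burn = 200, n_chains = 1,
                            seed = 42)
  f2 <- fit_detection_model(d, n_iter = 600, n_burn = 200, n_chains = 1,
                            seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_detection_model(d, n_iter = 600, n_burn = 200, n_chains = 1,
                            seed = 43)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("chains mix at the study design and recover the generating values", {
  expect_lt(max(rhat(fit_fix)$rhat), 1.1)
  td <- tidy(fit_fix)
  for (p in names(truth_fix)) {
    row <- td[td$term == p, ]
    expect_gt(truth_fix[[p]], row$conf.low)
    expect_lt(truth_fix[[p]], row$conf.high)
  }
  # acceptance rates in the adapted random-walk band
  expect_true(all(fit_fix$accept > 0.15 & fit_fix$accept < 0.6))
})

test_that("mark bias makes the SO marked proportion stochastically largest", {
  pr_so_gt_uav <- mean(fit_fix$draws$beta_UAV < 0)
  expect_gt(pr_so_gt_uav, 0.9)
  props <- marked_proportion(fit_fix)
  expect_gt(props$proportion[props$method == "SO"],
            props$proportion[props$method == "UAV"])
})

test_that("variance partition is dominated by the period level and normalised", {
  vp <- variance_partition(fit_fix)
  expect_gt(vp$share_mean[vp$component == "period"], 0.8)
  expect_equal(sum(vp$share_mean), 1, tolerance = 1e-12)
  s2 <- cbind(fit_fix$draws$sigma_period^2, fit_fix$draws$sigma_day^2,
              fit_fix$draws$sigma_diel^2)
  expect_lt(max(abs(rowSums(s2 / rowSums(s2)) - 1)), 1e-12)
})

test_that("degenerate partitions and proportions behave exactly", {
  mock <- structure(list(
    draws = tibble::tibble(chain = 1L, iter = 1:300,
                           alpha = rep(0, 300), beta_UAV = rep(0, 300),
                           sigma_period = rep(1.3, 300),
                           sigma_day = rep(0, 300),
                           sigma_diel = rep(0, 300),
                           sigma_resid = rep(0.1, 300)),
    methods = c("SO", "UAV"), reference = "SO"),
    class = "detection_fit")
  vp <- variance_partition(mock)
  expect_equal(vp$share_mean[vp$component == "period"], 1)
  # inverse logit of a zero linear predictor
  mp <- marked_proportion(mock)
  expect_equal(mp$proportion, c(0.5, 0.5))

  mock$draws$sigma_period <- rep(0, 300)
  mock$draws$sigma_resid <- rep(0, 300)
  expect_warning(vp0 <- variance_partition(mock), "uniform")
  expect_equal(vp0$share_mean, rep(1 / 3, 3))
})

test_that("identical counts across methods centre the contrasts on zero", {
  s <- tidyr::expand_grid(period_id = c("A", "B"), day = 1:3,
                          diel = c("AM", "PM"),
                          method = c("SO", "UWV", "UAV"))
  s$marked_seen <- 80L
  s$unmarked_seen <- 920L
  d <- resight_data(s, tibble::tibble(period_id = c("A", "B"),
                                      n_marked = 1000L))
  fit <- fit_detection_model(d, n_iter = 2500, n_burn = 800, n_chains = 2,
                             seed = 6)
  td <- tidy(fit)
  for (b in c("beta_UWV", "beta_UAV")) {
    row <- td[td$term == b, ]
    expect_lt(row$conf.low, 0)
    expect_gt(row$conf.high, 0)
  }
})

test_that("with variances pinned at zero the fit matches ML logistic regression", {
  cfg <- sim_config(n_true = 20000, n_marked = 1500, periods = "P1",
                    base_detect = c(SO = 0.05, UWV = 0.06, UAV = 0.07),
                    mark_bias = c(SO = 1.5, UWV = 1, UAV = 1),
                    sigma_period = 0, sigma_day = 0, sigma_diel = 0,
                    seed = 3)
  d <- simulate_surveys(cfg)
  ctrl <- detection_control(fix_sigma = c("period", "day", "diel", "resid"))
  fit <- fit_detection_model(d, n_iter = 6000, n_burn = 2000, n_chains = 2,
                             seed = 5, control = ctrl)
  ml <- stats::glm(
    cbind(marked_seen, unmarked_seen) ~
      factor(method, levels = c("SO", "UWV", "UAV")),
    family = stats::binomial(), data = d$surveys)
  got <- tidy(fit)
  expect_equal(got$estimate[got$term == "alpha"],
               unname(stats::coef(ml)[1]), tolerance = 0.05)
  expect_equal(got$estimate[got$term == "beta_UWV"],
               unname(stats::coef(ml)[2]), tolerance = 0.05)
  expect_equal(got$estimate[got$term == "beta_UAV"],
               unname(stats::coef(ml)[3]), tolerance = 0.05)
})

test_that("a prior-only run reproduces the prior moments", {
  d <- tiny_dataset()
  ctrl <- detection_control(prior_only = TRUE)
  fit <- fit_detection_model(d, n_iter = 12000, n_burn = 2000, n_chains = 2,
                             seed = 9, control = ctrl)
  # alpha ~ N(0, 10^2); random-walk draws are autocorrelated, so bounds
  # are generous multiples of the Monte-Carlo error
  expect_lt(abs(mean(fit$draws$alpha)), 2)
  expect_equal(sd(fit$draws$alpha), 10, tolerance = 0.15)
  # half-Cauchy(5): median 5, heavy right tail
  expect_gt(median(fit$draws$sigma_period), 3)
  expect_lt(median(fit$draws$sigma_period), 8)
})

test_that("recovered proportions reproduce the generating method contrast", {
  # SO ~ 9.4% and UAV ~ 6.3% marked, the study-scale contrast
  n_true <- 20000; M <- 1260L
  pop_odds <- M / (n_true - M)
  r_needed <- (0.094 / 0.906) / pop_odds
  p0 <- 0.04
  pm <- r_needed * p0
  kappa_so <- (pm / (1 - pm)) / (p0 / (1 - p0))
  cfg <- sim_config(n_true = n_true, n_marked = M,
                    periods = sprintf("P%02d", 1:6),
                    methods = c("SO", "UAV"),
                    base_detect = c(SO = p0, UAV = 0.06),
                    mark_bias = c(SO = kappa_so, UAV = 1),
                    sigma_period = 0.25, sigma_day = 0.05,
                    sigma_diel = 0.02, seed = 14)
  fit <- fit_detection_model(simulate_surveys(cfg), n_iter = 4000,
                             n_burn = 1200, n_chains = 1, seed = 15)
  mp <- marked_proportion(fit)
  expect_equal(mp$proportion[mp$method == "SO"], 0.094, tolerance = 0.02 / 0.094)
  expect_equal(mp$proportion[mp$method == "UAV"],
               plogis(log(pop_odds)), tolerance = 0.02 / 0.063)
})

test_that("model preconditions are enforced", {
  d <- tiny_dataset()
  one <- resight_data(dplyr::filter(d$surveys, method == "SO"), d$markings)
  expect_error(fit_detection_model(one, n_iter = 100, n_burn = 10),
               "two methods")
  expect_error(fit_detection_model(d, n_iter = 100, n_burn = 100),
               "exceed")
})
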