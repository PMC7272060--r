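test_that("Lincoln-Petersen point estimate and standard error are exact", {
  expect_equal(lp_point(50, 30, 30), 50)       # all sightings marked -> M
  expect_equal(lp_point(2000, 1000, 100), 20000)
  expect_equal(lp_point(100, 100, 100), 100)
  expect_error(lp_point(100, 50, 0), "no marked resights",
               class = "markresight_estimation_error")

  expect_equal(lp_se(2000, 1000, 100), sqrt(2000^2 * 1000 * 900 / 100^3))
  expect_equal(lp_se(2000, 1000, 100), 1897.3666, tolerance = 1e-6)
  expect_equal(lp_se(2000, 1000, 500), 126.49111, tolerance = 1e-6)
  expect_equal(lp_se(2000, 500, 500), 0)       # every sighting marked
  # delta-method cross-check: var(N_hat) ~ N_hat^2 (1 - p) / R with p = R/C
  nh <- lp_point(2000, 1000, 100); p <- 100 / 1000
  expect_equal(lp_se(2000, 1000, 100)^2,
               nh^2 * (1 - p) / 100, tolerance = 1e-9)

  # Chapman variant is defined at R = 0 and close to LP for big counts
  expect_equal(lp_chapman(100, 50, 0), 101 * 51 / 1 - 1)
  expect_lt(abs(lp_chapman(2000, 1000, 100) / lp_point(2000, 1000, 100) - 1),
            0.01)
})

test_that("period summaries average per-survey estimates with an SEM", {
  d <- resight_data(
    surveys = tibble::tribble(
      ~period_id, ~day, ~diel, ~method, ~marked_seen, ~unmarked_seen,
      "P1", 1L, "AM", "SO", 100L, 900L,
      "P1", 1L, "PM", "SO", 120L, 680L),
    markings = tibble::tibble(period_id = "P1", n_marked = 2000L))
  pe <- period_estimate(d, "P1", "SO")
  expect_equal(pe$n_hat, (20000 + 2000 * 800 / 120) / 2, tolerance = 1e-9)
  expect_equal(pe$n_hat, 16666.667, tolerance = 1e-6)
  expect_equal(pe$se, sd(c(20000, 13333.3333)) / sqrt(2), tolerance = 1e-6)
  expect_equal(pe$se, 3333.3333, tolerance = 1e-6)
  expect_equal(pe$mean_total, 900)
  expect_equal(pe$source, "period_mean")

  # single survey falls back to the analytic SE
  d1 <- resight_data(d$surveys[1, ], d$markings)
  p1 <- period_estimate(d1, "P1", "SO")
  expect_equal(p1$n_hat, lp_point(2000, 1000, 100))
  expect_equal(p1$se, lp_se(2000, 1000, 100))
  expect_equal(p1$source, "single")

  # identical repeated surveys have zero spread
  d6 <- resight_data(
    dplyr::bind_rows(lapply(1:3, function(day) {
      dplyr::mutate(d$surveys[c(1, 1), ], day = day, diel = c("AM", "PM"))
    })),
    d$markings)
  expect_equal(period_estimate(d6, "P1", "SO")$se, 0)
})

test_that("surveys without marked resights are excluded with a warning", {
  d <- resight_data(
    surveys = tibble::tribble(
      ~period_id, ~day, ~diel, ~method, ~marked_seen, ~unmarked_seen,
      "P1", 1L, "AM", "SO", 100L, 900L,
      "P1", 1L, "PM", "SO",   0L, 800L),
    markings = tibble::tibble(period_id = "P1", n_marked = 2000L))
  expect_warning(pe <- period_estimate(d, "P1", "SO"), "excluded")
  expect_equal(pe$n_surveys, 1L)
  d0 <- resight_data(d$surveys[2, ], d$markings)
  expect_error(suppressWarnings(period_estimate(d0, "P1", "SO")),
               class = "markresight_estimation_error")
})

test_that("cumulative pooling averages counts before the quotient", {
  d <- resight_data(
    surveys = tibble::tribble(
      ~period_id, ~day, ~diel, ~method, ~marked_seen, ~unmarked_seen,
      "P1", 1L, "AM", "SO", 100L, 900L,
      "P1", 1L, "PM", "SO", 120L, 680L),
    markings = tibble::tibble(period_id = "P1", n_marked = 2000L))
  ce <- cumulative_estimates(d, "P1", "SO")
  expect_equal(ce$n_hat[1], lp_point(2000, 1000, 100))
  expect_equal(ce$n_hat[2], 2000 * 900 / 110, tolerance = 1e-9)
  expect_equal(ce$n_hat[2], 16363.636, tolerance = 1e-6)
  expect_true(all(ce$ci_low <= ce$n_hat & ce$n_hat <= ce$ci_high))

  # identical surveys: estimate constant in k, jackknife width zero
  rep6 <- resight_data(
    dplyr::bind_rows(lapply(1:3, function(day)
      dplyr::mutate(d$surveys[c(1, 1), ], day = day, diel = c("AM", "PM")))),
    d$markings)
  c6 <- cumulative_estimates(rep6, "P1", "SO")
  expect_equal(unique(c6$n_hat), 20000)
  expect_equal(c6$ci_high[2:6] - c6$ci_low[2:6], rep(0, 5))
})

test_that("estimates are invariant to survey column order", {
  d <- tiny_dataset()
  reordered <- resight_data(
    d$surveys[, c("unmarked_seen", "method", "period_id", "marked_seen",
                  "diel", "day")],
    d$markings)
  expect_equal(period_estimate(reordered, "P1", "SO")$n_hat,
               period_estimate(d, "P1", "SO")$n_hat)
})

test_that("LP is unbiased under equal detectability at realistic counts", {
  nh <- vapply(1:50, function(r) {
    cfg <- sim_config(n_true = 20000, n_marked = 2000, periods = "P1",
                      methods = "SO", base_detect = c(SO = 0.15),
                      mark_bias = c(SO = 1), sigma_period = 0,
                      sigma_day = 0, sigma_diel = 0, seed = r)
    period_estimate(simulate_surveys(cfg), "P1", "SO")$n_hat
  }, numeric(1))
  expect_lt(abs(mean(nh) / 20000 - 1), 0.01)
})

test_that("marked-detection bias deflates the estimate by the predicted factor", {
  # over-detection of marked turtles inflates R and (mildly) C:
  # E[n_hat]/N = (1 + f(r-1)) / r, with f = M/N and r the exact
  # marked:unmarked detection-probability ratio
  f <- 2000 / 20000
  r <- detect_ratio(0.04, 1.6)
  pred <- (1 + f * (r - 1)) / r
  nh <- vapply(1:100, function(rep) {
    cfg <- sim_config(n_true = 20000, n_marked = 2000, periods = "P1",
                      methods = "SO", base_detect = c(SO = 0.04),
                      mark_bias = c(SO = 1.6), sigma_period = 0,
                      sigma_day = 0, sigma_diel = 0, seed = 400 + rep)
    period_estimate(simulate_surveys(cfg), "P1", "SO")$n_hat
  }, numeric(1))
  expect_lt(abs(mean(nh) / (20000 * pred) - 1), 0.02)
})
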