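#' Conversion factor between two survey methods
#'
#' Methods that detect marked and unmarked turtles with different relative
#' ease yield systematically different Lincoln-Petersen estimates from the
#' same population. A conversion factor places one method's estimates on
#' another's scale: per period the quotient of period-mean estimates,
#' `n_hat(to) / n_hat(from)`, then the arithmetic mean and sample standard
#' deviation over periods. A factor above 1 means `to_method` estimates more
#' turtles than `from_method` — the expected direction when `from_method`
#' over-detects the conspicuous marked animals.
#'
#' @param estimates Tibble of period-level estimates as produced by
#'   [lp_period_estimates()] (columns `period_id`, `method`, `n_hat`).
#' @param from_method,to_method Method labels.
#' @param periods Optional character vector restricting the periods used;
#'   default: every period in which both methods have an estimate.
#' @return A `conversion_factor` object: `from`, `to`, `per_period`
#'   (tibble of quotients), `mean_cf`, `sd_cf` (sample SD, `NA` with a
#'   single period). [tidy()] returns the per-period quotients; [glance()]
#'   the one-row summary.
#' @export
#' @examples
#' est <- tibble::tribble(
#'   ~period_id, ~method, ~n_hat,
#'   "Dec 2016", "SO",  12377.5, "Dec 2016", "UAV", 19682.9,
#'   "Dec 2017", "SO",  20009.4, "Dec 2017", "UAV", 37035.0)
#' glance(conversion_factor(est, "SO", "UAV"))
conversion_factor <- function(estimates, from_method, to_method,
                              periods = NULL) {
  estimates <- as_tibble(estimates)
  wide <- estimates %>%
    filter(.data$method %in% c(from_method, to_method)) %>%
    select("period_id", "method", "n_hat") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "n_hat")
  if (!all(c(from_method, to_method) %in% names(wide)))
    abort("no common period with estimates for both methods",
          class = "markresight_comparison_error")
  keep <- !is.na(wide[[from_method]]) & !is.na(wide[[to_method]])
  if (!is.null(periods)) keep <- keep & wide$period_id %in% periods
  wide <- wide[keep, , drop = FALSE]
  if (nrow(wide) == 0L)
    abort("no common period with estimates for both methods",
          class = "markresight_comparison_error")
  per <- tibble(period_id = wide$period_id,
                quotient = wide[[to_method]] / wide[[from_method]])
  structure(list(from = from_method, to = to_method, per_period = per,
                 mean_cf = mean(per$quotient),
                 sd_cf = if (nrow(per) >= 2L) sd(per$quotient) else NA_real_),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat("<conversion_factor> ", x$from, " -> ", x$to, ": mean ",
      format(x$mean_cf, digits = 4), " (SD ", format(x$sd_cf, digits = 3),
      ", n = ", nrow(x$per_period), " periods)\n", sep = "")
  invisible(x)
}

#' @rdname conversion_factor
#' @param x A `conversion_factor`.
#' @param ... Unused.
#' @method tidy conversion_factor
#' @export
tidy.conversion_factor <- function(x, ...) {
  mutate(x$per_period, from = x$from, to = x$to, .before = 1L)
}

#' @rdname conversion_factor
#' @method glance conversion_factor
#' @export
glance.conversion_factor <- function(x, ...) {
  tibble(from = x$from, to = x$to, mean_cf = x$mean_cf, sd_cf = x$sd_cf,
         n_periods = nrow(x$per_period))
}

#' Apply a conversion factor to a historical abundance series
#'
#' Rescales estimates collected by one method onto another method's scale,
#' the standard way to splice modern survey methods onto a historical
#' surface-observer time series. Missing values propagate as missing.
#'
#' @param series Data frame with columns `year` and `n_hat`.
#' @param cf A [conversion_factor()] (or a bare positive number).
#' @return The series tibble with an added `n_hat_adjusted` column.
#' @export
apply_conversion <- function(series, cf) {
  series <- as_tibble(series)
  f <- if (inherits(cf, "conversion_factor")) cf$mean_cf else as.numeric(cf)
  if (!is.finite(f) || f <= 0) abort("conversion factor must be positive")
  mutate(series, n_hat_adjusted = .data$n_hat * f)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)   # average ranks on ties
  stats::cor(rx, ry)
}

#' Trend of the conversion factor with population size
#'
#' Tests whether the between-method conversion factor drifts with abundance
#' (it would if marked-detection bias depends on turtle density): a
#' Spearman rank correlation of per-period quotients against the matching
#' abundance estimates, with the two-sided p-value obtained by complete
#' permutation enumeration for n <= 8 (printed p-values at these sample
#' sizes are exact, not asymptotic) and by the t approximation otherwise.
#' A least-squares line on the raw scale is returned alongside as a
#' descriptive trend.
#'
#' @param quotients Per-period conversion-factor quotients.
#' @param abundances Matching abundance estimates (same length, no missing
#'   values, n >= 3).
#' @return One-row tibble: `n`, `rho`, `p_value`, `p_method`
#'   (`"exact"`/`"asymptotic"`), `slope`, `intercept`.
#' @export
cf_trend_test <- function(quotients, abundances) {
  x <- as.numeric(quotients); y <- as.numeric(abundances)
  if (length(x) != length(y)) abort("inputs must have equal length")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  n <- length(x)
  if (n < 3L) abort("need at least 3 periods")
  if (sd(x) == 0 || sd(y) == 0)
    abort("rho undefined for a constant input vector",
          class = "markresight_comparison_error")
  rho <- spearman_rho(x, y)
  if (n <= 8L) {
    perms <- all_permutations(n)
    ry <- rank(y)
    rhos <- apply(perms, 1L, function(p) spearman_rho(x, ry[p]))
    p_val <- mean(abs(rhos) >= abs(rho) - 1e-12)
    p_method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p_val <- 2 * pt(-abs(tt), df = n - 2)
    p_method <- "asymptotic"
  }
  fit <- lm(x ~ y)
  tibble(n = n, rho = rho, p_value = p_val, p_method = p_method,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]))
}

#' Compare turtle totals and densities between survey methods
#'
#' Summarises how many turtles each method counts per survey period and
#' whether methods differ once the heavy between-period variation is
#' log-transformed away: per-method means of period-mean totals (and of the
#' derived densities, using each method's surveyed area), with
#' likelihood-ratio tests of the method effect in a Gaussian model on the
#' natural-log period totals (deviance \eqn{D = 2(\ell_{full} -
#' \ell_{null})} against \eqn{\chi^2} with `n_methods - 1` df), and the same
#' on log densities.
#'
#' @param data A [resight_data()] object with at least two methods, each
#'   surveyed in at least two periods — or a period-level summary tibble
#'   with columns `period_id`, `method`, `mean_total` (e.g. a published
#'   results table), used as-is.
#' @param geometry Per-method survey areas, as [default_geometry()].
#' @return A list of class `totals_comparison`: `by_method` (tibble
#'   `method`, `n_periods`, `mean_total`, `mean_density`), `period_totals`,
#'   and `tests` (tibble `response`, `D`, `df`, `p_value`).
#' @export
compare_totals <- function(data, geometry = default_geometry()) {
  pt <- if (inherits(data, "resight_data")) {
    data$surveys %>%
      group_by(.data$period_id, .data$method) %>%
      summarise(mean_total = mean(.data$total_seen), .groups = "drop")
  } else {
    as_tibble(data) %>% select("period_id", "method", "mean_total")
  }
  pt <- pt %>%
    left_join(select(geometry, "method", "area_km2"), by = "method") %>%
    mutate(density = .data$mean_total / .data$area_km2)
  n_per <- pt %>% count(.data$method)
  if (nrow(n_per) < 2L || any(n_per$n < 2L))
    abort("need at least two methods, each with two or more period means",
          class = "markresight_comparison_error")
  zero <- pt$mean_total <= 0
  if (any(zero))
    warn(paste0(sum(zero), " period total(s) of zero excluded from the ",
                "log-scale fit"))
  ptl <- pt[!zero, , drop = FALSE]
  df_test <- length(unique(ptl$method)) - 1L
  lr <- function(y) {
    full <- lm(y ~ factor(ptl$method))
    null <- lm(y ~ 1)
    D <- as.numeric(2 * (logLik(full) - logLik(null)))
    tibble(D = D, df = df_test, p_value = pchisq(D, df_test,
                                                 lower.tail = FALSE))
  }
  tests <- bind_rows(
    mutate(lr(log(ptl$mean_total)), response = "log_total", .before = 1L),
    mutate(lr(log(ptl$density)), response = "log_density", .before = 1L))
  by_method <- pt %>%
    group_by(.data$method) %>%
    summarise(n_periods = dplyr::n(),
              mean_total = mean(.data$mean_total),
              mean_density = mean(.data$density), .groups = "drop")
  structure(list(by_method = by_method, period_totals = pt, tests = tests),
            class = "totals_comparison")
}

#' @export
print.totals_comparison <- function(x, ...) {
  cat("<totals_comparison>\n")
  print(x$by_method)
  print(x$tests)
  invisible(x)
}
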