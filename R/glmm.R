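#' Sampler control settings for the detectability model
#'
#' @param prior_sd_fixed Standard deviation of the Gaussian prior on the
#'   intercept and method contrasts (default 10 — vague on the logit scale).
#' @param cauchy_scale Scale of the half-Cauchy prior on random-effect
#'   standard deviations (default 5), implemented as the exact
#'   inverse-gamma scale mixture so variance updates stay conjugate.
#' @param fix_sigma Character subset of
#'   `c("period", "day", "diel", "resid")`: variance components forced to
#'   zero (their intercepts are dropped). Useful for degenerate checks
#'   against a fixed-effects logistic fit.
#' @param prior_only Switch the likelihood off and sample the prior — a
#'   sampler-correctness diagnostic.
#' @param init_step Initial random-walk step size.
#' @param target_accept Target Metropolis acceptance rate; steps adapt
#'   toward it during burn-in only (default 0.37, inside the usual 30--45%
#'   band for low-dimensional random-walk updates).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return A list of class `detection_control`.
#' @export
detection_control <- function(prior_sd_fixed = 10, cauchy_scale = 5,
                              fix_sigma = character(), prior_only = FALSE,
                              init_step = 0.3, target_accept = 0.37,
                              thin = 1L) {
  if (length(fix_sigma) > 0L)
    fix_sigma <- match.arg(fix_sigma, c("period", "day", "diel", "resid"),
                           several.ok = TRUE)
  structure(list(prior_sd_fixed = prior_sd_fixed,
                 cauchy_scale = cauchy_scale,
                 fix_sigma = fix_sigma, prior_only = isTRUE(prior_only),
                 init_step = init_step, target_accept = target_accept,
                 thin = as.integer(thin)),
            class = "detection_control")
}

# Numerically stable binomial log-likelihood on the logit scale (constant
# binomial coefficient dropped).
binom_ll <- function(R, N, eta) {
  R * eta - N * (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

#' Fit the Bayesian detectability model
#'
#' Models the probability that a resighted turtle carries the paint mark:
#' for survey (period i, day j, diel k),
#' \deqn{R_{ijk} \sim \mathrm{Binomial}(N_{ijk}, P_{ijk})}
#' \deqn{\mathrm{logit}(P_{ijk}) = \alpha + \beta_{method} + b_i + b_{ij} + b_{ijk} + \varepsilon_{ijk}}
#' with a method fixed effect (reference level SO, so \eqn{\beta} are
#' contrasts against the historical surface-observer method), Gaussian
#' nested random intercepts for survey period, day within period and diel
#' slot within day, and an observation-level intercept \eqn{\varepsilon}
#' carrying any extra-binomial dispersion. Under equal detectability of
#' marked and unmarked turtles, \eqn{P} equals the marked fraction of the
#' population for every method; method differences in \eqn{P} are the
#' signature of marked-detection bias.
#'
#' Priors are vague: Gaussian(0, `prior_sd_fixed`^2) on \eqn{\alpha} and
#' \eqn{\beta}, half-Cauchy(`cauchy_scale`) on each random-effect standard
#' deviation. The model is fitted by a built-in Metropolis-within-Gibbs
#' sampler: random-walk Metropolis on the fixed effects and on each block of
#' latent intercepts (blocks are conditionally independent, so whole levels
#' update in one vectorised sweep), with step sizes adapted during burn-in;
#' variances update by conjugate Gibbs draws through the inverse-gamma scale
#' mixture representation of the half-Cauchy. Fits are deterministic given
#' `seed`.
#'
#' @param data A [resight_data()] with at least two methods present and
#'   `total_seen >= 1` in every survey (zero-sighting surveys carry no
#'   information about the marked fraction and are dropped with a warning).
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded per chain.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param control A [detection_control()] list.
#' @return A `detection_fit` object: `draws` (tibble with `chain`, `iter`,
#'   `alpha`, one `beta_*` per non-reference method, `sigma_period`,
#'   `sigma_day`, `sigma_diel`, `sigma_resid`), the acceptance rates, and
#'   the model frame. Methods: [tidy()], [glance()], [variance_partition()],
#'   [marked_proportion()], [autoplot.detection_fit()].
#' @references The model structure follows the standard binomial GLMM with
#'   nested random intercepts used for repeated mark-resight detectability
#'   comparisons.
#' @export
fit_detection_model <- function(data, n_iter = 5000L, n_burn = 1500L,
                                n_chains = 3L, seed = 1L,
                                control = detection_control()) {
  stopifnot(inherits(data, "resight_data"))
  s <- data$surveys
  if (any(s$total_seen < 1L)) {
    warn(paste0(sum(s$total_seen < 1L),
                " survey(s) with zero sightings dropped from the model"))
    s <- s[s$total_seen >= 1L, , drop = FALSE]
  }
  methods <- intersect(method_levels(), unique(s$method))
  if (length(methods) < 2L && !control$prior_only)
    abort("need surveys from at least two methods to contrast detectability")
  if (n_iter <= n_burn) abort("n_iter must exceed n_burn")

  R <- as.numeric(s$marked_seen); N <- as.numeric(s$total_seen)
  if (any(!is.finite(R)) || any(!is.finite(N)))
    abort(paste0("non-finite count in survey row ",
                 which(!is.finite(R + N))[1]))
  ref <- methods[1]
  beta_names <- paste0("beta_", methods[-1])
  midx <- match(s$method, methods)           # 1 = reference
  pidx <- match(s$period_id, unique(s$period_id))
  didx <- as.integer(factor(paste(s$period_id, s$day)))
  tidx <- as.integer(factor(paste(s$period_id, s$day, s$diel)))
  np <- max(pidx); nd <- max(didx); nt <- max(tidx); nobs <- length(R)

  use <- c(period = !"period" %in% control$fix_sigma,
           day    = !"day"    %in% control$fix_sigma,
           diel   = !"diel"   %in% control$fix_sigma,
           resid  = !"resid"  %in% control$fix_sigma)
  prior_only <- control$prior_only
  A2 <- control$cauchy_scale^2
  v0 <- control$prior_sd_fixed^2

  chains <- vector("list", n_chains)
  acc <- NULL
  for (ch in seq_len(n_chains)) {
    res <- with_seed(seed + ch - 1L,
      run_detection_chain(R, N, midx, pidx, didx, tidx,
                          np, nd, nt, nobs, length(methods),
                          n_iter, n_burn, use, prior_only, A2, v0, control))
    res$draws <- mutate(res$draws, chain = ch, .before = 1L)
    chains[[ch]] <- res$draws
    acc <- rbind(acc, res$accept)
  }
  draws <- bind_rows(chains)
  names(draws) <- c("chain", "iter", "alpha", beta_names,
                    "sigma_period", "sigma_day", "sigma_diel", "sigma_resid")
  n_kept <- nrow(draws) / n_chains
  if (n_kept < 200L)
    warn(paste0("only ", n_kept, " retained draws per chain; ",
                "summaries will be unstable"))
  structure(list(
    draws = draws, methods = methods, reference = ref,
    n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
    thin = control$thin, accept = colMeans(acc), control = control,
    model_frame = s
  ), class = "detection_fit")
}

run_detection_chain <- function(R, N, midx, pidx, didx, tidx,
                                np, nd, nt, nobs, nm,
                                n_iter, n_burn, use, prior_only, A2, v0,
                                control) {
  ll <- if (prior_only) function(eta) numeric(length(eta))
        else function(eta) binom_ll(R, N, eta)
  # state
  alpha <- 0; beta <- numeric(nm - 1L)
  u_p <- numeric(np); u_d <- numeric(nd); u_t <- numeric(nt)
  e <- numeric(nobs)
  s2 <- c(period = 1, day = 1, diel = 1, resid = 1)
  a_aux <- c(period = 1, day = 1, diel = 1, resid = 1)
  s2[!use] <- 0
  eta <- rep(alpha, nobs)
  cur <- ll(eta)

  blocks <- c("alpha", if (nm > 1L) paste0("beta", seq_len(nm - 1L)),
              "period", "day", "diel", "resid",
              "tr_alpha", "tr_period", "tr_day", "tr_diel",
              "sc_period", "sc_day", "sc_diel", "sc_resid")
  # group maps for translation moves along confounded directions
  pmap_d <- vapply(seq_len(nd), function(j) pidx[match(j, didx)], integer(1))
  dmap_t <- vapply(seq_len(nt), function(j) didx[match(j, tidx)], integer(1))
  step <- setNames(rep(control$init_step, length(blocks)), blocks)
  acc_n <- acc_d <- setNames(numeric(length(blocks)), blocks)
  win_n <- win_d <- setNames(numeric(length(blocks)), blocks)
  tgt <- control$target_accept

  keep <- seq.int(n_burn + 1L, n_iter, by = control$thin)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 2L + (nm - 1L) + 4L)
  ki <- 0L

  for (it in seq_len(n_iter)) {
    # --- alpha
    d <- step[["alpha"]] * rnorm(1)
    new_eta <- eta + d
    new <- ll(new_eta)
    lacc <- sum(new - cur) + (alpha^2 - (alpha + d)^2) / (2 * v0)
    ok <- log(runif(1)) < lacc
    if (ok) { alpha <- alpha + d; eta <- new_eta; cur <- new }
    win_n[["alpha"]] <- win_n[["alpha"]] + ok
    win_d[["alpha"]] <- win_d[["alpha"]] + 1

    # --- beta contrasts (reference method has none)
    for (j in seq_len(nm - 1L)) {
      nb <- paste0("beta", j)
      sel <- midx == j + 1L
      d <- step[[nb]] * rnorm(1)
      eta_s <- eta[sel] + d
      new_s <- if (prior_only) numeric(sum(sel)) else
        binom_ll(R[sel], N[sel], eta_s)
      lacc <- sum(new_s - cur[sel]) + (beta[j]^2 - (beta[j] + d)^2) / (2 * v0)
      ok <- log(runif(1)) < lacc
      if (ok) {
        beta[j] <- beta[j] + d; eta[sel] <- eta_s; cur[sel] <- new_s
      }
      win_n[[nb]] <- win_n[[nb]] + ok
      win_d[[nb]] <- win_d[[nb]] + 1
    }

    # --- latent intercept blocks (groups conditionally independent)
    for (lev in c("period", "day", "diel", "resid")) {
      if (!use[[lev]]) next
      g <- switch(lev, period = pidx, day = didx, diel = tidx,
                  resid = seq_len(nobs))
      u <- switch(lev, period = u_p, day = u_d, diel = u_t, resid = e)
      ng <- length(u)
      prop <- step[[lev]] * rnorm(ng)
      new_eta <- eta + prop[g]
      new <- ll(new_eta)
      dll <- if (lev == "resid") new - cur else
        as.numeric(rowsum(new - cur, g, reorder = TRUE))
      lacc <- dll + (u^2 - (u + prop)^2) / (2 * s2[[lev]])
      ok <- log(runif(ng)) < lacc
      if (any(ok)) {
        u[ok] <- u[ok] + prop[ok]
        upd <- ok[g]
        eta[upd] <- new_eta[upd]
        cur[upd] <- new[upd]
      }
      switch(lev, period = u_p <- u, day = u_d <- u, diel = u_t <- u,
             resid = e <- u)
      win_n[[lev]] <- win_n[[lev]] + sum(ok)
      win_d[[lev]] <- win_d[[lev]] + ng

      # conjugate variance update through the half-Cauchy scale mixture
      s2[[lev]] <- 1 / stats::rgamma(1, shape = (ng + 1) / 2,
                                     rate = sum(u^2) / 2 + 1 / a_aux[[lev]])

      # interweaved scale move: random walk on log(sigma) holding the
      # standardised intercepts u/sigma fixed — frees the sampler from the
      # centred parameterisation's stickiness near sigma = 0
      if (!prior_only) {
        sc <- paste0("sc_", lev)
        delta <- step[[sc]] * rnorm(1)
        ratio <- exp(delta)
        new_eta <- eta + (ratio - 1) * u[g]
        new <- ll(new_eta)
        lacc <- sum(new - cur) - delta -
          (1 / a_aux[[lev]]) * (1 / (s2[[lev]] * ratio^2) - 1 / s2[[lev]])
        ok <- log(runif(1)) < lacc
        if (ok) {
          u <- u * ratio
          s2[[lev]] <- s2[[lev]] * ratio^2
          eta <- new_eta; cur <- new
          switch(lev, period = u_p <- u, day = u_d <- u, diel = u_t <- u,
                 resid = e <- u)
        }
        win_n[[sc]] <- win_n[[sc]] + ok
        win_d[[sc]] <- win_d[[sc]] + 1
      }

      a_aux[[lev]] <- 1 / stats::rgamma(1, shape = 1,
                                        rate = 1 / s2[[lev]] + 1 / A2)
    }

    # --- translation moves: shift mass along likelihood-invariant
    # directions (alpha vs period intercepts, parent vs child level);
    # acceptance involves the Gaussian priors only.
    if (use[["period"]] && !prior_only) {
      d <- step[["tr_alpha"]] * rnorm(1)
      lacc <- (alpha^2 - (alpha + d)^2) / (2 * v0) +
        sum(u_p^2 - (u_p - d)^2) / (2 * s2[["period"]])
      ok <- log(runif(1)) < lacc
      if (ok) { alpha <- alpha + d; u_p <- u_p - d }
      win_n[["tr_alpha"]] <- win_n[["tr_alpha"]] + ok
      win_d[["tr_alpha"]] <- win_d[["tr_alpha"]] + 1
    }
    if (use[["period"]] && use[["day"]] && !prior_only) {
      d <- step[["tr_period"]] * rnorm(np)
      lacc <- (u_p^2 - (u_p + d)^2) / (2 * s2[["period"]]) +
        as.numeric(rowsum(u_d^2 - (u_d - d[pmap_d])^2, pmap_d)) /
          (2 * s2[["day"]])
      ok <- log(runif(np)) < lacc
      u_p[ok] <- u_p[ok] + d[ok]
      u_d <- u_d - ifelse(ok[pmap_d], d[pmap_d], 0)
      win_n[["tr_period"]] <- win_n[["tr_period"]] + sum(ok)
      win_d[["tr_period"]] <- win_d[["tr_period"]] + np
    }
    if (use[["day"]] && use[["diel"]] && !prior_only) {
      d <- step[["tr_day"]] * rnorm(nd)
      lacc <- (u_d^2 - (u_d + d)^2) / (2 * s2[["day"]]) +
        as.numeric(rowsum(u_t^2 - (u_t - d[dmap_t])^2, dmap_t)) /
          (2 * s2[["diel"]])
      ok <- log(runif(nd)) < lacc
      u_d[ok] <- u_d[ok] + d[ok]
      u_t <- u_t - ifelse(ok[dmap_t], d[dmap_t], 0)
      win_n[["tr_day"]] <- win_n[["tr_day"]] + sum(ok)
      win_d[["tr_day"]] <- win_d[["tr_day"]] + nd
    }
    if (use[["diel"]] && use[["resid"]] && !prior_only) {
      d <- step[["tr_diel"]] * rnorm(nt)
      lacc <- (u_t^2 - (u_t + d)^2) / (2 * s2[["diel"]]) +
        as.numeric(rowsum(e^2 - (e - d[tidx])^2, tidx)) /
          (2 * s2[["resid"]])
      ok <- log(runif(nt)) < lacc
      u_t[ok] <- u_t[ok] + d[ok]
      e <- e - ifelse(ok[tidx], d[tidx], 0)
      win_n[["tr_diel"]] <- win_n[["tr_diel"]] + sum(ok)
      win_d[["tr_diel"]] <- win_d[["tr_diel"]] + nt
    }

    # --- burn-in step adaptation
    if (it <= n_burn && it %% 50L == 0L) {
      for (b in blocks) {
        if (win_d[[b]] > 0) {
          rate <- win_n[[b]] / win_d[[b]]
          step[[b]] <- min(10, max(1e-3, step[[b]] * exp(1.2 * (rate - tgt))))
        }
      }
      acc_n <- acc_n + win_n; acc_d <- acc_d + win_d
      win_n[] <- 0; win_d[] <- 0
    }

    if (it > n_burn && (it - n_burn - 1L) %% control$thin == 0L) {
      ki <- ki + 1L
      out[ki, ] <- c(it, alpha, beta, sqrt(s2))
    }
  }
  acc_n <- acc_n + win_n; acc_d <- acc_d + win_d
  draws <- as_tibble(as.data.frame(out[seq_len(ki), , drop = FALSE]))
  names(draws) <- c("iter", "alpha",
                    if (nm > 1L) paste0("beta", seq_len(nm - 1L)),
                    "sigma_period", "sigma_day", "sigma_diel", "sigma_resid")
  list(draws = draws,
       accept = ifelse(acc_d > 0, acc_n / acc_d, NA_real_))
}

#' @export
print.detection_fit <- function(x, ...) {
  cat("<detection_fit> binomial mixed model of marked-turtle detectability\n")
  cat("  methods: ", paste(x$methods, collapse = ", "),
      " (reference ", x$reference, ")\n", sep = "")
  cat("  chains: ", x$n_chains, ", kept draws: ", nrow(x$draws), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

param_cols <- function(fit) setdiff(names(fit$draws), c("chain", "iter"))

#' Shortest interval containing a given posterior mass
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Probability mass (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' @rdname fit_detection_model
#' @param x,object A `detection_fit`.
#' @param conf_level Credible-interval mass.
#' @param hpd Use highest-posterior-density intervals instead of central
#'   quantile intervals?
#' @param ... Unused.
#' @method tidy detection_fit
#' @export
tidy.detection_fit <- function(x, conf_level = 0.95, hpd = FALSE, ...) {
  purrr::map_dfr(param_cols(x), function(p) {
    v <- x$draws[[p]]
    ci <- if (hpd) hpd_interval(v, conf_level) else
      unname(quantile(v, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
    tibble(term = p, estimate = mean(v), std.error = sd(v),
           conf.low = ci[1], conf.high = ci[2])
  })
}

#' @rdname fit_detection_model
#' @method glance detection_fit
#' @export
glance.detection_fit <- function(x, ...) {
  tibble(n_obs = nrow(x$model_frame), n_chains = x$n_chains,
         n_draws = nrow(x$draws), max_rhat = max(rhat(x)$rhat),
         mean_accept = mean(x$accept, na.rm = TRUE))
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic computed per parameter after
#' splitting each chain in half, so within-chain drift also inflates the
#' statistic. Values near 1 indicate the chains are mixing over the same
#' distribution.
#'
#' @param fit A `detection_fit`.
#' @return Tibble with `term` and `rhat`.
#' @export
rhat <- function(fit) {
  purrr::map_dfr(param_cols(fit), function(p) {
    halves <- fit$draws %>%
      group_by(.data$chain) %>%
      mutate(half = .data$chain * 2 - (row_number() <= n() / 2)) %>%
      ungroup()
    v <- split(halves[[p]], halves$half)
    v <- v[lengths(v) > 1L]
    m <- length(v); n <- min(lengths(v))
    v <- lapply(v, function(z) z[seq_len(n)])
    means <- vapply(v, mean, numeric(1))
    vars <- vapply(v, var, numeric(1))
    B <- n * var(means); W <- mean(vars)
    r <- if (W <= 0) 1 else sqrt(((n - 1) / n * W + B / n) / W)
    tibble(term = p, rhat = r)
  })
}

#' Posterior variance partition of the detectability model
#'
#' For each posterior draw the share of the grouped random-effect variance
#' attributed to each nesting level,
#' \eqn{\sigma^2_c / (\sigma^2_{period} + \sigma^2_{day} + \sigma^2_{diel})},
#' summarised by the posterior mean and a 95% HPD interval. Shares sum to
#' one within every draw. In a closed population resighted over a few days,
#' most variance is expected at the period level; sizeable day or diel
#' shares would flag availability changes within the sampling window.
#'
#' @param fit A `detection_fit` with at least 200 retained draws.
#' @param prob HPD mass (default 0.95).
#' @return Tibble: `component` (`period`, `day`, `diel`), `share_mean`,
#'   `hpd_low`, `hpd_high`.
#' @export
variance_partition <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "detection_fit"))
  if (nrow(fit$draws) < 200L)
    abort("need at least 200 posterior draws for a stable partition")
  s2 <- cbind(period = fit$draws$sigma_period^2,
              day    = fit$draws$sigma_day^2,
              diel   = fit$draws$sigma_diel^2)
  tot <- rowSums(s2)
  zero <- tot == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " draw(s) with all variance components zero; ",
                "their shares set to uniform"))
    s2[zero, ] <- 1; tot[zero] <- 3
  }
  shares <- s2 / tot
  purrr::map_dfr(colnames(shares), function(cmp) {
    v <- shares[, cmp]
    ci <- hpd_interval(v, prob)
    tibble(component = cmp, share_mean = mean(v),
           hpd_low = ci[1], hpd_high = ci[2])
  })
}

#' Posterior marked proportion by survey method
#'
#' The modelled probability that a detected turtle is marked, per method:
#' by default the inverse logit of the fixed linear predictor
#' \eqn{\alpha + \beta_{method}} (the conditional scale, random effects at
#' zero). With `marginal = TRUE` the proportion is averaged over the fitted
#' Gaussian random-effect distribution by quadrature.
#'
#' @param fit A `detection_fit`.
#' @param marginal Average over random effects?
#' @param conf_level Central credible-interval mass (default 0.95).
#' @return Tibble: `method`, `proportion`, `conf.low`, `conf.high`.
#' @export
marked_proportion <- function(fit, marginal = FALSE, conf_level = 0.95) {
  stopifnot(inherits(fit, "detection_fit"))
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  purrr::map_dfr(fit$methods, function(m) {
    eta <- fit$draws$alpha
    if (m != fit$reference) eta <- eta + fit$draws[[paste0("beta_", m)]]
    if (marginal) {
      s2 <- fit$draws$sigma_period^2 + fit$draws$sigma_day^2 +
        fit$draws$sigma_diel^2 + fit$draws$sigma_resid^2
      z <- stats::qnorm(seq(0.5, 20.5) / 21)   # quadrature over the REs
      p <- rowMeans(plogis(outer(eta, rep(1, 21)) +
                             outer(sqrt(s2), z)))
    } else {
      p <- plogis(eta)
    }
    ci <- unname(quantile(p, qs))
    tibble(method = m, proportion = mean(p),
           conf.low = ci[1], conf.high = ci[2])
  })
}
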