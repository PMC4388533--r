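#' Sample the intervention's relative risk reduction
#'
#' Draws from a normal distribution centred at the reported effect size with
#' the SD implied by its 95% confidence interval,
#' `sd = (upper - lower) / (2 * 1.96)`, truncated to `[0, 1)` by rejection
#' (a relative risk reduction cannot be negative or reach 1). Defaults match
#' an active-travel intervention: mean 0.19, 95% CI 0.11 to 0.27.
#'
#' @param n number of draws.
#' @param mean central relative risk reduction.
#' @param ci length-2 numeric, the 95% confidence interval.
#' @return numeric vector of `n` draws in `[0, 1)`.
#' @export
sample_risk_reduction <- function(n = 1, mean = 0.19, ci = c(0.11, 0.27)) {
  stopifnot(length(ci) == 2L, ci[2L] > ci[1L])
  sd <- (ci[2L] - ci[1L]) / (2 * stats::qnorm(0.975))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out >= 1)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0 | out[bad] >= 1]
  }
  out
}

#' Bias-corrected and accelerated (BCa) interval
#'
#' Computes the BCa interval from a sample of outcome replicates. The bias
#' correction `z0` is the normal quantile of the fraction of replicates below
#' the point estimate; the acceleration `a` comes from the skewness of the
#' jackknife (leave-one-out) means of the replicate sample. The adjusted
#' percentiles
#' \deqn{\alpha_j = \Phi\!\Big(z_0 + \frac{z_0 + z_{\alpha_j}}{1 - a (z_0 + z_{\alpha_j})}\Big)}
#' are applied to the empirical distribution of the replicates. With `z0 = 0`
#' and `a = 0` this reduces to the simple percentile interval.
#'
#' @param samples numeric vector of replicates (at least 100 for a stable
#'   interval).
#' @param point_estimate the reference estimate used for the bias correction.
#' @param level interval coverage in `(0, 1)`, default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
bca_interval <- function(samples, point_estimate, level = 0.95) {
  stopifnot(is.numeric(samples), level > 0, level < 1)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 100L) stop("at least 100 replicates are required for a BCa interval")
  if (all(samples == samples[1L])) {
    warning("all replicates identical: degenerate interval")
    return(c(lower = samples[1L], upper = samples[1L]))
  }
  frac_below <- mean(samples < point_estimate)
  if (frac_below == 0 || frac_below == 1) {
    stop("point estimate outside the replicate distribution: bias correction is infinite")
  }
  z0 <- stats::qnorm(frac_below)

  # jackknife acceleration from leave-one-out means
  loo <- (sum(samples) - samples) / (n - 1)
  d <- mean(loo) - loo
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0

  alpha <- (1 + c(-1, 1) * level) / 2
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  q <- stats::quantile(samples, probs = adj, names = FALSE)
  c(lower = q[1L], upper = q[2L])
}

#' Monte-Carlo propagation of input uncertainty
#'
#' Implements the resampling algorithm of the projection: for each of `K`
#' replicates and each sex, perturb the anchor observations (`i`, `m1`, `p`)
#' with log-normal noise, back-calculate the relative mortality at the
#' anchors, calibrate the reference log-parabola and log-line by
#' proportional-hazards offsets, draw a relative risk reduction `h`, solve
#' the prevalence equation for both scenarios and record the scalar
#' outcomes. A replicate whose perturbed inputs are epidemiologically
#' inconsistent (e.g. `m - p m1 <= 0`) is logged and redrawn.
#'
#' One master seed spawns per-replicate seeds up front, so enlarging `K`
#' extends the sequence without reshuffling earlier replicates.
#'
#' @param study a [synthetic_study()] or compatible object (per-sex
#'   `reference` shapes, `general_mortality`, `anchors`; a `config` with
#'   `anchor_log_sd`, `h_mean`, `h_ci`, grid settings).
#' @param K number of Monte-Carlo replicates (default 5000).
#' @param seed master seed.
#' @param report_ages ages at which scenario risks are recorded.
#' @param grid_step,a_max numerical grid; defaults from the study config.
#' @return An object of class `"outcome_distribution"`: `draws` (long
#'   data.frame with `replicate`, `sex`, `outcome`, `value`), `point` (the
#'   same outcomes from the unperturbed anchors and mean `h`), `K`,
#'   `redraws`, `seed`.
#' @export
run_resampling <- function(study, K = 5000, seed = 1,
                           report_ages = c(40, 50, 60, 70, 80, 90),
                           grid_step = study$config$grid_step,
                           a_max = study$config$a_max) {
  stopifnot(K >= 1)
  cfg <- study$config
  sexes <- names(study$sexes)
  point <- lapply(sexes, function(s) {
    os <- contrast_from_anchors(study, s, study$sexes[[s]]$anchors,
                                cfg$h_mean, report_ages, grid_step, a_max)
    cbind(sex = s, outcome_scalars(os, report_ages))
  })
  point <- do.call(rbind, point)

  # the per-sex rate grids are fixed across replicates up to the sampled
  # calibration factors, so evaluate them once
  pre <- lapply(sexes, function(s) {
    precompute_arm(study, s, report_ages, grid_step, a_max)
  })
  names(pre) <- sexes

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, K, replace = TRUE)
  redraws <- 0L
  vals <- vector("list", K)
  for (k in seq_len(K)) {
    attempt <- 0L
    repeat {
      set.seed(rep_seeds[k] + attempt)
      res <- tryCatch(
        lapply(pre, function(pr) replicate_arm(pr, cfg)),
        error = function(e) e)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 100L) {
        stop("replicate ", k, " failed 100 redraws; last error: ",
             conditionMessage(res))
      }
    }
    vals[[k]] <- res
  }
  if (redraws > 0L) {
    message(redraws, " replicate draw(s) were inconsistent and redrawn")
  }

  nout <- length(vals[[1L]][[1L]])
  draws <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(
      replicate = k,
      sex = rep(sexes, each = nout),
      outcome = rep(names(vals[[k]][[1L]]), times = length(sexes)),
      value = unlist(vals[[k]], use.names = FALSE)
    )
  }))
  structure(list(draws = draws, point = point, K = K,
                 redraws = redraws, seed = seed),
            class = "outcome_distribution")
}

# Everything about one sex's arm that does not change across replicates:
# rate grids of the reference shapes and the general mortality, the shared
# survival function, and the reference values at the anchor ages.
precompute_arm <- function(study, sex, report_ages, grid_step, a_max) {
  cfg <- study$config
  arm <- study$sexes[[sex]]
  onset <- cfg$onset_age
  k0 <- round(onset / grid_step)
  if (abs(k0 * grid_step - onset) > 1e-9) {
    stop("the onset age must fall on the integration grid")
  }
  ages <- seq(0, a_max, by = grid_step)
  half <- seq(0, a_max, by = grid_step / 2)
  idx <- (2L * k0 + 1L):length(half)
  ref_i <- enforce_onset_cutoff(arm$reference$incidence, onset)
  m_full <- rate_at(arm$general_mortality, ages)
  list(sex = sex, onset = onset, k0 = k0,
       ages = ages, grid_step = grid_step,
       N0 = cfg$cohort_size, report_ages = report_ages,
       i_half = rate_at(ref_i, half, lower_open = TRUE)[idx],
       m_half = rate_at(arm$general_mortality, half)[idx],
       R_half = rate_at(arm$reference$relative_mortality, half)[idx],
       i_full = rate_at(ref_i, ages, lower_open = TRUE),
       m_full = m_full,
       R_full = rate_at(arm$reference$relative_mortality, ages),
       S = survival_path(m_full, ages),
       anchors = arm$anchors,
       ref_i_anchor = rate_at(arm$reference$incidence, arm$anchors$age),
       ref_R_anchor = rate_at(arm$reference$relative_mortality, arm$anchors$age))
}

# One Monte-Carlo replicate for one sex: perturb the anchors, back-calculate
# R, refit the proportional-hazards offsets, sample h, run both scenarios.
# Errors (inconsistent sampled rates) propagate to the redraw loop.
replicate_arm <- function(pre, cfg) {
  a <- pre$anchors
  n <- nrow(a)
  sd <- cfg$anchor_log_sd
  i_o <- a$i * exp(stats::rnorm(n, 0, sd))
  m1_o <- a$m1 * exp(stats::rnorm(n, 0, sd))
  p_o <- a$p * exp(stats::rnorm(n, 0, sd))
  if (any(p_o >= 1)) stop("sampled anchor prevalence reached 1")
  R_o <- relative_mortality_from_inputs(m1_o, p_o, a$m)
  B <- exp(mean(log(i_o) - log(pre$ref_i_anchor)))
  G <- exp(mean(log(R_o) - log(pre$ref_R_anchor)))
  h <- sample_risk_reduction(1, cfg$h_mean, cfg$h_ci)
  arm_outcomes(pre, B, G, h)
}

# Scenario contrast on precomputed grids: the calibrated rates are the
# reference grids times the sampled factors, so no course object is touched.
arm_outcomes <- function(pre, B, G, h) {
  zeros <- rep(0, pre$k0)
  Rh <- G * pre$R_half
  ib_h <- B * pre$i_half
  pb <- c(zeros, rk4_prevalence_cpp(ib_h, pre$m_half, Rh, pre$grid_step, 0))
  pi_ <- c(zeros, rk4_prevalence_cpp((1 - h) * ib_h, pre$m_half, Rh,
                                     pre$grid_step, 0))
  ages <- pre$ages
  R <- G * pre$R_full
  ib <- B * pre$i_full
  ii <- (1 - h) * ib
  m0_b <- pre$m_full / (1 + pb * (R - 1))
  m0_i <- pre$m_full / (1 + pi_ * (R - 1))
  risk_b <- lifetime_risk(ib, m0_b, ages, pre$onset)
  risk_i <- lifetime_risk(ii, m0_i, ages, pre$onset)
  pc <- prevented_cases(ib, pb, ii, pi_, pre$S, pre$N0, pre$onset)
  df <- delta_disease_free(pb, pi_, pre$S, pre$onset)
  ra <- pre$report_ages
  out <- c(curve_at(risk_b, ra), curve_at(risk_i, ra),
           curve_at(risk_b, ra) - curve_at(risk_i, ra),
           pc$prevented_fraction, df$delta, df$relative_gain, df$ef_bau)
  names(out) <- c(paste0("risk_bau_", ra), paste0("risk_iat_", ra),
                  paste0("arr_", ra),
                  "prevented_fraction", "delta_disease_free",
                  "relative_gain", "ef_bau")
  out
}

# Calibrate shapes to a set of anchor observations, build the two scenario
# arms and run the analytic contrast.
contrast_from_anchors <- function(study, sex, anchors, h, report_ages,
                                  grid_step, a_max) {
  cfg <- study$config
  arm <- study$sexes[[sex]]
  R_obs <- relative_mortality_from_inputs(anchors$m1, anchors$p, anchors$m)
  fit_i <- fit_log_parabola_offset(arm$reference$incidence, anchors$age, anchors$i)
  fit_R <- fit_log_line_offset(arm$reference$relative_mortality, anchors$age, R_obs)
  bau <- scenario_inputs(fit_i$shape, arm$general_mortality, fit_R$shape,
                         sex = sex, scenario = "BAU",
                         onset_age = cfg$onset_age,
                         birth_year = cfg$birth_year,
                         cohort_size = cfg$cohort_size)
  iat <- scenario_inputs(apply_intervention(fit_i$shape, h),
                         arm$general_mortality, fit_R$shape,
                         sex = sex, scenario = "IAT",
                         onset_age = cfg$onset_age,
                         birth_year = cfg$birth_year,
                         cohort_size = cfg$cohort_size)
  scenario_contrast(bau, iat, grid_step = grid_step, a_max = a_max,
                    report_ages = report_ages, check = FALSE)
}

# Flatten an outcome_set into the long (outcome, value) form used by the
# Monte-Carlo machinery.
outcome_scalars <- function(os, report_ages) {
  tab <- os$risk_table
  data.frame(
    outcome = c(paste0("risk_bau_", report_ages),
                paste0("risk_iat_", report_ages),
                paste0("arr_", report_ages),
                "prevented_fraction", "delta_disease_free",
                "relative_gain", "ef_bau"),
    value = c(tab$risk_bau, tab$risk_iat, tab$arr,
              os$prevented_fraction, os$delta_disease_free,
              os$relative_gain, os$ef_bau)
  )
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat(sprintf("outcome distribution: %d replicates (%d redraws), seed %s\n",
              x$K, x$redraws, format(x$seed)))
  invisible(x)
}

#' Point estimates with BCa confidence intervals
#'
#' Applies [bca_interval()] to every scalar outcome in a Monte-Carlo
#' [run_resampling()] result, using the unperturbed point-estimate run as
#' the BCa reference estimate.
#'
#' @param dist an `outcome_distribution`.
#' @param level interval coverage (default 0.95).
#' @return data.frame with `sex`, `outcome`, `point`, `lower`, `upper`.
#' @export
summarize_uncertainty <- function(dist, level = 0.95) {
  stopifnot(inherits(dist, "outcome_distribution"))
  keys <- unique(dist$point[, c("sex", "outcome")])
  out <- lapply(seq_len(nrow(keys)), function(j) {
    s <- keys$sex[j]; o <- keys$outcome[j]
    v <- dist$draws$value[dist$draws$sex == s & dist$draws$outcome == o]
    pt <- dist$point$value[dist$point$sex == s & dist$point$outcome == o]
    ci <- bca_interval(v, pt, level = level)
    data.frame(sex = s, outcome = o, point = pt,
               lower = ci[["lower"]], upper = ci[["upper"]])
  })
  do.call(rbind, out)
}
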