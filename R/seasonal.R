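# Seasonal estimators: hierarchical-bootstrap monthly displacement
# estimates, penalized cyclic harmonic seasonal curves, and the
# lunar-illumination effect on night activity. These are in-repo
# replacements for mixed-model package fits, targeting the same
# estimands (group x month means; smooth month effects per light period).

#' Monthly displacement estimates per demographic group
#'
#' Point estimate per group x month: the mean of per-animal monthly mean
#' displacements (equal animal weighting, so unevenly sampled individuals
#' do not dominate). Uncertainty comes from a two-stage hierarchical
#' bootstrap: resample animals with replacement, then resample each chosen
#' animal's observations within month. Also reports, per group, the grand
#' seasonal mean +/- SE of the monthly estimates.
#'
#' @param disp Displacements (with `group`) from
#'   [compute_displacements()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param tz_offset_hours Civil offset for calendar month (default 8).
#' @return List with `monthly` (group, month, estimate, lwr, upr,
#'   n_animals, n_obs) and `grand` (group, grand_mean, grand_se,
#'   n_months).
#' @export
monthly_displacement_estimates <- function(disp, n_boot = 1000L,
                                           seed = NULL,
                                           tz_offset_hours = 8) {
  disp <- disp[!is.na(disp$group), , drop = FALSE]
  disp$month <- local_month(disp$t_start, tz_offset_hours)
  monthly <- list(); grand <- list()
  for (g in unique(disp$group)) {
    dg <- disp[disp$group == g, , drop = FALSE]
    ids <- unique(dg$animal_id)
    if (length(ids) < 2L)
      warning(sprintf("group '%s' has < 2 animals; estimates are fragile", g))
    # per-animal x month observation lists
    obs <- split(dg$distance_m, list(dg$animal_id, dg$month), drop = TRUE)
    months <- sort(unique(dg$month))
    point <- vapply(months, function(m) {
      am <- vapply(ids, function(id) {
        o <- obs[[paste(id, m, sep = ".")]]
        if (is.null(o)) NA_real_ else mean(o)
      }, numeric(1))
      mean(am, na.rm = TRUE)
    }, numeric(1))
    boot <- with_seed(derive_seed(seed, sum(utf8ToInt(g))), {
      vapply(seq_len(n_boot), function(b) {
        bids <- sample(ids, replace = TRUE)
        vapply(months, function(m) {
          am <- vapply(bids, function(id) {
            o <- obs[[paste(id, m, sep = ".")]]
            if (is.null(o)) NA_real_ else mean(sample(o, replace = TRUE))
          }, numeric(1))
          mean(am, na.rm = TRUE)
        }, numeric(1))
      }, numeric(length(months)))
    })
    boot <- matrix(boot, nrow = length(months))
    monthly[[g]] <- data.frame(
      group = g, month = months, estimate = point,
      lwr = apply(boot, 1, stats::quantile, 0.025, na.rm = TRUE),
      upr = apply(boot, 1, stats::quantile, 0.975, na.rm = TRUE),
      n_animals = vapply(months, function(m)
        length(unique(dg$animal_id[dg$month == m])), integer(1)),
      n_obs = vapply(months, function(m) sum(dg$month == m), integer(1))
    )
    grand[[g]] <- data.frame(
      group = g, grand_mean = mean(point),
      grand_se = stats::sd(point) / sqrt(length(point)),
      n_months = length(months)
    )
  }
  monthly <- do.call(rbind, monthly); rownames(monthly) <- NULL
  grand <- do.call(rbind, grand); rownames(grand) <- NULL
  list(monthly = monthly, grand = grand)
}

# Cyclic harmonic (Fourier) basis on month in [1, 12]; K harmonics.
# A 6th harmonic contributes cos only (its sine vanishes at integer
# months), so K = 6 spans all 12 monthly means exactly.
harmonic_basis <- function(month, K) {
  x <- 2 * pi * month / 12
  cols <- list(`(Intercept)` = rep(1, length(month)))
  for (k in seq_len(min(K, 5))) {
    cols[[paste0("cos", k)]] <- cos(k * x)
    cols[[paste0("sin", k)]] <- sin(k * x)
  }
  if (K >= 6) cols[["cos6"]] <- cos(6 * x)
  do.call(cbind, cols)
}

# Penalty multiplicities per basis column (0 for intercept, k^2 per
# harmonic pair) and a weighted ridge fit with GCV over a lambda grid.
.harmonic_pen <- function(K) {
  pen <- 0
  for (k in seq_len(min(K, 5))) pen <- c(pen, k^2, k^2)
  if (K >= 6) pen <- c(pen, 36)
  pen
}

.ridge_gcv <- function(B, y, w, pen, lambda_grid) {
  n <- length(y)
  W <- w / mean(w)
  BtWB <- crossprod(B, B * W)
  BtWy <- crossprod(B, y * W)
  best <- NULL
  for (lam in lambda_grid) {
    M <- BtWB + lam * diag(pen, nrow = length(pen))
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) next
    beta <- Minv %*% BtWy
    fit <- drop(B %*% beta)
    edf <- sum(diag(Minv %*% BtWB))
    rss <- sum(W * (y - fit)^2)
    gcv <- n * rss / (n - min(edf, n - 1e-6))^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(beta = beta, lambda = lam, edf = edf, gcv = gcv)
  }
  if (is.null(best)) stop("ridge system singular for all lambda")
  best
}

#' Seasonal activity curve per light period
#'
#' Smooth cyclic curve of a stratum response (proportion of time active,
#' or activity rate when active) against calendar month, fitted by
#' penalized cyclic harmonic regression: a Fourier basis in month with
#' ridge penalty chosen by generalised cross-validation. Individual
#' heterogeneity is handled by per-animal centring on the link scale;
#' the SE band comes from an animal-level bootstrap. Proportions are
#' fitted on the logit scale (empirical logits with the sample counts as
#' weights) and back-transformed, so fitted proportions stay in `[0, 1]`;
#' the curve is periodic (month 12 joins month 1).
#'
#' @param components Output of [activity_components()].
#' @param period Light period to fit (`"dawn"`, `"day"`, `"dusk"`,
#'   `"night"`).
#' @param response `"prop_active"` or `"rate_when_active"`.
#' @param n_harmonics Number of harmonics K (default 3; reduced with a
#'   warning when fewer distinct months are observed).
#' @param lambda_grid Ridge penalty grid for GCV.
#' @param n_boot Animal-bootstrap replicates for the SE band (default
#'   200).
#' @param seed RNG seed.
#' @param month_grid Months at which to evaluate the curve.
#' @return Object of class `seasonal_curve`: list with `month`, `fit`,
#'   `se`, `lambda`, `edf`, `period`, `response`.
#' @export
seasonal_activity_curve <- function(components, period, response = "prop_active",
                                    n_harmonics = 3L,
                                    lambda_grid = 10^seq(-5, 5, length.out = 31),
                                    n_boot = 200L, seed = NULL,
                                    month_grid = seq(1, 13, by = 0.1)) {
  d <- components[components$period == period, , drop = FALSE]
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  n_months <- length(unique(d$month))
  if (n_months < 3L) stop("need at least 3 distinct observed months")
  K <- n_harmonics
  while (1 + 2 * min(K, 5) + (K >= 6) > n_months && K > 1L) {
    K <- K - 1L
  }
  if (K < n_harmonics)
    warning(sprintf("n_harmonics reduced to %d for %d observed months",
                    K, n_months))
  logit_link <- response == "prop_active"
  link <- function(p, n) log((p * n + 0.5) / ((1 - p) * n + 0.5))
  y_raw <- if (logit_link) link(d[[response]], d$n) else d[[response]]
  w <- d$n

  fit_once <- function(idx) {
    yy <- y_raw[idx]; dd <- d[idx, , drop = FALSE]; ww <- w[idx]
    # per-animal centring on the link scale
    am <- tapply(yy, dd$animal_id, mean)
    yc <- yy - am[as.character(dd$animal_id)] + stats::weighted.mean(yy, ww)
    B <- harmonic_basis(dd$month, K)
    fit <- .ridge_gcv(B, yc, ww, .harmonic_pen(K), lambda_grid)
    list(curve = drop(harmonic_basis(month_grid, K) %*% fit$beta),
         lambda = fit$lambda, edf = fit$edf)
  }
  main <- fit_once(seq_len(nrow(d)))
  ids <- unique(d$animal_id)
  se <- rep(NA_real_, length(month_grid))
  if (n_boot > 0L && length(ids) > 1L) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      bids <- sample(ids, replace = TRUE)
      idx <- unlist(lapply(bids, function(id) which(d$animal_id == id)))
      fit_once(idx)$curve
    }, numeric(length(month_grid))))
    se <- apply(matrix(boots, nrow = length(month_grid)), 1, stats::sd)
  }
  fitv <- main$curve
  if (logit_link) {
    lwr <- stats::plogis(fitv - 2 * se); upr <- stats::plogis(fitv + 2 * se)
    fitv <- stats::plogis(fitv)
    se_out <- (upr - lwr) / 4
  } else se_out <- se
  structure(list(month = month_grid, fit = fitv, se = se_out,
                 lambda = main$lambda, edf = main$edf,
                 period = period, response = response, K = K),
            class = "seasonal_curve")
}

#' Lunar-illumination effect on night activity
#'
#' Regression (logit scale) of the probability of being active at night on
#' the moon's illuminated fraction, restricted to samples when the moon is
#' above the horizon. The CI comes from an animal-level bootstrap.
#'
#' @param night_samples data.frame with `animal_id`, `active` (logical)
#'   and `illuminated_fraction`, already restricted to night periods with
#'   the moon up.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @return List with `slope` (logit scale per unit illuminated fraction),
#'   `ci`, `n`.
#' @export
lunar_activity_effect <- function(night_samples, n_boot = 200L, seed = NULL) {
  d <- night_samples
  if (!nrow(d)) stop("no night-time samples with the moon above the horizon")
  if (stats::var(d$illuminated_fraction) == 0)
    stop("illumination has no variance; slope undefined")
  fit1 <- function(dd)
    stats::coef(stats::glm(active ~ illuminated_fraction,
                           family = stats::binomial(), data = dd))[2]
  slope <- unname(fit1(d))
  ids <- unique(d$animal_id)
  ci <- NULL
  if (n_boot > 0L && length(ids) > 1L) {
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      bids <- sample(ids, replace = TRUE)
      dd <- do.call(rbind, lapply(bids, function(id) {
        di <- d[d$animal_id == id, , drop = FALSE]
        di[sample(nrow(di), replace = TRUE), , drop = FALSE] # within-animal
      }))
      tryCatch(unname(fit1(dd)), error = function(e) NA_real_)
    }, numeric(1)))
    ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(slope = slope, ci = ci, n = nrow(d))
}
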