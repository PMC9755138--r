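# Synthetic telemetry generator.
#
# Hourly latent movement model: each animal takes one step per hour, a
# two-component mixture of short local displacements and longer forays.
# The foray probability follows a 24-bin circadian intensity over suntime,
# rotated and share-modulated by month, and is calibrated so that (a) the
# group's mean 5-h displacement and (b) the night share of the movement
# density match the configured study conditions. One bearing per 5-h block
# (per hour for hourly species) with no within-block jitter, so a 5-h fix
# displacement equals the sum of its hourly step lengths and the 1/5
# disaggregation used downstream is exactly invertible in expectation.
# Positions are planar around the site and never leave +/-0.5 degrees.

# ---- step-mixture moments and samplers ----

.lnorm_trunc_mean <- function(mu, sig, lo, hi) {
  num <- stats::pnorm((log(hi) - mu - sig^2) / sig) -
    stats::pnorm((log(lo) - mu - sig^2) / sig)
  den <- stats::pnorm((log(hi) - mu) / sig) - stats::pnorm((log(lo) - mu) / sig)
  exp(mu + sig^2 / 2) * num / den
}

.sample_lnorm_trunc <- function(n, mu, sig, lo, hi) {
  plo <- stats::plnorm(lo, mu, sig); phi <- stats::plnorm(hi, mu, sig)
  stats::qlnorm(stats::runif(n, plo, phi), mu, sig)
}

.exp_trunc_mean <- function(scale, hi) {
  if (scale <= 0) return(0)
  scale - hi * exp(-hi / scale) / (1 - exp(-hi / scale))
}

.sample_exp_trunc <- function(n, scale, hi) {
  if (scale <= 0) return(numeric(n))
  stats::qexp(stats::runif(n, 0, stats::pexp(hi, 1 / scale)), 1 / scale)
}

# ---- circadian weight machinery ----

.vm_bump <- function(theta, mu, kappa) exp(kappa * (cos(theta - mu) - 1))

# Template intensity shapes over suntime (unnormalised).
.template_shape <- function(template) {
  th <- bin_midpoints()
  switch(template,
    predator = 0.45 + 1.5 * .vm_bump(th, pi / 2, 3) +
      1.5 * .vm_bump(th, 3 * pi / 2, 3) +
      0.55 * .vm_bump(th, 0, 1.2), # night elevation
    wild_prey = 0.08 + 1.4 * .vm_bump(th, 0.75 * pi, 5) +
      1.4 * .vm_bump(th, 1.28 * pi, 5) + 0.25 * .vm_bump(th, pi, 2),
    livestock = 0.03 + 1.2 * .vm_bump(th, 0.8 * pi, 3) +
      1.2 * .vm_bump(th, 1.25 * pi, 3),
    stop("unknown species template: ", template)
  )
}

.night_bins <- function() {
  th <- bin_midpoints()
  th < pi / 2 | th >= 3 * pi / 2
}

# Rotate a 24-bin weight vector by delta radians (circular linear
# interpolation of the midpoint values).
rotate_weights <- function(w, delta) {
  if (delta == 0) return(w)
  th <- bin_midpoints()
  src <- wrap_2pi(th - delta)
  k0 <- floor((src - pi / 24) / (pi / 12)) %% 24 + 1
  k1 <- k0 %% 24 + 1
  frac <- ((src - bin_midpoints()[k0]) %% (2 * pi)) / (pi / 12)
  w[k0] * (1 - frac) + w[k1] * frac
}

# Movement density per bin implied by weights w (mean 1) and an activity
# scale: per-hour expected movement at suntime bin b.
.movement_density <- function(w, act_scale, m_foray, m_local) {
  p <- pmin(act_scale * w, 0.97)
  p * m_foray + (1 - p) * m_local
}

# Tilt the weights smoothly (exp(beta * cos(theta)), peaking at the night
# midpoint) so the movement density's night share equals `share`, then
# renormalise to mean 1. The tilt is smooth on the circle, so the density
# has no jump at the day/night boundaries and coarse-schedule smoothing
# does not bias the share.
.calibrate_share <- function(w, share, act_scale, m_foray, m_local) {
  night <- .night_bins()
  th <- bin_midpoints()
  tilt <- function(beta) {
    ww <- w * exp(beta * cos(th))
    ww / mean(ww)
  }
  f <- function(beta) {
    m <- .movement_density(tilt(beta), act_scale, m_foray, m_local)
    sum(m[night]) / sum(m) - share
  }
  beta <- stats::uniroot(f, c(-8, 8), tol = 1e-10)$root
  tilt(beta)
}

#' Synthetic telemetry configuration
#'
#' Study-condition parameters for the generator. Defaults emulate the
#' field conditions the analysis assumes: a 5-hourly nocturnal-crepuscular
#' predator whose activity shifts seasonally (night share of the movement
#' density 0.68 averaged over May-Aug and 0.58 over Dec-Feb, i.e. annual
#' level 0.633 with first-harmonic amplitude 0.058 peaking in July),
#' an hourly diurnal-bimodal wild prey (night share 0.36), and livestock
#' on a corral schedule (hourly 07:00-22:00 local plus one 03:00 fix).
#' Group mean 5-h displacements default to 1473 m (adult males), 1017 m
#' (subadults), 850 m (adult females) and 750 m (females with young
#' cubs).
#'
#' @param species_template `"predator"`, `"wild_prey"` or `"livestock"`.
#' @param n_animals Number of animals (> 0).
#' @param start_date,end_date Deployment window (Dates; end > start).
#' @param site_lon,site_lat Site coordinates (default 100 E, 43 N).
#' @param fix_schedule `"every_5h"`, `"hourly"` or `"corral"`; default by
#'   template.
#' @param circadian_weights Optional explicit 24-vector of nonnegative
#'   suntime-bin intensities (mean-normalised internally). When supplied,
#'   no night-share calibration is applied unless `night_share` is also
#'   given.
#' @param night_share Target night share of the movement density (annual
#'   level): a scalar applied to all groups, a named per-group vector, or
#'   NULL to keep `circadian_weights` as given. Predator defaults are
#'   0.66 (adult males), 0.63 (subadults) and 0.60 (adult females /
#'   females with cubs), the sex-specific night/day activity splits of
#'   the study conditions.
#' @param night_share_amplitude Seasonal first-harmonic amplitude of the
#'   night share (peaks in July).
#' @param seasonal_shift Amplitude (radians) of the month-dependent
#'   rotation of the circadian weights (summer rotates activity toward
#'   night/dawn, winter toward day/dusk).
#' @param step_mixture List: `p_local` (NULL = derive the foray
#'   probability from `group_mean_5h`), `local_scale_m`,
#'   `foray_log_mean`, `foray_log_sd`, `foray_min_m`, `foray_max_m`.
#' @param group_mean_5h Named vector of target mean 5-h displacements (m)
#'   per demographic group.
#' @param groups Group labels recycled over animals.
#' @param accel_active_mean,accel_rest_mean Accelerometer state means
#'   (0-255 scale).
#' @param accel_axis_corr Target Pearson correlation between the two
#'   accelerometer axes (default 0.96).
#' @param accel_active_prob Baseline probability of the active state at
#'   mean circadian intensity (default 0.45).
#' @param lunar_effect Logit-scale slope of night active-probability on
#'   the moon's illuminated fraction when the moon is up (default 0).
#' @param error_rate Fraction of fixes corrupted by [inject_gps_errors()].
#' @param killsite_rate Kill-site episodes per animal-month.
#' @param seed Integer seed; identical (config, seed) reproduces identical
#'   output byte for byte.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(species_template = c("predator", "wild_prey",
                                              "livestock"),
                         n_animals = 2L,
                         start_date = as.Date("2019-01-01"),
                         end_date = as.Date("2019-12-31"),
                         site_lon = 100, site_lat = 43,
                         fix_schedule = NULL,
                         circadian_weights = NULL,
                         night_share = NULL,
                         night_share_amplitude = NULL,
                         seasonal_shift = NULL,
                         step_mixture = list(),
                         group_mean_5h = NULL,
                         groups = NULL,
                         accel_active_mean = 115,
                         accel_rest_mean = 6,
                         accel_axis_corr = 0.96,
                         accel_active_prob = 0.45,
                         lunar_effect = 0,
                         error_rate = 0,
                         killsite_rate = 0,
                         seed = 1L) {
  template <- match.arg(species_template)
  if (n_animals < 1L) stop("config error: n_animals must be >= 1")
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("config error: end_date must follow start_date")
  fix_schedule <- fix_schedule %||% switch(template,
    predator = "every_5h", wild_prey = "hourly", livestock = "corral")
  defaults <- switch(template,
    predator = list(night_share = c(adult_male = 0.66, subadult = 0.63,
                                    adult_female = 0.60,
                                    female_with_cubs = 0.60),
                    amp = 0.058, shift = 0.15,
                    mix = list(p_local = NULL, local_scale_m = 20,
                               foray_log_mean = log(700), foray_log_sd = 1.0,
                               foray_min_m = 100, foray_max_m = 10000),
                    gm = c(adult_male = 1473, subadult = 1017,
                           adult_female = 850, female_with_cubs = 750),
                    groups = c("adult_male", "adult_female", "subadult",
                               "female_with_cubs")),
    wild_prey = list(night_share = 0.36, amp = 0, shift = 0,
                     mix = list(p_local = NULL, local_scale_m = 15,
                                foray_log_mean = log(500),
                                foray_log_sd = 0.9,
                                foray_min_m = 50, foray_max_m = 5000),
                     gm = c(ibex = 1100), groups = "ibex"),
    livestock = list(night_share = NULL, amp = 0, shift = 0,
                     mix = list(p_local = NULL, local_scale_m = 15,
                                foray_log_mean = log(350),
                                foray_log_sd = 0.8,
                                foray_min_m = 50, foray_max_m = 4000),
                     gm = c(goat = 1000), groups = "goat"))
  mix <- utils::modifyList(defaults$mix, step_mixture)
  if (!is.null(mix$p_local) && (mix$p_local < 0 || mix$p_local > 1))
    stop("config error: p_local must lie in [0, 1]")
  if (error_rate < 0 || error_rate > 1)
    stop("config error: error_rate must lie in [0, 1]")
  if (killsite_rate < 0) stop("config error: killsite_rate must be >= 0")
  if (accel_active_mean < 0 || accel_active_mean > 255 ||
      accel_rest_mean < 0 || accel_rest_mean > 255)
    stop("config error: accelerometer state means must lie in [0, 255]")
  if (abs(accel_axis_corr) > 1)
    stop("config error: accel_axis_corr must lie in [-1, 1]")
  if (!is.null(night_share) &&
      (any(night_share <= 0) || any(night_share >= 1)))
    stop("config error: night_share must lie in (0, 1)")
  explicit_w <- !is.null(circadian_weights)
  if (explicit_w) {
    stopifnot(length(circadian_weights) == 24L)
    if (any(circadian_weights < 0) || all(circadian_weights == 0))
      stop("config error: circadian_weights must be nonnegative, not all zero")
    circadian_weights <- circadian_weights / mean(circadian_weights)
  } else {
    sh <- .template_shape(template)
    circadian_weights <- sh / mean(sh)
  }
  cfg <- list(
    species_template = template, n_animals = as.integer(n_animals),
    start_date = start_date, end_date = end_date,
    site_lon = site_lon, site_lat = site_lat,
    fix_schedule = fix_schedule,
    circadian_weights = circadian_weights,
    night_share = if (explicit_w) night_share else
      night_share %||% defaults$night_share,
    night_share_amplitude = night_share_amplitude %||%
      (if (explicit_w) 0 else defaults$amp),
    seasonal_shift = seasonal_shift %||%
      (if (explicit_w) 0 else defaults$shift),
    step_mixture = mix,
    group_mean_5h = group_mean_5h %||% defaults$gm,
    groups = groups %||% defaults$groups,
    accel_active_mean = accel_active_mean,
    accel_rest_mean = accel_rest_mean,
    accel_axis_corr = accel_axis_corr,
    accel_active_prob = accel_active_prob,
    lunar_effect = lunar_effect,
    error_rate = error_rate, killsite_rate = killsite_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

# Mixture moments for a config.
.mixture_moments <- function(cfg) {
  mx <- cfg$step_mixture
  list(
    m_foray = .lnorm_trunc_mean(mx$foray_log_mean, mx$foray_log_sd,
                                mx$foray_min_m, mx$foray_max_m),
    m_local = .exp_trunc_mean(mx$local_scale_m, 150)
  )
}

# Per-hour foray probability scale for a group target 5-h mean.
.act_scale <- function(cfg, group) {
  mm <- .mixture_moments(cfg)
  if (!is.null(cfg$step_mixture$p_local)) return(1 - cfg$step_mixture$p_local)
  target_h <- unname(cfg$group_mean_5h[group]) / 5
  if (is.na(target_h)) stop("no group_mean_5h entry for group ", group)
  s <- (target_h - mm$m_local) / (mm$m_foray - mm$m_local)
  min(max(s, 0), 0.97)
}

# Night-share target for a group: scalar applies to all groups, a named
# vector is looked up (falling back to its mean for unlisted groups).
.group_share <- function(cfg, group) {
  ns <- cfg$night_share
  if (is.null(ns)) return(NULL)
  if (length(ns) == 1L && is.null(names(ns))) return(unname(ns))
  val <- unname(ns[group])
  if (is.na(val)) mean(ns) else val
}

# 12 x 24 month-by-bin weight matrix for a group: seasonal rotation then
# exact night-share calibration per month (when night_share is set).
.month_weights <- function(cfg, group) {
  mm <- .mixture_moments(cfg)
  s <- .act_scale(cfg, group)
  share0 <- .group_share(cfg, group)
  W <- matrix(0, 12, 24)
  for (m in 1:12) {
    phase <- cos(2 * pi * (m - 7) / 12)
    w <- rotate_weights(cfg$circadian_weights, -cfg$seasonal_shift * phase)
    w <- w / mean(w)
    if (!is.null(share0) && s > 1e-9) {
      share_m <- share0 + cfg$night_share_amplitude * phase
      w <- .calibrate_share(w, share_m, s, mm$m_foray, mm$m_local)
    }
    W[m, ] <- w
  }
  W
}

#' True night share of the movement density
#'
#' The generator's ground-truth night share (suntime in
#' `[3*pi/2, 2*pi) U [0, pi/2)`) of the expected movement density for a
#' group, averaged over the given months. This is the quantity the
#' pipeline's [day_night_proportion()] estimates.
#'
#' @param cfg A [synth_config()].
#' @param group Demographic group label.
#' @param months Months to average over (default all).
#' @return Scalar night share in `[0, 1]`.
#' @export
true_night_share <- function(cfg, group, months = 1:12) {
  mm <- .mixture_moments(cfg)
  s <- .act_scale(cfg, group)
  W <- .month_weights(cfg, group)
  night <- .night_bins()
  shares <- vapply(months, function(m) {
    dens <- .movement_density(W[m, ], s, mm$m_foray, mm$m_local)
    sum(dens[night]) / sum(dens)
  }, numeric(1))
  mean(shares)
}

# Schedule hour indices (into the hourly grid) for an animal.
.schedule_index <- function(hours_utc, schedule) {
  n <- length(hours_utc)
  if (schedule == "every_5h") {
    seq(1L, n, by = 5L)
  } else if (schedule == "hourly") {
    seq_len(n)
  } else if (schedule == "corral") {
    lh <- as.POSIXlt(hours_utc + 8 * 3600, tz = "UTC")$hour
    which(lh %in% c(3L, 7:22))
  } else stop("unknown fix_schedule: ", schedule)
}

#' Generate synthetic GPS tracks
#'
#' Simulates the hourly latent movement model and emits fixes on the
#' configured schedule, together with animal metadata and the ground
#' truth needed for round-trip tests (month-by-bin intensity, cub
#' windows, activity scales).
#'
#' @param cfg A [synth_config()].
#' @return List with `fixes` (animal_id, species, sex, age_class,
#'   timestamp, lon, lat), `metadata`, and `truth` (list: `births`,
#'   `month_weights`, `act_scale`, `error_labels`, `killsite_windows`).
#' @export
generate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  t0 <- as_utc(cfg$start_date); t1 <- as_utc(cfg$end_date)
  if (as.numeric(t1 - t0, units = "hours") <
      switch(cfg$fix_schedule, every_5h = 5, 1))
    stop("empty output: date range shorter than one fix interval")
  groups <- rep_len(cfg$groups, cfg$n_animals)
  prefix <- switch(cfg$species_template, predator = "SL", wild_prey = "IB",
                   livestock = "GT")
  ids <- sprintf("%s%02d", prefix, seq_len(cfg$n_animals))
  species <- switch(cfg$species_template, predator = "predator",
                    wild_prey = "ibex", livestock = "goat")
  sex <- ifelse(groups %in% c("adult_female", "female_with_cubs"), "F",
                ifelse(groups == "adult_male", "M",
                       ifelse(seq_along(groups) %% 2 == 0, "F", "M")))
  age <- ifelse(groups == "subadult", "subadult", "adult")
  mm <- .mixture_moments(cfg)
  mx <- cfg$step_mixture
  births <- NULL
  fixes <- vector("list", cfg$n_animals)
  Wlist <- list(); slist <- list()

  for (a in seq_len(cfg$n_animals)) {
    id <- ids[a]; grp <- groups[a]
    stagger <- (a - 1L) %% 5L
    dep0 <- t0 + stagger * 3600
    hours <- seq(dep0, t1, by = 3600)
    n_h <- length(hours) - 1L # steps between hourly nodes
    mid <- hours[-length(hours)] + 1800
    theta <- to_suntime(mid, cfg$site_lon, cfg$site_lat)
    bin <- suntime_bin(theta)
    month <- local_month(mid)
    base_grp <- if (grp == "female_with_cubs") "adult_female" else grp
    W <- .month_weights(cfg, base_grp)
    s_base <- .act_scale(cfg, base_grp)
    Wlist[[grp]] <- .month_weights(cfg, grp)
    slist[[grp]] <- .act_scale(cfg, grp)
    s_vec <- rep(s_base, n_h)
    if (grp == "female_with_cubs") {
      birth <- as.Date(cfg$start_date) + 60
      wend <- seq(birth, by = "month", length.out = 6L)[6L]
      births <- rbind(births, data.frame(animal_id = id, birth_date = birth))
      in_win <- as.numeric(mid) >= as.numeric(as_utc(birth)) &
        as.numeric(mid) < as.numeric(as_utc(wend))
      s_vec[in_win] <- .act_scale(cfg, "female_with_cubs")
      Wcub <- .month_weights(cfg, "female_with_cubs")
      w_h <- ifelse(in_win, Wcub[cbind(month, bin)], W[cbind(month, bin)])
    } else {
      w_h <- W[cbind(month, bin)]
    }
    p_f <- pmin(s_vec * w_h, 0.97)
    lens <- with_seed(derive_seed(cfg$seed, a), {
      active <- stats::runif(n_h) < p_f
      len <- .sample_exp_trunc(n_h, mx$local_scale_m, 150)
      len[active] <- .sample_lnorm_trunc(sum(active), mx$foray_log_mean,
                                         mx$foray_log_sd, mx$foray_min_m,
                                         mx$foray_max_m)
      len
    })
    # one bearing per block; walk with attraction to the site
    block_len <- if (cfg$fix_schedule == "every_5h") 5L else 1L
    blk <- (seq_len(n_h) - 1L) %/% block_len
    nb <- max(blk) + 1L
    Lb <- as.numeric(rowsum(lens, blk, reorder = TRUE))
    nh_tab <- tabulate(blk + 1L, nbins = nb)
    xy <- with_seed(derive_seed(cfg$seed, a + 10000L), {
      br <- stats::runif(nb, 0, 2 * pi)
      x <- numeric(n_h + 1L); y <- numeric(n_h + 1L)
      px <- 0; py <- 0; h <- 1L
      for (b in seq_len(nb)) {
        r <- sqrt(px^2 + py^2)
        bearing <- if (r + Lb[b] > 50000) atan2(-px, -py) else
          if (r > 30000) atan2(-px, -py) + stats::rnorm(1, 0, 0.5) else br[b]
        nh_b <- nh_tab[b]
        seg <- lens[h:(h + nh_b - 1L)]
        cx <- cumsum(seg * sin(bearing)); cy <- cumsum(seg * cos(bearing))
        x[(h + 1L):(h + nh_b)] <- px + cx
        y[(h + 1L):(h + nh_b)] <- py + cy
        px <- px + cx[nh_b]; py <- py + cy[nh_b]
        h <- h + nh_b
      }
      cbind(x, y)
    })
    lat <- cfg$site_lat + xy[, 2] / 111320
    lon <- cfg$site_lon + xy[, 1] / (111320 * cos(cfg$site_lat * pi / 180))
    idx <- .schedule_index(hours, cfg$fix_schedule)
    fixes[[a]] <- data.frame(
      animal_id = id, species = species, sex = sex[a], age_class = age[a],
      timestamp = hours[idx], lon = lon[idx], lat = lat[idx]
    )
  }
  fixes <- do.call(rbind, fixes)
  rownames(fixes) <- NULL
  metadata <- data.frame(
    animal_id = ids, species = species, sex = sex, age_class = age,
    group = groups, deploy_start = t0 + ((seq_len(cfg$n_animals) - 1L) %% 5L) * 3600,
    deploy_end = t1, transition_date = as_utc(rep(NA_real_, cfg$n_animals))
  )
  truth <- list(births = births, month_weights = Wlist, act_scale = slist,
                error_labels = NULL, killsite_windows = NULL)
  list(fixes = fixes, metadata = metadata, truth = truth)
}

#' Inject labelled GPS errors
#'
#' Corrupts a fraction of fixes either grossly (displaced 160-400 km, so
#' they exceed the gross-outlier screen distance from any window median)
#' or as single-point spikes (displaced 30-80 km, implying out-and-back
#' speeds above the speed threshold with a near-reversal turning angle).
#' Corrupted fixes are spaced at least three rows apart within an animal,
#' and each carries exactly one label in the returned ground truth.
#'
#' @param fixes Clean fix table.
#' @param error_rate Fraction of fixes to corrupt, in `[0, 1]`.
#' @param seed RNG seed.
#' @return List with `fixes` (corrupted table, same shape) and `labels`
#'   (data.frame: `animal_id`, `timestamp`, `label`).
#' @export
inject_gps_errors <- function(fixes, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  empty <- data.frame(animal_id = character(0),
                      timestamp = as_utc(numeric(0)), label = character(0))
  if (error_rate == 0) return(list(fixes = fixes, labels = empty))
  with_seed(seed, {
    labels <- list()
    for (id in unique(fixes$animal_id)) {
      rows <- which(fixes$animal_id == id)
      n <- length(rows)
      if (n < 7L) next
      eligible <- rows[3:(n - 2L)]
      target <- stats::rbinom(1L, length(eligible), error_rate)
      if (target == 0L) next
      perm <- sample(eligible)
      chosen <- integer(0)
      for (r in perm) {
        if (length(chosen) >= target) break
        if (!length(chosen) || min(abs(chosen - r)) >= 3L)
          chosen <- c(chosen, r)
      }
      kind <- ifelse(stats::runif(length(chosen)) < 0.5, "gross_outlier",
                     "spike")
      dist <- ifelse(kind == "gross_outlier",
                     stats::runif(length(chosen), 160000, 400000),
                     stats::runif(length(chosen), 30000, 80000))
      brg <- stats::runif(length(chosen), 0, 2 * pi)
      lat0 <- fixes$lat[chosen]
      fixes$lat[chosen] <- lat0 + dist * cos(brg) / 111320
      fixes$lon[chosen] <- fixes$lon[chosen] +
        dist * sin(brg) / (111320 * cos(lat0 * pi / 180))
      labels[[id]] <- data.frame(animal_id = id,
                                 timestamp = fixes$timestamp[chosen],
                                 label = kind)
    }
    labels <- if (length(labels)) do.call(rbind, labels) else empty
    rownames(labels) <- NULL
    list(fixes = fixes, labels = labels)
  })
}

#' Insert kill-site episodes
#'
#' Replaces short runs of fixes with tight clusters (all pairwise within
#' the kill-site radius) emulating a predator remaining at a carcass, at a
#' configured rate per animal-month. Episodes are at least 4 fixes long;
#' the fixes flanking each episode are pushed outside the cluster radius
#' so detected window boundaries are exact.
#'
#' @param fixes Predator fix table.
#' @param killsite_rate Episodes per animal-month (>= 0).
#' @param seed RNG seed.
#' @return List with `fixes` and `windows` (animal_id, start, end).
#' @export
generate_kill_site_episodes <- function(fixes, killsite_rate, seed = NULL) {
  if (killsite_rate < 0) stop("killsite_rate must be >= 0")
  if (killsite_rate == 0)
    return(list(fixes = fixes,
                windows = data.frame(animal_id = character(0),
                                     start = as_utc(numeric(0)),
                                     end = as_utc(numeric(0)))))
  with_seed(seed, {
    windows <- list()
    for (id in unique(fixes$animal_id)) {
      rows <- which(fixes$animal_id == id)
      n <- length(rows)
      months <- max(1, as.numeric(diff(range(fixes$timestamp[rows])),
                                  units = "days") / 30.44)
      n_ep <- stats::rpois(1L, killsite_rate * months)
      if (n_ep == 0L) next
      used <- integer(0)
      for (e in seq_len(n_ep)) {
        L <- 4L + stats::rpois(1L, 1.5)
        ok_start <- setdiff(3:(n - L - 2L),
                            unlist(lapply(used, function(u) (u - L - 2L):(u + L + 2L))))
        if (!length(ok_start)) break
        st <- sample(ok_start, 1L)
        used <- c(used, st)
        sel <- rows[st:(st + L - 1L)]
        clat <- fixes$lat[sel[1]]; clon <- fixes$lon[sel[1]]
        r <- stats::runif(L, 0, 70); ang <- stats::runif(L, 0, 2 * pi)
        fixes$lat[sel] <- clat + r * cos(ang) / 111320
        fixes$lon[sel] <- clon + r * sin(ang) / (111320 * cos(clat * pi / 180))
        # push flanking fixes out of the cluster radius
        for (fl in c(rows[st - 1L], rows[st + L])) {
          d <- geosphere::distGeo(c(clon, clat),
                                  c(fixes$lon[fl], fixes$lat[fl]))
          if (d < 450) {
            ang2 <- stats::runif(1, 0, 2 * pi)
            push <- stats::runif(1, 450, 700)
            fixes$lat[fl] <- clat + push * cos(ang2) / 111320
            fixes$lon[fl] <- clon + push * sin(ang2) /
              (111320 * cos(clat * pi / 180))
          }
        }
        windows[[length(windows) + 1L]] <- data.frame(
          animal_id = id, start = fixes$timestamp[sel[1]],
          end = fixes$timestamp[sel[L]]
        )
      }
    }
    windows <- if (length(windows)) do.call(rbind, windows) else
      data.frame(animal_id = character(0), start = as_utc(numeric(0)),
                 end = as_utc(numeric(0)))
    rownames(windows) <- NULL
    list(fixes = fixes, windows = windows)
  })
}

#' Generate a synthetic accelerometer stream
#'
#' 5-min two-axis accelerometer samples whose active-state probability
#' follows the animal's circadian intensity (and, optionally, a
#' lunar-illumination effect on night activity). Active samples are drawn
#' at or above the behavioural threshold (28), resting samples below it,
#' and the two axes share the latent activity value plus independent
#' noise calibrated so their Pearson correlation matches
#' `accel_axis_corr`.
#'
#' @param metadata Metadata from [generate_tracks()].
#' @param cfg The [synth_config()].
#' @param start,end Optional window restriction (defaults to deployment).
#' @return List with `samples` (animal_id, timestamp, act_x, act_y) and
#'   `truth` (per-sample active-state indicator and probability).
#' @export
generate_accelerometer <- function(metadata, cfg, start = NULL, end = NULL) {
  start <- as_utc(start %||% metadata$deploy_start[1])
  end <- as_utc(end %||% metadata$deploy_end[1])
  out <- list(); truth <- list()
  for (a in seq_len(nrow(metadata))) {
    id <- metadata$animal_id[a]
    grp <- metadata$group[a]
    base_grp <- if (grp == "female_with_cubs") "adult_female" else grp
    tm <- seq(max(start, as_utc(metadata$deploy_start[a])),
              min(end, as_utc(metadata$deploy_end[a])), by = 300)
    theta <- to_suntime(tm, cfg$site_lon, cfg$site_lat)
    bin <- suntime_bin(theta)
    month <- local_month(tm)
    W <- .month_weights(cfg, base_grp)
    p <- pmin(pmax(cfg$accel_active_prob * W[cbind(month, bin)], 0.02), 0.98)
    if (cfg$lunar_effect != 0) {
      per <- classify_period(tm, cfg$site_lon, cfg$site_lat)
      ls <- lunar_state(tm, cfg$site_lon, cfg$site_lat)
      adj <- per == "night" & ls$above_horizon
      lp <- stats::qlogis(p[adj]) +
        cfg$lunar_effect * ls$illuminated_fraction[adj]
      p[adj] <- stats::plogis(lp)
    }
    res <- with_seed(derive_seed(cfg$seed, a + 20000L), {
      n <- length(tm)
      active <- stats::runif(n) < p
      v <- numeric(n)
      v[active] <- pmin(255, pmax(28, round(stats::rnorm(sum(active),
        cfg$accel_active_mean, 42))))
      v[!active] <- pmin(27, round(.sample_exp_trunc(sum(!active),
        cfg$accel_rest_mean, 27)))
      # axis noise sd calibrated (with state-respecting clipping) to the
      # target correlation
      vv <- stats::var(v)
      r_t <- cfg$accel_axis_corr
      sig <- if (r_t >= 1) 0 else sqrt(vv * (1 / r_t - 1))
      clip_axis <- function(val, noise) {
        z <- round(val + noise)
        ifelse(active, pmin(255, pmax(28, z)), pmin(27, pmax(0, z)))
      }
      for (it in 1:3) {
        if (sig == 0) break
        ex <- stats::rnorm(n, 0, sig); ey <- stats::rnorm(n, 0, sig)
        r_hat <- stats::cor(clip_axis(v, ex), clip_axis(v, ey))
        if (abs(r_hat - r_t) < 0.003 || r_hat >= 1) break
        sig <- sig * sqrt(max(1 / r_t - 1, 1e-6) / max(1 / r_hat - 1, 1e-6))
      }
      ex <- stats::rnorm(n, 0, sig); ey <- stats::rnorm(n, 0, sig)
      list(x = clip_axis(v, ex), y = clip_axis(v, ey), active = active)
    })
    out[[a]] <- data.frame(animal_id = id, timestamp = tm,
                           act_x = as.integer(res$x),
                           act_y = as.integer(res$y))
    truth[[a]] <- data.frame(animal_id = id, timestamp = tm,
                             active = res$active, p_active = p)
  }
  list(samples = do.call(rbind, out), truth = do.call(rbind, truth))
}
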