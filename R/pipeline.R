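# End-to-end orchestration: screening -> ephemeris labelling ->
# displacement / accelerometer processing -> densities -> overlaps and
# day/night proportions -> seasonal summaries, with a row-count manifest
# at every filter stage. CSV is the canonical interchange format.

#' Pipeline run configuration
#'
#' Every tunable defaults to the study value: screening D = 100,000 m,
#' m = 25,000 m, a = 5,000 m/h, q = -0.97; cadence tolerance +/-15 min;
#' 24-h post-capture trim; kill sites at >= 4 fixes within 200 m; activity
#' threshold 28; 10,000 MH samples; summer = May-Aug, winter = Dec-Feb.
#'
#' @param screening A [screening_config()].
#' @param nominal_hours Predator fix cadence (default 5).
#' @param tolerance_minutes Cadence tolerance (default 15).
#' @param post_capture_hours Post-capture trim (default 24).
#' @param killsite_radius_m,killsite_min_fixes Kill-site rule (200 m, 4).
#' @param cub_months Cub dependence (5 months).
#' @param accel_threshold Active/resting threshold (28).
#' @param n_mh MH samples per group (10,000).
#' @param mh_proposal_sd,mh_burn_in MH tuning (0.5 rad, 1,000).
#' @param summer_months,winter_months Season definitions (5:8, c(12,1,2)).
#' @param exclude_killsites_from_gps Also drop displacement records fully
#'   inside kill-site windows (default FALSE: the kill-site exclusion is
#'   defined for accelerometer data, and a resting animal's near-zero
#'   displacements are part of the movement-activity signal; set TRUE to
#'   extend the exclusion to GPS records).
#' @param seed Global seed; all stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(screening = screening_config(),
                       nominal_hours = 5, tolerance_minutes = 15,
                       post_capture_hours = 24,
                       killsite_radius_m = 200, killsite_min_fixes = 4L,
                       cub_months = 5L, accel_threshold = 28,
                       n_mh = 10000L, mh_proposal_sd = 0.5,
                       mh_burn_in = 1000L,
                       summer_months = 5:8, winter_months = c(12L, 1L, 2L),
                       exclude_killsites_from_gps = FALSE,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

# Screen + filter one species' fixes; returns kept fixes and a manifest.
.screen_stage <- function(fixes, deployments, rc, nominal_hours) {
  n0 <- nrow(fixes)
  fx <- remove_post_capture(fixes, deployments, rc$post_capture_hours)
  n1 <- nrow(fx)
  scr <- screen_gps_errors(fx, rc$screening)
  n2 <- nrow(scr$kept)
  fx <- filter_fix_interval(scr$kept, nominal_hours, rc$tolerance_minutes)
  n3 <- nrow(fx)
  list(fixes = fx, removed = scr$removed,
       manifest = data.frame(
         stage = c("input", "post_capture", "error_screen", "cadence"),
         kept = c(n0, n1, n2, n3),
         removed = c(0L, n0 - n1, n1 - n2, n2 - n3)))
}

# Suntime observations for one species (5-h disaggregation or hourly).
.species_observations <- function(fixes, metadata, rc, cadence_h,
                                  cub_windows = NULL, kill_windows = NULL) {
  assigner <- make_group_assigner(metadata, cub_windows)
  disp <- compute_displacements(fixes, assigner)
  if (is.null(disp)) return(NULL)
  if (!is.null(kill_windows) && nrow(kill_windows) &&
      rc$exclude_killsites_from_gps) {
    # drop displacement records fully inside a kill-site window
    keep <- rep(TRUE, nrow(disp))
    for (k in seq_len(nrow(kill_windows))) {
      keep <- keep & !(disp$animal_id == kill_windows$animal_id[k] &
        as.numeric(disp$t_start) >= as.numeric(kill_windows$start[k]) &
        as.numeric(disp$t_end) <= as.numeric(kill_windows$end[k]))
    }
    disp <- disp[keep, , drop = FALSE]
  }
  if (cadence_h == 5) {
    obs <- disaggregate_5h(disp, rc$tolerance_minutes)$obs
  } else {
    obs <- hourly_observations(disp)
  }
  list(disp = disp, obs = obs)
}

# MH samples and density for a subset of observations.
.group_density <- function(obs, rc, salt) {
  prof <- build_profile(obs$suntime, obs$distance_m)
  smp <- mh_sample_activity(prof, n = rc$n_mh,
                            proposal_sd = rc$mh_proposal_sd,
                            burn_in = rc$mh_burn_in,
                            seed = derive_seed(rc$seed, salt))
  list(profile = prof, samples = smp, density = circular_kde(smp))
}

#' Run the full activity-analysis pipeline
#'
#' Executes screening, ephemeris labelling, displacement processing,
#' Metropolis-Hastings activity densities, overlap and day/night
#' statistics, and monthly displacement estimates for a predator fix
#' table plus optional prey/livestock tables, or for synthetic
#' configurations. Writes CSV outputs when `out_dir` is given; identical
#' config + seed reproduces identical outputs.
#'
#' @param predator List with `fixes`, `metadata` and optionally `births`
#'   (e.g. from [generate_tracks()]).
#' @param prey,livestock Optional lists like `predator` (hourly / corral
#'   cadence).
#' @param rc A [run_config()].
#' @param site Site coordinates `c(lon, lat)` used for season labels.
#' @param n_boot Bootstrap replicates for monthly estimates.
#' @param out_dir Optional output directory for CSV tables.
#' @return List of class `pipeline_result`: densities, overlaps,
#'   day/night proportions, monthly estimates, manifest.
#' @export
run_pipeline <- function(predator, prey = NULL, livestock = NULL,
                         rc = run_config(), site = c(100, 43),
                         n_boot = 200L, out_dir = NULL) {
  manifest <- list()
  deployments <- predator$metadata
  st <- .screen_stage(predator$fixes, deployments, rc, rc$nominal_hours)
  manifest$predator <- st$manifest
  kw <- detect_kill_sites(st$fixes, rc$killsite_radius_m,
                          rc$killsite_min_fixes)
  cw <- flag_cub_periods(predator$metadata, predator$births %||% NULL,
                         rc$cub_months)
  pred <- .species_observations(st$fixes, predator$metadata, rc, 5,
                                cub_windows = cw, kill_windows = kw)
  if (is.null(pred)) stop("pipeline aborted at stage 'displacement': no predator displacements")
  obs <- pred$obs
  month <- local_month(obs$time)
  adult <- obs$group %in% c("adult_male", "adult_female")

  dens <- list()
  dens$male <- .group_density(obs[obs$group == "adult_male", ], rc, 1L)
  dens$female <- .group_density(obs[obs$group == "adult_female", ], rc, 2L)
  dens$summer <- .group_density(obs[adult & month %in% rc$summer_months, ],
                                rc, 3L)
  dens$winter <- .group_density(obs[adult & month %in% rc$winter_months, ],
                                rc, 4L)
  dens$predator <- .group_density(obs[adult, ], rc, 5L)

  overlaps <- list(
    male_female = overlap_coefficient(dens$male$density,
                                      dens$female$density)$delta,
    summer_winter = overlap_coefficient(dens$summer$density,
                                        dens$winter$density)$delta
  )
  proportions <- list(
    male = day_night_proportion(dens$male$samples),
    female = day_night_proportion(dens$female$samples),
    summer = day_night_proportion(dens$summer$samples),
    winter = day_night_proportion(dens$winter$samples),
    predator = day_night_proportion(dens$predator$samples)
  )

  if (!is.null(prey)) {
    stp <- .screen_stage(prey$fixes, prey$metadata, rc, 1)
    manifest$prey <- stp$manifest
    pr <- .species_observations(stp$fixes, prey$metadata, rc, 1)
    dens$ibex <- .group_density(pr$obs, rc, 6L)
    overlaps$ibex_predator <- overlap_coefficient(dens$ibex$density,
                                                  dens$predator$density)$delta
    proportions$ibex <- day_night_proportion(dens$ibex$samples)
  }
  if (!is.null(livestock)) {
    stl <- .screen_stage(livestock$fixes, livestock$metadata, rc, 1)
    manifest$livestock <- stl$manifest
    lv <- .species_observations(stl$fixes, livestock$metadata, rc, 1)
    dens$goat <- .group_density(lv$obs, rc, 7L)
    overlaps$goat_predator <- overlap_coefficient(dens$goat$density,
                                                  dens$predator$density)$delta
    proportions$goat <- day_night_proportion(dens$goat$samples)
  }

  monthly <- monthly_displacement_estimates(pred$disp, n_boot = n_boot,
                                            seed = derive_seed(rc$seed, 8L))
  res <- structure(list(
    densities = dens, overlaps = overlaps, proportions = proportions,
    monthly = monthly, kill_windows = kw, cub_windows = cw,
    manifest = manifest, rc = rc
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs as CSV tables
#'
#' @param res A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  ov <- data.frame(comparison = names(res$overlaps),
                   delta = unlist(res$overlaps), row.names = NULL)
  p <- file.path(out_dir, "overlaps.csv")
  utils::write.csv(ov, p, row.names = FALSE); paths <- c(paths, p)
  pr <- do.call(rbind, lapply(names(res$proportions), function(g)
    data.frame(group = g, p_day = res$proportions[[g]]["p_day"],
               p_night = res$proportions[[g]]["p_night"],
               row.names = NULL)))
  p <- file.path(out_dir, "day_night_proportions.csv")
  utils::write.csv(pr, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(out_dir, "monthly_displacement.csv")
  utils::write.csv(res$monthly$monthly, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "grand_displacement.csv")
  utils::write.csv(res$monthly$grand, p, row.names = FALSE)
  paths <- c(paths, p)
  man <- do.call(rbind, lapply(names(res$manifest), function(s)
    cbind(species = s, res$manifest[[s]])))
  p <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, p, row.names = FALSE); paths <- c(paths, p)
  invisible(paths)
}

#' Ingest supplementary displacement tables
#'
#' Reads displacement CSV files in the deposited-data layout (an animal
#' identifier, basic demographics, the local time of each position sample,
#' and the displacement since the previous measure), converts local time
#' to UTC with a fixed civil offset, and returns normalised displacement
#' records. Column names are mapped via `column_map` because deposited
#' headers vary; unmappable columns raise an error listing candidates.
#'
#' @param files Character vector of CSV paths.
#' @param column_map Named list mapping the roles `id`, `time`,
#'   `displacement` and optionally `group`, `sex`, `age_class` to column
#'   names in the files.
#' @param tz_offset_hours Local-time offset from UTC (default 8, the
#'   study site; override via config for other deployments).
#' @param interval_h Nominal sampling interval of the files (default 5).
#' @param time_format Passed to [as.POSIXct()] (default ISO-like
#'   `"%Y-%m-%d %H:%M:%S"`, with `"%Y-%m-%d %H:%M"` as fallback).
#' @return data.frame of displacement records (`animal_id`, `t_start`,
#'   `t_end`, `distance_m`, `interval_h`, `group`) plus an attribute
#'   `rejected` with row-level rejects and reasons.
#' @export
ingest_supplementary <- function(files,
                                 column_map = list(id = "id",
                                                   time = "time",
                                                   displacement = "displacement",
                                                   group = "group"),
                                 tz_offset_hours = 8, interval_h = 5,
                                 time_format = "%Y-%m-%d %H:%M:%S") {
  out <- list(); rejected <- list()
  for (f in files) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    for (role in c("id", "time", "displacement")) {
      cn <- column_map[[role]]
      if (is.null(cn) || !cn %in% names(d))
        stop(sprintf("cannot map role '%s' in %s; available columns: %s",
                     role, basename(f), paste(names(d), collapse = ", ")))
    }
    tm <- as.POSIXct(d[[column_map$time]], tz = "UTC",
                     format = time_format)
    bad_t <- is.na(tm)
    if (any(bad_t))
      tm[bad_t] <- as.POSIXct(d[[column_map$time]][bad_t], tz = "UTC",
                              format = "%Y-%m-%d %H:%M")
    dist <- suppressWarnings(as.numeric(d[[column_map$displacement]]))
    reason <- rep(NA_character_, nrow(d))
    reason[is.na(tm)] <- "unparseable_time"
    reason[is.na(reason) & (is.na(dist) | dist < 0)] <- "invalid_displacement"
    ok <- is.na(reason)
    if (any(!ok))
      rejected[[f]] <- cbind(d[!ok, , drop = FALSE],
                             reason = reason[!ok], file = basename(f))
    t_end <- as_utc(tm[ok]) - tz_offset_hours * 3600
    out[[f]] <- data.frame(
      animal_id = as.character(d[[column_map$id]][ok]),
      t_start = t_end - interval_h * 3600,
      t_end = t_end,
      distance_m = dist[ok],
      interval_h = interval_h,
      group = if (!is.null(column_map$group) &&
                  column_map$group %in% names(d))
        as.character(d[[column_map$group]][ok]) else NA_character_
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejected") <- if (length(rejected)) do.call(rbind, rejected)
    else NULL
  res
}

#' Write a fix table as CSV
#'
#' Canonical fix CSV: `animal_id, species, sex, age_class, timestamp_utc
#' (ISO-8601), lon, lat`.
#'
#' @param fixes Fix table.
#' @param path Output path.
#' @export
write_fix_csv <- function(fixes, path) {
  out <- data.frame(
    animal_id = fixes$animal_id,
    species = fixes$species %||% NA, sex = fixes$sex %||% NA,
    age_class = fixes$age_class %||% NA,
    timestamp_utc = format(as_utc(fixes$timestamp), "%Y-%m-%dT%H:%M:%SZ"),
    lon = fixes$lon, lat = fixes$lat
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a fix table from CSV
#'
#' @param path CSV path in the [write_fix_csv()] layout.
#' @return Fix table with POSIXct UTC timestamps.
#' @export
read_fix_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp_utc, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%OSZ")
  d$timestamp_utc <- NULL
  d
}
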