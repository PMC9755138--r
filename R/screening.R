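# GPS track screening: two-stage error removal, cadence filtering,
# post-capture trimming, and behavioural exclusion windows.

#' Screening parameters
#'
#' Thresholds for the two-stage GPS error screen. Defaults are the values
#' used for 5-hourly snow leopard collar data: gross-outlier distance
#' `D` = 100,000 m from the running window median, spike neighbourhood span
#' `m` = 25,000 m, speed threshold `a` = 5,000 m/h and turning-angle cosine
#' threshold `q` = -0.97.
#'
#' @param D Gross-outlier distance from the surrounding-window median (m).
#' @param m Spike neighbourhood span (m); must satisfy `D > m > 0`.
#' @param a Speed threshold (m/h).
#' @param q Cosine-of-turning-angle threshold in `[-1, 1]`.
#' @param window Number of fixes on either side used for the stage-1
#'   median (default 10, truncated at track ends).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(D = 100000, m = 25000, a = 5000, q = -0.97,
                             window = 10L) {
  stopifnot(D > m, m > 0, a > 0, q >= -1, q <= 1)
  structure(list(D = D, m = m, a = a, q = q, window = as.integer(window)),
            class = "screening_config")
}

.check_fix_table <- function(fixes) {
  need <- c("animal_id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(fixes))
  if (length(miss))
    stop("fix table is missing columns: ", paste(miss, collapse = ", "))
  if (any(fixes$lat < -90 | fixes$lat > 90, na.rm = TRUE) ||
      any(fixes$lon < -180 | fixes$lon > 180, na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  fixes$timestamp <- as_utc(fixes$timestamp)
  fixes[order(fixes$animal_id, fixes$timestamp), , drop = FALSE]
}

#' Two-stage GPS error screening
#'
#' Stage 1 removes gross outliers: any fix whose geodesic distance to the
#' coordinate-wise median of its surrounding window (`window` fixes on
#' either side, excluding itself, truncated at track ends) exceeds `D`.
#' Stage 2 removes movement spikes among the survivors: a fix is a spike
#' when incoming and outgoing speeds both exceed `a` and the cosine of the
#' turning angle at the fix is below `q`, or when both adjacent legs are
#' longer than `m` with the same angle condition. Animals with fewer than
#' three fixes are passed through unscreened with a warning record.
#'
#' @param fixes data.frame with `animal_id`, `timestamp` (UTC), `lon`, `lat`.
#' @param cfg A [screening_config()].
#' @return List with `kept` (clean fixes), `removed` (fixes with a `stage`
#'   label, `gross_outlier` or `spike`), and `warnings` (animals passed
#'   through unscreened).
#' @export
screen_gps_errors <- function(fixes, cfg = screening_config()) {
  fixes <- .check_fix_table(fixes)
  kept_list <- list(); rem_list <- list(); warn <- character()
  for (id in unique(fixes$animal_id)) {
    fx <- fixes[fixes$animal_id == id, , drop = FALSE]
    n <- nrow(fx)
    if (n < 3L) {
      warn <- c(warn, id)
      kept_list[[length(kept_list) + 1L]] <- fx
      next
    }
    p <- cbind(fx$lon, fx$lat)
    # Stage 1: distance to surrounding-window median.
    med_dist <- vapply(seq_len(n), function(i) {
      idx <- setdiff(max(1L, i - cfg$window):min(n, i + cfg$window), i)
      geosphere::distGeo(c(stats::median(p[idx, 1]), stats::median(p[idx, 2])),
                         p[i, , drop = FALSE])
    }, numeric(1))
    gross <- med_dist > cfg$D
    if (any(gross)) {
      r <- fx[gross, , drop = FALSE]; r$stage <- "gross_outlier"
      rem_list[[length(rem_list) + 1L]] <- r
      fx <- fx[!gross, , drop = FALSE]
      p <- p[!gross, , drop = FALSE]
      n <- nrow(fx)
    }
    # Stage 2: speed/turning-angle spikes on the survivors.
    if (n >= 3L) {
      d_leg <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
      dt_h <- diff(as.numeric(fx$timestamp)) / 3600
      speed <- d_leg / pmax(dt_h, 1e-9)
      b <- geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
      i <- 2:(n - 1L)
      cos_turn <- cos((b[i] - b[i - 1L]) * pi / 180)
      spike_mid <- (((speed[i - 1L] > cfg$a & speed[i] > cfg$a) |
                       (d_leg[i - 1L] > cfg$m & d_leg[i] > cfg$m)) &
                      cos_turn < cfg$q)
      spike <- c(FALSE, spike_mid, FALSE)
      if (any(spike)) {
        r <- fx[spike, , drop = FALSE]; r$stage <- "spike"
        rem_list[[length(rem_list) + 1L]] <- r
        fx <- fx[!spike, , drop = FALSE]
      }
    }
    kept_list[[length(kept_list) + 1L]] <- fx
  }
  kept <- do.call(rbind, kept_list)
  kept <- kept[order(kept$animal_id, kept$timestamp), , drop = FALSE]
  removed <- if (length(rem_list)) do.call(rbind, rem_list) else
    cbind(fixes[0, , drop = FALSE], stage = character(0))
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, warnings = warn)
}

#' Fix-cadence filter
#'
#' Retain fixes on the nominal schedule. Walking forward per animal, a fix
#' is kept when its gap to the previous retained fix lies within
#' `nominal_hours` +/- `tolerance_minutes`; a longer gap keeps the fix but
#' restarts the cadence chain (no displacement is formed across it); a
#' shorter gap (off-schedule extra fix) is dropped. The first fix of each
#' animal is always retained. The returned table carries a `chain_id`
#' column identifying uninterrupted cadence chains.
#'
#' @param fixes Fix table (see [screen_gps_errors()]).
#' @param nominal_hours Nominal fix interval in hours (default 5).
#' @param tolerance_minutes Allowed deviation (default 15).
#' @return Fix table restricted to retained fixes, with `chain_id`.
#' @export
filter_fix_interval <- function(fixes, nominal_hours = 5,
                                tolerance_minutes = 15) {
  fixes <- .check_fix_table(fixes)
  lo <- nominal_hours - tolerance_minutes / 60
  hi <- nominal_hours + tolerance_minutes / 60
  out <- lapply(split(fixes, fixes$animal_id), function(fx) {
    n <- nrow(fx)
    keep <- logical(n); keep[1L] <- TRUE
    chain <- integer(n); chain[1L] <- 1L
    last <- 1L; cur_chain <- 1L
    t <- as.numeric(fx$timestamp) / 3600
    for (i in seq_len(n)[-1L]) {
      gap <- t[i] - t[last]
      if (gap >= lo && gap <= hi) {
        keep[i] <- TRUE; chain[i] <- cur_chain; last <- i
      } else if (gap > hi) {
        cur_chain <- cur_chain + 1L
        keep[i] <- TRUE; chain[i] <- cur_chain; last <- i
      } # gap < lo: off-schedule fix dropped; `last` unchanged
    }
    fx$chain_id <- chain
    fx[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Remove the post-capture window
#'
#' Drop all fixes within `hours` of the animal's deployment start, to avoid
#' capture effects.
#'
#' @param fixes Fix table.
#' @param deployments data.frame with `animal_id` and `deploy_start`
#'   (POSIXct, UTC). Every animal in `fixes` must be present.
#' @param hours Trim length (default 24).
#' @return Fix table without the post-capture fixes.
#' @export
remove_post_capture <- function(fixes, deployments, hours = 24) {
  fixes <- .check_fix_table(fixes)
  miss <- setdiff(unique(fixes$animal_id), deployments$animal_id)
  if (length(miss))
    stop("no deployment start for animal(s): ", paste(miss, collapse = ", "))
  st <- as_utc(deployments$deploy_start)[match(fixes$animal_id,
                                               deployments$animal_id)]
  fixes[as.numeric(fixes$timestamp) >= as.numeric(st) + hours * 3600, ,
        drop = FALSE]
}

#' Detect kill-site clusters
#'
#' Find maximal runs of at least `min_consecutive` consecutive fixes that
#' are all pairwise within `radius_m` of each other; such clusters indicate
#' a predator remaining at a carcass. Overlapping or adjacent qualifying
#' runs are merged into a single exclusion window spanning the first to the
#' last fix time.
#'
#' @param fixes Fix table (screened, per animal).
#' @param radius_m Cluster radius (default 200 m, all pairwise distances).
#' @param min_consecutive Minimum run length (default 4).
#' @return data.frame of exclusion windows: `animal_id`, `start`, `end`,
#'   `reason = "kill_site"`, plus the fix-index bounds `i_start`, `i_end`.
#' @export
detect_kill_sites <- function(fixes, radius_m = 200, min_consecutive = 4L) {
  fixes <- .check_fix_table(fixes)
  res <- list()
  for (id in unique(fixes$animal_id)) {
    fx <- fixes[fixes$animal_id == id, , drop = FALSE]
    n <- nrow(fx)
    if (n < min_consecutive) next
    p <- cbind(fx$lon, fx$lat)
    # Two-pointer scan: e(i) = largest end with [i, e] all pairwise within
    # radius; monotone because subsets of a valid run are valid.
    runs <- list()
    e <- 1L
    for (s in seq_len(n)) {
      if (e < s) e <- s
      while (e < n) {
        cand <- e + 1L
        d <- geosphere::distGeo(p[cand, , drop = FALSE], p[s:e, , drop = FALSE])
        if (all(d <= radius_m)) e <- cand else break
      }
      if (e - s + 1L >= min_consecutive) runs[[length(runs) + 1L]] <- c(s, e)
    }
    if (!length(runs)) next
    # Merge overlapping/adjacent runs into maximal windows.
    runs <- do.call(rbind, runs)
    runs <- runs[order(runs[, 1]), , drop = FALSE]
    merged <- list(runs[1, ])
    for (k in seq_len(nrow(runs))[-1L]) {
      last <- merged[[length(merged)]]
      if (runs[k, 1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], runs[k, 2]))
      else merged[[length(merged) + 1L]] <- runs[k, ]
    }
    for (w in merged) {
      res[[length(res) + 1L]] <- data.frame(
        animal_id = id,
        start = fx$timestamp[w[1]],
        end = fx$timestamp[w[2]],
        reason = "kill_site",
        i_start = w[1], i_end = w[2]
      )
    }
  }
  if (!length(res))
    return(data.frame(animal_id = character(0),
                      start = as_utc(numeric(0)), end = as_utc(numeric(0)),
                      reason = character(0), i_start = integer(0),
                      i_end = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag females with young cubs
#'
#' Build exclusion windows from cub birth dates: from birth until the cubs
#' are `months` calendar months old. Such females form a separate group in
#' displacement summaries and are excluded from general activity analyses.
#'
#' @param metadata Animal metadata with `animal_id` and `sex`.
#' @param births data.frame with `animal_id` and `birth_date` (Date); may
#'   be empty or NULL.
#' @param months Cub dependence length in calendar months (default 5).
#' @return data.frame of windows with `reason = "with_cubs"`.
#' @export
flag_cub_periods <- function(metadata, births, months = 5L) {
  empty <- data.frame(animal_id = character(0), start = as_utc(numeric(0)),
                      end = as_utc(numeric(0)), reason = character(0))
  if (is.null(births) || nrow(births) == 0L) return(empty)
  sex <- metadata$sex[match(births$animal_id, metadata$animal_id)]
  if (any(is.na(sex)))
    stop("birth dates for animals absent from metadata: ",
         paste(births$animal_id[is.na(sex)], collapse = ", "))
  if (any(sex == "M"))
    stop("birth dates recorded for male animal(s): ",
         paste(births$animal_id[sex == "M"], collapse = ", "))
  bd <- as.Date(births$birth_date)
  end <- as.Date(vapply(seq_along(bd), function(i)
    as.character(seq(bd[i], by = "month", length.out = months + 1L)[months + 1L]),
    character(1)))
  data.frame(animal_id = births$animal_id,
             start = as_utc(bd), end = as_utc(end), reason = "with_cubs")
}

#' Drop records inside exclusion windows
#'
#' Remove rows whose timestamp falls inside any half-open window
#' `[start, end)` for the same animal. Works for fix tables and
#' accelerometer tables alike.
#'
#' @param records data.frame with `animal_id` and `timestamp`.
#' @param windows data.frame of windows (`animal_id`, `start`, `end`,
#'   `reason`).
#' @return List with `kept`, `removed` (with a `reason` column) and
#'   `removed_by_reason` counts.
#' @export
exclude_windows <- function(records, windows) {
  if (is.null(windows) || nrow(windows) == 0L)
    return(list(kept = records,
                removed = cbind(records[0, , drop = FALSE],
                                reason = character(0)),
                removed_by_reason = integer(0)))
  t <- as.numeric(as_utc(records$timestamp))
  drop_reason <- rep(NA_character_, nrow(records))
  for (k in seq_len(nrow(windows))) {
    hit <- records$animal_id == windows$animal_id[k] &
      t >= as.numeric(as_utc(windows$start[k])) &
      t < as.numeric(as_utc(windows$end[k]))
    drop_reason[hit & is.na(drop_reason)] <- as.character(windows$reason[k])
  }
  removed <- records[!is.na(drop_reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- drop_reason[!is.na(drop_reason)]
  else removed <- cbind(removed, reason = character(0))
  list(kept = records[is.na(drop_reason), , drop = FALSE],
       removed = removed,
       removed_by_reason = table(drop_reason[!is.na(drop_reason)]))
}
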