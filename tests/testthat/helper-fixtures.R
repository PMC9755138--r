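# Shared in-code fixtures for the test suite. Everything is generated at
# test time; sizes are kept small so the default run stays fast.

SITE_LON <- 100
SITE_LAT <- 43

# A small clean predator cohort (cached per test run).
small_predator <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config("predator", n_animals = 2,
                          groups = c("adult_male", "adult_female"),
                          start_date = "2019-03-01",
                          end_date = "2019-05-30", seed = 101)
      cache <<- list(cfg = cfg, tracks = generate_tracks(cfg))
    }
    cache
  }
})

# Straight synthetic track with a constant step, for constructed cases.
toy_track <- function(n = 30, step_m = 500, dt_h = 5, animal = "A1",
                      t0 = as.POSIXct("2019-06-01 00:00:00", tz = "UTC")) {
  data.frame(
    animal_id = animal,
    timestamp = t0 + (seq_len(n) - 1) * dt_h * 3600,
    lon = SITE_LON + (seq_len(n) - 1) * step_m / (111320 * cos(SITE_LAT * pi / 180)),
    lat = SITE_LAT
  )
}

# Displace one fix of a track by `dist_m` at a bearing (planar).
displace_fix <- function(fixes, i, dist_m, bearing_rad = pi / 2) {
  fixes$lat[i] <- fixes$lat[i] + dist_m * cos(bearing_rad) / 111320
  fixes$lon[i] <- fixes$lon[i] +
    dist_m * sin(bearing_rad) / (111320 * cos(fixes$lat[i] * pi / 180))
  fixes
}

# Brute-force O(n^2) kill-site oracle: all maximal index intervals of
# length >= k whose fixes are all pairwise within radius, merged.
oracle_kill_sites <- function(fixes, radius = 200, k = 4) {
  p <- cbind(fixes$lon, fixes$lat)
  n <- nrow(p)
  ok <- function(s, e) {
    for (i in s:(e - 1)) {
      d <- geosphere::distGeo(p[i, , drop = FALSE],
                              p[(i + 1):e, , drop = FALSE])
      if (any(d > radius)) return(FALSE)
    }
    TRUE
  }
  ivs <- list()
  for (s in 1:(n - k + 1)) {
    e <- s + k - 1
    if (e > n || !ok(s, e)) next
    while (e < n && ok(s, e + 1)) e <- e + 1
    ivs[[length(ivs) + 1]] <- c(s, e)
  }
  if (!length(ivs)) return(NULL)
  ivs <- unique(do.call(rbind, ivs))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  merged <- list(ivs[1, ])
  for (j in seq_len(nrow(ivs))[-1]) {
    last <- merged[[length(merged)]]
    if (ivs[j, 1] <= last[2] + 1)
      merged[[length(merged)]] <- c(last[1], max(last[2], ivs[j, 2]))
    else merged[[length(merged) + 1]] <- ivs[j, ]
  }
  do.call(rbind, merged)
}

# Total-variation distance between MH samples' bin frequencies and the
# exactly normalised 24-bin target.
tv_to_target <- function(theta, weights) {
  p_emp <- tabulate(suntime_bin(theta), 24) / length(theta)
  p_tgt <- weights / sum(weights)
  sum(abs(p_emp - p_tgt)) / 2
}
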