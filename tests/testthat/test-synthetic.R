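# Synthetic telemetry generator: determinism, schedules, step-length
# structure, calibration, and labelled corruption.

test_that("identical config and seed reproduce identical output; validation rejects bad configs", {
  cfg <- synth_config("predator", n_animals = 2, start_date = "2019-02-01",
                      end_date = "2019-03-01", seed = 12)
  a <- generate_tracks(cfg); b <- generate_tracks(cfg)
  expect_identical(a, b)
  expect_error(synth_config("predator", n_animals = 0), "n_animals")
  expect_error(synth_config("predator", start_date = "2019-03-01",
                            end_date = "2019-03-01"), "end_date")
  expect_error(synth_config("predator", error_rate = 1.5), "error_rate")
  expect_error(synth_config("predator",
                            step_mixture = list(p_local = 2)), "p_local")
  expect_error(synth_config("predator", circadian_weights = rep(0, 24)),
               "not all zero")
})

test_that("the 5-h schedule yields ~144 fixes per animal over 30 days", {
  cfg <- synth_config("predator", n_animals = 2, start_date = "2019-06-01",
                      end_date = "2019-07-01", seed = 3)
  fx <- generate_tracks(cfg)$fixes
  counts <- table(fx$animal_id)
  expect_true(all(counts >= 144 & counts <= 145))
  gaps <- diff(as.numeric(fx$timestamp[fx$animal_id == fx$animal_id[1]]))
  expect_true(all(gaps == 5 * 3600))
})

test_that("the corral schedule emits only 07:00-22:00 local fixes plus the 03:00 fix", {
  cfg <- synth_config("livestock", n_animals = 2, start_date = "2019-06-01",
                      end_date = "2019-06-20", seed = 4)
  fx <- generate_tracks(cfg)$fixes
  local_hour <- as.POSIXlt(fx$timestamp + 8 * 3600, tz = "UTC")$hour
  expect_true(all(local_hour %in% c(3, 7:22)))
  expect_true(all(c(3, 7, 22) %in% local_hour))
})

test_that("positions stay within half a degree of the site", {
  cfg <- synth_config("predator", n_animals = 2, start_date = "2019-01-01",
                      end_date = "2019-12-31", seed = 8)
  fx <- generate_tracks(cfg)$fixes
  expect_true(all(abs(fx$lat - 43) < 0.5))
  expect_true(all(abs(fx$lon - 100) < 0.5 / cos(43 * pi / 180)))
})

test_that("predator 5-h log displacements are bimodal (two-component fit preferred)", {
  tr <- small_predator()$tracks
  fx <- tr$fixes[tr$fixes$animal_id == tr$fixes$animal_id[1], ]
  d <- geosphere::distGeo(cbind(fx$lon, fx$lat)[-nrow(fx), ],
                          cbind(fx$lon, fx$lat)[-1, ])
  x <- log(d[d > 0])
  # simple two-component normal EM vs single normal, BIC comparison
  em2 <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75))
    mu <- as.numeric(q); sd1 <- stats::sd(x) / 2; sd2 <- sd1; p <- 0.5
    for (i in 1:100) {
      d1 <- p * stats::dnorm(x, mu[1], sd1)
      d2 <- (1 - p) * stats::dnorm(x, mu[2], sd2)
      g <- d1 / (d1 + d2)
      p <- mean(g)
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      sd1 <- sqrt(sum(g * (x - mu[1])^2) / sum(g))
      sd2 <- sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g))
    }
    ll <- sum(log(p * stats::dnorm(x, mu[1], sd1) +
                    (1 - p) * stats::dnorm(x, mu[2], sd2)))
    list(ll = ll, mu = mu)
  }
  fit2 <- em2(x)
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(length(x))
  bic2 <- -2 * fit2$ll + 5 * log(length(x))
  expect_lt(bic2, bic1)
  expect_gt(abs(diff(fit2$mu)), 1) # well-separated modes on the log scale
})

test_that("flat circadian weights give a near-uniform suntime distribution of forays", {
  # hourly schedule: every displacement is a single step, so foray steps
  # (> 150 m, beyond the local-step cap) can be read off directly
  cfg <- synth_config("wild_prey", n_animals = 4,
                      circadian_weights = rep(1, 24), seasonal_shift = 0,
                      start_date = "2019-01-01", end_date = "2019-12-31",
                      seed = 21)
  tr <- generate_tracks(cfg)
  kept <- filter_fix_interval(tr$fixes, nominal_hours = 1)
  disp <- compute_displacements(kept)
  expect_gt(nrow(disp), 10000)
  big <- disp[disp$distance_m > 150, ]
  th <- to_suntime(as_utc(as.numeric(big$t_start) + 1800), big$lon, big$lat)
  expect_gt(nrow(big), 8000)
  tv <- sum(abs(tabulate(suntime_bin(th), 24) / length(th) - 1 / 24)) / 2
  expect_lt(tv, 0.05)
})

test_that("the degenerate all-local mixture produces near-constant positions", {
  cfg <- synth_config("predator", n_animals = 1,
                      step_mixture = list(p_local = 1, local_scale_m = 1e-9),
                      start_date = "2019-06-01", end_date = "2019-06-10",
                      seed = 5)
  fx <- generate_tracks(cfg)$fixes
  d <- geosphere::distGeo(cbind(fx$lon, fx$lat)[-nrow(fx), ],
                          cbind(fx$lon, fx$lat)[-1, ])
  expect_lt(max(d), 0.01)
})

test_that("group displacement calibration hits the configured 5-h means", {
  cfg <- synth_config("predator", n_animals = 4,
                      groups = c("adult_male", "adult_female"),
                      start_date = "2019-01-01", end_date = "2019-12-31",
                      seed = 60)
  tr <- generate_tracks(cfg)
  for (g in c("adult_male", "adult_female")) {
    ids <- tr$metadata$animal_id[tr$metadata$group == g]
    m <- sapply(ids, function(id) {
      fx <- tr$fixes[tr$fixes$animal_id == id, ]
      mean(geosphere::distGeo(cbind(fx$lon, fx$lat)[-nrow(fx), ],
                              cbind(fx$lon, fx$lat)[-1, ]))
    })
    expect_equal(mean(m), unname(cfg$group_mean_5h[g]), tolerance = 0.08)
  }
})

test_that("error injection is labelled, rate-faithful, and geometrically extreme", {
  tr <- small_predator()$tracks
  none <- inject_gps_errors(tr$fixes, 0)
  expect_identical(none$fixes, tr$fixes)
  expect_equal(nrow(none$labels), 0L)
  inj <- inject_gps_errors(tr$fixes, 0.05, seed = 17)
  n <- nrow(tr$fixes)
  expect_lt(abs(nrow(inj$labels) - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
  expect_true(all(inj$labels$label %in% c("gross_outlier", "spike")))
  # every gross outlier lies far outside the track envelope
  for (k in which(inj$labels$label == "gross_outlier")) {
    id <- inj$labels$animal_id[k]
    row <- which(inj$fixes$animal_id == id &
                   inj$fixes$timestamp == inj$labels$timestamp[k])
    cen <- c(mean(tr$fixes$lon[tr$fixes$animal_id == id]),
             mean(tr$fixes$lat[tr$fixes$animal_id == id]))
    expect_gt(geosphere::distGeo(cen, c(inj$fixes$lon[row],
                                        inj$fixes$lat[row])), 100000)
  }
  expect_error(inject_gps_errors(tr$fixes, -0.1), "error_rate")
})

test_that("inserted kill-site episodes are recovered with exact boundaries", {
  tr <- small_predator()$tracks
  none <- generate_kill_site_episodes(tr$fixes, 0)
  expect_equal(nrow(none$windows), 0L)
  eps <- generate_kill_site_episodes(tr$fixes, 0.8, seed = 23)
  expect_gt(nrow(eps$windows), 2)
  det <- detect_kill_sites(eps$fixes)
  key_det <- paste(det$animal_id, det$start, det$end)
  key_tru <- paste(eps$windows$animal_id, eps$windows$start, eps$windows$end)
  expect_true(all(key_tru %in% key_det))
  expect_error(generate_kill_site_episodes(tr$fixes, -1), "killsite_rate")
})

test_that("the generator's night-share truth matches its configuration", {
  cfg <- synth_config("predator", n_animals = 1, groups = "adult_male",
                      night_share = 0.68, night_share_amplitude = 0,
                      seasonal_shift = 0)
  expect_equal(true_night_share(cfg, "adult_male"), 0.68, tolerance = 1e-6)
  cfg2 <- small_predator()$cfg
  expect_equal(true_night_share(cfg2, "adult_male", 7), 0.66 + 0.058,
               tolerance = 1e-6)
  expect_equal(true_night_share(cfg2, "adult_female", 1), 0.60 - 0.058,
               tolerance = 1e-6)
})
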