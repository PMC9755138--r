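# GPS error screening, cadence filter, post-capture trim, exclusion
# windows and kill-site detection.

test_that("a gross outlier beyond D is removed at stage 1, partition holds, and screening is idempotent", {
  fx <- displace_fix(toy_track(30), 15, 150000)
  res <- screen_gps_errors(fx)
  expect_equal(nrow(res$removed), 1L)
  expect_equal(res$removed$stage, "gross_outlier")
  expect_equal(res$removed$timestamp, fx$timestamp[15])
  # kept U removed = input, nothing duplicated
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(fx))
  expect_equal(sort(c(res$kept$timestamp, res$removed$timestamp)),
               sort(fx$timestamp))
  # idempotence
  res2 <- screen_gps_errors(res$kept)
  expect_equal(nrow(res2$removed), 0L)
})

test_that("an out-and-back spike violating speed and angle thresholds is removed at stage 2", {
  # 5-h legs of 30 km out and back: speed 6,000 m/h > a, cos(turn) = -1 < q
  fx <- displace_fix(toy_track(20, step_m = 500), 10, 30000, bearing_rad = 0)
  res <- screen_gps_errors(fx)
  expect_equal(res$removed$stage, "spike")
  expect_equal(res$removed$timestamp, fx$timestamp[10])
})

test_that("slow direction reversals and fast straight movement are not spikes", {
  # reversal at normal speed: cos(turn) = -1 but speed ~100 m/h
  back <- toy_track(20, step_m = 500)
  back$lon[11:20] <- back$lon[c(9:1, 1)]
  expect_equal(nrow(screen_gps_errors(back)$removed), 0L)
  # a short fast straight burst: speed > a on both legs, cos(turn) = +1
  steps <- c(rep(500, 8), rep(26000, 3), rep(500, 8))
  fast <- toy_track(20)
  fast$lon <- SITE_LON + cumsum(c(0, steps)) / (111320 * cos(SITE_LAT * pi / 180))
  expect_equal(nrow(screen_gps_errors(fast)$removed), 0L)
})

test_that("animals with fewer than three fixes pass through with a warning record", {
  fx <- toy_track(2)
  res <- screen_gps_errors(fx)
  expect_equal(nrow(res$kept), 2L)
  expect_equal(res$warnings, "A1")
})

test_that("cadence filter keeps in-tolerance gaps, drops early fixes, and restarts chains", {
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  gaps_min <- c(300, 310, 290, 320, 300, 601, 300) # 5h00,5h10,4h50,5h20,5h00,10h01,5h00
  ts <- t0 + cumsum(c(0, gaps_min * 60))
  fx <- data.frame(animal_id = "A1", timestamp = ts,
                   lon = SITE_LON + seq_along(ts) * 0.001, lat = SITE_LAT)
  kept <- filter_fix_interval(fx)
  # 5h20 gap: fix kept but chain restarts; 10h01 the same
  expect_equal(nrow(kept), length(ts))
  expect_equal(kept$chain_id, c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  disp <- compute_displacements(kept)
  # no displacement across either restart
  expect_equal(nrow(disp), 5L)
  expect_false(any(abs(disp$interval_h - 5) > 0.25))
  # an off-schedule extra fix (2 h after the previous) is dropped
  fx2 <- rbind(fx[1:3, ],
               data.frame(animal_id = "A1", timestamp = fx$timestamp[3] + 7200,
                          lon = 100.5, lat = SITE_LAT))
  expect_equal(nrow(filter_fix_interval(fx2)), 3L)
})

test_that("post-capture trim removes exactly the first 24 h", {
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  fx <- data.frame(animal_id = "A1",
                   timestamp = t0 + c(23 * 3600 + 59 * 60, 24 * 3600 + 60),
                   lon = SITE_LON, lat = SITE_LAT)
  dep <- data.frame(animal_id = "A1", deploy_start = t0)
  kept <- remove_post_capture(fx, dep)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$timestamp, fx$timestamp[2])
  expect_equal(nrow(remove_post_capture(fx[0, ], dep)), 0L)
  expect_error(remove_post_capture(fx, data.frame(animal_id = "B9",
                                                  deploy_start = t0)),
               "A1")
})

test_that("kill-site detection applies the >=4-within-200m rule with exact windows", {
  fx <- toy_track(12, step_m = 2000)
  fx[4:8, c("lon", "lat")] <- fx[rep(4, 5), c("lon", "lat")] +
    cbind(runif(5, 0, 0.0005), runif(5, 0, 0.0005)) # ~<60 m jitter
  w <- detect_kill_sites(fx)
  expect_equal(nrow(w), 1L)
  expect_equal(w$i_start, 4L)
  expect_equal(w$i_end, 8L)
  expect_equal(w$start, fx$timestamp[4])
  expect_equal(w$end, fx$timestamp[8])
  # three clustered fixes then a big move: below the run threshold
  fx3 <- toy_track(10, step_m = 2000)
  fx3[4:6, c("lon", "lat")] <- fx3[rep(4, 3), c("lon", "lat")]
  expect_equal(nrow(detect_kill_sites(fx3)), 0L)
})

test_that("kill-site detection agrees with a brute-force pairwise oracle", {
  set.seed(42)
  for (rep in 1:4) {
    n <- 400
    # random walk with sticky rest phases to create natural clusters
    rest <- rep(rbinom(40, 1, 0.45), each = 10)[1:n]
    step <- ifelse(rest == 1, runif(n, 0, 60), runif(n, 0, 1500))
    brg <- runif(n, 0, 2 * pi)
    x <- cumsum(step * sin(brg)); y <- cumsum(step * cos(brg))
    fx <- data.frame(
      animal_id = "A1",
      timestamp = as.POSIXct("2019-01-01", tz = "UTC") + (1:n) * 18000,
      lon = SITE_LON + x / (111320 * cos(SITE_LAT * pi / 180)),
      lat = SITE_LAT + y / 111320
    )
    w <- detect_kill_sites(fx)
    o <- oracle_kill_sites(fx)
    if (is.null(o)) {
      expect_equal(nrow(w), 0L)
    } else {
      expect_equal(cbind(w$i_start, w$i_end), unname(o))
    }
  }
})

test_that("cub windows span five calendar months and reject males", {
  meta <- data.frame(animal_id = c("F1", "M1"), sex = c("F", "M"))
  w <- flag_cub_periods(meta, data.frame(animal_id = "F1",
                                         birth_date = as.Date("2019-05-01")))
  expect_equal(as.Date(w$start), as.Date("2019-05-01"))
  expect_equal(as.Date(w$end), as.Date("2019-10-01"))
  expect_equal(w$reason, "with_cubs")
  expect_error(flag_cub_periods(meta,
                                data.frame(animal_id = "M1",
                                           birth_date = as.Date("2019-05-01"))),
               "male")
  expect_equal(nrow(flag_cub_periods(meta, NULL)), 0L)
})

test_that("exclusion windows are half-open and no-window input is identity", {
  t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
  rec <- data.frame(animal_id = "A1", timestamp = t0 + c(-1, 0, 3599, 3600),
                    v = 1:4)
  win <- data.frame(animal_id = "A1", start = t0, end = t0 + 3600,
                    reason = "kill_site")
  res <- exclude_windows(rec, win)
  expect_equal(res$kept$v, c(1L, 4L))
  expect_equal(res$removed$v, c(2L, 3L))
  expect_equal(unname(res$removed_by_reason["kill_site"]), 2L)
  expect_identical(exclude_windows(rec, NULL)$kept, rec)
})

test_that("screening retains clean synthetic tracks and removes injected labelled errors", {
  fx <- small_predator()$tracks$fixes
  clean <- screen_gps_errors(fx)
  expect_gte(nrow(clean$kept) / nrow(fx), 0.99)
  inj <- inject_gps_errors(fx, 0.05, seed = 9)
  scr <- screen_gps_errors(inj$fixes)
  expect_gt(nrow(inj$labels), 20)
  hit <- paste(scr$removed$animal_id, scr$removed$timestamp) # removed set
  lab <- paste(inj$labels$animal_id, inj$labels$timestamp)
  sens <- mean(lab %in% hit)
  false_removal <- sum(!hit %in% lab) / (nrow(fx) - length(lab))
  expect_gte(sens, 0.95)
  expect_lte(false_removal, 0.01)
})

test_that("screening order relative to the post-capture trim does not change the kept set", {
  tr <- small_predator()$tracks
  inj <- inject_gps_errors(tr$fixes, 0.03, seed = 5)
  dep <- tr$metadata
  a <- screen_gps_errors(remove_post_capture(inj$fixes, dep))$kept
  b <- remove_post_capture(screen_gps_errors(inj$fixes)$kept, dep)
  expect_equal(paste(a$animal_id, a$timestamp), paste(b$animal_id, b$timestamp))
})
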