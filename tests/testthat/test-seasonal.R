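# Seasonal estimators: hierarchical bootstrap, cyclic harmonic curves,
# lunar effect.

make_disp <- function(per_animal, t0 = as.POSIXct("2019-01-15", tz = "UTC")) {
  # per_animal: named list animal -> constant displacement, monthly grid
  do.call(rbind, lapply(names(per_animal), function(id) {
    months <- seq(t0, by = "month", length.out = 12)
    do.call(rbind, lapply(months, function(m) data.frame(
      animal_id = id, t_start = m + (0:9) * 18000, t_end = m + (1:10) * 18000,
      distance_m = per_animal[[id]], interval_h = 5,
      lon = SITE_LON, lat = SITE_LAT, group = "adult_male")))
  }))
}

test_that("degenerate constant displacements give exact monthly estimates", {
  d1 <- make_disp(list(A = 300))
  est <- suppressWarnings(monthly_displacement_estimates(d1, n_boot = 50,
                                                         seed = 1))
  expect_true(all(est$monthly$estimate == 300))
  expect_true(all(est$monthly$lwr == 300 & est$monthly$upr == 300))
  expect_equal(est$grand$grand_mean, 300)
  expect_equal(est$grand$grand_se, 0)
  # two animals at 200 and 400: equal animal weighting gives 300
  d2 <- make_disp(list(A = 200, B = 400))
  est2 <- monthly_displacement_estimates(d2, n_boot = 50, seed = 1)
  expect_true(all(est2$monthly$estimate == 300))
})

test_that("duplicating one animal's observations leaves group estimates unchanged", {
  set.seed(4)
  base <- make_disp(list(A = 200, B = 400))
  dup <- rbind(base, base[base$animal_id == "B", ])
  e1 <- monthly_displacement_estimates(base, n_boot = 0, seed = 1)
  e2 <- monthly_displacement_estimates(dup, n_boot = 0, seed = 1)
  expect_equal(e1$monthly$estimate, e2$monthly$estimate)
})

test_that("doubling the bootstrap leaves CI endpoints stable within 5%", {
  set.seed(9)
  d <- make_disp(list(A = 250, B = 350, C = 500, D = 420))
  d$distance_m <- d$distance_m * exp(rnorm(nrow(d), 0, 0.4))
  e1 <- monthly_displacement_estimates(d, n_boot = 400, seed = 2)
  e2 <- monthly_displacement_estimates(d, n_boot = 800, seed = 3)
  rel <- abs(e1$monthly$upr - e2$monthly$upr) / e2$monthly$estimate
  expect_lt(stats::median(rel), 0.05)
})

make_components <- function(f, animals = paste0("A", 1:4), period = "night",
                            n = 200, noise = 0, seed = 11) {
  set.seed(seed)
  do.call(rbind, lapply(animals, function(id) {
    off <- rnorm(1, 0, 0.2)
    data.frame(animal_id = id, month = 1:12, period = period, n = n,
               prop_active = plogis(qlogis(f(1:12)) + off +
                                      rnorm(12, 0, noise)),
               rate_when_active = 60 + 20 * f(1:12) + rnorm(12, 0, noise))
  }))
}

test_that("constant responses fit a flat curve and the curve is cyclic", {
  comp <- make_components(function(m) rep(0.4, length(m)))
  cv <- seasonal_activity_curve(comp, "night", n_boot = 0)
  expect_lt(max(cv$fit) - min(cv$fit), 1e-4)
  f1 <- cv$fit[which.min(abs(cv$month - 1))]
  f13 <- cv$fit[which.min(abs(cv$month - 12.999))]
  expect_equal(f1, f13, tolerance = 1e-6)
  expect_true(all(cv$fit >= 0 & cv$fit <= 1))
})

test_that("a summer-rising night proportion peaks in May-August", {
  comp <- make_components(function(m) 0.4 + 0.2 * cos(2 * pi * (m - 7) / 12),
                          noise = 0.05)
  cv <- seasonal_activity_curve(comp, "night", n_boot = 0)
  peak_month <- cv$month[which.max(cv$fit)]
  expect_true(peak_month >= 5 && peak_month <= 8.5)
})

test_that("ridge limits behave: lambda -> Inf flattens, K = 6 with lambda = 0 interpolates monthly means", {
  comp <- make_components(function(m) 0.35 + 0.015 * m, noise = 0.03)
  flat <- seasonal_activity_curve(comp, "night", lambda_grid = 1e9,
                                  n_boot = 0)
  expect_lt(max(flat$fit) - min(flat$fit), 1e-3)
  interp <- seasonal_activity_curve(comp, "night", n_harmonics = 6,
                                    lambda_grid = 1e-12, n_boot = 0,
                                    month_grid = 1:12)
  # weighted centred monthly means on the empirical-logit scale
  y <- log((comp$prop_active * comp$n + 0.5) / ((1 - comp$prop_active) * comp$n + 0.5))
  am <- tapply(y, comp$animal_id, mean)
  yc <- y - am[as.character(comp$animal_id)] + weighted.mean(y, comp$n)
  mm <- plogis(tapply(yc * comp$n, comp$month, sum) /
                 tapply(comp$n, comp$month, sum))
  expect_equal(interp$fit, unname(as.numeric(mm)), tolerance = 1e-6)
})

test_that("too few months reduces the harmonic order with a warning", {
  comp <- make_components(function(m) rep(0.4, length(m)))
  comp <- comp[comp$month %in% 1:4, ]
  expect_warning(cv <- seasonal_activity_curve(comp, "night", n_harmonics = 3,
                                               n_boot = 0),
                 "reduced")
  expect_lt(cv$K, 3)
  expect_error(seasonal_activity_curve(comp[comp$month %in% 1:2, ], "night"),
               "3 distinct")
})

make_lunar <- function(beta, n_per = 60, animals = paste0("L", 1:5),
                       seed = 21) {
  set.seed(seed)
  do.call(rbind, lapply(animals, function(id) {
    illum <- runif(n_per, 0, 1)
    p <- plogis(qlogis(0.45) + beta * illum + rnorm(1, 0, 0.1))
    data.frame(animal_id = id, illuminated_fraction = illum,
               active = runif(n_per) < p)
  }))
}

test_that("lunar effect: null is covered, an injected negative slope is recovered", {
  null_fit <- lunar_activity_effect(make_lunar(0, n_per = 300), n_boot = 100,
                                    seed = 4)
  expect_true(null_fit$ci[1] < 0 && null_fit$ci[2] > 0)
  neg <- lunar_activity_effect(make_lunar(-1.2, n_per = 500), n_boot = 100,
                               seed = 5)
  expect_lt(neg$slope, 0)
  expect_lt(neg$ci[2], 0)
  const <- make_lunar(0); const$illuminated_fraction <- 0.5
  expect_error(lunar_activity_effect(const), "variance")
})
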