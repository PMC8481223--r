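# desk-scale simulated dataset shared by the fitting tests
desk_sim <- local({
  det <- detector_grid(49, 2000, core_n = 0)
  cen <- simulate_centres(det, density = 0.14, buffer = 8000, seed = 11)
  simd <- simulate_detections(cen, det, list(kind = "HN", g0 = 0.05, sigma = 2000),
                              n_occasions = 50, seed = 12)
  list(det = det, ch = simd$ch, n_true = nrow(cen))
})

test_that("capture histories tabulate detections with the one-per-day rule", {
  det <- tibble::tibble(detector_id = c("a", "b"), x = c(0, 1000), y = 0)
  occ <- as.Date("2018-03-01") + 0:2
  ch <- build_capture_histories(
    tibble::tibble(individual = "i1", date = occ[2], detector = "a"), det, occ)
  expect_equal(dim(ch$y), c(1, 3, 2))
  expect_equal(sum(ch$y), 1)
  expect_equal(ch$y[1, 2, 1], 1L)

  # same individual twice at one detector on one day collapses to one
  expect_message(
    ch2 <- build_capture_histories(
      tibble::tibble(individual = c("i1", "i1"), date = occ[1], detector = "a"),
      det, occ),
    "collapsed 1")
  expect_equal(sum(ch2$y), 1)

  # planted detections reproduce a brute-force tabulation
  set.seed(3)
  dd <- tibble::tibble(individual = sample(paste0("i", 1:4), 12, TRUE),
                       date = sample(occ, 12, TRUE),
                       detector = sample(det$detector_id, 12, TRUE))
  dd <- unique(dd)
  ch3 <- build_capture_histories(dd, det, occ)
  for (r in seq_len(nrow(dd))) {
    expect_equal(ch3$y[match(dd$individual[r], ch3$individuals),
                       match(dd$date[r], ch3$occasions),
                       match(dd$detector[r], det$detector_id)], 1L)
  }
  expect_equal(sum(ch3$y), nrow(dd))

  usage <- matrix(1L, 2, 3); usage[1, 1] <- 0L
  expect_error(build_capture_histories(
    tibble::tibble(individual = "i1", date = occ[1], detector = "a"),
    det, occ, usage = usage), "zero usage")
  expect_error(build_capture_histories(
    tibble::tibble(individual = "i1", date = occ[3] + 5, detector = "a"),
    det, occ), "outside the occasion calendar")
})

test_that("the habitat mask clips a square grid to the buffered layout", {
  det <- tibble::tibble(detector_id = "d1", x = 0, y = 0)
  m <- make_mask(det, buffer = 100, spacing = 100)
  # 3x3 candidates, corners at 141 m are outside the 100 m disc
  expect_equal(nrow(m$points), 5)
  expect_equal(m$area_km2, 0.05)

  # doubling the spacing roughly quarters the point count
  det2 <- detector_grid(25, 1500, core_n = 0)
  m1 <- make_mask(det2, buffer = 4000, spacing = 250)
  m2 <- make_mask(det2, buffer = 4000, spacing = 500)
  expect_equal(nrow(m1$points) / nrow(m2$points), 4, tolerance = 0.05)

  # every detector lies inside its own mask
  d <- ctdemog:::edist(cbind(det2$x, det2$y), m1$points)
  expect_true(all(apply(d, 1, min) <= 250))

  expect_warning(make_mask(det, buffer = 100, spacing = 150), "coarse")
})

test_that("mask area agrees with a Monte-Carlo buffered-union area", {
  set.seed(19)
  det <- detector_grid(12, 3000, core_n = 0)[sample(12, 9), ]
  buffer <- 2500
  m <- make_mask(det, buffer = buffer, spacing = 200)
  reg <- c(min(det$x) - buffer, max(det$x) + buffer,
           min(det$y) - buffer, max(det$y) + buffer)
  pts <- cbind(runif(2e5, reg[1], reg[2]), runif(2e5, reg[3], reg[4]))
  inside <- apply(ctdemog:::edist(pts, cbind(det$x, det$y)), 1, min) <= buffer
  mc_area <- mean(inside) * (reg[2] - reg[1]) * (reg[4] - reg[3]) / 1e6
  expect_equal(m$area_km2, mc_area, tolerance = 0.02)
})

test_that("detection functions hit their closed-form anchors", {
  for (kind in c("HN", "EX", "HR")) {
    expect_equal(detection_probability(0, kind, g0 = 0.3, sigma = 1500, z = 3), 0.3)
  }
  expect_equal(detection_probability(2000, "HN", g0 = 1, sigma = 2000), exp(-0.5))
  expect_equal(detection_probability(2000, "HR", g0 = 1, sigma = 2000, z = 3),
               1 - exp(-1))
  d <- seq(0, 10000, by = 250)
  for (kind in c("HN", "EX", "HR")) {
    g <- detection_probability(d, kind, g0 = 0.4, sigma = 1800, z = 2.2)
    expect_true(all(diff(g) <= 0))
    expect_true(all(g <= 0.4))
  }
  expect_error(detection_probability(100, "HN", g0 = 1.4, sigma = 100), "\\[0, 1\\]")
  expect_error(detection_probability(100, "HR", g0 = 0.4, sigma = 100, z = 0.5),
               "z > 1")
  expect_error(detection_probability(-5, "HN", g0 = 0.4, sigma = 100),
               "non-negative")
})

test_that("the conditional likelihood matches hand computations", {
  det1 <- tibble::tibble(detector_id = "d", x = 0, y = 0)
  mask1 <- point_mask()
  occ2 <- as.Date("2018-01-01") + 0:1
  ch <- build_capture_histories(
    tibble::tibble(individual = "i1", date = occ2[1], detector = "d"), det1, occ2)
  # p = 0.5, history (1,0): -log[(0.5)(0.5) / (1 - 0.25)]
  expect_equal(secr_nll(ch, mask1, "HN", g0 = 0.5, sigma = 100),
               -log(0.25 / 0.75), tolerance = 1e-12)

  # one occasion on a one-point mask: conditioning cancels exactly
  ch1 <- build_capture_histories(
    tibble::tibble(individual = "i1", date = occ2[1], detector = "d"),
    det1, occ2[1])
  expect_equal(secr_nll(ch1, mask1, "HN", g0 = 0.5, sigma = 100), 0,
               tolerance = 1e-12)
})

test_that("the likelihood equals brute-force enumeration on random small instances", {
  set.seed(202)
  for (rep in 1:12) {
    inst <- random_secr_instance()
    g0 <- runif(1, 0.1, 0.7); sigma <- runif(1, 300, 1500); z <- runif(1, 1.5, 4)
    for (kind in c("HN", "EX", "HR")) {
      a <- secr_nll(inst$ch, inst$mask, kind, g0 = g0, sigma = sigma,
                    z = if (kind == "HR") z else NULL)
      b <- oracle_secr_nll(inst$ch, inst$mask, kind, g0 = g0, sigma = sigma,
                           z = if (kind == "HR") z else NULL)
      expect_equal(a, b, tolerance = 1e-10)
    }
  }
})

test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(0, 2, 30), 4 + 12 / 27)
  expect_error(aicc(0, 2, 3), "undefined")
})

test_that("the fit recovers known parameters and is an optimizer fixed point", {
  mask <- make_mask(desk_sim$det, buffer = 8000, spacing = 1000)
  fit <- fit_secr(desk_sim$ch, mask, "HN")
  expect_equal(fit$convergence, 0)
  est <- fit$estimates
  expect_lt(abs(est$estimate[est$param == "g0"] - 0.05),
            3 * est$se[est$param == "g0"])
  expect_lt(abs(est$estimate[est$param == "sigma"] - 2000),
            3 * est$se[est$param == "sigma"])

  refit <- fit_secr(desk_sim$ch, mask, "HN",
                    start = est$estimate)
  expect_equal(refit$par, fit$par, tolerance = 1e-6)
  expect_equal(refit$logLik, fit$logLik, tolerance = 1e-8)
})

test_that("esa saturates to the mask area and grows with g0 and occasions", {
  det1 <- tibble::tibble(detector_id = "d", x = 0, y = 0)
  mask1 <- point_mask()
  occ <- as.Date("2018-01-01") + 0:9
  ch <- build_capture_histories(
    tibble::tibble(individual = "i1", date = occ[1], detector = "d"), det1, occ)
  expect_equal(esa(ch, mask1, "HN", g0 = 1 - 1e-15, sigma = 1e9), mask1$area_km2,
               tolerance = 1e-6)

  mask <- make_mask(desk_sim$det, buffer = 8000, spacing = 1000)
  a_g0 <- vapply(c(0.01, 0.05, 0.2, 0.6), function(g)
    esa(desk_sim$ch, mask, "HN", g0 = g, sigma = 2000), numeric(1))
  expect_true(all(diff(a_g0) > 0))

  occ_esa <- vapply(c(5, 20, 50), function(S) {
    ch_s <- desk_sim$ch
    ch_s$usage <- ch_s$usage[, seq_len(S), drop = FALSE]
    esa(ch_s, mask, "HN", g0 = 0.05, sigma = 2000)
  }, numeric(1))
  expect_true(all(diff(occ_esa) > 0))
})

test_that("derived density is coherent and abundance scales with mask area", {
  mask <- make_mask(desk_sim$det, buffer = 8000, spacing = 1000)
  fit <- fit_secr(desk_sim$ch, mask, "HN")
  de <- derive_density(fit)
  expect_equal(de$D, fit$n / fit$esa)
  expect_true(de$D_lcl <= de$D && de$D <= de$D_ucl)
  expect_equal(de$N_hat, de$D * mask$area_km2)
  expect_equal(de$N_lcl / de$D_lcl, mask$area_km2)
})

test_that("density is invariant under translation and rotation of coordinates", {
  mask <- make_mask(desk_sim$det, buffer = 8000, spacing = 1000)
  fit <- fit_secr(desk_sim$ch, mask, "HN")
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rot <- function(xy) sweep(as.matrix(xy) %*% R, 2, c(-5000, 3000), "+")
  det_r <- desk_sim$det
  det_r[, c("x", "y")] <- rot(desk_sim$det[, c("x", "y")])
  ch_r <- desk_sim$ch
  ch_r$detectors <- det_r
  mask_r <- mask
  mask_r$points <- rot(mask$points)
  fit_r <- fit_secr(ch_r, mask_r, "HN", start = fit$estimates$estimate)
  expect_equal(derive_density(fit_r)$D, derive_density(fit)$D, tolerance = 1e-6)
})

test_that("density stabilises once the buffer is wide enough", {
  mask4 <- make_mask(desk_sim$det, buffer = 4 * 2000, spacing = 1000)
  mask8 <- make_mask(desk_sim$det, buffer = 8 * 2000, spacing = 1000)
  d4 <- derive_density(fit_secr(desk_sim$ch, mask4, "HN"))$D
  d8 <- derive_density(fit_secr(desk_sim$ch, mask8, "HN"))$D
  expect_lt(abs(d8 - d4) / d4, 0.02)
})

test_that("model ranking orders by AICc with Akaike weights", {
  mask <- make_mask(desk_sim$det, buffer = 8000, spacing = 1250)
  fit_hn <- fit_secr(desk_sim$ch, mask, "HN")
  rk1 <- rank_models(list(fit_hn))
  expect_equal(rk1$dAICc, 0)
  expect_equal(rk1$weight, 1)

  rk2 <- rank_models(list(fit_hn, fit_hn))
  expect_equal(rk2$weight, c(0.5, 0.5))

  fits <- list(fit_hn, fit_secr(desk_sim$ch, mask, "EX"),
               fit_secr(desk_sim$ch, mask, "HR"))
  rk <- rank_models(fits)
  expect_equal(rk$AICc, sort(rk$AICc))
  expect_equal(sum(rk$weight), 1)
  expect_equal(rk$kind[1], "HN")  # truth is half-normal on this dataset

  ch_alt <- build_capture_histories(
    tibble::tibble(individual = paste0("i", c(1, 2, 3, 4, 1)),
                   date = as.Date("2018-01-01") + c(0, 0, 1, 1, 1),
                   detector = desk_sim$det$detector_id[c(1, 2, 3, 4, 2)]),
    desk_sim$det, as.Date("2018-01-01") + 0:1)
  fit_alt <- suppressWarnings(fit_secr(ch_alt, mask, "HN", start = c(0.1, 1500)))
  expect_error(rank_models(list(fit_hn, fit_alt)), "same data")
})
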