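make_sphere_cloud <- function(n, radius = 350, seed = 1, r_jitter = 0) {
  set.seed(seed)
  u <- runif(n, -1, 1)
  az <- runif(n, 0, 2 * pi)
  r <- radius + rnorm(n, 0, r_jitter)
  tibble::tibble(
    x = r * sqrt(1 - u^2) * cos(az),
    y = r * sqrt(1 - u^2) * sin(az),
    z = r * u,
    dna = 1, signal = 1, embryo = 1L
  )
}

test_that("sphere fitting recovers centre and radius", {
  cloud <- make_sphere_cloud(200)
  cloud$x <- cloud$x + 10 ; cloud$y <- cloud$y - 5
  fit <- fit_sphere(cloud)
  expect_equal(fit$center, c(10, -5, 0), tolerance = 1e-6)
  expect_equal(fit$radius, 350, tolerance = 1e-6)
  flat <- tibble::tibble(x = runif(50), y = runif(50), z = 0,
                         dna = 1, signal = 1)
  expect_error(fit_sphere(flat), "oplanar")
})

test_that("dividing and shell filters remove the documented counts", {
  cloud <- make_sphere_cloud(100, seed = 3, r_jitter = 10)
  cloud$dna <- c(rep(2, 10), rep(1, 90)) # mean 1.1, cutoff 1.54: 10 removed
  filt <- filter_nuclei(cloud)
  expect_equal(attr(filt, "dividing_cutoff"), 1.4 * 1.1)
  expect_true(all(filt$dna == 1))
  # shell removal keeps radial distances (from the fitted centre) between the
  # 15th and 85th percentile of the 90 non-dividing nuclei
  ctr <- fit_sphere(cloud[11:100, ])$center
  r <- sqrt(colSums((t(as.matrix(cloud[11:100, c("x", "y", "z")])) - ctr)^2))
  keep <- r >= quantile(r, 0.15) & r <= quantile(r, 0.85)
  expect_equal(nrow(filt), sum(keep))
  # all dna = 1: nothing removed by the dividing filter
  cloud2 <- make_sphere_cloud(100, seed = 4, r_jitter = 10)
  filt2 <- filter_nuclei(cloud2)
  expect_equal(attr(filt2, "dividing_cutoff"), 1.4)
  # idempotency: re-filtering the output removes nothing more
  expect_equal(nrow(filter_nuclei(filt)), nrow(filt))
})

test_that("marginal band membership matches the geometric rule", {
  cloud <- make_sphere_cloud(2000, seed = 6)
  band <- marginal_band(cloud, 40)
  expect_true(all(band$z >= 0 & band$z <= 40))
  expect_equal(nrow(band), sum(cloud$z >= 0 & cloud$z <= 40))
  # spherical-zone area fraction: a band of height h holds h / (2 R) of a
  # uniform sphere
  expect_equal(nrow(band) / nrow(cloud), 40 / 700, tolerance = 0.3)
  expect_warning(marginal_band(cloud, 0), "empty")
})

test_that("angular binning recovers uniform and cosine ground truths", {
  cloud <- make_sphere_cloud(5000, seed = 8)
  band <- marginal_band(cloud, 40)
  band$signal <- 5
  p36 <- bin_profile(band)
  expect_equal(nrow(p36), 36)
  expect_equal(sum(p36$n), nrow(band))
  expect_true(all(p36$mean[p36$n > 0] == 5))
  # intensity = cos(angle): bin means match the analytic bin average
  ang <- (atan2(band$y, band$x) * 180 / pi + 360) %% 360
  band$signal <- cos(ang * pi / 180)
  p36c <- bin_profile(band)
  lo <- (p36c$angle - 5) * pi / 180
  hi <- (p36c$angle + 5) * pi / 180
  analytic <- (sin(hi) - sin(lo)) / (hi - lo)
  ok <- p36c$n > 1
  expect_true(all(abs(p36c$mean[ok] - analytic[ok]) <=
                    4 * p36c$sd[ok] / sqrt(p36c$n[ok]) + 1e-8))
})

test_that("folding averages mirror bins with n-weighting", {
  p36 <- tibble::tibble(angle = seq(5, 355, by = 10),
                        mean = 1, sd = 0, n = 10L)
  p36$mean[p36$angle == 15] <- 4 ; p36$n[p36$angle == 15] <- 10L
  p36$mean[p36$angle == 345] <- 6 ; p36$n[p36$angle == 345] <- 30L
  class(p36) <- c("dv_profile", class(p36))
  p18 <- fold_profile(p36)
  expect_equal(nrow(p18), 18)
  expect_equal(p18$mean[p18$angle == 15], 5.5) # (4*10 + 6*30) / 40
  expect_equal(p18$n[p18$angle == 15], 40L)
  # weighted intensity is conserved
  expect_equal(sum(p18$mean * p18$n), sum(p36$mean * p36$n))
  # left-right symmetric input: folding is the identity on the half profile
  sym <- p36
  sym$mean <- rep(1:18, length.out = 36)
  sym$mean[19:36] <- rev(sym$mean[1:18])
  folded <- fold_profile(sym)
  expect_equal(folded$mean, sym$mean[1:18])
})

test_that("batch normalization scalars solve the least-squares problem", {
  ref <- tibble::tibble(batch = "a", angle = seq(5, 175, 10),
                        value = seq(2, 0.3, length.out = 18))
  twice <- dplyr::mutate(ref, batch = "b", value = value * 2)
  set.seed(5)
  noisy <- dplyr::mutate(ref, batch = "c",
                         value = value * 2 + rnorm(18, 0, 0.05))
  controls <- dplyr::bind_rows(ref, twice, noisy)
  sc <- normalize_batches(controls, reference = "a")
  expect_equal(sc$scalar[sc$batch == "a"], 1)
  expect_equal(sc$scalar[sc$batch == "b"], 0.5)
  b <- noisy$value
  expect_equal(sc$scalar[sc$batch == "c"], sum(ref$value * b) / sum(b^2))
  expect_error(normalize_batches(controls, reference = "zz"), "not found")
})

test_that("profile comparison flags true differences and not identical groups", {
  set.seed(12)
  mk <- function(shift, n = 10) {
    tidyr::expand_grid(embryo = seq_len(n), angle = seq(5, 175, 10)) |>
      dplyr::mutate(value = rnorm(dplyr::n(), 1 + shift, 0.1))
  }
  same <- compare_profiles(mk(0), mk(0))
  expect_false(any(same$significant, na.rm = TRUE) &&
                 sum(same$significant, na.rm = TRUE) > 3) # few false positives
  far <- compare_profiles(mk(0), mk(1)) # shifted by 10 sds
  expect_true(all(far$significant))
  # bins with n < 2 are masked
  tiny <- compare_profiles(mk(0, n = 1), mk(0))
  expect_true(all(is.na(tiny$p)))
})

test_that("per-bin type-I error stays at the nominal 5% level", {
  set.seed(99)
  angles <- seq(5, 55, 10)
  rejections <- 0L ; tests <- 0L
  for (rep in seq_len(1000)) {
    a <- tibble::tibble(
      embryo = rep(1:6, each = length(angles)),
      angle = rep(angles, 6), value = rnorm(6 * length(angles))
    )
    b <- tibble::tibble(
      embryo = rep(1:6, each = length(angles)),
      angle = rep(angles, 6), value = rnorm(6 * length(angles))
    )
    res <- compare_profiles(a, b, alpha = 0.05)
    rejections <- rejections + sum(res$significant, na.rm = TRUE)
    tests <- tests + sum(!is.na(res$significant))
  }
  expect_equal(rejections / tests, 0.05, tolerance = 0.015 / 0.05)
})

test_that("lowess slope matches linear and smooth ground truths", {
  lin <- tibble::tibble(angle = seq(5, 175, 10), mean = 2 * seq(5, 175, 10),
                        sd = 0, n = 10L)
  sl <- profile_slope(lin, span = 0.5, threshold = 0.5)
  expect_equal(sl$slope[3:16], rep(2, 14), tolerance = 1e-6)
  expect_true(all(sl$high_slope[3:16]))
  flat <- dplyr::mutate(lin, mean = 7)
  expect_equal(max(abs(profile_slope(flat)$slope)), 0)
  # smoothed slope of a noisy sine tracks the analytic derivative
  set.seed(2)
  th <- seq(2.5, 177.5, 5)
  sine <- tibble::tibble(angle = th,
                         mean = sin(th * pi / 90) + rnorm(length(th), 0, 0.01),
                         sd = 0, n = 10L)
  ssl <- profile_slope(sine, span = 0.25)
  truth <- (pi / 90) * cos(th * pi / 90)
  interior <- 8:28
  expect_lt(max(abs(ssl$slope[interior] - truth[interior])),
            0.1 * max(abs(truth)))
  expect_error(profile_slope(lin[1:4, ]), "at least 5")
  expect_error(profile_slope(lin, span = 0.05), "3 points")
})

test_that("resampling to the model grid is exact for linear profiles", {
  g <- fx_geom()
  const <- tibble::tibble(angle = seq(5, 175, 10), mean = 3, sd = 0, n = 1L)
  expect_equal(resample_to_model_grid(const, g), rep(3, 36))
  lin <- dplyr::mutate(const, mean = angle * 0.01)
  v <- resample_to_model_grid(lin, g)
  inside <- g$x >= 5 / 180 * 700 & g$x <= 175 / 180 * 700
  expect_equal(v[inside], (g$x[inside] / 700 * 180) * 0.01, tolerance = 1e-10)
  # round-trip: re-reading values at bin-centre positions reproduces them
  set.seed(3)
  rnd <- dplyr::mutate(const, mean = runif(18))
  vr <- resample_to_model_grid(rnd, g)
  back <- approx(g$x, vr, xout = rnd$angle / 180 * 700)$y
  expect_equal(back, rnd$mean, tolerance = 0.08) # linear-interp error bound
  expect_error(resample_to_model_grid(const[1, ], g), "2 valid bins")
})
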