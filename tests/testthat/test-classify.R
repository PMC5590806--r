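test_that("half_max_position interpolates ventral-to-dorsal crossings", {
  # linear ramp over a 700 um axis crosses half-max at the midpoint
  x <- seq(0, 700, length.out = 36)
  expect_equal(half_max_position(1 - x / 700), 350)
  # constant profile never crosses: axis length returned
  expect_equal(half_max_position(rep(2, 36)), 700)
  # exponential with length scale 100 um: analytic ln(2) * 100
  prof <- exp(-x / 100)
  expect_equal(half_max_position(prof), 100 * log(2), tolerance = 0.01)
  expect_error(half_max_position(rep(0, 36)), "positive maximum")
})

test_that("classifier applies the rules in precedence order", {
  cfg <- fit_config()
  bal <- tibble::tibble(
    produced = 10, decayed = 1, net_diffused_out = 3, net_bound_chd = 1,
    net_bound_nog = 0, tld_release = 0, accumulated = 5, closure_rel = 0
  )
  B_wt <- c(1, 0.8, 0.5, 0.2)
  # ventral point at 70% of wild type: 20% rule fires first
  expect_equal(classify_mechanism(bal, B_wt, c(0.7, 0.8, 0.5, 0.2), cfg),
               "shuttling")
  # boundary case: exactly 20% decrease is shuttling (inclusive)
  expect_equal(classify_mechanism(bal, B_wt, c(0.8, 0.8, 0.5, 0.2), cfg),
               "shuttling")
  # (decayed + accumulated)/produced = 0.85 without ventral drop
  bal_t <- bal
  bal_t$decayed <- 3.5 ; bal_t$accumulated <- 5 ; bal_t$net_diffused_out <- 1.5
  expect_equal(classify_mechanism(bal_t, B_wt, B_wt, cfg), "transcriptional")
  # majority of BMP diffused away (3 vs 1 nM um): source-sink
  expect_equal(classify_mechanism(bal, B_wt, B_wt, cfg), "source_sink")
  # majority bound by Chordin at the source: counter-gradient
  bal_c <- bal
  bal_c$net_diffused_out <- 1 ; bal_c$net_bound_chd <- 3
  expect_equal(classify_mechanism(bal_c, B_wt, B_wt, cfg), "counter_gradient")
  # no production: unclassified
  bal_0 <- bal ; bal_0$produced <- 0
  expect_equal(classify_mechanism(bal_0, B_wt, B_wt, cfg), "unclassified")
})

test_that("Drosophila-like flag needs steepness, peak drop and little Noggin", {
  cfg <- fit_config()
  x <- seq(0, 700, length.out = 36)
  steep <- exp(-x / 35)   # half-max at 24.3 um = 3.5% of the axis
  broad <- exp(-x / 300)
  bal <- tibble::tibble(
    produced = 10, decayed = 1, net_diffused_out = 5, net_bound_chd = 1,
    net_bound_nog = 0.1, tld_release = 0, accumulated = 2.9, closure_rel = 0
  )
  expect_true(drosophila_like(bal, steep, 0.4 * steep, cfg))
  # 40% ventral drop misses the 50% requirement
  expect_false(drosophila_like(bal, steep, 0.6 * steep, cfg))
  # broad gradient fails the 10% half-max criterion
  expect_false(drosophila_like(bal, broad, 0.4 * broad, cfg))
  # heavy BMP-Noggin flux (20% of produced) is excluded
  bal_n <- bal ; bal_n$net_bound_nog <- 2
  expect_false(drosophila_like(bal_n, steep, 0.4 * steep, cfg))
})

test_that("uniform-Chordin robustness uses the wild-type scale, inclusive", {
  tgt <- fx_targets()$WT
  cfg <- fit_config()
  expect_true(uniform_chd_robust(tgt, tgt, s = 1, cfg))
  # flattened profile is no longer wild-type-like
  expect_false(uniform_chd_robust(rep(mean(tgt), length(tgt)), tgt, 1, cfg))
  # borderline: NRMSD exactly at the threshold counts as robust
  off <- tgt + cfg$nrmsd_threshold * max(tgt)
  expect_equal(nrmsd(off, tgt), cfg$nrmsd_threshold)
  expect_true(uniform_chd_robust(off, tgt, s = 1, cfg))
  expect_error(uniform_chd_robust(NULL, tgt, 1, cfg), "chd_uniform")
})

test_that("hand-built mechanism fixtures recover their intended labels", {
  runs <- fx_mechanism_runs()
  cfg <- fit_config()
  for (mech in names(runs)) {
    r <- runs[[mech]]
    expect_true(r$wt$success)
    # a target generated from the fixture's own output passes the WT gate
    gate <- gate_solution(list(WT = r$wt$final$B), list(WT = r$wt$final$B), cfg)
    expect_true(gate$pass_wt)
    expect_equal(
      classify_mechanism(r$balance, r$wt$final$B, r$chd_null$final$B, cfg),
      mech
    )
  }
  # spec'd quantitative features of individual fixtures
  sh <- runs$shuttling
  expect_lte(sh$chd_null$final$B[1], 0.8 * sh$wt$final$B[1])
  tr <- runs$transcriptional
  expect_gte((tr$balance$decayed + tr$balance$accumulated) /
               tr$balance$produced, 0.8)
})

test_that("every gated solution gets exactly one of the four labels", {
  labels <- c("shuttling", "transcriptional", "source_sink", "counter_gradient")
  runs <- fx_mechanism_runs()
  cfg <- fit_config()
  # randomized balances + profiles: classification is total and single-valued
  set.seed(21)
  for (i in 1:50) {
    bal <- tibble::tibble(
      produced = runif(1, 0.1, 10), decayed = runif(1, 0, 5),
      net_diffused_out = runif(1, -1, 5), net_bound_chd = runif(1, 0, 5),
      net_bound_nog = runif(1, 0, 1), tld_release = runif(1, 0, 1),
      accumulated = runif(1, 0, 5), closure_rel = 0
    )
    B_wt <- runif(36, 0.1, 1)
    B_cn <- runif(36, 0, 1.5)
    lab <- classify_mechanism(bal, B_wt, B_cn, cfg)
    expect_length(lab, 1)
    expect_true(lab %in% labels)
  }
  for (mech in names(runs)) {
    r <- runs[[mech]]
    expect_true(classify_mechanism(r$balance, r$wt$final$B,
                                   r$chd_null$final$B, cfg) %in% labels)
  }
})
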