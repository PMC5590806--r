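test_that("rd_rhs reproduces closed-form special cases", {
  g <- dv_geometry(n_nodes = 12)
  p0 <- dv_params(eta_B = 0, eta_C = 0, eta_N = 0)
  f0 <- production_fields(g, p0)
  # all-zero state, no production: derivatives vanish
  expect_equal(rd_rhs(matrix(0, 12, 5), p0, f0),
               matrix(0, 12, 5, dimnames = list(NULL, c("B","C","N","BC","BN"))))
  # spatially uniform state, no production or reactions: Laplacian of constant
  pnr <- dv_params(eta_B = 0, eta_C = 0, eta_N = 0,
                   dec_B = 0, dec_C = 0, dec_N = 0, dec_BC = 0, dec_BN = 0,
                   lambda_C = 0, lambda_BC = 0, kon_BC = 0, kon_BN = 0)
  fnr <- production_fields(g, pnr)
  u <- matrix(rep(c(1, 2, 3, 4, 5), each = 12), 12, 5)
  expect_equal(max(abs(rd_rhs(u, pnr, fnr))), 0)
  # single species uniform decay: dB/dt = -dec_B * B at every node
  pd <- dv_params(eta_B = 0, eta_C = 0, eta_N = 0, dec_B = 1e-3,
                  kon_BC = 0, kon_BN = 0, lambda_C = 0, lambda_BC = 0)
  fd <- production_fields(g, pd)
  st <- matrix(0, 12, 5); st[, 1] <- 1
  d <- rd_rhs(st, pd, fd)
  expect_equal(d[, 1], rep(-1e-3, 12))
  expect_equal(max(abs(d[, -1])), 0)
  # non-finite states are reported with their node index
  st[7, 1] <- NaN
  expect_error(rd_rhs(st, pd, fd), "node 7")
})

test_that("zero production gives an identically zero solution", {
  g <- dv_geometry(n_nodes = 10, t_final = 600)
  p <- dv_params(eta_B = 0, eta_C = 0, eta_N = 0)
  sim <- simulate_gradient(p, production_fields(g, p))
  expect_true(sim$success)
  expect_equal(max(abs(as.matrix(sim$final[, c("B","C","N","BC","BN")]))), 0)
})

test_that("molecule counts are conserved without decay or cleavage", {
  g <- fx_geom()
  for (seed in 1:3) {
    set.seed(seed)
    p <- dv_params(
      eta_B = runif(1, 0.01, 1), eta_C = runif(1, 0.01, 1),
      eta_N = runif(1, 0.01, 1),
      dec_B = 0, dec_C = 0, dec_N = 0, dec_BC = 0, dec_BN = 0,
      lambda_C = 0, lambda_BC = 0,
      D_B = 10^runif(1, -1, 1), D_C = 10^runif(1, -1, 1),
      D_N = 1, D_BC = 1, D_BN = 1,
      kon_BC = 10^runif(1, -3, -1), kon_BN = 10^runif(1, -3, -1)
    )
    f <- production_fields(g, p)
    sim <- simulate_gradient(p, f)
    w <- g$weights
    fin <- sim$final
    # each BMP molecule counted once (free or in either complex)
    bmp <- sum(w * (fin$B + fin$BC + fin$BN))
    expect_equal(bmp, g$t_final * sum(w * f$eta_B), tolerance = 1e-3)
    chd <- sum(w * (fin$C + fin$BC))
    expect_equal(chd, g$t_final * sum(w * f$eta_C), tolerance = 1e-3)
    nog <- sum(w * (fin$N + fin$BN))
    expect_equal(nog, g$t_final * sum(w * f$eta_N), tolerance = 1e-3)
    expect_gt(sim$min_conc, -1e-6) # non-negativity
  }
})

test_that("uniform binding run reaches the closed-form equilibrium", {
  # totals B_tot = C_tot = 2 nM at Kd = 1 nM: BC^2 - 5 BC + 4 = 0 -> BC = 1
  g <- dv_geometry(n_nodes = 8)
  p <- dv_params(eta_B = 2 / g$t_final, eta_C = 2 / g$t_final, eta_N = 0,
                 dec_B = 0, dec_C = 0, dec_N = 0, dec_BC = 0, dec_BN = 0,
                 lambda_C = 0, lambda_BC = 0, kon_BC = 1, kon_BN = 0)
  f <- production_fields(g, p, bmp_shape = rep(1, 8))
  f$eta_C <- rep(2 / g$t_final, 8) # uniform Chordin production too
  sim <- simulate_gradient(p, f)
  expect_equal(sim$final$B, rep(1, 8), tolerance = 5e-3)
  expect_equal(sim$final$C, rep(1, 8), tolerance = 5e-3)
  expect_equal(sim$final$BC, rep(1, 8), tolerance = 5e-3)
})

test_that("mirror-reflected production fields give the mirrored solution", {
  g <- fx_geom()
  p <- dv_params()
  f <- production_fields(g, p)
  fr <- f
  for (nm in c("eta_B", "eta_C", "eta_N", "tld", "shape")) {
    fr[[nm]] <- rev(f[[nm]])
  }
  s1 <- simulate_gradient(p, f)
  s2 <- simulate_gradient(p, fr)
  d <- max(abs(as.matrix(s1$final[, c("B","C","N","BC","BN")]) -
                 as.matrix(s2$final[nrow(s2$final):1, c("B","C","N","BC","BN")])))
  expect_lt(d, 1e-9)
})

test_that("adaptive solution matches a fixed-step explicit Euler oracle", {
  g <- dv_geometry(n_nodes = 8, t_final = 300)
  p <- dv_params(kon_BC = 0.05, kon_BN = 0.05)
  f <- production_fields(g, p)
  state <- matrix(0, 8, 5)
  dt <- 0.01
  for (i in seq_len(g$t_final / dt)) state <- state + dt * rd_rhs(state, p, f)
  sim <- simulate_gradient(p, f, n_save = 2)
  fin <- as.matrix(sim$final[, c("B", "C", "N", "BC", "BN")])
  expect_lt(max(abs(fin - state)) / max(abs(state)), 0.005)
})

test_that("doubling the grid changes the final BMP profile by < 5%", {
  p <- dv_params()
  g36 <- fx_geom()
  g71 <- dv_geometry(n_nodes = 71)
  B36 <- simulate_gradient(p, production_fields(g36, p))$final$B
  B71 <- simulate_gradient(p, production_fields(g71, p))$final$B
  interp <- approx(g71$x, B71, xout = g36$x)$y
  expect_lt(max(abs(interp - B36)) / max(B36), 0.05)
})

test_that("mass balance closes and degenerates correctly", {
  g <- fx_geom()
  p <- dv_params()
  f <- production_fields(g, p)
  sim <- simulate_gradient(p, f)
  b <- mass_balance(sim, production_region(f))
  expect_lt(b$closure_rel, 0.01)

  # whole axis, no decay or binding: no-flux boundaries keep everything in
  pc <- dv_params(dec_B = 0, kon_BC = 0, kon_BN = 0, lambda_BC = 0)
  simc <- simulate_gradient(pc, production_fields(g, pc))
  bc <- mass_balance(simc)
  expect_equal(bc$net_diffused_out, 0, tolerance = 1e-8 * bc$produced)
  expect_equal(bc$accumulated, bc$produced, tolerance = 1e-3 * bc$produced)

  # production region, pure diffusion: produced = diffused out + accumulated
  br <- mass_balance(simc, production_region(production_fields(g, pc)))
  expect_equal(br$produced, br$net_diffused_out + br$accumulated,
               tolerance = 1e-3 * br$produced)
  expect_gt(br$net_diffused_out, 0)

  # zero production vector: every term vanishes
  p0 <- dv_params(eta_B = 0, eta_C = 0, eta_N = 0)
  b0 <- mass_balance(simulate_gradient(p0, production_fields(g, p0)))
  expect_true(all(abs(unlist(b0[1, 1:7])) == 0))

  expect_error(mass_balance(sim, integer(0)), "at least one node")
  expect_error(mass_balance(sim, c(1, 99)), "out of range")
})
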