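p_spot <- model_params("cima", 9.74, 0.27, 1.5, 12.5)

test_that("random initial conditions are seeded Gaussian perturbations", {
  g <- build_grid(20, 20, 0.5)
  ss <- steady_state(p_spot)

  ic0 <- random_ic(p_spot, g, sd = 0, seed = 1)
  expect_equal(ic0$u$values, rep(ss[["u"]], 1681))
  expect_equal(ic0$v$values, rep(ss[["v"]], 1681))

  ic1 <- random_ic(p_spot, g, sd = 0.1, seed = 42)
  ic2 <- random_ic(p_spot, g, sd = 0.1, seed = 42)
  expect_identical(ic1$u$values, ic2$u$values)
  expect_identical(ic1$v$values, ic2$v$values)
  expect_false(identical(ic1$u$values,
                         random_ic(p_spot, g, sd = 0.1, seed = 43)$u$values))

  # CLT bound on the sample mean (prob > 0.999 at 4 sigma)
  expect_lt(abs(mean(ic1$u$values) - ss[["u"]]), 4 * 0.1 / sqrt(1681))
})

test_that("the unperturbed steady state stays steady", {
  g <- build_grid(20, 20, 0.5)
  ic <- random_ic(p_spot, g, sd = 0, seed = 1)
  sim <- integrate_rd(p_spot, ic$u, ic$v, sim_config(tau_end = 250))
  ss <- steady_state(p_spot)
  expect_lt(max(abs(sim$u$values - ss[["u"]])), 1e-6)
  expect_lt(max(abs(sim$v$values - ss[["v"]])), 1e-6)
})

test_that("pure diffusion conserves the trapezoidal mean", {
  g <- build_grid(10, 10, 0.5)
  ic <- random_ic(p_spot, g, sd = 0.3, seed = 9)
  m0 <- c(field_mean(ic$u), field_mean(ic$v))
  sim <- integrate_rd(p_spot, ic$u, ic$v,
                      sim_config(tau_end = 20, steady_tol = 1e-14),
                      reaction = FALSE)
  expect_lt(abs(field_mean(sim$u) - m0[1]), 1e-8)
  expect_lt(abs(field_mean(sim$v) - m0[2]), 1e-8)
  # diffusion-only flattens towards the mean
  expect_lt(diff(range(sim$u$values)), diff(range(ic$u$values)))
})

test_that("a single unstable mode grows at its linear rate", {
  g <- build_grid(20, 20, 0.5)
  p <- model_params("cima", 10, 0.3, 1.5, 20)
  lin <- linearise(p)
  m <- 5
  k2 <- pi^2 * m^2 / 400
  lam <- dispersion(lin, k2)$lambda
  ss <- steady_state(p)
  co <- grid_coords(g)
  u0 <- new_field(g, ss[["u"]] + 1e-4 * cos(m * pi * co$x / 20), "u")
  v0 <- new_field(g, rep(ss[["v"]], nrow(co)), "v")
  amp <- function(f) {
    w <- cos(m * pi * co$x / 20)
    sum(w * (f$values - mean(f$values))) / sum(w^2)
  }
  cfg <- function(te) sim_config(tau_end = te, method = "rk45",
                                 steady_tol = 1e-12)
  s1 <- integrate_rd(p, u0, v0, cfg(10))
  s2 <- integrate_rd(p, u0, v0, cfg(30))
  rate <- (log(abs(amp(s2$u))) - log(abs(amp(s1$u)))) / 20
  expect_lt(abs(rate - lam) / lam, 0.1)
})

test_that("the implicit and explicit integrators agree on a pattern", {
  g <- build_grid(20, 20, 0.5)
  ic <- random_ic(p_spot, g, sd = 0.1, seed = 5)
  a <- integrate_rd(p_spot, ic$u, ic$v, sim_config(tau_end = 5))
  b <- integrate_rd(p_spot, ic$u, ic$v, sim_config(tau_end = 5,
                                                   method = "rk45"))
  # same trajectory to within the splitting error (u_s is O(1) here)
  expect_lt(max(abs(a$u$values - b$u$values)), 0.01)
  expect_lt(max(abs(a$v$values - b$v$values)), 0.01)
})

test_that("the spots-region node produces a spotted pattern", {
  # stochastic but robust: many persistent components in the u lower-star
  g <- build_grid(20, 20, 0.5)
  sim <- simulate_pattern(p_spot, g, sim_config(seed = 42))
  bc <- compute_barcodes(star_filtration(sim$u, direction = "lower"))
  expect_gte(nrow(clean_barcode(bc$B0, 5)), 5L)
})

test_that("an under-resolved grid triggers the sampling warning", {
  g <- build_grid(20, 20, 4)
  p <- model_params("cima", 10, 0.3, 1.5, 20)
  ic <- random_ic(p, g, sd = 0.1, seed = 1)
  expect_warning(integrate_rd(p, ic$u, ic$v, sim_config(tau_end = 0.1)),
                 "sampling bound")
})
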