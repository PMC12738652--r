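test_that("steady states satisfy the kinetics and match closed forms", {
  p <- model_params("cima", alpha = 5, beta = 1, delta = 1.5, sigma = 1)
  expect_equal(unname(steady_state(p)), c(1, 2))

  p0 <- model_params("cima", alpha = 0, beta = 1, delta = 1.5, sigma = 1)
  expect_equal(unname(steady_state(p0)), c(0, 1))

  ps <- model_params("schnakenberg", alpha = 0.1, beta = 0.9, delta = 30)
  expect_equal(unname(steady_state(ps)), c(1.0, 0.9))

  # kinetics vanish at the steady state for a random parameter sample
  set.seed(1)
  for (i in 1:25) {
    p <- model_params(sample(c("cima", "schnakenberg"), 1),
                      alpha = runif(1, 0.1, 20), beta = runif(1, 0.1, 3),
                      delta = runif(1, 0.5, 40), sigma = runif(1, 1, 20))
    ss <- steady_state(p)
    kin <- kinetics(p, ss[["u"]], ss[["v"]])
    expect_lt(max(abs(c(kin$f, kin$g))), 1e-10 * max(1, abs(ss)))
  }
})

test_that("CIMA linearisation matches the printed Jacobian", {
  p <- model_params("cima", alpha = 5, beta = 1, delta = 1.5, sigma = 1)
  lin <- linearise(p)
  expect_equal(c(lin$f_u, lin$f_v, lin$g_u, lin$g_v), c(-1, -2, 1, -0.5))
  expect_equal(lin$d_u, 1)
  expect_equal(lin$d_v, 1.5)

  # agreement with the closed form across a random sample, and via numerical
  # differentiation of the kinetics
  set.seed(2)
  for (i in 1:100) {
    a <- runif(1, 0.01, 20); b <- runif(1, 0.05, 3)
    s <- runif(1, 1, 20); d <- runif(1, 0.5, 3)
    lin <- linearise(model_params("cima", a, b, d, s))
    A <- a^2 + 25
    expect_equal(lin$f_u, (3 * a^2 - 125) / A, tolerance = 1e-12)
    expect_equal(lin$f_v, -20 * a / A, tolerance = 1e-12)
    expect_equal(lin$g_u, 2 * a^2 * b * s / A, tolerance = 1e-12)
    expect_equal(lin$g_v, -5 * a * b * s / A, tolerance = 1e-12)
    expect_lt(lin$f_v, 0)
  }
})

test_that("Schnakenberg linearisation equals kinetics derivatives", {
  p <- model_params("schnakenberg", alpha = 0.1, beta = 0.9, delta = 30)
  lin <- linearise(p)
  expect_equal(c(lin$f_u, lin$f_v, lin$g_u, lin$g_v), c(0.8, 1.0, -1.8, -1.0))
  expect_equal(lin$d_v, 30)

  # finite differences as an independent check
  ss <- steady_state(p)
  h <- 1e-6
  num <- function(f, wrt) {
    du <- if (wrt == "u") h else 0
    dv <- if (wrt == "v") h else 0
    kp <- kinetics(p, ss[["u"]] + du, ss[["v"]] + dv)
    km <- kinetics(p, ss[["u"]] - du, ss[["v"]] - dv)
    (unlist(kp) - unlist(km)) / (2 * h)
  }
  expect_equal(unname(num("f", "u")), c(lin$f_u, lin$g_u), tolerance = 1e-6)
  expect_equal(unname(num("f", "v")), c(lin$f_v, lin$g_v), tolerance = 1e-6)
})

test_that("Turing conditions classify example parameter points", {
  inside <- turing_conditions(linearise(
    model_params("cima", 10, 0.3, 1.5, 20)))
  expect_true(all(inside))

  out <- turing_conditions(linearise(model_params("cima", 5, 1, 1.5, 1)))
  expect_false(out[["c3"]])
  expect_false(out[["in_space"]])

  # f_u <= 0 and g_v <= 0 (not both 0) force C3 to fail
  lin <- linearise(model_params("cima", 5, 1, 1.5, 1)) # f_u = -1, g_v = -0.5
  expect_lte(lin$f_u, 0)
  expect_lte(lin$g_v, 0)
  expect_false(turing_conditions(lin)[["c3"]])
})

test_that("the Hopf boundary f_u + g_v = 0 is excluded (C1 strict)", {
  # pick beta so that f_u + g_v = 0 exactly
  a <- 10; s <- 20; A <- a^2 + 25
  f_u <- (3 * a^2 - 125) / A
  b <- f_u * A / (5 * a * s)
  lin <- linearise(model_params("cima", a, b, 1.5, s))
  expect_equal(lin$f_u + lin$g_v, 0, tolerance = 1e-12)
  expect_false(turing_conditions(lin)[["in_space"]])
})

test_that("dispersion relation h and lambda behave as determinant and growth", {
  lin <- linearise(model_params("cima", 10, 0.3, 1.5, 20))
  # constant term of the quartic is the kinetic determinant
  d0 <- dispersion(lin, 0)
  expect_equal(d0$h, lin$f_u * lin$g_v - lin$f_v * lin$g_u)
  # frozen spot check at k2 = 0.66: 30*0.66^2 - 39.6*0.66 + 12
  expect_equal(dispersion(lin, 0.66)$h, -1.068, tolerance = 1e-10)

  set.seed(3)
  for (i in 1:50) {
    p <- model_params("cima", runif(1, 0.1, 20), runif(1, 0.05, 3),
                      runif(1, 0.5, 3), runif(1, 1, 20))
    lin <- linearise(p)
    k2 <- runif(1, 0, 3)
    d <- dispersion(lin, k2)
    # h equals the determinant of the k2-shifted Jacobian
    J <- matrix(c(lin$f_u - lin$d_u * k2, lin$g_u,
                  lin$f_v, lin$g_v - lin$d_v * k2), 2, 2)
    expect_equal(d$h, det(J), tolerance = 1e-10)
    # lambda is the largest real part of its eigenvalues
    expect_equal(d$lambda, max(Re(eigen(J)$values)), tolerance = 1e-10)
    # negative determinant forces a positive growth rate
    if (d$h < 0) expect_gt(d$lambda, 0)
  }
})
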