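test_that("feasible beta interval matches direct condition checks", {
  set.seed(14)
  for (i in 1:30) {
    al <- runif(1, 6.5, 20); sg <- runif(1, 1, 20); de <- 1.5
    bb <- cima_beta_bounds(al, sg, de)
    # just inside the interval C1 and C3 hold; outside, one of them fails
    for (be in c(bb$lo + 1e-6, bb$hi - 1e-6)) {
      if (be <= 0 || bb$hi <= bb$lo) next
      tc <- turing_conditions(linearise(model_params("cima", al, be, de, sg)))
      expect_true(tc[["c1"]] && tc[["c3"]])
    }
    if (bb$lo > 0) {
      tc <- turing_conditions(linearise(model_params("cima", al, bb$lo - 1e-6,
                                                     de, sg)))
      expect_false(tc[["c1"]])
    }
    tc <- turing_conditions(linearise(model_params("cima", al, bb$hi + 1e-6,
                                                   de, sg)))
    expect_false(tc[["c3"]])
  }
})

test_that("degenerate bounds dominate the single-point unstable band", {
  # collapsing the scan to alpha = 10, sigma = 20 (beta still scanned) must
  # return a mode with k2 at least that of any unstable mode at beta = 0.3
  res <- max_unstable_wavenumber(alpha_range = c(10, 10),
                                 sigma_range = c(20, 20),
                                 alpha_step = 1, sigma_step = 1)
  modes <- enumerate_modes(linearise(model_params("cima", 10, 0.3, 1.5, 20)),
                           20, 20, 10L)
  expect_gte(res$k2, max(modes$k2[modes$unstable]))
})

test_that("an empty scan region is reported", {
  expect_error(max_unstable_wavenumber(alpha_range = c(0, 5),
                                       sigma_range = c(1, 2)),
               "no point of the Turing space")
})

test_that("insufficient mode enumeration is caught, not truncated", {
  expect_error(max_unstable_wavenumber(alpha_range = c(10, 10),
                                       sigma_range = c(20, 20),
                                       alpha_step = 1, sigma_step = 1,
                                       max_index = 3L),
               "max_index too small")
})

test_that("membership sweeps tabulate conditions and dominant modes", {
  tab <- turing_space_sweep("cima", alpha = c(5, 10), beta = c(0.3, 1),
                            delta = 1.5, sigma = 20)
  expect_equal(nrow(tab), 4L)
  row <- tab[tab$alpha == 10 & tab$beta == 0.3, ]
  expect_true(row$in_space)
  expect_equal(row$n_unstable, 13L)
  expect_equal(row$m_star^2 + row$n_star^2, 26)
  expect_false(any(tab$in_space[tab$alpha == 5]))
})
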