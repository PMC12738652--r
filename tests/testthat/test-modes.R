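lin_ref <- linearise(model_params("cima", 10, 0.3, 1.5, 20))

test_that("unstable Neumann modes are enumerated exactly", {
  modes <- enumerate_modes(lin_ref, 20, 20, 10L)
  expect_equal(nrow(modes), 11L * 11L - 1L)
  expect_equal(sum(modes$unstable), 13L)
  expect_setequal(unique(modes$m[modes$unstable]^2 + modes$n[modes$unstable]^2),
                  c(20, 25, 26, 29, 32, 34))
  # every unstable record satisfies h < 0 (and hence lambda > 0)
  expect_true(all(modes$h[modes$unstable] < 0))
  expect_true(all(modes$lambda[modes$unstable] > 0))

  # brute-force recount via the dispersion relation directly
  brute <- 0L
  for (m in 0:10) for (n in 0:10) {
    if (m + n == 0) next
    d <- dispersion(lin_ref, pi^2 * (m^2 + n^2) / 400)
    if (d$h < 0 && d$lambda > 0) brute <- brute + 1L
  }
  expect_identical(sum(modes$unstable), brute)
})

test_that("a point outside the Turing space has no unstable modes", {
  lin <- linearise(model_params("cima", 5, 1, 1.5, 1))
  modes <- enumerate_modes(lin, 20, 20, 10L)
  expect_equal(sum(modes$unstable), 0L)
  expect_error(dominant_mode(lin, 20, 20, 10L), "no unstable mode")
})

test_that("too small max_index raises the coverage error", {
  expect_error(enumerate_modes(lin_ref, 20, 20, 2L), "max_index too small")
})

test_that("doubling the domain rescales mode indices but not the k2 band", {
  # band in k2 is a property of the kinetics alone
  band <- unstable_band(lin_ref)
  m1 <- enumerate_modes(lin_ref, 20, 20, 10L)
  m2 <- enumerate_modes(lin_ref, 40, 40, 20L)
  # (m, n) unstable on L iff (2m, 2n) unstable on 2L (same k2)
  un1 <- m1[m1$unstable, ]
  for (i in seq_len(nrow(un1))) {
    j <- which(m2$m == 2 * un1$m[i] & m2$n == 2 * un1$n[i])
    expect_equal(m2$k2[j], un1$k2[i])
    expect_true(m2$unstable[j])
  }
  expect_equal(unstable_band(lin_ref), band)
})

test_that("the dominant mode maximises lambda, with symmetric ties on squares", {
  dm <- dominant_mode(lin_ref, 20, 20, 10L)
  expect_equal(dm$m^2 + dm$n^2, 26)
  # the reflected index pair attains the same growth rate
  modes <- dm$modes
  twin <- modes[modes$m == dm$n & modes$n == dm$m, ]
  expect_equal(twin$lambda, dm$lambda)
  expect_true(dm$gap_percent > 0) # several distinct unstable k2 here

  # gap over distinct k2 values: reflected twins must not produce a 0 gap
  lam_un <- modes$lambda[modes$unstable]
  second <- max(lam_un[abs(lam_un - dm$lambda) > 1e-12])
  expect_equal(dm$gap_percent, 100 * (dm$lambda - second) / dm$lambda)
})

test_that("a single unstable k2 yields a zero eigenvalue gap", {
  # shrink the domain until exactly one distinct k2 is unstable
  dm <- dominant_mode(lin_ref, 20 / sqrt(26), 20 / sqrt(26), 10L)
  un <- dm$modes[dm$modes$unstable, ]
  expect_equal(length(unique(round(un$k2, 12))), 1L)
  expect_equal(dm$gap_percent, 0)
})
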