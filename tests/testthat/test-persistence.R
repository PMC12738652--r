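test_that("the grid triangulation is a disk with the expected counts", {
  g2 <- build_grid(1, 1, 1)
  cx2 <- triangulate_grid(g2)
  expect_equal(cx2$n_vertices, 4L)
  expect_equal(nrow(cx2$edges), 5L)
  expect_equal(nrow(cx2$triangles), 2L)
  expect_equal(euler_characteristic(cx2), 1L)

  g <- build_grid(20, 20, 0.5)
  cx <- triangulate_grid(g)
  expect_equal(nrow(cx$triangles), 3200L)
  expect_equal(euler_characteristic(cx), 1L)
})

test_that("complexes must be closed under faces", {
  expect_error(new_simplicial_complex(3, rbind(c(1, 2), c(2, 3)),
                                      rbind(c(1, 2, 3))),
               "not closed")
})

test_that("star filtration levels follow the threshold arithmetic", {
  g <- build_grid(20, 1, 1)
  co <- grid_coords(g)
  ramp <- new_field(g, co$x, "u")
  fc <- star_filtration(ramp, direction = "lower", n_levels = 20L)
  # vertex at x enters at level ceiling(x), except level 1 at x = 0
  expect_equal(fc$level_v, pmax(1, ceiling(co$x)))

  # upper-star of u equals lower-star of -u, level by level
  neg <- new_field(g, -co$x, "u")
  fc_up <- star_filtration(ramp, direction = "upper")
  fc_lo <- star_filtration(neg, direction = "lower")
  expect_identical(fc_up$level_v, fc_lo$level_v)
  expect_identical(fc_up$level_e, fc_lo$level_e)
  expect_identical(fc_up$level_t, fc_lo$level_t)

  # constant field: everything enters at level 1
  const <- new_field(g, rep(2, nrow(co)), "u")
  fcc <- star_filtration(const)
  expect_true(all(fcc$level_v == 1L))
  expect_true(all(fcc$level_t == 1L))
})

test_that("filtrations are nested: no face after its coface", {
  set.seed(4)
  g <- build_grid(6, 6, 1)
  f <- new_field(g, rnorm(49), "u")
  for (dir in c("lower", "upper")) {
    fc <- star_filtration(f, direction = dir)
    expect_true(all(fc$level_e >=
      pmax(fc$level_v[fc$complex$edges[, 1]], fc$level_v[fc$complex$edges[, 2]])))
    expect_true(all(fc$level_t >= pmax(
      fc$level_v[fc$complex$triangles[, 1]],
      fc$level_v[fc$complex$triangles[, 2]],
      fc$level_v[fc$complex$triangles[, 3]])))
  }
  # constructor rejects a broken nesting
  cx <- new_simplicial_complex(2, rbind(c(1, 2)))
  expect_error(filtered_complex(cx, c(2L, 2L), 1L, n_levels = 3L),
               "not nested")
})

test_that("the worked 2-simplex filtration yields the textbook barcodes", {
  cx <- new_simplicial_complex(3, rbind(c(1, 2), c(2, 3), c(1, 3)),
                               rbind(c(1, 2, 3)))
  fc <- filtered_complex(cx, level_v = c(1, 1, 2), level_e = c(1, 3, 3),
                         level_t = 4L, n_levels = 4L)
  bc <- compute_barcodes(fc)
  expect_equal(as.data.frame(bc$B0),
               data.frame(birth = c(1, 2), death = c(Inf, 3)),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(bc$B1),
               data.frame(birth = 3, death = 4), ignore_attr = TRUE)
})

test_that("a single vertex has one essential component and no loops", {
  cx <- new_simplicial_complex(1, matrix(integer(), 0, 2))
  fc <- filtered_complex(cx, 1L, integer(0), n_levels = 1L)
  bc <- compute_barcodes(fc)
  expect_equal(as.data.frame(bc$B0), data.frame(birth = 1, death = Inf),
               ignore_attr = TRUE)
  expect_equal(nrow(bc$B1), 0L)
})

test_that("reduction agrees with the rank-based oracle on random complexes", {
  set.seed(7)
  for (i in 1:30) {
    fc <- random_filtered_complex()
    bc <- compute_barcodes(fc, p = 2L)
    expect_true(diagram_equal(bc$B0, oracle_barcode(fc, 0L, 2L)))
    expect_true(diagram_equal(bc$B1, oracle_barcode(fc, 1L, 2L)))
  }
})

test_that("coefficients F_2 and F_11 agree on grid filtrations (no torsion)", {
  set.seed(8)
  g <- build_grid(8, 8, 1)
  f <- new_field(g, rnorm(81), "u")
  fc <- star_filtration(f)
  b2 <- compute_barcodes(fc, p = 2L)
  b11 <- compute_barcodes(fc, p = 11L)
  expect_true(diagram_equal(b2$B0, b11$B0))
  expect_true(diagram_equal(b2$B1, b11$B1))
})

test_that("one component survives to the final level on connected grids", {
  set.seed(9)
  g <- build_grid(10, 6, 1)
  f <- new_field(g, rnorm(77), "u")
  bc <- compute_barcodes(star_filtration(f))
  expect_equal(sum(is.infinite(bc$B0$death)), 1L)
  expect_equal(sum(is.infinite(bc$B1$death)), 0L) # disk: no essential loops
})

test_that("cleaning drops short bars but never essential ones", {
  d <- persistence_diagram(c(0, 3), c(20, 4), 0L)
  expect_equal(nrow(clean_barcode(d, 0)), 2L)
  cleaned <- clean_barcode(d, 5)
  expect_equal(as.data.frame(cleaned), data.frame(birth = 0, death = 20),
               ignore_attr = TRUE)
  dinf <- persistence_diagram(1, Inf, 0L)
  expect_equal(as.data.frame(clean_barcode(dinf, 100)),
               data.frame(birth = 1, death = Inf), ignore_attr = TRUE)
})

test_that("length histogram finds the valley of a bimodal density", {
  h <- length_histogram(c(1, 1, 1, 9, 10, 11))
  expect_true(h$cutoff > 1 && h$cutoff < 9)
  # unimodal lengths: no cutoff
  h2 <- length_histogram(c(5, 5.5, 6, 6.2, 7))
  expect_true(is.na(h2$cutoff))
  expect_error(length_histogram(numeric(0)), "at least one")
})
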