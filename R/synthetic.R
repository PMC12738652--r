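#' Synthetic pattern fields with known topological content
#'
#' Seeded generators of the three pattern archetypes built from the Neumann
#' cosine eigenfunctions of the rectangle, so persistence and clustering can
#' be exercised against analytically known topology without PDE runs:
#'
#' * `"spots"` — \eqn{A\cos(m\pi x/L_x)\cos(n\pi y/L_y)}, `m, n >= 1`;
#' * `"stripes"` — \eqn{A\cos(m\pi x/L_x)}, `m >= 1`;
#' * `"labyrinth"` — a seeded random-sign superposition of at least
#'   `min_modes` eigenfunctions whose \eqn{m^2 + n^2} lies in a narrow band
#'   around the requested magnitude, rescaled to amplitude `A` — mimicking
#'   the mode mixing of a degenerate unstable band without claiming PDE
#'   fidelity. Equal mode amplitudes (random signs only) keep the topological
#'   statistics of the family consistent across seeds, so the labyrinths form
#'   a coherent class for clustering tests.
#'
#' Ground truth is computed on the noiseless field by direct grid search:
#' for spots the number of strict local minima (8-neighbourhood) below the
#' mid-range \eqn{(\max + \min)/2}, for stripes and labyrinths the number of
#' connected components (4-neighbourhood) of the sub-mid-range set. Gaussian
#' noise of standard deviation `noise_sd` is added after the ground truth is
#' taken.
#'
#' @param kind `"spots"`, `"stripes"` or `"labyrinth"`.
#' @param grid an [build_grid()] object.
#' @param m,n mode indices (for `"labyrinth"`, the band is centred on
#'   `m^2 + n^2`).
#' @param amplitude positive scale (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer seed (labyrinth composition and noise).
#' @param min_modes minimum number of superposed modes for labyrinths.
#' @return list with `field` ([new_field()]), `ground_truth` (integer count)
#'   and `spec` (the arguments).
#' @export
make_pattern <- function(kind = c("spots", "stripes", "labyrinth"),
                         grid, m, n = 0L, amplitude = 1, noise_sd = 0,
                         seed = 1L, min_modes = 14L) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "rd_grid"), amplitude > 0, noise_sd >= 0)
  co <- grid_coords(grid)
  cosx <- function(mm) cos(mm * pi * co$x / grid$Lx)
  cosy <- function(nn) cos(nn * pi * co$y / grid$Ly)
  set.seed(as.integer(seed))

  base <- switch(kind,
    spots = {
      if (m < 1L || n < 1L) stop("spots require m >= 1 and n >= 1")
      amplitude * cosx(m) * cosy(n)
    },
    stripes = {
      if (m < 1L) stop("stripes require m >= 1")
      amplitude * cosx(m)
    },
    labyrinth = {
      target <- m^2 + n^2
      if (target < 1) stop("labyrinth requires a positive mode magnitude")
      band <- 0
      repeat {
        g <- expand.grid(mm = 0:(2 * (m + n) + 4), nn = 0:(2 * (m + n) + 4))
        g <- g[g$mm + g$nn > 0 & abs(g$mm^2 + g$nn^2 - target) <= band, ]
        if (nrow(g) >= min_modes) break
        band <- band + 1
      }
      w <- sample(c(-1, 1), nrow(g), replace = TRUE)
      f <- rep(0, nrow(co))
      for (i in seq_len(nrow(g))) f <- f + w[i] * cosx(g$mm[i]) * cosy(g$nn[i])
      amplitude * f / max(abs(f))
    })

  truth <- if (kind == "spots") count_strict_minima(base, grid)
           else count_submid_components(base, grid)
  values <- base + if (noise_sd > 0) stats::rnorm(length(base), 0, noise_sd)
                   else 0
  list(field = new_field(grid, values, "u"),
       ground_truth = truth,
       spec = list(kind = kind, m = m, n = n, amplitude = amplitude,
                   noise_sd = noise_sd, seed = seed))
}

# strict local minima below (max+min)/2, 8-neighbourhood, boundary-aware
count_strict_minima <- function(values, grid) {
  M <- matrix(values, grid$nx, grid$ny)
  mid <- (max(values) + min(values)) / 2
  nx <- grid$nx; ny <- grid$ny
  count <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    v <- M[ix, iy]
    if (v >= mid) next
    ok <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      jx <- ix + dx; jy <- iy + dy
      if (jx < 1 || jx > nx || jy < 1 || jy > ny) next
      if (M[jx, jy] <= v) ok <- FALSE
    }
    if (ok) count <- count + 1L
  }
  count
}

# connected components (4-neighbourhood) of {value < midrange}
count_submid_components <- function(values, grid) {
  nx <- grid$nx; ny <- grid$ny
  mid <- (max(values) + min(values)) / 2
  inset <- values < mid
  comp <- integer(length(values))
  nc <- 0L
  for (start in which(inset)) {
    if (comp[start] != 0L) next
    nc <- nc + 1L
    queue <- start
    comp[start] <- nc
    while (length(queue) > 0L) {
      i <- queue[[1L]]; queue <- queue[-1L]
      ix <- (i - 1L) %% nx + 1L; iy <- (i - 1L) %/% nx + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        jx <- ix + d[1L]; jy <- iy + d[2L]
        if (jx < 1L || jx > nx || jy < 1L || jy > ny) next
        j <- (jy - 1L) * nx + jx
        if (inset[j] && comp[j] == 0L) { comp[j] <- nc; queue <- c(queue, j) }
      }
    }
  }
  nc
}

#' Sup-norm-bounded perturbation of a field
#'
#' Adds seeded uniform noise on \eqn{[-\varepsilon, \varepsilon]}, so
#' \eqn{\|f - g\|_\infty \le \varepsilon} holds by construction — the exact
#' hypothesis of the diagram stability theorem.
#'
#' @param field an [new_field()] object.
#' @param eps nonnegative bound.
#' @param seed integer seed.
#' @return perturbed [new_field()].
#' @export
perturb_field <- function(field, eps, seed = 1L) {
  stopifnot(inherits(field, "rd_field"), eps >= 0)
  set.seed(as.integer(seed))
  noise <- stats::runif(length(field$values), -eps, eps)
  new_field(field$grid, field$values + noise, field$species)
}
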