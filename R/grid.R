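#' Rectangular Neumann grid
#'
#' A uniform vertex grid on the closed rectangle \eqn{[0,L_x]\times[0,L_y]}
#' with spacing `stepsize` along both axes. Vertices are stored row-major with
#' y as the outer index: vertex `(ix, iy)` (0-based) sits at
#' `(ix*stepsize, iy*stepsize)` and occupies position `iy*nx + ix + 1`.
#'
#' @param Lx,Ly positive side lengths.
#' @param stepsize positive spacing; `Lx/stepsize` and `Ly/stepsize` must be
#'   integers (to within 1e-9) — the grid is never silently remeshed.
#' @return object of class `rd_grid` with fields `Lx`, `Ly`, `stepsize`,
#'   `nx`, `ny`.
#' @examples
#' g <- build_grid(20, 20, 0.5) # 41 x 41 = 1681 vertices
#' @export
build_grid <- function(Lx, Ly, stepsize) {
  stopifnot(Lx > 0, Ly > 0, stepsize > 0)
  if (stepsize > min(Lx, Ly)) stop("stepsize must not exceed min(Lx, Ly)")
  rx <- Lx / stepsize; ry <- Ly / stepsize
  if (abs(rx - round(rx)) > 1e-9 || abs(ry - round(ry)) > 1e-9)
    stop("Lx and Ly must be integer multiples of stepsize")
  structure(list(Lx = Lx, Ly = Ly, stepsize = stepsize,
                 nx = as.integer(round(rx)) + 1L,
                 ny = as.integer(round(ry)) + 1L),
            class = "rd_grid")
}

#' @export
print.rd_grid <- function(x, ...) {
  cat(sprintf("<rd_grid> [0,%g]x[0,%g], stepsize %g, %d x %d = %d vertices\n",
              x$Lx, x$Ly, x$stepsize, x$nx, x$ny, x$nx * x$ny))
  invisible(x)
}

#' Vertex coordinates of a grid
#'
#' @param grid an [build_grid()] object.
#' @return data.frame with columns `x`, `y` in vertex storage order.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "rd_grid"))
  x <- (seq_len(grid$nx) - 1) * grid$stepsize
  y <- (seq_len(grid$ny) - 1) * grid$stepsize
  data.frame(x = rep(x, times = grid$ny), y = rep(y, each = grid$nx))
}

#' Scalar field on a grid
#'
#' @param grid an [build_grid()] object.
#' @param values numeric vector of length `nx*ny` in vertex storage order.
#' @param species tag, conventionally `"u"` or `"v"`.
#' @return object of class `rd_field`.
#' @export
new_field <- function(grid, values, species = "u") {
  stopifnot(inherits(grid, "rd_grid"),
            length(values) == grid$nx * grid$ny,
            all(is.finite(values)))
  structure(list(grid = grid, values = as.numeric(values),
                 species = species),
            class = "rd_field")
}

#' @export
print.rd_field <- function(x, ...) {
  cat(sprintf("<rd_field '%s'> %d x %d, range [%.4g, %.4g]\n",
              x$species, x$grid$nx, x$grid$ny,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Field values as a matrix
#'
#' @param field an [new_field()] object.
#' @return `nx` x `ny` matrix: `[ix, iy]` indexes x by row, y by column.
#' @export
field_matrix <- function(field) {
  stopifnot(inherits(field, "rd_field"))
  matrix(field$values, nrow = field$grid$nx, ncol = field$grid$ny)
}

#' Trapezoidal-rule mean of a field
#'
#' The domain integral of the mirrored-ghost Neumann discretisation is
#' conserved by pure diffusion under trapezoid quadrature (boundary vertices
#' weighted 1/2, corners 1/4), so this is the natural conserved "mean".
#'
#' @param field an [new_field()] object.
#' @return scalar weighted mean.
#' @export
field_mean <- function(field) {
  g <- field$grid
  wx <- c(0.5, rep(1, g$nx - 2L), 0.5)
  wy <- c(0.5, rep(1, g$ny - 2L), 0.5)
  w <- as.vector(outer(wx, wy))
  sum(w * field$values) / sum(w)
}
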