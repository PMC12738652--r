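#' Triangulate a rectangular grid
#'
#' Splits every grid cell along the same diagonal (lower-left to upper-right)
#' into two triangles, giving a simplicial complex whose vertices are the grid
#' vertices. The diagonal choice is a fixed, reproducible convention; the
#' resulting complex is a triangulated disk with Euler characteristic
#' \eqn{V - E + F = 1}.
#'
#' @param grid an [build_grid()] object.
#' @return object of class `simplicial_complex` with fields `n_vertices`,
#'   `edges` (2-column matrix of vertex indices, each row sorted increasing),
#'   `triangles` (3-column, sorted rows) and the `grid`.
#' @export
triangulate_grid <- function(grid) {
  stopifnot(inherits(grid, "rd_grid"))
  nx <- grid$nx; ny <- grid$ny
  vid <- function(ix, iy) (iy - 1L) * nx + ix   # 1-based grid indices

  ixh <- rep(seq_len(nx - 1L), times = ny); iyh <- rep(seq_len(ny), each = nx - 1L)
  h_edges <- cbind(vid(ixh, iyh), vid(ixh + 1L, iyh))
  ixv <- rep(seq_len(nx), times = ny - 1L); iyv <- rep(seq_len(ny - 1L), each = nx)
  v_edges <- cbind(vid(ixv, iyv), vid(ixv, iyv + 1L))
  ixd <- rep(seq_len(nx - 1L), times = ny - 1L)
  iyd <- rep(seq_len(ny - 1L), each = nx - 1L)
  d_edges <- cbind(vid(ixd, iyd), vid(ixd + 1L, iyd + 1L))

  # cell (ix, iy): lower triangle (ll, lr, ur), upper triangle (ll, ul, ur)
  ll <- vid(ixd, iyd); lr <- vid(ixd + 1L, iyd)
  ul <- vid(ixd, iyd + 1L); ur <- vid(ixd + 1L, iyd + 1L)
  tris <- rbind(cbind(ll, lr, ur), cbind(ll, ul, ur))
  tris <- t(apply(tris, 1L, sort))

  new_simplicial_complex(nx * ny, rbind(h_edges, v_edges, d_edges), tris,
                         grid = grid)
}

#' Construct a 2-dimensional simplicial complex
#'
#' @param n_vertices number of vertices (labelled `1..n_vertices`).
#' @param edges 2-column integer matrix; rows are sorted on construction.
#' @param triangles 3-column integer matrix (may have zero rows); every edge
#'   of every triangle must be present in `edges` (closure under faces).
#' @param grid optional originating [build_grid()] object.
#' @return object of class `simplicial_complex`.
#' @export
new_simplicial_complex <- function(n_vertices, edges,
                                   triangles = matrix(integer(), 0L, 3L),
                                   grid = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (nrow(edges) > 0L) edges <- t(apply(edges, 1L, sort))
  if (nrow(triangles) > 0L) triangles <- t(apply(triangles, 1L, sort))
  if (nrow(edges) != nrow(unique(edges))) stop("duplicate edges")
  ekey <- edge_key(edges[, 1L], edges[, 2L], n_vertices)
  if (nrow(triangles) > 0L) {
    faces <- rbind(cbind(triangles[, 1L], triangles[, 2L]),
                   cbind(triangles[, 1L], triangles[, 3L]),
                   cbind(triangles[, 2L], triangles[, 3L]))
    if (!all(edge_key(faces[, 1L], faces[, 2L], n_vertices) %in% ekey))
      stop("triangle face missing from edge set: complex not closed")
  }
  structure(list(n_vertices = as.integer(n_vertices), edges = edges,
                 triangles = triangles, grid = grid),
            class = "simplicial_complex")
}

edge_key <- function(a, b, n_vertices) (as.numeric(a) - 1) * n_vertices + b

#' @export
print.simplicial_complex <- function(x, ...) {
  cat(sprintf("<simplicial_complex> V=%d E=%d F=%d (chi=%d)\n",
              x$n_vertices, nrow(x$edges), nrow(x$triangles),
              x$n_vertices - nrow(x$edges) + nrow(x$triangles)))
  invisible(x)
}

#' Euler characteristic of a complex
#'
#' @param complex a [new_simplicial_complex()] object.
#' @return integer `V - E + F`.
#' @export
euler_characteristic <- function(complex) {
  complex$n_vertices - nrow(complex$edges) + nrow(complex$triangles)
}
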