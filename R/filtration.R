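#' Construct a filtered 2-D simplicial complex
#'
#' Assigns an integer filtration level in `1..n_levels` to every simplex.
#' The nesting (monotonicity) requirement — every face enters no later than
#' its cofaces — is validated at construction.
#'
#' @param complex a [new_simplicial_complex()] object.
#' @param level_v,level_e,level_t integer levels for vertices, edges,
#'   triangles.
#' @param n_levels number of filtration levels (default 20).
#' @param direction `"lower"` or `"upper"` (metadata).
#' @param species species tag (metadata).
#' @param thresholds optional numeric vector of length `n_levels` recording
#'   the field threshold at each level (used to convert bar endpoints back to
#'   field units for stability checks).
#' @return object of class `filtered_complex`.
#' @export
filtered_complex <- function(complex, level_v, level_e,
                             level_t = integer(0), n_levels = 20L,
                             direction = "lower", species = "u",
                             thresholds = NULL) {
  stopifnot(inherits(complex, "simplicial_complex"),
            length(level_v) == complex$n_vertices,
            length(level_e) == nrow(complex$edges),
            length(level_t) == nrow(complex$triangles))
  level_v <- as.integer(level_v); level_e <- as.integer(level_e)
  level_t <- as.integer(level_t)
  lv <- c(level_v, level_e, level_t)
  if (any(lv < 1L | lv > n_levels)) stop("levels must lie in 1..n_levels")
  if (nrow(complex$edges) > 0L) {
    vmax <- pmax(level_v[complex$edges[, 1L]], level_v[complex$edges[, 2L]])
    if (any(level_e < vmax)) stop("filtration not nested: edge before vertex")
  }
  if (nrow(complex$triangles) > 0L) {
    emax <- pmax(level_v[complex$triangles[, 1L]],
                 level_v[complex$triangles[, 2L]],
                 level_v[complex$triangles[, 3L]])
    if (any(level_t < emax)) stop("filtration not nested: triangle before vertex")
  }
  structure(list(complex = complex, level_v = level_v, level_e = level_e,
                 level_t = level_t, n_levels = as.integer(n_levels),
                 direction = direction, species = species,
                 thresholds = thresholds),
            class = "filtered_complex")
}

#' Star filtration of a field on a triangulated grid
#'
#' Builds the 20-level (by default) discrete approximation of the sublevel
#' (lower-star) or superlevel (upper-star) filtration of a vertex-valued
#' field. Level thresholds divide the field's range evenly:
#' \deqn{t_j = \min u + j\,(\max u - \min u)/n\quad\text{(lower)},\qquad
#'       t_j = \max u - j\,(\max u - \min u)/n\quad\text{(upper)},}
#' \eqn{j = 1..n}. A vertex enters at the smallest level whose threshold it
#' passes, and a higher simplex enters once all its vertices have (its level
#' is the maximum of its vertex levels). Because thresholds are tied to the
#' field's own min and max, the filtration normalises amplitude away and
#' diagrams from different parameter points are directly comparable. A
#' constant field (zero range) places every simplex at level 1.
#'
#' With `n_levels = "exact"` no quantisation is applied: each distinct vertex
#' value becomes its own level and the thresholds are the sorted values
#' themselves. This is the exact lower-/upper-star filtration of the
#' piecewise-linear field, the object for which the diagram stability theorem
#' holds verbatim in field units; the quantised 20-level form is the
#' amplitude-normalised summary used by the clustering pipeline.
#'
#' @param field an [new_field()] object.
#' @param complex triangulation of the field's grid (default
#'   [triangulate_grid()] of it).
#' @param direction `"lower"` or `"upper"`.
#' @param n_levels number of levels (default 20), or `"exact"`.
#' @return a [filtered_complex()].
#' @export
star_filtration <- function(field, complex = NULL,
                            direction = c("lower", "upper"),
                            n_levels = 20L) {
  direction <- match.arg(direction)
  exact <- identical(n_levels, "exact")
  stopifnot(inherits(field, "rd_field"), exact || n_levels >= 1L)
  if (is.null(complex)) complex <- triangulate_grid(field$grid)
  if (!is.null(complex$grid) && !identical(complex$grid, field$grid))
    stop("complex was built on a different grid")
  if (complex$n_vertices != length(field$values))
    stop("complex size does not match field")
  u <- field$values
  lo <- min(u); hi <- max(u); rng <- hi - lo
  if (exact) {
    key <- if (direction == "lower") u else -u
    thresholds <- sort(unique(key))
    level_v <- match(key, thresholds)
    if (direction == "upper") thresholds <- -thresholds
    n_levels <- length(thresholds)
  } else if (rng == 0) {
    level_v <- rep(1L, length(u))
    thresholds <- rep(lo, n_levels)
  } else {
    frac <- if (direction == "lower") (u - lo) / rng else (hi - u) / rng
    level_v <- pmin(n_levels, pmax(1L, as.integer(ceiling(frac * n_levels - 1e-9))))
    thresholds <- if (direction == "lower")
      lo + rng * seq_len(n_levels) / n_levels
    else hi - rng * seq_len(n_levels) / n_levels
  }
  level_e <- pmax(level_v[complex$edges[, 1L]], level_v[complex$edges[, 2L]])
  level_t <- if (nrow(complex$triangles) > 0L)
    pmax(level_v[complex$triangles[, 1L]],
         level_v[complex$triangles[, 2L]],
         level_v[complex$triangles[, 3L]])
  else integer(0)
  filtered_complex(complex, level_v, level_e, level_t, n_levels = n_levels,
                   direction = direction, species = field$species,
                   thresholds = thresholds)
}
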