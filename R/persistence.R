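#' Persistence diagram
#'
#' A multiset of (birth, death) pairs for a single homology degree, in
#' filtration-level units; `death = Inf` marks essential classes.
#'
#' @param birth,death numeric vectors; `birth <= death` elementwise.
#' @param degree homology degree (0 or 1).
#' @return data.frame of class `persistence_diagram` with columns `birth`,
#'   `death` and attribute `degree`.
#' @export
persistence_diagram <- function(birth = numeric(0), death = numeric(0),
                                degree = 0L) {
  stopifnot(length(birth) == length(death), all(birth <= death))
  d <- data.frame(birth = as.numeric(birth), death = as.numeric(death))
  o <- order(d$birth, d$death)
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  structure(d, degree = as.integer(degree),
            class = c("persistence_diagram", "data.frame"))
}

#' Barcodes of a filtered complex by boundary-matrix reduction
#'
#' Computes degree-0 and degree-1 persistent homology over the prime field
#' \eqn{\mathbb{F}_p} by the standard column-reduction of the level-sorted
#' boundary matrix. Simplices are ordered by (level, dimension, construction
#' index); a column that reduces to zero creates a class and an unreduced
#' column kills the class created by its pivot row. Bars are reported in
#' filtration-level units; pairs born and dying at the same level are dropped
#' (zero persistence); unpaired creators become essential bars with
#' `death = Inf`.
#'
#' @param fc a [filtered_complex()].
#' @param p prime characteristic of the coefficient field (default 2).
#' @return list with elements `B0` and `B1` ([persistence_diagram()]s).
#' @export
compute_barcodes <- function(fc, p = 2L) {
  stopifnot(inherits(fc, "filtered_complex"), p >= 2L)
  p <- as.integer(p)
  cx <- fc$complex
  nv <- cx$n_vertices; ne <- nrow(cx$edges); nt <- nrow(cx$triangles)
  n <- nv + ne + nt
  dim_s <- rep.int(c(0L, 1L, 2L), c(nv, ne, nt))
  level <- c(fc$level_v, fc$level_e, fc$level_t)
  ord <- order(level, dim_s, seq_len(n))
  pos <- integer(n); pos[ord] <- seq_len(n)

  # boundary-matrix entries (column in sorted position, row, F_p coefficient)
  ej <- integer(0); er <- integer(0); ec <- integer(0)
  if (ne > 0L) {
    j <- pos[nv + seq_len(ne)]
    ej <- c(j, j)
    er <- c(pos[cx$edges[, 1L]], pos[cx$edges[, 2L]])
    ec <- c(rep(p - 1L, ne), rep(1L, ne))       # [b] - [a]
  }
  if (nt > 0L) {
    ekey <- edge_key(cx$edges[, 1L], cx$edges[, 2L], nv)
    e_bd <- match(edge_key(cx$triangles[, 2L], cx$triangles[, 3L], nv), ekey)
    e_ad <- match(edge_key(cx$triangles[, 1L], cx$triangles[, 3L], nv), ekey)
    e_ab <- match(edge_key(cx$triangles[, 1L], cx$triangles[, 2L], nv), ekey)
    jt <- pos[nv + ne + seq_len(nt)]
    ej <- c(ej, jt, jt, jt)
    er <- c(er, pos[nv + e_bd], pos[nv + e_ad], pos[nv + e_ab])
    ec <- c(ec, rep(1L, nt), rep(p - 1L, nt), rep(1L, nt)) # [bd]-[ad]+[ab]
  }
  o <- order(ej, er)
  rows_flat <- er[o]; coef_flat <- ec[o]
  col_ptr <- c(0L, cumsum(tabulate(ej, nbins = n)))
  lows <- .reduce_boundary_cpp(n, col_ptr, rows_flat, coef_flat, p)

  level_sorted <- level[ord]; dim_sorted <- dim_s[ord]
  killed <- logical(n)
  neg <- which(lows > 0L)                       # columns that kill a class
  killed[lows[neg]] <- TRUE
  pair_ok <- level_sorted[neg] > level_sorted[lows[neg]]
  births <- level_sorted[lows[neg]][pair_ok]
  deaths <- level_sorted[neg][pair_ok]
  degs <- dim_sorted[lows[neg]][pair_ok]

  # essential classes: creators (zero columns) never killed
  ess <- which(!killed & lows == 0L)
  ess <- ess[dim_sorted[ess] <= 1L]
  births <- c(births, level_sorted[ess])
  deaths <- c(deaths, rep(Inf, length(ess)))
  degs <- c(degs, dim_sorted[ess])

  list(B0 = persistence_diagram(births[degs == 0L], deaths[degs == 0L], 0L),
       B1 = persistence_diagram(births[degs == 1L], deaths[degs == 1L], 1L))
}

#' Remove short bars from a persistence diagram
#'
#' Keeps bars whose length `death - birth` is at least `min_length`; infinite
#' bars are always kept. The stability theorem licenses reading short bars as
#' noise, so this is the denoising step applied before distances are taken.
#'
#' @param diag a [persistence_diagram()].
#' @param min_length nonnegative cutoff in filtration-level units.
#' @return a [persistence_diagram()].
#' @export
clean_barcode <- function(diag, min_length) {
  stopifnot(inherits(diag, "persistence_diagram"), min_length >= 0)
  keep <- is.infinite(diag$death) | (diag$death - diag$birth >= min_length)
  persistence_diagram(diag$birth[keep], diag$death[keep],
                      attr(diag, "degree"))
}

#' Histogram of finite bar lengths with a suggested noise cutoff
#'
#' Pools the finite bar lengths of one barcode channel across nodes, smooths
#' their density, and — when the density is multimodal — proposes the valley
#' (argmin) between the two lowest-length modes as the cleaning cutoff. A
#' unimodal density yields no cutoff.
#'
#' @param lengths numeric vector of finite bar lengths (or a list of
#'   [persistence_diagram()]s, from which finite lengths are pooled).
#' @param bw density bandwidth passed to [stats::density()] (default
#'   `"nrd0"`).
#' @return list with `lengths`, the `density` object, and `cutoff` (numeric or
#'   `NA` when unimodal).
#' @export
length_histogram <- function(lengths, bw = "nrd0") {
  if (is.list(lengths) && !is.numeric(lengths)) {
    lengths <- unlist(lapply(lengths, function(d) {
      fin <- is.finite(d$death)
      d$death[fin] - d$birth[fin]
    }))
  }
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) < 1L) stop("need at least one finite bar")
  if (length(unique(lengths)) == 1L)
    return(list(lengths = lengths, density = NULL, cutoff = NA_real_))
  den <- stats::density(lengths, bw = bw)
  y <- den$y
  # interior local maxima of the smoothed density
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2L)
    return(list(lengths = lengths, density = den, cutoff = NA_real_))
  m <- sort(is_max[order(den$x[is_max])][1:2])
  valley <- m[1] + which.min(y[m[1]:m[2]]) - 1L
  list(lengths = lengths, density = den, cutoff = den$x[valley])
}
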