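#' q-Wasserstein distance between persistence diagrams
#'
#' Optimal-matching distance in which any point may be matched to the diagonal
#' \eqn{\Delta}. Point-to-point cost is the \eqn{\ell_p} norm of the
#' difference, point-to-diagonal cost the \eqn{\ell_p} distance to the nearest
#' diagonal point, \eqn{(d-b)\,2^{1/p - 1}}. With the convention
#' \eqn{\infty - \infty = 0}, bars with infinite death match only each other
#' (at cost equal to their birth difference); diagrams with different numbers
#' of infinite bars are infinitely far apart. `q = Inf` gives the bottleneck
#' distance. Finite diagrams are solved exactly: the finite part by
#' minimum-cost assignment on the diagonal-augmented bipartite problem, the
#' infinite part by sorted matching of births (optimal in one dimension); for
#' `q = Inf` the assignment is replaced by a feasibility binary search over
#' candidate costs.
#'
#' @param d1,d2 [persistence_diagram()]s (or data.frames with `birth`,
#'   `death`).
#' @param p ground-metric exponent in `[1, Inf]` (default 2).
#' @param q outer exponent in `[1, Inf]` (default 2).
#' @return nonnegative number (possibly `Inf`).
#' @export
wasserstein_distance <- function(d1, d2, p = 2, q = 2) {
  stopifnot(p >= 1, q >= 1)
  b1 <- d1$birth; e1 <- d1$death
  b2 <- d2$birth; e2 <- d2$death
  i1 <- is.infinite(e1); i2 <- is.infinite(e2)
  if (sum(i1) != sum(i2)) return(Inf)

  # infinite bars: sorted matching of births; cost |db| (infinite coords cancel)
  inf_costs <- if (any(i1)) abs(sort(b1[i1]) - sort(b2[i2])) else numeric(0)

  x <- cbind(b1[!i1], e1[!i1]); y <- cbind(b2[!i2], e2[!i2])
  n <- nrow(x); m <- nrow(y)

  lp <- function(db, dd) {
    if (is.infinite(p)) pmax(abs(db), abs(dd)) else
      (abs(db)^p + abs(dd)^p)^(1 / p)
  }
  diag_cost <- function(pts) {
    if (nrow(pts) == 0L) return(numeric(0))
    (pts[, 2L] - pts[, 1L]) * if (is.infinite(p)) 0.5 else 2^(1 / p - 1)
  }

  if (n == 0L && m == 0L) {
    return(if (is.infinite(q)) max(0, inf_costs) else
             sum(inf_costs^q)^(1 / q))
  }

  N <- n + m
  C <- matrix(0, N, N)
  if (n > 0L && m > 0L)
    C[seq_len(n), seq_len(m)] <- outer(seq_len(n), seq_len(m),
      function(i, j) lp(x[i, 1L] - y[j, 1L], x[i, 2L] - y[j, 2L]))
  big <- Inf
  if (n > 0L) {
    C[seq_len(n), m + seq_len(n)] <- big
    C[cbind(seq_len(n), m + seq_len(n))] <- diag_cost(x)
  }
  if (m > 0L) {
    C[n + seq_len(m), seq_len(m)] <- big
    C[cbind(n + seq_len(m), seq_len(m))] <- diag_cost(y)
  }

  if (is.infinite(q)) {
    finite_part <- bottleneck_value(C)
    return(max(finite_part, if (length(inf_costs)) max(inf_costs) else 0))
  }

  Cq <- C^q
  finite_max <- max(Cq[is.finite(Cq)], 1)
  Cq[!is.finite(Cq)] <- finite_max * N * 2 + 1
  res <- .solve_assignment_cpp(Cq)
  (res$cost + sum(inf_costs^q))^(1 / q)
}

# smallest threshold t for which a perfect matching using edges of cost <= t
# exists; candidates are the matrix entries themselves
bottleneck_value <- function(C) {
  cand <- sort(unique(as.vector(C[is.finite(C)])))
  lo <- 1L; hi <- length(cand)
  if (.bottleneck_feasible_cpp(C, cand[lo])) return(cand[lo])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (.bottleneck_feasible_cpp(C, cand[mid])) hi <- mid else lo <- mid
  }
  cand[hi]
}

#' Bottleneck distance between persistence diagrams
#'
#' Shorthand for [wasserstein_distance()] with `p = Inf, q = Inf`, the metric
#' in which the diagram stability theorem is stated: perturbing the input
#' field by at most \eqn{\varepsilon} in sup-norm moves the diagram by at most
#' \eqn{\varepsilon} in bottleneck distance.
#'
#' @inheritParams wasserstein_distance
#' @return nonnegative number (possibly `Inf`).
#' @export
bottleneck_distance <- function(d1, d2) wasserstein_distance(d1, d2, Inf, Inf)

#' Convert a level-unit diagram to field-threshold units
#'
#' Bars produced by [compute_barcodes()] are indexed by filtration level.
#' Stability statements compare diagrams in the units of the field, so this
#' maps each finite endpoint level \eqn{j} to its threshold \eqn{t_j}
#' (recorded by [star_filtration()]).
#'
#' @param diag a [persistence_diagram()] in level units.
#' @param fc the [filtered_complex()] the diagram came from (must carry
#'   thresholds).
#' @return a [persistence_diagram()] in field units.
#' @export
diagram_in_field_units <- function(diag, fc) {
  stopifnot(inherits(fc, "filtered_complex"), !is.null(fc$thresholds))
  thr <- fc$thresholds
  conv <- function(lv) ifelse(is.infinite(lv), Inf, thr[pmin(lv, length(thr))])
  # upper-star thresholds decrease with level; flip sign so birth <= death
  s <- if (fc$direction == "upper") -1 else 1
  persistence_diagram(s * conv(diag$birth),
                      ifelse(is.infinite(diag$death), Inf,
                             s * conv(diag$death)),
                      attr(diag, "degree"))
}
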