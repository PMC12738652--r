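# Independent oracles used to validate the persistence and Wasserstein
# implementations. These deliberately share no code with the package: ranks of
# boundary operators over F_p via Gaussian elimination, and exhaustive
# enumeration of diagram matchings.

# rank of an integer matrix over F_p
rank_mod_p <- function(M, p) {
  if (length(M) == 0L || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- M %% p
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] != 0 & seq_len(nrow(M)) > r)
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    inv <- which((M[r, j] * 1:(p - 1)) %% p == 1)[1L]
    M[r, ] <- (M[r, ] * inv) %% p
    for (i in seq_len(nrow(M))) {
      if (i != r && M[i, j] != 0)
        M[i, ] <- (M[i, ] - M[i, j] * M[r, ]) %% p
    }
  }
  r
}

# kernel basis (columns) of an integer matrix over F_p
kernel_mod_p <- function(M, p) {
  n <- ncol(M)
  if (n == 0L) return(matrix(0L, max(nrow(M), 0L), 0L))
  if (nrow(M) == 0L) return(diag(1L, n))
  A <- M %% p
  pivots <- integer(0)
  r <- 0L
  for (j in seq_len(n)) {
    piv <- which(A[, j] != 0 & seq_len(nrow(A)) > r)
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1L] != r) A[c(r, piv[1L]), ] <- A[c(piv[1L], r), ]
    inv <- which((A[r, j] * 1:(p - 1)) %% p == 1)[1L]
    A[r, ] <- (A[r, ] * inv) %% p
    for (i in seq_len(nrow(A))) {
      if (i != r && A[i, j] != 0) A[i, ] <- (A[i, ] - A[i, j] * A[r, ]) %% p
    }
    pivots <- c(pivots, j)
  }
  free <- setdiff(seq_len(n), pivots)
  K <- matrix(0L, n, length(free))
  for (fidx in seq_along(free)) {
    f <- free[fidx]
    K[f, fidx] <- 1L
    for (ridx in seq_along(pivots)) {
      K[pivots[ridx], fidx] <- (-A[ridx, f]) %% p
    }
  }
  K
}

# full boundary matrices of a filtered complex (ambient: all simplices)
oracle_boundaries <- function(fc) {
  cx <- fc$complex
  nv <- cx$n_vertices; ne <- nrow(cx$edges); nt <- nrow(cx$triangles)
  d1 <- matrix(0L, nv, ne)
  for (e in seq_len(ne)) {
    d1[cx$edges[e, 1L], e] <- -1L
    d1[cx$edges[e, 2L], e] <- 1L
  }
  d2 <- matrix(0L, max(ne, 1L), nt)
  if (nt > 0L) {
    ekey <- paste(cx$edges[, 1L], cx$edges[, 2L])
    for (tr in seq_len(nt)) {
      a <- cx$triangles[tr, 1L]; b <- cx$triangles[tr, 2L]
      d <- cx$triangles[tr, 3L]
      d2[match(paste(b, d), ekey), tr] <- 1L
      d2[match(paste(a, d), ekey), tr] <- -1L
      d2[match(paste(a, b), ekey), tr] <- 1L
    }
  }
  list(d1 = d1, d2 = d2)
}

# persistent Betti number dim im(H_k(F_i) -> H_k(F_j)) via ranks
oracle_persistent_betti <- function(fc, k, i, j, p) {
  cx <- fc$complex
  bd <- oracle_boundaries(fc)
  if (k == 0L) {
    vin <- which(fc$level_v <= i)
    if (length(vin) == 0L) return(0L)
    # cycles: every vertex chain; embed as indicator basis
    Z <- diag(1L, cx$n_vertices)[, vin, drop = FALSE]
    Bcols <- bd$d1[, fc$level_e <= j, drop = FALSE]
  } else if (k == 1L) {
    ein <- which(fc$level_e <= i)
    if (length(ein) == 0L) return(0L)
    # cycles supported on F_i: kernel of d1 restricted to edges of F_i
    K <- kernel_mod_p(bd$d1[, ein, drop = FALSE], p)
    if (ncol(K) == 0L) return(0L)
    Z <- matrix(0L, max(nrow(cx$edges), 1L), ncol(K))
    Z[ein, ] <- K
    Bcols <- bd$d2[, fc$level_t <= j, drop = FALSE]
  } else stop("degree 0 or 1 only")
  rb <- rank_mod_p(Bcols, p)
  rank_mod_p(cbind(Z, Bcols), p) - rb
}

# full barcode of a filtered complex from persistent Betti numbers
# (inclusion-exclusion of ranks); independent of the reduction algorithm
oracle_barcode <- function(fc, k, p = 2L) {
  L <- fc$n_levels
  r <- matrix(0L, L + 1L, L + 1L) # r[i+1, j+1] = betti(i, j); index 1 = level 0
  for (i in seq_len(L)) for (j in i:L)
    r[i + 1L, j + 1L] <- oracle_persistent_betti(fc, k, i, j, p)
  births <- numeric(0); deaths <- numeric(0)
  for (b in seq_len(L)) {
    for (d in seq.int(b + 1L, L + 1L)) {
      if (d > L) break
      mu <- (r[b + 1L, d] - r[b + 1L, d + 1L]) -
            (r[b, d] - r[b, d + 1L])
      if (mu > 0L) { births <- c(births, rep(b, mu)); deaths <- c(deaths, rep(d, mu)) }
    }
    mu_inf <- r[b + 1L, L + 1L] - r[b, L + 1L]
    if (mu_inf > 0L) {
      births <- c(births, rep(b, mu_inf))
      deaths <- c(deaths, rep(Inf, mu_inf))
    }
  }
  persistence_diagram(births, deaths, k)
}

# random valid filtered 2-complex on up to max_v vertices
random_filtered_complex <- function(max_v = 8L, n_levels = 6L) {
  nv <- sample(3:max_v, 1L)
  pairs <- t(combn(nv, 2L))
  pairs <- pairs[stats::runif(nrow(pairs)) < 0.5, , drop = FALSE]
  ekey <- paste(pairs[, 1L], pairs[, 2L])
  tris <- if (nv >= 3L) t(combn(nv, 3L)) else matrix(integer(), 0L, 3L)
  has_all <- apply(tris, 1L, function(t3)
    all(paste(c(t3[1L], t3[1L], t3[2L]), c(t3[2L], t3[3L], t3[3L])) %in% ekey))
  tris <- tris[has_all & stats::runif(nrow(tris)) < 0.6, , drop = FALSE]
  cx <- new_simplicial_complex(nv, pairs, tris)
  lv <- sample.int(max(n_levels - 2L, 1L), nv, replace = TRUE)
  le <- pmin(n_levels, pmax(lv[cx$edges[, 1L]], lv[cx$edges[, 2L]]) +
               sample(0:2, nrow(cx$edges), replace = TRUE))
  lt <- if (nrow(cx$triangles) > 0L) {
    emax <- pmax(lv[cx$triangles[, 1L]], lv[cx$triangles[, 2L]],
                 lv[cx$triangles[, 3L]])
    ekey2 <- paste(cx$edges[, 1L], cx$edges[, 2L])
    et <- function(a, b) le[match(paste(a, b), ekey2)]
    emax2 <- pmax(et(cx$triangles[, 1L], cx$triangles[, 2L]),
                  et(cx$triangles[, 1L], cx$triangles[, 3L]),
                  et(cx$triangles[, 2L], cx$triangles[, 3L]))
    pmin(n_levels, emax2 + sample(0:2, nrow(cx$triangles), replace = TRUE))
  } else integer(0)
  filtered_complex(cx, lv, le, lt, n_levels = n_levels)
}

# exhaustive-matching Wasserstein oracle for small finite diagrams
oracle_wasserstein <- function(d1, d2, p, q) {
  x <- cbind(d1$birth, d1$death); y <- cbind(d2$birth, d2$death)
  n <- nrow(x); m <- nrow(y)
  lp <- function(a, b) if (is.infinite(p)) max(abs(a), abs(b)) else
    (abs(a)^p + abs(b)^p)^(1 / p)
  dcost <- function(pt) (pt[2] - pt[1]) * if (is.infinite(p)) 0.5 else 2^(1 / p - 1)
  agg <- function(costs) if (is.infinite(q)) max(c(costs, 0)) else
    sum(costs^q)^(1 / q)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (k in 0:min(n, m)) {
    s1 <- if (k == 0L) list(integer(0)) else
      asplit(combn(n, k), 2L)
    s2 <- if (k == 0L) list(integer(0)) else
      asplit(combn(m, k), 2L)
    for (a in s1) for (b in s2) {
      for (pb in perms(as.integer(b))) {
        costs <- c(
          if (k > 0L) mapply(function(i, j) lp(x[i, 1] - y[j, 1],
                                               x[i, 2] - y[j, 2]),
                             as.integer(a), pb),
          if (n - k > 0L) apply(x[setdiff(seq_len(n), a), , drop = FALSE],
                                1L, dcost),
          if (m - k > 0L) apply(y[setdiff(seq_len(m), b), , drop = FALSE],
                                1L, dcost))
        best <- min(best, agg(costs))
      }
    }
  }
  if (n == 0L && m == 0L) best <- 0
  best
}

# random small finite diagram
random_diagram <- function(max_pts = 4L) {
  n <- sample(0:max_pts, 1L)
  b <- round(stats::runif(n, 0, 5), 2)
  d <- b + round(stats::runif(n, 0.1, 5), 2)
  persistence_diagram(b, d, 0L)
}

# barcode set from a synthetic field via lower/upper star filtrations
field_barcode_set <- function(field, id, cleaned = TRUE, n_levels = 20L) {
  lo <- compute_barcodes(star_filtration(field, direction = "lower",
                                         n_levels = n_levels))
  up <- compute_barcodes(star_filtration(field, direction = "upper",
                                         n_levels = n_levels))
  bs <- barcode_set(id, B0u = lo$B0, B1u = lo$B1, B0v = up$B0, B1v = up$B1)
  if (cleaned) clean_barcode_set(bs) else bs
}

diagram_equal <- function(a, b) {
  nrow(a) == nrow(b) &&
    isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                     check.attributes = FALSE))
}
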