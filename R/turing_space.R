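#' Feasible beta interval for the CIMA Turing conditions
#'
#' At fixed \eqn{(\alpha, \sigma, \delta)} the CIMA Turing conditions are
#' monotone or quadratic in \eqn{\beta}: C2 holds for every \eqn{\beta > 0}
#' (its coefficient is \eqn{25\alpha\sigma/(\alpha^2+25) > 0}), C1 gives the
#' lower bound \eqn{\beta > (3\alpha^2-125)/(5\alpha\sigma)} and C3 the upper
#' bound \eqn{\beta < \delta(3\alpha^2-125)/(5\alpha)}, which is nonempty only
#' for \eqn{f_u > 0} (\eqn{\alpha^2 > 125/3}). C4 must still be checked inside
#' the interval.
#'
#' @param alpha,sigma,delta CIMA parameters (vectorised over `alpha`/`sigma`).
#' @return list with vectors `lo` and `hi`; `lo >= hi` signals an empty
#'   interval.
#' @keywords internal
cima_beta_bounds <- function(alpha, sigma, delta) {
  num <- 3 * alpha^2 - 125
  lo <- pmax(0, num / (5 * alpha * sigma))
  hi <- ifelse(num > 0, delta * num / (5 * alpha), 0)
  n <- max(length(lo), length(hi))
  list(lo = rep_len(lo, n), hi = rep_len(hi, n))
}

#' Unstable mode of largest wavenumber over a restricted Turing space
#'
#' Scans the rectangle of \eqn{(\alpha, \sigma)} values (at fixed
#' \eqn{\delta}), and at each point scans \eqn{\beta} over its Turing-feasible
#' range, collecting the band \eqn{(k^2_-, k^2_+)} of unstable squared
#' wavenumbers wherever all four Turing conditions hold. Returns the Neumann
#' mode \eqn{(m, n)} on the \eqn{L_x \times L_y} rectangle whose \eqn{k^2} is
#' the largest attained by any unstable mode anywhere in the scan; this mode
#' sets the minimal unstable wavelength, and hence the mesh bound of
#' [nyquist_stepsize()]. Ties between index pairs with equal \eqn{k^2} are
#' broken towards \eqn{m \ge n}, then the larger `m`.
#'
#' @param model currently `"cima"` only.
#' @param alpha_range,sigma_range numeric length-2 bounds.
#' @param delta fixed diffusivity ratio.
#' @param Lx,Ly domain side lengths.
#' @param alpha_step,sigma_step,beta_step scan resolutions.
#' @param max_index largest mode index enumerated per axis; an error is raised
#'   if the unstable band ever extends beyond the enumerated wavenumbers.
#' @return list with `m`, `n`, `k2` and `k2_plus_max`, the largest band edge
#'   seen.
#' @export
max_unstable_wavenumber <- function(model = "cima",
                                    alpha_range = c(0, 20),
                                    sigma_range = c(1, 20),
                                    delta = 1.5,
                                    Lx = 20, Ly = 20,
                                    alpha_step = 0.1, sigma_step = 0.1,
                                    beta_step = 0.01,
                                    max_index = 20L) {
  model <- match.arg(tolower(model), "cima")
  stopifnot(alpha_range[1] <= alpha_range[2], sigma_range[1] <= sigma_range[2])

  # lattice of enumerable squared wavenumbers with representative index pairs
  g <- expand.grid(m = 0:max_index, n = 0:max_index)
  g <- g[g$m + g$n > 0L & g$m >= g$n, , drop = FALSE]
  g$k2 <- pi^2 * (g$m^2 / Lx^2 + g$n^2 / Ly^2)
  g <- g[order(g$k2, -g$m), ]
  g <- g[!duplicated(round(g$k2, 12)), ]
  lat_k2 <- g$k2
  k2_cap <- pi^2 * max_index^2 * (1 / Lx^2 + 1 / Ly^2)

  alphas <- seq(alpha_range[1], alpha_range[2], by = alpha_step)
  sigmas <- seq(sigma_range[1], sigma_range[2], by = sigma_step)
  best_k2 <- -Inf
  k2p_max <- -Inf
  any_feasible <- FALSE

  for (al in alphas) {
    if (al <= 0 || 3 * al^2 - 125 <= 0) next   # C3 requires f_u > 0
    A <- al^2 + 25
    f_u <- (3 * al^2 - 125) / A
    f_v <- -20 * al / A
    bb <- cima_beta_bounds(al, sigmas, delta)
    hi <- max(bb$hi)
    if (hi <= beta_step) next
    betas <- seq(beta_step, hi, by = beta_step)
    grid <- expand.grid(sigma = sigmas, beta = betas)
    lo_s <- bb$lo[match(grid$sigma, sigmas)]
    keep <- grid$beta > lo_s & grid$beta < bb$hi[match(grid$sigma, sigmas)]
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0L) next
    s <- grid$sigma; be <- grid$beta
    g_u <- 2 * al^2 * be * s / A
    g_v <- -5 * al * be * s / A
    dv <- delta * s
    det0 <- f_u * g_v - f_v * g_u
    cross <- dv * f_u + g_v
    c1 <- f_u + g_v < 0
    c4 <- cross^2 - 4 * dv * det0
    ok <- c1 & cross > 0 & c4 > 0 & det0 > 0
    if (!any(ok)) next
    any_feasible <- TRUE
    r <- sqrt(c4[ok])
    k2m <- (cross[ok] - r) / (2 * dv[ok])
    k2p <- (cross[ok] + r) / (2 * dv[ok])
    k2p_max <- max(k2p_max, max(k2p))
    idx <- findInterval(k2p * (1 - 1e-12), lat_k2)
    valid <- idx >= 1L
    valid[valid] <- lat_k2[idx[valid]] > k2m[valid]
    if (any(valid)) best_k2 <- max(best_k2, lat_k2[idx[valid]])
  }

  if (!any_feasible)
    stop("bounds contain no point of the Turing space")
  if (k2p_max > k2_cap)
    stop("max_index too small: unstable band extends beyond enumerated modes")
  if (!is.finite(best_k2))
    stop("no unstable Neumann mode found in the scanned region")
  i <- which.min(abs(lat_k2 - best_k2))
  list(m = g$m[i], n = g$n[i], k2 = lat_k2[i], k2_plus_max = k2p_max)
}

#' Upper bound on the mesh stepsize from the minimal unstable wavelength
#'
#' A mesh must resolve the finest unstable pattern: by the sampling-theorem
#' heuristic, the simplex diameter should not exceed half the minimal unstable
#' wavelength. For the Neumann cosine mode \eqn{(m, n)} the half-period along
#' x is \eqn{L_x/m} (and \eqn{L_y/n} along y), so the bound is
#' \eqn{\tfrac{1}{2}\min(L_x/m, L_y/n)}, zero indices excluded.
#'
#' @param m,n mode indices (nonnegative integers, not both zero), e.g. from
#'   [max_unstable_wavenumber()].
#' @param Lx,Ly domain side lengths.
#' @return upper bound on the grid stepsize.
#' @export
nyquist_stepsize <- function(m, n, Lx, Ly) {
  stopifnot(m >= 0, n >= 0)
  if (m == 0 && n == 0) stop("mode indices must not both be zero")
  cand <- c(if (m > 0) Lx / m, if (n > 0) Ly / n)
  min(cand) / 2
}

#' Sweep a parameter grid and tabulate Turing-space membership
#'
#' Evaluates the Turing conditions, unstable-mode count and dominant mode over
#' a rectangular grid of parameter values for either model. Intended for
#' mapping the Turing space and for CSV export via [write_sweep_csv()].
#'
#' @param model `"cima"` or `"schnakenberg"`.
#' @param alpha,beta numeric vectors of grid values.
#' @param delta,sigma scalars.
#' @param Lx,Ly domain side lengths.
#' @param max_index mode enumeration bound.
#' @return data.frame with columns `alpha`, `beta`, `sigma`, `delta`,
#'   `in_space`, `n_unstable`, `m_star`, `n_star`, `gap_percent`.
#' @export
turing_space_sweep <- function(model, alpha, beta, delta, sigma = 1,
                               Lx = 20, Ly = 20, max_index = 10L) {
  grid <- expand.grid(alpha = alpha, beta = beta)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- model_params(model, alpha = grid$alpha[i], beta = grid$beta[i],
                      delta = delta, sigma = sigma)
    lin <- linearise(p)
    tc <- turing_conditions(lin)
    row <- data.frame(alpha = p$alpha, beta = p$beta, sigma = p$sigma,
                      delta = p$delta, in_space = unname(tc["in_space"]),
                      n_unstable = 0L, m_star = NA_integer_,
                      n_star = NA_integer_, gap_percent = NA_real_)
    if (tc[["in_space"]]) {
      modes <- enumerate_modes(lin, Lx, Ly, max_index)
      row$n_unstable <- sum(modes$unstable)
      if (row$n_unstable > 0L) {
        dm <- dominant_mode(lin, Lx, Ly, max_index)
        row$m_star <- dm$m; row$n_star <- dm$n
        row$gap_percent <- dm$gap_percent
      }
    }
    row
  })
  do.call(rbind, out)
}
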