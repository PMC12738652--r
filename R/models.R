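#' Model parameters for a two-species Turing system
#'
#' Constructs the nondimensional parameter set for one of the two built-in
#' reaction-diffusion models:
#'
#' * `"cima"` — the Lengyel–Epstein model of the chlorite–iodide–malonic acid
#'   reaction,
#'   \deqn{u_\tau = \nabla^2 u + \alpha - u - 4uv/(1+u^2),\quad
#'         v_\tau = \sigma(\delta \nabla^2 v + \beta u - \beta u v/(1+u^2)),}
#'   where \eqn{\alpha} is the nondimensional iodide feed, \eqn{\delta} the
#'   diffusivity ratio and \eqn{\sigma} scales with the starch concentration.
#' * `"schnakenberg"` — the prototypical autocatalytic model
#'   \deqn{u_\tau = \nabla^2 u + \alpha - u + u^2 v,\quad
#'         v_\tau = \delta \nabla^2 v + \beta - u^2 v.}
#'   `sigma` is not part of this model and is pinned to 1.
#'
#' @param model one of `"cima"`, `"schnakenberg"` (case-insensitive).
#' @param alpha nonnegative feed parameter.
#' @param beta positive kinetic parameter.
#' @param delta positive diffusivity ratio \eqn{D_v / D_u}.
#' @param sigma positive starch factor (CIMA only; forced to 1 otherwise).
#' @return an object of class `model_params`.
#' @examples
#' model_params("cima", alpha = 10, beta = 0.3, delta = 1.5, sigma = 20)
#' @export
model_params <- function(model = c("cima", "schnakenberg"),
                         alpha, beta, delta, sigma = 1) {
  model <- match.arg(tolower(model), c("cima", "schnakenberg"))
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (beta <= 0 || delta <= 0 || sigma <= 0)
    stop("`beta`, `delta` and `sigma` must be > 0")
  if (model == "schnakenberg") sigma <- 1
  structure(list(model = model, alpha = alpha, beta = beta,
                 delta = delta, sigma = sigma),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<%s> alpha=%g beta=%g delta=%g sigma=%g\n",
              x$model, x$alpha, x$beta, x$delta, x$sigma))
  invisible(x)
}

#' Reaction kinetics evaluated pointwise
#'
#' Returns the reaction terms \eqn{(f, g)} of the chosen model at concentration
#' values `u`, `v` (vectorised). For CIMA the printed \eqn{\sigma} prefactor on
#' the inhibitor equation is folded into `g`.
#'
#' @param params a [model_params()] object.
#' @param u,v numeric vectors of equal length.
#' @return list with components `f` and `g`.
#' @export
kinetics <- function(params, u, v) {
  stopifnot(inherits(params, "model_params"))
  a <- params$alpha; b <- params$beta; s <- params$sigma
  if (params$model == "cima") {
    list(f = a - u - 4 * u * v / (1 + u^2),
         g = s * (b * u - b * u * v / (1 + u^2)))
  } else {
    list(f = a - u + u^2 * v,
         g = b - u^2 * v)
  }
}

#' Spatially uniform steady state
#'
#' CIMA has the closed form \eqn{(u_s, v_s) = (\alpha/5,\; 1 + \alpha^2/25)};
#' Schnakenberg has \eqn{(u_s, v_s) = (\alpha + \beta,\; \beta/(\alpha+\beta)^2)}
#' (the unique positive root of its kinetics).
#'
#' @param params a [model_params()] object.
#' @return named numeric vector `c(u = u_s, v = v_s)`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "model_params"))
  ss <- if (params$model == "cima") {
    c(u = params$alpha / 5, v = 1 + params$alpha^2 / 25)
  } else {
    us <- params$alpha + params$beta
    if (us <= 0) stop("Schnakenberg steady state requires alpha + beta > 0")
    c(u = us, v = params$beta / us^2)
  }
  if (any(ss < 0)) stop("nonpositive steady state: invalid parameters")
  kin <- kinetics(params, ss[["u"]], ss[["v"]])
  scale <- max(1, abs(ss))
  if (max(abs(c(kin$f, kin$g))) > 1e-12 * scale)
    stop("steady-state residual exceeds tolerance")
  ss
}

#' Linearisation at the uniform steady state
#'
#' Jacobian entries of the (diffusionless) kinetics at the steady state,
#' together with the effective diffusivities of the two species. For CIMA the
#' entries equal
#' \deqn{\frac{1}{\alpha^2+25}
#'   \begin{pmatrix} 3\alpha^2-125 & -20\alpha \\
#'                   2\alpha^2\beta\sigma & -5\alpha\beta\sigma \end{pmatrix}}
#' with \eqn{d_u = 1}, \eqn{d_v = \sigma\delta}; for Schnakenberg the entries
#' are the partial derivatives of its kinetics with \eqn{d_u = 1},
#' \eqn{d_v = \delta}.
#'
#' @param params a [model_params()] object.
#' @return an object of class `linearised_system` with fields `f_u`, `f_v`,
#'   `g_u`, `g_v`, `d_u`, `d_v` and the originating `params`.
#' @export
linearise <- function(params) {
  stopifnot(inherits(params, "model_params"))
  a <- params$alpha; b <- params$beta; s <- params$sigma
  if (params$model == "cima") {
    A <- a^2 + 25
    lin <- list(f_u = (3 * a^2 - 125) / A,
                f_v = -20 * a / A,
                g_u = 2 * a^2 * b * s / A,
                g_v = -5 * a * b * s / A,
                d_u = 1, d_v = s * params$delta)
  } else {
    ss <- steady_state(params)
    us <- ss[["u"]]; vs <- ss[["v"]]
    lin <- list(f_u = -1 + 2 * us * vs,
                f_v = us^2,
                g_u = -2 * us * vs,
                g_v = -us^2,
                d_u = 1, d_v = params$delta)
  }
  lin$params <- params
  structure(lin, class = "linearised_system")
}

#' @export
print.linearised_system <- function(x, ...) {
  cat(sprintf("linearised system: J = [[%.4g, %.4g], [%.4g, %.4g]], d = (%g, %g)\n",
              x$f_u, x$f_v, x$g_u, x$g_v, x$d_u, x$d_v))
  invisible(x)
}

#' Turing (diffusion-driven instability) conditions
#'
#' Evaluates the four classical conditions at a linearised system:
#' C1 \eqn{f_u + g_v < 0}; C2 \eqn{f_u g_v - f_v g_u > 0};
#' C3 \eqn{d_v f_u + d_u g_v > 0};
#' C4 \eqn{(d_v f_u + d_u g_v)^2 - 4 d_u d_v (f_u g_v - f_v g_u) > 0}.
#' The parameter point lies in the Turing space iff all four hold (all
#' inequalities strict, so the Hopf boundary \eqn{f_u + g_v = 0} is excluded).
#'
#' @param lin a [linearise()] result.
#' @return named logical vector `c(c1, c2, c3, c4, in_space)`.
#' @export
turing_conditions <- function(lin) {
  stopifnot(inherits(lin, "linearised_system"))
  tr <- lin$f_u + lin$g_v
  det <- lin$f_u * lin$g_v - lin$f_v * lin$g_u
  cross <- lin$d_v * lin$f_u + lin$d_u * lin$g_v
  c1 <- tr < 0
  c2 <- det > 0
  c3 <- cross > 0
  c4 <- cross^2 - 4 * lin$d_u * lin$d_v * det > 0
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, in_space = c1 && c2 && c3 && c4)
}

#' Dispersion relation at a squared wavenumber
#'
#' Computes \eqn{h(k^2) = d_u d_v k^4 - (d_v f_u + d_u g_v)k^2 +
#' (f_u g_v - f_v g_u)} (the determinant of the \eqn{k^2}-shifted Jacobian) and
#' \eqn{\lambda(k^2)}, the largest real part of the eigenvalues of
#' \eqn{[[f_u - d_u k^2, f_v], [g_u, g_v - d_v k^2]]}. A mode is linearly
#' unstable when \eqn{h(k^2) < 0 < \lambda(k^2)}.
#'
#' @param lin a [linearise()] result.
#' @param k2 nonnegative squared wavenumber(s); vectorised.
#' @return data.frame with columns `k2`, `h`, `lambda`.
#' @export
dispersion <- function(lin, k2) {
  stopifnot(inherits(lin, "linearised_system"), all(k2 >= 0))
  det0 <- lin$f_u * lin$g_v - lin$f_v * lin$g_u
  cross <- lin$d_v * lin$f_u + lin$d_u * lin$g_v
  h <- lin$d_u * lin$d_v * k2^2 - cross * k2 + det0
  tr <- lin$f_u + lin$g_v - (lin$d_u + lin$d_v) * k2
  disc <- tr^2 - 4 * h
  lambda <- ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
  data.frame(k2 = k2, h = h, lambda = lambda)
}

#' Band of unstable squared wavenumbers
#'
#' Roots \eqn{k^2_- \le k^2_+} of \eqn{h(k^2)}, or `NULL` when h has no real
#' roots (no diffusion-driven instability).
#'
#' @param lin a [linearise()] result.
#' @return numeric vector `c(k2_minus, k2_plus)` or `NULL`.
#' @export
unstable_band <- function(lin) {
  det0 <- lin$f_u * lin$g_v - lin$f_v * lin$g_u
  cross <- lin$d_v * lin$f_u + lin$d_u * lin$g_v
  a <- lin$d_u * lin$d_v
  disc <- cross^2 - 4 * a * det0
  if (disc <= 0) return(NULL)
  r <- sqrt(disc)
  c((cross - r) / (2 * a), (cross + r) / (2 * a))
}

#' Enumerate Neumann modes on a rectangle
#'
#' The Neumann eigenfunctions on \eqn{[0,L_x]\times[0,L_y]} are
#' \eqn{\cos(m\pi x/L_x)\cos(n\pi y/L_y)} with
#' \eqn{k^2_{m,n} = \pi^2 m^2/L_x^2 + \pi^2 n^2/L_y^2}, indexed by integer
#' pairs \eqn{(m,n)\ge 0}, not both zero; `(m,n)` and `(n,m)` are distinct
#' modes. Each is flagged unstable when \eqn{h(k^2) < 0 < \lambda(k^2)}.
#'
#' @param lin a [linearise()] result.
#' @param Lx,Ly domain side lengths.
#' @param max_index largest index enumerated per axis.
#' @return data.frame with columns `m`, `n`, `k2`, `h`, `lambda`, `unstable`.
#'   Errors if the unstable band of `h` extends beyond the enumerated range,
#'   since the count would then be incomplete.
#' @export
enumerate_modes <- function(lin, Lx, Ly, max_index = 10L) {
  stopifnot(inherits(lin, "linearised_system"),
            Lx > 0, Ly > 0, max_index >= 1)
  band <- unstable_band(lin)
  if (!is.null(band)) {
    k2max <- pi^2 * max_index^2 * (1 / Lx^2 + 1 / Ly^2)
    if (band[2] > k2max)
      stop("max_index too small: unstable band extends beyond enumerated modes")
  }
  g <- expand.grid(m = 0:max_index, n = 0:max_index)
  g <- g[g$m + g$n > 0L, , drop = FALSE]
  g$k2 <- pi^2 * (g$m^2 / Lx^2 + g$n^2 / Ly^2)
  dsp <- dispersion(lin, g$k2)
  g$h <- dsp$h
  g$lambda <- dsp$lambda
  g$unstable <- g$h < 0 & g$lambda > 0
  rownames(g) <- NULL
  g
}

#' Dominant unstable mode and eigenvalue gap
#'
#' The unstable mode \eqn{(m^*, n^*)} maximising \eqn{\lambda(k^2_{m,n})},
#' together with the percentage gap \eqn{100(\lambda_1-\lambda_2)/\lambda_1}
#' between the two largest growth rates over *distinct* values of \eqn{k^2}
#' (so the symmetric twin \eqn{(n^*, m^*)} on a square does not register a
#' spurious zero gap); 0 when a single unstable \eqn{k^2} exists.
#'
#' @inheritParams enumerate_modes
#' @return list with `m`, `n`, `lambda`, `gap_percent`, and the `modes` table.
#' @export
dominant_mode <- function(lin, Lx, Ly, max_index = 10L) {
  modes <- enumerate_modes(lin, Lx, Ly, max_index)
  un <- modes[modes$unstable, , drop = FALSE]
  if (nrow(un) == 0L) stop("no unstable mode at these parameters")
  best <- un[order(-un$lambda, un$k2, un$m, un$n), ][1L, ]
  lam_by_k2 <- tapply(un$lambda, round(un$k2, 12), max)
  lam_sorted <- sort(unname(lam_by_k2), decreasing = TRUE)
  gap <- if (length(lam_sorted) < 2L) 0 else
    100 * (lam_sorted[1] - lam_sorted[2]) / lam_sorted[1]
  list(m = best$m, n = best$n, lambda = best$lambda,
       gap_percent = gap, modes = modes)
}
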