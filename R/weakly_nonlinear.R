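#' Weakly nonlinear stripe/spot selection for the CIMA model
#'
#' On a sufficiently small square with periodic boundaries, amplitude-equation
#' analysis reduces pattern selection at onset to two scalars \eqn{a} and
#' \eqn{b}: the stripe solution (modes \eqn{k_{0,1}, k_{1,0}}) is stable iff
#' \eqn{b < a < 0} and the spot solution (mode \eqn{k_{1,1}}) is stable iff
#' \eqn{a < -|b| < 0}. For the CIMA kinetics these evaluate to closed forms in
#' \eqn{\alpha} with a common positive prefactor carrying all the
#' \eqn{\delta, \sigma} dependence, so the classification depends on
#' \eqn{\alpha} alone wherever the prefactor is positive.
#'
#' @param params a [model_params()] object with `model = "cima"`.
#' @return list with `a`, `b` and `classification` in
#'   `c("stripes", "spots", "neither")`.
#' @export
ermentrout <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$model != "cima")
    stop("stripe/spot selection closed forms are implemented for CIMA only")
  al <- params$alpha; ds <- params$delta * params$sigma
  if (abs(al^2 - 75) < 1e-12 || abs(al^2 * (2 * ds - 3) + 225) < 1e-12)
    stop("singular prefactor: (alpha^2 - 75) and alpha^2(2*delta*sigma - 3) + 225 must be nonzero")
  pref <- 1875 * ds / ((al^2 - 75)^2 * (al^2 * (2 * ds - 3) + 225))
  a <- pref * (28 * al^4 - 5175 * al^2 - 39375) / (7 * al^2 + 675)
  b <- pref * 3 * (11 * al^6 - 875 * al^4 - 119375 * al^2 + 234375) /
    ((al^2 + 25) * (al^2 + 525))
  classification <- if (b < a && a < 0) "stripes"
    else if (a < -abs(b) && -abs(b) < 0) "spots"
    else "neither"
  list(a = a, b = b, classification = classification)
}

#' Critical feed values where the stripe/spot classification changes
#'
#' Scans \eqn{\alpha} over `(0, alpha_max)` at resolution `step`, classifying
#' each point by [ermentrout()], and bisects every classification change to
#' within `tol`. For the CIMA model with a positive prefactor exactly three
#' boundaries exist below 20: spots below the first, stripes between the first
#' and second, spots between the second and third, and neither above.
#'
#' @param delta,sigma model parameters (the boundaries are independent of them
#'   wherever the common prefactor is positive).
#' @param alpha_max upper end of the scan (default 20).
#' @param step scan resolution (default 0.01).
#' @param tol bisection tolerance on alpha (default 1e-5).
#' @return numeric vector of boundary values of alpha, increasing.
#' @export
critical_alphas <- function(delta, sigma, alpha_max = 20, step = 0.01,
                            tol = 1e-5) {
  classify <- function(al)
    ermentrout(model_params("cima", alpha = al, beta = 1,
                            delta = delta, sigma = sigma))$classification
  # offset start by step/2 so the scan never lands on alpha^2 = 75 exactly
  alphas <- seq(step / 2, alpha_max - step / 2, by = step)
  cls <- vapply(alphas, classify, character(1))
  idx <- which(cls[-1L] != cls[-length(cls)])
  if (length(idx) != 3L)
    stop(sprintf("expected 3 classification changes on (0, %g), found %d",
                 alpha_max, length(idx)))
  vapply(idx, function(i) {
    lo <- alphas[i]; hi <- alphas[i + 1L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (classify(mid) == cls[i]) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
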