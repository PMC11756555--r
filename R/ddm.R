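#' Five-parameter drift diffusion model parameter set
#'
#' Bundles the free parameters of the diffusion model used throughout the
#' package: drift rate \code{v} (evidence/s), threshold separation \code{a},
#' nondecision time \code{t0} (s), the range \code{st0} of uniform
#' across-trial nondecision-time variability (s), and the standard deviation
#' \code{sv} of Gaussian across-trial drift variability.  The start point is
#' always fixed at \code{a/2} (unbiased between the correct and incorrect
#' boundary) and the diffusion coefficient at 1, so none of them are fields.
#'
#' @param v Drift rate; positive values favour the correct boundary.
#' @param a Threshold separation, must be > 0.
#' @param t0 Nondecision time in seconds, must satisfy \code{t0 - st0/2 > 0}.
#' @param st0 Range of uniform t0 variability, >= 0.
#' @param sv SD of across-trial drift variability, >= 0.
#' @return An object of class \code{ddm_params} (a named list).
#' @examples
#' p <- ddm_params(v = 4.1, a = 1.5, t0 = 0.35, st0 = 0.1, sv = 0.8)
#' p_correct(p)
#' @export
ddm_params <- function(v, a, t0, st0 = 0, sv = 0) {
  p <- structure(list(v = as.numeric(v), a = as.numeric(a),
                      t0 = as.numeric(t0), st0 = as.numeric(st0),
                      sv = as.numeric(sv)),
                 class = "ddm_params")
  validate_ddm_params(p)
  p
}

validate_ddm_params <- function(p) {
  stopifnot(is.list(p))
  vals <- unlist(p[c("v", "a", "t0", "st0", "sv")])
  if (any(!is.finite(vals)))
    stop("non-finite DDM parameter", call. = FALSE)
  if (p$a <= 0) stop("threshold separation a must be positive", call. = FALSE)
  if (p$st0 < 0) stop("st0 must be nonnegative", call. = FALSE)
  if (p$sv < 0) stop("sv must be nonnegative", call. = FALSE)
  if (p$t0 - p$st0 / 2 <= 0)
    stop("t0 - st0/2 must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.3f, a = %.3f, t0 = %.3f, st0 = %.3f, sv = %.3f (z = a/2)\n",
              x$v, x$a, x$t0, x$st0, x$sv))
  invisible(x)
}

#' Defective first-passage-time density
#'
#' Density of responding at the given boundary at observed time \code{t}
#' (decision plus nondecision time).  Gaussian across-trial drift variability
#' is integrated in closed form; the uniform nondecision window is integrated
#' by composite 10-point Gauss-Legendre quadrature whose panel count scales
#' with the ratio of the window width to the mean decision time, so narrow
#' decision-time peaks stay resolved.  The density is defective: it
#' integrates over time to the probability of that response, not to 1.
#'
#' @param t Vector of observed times (s), must be positive.
#' @param boundary "correct" (upper) or "incorrect" (lower); recycled.
#' @param params A [ddm_params()] object.
#' @param eps Absolute truncation error of the series expansion.
#' @return Vector of nonnegative density values; 0 for
#'   \code{t <= t0 - st0/2}.
#' @export
fpt_density <- function(t, boundary = c("correct", "incorrect"), params,
                        eps = 1e-7) {
  validate_ddm_params(params)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  boundary <- match.arg(boundary, several.ok = TRUE)
  upper <- rep_len(boundary == "correct", length(t))
  ddm_density_cpp(as.numeric(t), upper, params$v, params$a, params$t0,
                  params$st0, params$sv, eps)
}

#' Joint log-likelihood of a set of trials under the diffusion model
#'
#' Correct responses are scored against the upper boundary, errors against
#' the lower.  Each trial's density is floored at \code{floor_val} before
#' taking the log so that proposal excursions during sampling never produce
#' \code{-Inf}.
#'
#' @param rt Vector of reaction times in seconds.
#' @param correct Logical vector, TRUE for correct responses.
#' @param params A [ddm_params()] object.
#' @param floor_val Per-trial density floor.
#' @return Scalar log-likelihood.
#' @export
ddm_log_likelihood <- function(rt, correct, params, floor_val = 1e-29) {
  validate_ddm_params(params)
  if (length(rt) == 0) stop("empty trial list", call. = FALSE)
  if (length(correct) != length(rt))
    stop("rt and correct must have equal length", call. = FALSE)
  ddm_loglik_cpp(as.numeric(rt), as.logical(correct), params$v, params$a,
                 params$t0, params$st0, params$sv, floor_val)
}

#' Probability of a correct response
#'
#' With the start point fixed at a/2 and unit diffusion the closed form for
#' constant drift is \code{1 / (1 + exp(-v * a))}; with across-trial drift
#' variability the closed form is averaged over the Gaussian drift
#' distribution by quadrature.
#'
#' @param params A [ddm_params()] object.
#' @return Probability of absorption at the correct (upper) boundary.
#' @export
p_correct <- function(params) {
  validate_ddm_params(params)
  pc <- function(u) 1 / (1 + exp(-u * params$a))
  if (params$sv <= 0) return(pc(params$v))
  f <- function(u) dnorm(u, params$v, params$sv) * pc(u)
  integrate(f, params$v - 8 * params$sv, params$v + 8 * params$sv,
            rel.tol = 1e-10)$value
}

#' Simulate first-passage times and choices from the diffusion process
#'
#' Forward simulation independent of the series density: exact Gaussian
#' increments of the constant-coefficient process with a Brownian-bridge
#' correction for boundary crossings inside a step.  Used both as the trial
#' generator for synthetic studies and as the Monte-Carlo oracle in tests.
#'
#' @param n Number of trials.
#' @param params A [ddm_params()] object.
#' @param seed Integer seed (simulation uses its own generator; R's RNG
#'   state is untouched).
#' @param dt Step size in seconds; the default scales with the mean
#'   decision time (capped at 5e-4 s) so fast-decision regimes keep the
#'   same relative resolution.
#' @return A data.frame with columns \code{rt} (s) and \code{correct}
#'   (logical).
#' @export
simulate_ddm <- function(n, params, seed, dt = NULL) {
  validate_ddm_params(params)
  if (is.null(dt)) {
    va <- abs(params$v) * params$a
    mean_dt <- if (va < 1e-6) params$a^2 / 4
      else params$a / (2 * abs(params$v)) * tanh(va / 2)
    dt <- min(5e-4, mean_dt / 300)
  }
  stopifnot(n >= 1, dt > 0)
  res <- ddm_simulate_cpp(as.integer(n), params$v, params$a, params$t0,
                          params$st0, params$sv, dt, as.numeric(seed))
  data.frame(rt = res$rt, correct = res$correct)
}
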