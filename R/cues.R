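#' Eccentricity-dependent visual uncertainty
#'
#' Standard deviation of the visual (cursor) cue as a function of the angular
#' separation between the cursor and the fixated/aiming direction. Fixation
#' during a VMR reach sits near the aiming direction, so the cursor lands in
#' peripheral vision at an eccentricity equal in magnitude to the sensory
#' prediction error; visual direction discrimination degrades with that
#' eccentricity.
#'
#' Three parametric forms are available, all equal to `b` at zero
#' eccentricity and monotone nondecreasing in eccentricity:
#' * `"linear"`: `sigma_v = k * ecc + b`
#' * `"exponential"`: `sigma_v = b * exp(k * ecc)`
#' * `"power_law"`: `sigma_v = b + k * ecc^gamma`
#'
#' @param k slope (degrees of sigma per degree of eccentricity for the linear
#'   form; shape parameter otherwise), `>= 0`.
#' @param b intercept in degrees, `> 0`.
#' @param eccentricity absolute cursor-to-aim angular separation in degrees,
#'   `>= 0`. Vectorized.
#' @param form uncertainty form.
#' @param gamma power-law exponent, `> 0`.
#' @return Visual uncertainty in degrees (same length as `eccentricity`).
#' @examples
#' visual_uncertainty(0.204, 1.853, 30)   # 7.973
#' @export
visual_uncertainty <- function(k, b, eccentricity,
                               form = c("linear", "exponential", "power_law"),
                               gamma = 1) {
  form <- match.arg(form)
  if (any(eccentricity < 0)) stop("eccentricity must be >= 0", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (b <= 0) stop("b must be > 0", call. = FALSE)
  switch(form,
    linear      = k * eccentricity + b,
    exponential = b * exp(k * eccentricity),
    power_law   = b + k * eccentricity^gamma)
}

#' Reliability weights for multisensory hand localization
#'
#' Inverse-variance (reliability) weights of the motor-prediction,
#' proprioceptive, and visual cues used in Bayesian integration of hand
#' direction. Each weight is the cue's inverse variance normalized by the sum
#' of inverse variances, so the weights are nonnegative and sum to one.
#'
#' @param sigma_u,sigma_p,sigma_v cue standard deviations in degrees, `> 0`
#'   (`sigma_v` may be `Inf` to remove the visual cue).
#' @return Named numeric vector `c(W_u, W_p, W_v)`.
#' @examples
#' cue_weights(5, 5, 5)
#' cue_weights(5.05, 11.12, 1.853)
#' @export
cue_weights <- function(sigma_u, sigma_p, sigma_v) {
  if (sigma_u <= 0 || sigma_p <= 0 || sigma_v <= 0)
    stop("all cue uncertainties must be > 0", call. = FALSE)
  iv <- c(W_u = 1 / sigma_u^2, W_p = 1 / sigma_p^2, W_v = 1 / sigma_v^2)
  iv / sum(iv)
}

#' Perceived hand direction
#'
#' Reliability-weighted fusion of the motor-prediction cue `x_u`, the
#' proprioceptive cue `x_p` (the actual hand direction), and the visual cue
#' `x_v` (the cursor direction). The percept is a convex combination of the
#' three cues and therefore lies between their minimum and maximum.
#'
#' @param x_u,x_p,x_v cue directions in degrees.
#' @param weights weights from [cue_weights()].
#' @return Perceived hand direction in degrees.
#' @examples
#' w <- cue_weights(5.05, 11.12, visual_uncertainty(0.204, 1.853, 30))
#' perceived_hand(0, 0, -30, w)   # approx -7.49
#' @export
perceived_hand <- function(x_u, x_p, x_v, weights) {
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  weights[[1]] * x_u + weights[[2]] * x_p + weights[[3]] * x_v
}
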