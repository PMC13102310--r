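#' Model parameters for a VMR adaptation model
#'
#' Bundles the retention/learning rates of the explicit and implicit states,
#' the sensory-uncertainty parameters of the Bayesian hand-localization stage,
#' and the model-kind tag selecting which error drives implicit learning.
#'
#' The explicit state is updated by performance error in every model; the
#' models differ only in the implicit update: `"PPE"` uses the perceptual
#' prediction error (perceived hand minus predicted hand), `"PE"` the
#' performance error (cursor minus target), `"SPE"` the sensory prediction
#' error (cursor minus predicted hand), and `"TWO_STATE"` splits the implicit
#' state into a fast component driven by PE and a slow component driven by SPE.
#'
#' The fixed sensory parameters default to `sigma_u = 5.05`, `sigma_p = 11.12`
#' and `b = 1.853` degrees, estimates of prediction-cue uncertainty,
#' proprioceptive uncertainty, and the visual-uncertainty intercept taken from
#' error-clamp hand-localization work; they are treated as stable properties of
#' the sensorimotor system rather than free parameters.
#'
#' @param Ae,Be explicit retention and learning rate, in `[0, 1]`.
#' @param Ai,Bi implicit retention and learning rate, in `[0, 1]`.
#' @param k visual-uncertainty slope (degrees of sigma per degree of
#'   eccentricity; shape parameter for the non-linear forms), `>= 0`.
#' @param b visual-uncertainty intercept in degrees, `> 0`.
#' @param sigma_u prediction-cue uncertainty in degrees, `> 0`.
#' @param sigma_p proprioceptive-cue uncertainty in degrees, `> 0`.
#' @param model_kind one of `"PPE"`, `"PE"`, `"SPE"`, `"TWO_STATE"`.
#' @param uncertainty_form one of `"linear"`, `"exponential"`, `"power_law"`;
#'   see [visual_uncertainty()].
#' @param gamma exponent of the power-law uncertainty form (ignored
#'   otherwise), `> 0`.
#' @param Af,Bf,As,Bs fast/slow retention and learning rates for the
#'   `"TWO_STATE"` implicit model; `NA` otherwise.
#' @param check enforce the conventional orderings `Ae < Ai` and `Be > Bi`
#'   (and `Af < As`, `Bf > Bs` for the two-state model). Disable for
#'   degenerate configurations used in reductions and tests.
#'
#' @return An object of class `vmr_params` (a named list).
#' @examples
#' p <- model_params(model_kind = "PPE")
#' p$k
#' @export
model_params <- function(Ae = 0.7, Be = 0.513, Ai = 0.98, Bi = 0.151,
                         k = 0.204, b = 1.853,
                         sigma_u = 5.05, sigma_p = 11.12,
                         model_kind = c("PPE", "PE", "SPE", "TWO_STATE"),
                         uncertainty_form = c("linear", "exponential", "power_law"),
                         gamma = 1,
                         Af = NA_real_, Bf = NA_real_,
                         As = NA_real_, Bs = NA_real_,
                         check = TRUE) {
  model_kind <- match.arg(model_kind)
  uncertainty_form <- match.arg(uncertainty_form)
  p <- list(Ae = Ae, Be = Be, Ai = Ai, Bi = Bi, k = k, b = b,
            sigma_u = sigma_u, sigma_p = sigma_p,
            model_kind = model_kind, uncertainty_form = uncertainty_form,
            gamma = gamma, Af = Af, Bf = Bf, As = As, Bs = Bs)
  class(p) <- "vmr_params"
  validate_params(p, check = check)
  p
}

validate_params <- function(p, check = TRUE) {
  rates <- c(Ae = p$Ae, Be = p$Be, Ai = p$Ai, Bi = p$Bi)
  if (any(!is.finite(unlist(rates))))
    stop("retention/learning rates must be finite", call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("retention/learning rates must lie in [0, 1]", call. = FALSE)
  if (!is.finite(p$k) || p$k < 0) stop("k must be >= 0", call. = FALSE)
  if (!is.finite(p$b) || p$b <= 0) stop("b must be > 0", call. = FALSE)
  if (p$sigma_u <= 0 || p$sigma_p <= 0)
    stop("sigma_u and sigma_p must be > 0", call. = FALSE)
  if (p$uncertainty_form == "power_law" && (!is.finite(p$gamma) || p$gamma <= 0))
    stop("gamma must be > 0 for the power-law uncertainty form", call. = FALSE)
  if (p$model_kind == "TWO_STATE") {
    ts <- c(p$Af, p$Bf, p$As, p$Bs)
    if (any(is.na(ts)))
      stop("TWO_STATE model requires Af, Bf, As, Bs", call. = FALSE)
    if (any(ts < 0 | ts > 1))
      stop("two-state rates must lie in [0, 1]", call. = FALSE)
    if (check && (p$Af >= p$As || p$Bf <= p$Bs))
      stop("two-state convention requires Af < As and Bf > Bs", call. = FALSE)
  }
  # Conventional ordering of the explicit and implicit pathways: the explicit
  # state forgets faster and learns faster than the implicit state.
  if (check && (p$Ae >= p$Ai || p$Be <= p$Bi))
    stop("parameters must satisfy Ae < Ai and Be > Bi", call. = FALSE)
  invisible(p)
}

#' @export
print.vmr_params <- function(x, ...) {
  cat(sprintf("<vmr_params> %s model (%s visual uncertainty)\n",
              x$model_kind, x$uncertainty_form))
  cat(sprintf("  explicit: Ae = %.3f, Be = %.3f\n", x$Ae, x$Be))
  cat(sprintf("  implicit: Ai = %.3f, Bi = %.3f\n", x$Ai, x$Bi))
  if (x$model_kind == "TWO_STATE")
    cat(sprintf("  fast/slow: Af = %.3f, Bf = %.3f, As = %.3f, Bs = %.3f\n",
                x$Af, x$Bf, x$As, x$Bs))
  cat(sprintf("  uncertainty: k = %.3f, b = %.3f, sigma_u = %.2f, sigma_p = %.2f\n",
              x$k, x$b, x$sigma_u, x$sigma_p))
  invisible(x)
}

# Replace fields of a vmr_params object, revalidating. Internal.
set_params <- function(p, values, check = FALSE) {
  for (nm in names(values)) p[[nm]] <- values[[nm]]
  validate_params(p, check = check)
  p
}
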