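#' Learning state of the two-pathway model
#'
#' @param x_e explicit state (deliberate re-aiming), degrees.
#' @param x_i implicit state, degrees. For the two-state implicit model this
#'   is the sum of `x_i_fast` and `x_i_slow`.
#' @param x_i_fast,x_i_slow fast and slow implicit components (two-state
#'   model only).
#' @return A `vmr_state` list with an additional `x` entry, the total
#'   learning `x_e + x_i`.
#' @export
learning_state <- function(x_e = 0, x_i = 0,
                           x_i_fast = NA_real_, x_i_slow = NA_real_) {
  if (!is.na(x_i_fast) || !is.na(x_i_slow)) {
    if (is.na(x_i_fast) || is.na(x_i_slow))
      stop("both two-state components must be given", call. = FALSE)
    x_i <- x_i_fast + x_i_slow
  }
  structure(list(x_e = x_e, x_i = x_i, x = x_e + x_i,
                 x_i_fast = x_i_fast, x_i_slow = x_i_slow),
            class = "vmr_state")
}

#' Trial errors for one VMR trial
#'
#' Computes the three competing error signals (and the re-aiming performance
#' error) for a single trial. All directions are measured relative to the
#' original target with the direction countering the perturbation taken as
#' positive, so the cursor direction is `x - r` where `x = x_e + x_i` is the
#' executed hand direction and `r` the imposed rotation.
#'
#' * performance error `e_pe = cursor - target = x - r`
#' * sensory prediction error `e_spe = cursor - x_u`
#' * re-aiming performance error `e_pe_reaim = cursor - aim_reference`
#' * perceptual prediction error `e_ppe = perceived_hand - x_u`, with the
#'   percept integrating `x_u`, the actual hand, and the cursor, and the
#'   visual uncertainty evaluated at eccentricity `|cursor - x_u|`
#'
#' The prediction `x_u` equals the explicit state under free aiming and the
#' instructed direction under instructed re-aiming (where the hand is
#' `aim_reference + x_i`). Under free aiming `e_spe = x_i - r` holds as an
#' identity. In the `no_feedback` regime all errors are `NA` (no update).
#'
#' @param state a [learning_state()].
#' @param r imposed rotation in degrees (signed).
#' @param params a [model_params()].
#' @param regime `"free_aiming"`, `"instructed_reaiming"`, or
#'   `"no_feedback"`.
#' @param aim_reference instructed aiming direction in degrees (required for
#'   instructed re-aiming).
#' @return A list with `e_pe`, `e_pe_reaim`, `e_spe`, `e_ppe`, `sigma_v`,
#'   plus the underlying `x_u`, `x_v`, `hand` and `perceived` directions.
#' @examples
#' trial_errors(learning_state(0, 0), r = 30, params = model_params())
#' @export
trial_errors <- function(state, r, params,
                         regime = c("free_aiming", "instructed_reaiming",
                                    "no_feedback"),
                         aim_reference = NULL) {
  regime <- match.arg(regime)
  if (regime == "no_feedback") {
    return(list(e_pe = NA_real_, e_pe_reaim = NA_real_, e_spe = NA_real_,
                e_ppe = NA_real_, sigma_v = NA_real_, x_u = NA_real_,
                x_v = NA_real_, hand = NA_real_, perceived = NA_real_))
  }
  if (regime == "instructed_reaiming") {
    if (is.null(aim_reference))
      stop("instructed_reaiming requires aim_reference", call. = FALSE)
    x_u <- aim_reference
    hand <- aim_reference + state$x_i
  } else {
    x_u <- state$x_e
    hand <- state$x_e + state$x_i
  }
  x_v <- hand - r
  sigma_v <- visual_uncertainty(params$k, params$b, abs(x_v - x_u),
                                form = params$uncertainty_form,
                                gamma = params$gamma)
  w <- cue_weights(params$sigma_u, params$sigma_p, sigma_v)
  percept <- perceived_hand(x_u, hand, x_v, w)
  list(e_pe = x_v,
       e_pe_reaim = if (is.null(aim_reference)) NA_real_ else x_v - aim_reference,
       e_spe = x_v - x_u,
       e_ppe = percept - x_u,
       sigma_v = sigma_v, x_u = x_u, x_v = x_v, hand = hand,
       perceived = percept)
}

#' Advance the learning state by one trial
#'
#' Applies the state-space update for the model kind in `params`. On feedback
#' trials the explicit state is updated by performance error
#' (`x_e' = Ae x_e - Be e_pe`) and the implicit state by the model-specific
#' error: PPE (`e_ppe`), PE (`e_pe`), or SPE (`e_spe`), each as
#' `x_i' = Ai x_i - Bi e`. In the instructed-re-aiming regime the explicit
#' state is clamped to the instructed direction (no performance-error
#' update), and the PE model's implicit error is the re-aiming performance
#' error unless `pe_reaiming = FALSE`. On no-feedback trials (errors all
#' `NA`) both states decay by their retention rates.
#'
#' @param state a [learning_state()].
#' @param errors output of [trial_errors()] for the same trial.
#' @param params a [model_params()].
#' @param regime trial regime, as in [trial_errors()].
#' @param aim_reference instructed direction (instructed re-aiming only).
#' @param pe_reaiming should the PE model use the re-aiming performance error
#'   during instructed re-aiming? Default `TRUE`, which lets the PE model
#'   produce implicit drift in that regime; `FALSE` measures performance
#'   error against the original target throughout.
#' @return The next [learning_state()].
#' @examples
#' s <- learning_state()
#' p <- model_params(model_kind = "PE", Ai = 1, Bi = 0.151, Be = 0.513,
#'                   check = FALSE)
#' e <- trial_errors(s, r = 30, params = p)
#' step_state(s, e, p)$x_i   # 0.151 * 30 = 4.53
#' @export
step_state <- function(state, errors, params,
                       regime = c("free_aiming", "instructed_reaiming",
                                  "no_feedback"),
                       aim_reference = NULL, pe_reaiming = TRUE) {
  regime <- match.arg(regime)
  no_fb <- regime == "no_feedback" || is.na(errors$e_pe)
  if (params$model_kind == "TWO_STATE")
    return(two_state_step_internal(state, errors, params, no_fb,
                                   regime, pe_reaiming))
  if (no_fb) {
    x_e <- params$Ae * state$x_e
    x_i <- params$Ai * state$x_i
    return(learning_state(x_e, x_i))
  }
  x_e <- if (regime == "instructed_reaiming") {
    if (is.null(aim_reference))
      stop("instructed_reaiming requires aim_reference", call. = FALSE)
    aim_reference
  } else {
    params$Ae * state$x_e - params$Be * errors$e_pe
  }
  err_i <- switch(params$model_kind,
    PPE = errors$e_ppe,
    PE  = if (regime == "instructed_reaiming" && pe_reaiming)
            errors$e_pe_reaim else errors$e_pe,
    SPE = errors$e_spe,
    stop("unknown model_kind", call. = FALSE))
  x_i <- params$Ai * state$x_i - params$Bi * err_i
  learning_state(x_e, x_i)
}

two_state_step_internal <- function(state, errors, params, no_fb,
                                    regime, pe_reaiming) {
  xf <- if (is.na(state$x_i_fast)) 0 else state$x_i_fast
  xs <- if (is.na(state$x_i_slow)) 0 else state$x_i_slow
  if (no_fb) {
    st <- learning_state(params$Ae * state$x_e,
                         x_i_fast = params$Af * xf, x_i_slow = params$As * xs)
    return(st)
  }
  e_pe <- if (regime == "instructed_reaiming" && pe_reaiming)
    errors$e_pe_reaim else errors$e_pe
  x_e <- if (regime == "instructed_reaiming") errors$x_u
         else params$Ae * state$x_e - params$Be * errors$e_pe
  learning_state(x_e,
                 x_i_fast = params$Af * xf - params$Bf * e_pe,
                 x_i_slow = params$As * xs - params$Bs * errors$e_spe)
}

#' Two-state implicit update
#'
#' Implicit-only update of the dual-error two-state variant, in which the
#' fast implicit component is driven by performance error and the slow
#' component by sensory prediction error:
#' `x_i_fast' = Af x_i_fast - Bf e_pe`, `x_i_slow' = As x_i_slow - Bs e_spe`,
#' with `x_i'` their sum. Setting `Bs = 0` (and ignoring the slow component)
#' reduces the fast component exactly to the PE model's implicit update.
#'
#' @param state a [learning_state()] with two-state components.
#' @param e_pe,e_spe performance and sensory prediction errors in degrees.
#' @param params a [model_params()] with `model_kind = "TWO_STATE"`.
#' @return The next [learning_state()].
#' @export
two_state_implicit_step <- function(state, e_pe, e_spe, params) {
  if (params$model_kind != "TWO_STATE" || any(is.na(c(params$Af, params$Bf,
                                                      params$As, params$Bs))))
    stop("two_state_implicit_step requires a TWO_STATE model with Af, Bf, As, Bs",
         call. = FALSE)
  xf <- if (is.na(state$x_i_fast)) 0 else state$x_i_fast
  xs <- if (is.na(state$x_i_slow)) 0 else state$x_i_slow
  learning_state(state$x_e,
                 x_i_fast = params$Af * xf - params$Bf * e_pe,
                 x_i_slow = params$As * xs - params$Bs * e_spe)
}

#' Model-predicted proprioceptive bias
#'
#' Predicted bias of a passive hand-localization judgment made immediately
#' after an adaptation trial: the difference between the perceived and the
#' actual hand direction on that preceding trial. With the countering
#' direction positive the bias is negative (toward the visual perturbation,
#' i.e., opposite to the direction of learning), and its magnitude follows
#' the same concave dependence on perturbation size as the perceptual
#' prediction error.
#'
#' @param state the [learning_state()] with which the preceding adaptation
#'   trial was executed.
#' @param r rotation of the preceding trial in degrees.
#' @param params a [model_params()].
#' @return Bias in degrees (perceived minus actual hand).
#' @examples
#' predicted_proprioceptive_bias(learning_state(), 30, model_params())
#' @export
predicted_proprioceptive_bias <- function(state, r, params) {
  if (r == 0 && state$x_i == 0 && state$x_e == 0) return(0)
  e <- trial_errors(state, r, params, regime = "free_aiming")
  e$perceived - e$hand
}

#' Single-trial implicit learning response from rest
#'
#' Change of the implicit state produced by one perturbed trial starting from
#' zero explicit and implicit states. For the PE and SPE models this is
#' exactly `Bi * r`, a straight line through the origin; for the PPE model it
#' is `Bi * W_v(|r|) * r`, which rises and then falls with perturbation size
#' because large rotations inflate visual uncertainty and so shrink the
#' visual weight.
#'
#' @param params a [model_params()].
#' @param r signed rotation(s) in degrees. Vectorized.
#' @return Implicit change in degrees, same length as `r`.
#' @export
single_trial_response <- function(params, r) {
  vapply(r, function(ri) {
    e <- trial_errors(learning_state(), ri, params, regime = "free_aiming")
    err <- switch(params$model_kind,
                  PPE = e$e_ppe, PE = e$e_pe, SPE = e$e_spe,
                  stop("single_trial_response supports PPE, PE, SPE",
                       call. = FALSE))
    -params$Bi * err
  }, numeric(1))
}
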