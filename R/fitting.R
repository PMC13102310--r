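#' Fitting specification
#'
#' Describes which model to fit, which parameters are free (with box
#' bounds), which data channels enter the objective, and the optimizer
#' settings. The remaining parameters are fixed at the values in `fixed`
#' (the sensory parameters `sigma_u`, `sigma_p`, `b` are fixed by default).
#'
#' Two inequality constraints of the two-pathway convention are enforced by
#' construction rather than by penalties: when `Ae` and `Ai` are both free
#' the optimizer works with `u = Ae / Ai` in `[0, 1)`, and when `Be` and
#' `Bi` are both free it works with `v = Bi / Be` in `[0, 1)`. When one
#' member of a pair is fixed, the free member's bound is tightened instead.
#'
#' @param model_kind model to fit (`"PPE"`, `"PE"`, `"SPE"`, `"TWO_STATE"`).
#' @param free character vector of free parameter names (fields of
#'   [model_params()]).
#' @param fixed named list of fixed parameter values (overrides the
#'   defaults of [model_params()]).
#' @param lower,upper named numeric vectors overriding default bounds for
#'   free parameters.
#' @param channels data channels entering the sum-of-squares objective:
#'   subset of `"total"` (mean hand on feedback trials), `"implicit"` (mean
#'   hand on exclusion/null trials during adaptation), `"explicit"` (mean
#'   aiming reports).
#' @param clamp_explicit treat the observed explicit series as known data:
#'   the model's explicit state is set per trial from the observed aiming
#'   reports and only the remaining channels are fit.
#' @param Ai_min lower bound for `Ai` (e.g. 0.7 for single-trial designs).
#' @param n_starts number of seeded Latin-hypercube multi-starts.
#' @param pe_reaiming see [step_state()].
#' @param seed seed for the multi-start draw.
#' @return A `vmr_fitspec` list.
#' @export
fit_spec <- function(model_kind = "PPE",
                     free = c("k", "Ai", "Bi"),
                     fixed = list(),
                     lower = NULL, upper = NULL,
                     channels = c("total", "implicit"),
                     clamp_explicit = FALSE,
                     Ai_min = 0,
                     n_starts = 20, pe_reaiming = TRUE, seed = 1L) {
  channels <- match.arg(channels, c("total", "implicit", "explicit"),
                        several.ok = TRUE)
  # placeholder-tolerant parameter template (free parameters are filled in
  # by the optimizer, so two-state fields may still be NA here)
  base <- unclass(model_params(check = FALSE))
  base$model_kind <- model_kind
  for (nm in names(fixed)) base[[nm]] <- fixed[[nm]]
  bad <- setdiff(free, names(base))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lo <- c(Ae = 0, Be = 0, Ai = Ai_min, Bi = 0, k = 0, b = 0.1,
          gamma = 0.1, Af = 0, Bf = 0, As = 0, Bs = 0,
          sigma_u = 0.5, sigma_p = 0.5)
  up <- c(Ae = 1, Be = 1, Ai = 1, Bi = 1, k = 1, b = 20,
          gamma = 3, Af = 1, Bf = 1, As = 1, Bs = 1,
          sigma_u = 50, sigma_p = 50)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  structure(list(model_kind = model_kind, free = free, base = base,
                 lower = lo[free], upper = up[free],
                 channels = channels, clamp_explicit = clamp_explicit,
                 n_starts = n_starts, pe_reaiming = pe_reaiming,
                 seed = seed),
            class = "vmr_fitspec")
}

#' Assemble fitting data from simulated datasets
#'
#' Bundles one or more condition datasets into the structure consumed by
#' [objective_sse()] and [fit_model()]: per condition, the schedule and the
#' across-participant mean series.
#'
#' @param ... `vmr_dataset` objects (or a single list of them), one per
#'   condition, fitted simultaneously.
#' @param participants optional list (same length) of participant-id vectors
#'   passed to [condition_means()], used by the bootstrap.
#' @return A `vmr_fitdata` list of conditions.
#' @export
fit_data <- function(..., participants = NULL) {
  dsl <- list(...)
  if (length(dsl) == 1L && !inherits(dsl[[1]], "vmr_dataset")) dsl <- dsl[[1]]
  stopifnot(all(vapply(dsl, inherits, logical(1), "vmr_dataset")))
  conds <- lapply(seq_along(dsl), function(i) {
    ds <- dsl[[i]]
    obs <- condition_means(ds, participants = participants[[i]])
    list(schedule = ds$schedule, obs = obs,
         condition = as.character(ds$condition), design = ds$design)
  })
  structure(conds, class = "vmr_fitdata")
}

# Per-condition channel index/value pairs, precomputed once per fit.
channel_targets <- function(cond, channels, clamp_explicit) {
  sched <- cond$schedule
  obs <- cond$obs
  codes <- schedule_trial_codes(sched)
  adapt <- sched$phase %in% c("adaptation", "reaiming")
  out <- list()
  if ("total" %in% channels) {
    idx <- which(codes == 0L & !is.na(obs$hand_deg))
    out$total <- list(idx = idx, obs = obs$hand_deg[idx], col = "hand")
  }
  if ("implicit" %in% channels) {
    # every movement executed under the aim-straight instruction reads out
    # the implicit state: exclusion/null trials during adaptation and the
    # washout trials
    idx <- which(codes == 1L &
                   ((adapt & sched$trial_type %in%
                       c("exclusion", "null_nofeedback")) |
                      sched$phase == "washout") &
                   !is.na(obs$hand_deg))
    out$implicit <- list(idx = idx, obs = obs$hand_deg[idx], col = "hand")
  }
  if ("explicit" %in% channels && !clamp_explicit) {
    idx <- which(!is.na(obs$aim_report_deg) & adapt)
    out$explicit <- list(idx = idx, obs = obs$aim_report_deg[idx], col = "x_e")
  }
  clamp <- NULL
  if (clamp_explicit) {
    # observed explicit series as known data: 0 in baseline, last
    # observation carried forward elsewhere
    aim <- obs$aim_report_deg
    aim[sched$phase == "baseline" & is.na(aim)] <- 0
    last <- 0
    for (t in seq_along(aim)) {
      if (is.na(aim[t])) aim[t] <- last else last <- aim[t]
    }
    clamp <- aim
  }
  list(targets = out, clamp = clamp)
}

build_params <- function(spec, values) {
  p <- spec$base
  for (nm in names(values)) p[[nm]] <- values[[nm]]
  class(p) <- "vmr_params"
  p
}

#' Sum-of-squares objective
#'
#' Unweighted sum over conditions and selected channels of squared
#' differences between the observed mean series and the noise-free model
#' prediction. With `clamp_explicit`, the explicit state is set per trial
#' from the observed aiming-report series before the implicit prediction is
#' computed.
#'
#' @param values named numeric vector of free-parameter values.
#' @param data a [fit_data()] object.
#' @param spec a [fit_spec()].
#' @return The SSE (scalar, `>= 0`).
#' @export
objective_sse <- function(values, data, spec) {
  stopifnot(inherits(data, "vmr_fitdata"))
  params <- build_params(spec, values)
  total <- 0
  for (cond in data) {
    ct <- channel_targets(cond, spec$channels, spec$clamp_explicit)
    traj <- simulate_trajectory(cond$schedule, params,
                                clamp_explicit = ct$clamp,
                                pe_reaiming = spec$pe_reaiming)
    for (ch in ct$targets) {
      res <- ch$obs - traj[[ch$col]][ch$idx]
      total <- total + sum(res^2)
    }
  }
  total
}

# free-parameter vector <-> optimizer coordinates (ratio reparameterization
# for the Ae<Ai and Bi<Be constraints when both members are free)
make_par_map <- function(spec) {
  free <- spec$free
  pair_A <- all(c("Ae", "Ai") %in% free)
  pair_B <- all(c("Be", "Bi") %in% free)
  onames <- free
  lo <- spec$lower; up <- spec$upper
  if (pair_A) { onames[onames == "Ae"] <- "uA"; lo["Ae"] <- 0;  up["Ae"] <- 0.999 }
  if (pair_B) { onames[onames == "Bi"] <- "vB"; lo["Bi"] <- 0;  up["Bi"] <- 0.999 }
  if (!pair_A && "Ai" %in% free && !"Ae" %in% free)
    lo["Ai"] <- max(lo["Ai"], spec$base$Ae)
  if (!pair_B && "Bi" %in% free && !"Be" %in% free)
    up["Bi"] <- min(up["Bi"], spec$base$Be)
  to_values <- function(theta) {
    names(theta) <- free
    if (pair_A) theta["Ae"] <- theta["Ae"] * theta["Ai"]
    if (pair_B) theta["Bi"] <- theta["Bi"] * theta["Be"]
    theta
  }
  list(lower = unname(lo[free]), upper = unname(up[free]),
       to_values = to_values, names = onames)
}

#' Fit a model to condition-mean learning series
#'
#' Bounded, constraint-respecting least-squares minimization of
#' [objective_sse()] with seeded Latin-hypercube multi-start (L-BFGS-B local
#' searches). Returns the best local solution; if no start converges the
#' result is flagged, not an error.
#'
#' @param data a [fit_data()] object.
#' @param spec a [fit_spec()].
#' @param extra_starts optional matrix of additional start values (one row
#'   per start, columns in `spec$free` order, on the natural scale).
#' @return A `vmr_fit` with the fitted [model_params()], free-parameter
#'   `estimate`, `sse`, data-point count `n`, free-parameter count `p`,
#'   `converged` flag, and `boundary` flag (solution at a bound).
#' @export
fit_model <- function(data, spec, extra_starts = NULL) {
  stopifnot(inherits(data, "vmr_fitdata"), inherits(spec, "vmr_fitspec"))
  pm <- make_par_map(spec)
  pn <- length(spec$free)

  # data-point count over selected channels
  n_pts <- 0
  for (cond in data) {
    ct <- channel_targets(cond, spec$channels, spec$clamp_explicit)
    n_pts <- n_pts + sum(vapply(ct$targets, function(ch) length(ch$idx),
                                numeric(1)))
  }
  if (n_pts <= pn)
    stop("fewer data points than free parameters", call. = FALSE)

  # per-condition quantities that depend only on data and spec
  cts <- lapply(data, channel_targets, channels = spec$channels,
                clamp_explicit = spec$clamp_explicit)
  col_idx <- c(x_e = 1L, x_i = 2L, hand = 3L)
  pre <- lapply(data, function(cond) {
    sched <- cond$schedule
    list(rot = sched$rotation_deg,
         codes = schedule_trial_codes(sched),
         instr = as.integer(sched$regime == "instructed_reaiming"),
         aim = ifelse(is.na(sched$aim_reference), 0, sched$aim_reference),
         open_aim = any(sched$regime == "instructed_reaiming" &
                          is.na(sched$aim_reference)))
  })
  kind_code <- match(spec$model_kind, c("PPE", "PE", "SPE", "TWO_STATE")) - 1L
  obj <- function(theta) {
    v <- pm$to_values(theta)
    params <- build_params(spec, v)
    out <- try({
      total <- 0
      for (ci in seq_along(data)) {
        ct <- cts[[ci]]
        if (pre[[ci]]$open_aim) {  # aim reference depends on the parameters
          traj <- simulate_trajectory(data[[ci]]$schedule, params,
                                      clamp_explicit = ct$clamp,
                                      pe_reaiming = spec$pe_reaiming)
          for (ch in ct$targets)
            total <- total + sum((ch$obs - traj[[ch$col]][ch$idx])^2)
        } else {
          pl <- unclass(params)
          pl$kind <- kind_code
          pl$form <- match(params$uncertainty_form,
                           c("linear", "exponential", "power_law")) - 1L
          for (nm in c("Af", "Bf", "As", "Bs"))
            if (is.na(pl[[nm]])) pl[[nm]] <- 0
          m <- .sim_trajectory_cpp(pre[[ci]]$rot, pre[[ci]]$codes,
                                   pre[[ci]]$instr, pre[[ci]]$aim, pl,
                                   if (is.null(ct$clamp)) numeric(0)
                                   else ct$clamp,
                                   spec$pe_reaiming)
          for (ch in ct$targets)
            total <- total + sum((ch$obs - m[ch$idx, col_idx[[ch$col]]])^2)
        }
      }
      total
    }, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e12 else out
  }

  set.seed(as.integer(spec$seed))
  grid <- lhs::randomLHS(max(spec$n_starts, 1L), pn)
  starts <- sweep(sweep(grid, 2, pm$upper - pm$lower, "*"), 2, pm$lower, "+")
  if (!is.null(extra_starts)) {
    es <- matrix(extra_starts, ncol = pn)
    # map natural-scale extra starts into optimizer coordinates
    es_t <- t(apply(es, 1, function(row) {
      names(row) <- spec$free
      if (all(c("Ae", "Ai") %in% spec$free))
        row["Ae"] <- min(row["Ae"] / max(row["Ai"], 1e-9), 0.999)
      if (all(c("Be", "Bi") %in% spec$free))
        row["Bi"] <- min(row["Bi"] / max(row["Be"], 1e-9), 0.999)
      pmin(pmax(row, pm$lower), pm$upper)
    }))
    starts <- rbind(starts, es_t)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- try(optim(starts[i, ], obj, method = "L-BFGS-B",
                     lower = pm$lower, upper = pm$upper,
                     control = list(maxit = 500, factr = 1e4,
                                    ndeps = rep(1e-6, pn))),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, sse = NA_real_, spec = spec),
                     class = "vmr_fit"))

  est <- pm$to_values(best$par)
  at_bound <- any(abs(best$par - pm$lower) < 1e-6 |
                    abs(best$par - pm$upper) < 1e-6)
  structure(list(params = build_params(spec, est),
                 estimate = est, sse = best$value,
                 n = n_pts, p = pn,
                 converged = best$convergence == 0,
                 boundary = at_bound,
                 spec = spec, data = data),
            class = "vmr_fit")
}

#' @export
print.vmr_fit <- function(x, ...) {
  if (is.na(x$sse)) {
    cat("<vmr_fit> optimizer failed on all starts\n")
    return(invisible(x))
  }
  cat(sprintf("<vmr_fit> %s model: SSE = %.4g (n = %d, p = %d)%s\n",
              x$spec$model_kind, x$sse, x$n, x$p,
              if (x$boundary) " [at bound]" else ""))
  print(round(x$estimate, 4))
  invisible(x)
}

#' Predict a held-out schedule from a fitted model
#'
#' Noise-free model trajectory on a new schedule using the fitted
#' parameters, for cross-design validation (fit stepwise, predict one-step)
#' and phase-2 prediction in the late re-aiming design.
#'
#' @param fit a `vmr_fit`.
#' @param schedule the (possibly new) [build_schedule()] to predict.
#' @param override named list of parameter values replacing fitted ones
#'   (e.g. a condition-specific visual-uncertainty slope).
#' @return The [simulate_trajectory()] data frame for the new schedule.
#' @export
predict_heldout <- function(fit, schedule, override = NULL) {
  stopifnot(inherits(fit, "vmr_fit"))
  if (is.na(fit$sse)) stop("cannot predict from a failed fit", call. = FALSE)
  p <- fit$params
  if (!is.null(override)) p <- set_params(p, override, check = FALSE)
  simulate_trajectory(schedule, p, pe_reaiming = fit$spec$pe_reaiming)
}
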