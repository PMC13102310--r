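#' Goodness of fit
#'
#' Computes R-squared, RMSE, AIC and BIC for a fitted model from its SSE.
#' R-squared is `1 - SSE/SST` with SST about the mean of the observed
#' channel values (it can be negative for a fit worse than the mean); AIC
#' and BIC use the concentrated Gaussian log-likelihood,
#' `n log(SSE/n) + 2p` and `n log(SSE/n) + p log(n)`.
#'
#' @param fit a `vmr_fit` from [fit_model()].
#' @return A `vmr_goodness` list with `R2`, `RMSE`, `AIC`, `BIC`, `n`, `p`.
#' @export
goodness <- function(fit) {
  stopifnot(inherits(fit, "vmr_fit"))
  if (is.na(fit$sse)) stop("fit did not converge", call. = FALSE)
  obs <- unlist(lapply(fit$data, function(cond) {
    ct <- channel_targets(cond, fit$spec$channels, fit$spec$clamp_explicit)
    unlist(lapply(ct$targets, `[[`, "obs"))
  }))
  n <- fit$n; p <- fit$p
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - fit$sse / sst
  sse <- max(fit$sse, .Machine$double.xmin)
  structure(list(R2 = r2, RMSE = sqrt(fit$sse / n),
                 AIC = n * log(sse / n) + 2 * p,
                 BIC = n * log(sse / n) + p * log(n),
                 n = n, p = p),
            class = "vmr_goodness")
}

#' @export
print.vmr_goodness <- function(x, ...) {
  cat(sprintf("R2 = %.3f, RMSE = %.3f, AIC = %.2f, BIC = %.2f (n = %d, p = %d)\n",
              x$R2, x$RMSE, x$AIC, x$BIC, x$n, x$p))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two numeric sequences on the identity line:
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments. Equals 1 iff `y = x`, is bounded by `[-1, 1]`,
#' and is penalized by both location and scale shifts.
#'
#' @param x,y equal-length numeric vectors, length `>= 2`.
#' @return The CCC, or `NA` when both variances are zero and the means are
#'   equal (degenerate case).
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * cxy / denom
}

#' Participant bootstrap of a model fit
#'
#' Resamples participants with replacement within each condition, recomputes
#' the condition-mean series, and refits the model, yielding the sampling
#' distribution of the parameter estimates (and of any prediction derived
#' from them). Deterministic given `seed`.
#'
#' @param datasets a `vmr_dataset` or list of them (one per condition).
#' @param spec a [fit_spec()].
#' @param n_boot number of bootstrap resamples, `>= 2`.
#' @param seed integer seed.
#' @param n_starts_boot multi-starts per resample fit (resample objectives
#'   are close to the original, so fewer starts suffice; the original fit's
#'   estimate is always included as a start).
#' @return A `vmr_bootstrap` list with the matrix `estimates` (one row per
#'   resample), per-parameter `sd` and 2.5/97.5 percentile intervals, and
#'   the resample `indices`.
#' @export
bootstrap_fits <- function(datasets, spec, n_boot = 5000, seed = 1L,
                           n_starts_boot = 3) {
  if (inherits(datasets, "vmr_dataset")) datasets <- list(datasets)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  ids <- lapply(datasets, function(d) unique(d$trials$participant_id))

  fit0 <- fit_model(fit_data(datasets), spec)
  spec_b <- spec
  spec_b$n_starts <- n_starts_boot

  set.seed(as.integer(seed))
  idx_draws <- lapply(seq_len(n_boot), function(b)
    lapply(ids, function(v) sample(v, length(v), replace = TRUE)))

  est <- matrix(NA_real_, n_boot, length(spec$free),
                dimnames = list(NULL, spec$free))
  for (b in seq_len(n_boot)) {
    db <- fit_data(datasets, participants = idx_draws[[b]])
    fb <- fit_model(db, spec_b,
                    extra_starts = matrix(fit0$estimate, nrow = 1))
    if (!is.na(fb$sse)) est[b, ] <- fb$estimate[spec$free]
  }
  structure(list(estimates = est,
                 sd = apply(est, 2, sd, na.rm = TRUE),
                 ci = apply(est, 2, quantile, c(0.025, 0.975), na.rm = TRUE),
                 fit = fit0, indices = idx_draws, seed = seed),
            class = "vmr_bootstrap")
}

#' Realistic recovery parameter ranges
#'
#' Uniform sampling ranges for the implicit-pathway parameters of the PPE
#' model used by [parameter_recovery()] and [confusion_models()], centered
#' on published point estimates (`k` about 0.204, `Bi` about 0.151) with a
#' retention range typical of implicit adaptation.
#'
#' @param design design name (currently the same ranges for all designs).
#' @return Named list of `c(lower, upper)` ranges.
#' @export
recovery_ranges <- function(design = "exp1") {
  list(k = c(0.10, 0.35), Ai = c(0.90, 0.995), Bi = c(0.08, 0.25))
}

draw_in_ranges <- function(ranges) {
  vapply(ranges, function(r) runif(1, r[1], r[2]), numeric(1))
}

recovery_conditions <- function(design) {
  switch(design,
         exp1 = list(design = "exp1", conditions = c(15, 30, 60, 90)),
         exp4 = list(design = "exp4", conditions = c(45, 90)),
         exp6 = list(design = "exp6", conditions = c(15, 30, 90)),
         bond2015 = list(design = "bond2015", conditions = c(15, 30, 60, 90)),
         stop("no default condition set for design ", design, call. = FALSE))
}

sim_design_group <- function(design, conditions, params, noise, n_per_group,
                             seed) {
  lapply(seq_along(conditions), function(j)
    simulate_group(design, conditions[j], params, noise,
                   n_participants = n_per_group,
                   seed = (seed + 7717 * j) %% 2147483647))
}

#' Parameter recovery study
#'
#' Draws true parameter values uniformly within `ranges`, simulates group
#' datasets for every condition of the design with motor noise, refits the
#' model to the condition means, and measures the agreement between
#' simulated and recovered values per parameter with Lin's [concordance()].
#'
#' @param design design name (e.g. `"exp1"`, `"exp4"`).
#' @param conditions condition vector; defaults to the design's standard set.
#' @param model_kind generative and fitted model kind.
#' @param ranges named list of `c(lower, upper)` per free parameter (see
#'   [recovery_ranges()]); parameters not listed are held at the defaults of
#'   [fit_spec()]'s `fixed`.
#' @param noise a [noise_spec()].
#' @param n_sims number of simulated datasets, `>= 20`.
#' @param n_per_group participants per condition group.
#' @param seed integer seed.
#' @param spec optional [fit_spec()] template; `free` is replaced by
#'   `names(ranges)`.
#' @param n_starts multi-starts per fit (the true values are always added
#'   as a start, mirroring a practitioner's informed initialization).
#' @return A `vmr_recovery` with per-parameter `ccc`, the `truth` and
#'   `recovered` matrices, and `n_sims`.
#' @export
parameter_recovery <- function(design, conditions = NULL,
                               model_kind = "PPE",
                               ranges = recovery_ranges(design),
                               noise = noise_spec(), n_sims = 100,
                               n_per_group = 15, seed = 1L,
                               spec = NULL, n_starts = 3) {
  if (n_sims < 20) stop("n_sims must be >= 20", call. = FALSE)
  if (any(vapply(ranges, function(r) diff(r) <= 0, logical(1))))
    warning("degenerate (zero-width) range: CCC undefined for that parameter")
  if (is.null(conditions)) conditions <- recovery_conditions(design)$conditions
  if (is.null(spec))
    spec <- fit_spec(model_kind = model_kind, free = names(ranges),
                     channels = if (design == "exp4") "total"
                                else c("total", "implicit"),
                     n_starts = n_starts)
  spec$free <- names(ranges)
  spec$lower <- spec$lower[names(ranges)]
  spec$upper <- spec$upper[names(ranges)]
  spec$n_starts <- n_starts

  truth <- matrix(NA_real_, n_sims, length(ranges),
                  dimnames = list(NULL, names(ranges)))
  rec <- truth
  set.seed(as.integer(seed))
  sim_seeds <- sample.int(2147483646, n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(sim_seeds[s])
    tv <- draw_in_ranges(ranges)
    params <- build_params(spec, tv)
    dsl <- sim_design_group(design, conditions, params, noise, n_per_group,
                            seed = sim_seeds[s])
    spec_s <- spec
    spec_s$seed <- sim_seeds[s]
    fit <- fit_model(fit_data(dsl), spec_s,
                     extra_starts = matrix(tv, nrow = 1))
    truth[s, ] <- tv
    if (!is.na(fit$sse)) rec[s, ] <- fit$estimate[names(ranges)]
  }
  ok <- stats::complete.cases(rec)
  ccc <- vapply(names(ranges), function(nm)
    concordance(truth[ok, nm], rec[ok, nm]), numeric(1))
  structure(list(ccc = ccc, truth = truth, recovered = rec,
                 n_sims = n_sims, design = design, seed = seed),
            class = "vmr_recovery")
}

#' @export
print.vmr_recovery <- function(x, ...) {
  cat(sprintf("<vmr_recovery> %s, %d simulations\n", x$design, x$n_sims))
  print(round(x$ccc, 4))
  invisible(x)
}

#' Model-confusion analysis
#'
#' Simulates datasets from each generative model (parameters drawn within
#' `ranges`, visual-uncertainty slope only where the model uses one), fits
#' every candidate model, selects the fit with the lowest BIC (ties broken
#' toward the model with fewer free parameters), and tabulates the selection
#' proportions. Rows are generative models, columns selected models; each
#' row sums to 1.
#'
#' @inheritParams parameter_recovery
#' @param generative character vector of generative model kinds (also the
#'   candidate set), `>= 2` unless a single-candidate identity check is
#'   wanted.
#' @param n_sims simulations per generative model.
#' @return A `vmr_confusion` with the proportion `matrix`, `n_sims`, and a
#'   `ties` count.
#' @export
confusion_models <- function(design, conditions = NULL,
                             generative = c("PPE", "PE", "SPE"),
                             ranges = recovery_ranges(design),
                             noise = noise_spec(), n_sims = 50,
                             n_per_group = 15, seed = 1L, n_starts = 3) {
  if (is.null(conditions)) conditions <- recovery_conditions(design)$conditions
  channels <- if (design == "exp4") "total" else c("total", "implicit")
  free_for <- function(kind) if (kind == "PPE") c("k", "Ai", "Bi") else c("Ai", "Bi")

  cm <- matrix(0, length(generative), length(generative),
               dimnames = list(generative, generative))
  ties <- 0L
  set.seed(as.integer(seed))
  sim_seeds <- matrix(sample.int(2147483646, length(generative) * n_sims),
                      nrow = length(generative))
  for (g in seq_along(generative)) {
    gkind <- generative[g]
    granges <- ranges[intersect(names(ranges), free_for(gkind))]
    for (s in seq_len(n_sims)) {
      set.seed(sim_seeds[g, s])
      tv <- draw_in_ranges(granges)
      gspec <- fit_spec(model_kind = gkind, free = names(granges),
                        channels = channels, n_starts = n_starts,
                        seed = sim_seeds[g, s])
      params <- build_params(gspec, tv)
      dsl <- sim_design_group(design, conditions, params, noise,
                              n_per_group, seed = sim_seeds[g, s])
      dat <- fit_data(dsl)
      bics <- ps <- numeric(length(generative))
      for (cnd in seq_along(generative)) {
        ckind <- generative[cnd]
        cspec <- fit_spec(model_kind = ckind, free = free_for(ckind),
                          channels = channels, n_starts = n_starts,
                          seed = sim_seeds[g, s])
        starts <- if (ckind == gkind) matrix(tv, nrow = 1) else NULL
        f <- fit_model(dat, cspec, extra_starts = starts)
        bics[cnd] <- if (is.na(f$sse)) Inf else goodness(f)$BIC
        ps[cnd] <- length(free_for(ckind))
      }
      winners <- which(bics == min(bics))
      if (length(winners) > 1) {
        ties <- ties + 1L
        winners <- winners[which.min(ps[winners])]
      }
      cm[g, winners[1]] <- cm[g, winners[1]] + 1
    }
  }
  structure(list(matrix = cm / n_sims, n_sims = n_sims, ties = ties,
                 design = design, seed = seed),
            class = "vmr_confusion")
}

#' @export
print.vmr_confusion <- function(x, ...) {
  cat(sprintf("<vmr_confusion> %s, %d simulations per generative model (rows)\n",
              x$design, x$n_sims))
  print(round(x$matrix, 3))
  if (x$ties > 0) cat(sprintf("  %d BIC tie(s) broken toward fewer parameters\n",
                              x$ties))
  invisible(x)
}

#' Linear regression of learning on perturbation size
#'
#' Ordinary least squares of single-trial learning against perturbation
#' size, the summary used to test whether the size dependence is linear.
#'
#' @param table data frame with columns `size` and `learning` (as from
#'   [single_trial_learning()]), at least 3 rows and 2 distinct sizes.
#' @return List with `intercept`, `slope`, `R2`.
#' @export
size_dependency_regression <- function(table) {
  if (nrow(table) < 3 || length(unique(table$size)) < 2)
    stop("need >= 3 rows and >= 2 distinct sizes", call. = FALSE)
  fit <- lm(learning ~ size, data = table)
  # exact lines are legitimate inputs (closed-form model tables)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       R2 = r2)
}
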