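# Objective, constrained optimization, held-out prediction.

test_that("the objective is zero at the generating parameters", {
  p <- model_params(k = 0.25, Ai = 0.96, Bi = 0.12)
  dat <- fit_data(quiet_dataset("exp1", 30, p), quiet_dataset("exp1", 60, p))
  spec <- fit_spec("PPE", free = c("k", "Ai", "Bi"))
  expect_equal(objective_sse(c(k = 0.25, Ai = 0.96, Bi = 0.12), dat, spec), 0,
               tolerance = 1e-18)
  # quadratic form: perturbing one observed point by delta adds delta^2
  dat2 <- dat
  idx <- which(!is.na(dat2[[1]]$obs$hand_deg) &
                 dat2[[1]]$obs$trial_type == "feedback")[10]
  dat2[[1]]$obs$hand_deg[idx] <- dat2[[1]]$obs$hand_deg[idx] + 0.5
  expect_equal(objective_sse(c(k = 0.25, Ai = 0.96, Bi = 0.12), dat2, spec),
               0.25, tolerance = 1e-10)
})

test_that("clamping explicit to the model's own series reproduces the SSE", {
  # bond-style data carry a per-trial aiming report; clamping to those
  # observed values must equal the unclamped implicit objective when the
  # observed explicit is exactly the model's explicit
  p <- model_params(k = 0.2, Ai = 0.97, Bi = 0.15)
  ds <- quiet_dataset("bond2015", 30, p, n = 1)
  dat <- fit_data(ds)
  spec_cl <- fit_spec("PPE", free = c("k", "Ai", "Bi"),
                      channels = "total", clamp_explicit = TRUE)
  expect_equal(objective_sse(c(k = 0.2, Ai = 0.97, Bi = 0.15), dat, spec_cl),
               0, tolerance = 1e-16)
  # and at wrong implicit parameters the clamped SSE is positive
  expect_gt(objective_sse(c(k = 0.2, Ai = 0.97, Bi = 0.05), dat, spec_cl), 1)
})

test_that("noise-free self-generated data are recovered exactly", {
  cases <- list(
    list(kind = "PPE", free = c("k", "Ai", "Bi"),
         truth = c(k = 0.25, Ai = 0.96, Bi = 0.12)),
    list(kind = "PE", free = c("Ai", "Bi"),
         truth = c(Ai = 0.95, Bi = 0.1)),
    list(kind = "SPE", free = c("Ai", "Bi"),
         truth = c(Ai = 0.93, Bi = 0.08)))
  for (cs in cases) {
    p <- do.call(model_params,
                 c(as.list(cs$truth), list(model_kind = cs$kind)))
    dsl <- lapply(c(30, 60), function(r)
      quiet_dataset("exp1", r, p, n = 1))
    f <- fit_model(fit_data(dsl),
                   fit_spec(cs$kind, free = cs$free, n_starts = 5, seed = 2))
    expect_lt(f$sse, 1e-8)
    expect_equal(unname(f$estimate[names(cs$truth)]), unname(cs$truth),
                 tolerance = 1e-3)
  }
})

test_that("bounds and pathway-order constraints are respected", {
  # five-parameter fit with the ratio reparameterization: Ae < Ai, Bi < Be
  p <- model_params(k = 0.2, Ai = 0.97, Bi = 0.14, Ae = 0.75, Be = 0.45)
  dsl <- lapply(c(30, 90), function(r) quiet_dataset("exp1", r, p, n = 1))
  spec <- fit_spec("PPE", free = c("k", "Ai", "Bi", "Ae", "Be"),
                   n_starts = 6, seed = 5)
  f <- fit_model(fit_data(dsl), spec,
                 extra_starts = matrix(c(0.2, 0.97, 0.14, 0.75, 0.45), 1))
  expect_lt(f$sse, 1e-6)
  expect_lt(f$estimate[["Ae"]], f$estimate[["Ai"]])
  expect_gt(f$estimate[["Be"]], f$estimate[["Bi"]])
  expect_equal(unname(f$estimate[c("k", "Ai", "Bi", "Ae", "Be")]),
               c(0.2, 0.97, 0.14, 0.75, 0.45), tolerance = 5e-3)
  # Ai lower-bound option used for the single-trial design
  spec3 <- fit_spec("PPE", free = c("k", "Ai", "Bi"), Ai_min = 0.7)
  expect_equal(unname(spec3$lower["Ai"]), 0.7)
})

test_that("the SSE is invariant to a global CW/CCW sign flip", {
  p <- model_params()
  ds <- noisy_dataset("exp1", 30, n = 3, seed = 21)
  dat <- fit_data(ds)
  dat_flip <- dat
  dat_flip[[1]]$schedule$rotation_deg <- -dat_flip[[1]]$schedule$rotation_deg
  dat_flip[[1]]$schedule$aim_reference <- -dat_flip[[1]]$schedule$aim_reference
  dat_flip[[1]]$obs$hand_deg <- -dat_flip[[1]]$obs$hand_deg
  dat_flip[[1]]$obs$aim_report_deg <- -dat_flip[[1]]$obs$aim_report_deg
  spec <- fit_spec("PPE", free = c("k", "Ai", "Bi"))
  v <- c(k = 0.2, Ai = 0.95, Bi = 0.12)
  expect_equal(objective_sse(v, dat, spec), objective_sse(v, dat_flip, spec),
               tolerance = 1e-9)
})

test_that("adding a free parameter never increases the minimized SSE", {
  ds <- noisy_dataset("exp1", 30, n = 4, seed = 13)
  dat <- fit_data(ds)
  f2 <- fit_model(dat, fit_spec("PPE", free = c("Ai", "Bi"),
                                n_starts = 4, seed = 3))
  start3 <- matrix(c(0.204, f2$estimate[["Ai"]], f2$estimate[["Bi"]]), 1)
  f3 <- fit_model(dat, fit_spec("PPE", free = c("k", "Ai", "Bi"),
                                n_starts = 4, seed = 3),
                  extra_starts = start3)
  expect_lte(f3$sse, f2$sse + 1e-8)
})

test_that("held-out prediction reproduces the training trajectory", {
  p <- model_params(k = 0.22, Ai = 0.95, Bi = 0.13)
  ds <- quiet_dataset("exp2_stepwise", NULL, p, n = 1)
  f <- fit_model(fit_data(ds),
                 fit_spec("PPE", free = c("k", "Ai", "Bi"),
                          n_starts = 4, seed = 6))
  pred <- predict_heldout(f, ds$schedule)
  traj <- simulate_trajectory(ds$schedule, p)
  expect_equal(pred$hand, traj$hand, tolerance = 1e-4)
  # cross-design transfer: a stepwise fit predicts smaller one-step implicit
  # learning at matched 60 degrees under the PPE model
  pred_on <- predict_heldout(f, build_schedule("exp2_onestep"))
  excl <- which(pred$trial_type == "exclusion")
  last_block <- utils::tail(excl, 2)
  expect_gt(mean(pred$x_i[last_block]), mean(pred_on$x_i[last_block]))
  # parameter override switches the uncertainty slope
  pred_k <- predict_heldout(f, ds$schedule, override = list(k = 0))
  expect_false(isTRUE(all.equal(pred_k$x_i, pred$x_i)))
})
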