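# Cue integration, error definitions, and one-trial updates.

test_that("visual uncertainty follows the linear form and its variants", {
  expect_equal(visual_uncertainty(0.204, 1.853, 0), 1.853)
  expect_equal(visual_uncertainty(0.204, 1.853, 30), 7.973)
  expect_equal(visual_uncertainty(0, 1.853, 90), 1.853)
  # nonlinear forms: equal b at zero eccentricity, monotone nondecreasing
  ecc <- seq(0, 90, by = 5)
  for (form in c("exponential", "power_law")) {
    sv <- visual_uncertainty(0.05, 1.853, ecc, form = form, gamma = 0.8)
    expect_equal(sv[1], 1.853)
    expect_true(all(diff(sv) >= 0))
  }
  expect_error(visual_uncertainty(0.2, 1.853, -1), "eccentricity")
  expect_error(visual_uncertainty(0.2, 0, 10), "b must")
  expect_error(visual_uncertainty(-0.1, 1.853, 10), "k must")
})

test_that("cue weights are inverse-variance normalized", {
  expect_equal(unname(cue_weights(5, 5, 5)), rep(1 / 3, 3))
  w <- cue_weights(5.05, 11.12, 1.853)
  expect_equal(unname(w), c(0.115827, 0.023888, 0.860285), tolerance = 1e-5)
  # infinitely unreliable visual cue is ignored
  w_inf <- cue_weights(5.05, 11.12, Inf)
  expect_equal(w_inf[["W_v"]], 0)
  expect_equal(sum(w_inf), 1)
  expect_equal(w_inf[["W_u"]] / w_inf[["W_p"]], (11.12 / 5.05)^2)
  expect_error(cue_weights(0, 5, 5), "must be > 0")
})

test_that("cue weights normalize and stay in [0,1] over random sigma triples", {
  set.seed(42)
  for (i in 1:200) {
    s <- runif(3, 0.01, 100)
    w <- cue_weights(s[1], s[2], s[3])
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("perceived hand is a convex combination of the cues", {
  w <- cue_weights(5, 7, 9)
  expect_equal(perceived_hand(10, 10, 10, w), 10)
  # frozen worked example: zero states, 30 deg rotation
  w30 <- cue_weights(5.05, 11.12, visual_uncertainty(0.204, 1.853, 30))
  expect_equal(perceived_hand(0, 0, -30, w30), -7.487401, tolerance = 1e-6)
  expect_equal(perceived_hand(1, 2, -30, c(0, 0, 1)), -30)
  set.seed(1)
  for (i in 1:100) {
    cues <- runif(3, -90, 90)
    w <- cue_weights(runif(1, 1, 20), runif(1, 1, 20), runif(1, 1, 20))
    ph <- perceived_hand(cues[1], cues[2], cues[3], w)
    expect_gte(ph, min(cues) - 1e-12)
    expect_lte(ph, max(cues) + 1e-12)
  }
})

test_that("trial errors follow the target-relative countering-positive frame", {
  p <- model_params()
  e <- trial_errors(learning_state(), 30, p)
  expect_equal(e$e_pe, -30)
  expect_equal(e$e_spe, -30)
  expect_equal(e$e_ppe, -7.487401, tolerance = 1e-6)
  expect_equal(e$sigma_v, 7.973)

  e0 <- trial_errors(learning_state(), 0, p)
  expect_equal(e0$e_pe, 0)
  expect_equal(e0$e_spe, 0)
  expect_equal(e0$e_ppe, 0)

  # instructed re-aiming at the offset matching the rotation: cursor hits
  # the original target, so PE vanishes while SPE equals the offset
  ei <- trial_errors(learning_state(), 45, p, regime = "instructed_reaiming",
                     aim_reference = 45)
  expect_equal(ei$e_pe, 0)
  expect_equal(ei$e_spe, -45)
  expect_equal(ei$e_pe_reaim, -45)
  expect_error(trial_errors(learning_state(), 45, p,
                            regime = "instructed_reaiming"),
               "aim_reference")

  # no-feedback trials report no errors
  en <- trial_errors(learning_state(5, 3), 30, p, regime = "no_feedback")
  expect_true(is.na(en$e_pe) && is.na(en$e_ppe))
})

test_that("the SPE identity holds under free aiming", {
  p <- model_params()
  set.seed(3)
  for (i in 1:50) {
    st <- learning_state(runif(1, -10, 60), runif(1, -5, 30))
    r <- runif(1, -90, 90)
    e <- trial_errors(st, r, p)
    expect_equal(e$e_spe, st$x_i - r, tolerance = 1e-12)
    # and equals the re-aiming PE when the reference is the explicit state
    ei <- trial_errors(st, r, p, regime = "instructed_reaiming",
                       aim_reference = st$x_e)
    expect_equal(ei$e_spe, ei$e_pe_reaim, tolerance = 1e-12)
  }
})

test_that("one-trial state updates match the model equations", {
  # PE model from rest: x_i' = -Bi * e_pe = Bi * r
  p_pe <- model_params(model_kind = "PE", Ai = 1, Bi = 0.151, check = FALSE)
  s <- learning_state()
  e <- trial_errors(s, 30, p_pe)
  expect_equal(step_state(s, e, p_pe)$x_i, 4.53)
  # PPE model from rest: x_i' = -Bi * e_ppe
  p_ppe <- model_params(Ai = 1, Bi = 0.151, check = FALSE)
  e2 <- trial_errors(s, 30, p_ppe)
  expect_equal(step_state(s, e2, p_ppe)$x_i, 1.130598, tolerance = 1e-6)
  # fixed point at the origin with zero errors
  e0 <- trial_errors(s, 0, p_ppe)
  s1 <- step_state(s, e0, p_ppe)
  expect_equal(c(s1$x_e, s1$x_i), c(0, 0))
  # retention-only decay on no-feedback trials
  st <- learning_state(10, 20)
  en <- trial_errors(st, 30, p_ppe, regime = "no_feedback")
  sd <- step_state(st, en, p_ppe)
  expect_equal(sd$x_e, p_ppe$Ae * 10)
  expect_equal(sd$x_i, p_ppe$Ai * 20)
  p_bad <- model_params()
  p_bad$model_kind <- "XX"
  expect_error(step_state(s, e, p_bad), "model_kind")
})

test_that("two-state implicit update combines PE-fast and SPE-slow pathways", {
  p <- model_params(model_kind = "TWO_STATE", Af = 1, Bf = 0.2,
                    As = 1, Bs = 0.05, check = FALSE)
  s <- learning_state(x_i_fast = 0, x_i_slow = 0)
  s0 <- two_state_implicit_step(s, 0, 0, p)
  expect_equal(s0$x_i, 0)
  s1 <- two_state_implicit_step(s, -30, -30, p)
  expect_equal(s1$x_i_fast, 6)
  expect_equal(s1$x_i_slow, 1.5)
  expect_equal(s1$x_i, 7.5)
  # Bs = 0 reduces the fast component to the PE model's implicit update
  p0 <- model_params(model_kind = "TWO_STATE", Af = 0.9, Bf = 0.151,
                     As = 1, Bs = 0, check = FALSE)
  s2 <- two_state_implicit_step(learning_state(x_i_fast = 5, x_i_slow = 0),
                                -30, -12, p0)
  expect_equal(s2$x_i_fast, 0.9 * 5 + 0.151 * 30)
  expect_equal(s2$x_i_slow, 0)
  expect_error(two_state_implicit_step(s, -1, -1, model_params()),
               "TWO_STATE")
})

test_that("single-trial response is linear for PE/SPE and nonmonotone for PPE", {
  r <- c(4, 8, 16, 32, 64)
  for (kind in c("PE", "SPE")) {
    p <- model_params(model_kind = kind, Ai = 1, Bi = 0.151, check = FALSE)
    expect_equal(single_trial_response(p, r), 0.151 * r, tolerance = 1e-12)
  }
  p <- model_params(Ai = 1, Bi = 0.151, check = FALSE)
  resp <- single_trial_response(p, r)
  # frozen closed-form values Bi * W_v(|r|) * r
  expect_equal(resp, c(0.4518, 0.7672, 1.0793, 1.1179, 0.8394),
               tolerance = 1e-4)
  # rises then falls over a dense grid up to 90 degrees
  grid <- single_trial_response(p, seq(1, 90, by = 1))
  peak <- which.max(grid)
  expect_gt(peak, 1)
  expect_lt(peak, 90)
  expect_true(all(diff(grid[1:peak]) > 0))
  expect_true(all(diff(grid[peak:90]) < 0))
})

test_that("the PPE model converges to the SPE model as vision becomes exact", {
  sched <- build_schedule("exp1", 30)
  p_spe <- model_params(model_kind = "SPE")
  t_spe <- simulate_trajectory(sched, p_spe)
  p_lim <- model_params(k = 0, b = 1e-7, sigma_u = 5.05, sigma_p = 11.12)
  t_lim <- simulate_trajectory(sched, p_lim)
  expect_equal(t_lim$x_i, t_spe$x_i, tolerance = 1e-4)
  expect_equal(t_lim$x_e, t_spe$x_e, tolerance = 1e-4)
})

test_that("predicted proprioceptive bias points toward the perturbation", {
  p <- model_params()
  expect_equal(predicted_proprioceptive_bias(learning_state(), 0, p), 0)
  b30 <- predicted_proprioceptive_bias(learning_state(), 30, p)
  expect_equal(b30, -7.487401, tolerance = 1e-6)
  # opposite in sign to the (positive) direction of learning, concave in size
  sizes <- c(15, 30, 60, 90)
  bias <- vapply(sizes, function(r)
    predicted_proprioceptive_bias(learning_state(), r, p), numeric(1))
  expect_true(all(bias < 0))
  mag <- -bias
  expect_true(which.max(mag) %in% 2:3)  # interior peak
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(model_params(Ai = 1.2), "\\[0, 1\\]")
  expect_error(model_params(b = 0), "b must")
  expect_error(model_params(Ae = 0.99, Ai = 0.9), "Ae < Ai")
  expect_error(model_params(Be = 0.1, Bi = 0.2), "Ae < Ai|Be > Bi")
  expect_silent(model_params(Ae = 0.99, Ai = 0.9, check = FALSE))
  expect_error(model_params(model_kind = "TWO_STATE"), "requires Af")
})
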