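# Simulator: engines, determinism, noise handling, measure extraction.

test_that("compiled and pure-R recursions agree trial by trial", {
  scheds <- list(build_schedule("exp1", 60),
                 build_schedule("exp2_stepwise"),
                 build_schedule("exp3"),
                 build_schedule("exp4", 45),
                 build_schedule("exp5"))
  kinds <- c("PPE", "PE", "SPE")
  set.seed(8)
  for (s in scheds) {
    for (kind in kinds) {
      p <- model_params(model_kind = kind,
                        Ai = runif(1, 0.9, 0.99), Bi = runif(1, 0.05, 0.2),
                        k = runif(1, 0.05, 0.4))
      a <- simulate_trajectory(s, p, engine = "cpp")
      b <- simulate_trajectory(s, p, engine = "r")
      for (col in c("x_e", "x_i", "hand", "e_pe", "e_spe", "e_ppe"))
        expect_equal(a[[col]], b[[col]], tolerance = 1e-12)
    }
  }
  # two-state variant as well
  p2 <- model_params(model_kind = "TWO_STATE", Af = 0.7, Bf = 0.2,
                     As = 0.99, Bs = 0.05)
  a <- simulate_trajectory(scheds[[1]], p2, engine = "cpp")
  b <- simulate_trajectory(scheds[[1]], p2, engine = "r")
  expect_equal(a$x_i, b$x_i, tolerance = 1e-12)
  expect_equal(a$x_i_fast + a$x_i_slow, a$x_i, tolerance = 1e-12)
})

test_that("zero rotation with zero noise stays at the origin", {
  s <- build_schedule("exp1", 30)
  s$rotation_deg[] <- 0
  rec <- simulate_participant(s, model_params(), noise_spec(0, 0), seed = 1)
  move <- rec$trial_type != "prop_test"
  expect_true(all(abs(rec$hand_deg[move]) < 1e-12))
  expect_true(all(abs(rec$x_i_true) < 1e-12))
})

test_that("simulation is deterministic given the seed", {
  s <- build_schedule("exp1", 30)
  a <- simulate_participant(s, model_params(), noise_spec(4, 2), seed = 11)
  b <- simulate_participant(s, model_params(), noise_spec(4, 2), seed = 11)
  expect_identical(a, b)
  c <- simulate_participant(s, model_params(), noise_spec(4, 2), seed = 12)
  expect_false(isTRUE(all.equal(a$hand_deg, c$hand_deg)))
  g1 <- simulate_group("exp1", 30, n_participants = 3, seed = 5)
  g2 <- simulate_group("exp1", 30, n_participants = 3, seed = 5)
  expect_identical(g1$trials, g2$trials)
})

test_that("noise perturbs observables but never the latent states", {
  s <- build_schedule("exp1", 30)
  quiet <- simulate_participant(s, model_params(), noise_spec(0, 0), seed = 3)
  loud <- simulate_participant(s, model_params(), noise_spec(6, 3), seed = 3)
  expect_equal(loud$x_e_true, quiet$x_e_true)
  expect_equal(loud$x_i_true, quiet$x_i_true)
  move <- s$trial_type %in% c("feedback", "aiming_report")
  expect_false(isTRUE(all.equal(loud$hand_deg[move], quiet$hand_deg[move])))
})

test_that("group means shrink toward the deterministic trajectory as 1/sqrt(n)", {
  # Monte-Carlo: residual SD of the mean curve halves from n to 4n
  p <- model_params()
  traj <- simulate_trajectory(build_schedule("exp1", 30), p)
  resid_sd <- function(n, seed) {
    ds <- simulate_group("exp1", 30, p, noise_spec(4, 0),
                         n_participants = n, seed = seed)
    mm <- condition_means(ds)
    keep <- !is.na(traj$hand)
    sd(mm$hand_deg[keep] - traj$hand[keep])
  }
  r5 <- mean(vapply(1:4, function(s) resid_sd(5, s), numeric(1)))
  r20 <- mean(vapply(1:4, function(s) resid_sd(20, s), numeric(1)))
  expect_equal(r5 / r20, 2, tolerance = 0.35)
  # zero-noise group mean equals the deterministic trajectory exactly
  ds0 <- simulate_group("exp1", 30, p, noise_spec(0, 0),
                        n_participants = 3, seed = 1)
  mm0 <- condition_means(ds0)
  keep <- !is.na(traj$hand)
  expect_equal(mm0$hand_deg[keep], traj$hand[keep], tolerance = 1e-10)
})

test_that("noise-free measures equal the latent truth", {
  ds <- quiet_dataset("exp1", 30)
  m <- extract_measures(ds)
  traj <- simulate_trajectory(ds$schedule, ds$params)
  # implicit measure = latent x_i at exclusion trials
  excl <- ds$schedule$trial[ds$schedule$trial_type == "exclusion"]
  expect_equal(unique(round(m$implicit$value, 10)),
               round(mean(traj$x_i[excl]), 10))
  # proprioceptive bias equals the model-predicted perceptual bias
  expect_true(all(m$prop_bias$value < 0))
  # extraction does not mutate the records
  before <- ds$trials
  invisible(extract_measures(ds))
  expect_identical(ds$trials, before)
})

test_that("probe-trial PPE measure equals the model's perceptual error", {
  ds <- quiet_dataset("exp6", 30)
  m <- extract_measures(ds, "probe_ppe")
  traj <- simulate_trajectory(ds$schedule, ds$params)
  probes <- ds$schedule$trial[ds$schedule$trial_type == "probe" &
                                ds$schedule$phase == "adaptation"]
  expected <- mean(traj$e_ppe[probes])
  expect_equal(unique(round(m$value, 10)), round(expected, 10))
  expect_true(all(m$value < 0))  # percept pulled toward the perturbation
  expect_error(extract_measures(quiet_dataset("exp1", 30), "probe_ppe"),
               "not available")
})

test_that("single-trial learning recovers the closed-form size response", {
  p <- model_params(model_kind = "PE", Ai = 1, Bi = 0.151, Ae = 0, Be = 0,
                    check = FALSE)
  ds <- simulate_group("exp3", params = p, noise = noise_spec(0, 0),
                       n_participants = 1, seed = 2)
  tab <- single_trial_learning(ds)
  expect_equal(tab$size, c(0, 4, 8, 16, 32, 64))
  # with perfect retention and no explicit learning the measured response
  # tracks Bi * r up to carry-over from the zero-mean sequence
  expect_equal(tab$learning[-1], 0.151 * tab$size[-1], tolerance = 0.12)
  # the zero-size rows stay small relative to the largest response
  # (deterministic carry-over from the fixed zero-mean sequence remains)
  expect_lt(abs(tab$learning[1]), 0.15 * max(tab$learning))

  p_ppe <- model_params(Ai = 1, Bi = 0.151, Ae = 0, Be = 0, check = FALSE)
  ds2 <- simulate_group("exp3", params = p_ppe, noise = noise_spec(0, 0),
                        n_participants = 1, seed = 2)
  tab2 <- single_trial_learning(ds2)
  closed <- single_trial_response(p_ppe, tab2$size[-1])
  expect_equal(tab2$learning[-1], closed, tolerance = 0.12)
  # nonmonotone: the response drops from 32 to 64 degrees
  expect_lt(tab2$learning[tab2$size == 64], tab2$learning[tab2$size == 32])
  expect_error(single_trial_learning(quiet_dataset("exp1", 30)), "exp3")
})

test_that("exp5 aim reference resolves to the last reported aim", {
  p <- model_params()
  sched <- build_schedule("exp5")
  traj <- simulate_trajectory(sched, p)
  reports <- which(sched$trial_type == "aiming_report")
  re <- which(sched$phase == "reaiming")
  expect_equal(traj$x_e[re[1]], traj$x_e[max(reports)], tolerance = 1e-10)
  # explicit stays clamped throughout the instructed phase
  expect_true(all(abs(diff(traj$x_e[re])) < 1e-12))
})
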