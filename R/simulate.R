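#' Noise-free model trajectory over a schedule
#'
#' Runs the deterministic trial-by-trial recursion of the chosen model over a
#' schedule, starting from zero states. On feedback trials the states are
#' updated from the model's error signal; on no-feedback trials (exclusion,
#' null, washout, proprioception tests) both states decay by their retention
#' rates. The executed hand is `x_e + x_i` on free-aiming feedback trials,
#' `aim_reference + x_i` under instructed re-aiming, and `x_i` on
#' no-feedback movement trials (the participant aims straight at the
#' target).
#'
#' If the schedule contains instructed trials with `NA` aim reference (the
#' late re-aiming design), the reference is resolved to the explicit state at
#' the last aiming-report trial preceding the instructed phase.
#'
#' @param schedule a [build_schedule()] result.
#' @param params a [model_params()].
#' @param clamp_explicit optional per-trial explicit series (length
#'   `nrow(schedule)`) overriding the model's explicit state, used when
#'   explicit learning is treated as known data.
#' @param pe_reaiming see [step_state()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation built from [trial_errors()] and [step_state()]).
#' @return A data frame with one row per trial: latent states `x_e`, `x_i`
#'   (and fast/slow components), executed `hand`, `cursor`, the four error
#'   signals, `sigma_v`, and the `perceived` hand direction.
#' @examples
#' traj <- simulate_trajectory(build_schedule("exp1", 30), model_params())
#' tail(traj$x_i)
#' @export
simulate_trajectory <- function(schedule, params, clamp_explicit = NULL,
                                pe_reaiming = TRUE,
                                engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(schedule, "vmr_schedule"))
  schedule <- resolve_aim_reference(schedule, params, clamp_explicit,
                                    pe_reaiming)
  n <- nrow(schedule)
  if (!is.null(clamp_explicit) && length(clamp_explicit) != n)
    stop("clamp_explicit must have one value per trial", call. = FALSE)
  codes <- schedule_trial_codes(schedule)
  instr <- as.integer(schedule$regime == "instructed_reaiming")
  aim <- schedule$aim_reference
  aim[is.na(aim)] <- 0
  if (engine == "cpp") {
    pl <- c(unclass(params),
            list(kind = match(params$model_kind,
                              c("PPE", "PE", "SPE", "TWO_STATE")) - 1L,
                 form = match(params$uncertainty_form,
                              c("linear", "exponential", "power_law")) - 1L))
    pl$Af <- if (is.na(pl$Af)) 0 else pl$Af
    pl$Bf <- if (is.na(pl$Bf)) 0 else pl$Bf
    pl$As <- if (is.na(pl$As)) 0 else pl$As
    pl$Bs <- if (is.na(pl$Bs)) 0 else pl$Bs
    m <- .sim_trajectory_cpp(schedule$rotation_deg, codes, instr, aim, pl,
                             if (is.null(clamp_explicit)) numeric(0)
                             else clamp_explicit,
                             pe_reaiming)
    out <- as.data.frame(m)
  } else {
    out <- sim_trajectory_r(schedule, params, codes, instr, aim,
                            clamp_explicit, pe_reaiming)
  }
  out$trial <- schedule$trial
  out$trial_type <- schedule$trial_type
  out$phase <- schedule$phase
  out$rotation_deg <- schedule$rotation_deg
  out
}

# Pure-R reference recursion; the oracle against which the compiled engine
# is tested. One trial at a time through trial_errors()/step_state().
sim_trajectory_r <- function(schedule, params, codes, instr, aim,
                             clamp_explicit, pe_reaiming) {
  n <- nrow(schedule)
  cols <- c("x_e", "x_i", "hand", "cursor", "e_pe", "e_spe", "e_pe_reaim",
            "e_ppe", "sigma_v", "perceived", "x_i_fast", "x_i_slow")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  two <- params$model_kind == "TWO_STATE"
  st <- if (two) learning_state(x_i_fast = 0, x_i_slow = 0) else learning_state()
  for (t in seq_len(n)) {
    if (!is.null(clamp_explicit)) st$x_e <- clamp_explicit[t]
    if (instr[t] == 1) st$x_e <- aim[t]
    st$x <- st$x_e + st$x_i
    regime <- if (codes[t] != 0L) "no_feedback"
              else if (instr[t] == 1) "instructed_reaiming" else "free_aiming"
    e <- trial_errors(st, schedule$rotation_deg[t], params, regime = regime,
                      aim_reference = if (instr[t] == 1) aim[t] else NULL)
    out[t, "x_e"] <- st$x_e
    out[t, "x_i"] <- st$x_i
    if (two) { out[t, "x_i_fast"] <- st$x_i_fast; out[t, "x_i_slow"] <- st$x_i_slow }
    out[t, "hand"] <- if (codes[t] == 0L) e$hand
                      else if (codes[t] == 1L) st$x_i else NA_real_
    out[t, "cursor"] <- e$x_v
    out[t, "e_pe"] <- e$e_pe; out[t, "e_spe"] <- e$e_spe
    out[t, "e_pe_reaim"] <- e$e_pe_reaim; out[t, "e_ppe"] <- e$e_ppe
    out[t, "sigma_v"] <- e$sigma_v; out[t, "perceived"] <- e$perceived
    st_new <- step_state(st, e, params, regime = regime,
                         aim_reference = if (instr[t] == 1) aim[t] else NULL,
                         pe_reaiming = pe_reaiming)
    if (!is.null(clamp_explicit)) st_new$x_e <- st$x_e
    st <- st_new
  }
  as.data.frame(out)
}

# Resolve NA aim references of an instructed phase to the explicit state at
# the last aiming-report trial before that phase (the participant's last
# reported aim).
resolve_aim_reference <- function(schedule, params, clamp_explicit,
                                  pe_reaiming) {
  open <- schedule$regime == "instructed_reaiming" & is.na(schedule$aim_reference)
  if (!any(open)) return(schedule)
  first_instr <- min(which(open))
  prefix <- schedule[seq_len(first_instr - 1L), , drop = FALSE]
  class(prefix) <- class(schedule)
  traj <- simulate_trajectory(prefix, params,
                              clamp_explicit = clamp_explicit[seq_len(first_instr - 1L)],
                              pe_reaiming = pe_reaiming)
  reports <- which(prefix$trial_type == "aiming_report")
  ref <- if (length(reports)) traj$x_e[max(reports)] else traj$x_e[first_instr - 1L]
  schedule$aim_reference[open] <- ref
  schedule
}

#' Noise specification for the simulator
#'
#' @param sigma_motor standard deviation of trial-to-trial motor execution
#'   noise in degrees (added to executed hand directions, never to the
#'   latent states). Default 4, a typical baseline reach variability.
#' @param sigma_report standard deviation of report noise in degrees (added
#'   to aiming reports and perceptual reports). Default 2.
#' @return A `vmr_noise` list.
#' @export
noise_spec <- function(sigma_motor = 4, sigma_report = 2) {
  if (sigma_motor < 0 || sigma_report < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  structure(list(sigma_motor = sigma_motor, sigma_report = sigma_report),
            class = "vmr_noise")
}

#' Simulate one participant
#'
#' Runs the deterministic recursion over the schedule and adds measurement
#' noise to the executed and reported quantities. Latent states are retained
#' in the output for oracle checks. The executed hand on movement trials is
#' the deterministic hand plus motor noise; aiming reports are the explicit
#' state (or instructed direction) plus report noise; the perceptual report
#' on probe trials is the model's perceived hand plus report noise (computed
#' without the visual cue on no-feedback probes); proprioception-test
#' reports are the passive target location plus the model-predicted bias
#' carried over from the preceding feedback trial, plus report noise.
#'
#' @param schedule a [build_schedule()] result.
#' @param params a [model_params()].
#' @param noise a [noise_spec()].
#' @param seed integer seed; identical seeds give identical records.
#' @param participant_id identifier stored in the records.
#' @param pe_reaiming see [step_state()].
#' @return A data frame of trial records (one row per trial) with columns
#'   `participant_id`, `condition`, `trial`, `cycle`, `trial_type`,
#'   `rotation_deg`, `hand_deg`, `aim_report_deg`, `percept_report_deg`,
#'   `regime`, plus latent `x_e_true`, `x_i_true`.
#' @export
simulate_participant <- function(schedule, params, noise = noise_spec(),
                                 seed = 1L, participant_id = "p1",
                                 pe_reaiming = TRUE) {
  stopifnot(inherits(schedule, "vmr_schedule"))
  set.seed(as.integer(seed))
  traj <- simulate_trajectory(schedule, params, pe_reaiming = pe_reaiming)
  n <- nrow(schedule)
  codes <- schedule_trial_codes(schedule)
  hand <- traj$hand
  move <- codes %in% c(0L, 1L)
  hand[move] <- hand[move] + rnorm(sum(move), 0, noise$sigma_motor)

  aim_rep <- rep(NA_real_, n)
  pct_rep <- rep(NA_real_, n)

  # aiming reports: the participant's re-aiming intention
  rep_tr <- schedule$trial_type == "aiming_report" |
    (schedule$trial_type == "probe")
  x_u <- ifelse(schedule$regime == "instructed_reaiming",
                schedule$aim_reference, traj$x_e)
  aim_rep[rep_tr] <- x_u[rep_tr] + rnorm(sum(rep_tr), 0, noise$sigma_report)

  # probe trials: post-movement hand-percept report
  pr <- which(schedule$trial_type == "probe")
  if (length(pr)) {
    percept <- traj$perceived[pr]
    nf <- is.na(percept)  # no-feedback probes: integrate prediction + proprioception
    if (any(nf)) {
      w_np <- cue_weights(params$sigma_u, params$sigma_p, Inf)[1:2]
      w_np <- w_np / sum(w_np)
      # aimed at the target (x_u = 0), hand = x_i
      percept[nf] <- w_np[[2]] * traj$x_i[pr[nf]]
    }
    pct_rep[pr] <- percept + rnorm(length(pr), 0, noise$sigma_report)
  }

  # proprioception tests: passive hand placed near the target; the judgment
  # inherits the localization bias of the preceding feedback trial
  pt <- which(schedule$trial_type == "prop_test")
  if (length(pt)) {
    passive <- rep(c(-5, 5, -15, 15), length.out = length(pt))
    fb_trials <- which(codes == 0L)
    for (j in seq_along(pt)) {
      prev <- fb_trials[fb_trials < pt[j]]
      bias <- if (length(prev)) {
        pv <- max(prev)
        traj$perceived[pv] - traj$hand[pv]
      } else 0
      hand[pt[j]] <- passive[j]
      pct_rep[pt[j]] <- passive[j] + bias + rnorm(1, 0, noise$sigma_report)
    }
  }

  data.frame(participant_id = participant_id,
             condition = as.character(attr(schedule, "condition")),
             trial = schedule$trial, cycle = schedule$cycle,
             trial_type = schedule$trial_type,
             rotation_deg = schedule$rotation_deg,
             hand_deg = hand, aim_report_deg = aim_rep,
             percept_report_deg = pct_rep,
             regime = schedule$regime,
             x_e_true = traj$x_e, x_i_true = traj$x_i,
             stringsAsFactors = FALSE)
}

#' Simulate a group of participants
#'
#' Generates `n_participants` independent participant streams over the same
#' schedule, with per-participant seeds derived deterministically from the
#' group seed.
#'
#' @inheritParams simulate_participant
#' @param design,condition design name and condition passed to
#'   [build_schedule()]; alternatively supply `schedule`.
#' @param schedule optional prebuilt schedule (overrides design/condition).
#' @param n_participants number of participants, `> 0`.
#' @return A `vmr_dataset`: list with `trials` (stacked records), `design`,
#'   `condition`, `params`, `noise`, `seed`, and the `schedule`.
#' @examples
#' ds <- simulate_group("exp1", 30, model_params(), noise_spec(0, 0),
#'                      n_participants = 2, seed = 7)
#' @export
simulate_group <- function(design, condition = NULL, params = model_params(),
                           noise = noise_spec(), n_participants = 15,
                           seed = 1L, schedule = NULL, pe_reaiming = TRUE) {
  if (n_participants <= 0) stop("n_participants must be > 0", call. = FALSE)
  if (is.null(schedule)) schedule <- build_schedule(design, condition)
  else design <- attr(schedule, "design")
  seeds <- derive_seeds(seed, n_participants)
  recs <- lapply(seq_len(n_participants), function(i)
    simulate_participant(schedule, params, noise, seed = seeds[i],
                         participant_id = sprintf("p%02d", i),
                         pe_reaiming = pe_reaiming))
  structure(list(trials = do.call(rbind, recs),
                 design = design,
                 condition = attr(schedule, "condition"),
                 params = params, noise = noise, seed = seed,
                 schedule = schedule),
            class = "vmr_dataset")
}

# Per-participant seeds derived from a group seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}

#' @export
print.vmr_dataset <- function(x, ...) {
  cat(sprintf("<vmr_dataset> %s (condition %s): %d participants x %d trials\n",
              x$design, as.character(x$condition),
              length(unique(x$trials$participant_id)),
              nrow(x$schedule)))
  invisible(x)
}

#' Condition-mean series of a simulated dataset
#'
#' Trial-by-trial across-participant means of the executed hand direction and
#' the reported quantities, the unit to which models are fitted.
#'
#' @param dataset a `vmr_dataset` from [simulate_group()].
#' @param participants optional subset (or resample, with repeats) of
#'   participant ids to average over.
#' @return A data frame with one row per trial: `trial`, `trial_type`,
#'   `rotation_deg`, `hand_deg`, `aim_report_deg`, `percept_report_deg`, `n`.
#' @export
condition_means <- function(dataset, participants = NULL) {
  tr <- dataset$trials
  if (!is.null(participants)) {
    tr <- do.call(rbind, lapply(seq_along(participants), function(i) {
      ti <- tr[tr$participant_id == participants[i], , drop = FALSE]
      ti$participant_id <- sprintf("r%03d", i)
      ti
    }))
  }
  sp <- split(tr, tr$trial)
  out <- dataset$schedule[, c("trial", "trial_type", "rotation_deg")]
  idx <- as.character(out$trial)
  out$hand_deg <- vapply(sp[idx], function(d) mean(d$hand_deg), numeric(1))
  out$aim_report_deg <- vapply(sp[idx], function(d)
    if (all(is.na(d$aim_report_deg))) NA_real_
    else mean(d$aim_report_deg, na.rm = TRUE), numeric(1))
  out$percept_report_deg <- vapply(sp[idx], function(d)
    if (all(is.na(d$percept_report_deg))) NA_real_
    else mean(d$percept_report_deg, na.rm = TRUE), numeric(1))
  out$n <- vapply(sp[idx], nrow, numeric(1))
  out
}
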