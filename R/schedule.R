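#' Build a perturbation schedule for a VMR experiment design
#'
#' Constructs the per-trial schedule (rotation, trial type, regime, aiming
#' reference) for one of the packaged experiment designs. All directions are
#' target-relative with the countering direction positive; the same schedule
#' is shared by every simulated participant in a condition.
#'
#' Designs:
#' * `"exp1"` — blocked one-step perturbation of `condition` degrees (15, 30,
#'   60, or 90): 35 baseline trials (proprioception tests at baseline trials
#'   5, 10, 15, 20), 75 adaptation trials (proprioception tests at adaptation
#'   trials 15, 20, 25, 30, 35; exclusion trials at 50, 55, 60, 65), 20
#'   no-feedback washout trials.
#' * `"exp2_stepwise"` / `"exp2_onestep"` — 35 baseline trials, then four
#'   40-trial blocks at 15/30/45/60 degrees (stepwise) or 160 trials at 60
#'   degrees (one-step), with proprioception tests at within-block trials 5,
#'   10, 15, 20 and exclusion trials at 30, 35; 20 washout trials.
#' * `"exp3"` — pseudo-random single-trial perturbations: 30 baseline trials
#'   alternating veridical feedback and no-feedback null trials, then 33
#'   six-trial mini-blocks alternating null and feedback trials (99
#'   perturbation and 99 null trials). Rotations 0, +/-4, +/-8, +/-16,
#'   +/-32, +/-64 degrees each appear 9 times in a fixed zero-mean
#'   pseudo-random order identical for all participants.
#' * `"exp4"` — instructed re-aiming from perturbation onset: 16 baseline
#'   trials, then 120 trials with rotation `condition` (45 or 90) and the
#'   re-aiming target at `condition` degrees in the countering direction.
#' * `"exp5"` — late re-aiming: 16 baseline trials (last cycle no-feedback),
#'   60 four-trial cycles of 45-degree adaptation with aiming reports at
#'   cycles 5, 19, 33, 47 and exclusion cycles at 6, 20, 34, 48; then 40
#'   instructed re-aiming cycles (aim reference = each participant's last
#'   reported aim, resolved at simulation time) with exclusion cycles at 1,
#'   11, 21; then 15 washout cycles of exclusion trials.
#' * `"exp6"` — perceptual probes: 20 baseline, 44 adaptation (rotation
#'   `condition`, one of 15, 30, 90), 20 no-feedback washout trials, with a
#'   probe trial (pre-movement aiming report plus post-movement hand-percept
#'   report) every fourth trial except the first 8 adaptation trials.
#' * `"bond2015"` — blocked perturbation of `condition` degrees (15, 30, 60,
#'   90) with a trial-by-trial aiming report: 40 baseline, 160 adaptation
#'   (all aiming-report trials), 16 no-feedback washout trials.
#'
#' @param design design name (see Details).
#' @param condition perturbation size or re-aiming offset in degrees, for
#'   designs with conditions.
#' @return A `vmr_schedule` data frame with columns `trial`, `phase`,
#'   `cycle`, `rotation_deg`, `trial_type`, `regime`, `aim_reference`,
#'   `target`, and attributes `design` and `condition`.
#' @examples
#' sched <- build_schedule("exp1", 30)
#' table(sched$trial_type)
#' @export
build_schedule <- function(design = c("exp1", "exp2_onestep", "exp2_stepwise",
                                      "exp3", "exp4", "exp5", "exp6",
                                      "bond2015"),
                           condition = NULL) {
  design <- match.arg(design)
  sched <- switch(design,
    exp1          = schedule_exp1(condition),
    exp2_onestep  = schedule_exp2(stepwise = FALSE),
    exp2_stepwise = schedule_exp2(stepwise = TRUE),
    exp3          = schedule_exp3(),
    exp4          = schedule_exp4(condition),
    exp5          = schedule_exp5(),
    exp6          = schedule_exp6(condition),
    bond2015      = schedule_bond2015(condition))
  sched$trial <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  structure(sched, design = design,
            condition = attr(sched, "condition", exact = TRUE),
            class = c("vmr_schedule", "data.frame"))
}

new_phase <- function(phase, n, rotation, trial_type = "feedback",
                      regime = "free_aiming", aim_reference = NA_real_,
                      cycle = NA_integer_, target = 0) {
  data.frame(trial = NA_integer_, phase = phase,
             cycle = if (length(cycle) == 1L) rep(cycle, n) else cycle,
             rotation_deg = rep(rotation, length.out = n),
             trial_type = rep(trial_type, length.out = n),
             regime = regime,
             aim_reference = aim_reference, target = target,
             stringsAsFactors = FALSE)
}

check_condition <- function(condition, allowed, design) {
  if (is.null(condition) || !condition %in% allowed)
    stop(sprintf("condition for %s must be one of %s", design,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  condition
}

schedule_exp1 <- function(condition) {
  r <- check_condition(condition, c(15, 30, 60, 90), "exp1")
  base <- new_phase("baseline", 35, 0)
  base$trial_type[c(5, 10, 15, 20)] <- "prop_test"
  adapt <- new_phase("adaptation", 75, r)
  adapt$trial_type[c(15, 20, 25, 30, 35)] <- "prop_test"
  adapt$trial_type[c(50, 55, 60, 65)] <- "exclusion"
  wash <- new_phase("washout", 20, 0, trial_type = "washout")
  out <- rbind(base, adapt, wash)
  attr(out, "condition") <- r
  out
}

schedule_exp2 <- function(stepwise) {
  base <- new_phase("baseline", 35, 0)
  steps <- if (stepwise) c(15, 30, 45, 60) else rep(60, 4)
  blocks <- lapply(seq_along(steps), function(i) {
    blk <- new_phase("adaptation", 40, steps[i], cycle = i)
    blk$trial_type[c(5, 10, 15, 20)] <- "prop_test"
    blk$trial_type[c(30, 35)] <- "exclusion"
    blk
  })
  wash <- new_phase("washout", 20, 0, trial_type = "washout")
  out <- do.call(rbind, c(list(base), blocks, list(wash)))
  attr(out, "condition") <- if (stepwise) "stepwise" else "onestep"
  out
}

# Fixed pseudo-random zero-mean rotation sequence for the single-trial
# design: each of 0, +/-4, +/-8, +/-16, +/-32, +/-64 appears 9 times, in a
# permutation frozen by an internal seed so every participant (and every
# session) sees the identical order.
exp3_rotation_sequence <- function() {
  values <- rep(c(0, 4, -4, 8, -8, 16, -16, 32, -32, 64, -64), times = 9)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(190703L)
  sample(values)
}

schedule_exp3 <- function() {
  base <- new_phase("baseline", 30, 0)
  base$trial_type <- rep(c("feedback", "null_nofeedback"), 15)
  rots <- exp3_rotation_sequence()
  n_ad <- 198L
  adapt <- new_phase("adaptation", n_ad, 0)
  is_fb <- seq_len(n_ad) %% 2 == 0          # null, FB, null, FB, ...
  adapt$trial_type[!is_fb] <- "null_nofeedback"
  adapt$rotation_deg[is_fb] <- rots
  adapt$cycle <- rep(seq_len(33), each = 6)
  adapt$target <- rep(c(25, 45, 65) - 45, length.out = n_ad)  # bookkeeping
  out <- rbind(base, adapt)
  attr(out, "condition") <- "random"
  out
}

schedule_exp4 <- function(condition) {
  r <- check_condition(condition, c(45, 90), "exp4")
  base <- new_phase("baseline", 16, 0, cycle = rep(1:2, each = 8))
  adapt <- new_phase("adaptation", 120, r, regime = "instructed_reaiming",
                     aim_reference = r, cycle = rep(1:15, each = 8))
  out <- rbind(base, adapt)
  attr(out, "condition") <- r
  out
}

schedule_exp5 <- function() {
  base <- new_phase("baseline", 16, 0, cycle = rep(1:4, each = 4))
  base$trial_type[13:16] <- "null_nofeedback"
  adapt <- new_phase("adaptation", 240, 45, cycle = rep(1:60, each = 4))
  report_cycles <- c(5, 19, 33, 47)
  excl_cycles <- c(6, 20, 34, 48)
  adapt$trial_type[adapt$cycle %in% report_cycles] <- "aiming_report"
  adapt$trial_type[adapt$cycle %in% excl_cycles] <- "exclusion"
  ream <- new_phase("reaiming", 160, 45, regime = "instructed_reaiming",
                    aim_reference = NA_real_, cycle = rep(1:40, each = 4))
  ream$trial_type[ream$cycle %in% c(1, 11, 21)] <- "exclusion"
  wash <- new_phase("washout", 60, 0, trial_type = "washout",
                    cycle = rep(1:15, each = 4))
  out <- rbind(base, adapt, ream, wash)
  attr(out, "condition") <- 45
  out
}

schedule_exp6 <- function(condition) {
  r <- check_condition(condition, c(15, 30, 90), "exp6")
  base <- new_phase("baseline", 20, 0)
  base$trial_type[seq(4, 20, by = 4)] <- "probe"
  adapt <- new_phase("adaptation", 44, r)
  adapt$trial_type[seq(12, 44, by = 4)] <- "probe"
  wash <- new_phase("washout", 20, 0, trial_type = "washout")
  wash$trial_type[seq(4, 20, by = 4)] <- "probe"
  out <- rbind(base, adapt, wash)
  attr(out, "condition") <- r
  out
}

schedule_bond2015 <- function(condition) {
  r <- check_condition(condition, c(15, 30, 60, 90), "bond2015")
  base <- new_phase("baseline", 40, 0, cycle = rep(1:5, each = 8))
  adapt <- new_phase("adaptation", 160, r, trial_type = "aiming_report",
                     cycle = rep(1:20, each = 8))
  wash <- new_phase("washout", 16, 0, trial_type = "washout",
                    cycle = rep(1:2, each = 8))
  out <- rbind(base, adapt, wash)
  attr(out, "condition") <- r
  out
}

# Integer trial codes for the compiled recursion: 0 movement with visual
# feedback, 1 no-feedback movement aimed at the target, 2 passive
# proprioception test. Probe trials carry feedback except during washout.
schedule_trial_codes <- function(schedule) {
  type <- schedule$trial_type
  code <- integer(nrow(schedule))
  code[type %in% c("exclusion", "null_nofeedback", "washout")] <- 1L
  code[type == "prop_test"] <- 2L
  code[type == "probe" & schedule$phase == "washout"] <- 1L
  code
}

#' @export
print.vmr_schedule <- function(x, ...) {
  cat(sprintf("<vmr_schedule> %s (condition %s): %d trials\n",
              attr(x, "design"), as.character(attr(x, "condition")), nrow(x)))
  tab <- table(x$phase, x$trial_type)
  print(tab)
  invisible(x)
}
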