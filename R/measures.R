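#' Behavioral measures of a simulated dataset
#'
#' Extracts the standard condition summaries from a simulated (or ingested)
#' dataset: the trial-by-trial mean total learning; implicit learning from
#' exclusion trials; explicit learning from aiming reports where present,
#' otherwise total minus implicit; proprioceptive bias (mean reported minus
#' actual hand direction over adaptation proprioception tests); and
#' probe-trial perceptual prediction error (reported hand percept minus
#' reported aim).
#'
#' @param dataset a `vmr_dataset`.
#' @param measure one of `"all"`, `"total"`, `"implicit"`, `"explicit"`,
#'   `"prop_bias"`, `"probe_ppe"`. Requesting a measure whose trials are
#'   absent from the design is an error.
#' @return For `"all"`, a list of the available measures; otherwise the
#'   requested measure. Series measures are data frames, scalar measures are
#'   per-participant data frames with a `value` column.
#' @export
extract_measures <- function(dataset,
                             measure = c("all", "total", "implicit",
                                         "explicit", "prop_bias",
                                         "probe_ppe")) {
  measure <- match.arg(measure)
  stopifnot(inherits(dataset, "vmr_dataset"))
  tr <- dataset$trials
  sched <- dataset$schedule
  codes <- schedule_trial_codes(sched)
  adapt <- sched$phase %in% c("adaptation", "reaiming")

  have <- list(
    total = any(codes == 0L),
    implicit = any(sched$trial_type == "exclusion" |
                     (sched$trial_type == "null_nofeedback" & adapt)),
    explicit = TRUE,
    prop_bias = any(sched$trial_type == "prop_test" & adapt),
    probe_ppe = any(sched$trial_type == "probe" & adapt))

  get_one <- function(m) {
    if (!have[[m]])
      stop(sprintf("measure '%s' is not available for design %s", m,
                   dataset$design), call. = FALSE)
    switch(m,
      total = {
        mm <- condition_means(dataset)
        mm[codes == 0L, c("trial", "trial_type", "rotation_deg", "hand_deg")]
      },
      implicit = {
        keep <- sched$trial[(sched$trial_type == "exclusion" |
                               sched$trial_type == "null_nofeedback") & adapt]
        d <- tr[tr$trial %in% keep, , drop = FALSE]
        agg_by_participant(d, d$hand_deg)
      },
      explicit = {
        rep_tr <- sched$trial[sched$trial_type %in% c("aiming_report", "probe") & adapt]
        if (length(rep_tr)) {
          d <- tr[tr$trial %in% rep_tr & !is.na(tr$aim_report_deg), , drop = FALSE]
          agg_by_participant(d, d$aim_report_deg)
        } else {
          # subtraction method: late total minus exclusion-trial implicit
          tot <- late_total_by_participant(dataset)
          imp <- get_one("implicit")
          merge_val <- merge(tot, imp, by = "participant_id",
                             suffixes = c("_total", "_implicit"))
          data.frame(participant_id = merge_val$participant_id,
                     value = merge_val$value_total - merge_val$value_implicit)
        }
      },
      prop_bias = {
        keep <- sched$trial[sched$trial_type == "prop_test" & adapt]
        d <- tr[tr$trial %in% keep, , drop = FALSE]
        agg_by_participant(d, d$percept_report_deg - d$hand_deg)
      },
      probe_ppe = {
        keep <- sched$trial[sched$trial_type == "probe" & adapt]
        d <- tr[tr$trial %in% keep, , drop = FALSE]
        agg_by_participant(d, d$percept_report_deg - d$aim_report_deg)
      })
  }
  if (measure != "all") return(get_one(measure))
  out <- lapply(names(have)[unlist(have)], get_one)
  names(out) <- names(have)[unlist(have)]
  out
}

agg_by_participant <- function(d, values) {
  d$value <- values
  sp <- split(d$value, d$participant_id)
  data.frame(participant_id = names(sp),
             value = vapply(sp, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

late_total_by_participant <- function(dataset) {
  sched <- dataset$schedule
  codes <- schedule_trial_codes(sched)
  fb <- sched$trial[codes == 0L & sched$phase == "adaptation"]
  late <- utils::tail(fb, 8)
  d <- dataset$trials[dataset$trials$trial %in% late, , drop = FALSE]
  agg_by_participant(d, d$hand_deg)
}

#' Single-trial learning versus signed perturbation size
#'
#' For the pseudo-random single-trial design, quantifies learning from each
#' perturbation trial as the hand-direction difference between the two
#' flanking no-feedback null trials (post minus pre). Clockwise and
#' counter-clockwise perturbations are pooled by sign-alignment (the
#' response to a rotation of size `-s` is negated before averaging with the
#' responses to `+s`).
#'
#' @param dataset a `vmr_dataset` built from the `"exp3"` design.
#' @return A data frame with one row per absolute perturbation size:
#'   `size`, `learning` (mean sign-aligned single-trial change in degrees),
#'   `sd`, `n_obs`.
#' @export
single_trial_learning <- function(dataset) {
  stopifnot(inherits(dataset, "vmr_dataset"))
  if (dataset$design != "exp3")
    stop("single_trial_learning requires an exp3 dataset", call. = FALSE)
  sched <- dataset$schedule
  fb <- which(sched$phase == "adaptation" & sched$trial_type == "feedback")
  fb <- fb[fb > 1 & fb < nrow(sched)]
  pre <- fb - 1L
  post <- fb + 1L
  ok <- sched$trial_type[pre] == "null_nofeedback" &
        sched$trial_type[post] == "null_nofeedback"
  fb <- fb[ok]; pre <- pre[ok]; post <- post[ok]
  r <- sched$rotation_deg[fb]

  tr <- dataset$trials
  sp <- split(tr, tr$participant_id)
  per <- lapply(sp, function(d) {
    d <- d[order(d$trial), ]
    delta <- d$hand_deg[post] - d$hand_deg[pre]
    aligned <- ifelse(r == 0, delta, delta * sign(r))
    data.frame(size = abs(r), aligned = aligned)
  })
  all <- do.call(rbind, per)
  sizes <- sort(unique(all$size))
  data.frame(size = sizes,
             learning = vapply(sizes, function(s)
               mean(all$aligned[all$size == s]), numeric(1)),
             sd = vapply(sizes, function(s)
               sd(all$aligned[all$size == s]), numeric(1)),
             n_obs = vapply(sizes, function(s)
               sum(all$size == s), numeric(1)))
}
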