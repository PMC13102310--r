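trial_schema_cols <- c("participant_id", "condition", "trial", "cycle",
                       "trial_type", "rotation_deg", "hand_deg",
                       "aim_report_deg", "percept_report_deg", "regime")

trial_type_vocab <- c("feedback", "exclusion", "null_nofeedback", "prop_test",
                      "aiming_report", "probe", "washout")

#' Write / read a long-form trial table
#'
#' The trial CSV stores one row per participant and trial with the schema
#' columns `participant_id`, `condition`, `trial`, `cycle`, `trial_type`,
#' `rotation_deg`, `hand_deg`, `aim_report_deg`, `percept_report_deg`,
#' `regime` (angles in degrees, target-relative, countering-positive; UTF-8,
#' comma separator, `.` decimal). Unknown extra columns are preserved.
#' `write_trials()` additionally writes a JSON sidecar
#' (`<path>.meta.json`) with the generator parameters and seed when given a
#' `vmr_dataset`.
#'
#' @param dataset a `vmr_dataset` or plain trial data frame.
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial data frame with the sidecar metadata (if found)
#'   attached as attribute `"meta"`.
#' @export
write_trials <- function(dataset, path) {
  tr <- if (inherits(dataset, "vmr_dataset")) dataset$trials else dataset
  write.csv(tr, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (inherits(dataset, "vmr_dataset")) {
    meta <- list(design = dataset$design,
                 condition = dataset$condition,
                 params = unclass(dataset$params),
                 noise = unclass(dataset$noise),
                 seed = dataset$seed)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(trial_schema_cols, names(tr))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("rotation_deg", "hand_deg", "aim_report_deg",
                "percept_report_deg")) {
    v <- tr[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric angle in column %s at row(s) %s", col,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      tr[[col]] <- num
    }
  }
  bad_type <- setdiff(unique(tr$trial_type), trial_type_vocab)
  if (length(bad_type))
    stop("unknown trial_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  dup <- any(vapply(split(tr$trial, tr$participant_id),
                    function(v) anyDuplicated(v) > 0, logical(1)))
  if (dup) stop("trial indices must be unique per participant", call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    attr(tr, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tr
}

#' Direction-based trial exclusion filter
#'
#' Removes rows whose executed hand direction falls outside
#' `[min_dir, max_dir]` (systematic movements in the wrong direction), the
#' standard ingestion filter for real datasets, and logs per-participant
#' exclusion counts. `c(-Inf, Inf)` disables filtering.
#'
#' @param trials a trial data frame (or `vmr_dataset`, whose `trials` are
#'   filtered in place).
#' @param min_dir,max_dir direction window in degrees.
#' @return List with the filtered `trials` (or dataset) and `exclusions`, a
#'   per-participant count data frame.
#' @export
clean_trials <- function(trials, min_dir = -20, max_dir = 120) {
  is_ds <- inherits(trials, "vmr_dataset")
  tr <- if (is_ds) trials$trials else trials
  out_of_range <- !is.na(tr$hand_deg) &
    (tr$hand_deg < min_dir | tr$hand_deg > max_dir)
  ids <- unique(tr$participant_id)
  log <- data.frame(participant_id = ids,
                    n_excluded = vapply(ids, function(id)
                      sum(out_of_range[tr$participant_id == id]), numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  kept <- tr[!out_of_range, , drop = FALSE]
  if (is_ds) {
    trials$trials <- kept
    list(trials = trials, exclusions = log)
  } else {
    list(trials = kept, exclusions = log)
  }
}
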