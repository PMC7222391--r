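# Study input: containers, condition classification, exclusion rules.

#' Construct a trial recording
#'
#' One trial's multichannel time series. Channels are the network nodes;
#' the standard montage has 32 of them ([deap_channels()]), and inputs read
#' through the DEAP-shaped path are required to provide exactly that many.
#'
#' @param data numeric channels x samples matrix; no NA/Inf.
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels, one per row of `data`.
#' @param subject_id,trial_id optional identifiers.
#' @return a `trial_recording` object.
#' @export
trial_recording <- function(data, fs, channel_names = NULL,
                            subject_id = NA, trial_id = NA) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric channels x samples matrix")
  if (anyNA(data) || any(!is.finite(data)))
    stop("trial data contain NA or non-finite values")
  if (nrow(data) < 2L) stop("a trial needs at least 2 channels")
  stopifnot(is.numeric(fs), fs > 0)
  channel_names <- channel_names %||% default_channel_names(nrow(data))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match the number of channels")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, trial_id = trial_id),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d channels x %d samples at %g Hz (subject %s, trial %s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              as.character(x$subject_id), as.character(x$trial_id)))
  invisible(x)
}

n_samples <- function(trial) ncol(trial$data)

#' Classify a trial into an emotion condition
#'
#' Self-report ratings on the 1--9 scale are split into low (1--4) and
#' high (6--9) on each axis; ratings in the open middle band (4, 6) on
#' either axis leave the trial UNCLASSIFIED. Both axes must classify for a
#' named condition. The threshold intervals are closed at 4 and 6, so a
#' rating of exactly 4 is low and exactly 6 is high.
#'
#' @param valence,arousal ratings in `[1, 9]`.
#' @return one of `"HAHV"`, `"HALV"`, `"LAHV"`, `"LALV"`,
#'   `"UNCLASSIFIED"`. Vectorised over inputs.
#' @examples
#' classify_trial(valence = 7.1, arousal = 8.0)  # HAHV
#' classify_trial(valence = 3.0, arousal = 5.2)  # UNCLASSIFIED
#' @export
classify_trial <- function(valence, arousal) {
  stopifnot(length(valence) == length(arousal))
  if (anyNA(valence) || anyNA(arousal) ||
      any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9))
    stop("ratings must lie in [1, 9]")
  level <- function(x) ifelse(x <= 4, "L", ifelse(x >= 6, "H", NA))
  a <- level(arousal); v <- level(valence)
  out <- ifelse(is.na(a) | is.na(v), "UNCLASSIFIED", paste0(a, "A", v, "V"))
  unname(out)
}

#' Write a study to its native on-disk container
#'
#' One `.rds` per subject holding the trials x channels x samples array,
#' sampling rate, channel names and label table; a sidecar CSV with the
#' labels; and the ground-truth coupling edge lists (condition, i, j,
#' strength, lag) when the study is synthetic.
#'
#' @param study an `eeg_study` from [generate_group()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "eeg_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (sub in study$subjects) {
    id <- sprintf("s%02d", sub$subject_id)
    arr <- simplify2array(lapply(sub$trials, function(t) t$data))
    arr <- aperm(arr, c(3, 1, 2))  # trials x channels x samples
    obj <- list(data = arr, fs = sub$trials[[1]]$fs,
                channel_names = sub$trials[[1]]$channel_names,
                labels = sub$labels, subject_id = sub$subject_id)
    f <- file.path(dir, paste0(id, ".rds"))
    saveRDS(obj, f)
    fl <- file.path(dir, paste0(id, "_labels.csv"))
    write.csv(sub$labels, fl, row.names = FALSE)
    files <- c(files, f, fl)
    if (!is.null(sub$truth)) {
      tt <- do.call(rbind, lapply(names(sub$truth), function(cn) {
        p <- sub$truth[[cn]]$pairs
        data.frame(condition = cn, i = p$i, j = p$j,
                   strength = p$strength, lag = p$lag)
      }))
      ft <- file.path(dir, paste0(id, "_truth.csv"))
      write.csv(tt, ft, row.names = FALSE)
      files <- c(files, ft)
    }
  }
  invisible(files)
}

#' Read one subject's trials and labels
#'
#' Two formats are supported. `"native"` is the container written by
#' [write_study()] and round-trips at full floating precision. `"deap"`
#' accepts an `.rds` holding a list with `data` (trials x channels x
#' samples array, >= 32 channels, 8064 samples at 128 Hz) and `labels`
#' (data frame with `valence`, `arousal`); only the first 32 rows (the EEG
#' channels) are kept and the first 3 s of each trial — the pre-stimulus
#' baseline — are dropped, leaving the 60-s viewing window.
#'
#' @param path path to the subject file.
#' @param format `"native"` or `"deap"`.
#' @return a subject bundle: list with `subject_id`, `trials` (list of
#'   [trial_recording()]) and `labels` (data frame).
#' @export
read_subject <- function(path, format = c("native", "deap")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data))
    stop("format error: expected a list with a 'data' array")
  arr <- obj$data
  if (length(dim(arr)) != 3L)
    stop("format error: 'data' must be trials x channels x samples")
  fs <- obj$fs %||% 128
  if (fs != 128)
    stop("sampling rate is ", fs,
         " Hz, not 128 Hz; resampling is out of scope - refusing to load")
  labels <- obj$labels
  if (is.null(labels) || !all(c("valence", "arousal") %in% names(labels)))
    stop("format error: labels with valence and arousal required")
  if (format == "deap") {
    if (dim(arr)[2] < 32L)
      stop("format error: DEAP-shaped input needs >= 32 channels, got ",
           dim(arr)[2])
    drop_n <- 3 * fs  # 3-s pre-stimulus baseline
    if (dim(arr)[3] <= drop_n)
      stop("format error: trials shorter than the 3-s baseline")
    arr <- arr[, seq_len(32L), -seq_len(drop_n), drop = FALSE]
    channel_names <- deap_channels()
  } else {
    channel_names <- obj$channel_names %||% default_channel_names(dim(arr)[2])
  }
  subject_id <- obj$subject_id %||% sub("\\.rds$", "", basename(path))
  trials <- lapply(seq_len(dim(arr)[1]), function(t)
    trial_recording(arr[t, , ], fs = fs, channel_names = channel_names,
                    subject_id = subject_id, trial_id = t))
  if (is.null(labels$trial_id)) labels$trial_id <- seq_len(dim(arr)[1])
  list(subject_id = subject_id, trials = trials, labels = labels)
}

#' Classify every trial of a study
#'
#' Adds/overwrites a `condition` column on each subject's label table using
#' [classify_trial()].
#'
#' @param study an `eeg_study` or plain list of subject bundles.
#' @return the study with conditions assigned.
#' @export
classify_study <- function(study) {
  subs <- study_subjects(study)
  subs <- lapply(subs, function(sub) {
    sub$labels$condition <- classify_trial(sub$labels$valence,
                                           sub$labels$arousal)
    sub
  })
  set_study_subjects(study, subs)
}

study_subjects <- function(study) {
  if (inherits(study, "eeg_study")) study$subjects else study
}

set_study_subjects <- function(study, subs) {
  if (inherits(study, "eeg_study")) {
    study$subjects <- subs
    study
  } else subs
}

#' Drop subjects lacking trials in any emotion condition
#'
#' A within-subject 2x2 comparison needs every subject in all four
#' conditions; a subject whose ratings fail to populate one of them (the
#' situation that led to a subject's removal in the DEAP-based analysis)
#' is excluded and logged.
#'
#' @param study classified study (see [classify_study()]).
#' @return list with `study` (retained subjects) and `log` (data frame
#'   `subject_id`, `reason`).
#' @export
exclude_subjects <- function(study) {
  subs <- study_subjects(study)
  if (length(subs) == 0L) stop("empty study")
  keep <- logical(length(subs))
  log <- data.frame(subject_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  for (k in seq_along(subs)) {
    cond <- subs[[k]]$labels$condition
    if (is.null(cond)) stop("study is not classified; run classify_study()")
    missing <- setdiff(emotion_conditions(), cond)
    if (length(missing) == 0L) {
      keep[k] <- TRUE
    } else {
      log <- rbind(log, data.frame(
        subject_id = as.character(subs[[k]]$subject_id),
        reason = paste0("missing condition(s): ",
                        paste(missing, collapse = "+"))))
    }
  }
  if (!any(keep)) stop("all subjects excluded; no condition-complete subject")
  list(study = set_study_subjects(study, subs[keep]), log = log)
}
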