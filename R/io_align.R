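# Reading device streams, phase labelling (with relaxation merging) and
# epoch-level alignment of the two devices.

#' Read long-format heart-rate series from CSV
#'
#' Expects the dialect `subject,device,phase,epoch_time_s,bpm` (the `phase`
#' column is optional; [label_and_merge()] assigns phases from a schedule).
#' Rows with bpm outside the physiologically plausible open interval
#' (20, 250) are dropped with a warning stating the count. One series is the
#' set of rows sharing `(subject, device)`.
#'
#' @param path CSV file path.
#' @param devices optional character vector of expected device labels; any
#'   other label in the file is an error.
#' @return data.frame ordered by subject, device and time.
#' @export
read_hr_csv <- function(path, devices = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject", "device", "epoch_time_s", "bpm")
  absent <- setdiff(req, names(df))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  }
  if (!is.null(devices)) {
    unknown <- setdiff(unique(df$device), devices)
    if (length(unknown)) {
      stop("unknown device label(s): ", paste(unknown, collapse = ", "))
    }
  }
  bad <- !is.finite(df$bpm) | df$bpm <= 20 | df$bpm >= 250
  if (any(bad)) {
    warning(sprintf("dropped %d sample(s) with bpm outside (20, 250)", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  key <- interaction(df$subject, df$device, drop = TRUE)
  dup <- tapply(df$epoch_time_s, key, function(t) anyDuplicated(t) > 0)
  if (any(dup)) {
    first <- names(dup)[which(dup)[1]]
    stop("duplicate timestamps within series ", first)
  }
  df <- df[order(df$subject, df$device, df$epoch_time_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_schedule <- function(schedule) {
  req <- c("phase", "start_s", "end_s")
  absent <- setdiff(req, names(schedule))
  if (length(absent)) {
    stop("schedule missing column(s): ", paste(absent, collapse = ", "))
  }
  unknown <- setdiff(unique(schedule$phase), .protocol_phases)
  if (length(unknown)) {
    stop("unknown phase label(s) in schedule: ", paste(unknown, collapse = ", "))
  }
  split_by <- if ("subject" %in% names(schedule)) schedule$subject else
    rep(1L, nrow(schedule))
  for (part in split(schedule, split_by)) {
    part <- part[order(part$start_s), , drop = FALSE]
    if (any(part$end_s <= part$start_s)) {
      stop("schedule entries must have end_s > start_s")
    }
    if (nrow(part) > 1 && any(part$start_s[-1] < part$end_s[-nrow(part)])) {
      stop("schedule entries must not overlap")
    }
    pos <- match(part$phase, .protocol_phases)
    if (any(diff(pos) <= 0)) {
      stop("schedule phases must follow the protocol order ",
           paste(.protocol_phases, collapse = " < "))
    }
  }
  invisible(schedule)
}

#' Label samples with experimental phases and merge the relaxations
#'
#' Each sample is tagged with the phase whose half-open window
#' `[start_s, end_s)` contains its timestamp; samples falling in gaps or
#' outside the schedule are discarded. The opening and closing relaxation
#' blocks are relabelled to a single `"relaxation"` phase, mirroring the
#' analysis convention for the TSST.
#'
#' @param hr data.frame as returned by [read_hr_csv()] or [generate_study()].
#' @param schedule data.frame with `phase`, `start_s`, `end_s` and optionally
#'   `subject` (per-subject schedules); phases must follow the protocol order.
#' @return data.frame with a (merged) `phase` column; other columns unchanged.
#' @export
label_and_merge <- function(hr, schedule) {
  validate_schedule(schedule)
  per_subject <- "subject" %in% names(schedule)
  assign_one <- function(times, sched) {
    sched <- sched[order(sched$start_s), , drop = FALSE]
    idx <- findInterval(times, sched$start_s)
    ok <- idx >= 1 & times < sched$end_s[pmax(idx, 1L)]
    lab <- rep(NA_character_, length(times))
    lab[ok] <- sched$phase[idx[ok]]
    lab
  }
  if (per_subject) {
    lab <- rep(NA_character_, nrow(hr))
    for (s in unique(hr$subject)) {
      sel <- hr$subject == s
      sched_s <- schedule[schedule$subject == s, , drop = FALSE]
      if (!nrow(sched_s)) stop("no schedule entries for subject ", s)
      lab[sel] <- assign_one(hr$epoch_time_s[sel], sched_s)
    }
  } else {
    lab <- assign_one(hr$epoch_time_s, schedule)
  }
  key <- interaction(hr$subject, hr$device, drop = TRUE)
  lost <- tapply(lab, key, function(x) all(is.na(x)))
  if (any(lost)) {
    stop("sample span disjoint from schedule for series ",
         names(lost)[which(lost)[1]])
  }
  hr$phase <- merge_phase(lab)
  hr <- hr[!is.na(lab), , drop = FALSE]
  rownames(hr) <- NULL
  hr
}

#' Align two devices onto shared epochs
#'
#' Cuts the protocol-relative time axis into half-open windows
#' `[k*epoch_s, (k+1)*epoch_s)`, averages each device within a window, and
#' keeps windows where both devices contribute at least half of their
#' expected sample count (expected = epoch length over the device's median
#' sampling interval). The between-device difference is oriented as
#' test minus reference.
#'
#' @param labeled output of [label_and_merge()] (both devices present).
#' @param ref_device,test_device device labels.
#' @param epoch_s epoch length in seconds (default 5, the coarser wearable
#'   reporting granularity).
#' @return data.frame with columns `subject`, `phase`, `epoch_index`,
#'   `hr_ref`, `hr_test` and `diff = hr_test - hr_ref`.
#' @export
pair_epochs <- function(labeled, ref_device, test_device, epoch_s = 5) {
  if (epoch_s <= 0) stop("`epoch_s` must be positive")
  for (d in c(ref_device, test_device)) {
    if (!any(labeled$device == d)) stop("device not present in data: ", d)
  }
  side <- function(dev) {
    x <- labeled[labeled$device == dev, , drop = FALSE]
    key <- interaction(x$subject, x$device, drop = TRUE)
    ivals <- unlist(tapply(x$epoch_time_s, key,
                           function(t) diff(sort(t)), simplify = FALSE))
    interval <- if (length(ivals)) stats::median(ivals) else epoch_s
    x$epoch_index <- floor(x$epoch_time_s / epoch_s)
    agg <- stats::aggregate(bpm ~ subject + phase + epoch_index, data = x,
                            FUN = mean)
    cnt <- stats::aggregate(bpm ~ subject + phase + epoch_index, data = x,
                            FUN = length)
    agg$n <- cnt$bpm
    agg$expected <- max(1, epoch_s / interval)
    agg
  }
  r <- side(ref_device)
  t <- side(test_device)
  m <- merge(r, t, by = c("subject", "phase", "epoch_index"),
             suffixes = c("_ref", "_test"))
  keep <- m$n_ref >= 0.5 * m$expected_ref & m$n_test >= 0.5 * m$expected_test
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) stop("zero overlapping epochs between the two devices")
  out <- data.frame(subject = m$subject, phase = m$phase,
                    epoch_index = m$epoch_index,
                    hr_ref = m$bpm_ref, hr_test = m$bpm_test,
                    diff = m$bpm_test - m$bpm_ref,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject, out$epoch_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
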