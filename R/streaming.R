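#' Streaming per-device recalibration engine
#'
#' Continuous recalibration over a weekly stream: the decision threshold is
#' fixed once on a labelled reference set and never refitted; each device
#' (scanner) maintains its own running window of recent unlabelled scores
#' from which a fresh alignment transform is fitted every week. Devices are
#' fully isolated — one scanner's software update never perturbs another's
#' calibration.
#'
#' @param reference A labelled [record_set()] from the in-distribution
#'   domain; sets the balanced operating point and serves as the matching
#'   target throughout the run.
#' @param window_length Running-window length in weeks (default 2: the
#'   transform for week `T` is fitted on that device's data from weeks
#'   `T-2` and `T-1`, never on week `T` itself).
#' @param min_fit_size Minimum number of buffered scores before a transform
#'   is fitted (default 50 images); below it the device stays on the raw
#'   (identity-aligned) scores — the cold-start rule.
#' @return A `upa_engine` state object.
#' @seealso [engine_step()], [run_scenario()]
#' @export
upa_engine <- function(reference, window_length = 2L, min_fit_size = 50L) {
  stopifnot(inherits(reference, "record_set"))
  window_length <- assert_count(window_length, min = 1L)
  min_fit_size <- assert_count(min_fit_size, min = 2L)
  if (anyNA(reference$label)) {
    stop("the reference set must be fully labelled to set the operating point",
         call. = FALSE)
  }
  op <- select_threshold_balanced(reference$score, reference$label)
  structure(
    list(reference_scores = reference$score, operating_point = op,
         window_length = window_length, min_fit_size = min_fit_size,
         buffer = NULL, transforms = list(), last_time = -1L),
    class = "upa_engine"
  )
}

#' Advance the streaming engine by one week
#'
#' For each device present in `week_records`: fit an alignment transform from
#' that device's running-window buffer against the frozen reference scores
#' (identity while the buffer holds fewer than `min_fit_size` scores), align
#' the week's scores, and evaluate sensitivity/specificity at the frozen
#' threshold before and after alignment, per device and pooled. The week is
#' then pushed into the buffers and weeks older than the window are evicted.
#' The evaluation week is never part of the window it is evaluated with.
#'
#' @param engine A `upa_engine`.
#' @param week_records A [record_set()] whose rows all share one
#'   `time_index`, strictly greater than any week already processed.
#' @return A list: `engine` (advanced state) and `metrics`, a data.frame with
#'   one row per (device or `"overall"`) x (aligned TRUE/FALSE) holding
#'   `sensitivity`, `specificity`, `gap` (= SEN - SPC), `youden`, counts and
#'   whether a fitted transform was in force.
#' @export
engine_step <- function(engine, week_records) {
  stopifnot(inherits(engine, "upa_engine"), inherits(week_records, "record_set"))
  if (nrow(week_records) == 0L) stop("empty week", call. = FALSE)
  week <- unique(week_records$time_index)
  if (length(week) != 1L) {
    stop("week_records must share a single time_index", call. = FALSE)
  }
  if (week <= engine$last_time) {
    stop(sprintf("out-of-order week %d after week %d", week, engine$last_time),
         call. = FALSE)
  }
  buffer <- engine$buffer
  if (!is.null(buffer)) {
    # the running window: weeks T-window_length ... T-1 only
    buffer <- buffer[buffer$time_index >= week - engine$window_length &
                       buffer$time_index < week, , drop = FALSE]
    overlap <- intersect(paste(buffer$case_id, buffer$image_id),
                         paste(week_records$case_id, week_records$image_id))
    if (length(overlap) > 0L) {
      stop("evaluation week overlaps the fitting window", call. = FALSE)
    }
  }

  devices <- sort(unique(week_records$device_id))
  transforms <- list()
  aligned <- week_records$score
  fitted <- logical(length(devices))
  names(fitted) <- devices
  for (d in devices) {
    idx <- week_records$device_id == d
    buf_scores <- if (is.null(buffer)) numeric(0) else {
      buffer$score[buffer$device_id == d]
    }
    if (length(buf_scores) >= engine$min_fit_size) {
      tr <- fit_alignment(engine$reference_scores, buf_scores)
      transforms[[d]] <- tr
      aligned[idx] <- apply_alignment(tr, week_records$score[idx])
      fitted[d] <- TRUE
    } # else: cold start, identity transform (raw scores kept)
  }

  thr <- engine$operating_point$threshold
  rows <- list()
  for (d in devices) {
    idx <- week_records$device_id == d
    rows[[length(rows) + 1L]] <- data.frame(
      time_index = week, device_id = d, aligned = FALSE,
      t(gap_metrics(week_records$score[idx], week_records$label[idx], thr)),
      transform_fitted = fitted[d])
    rows[[length(rows) + 1L]] <- data.frame(
      time_index = week, device_id = d, aligned = TRUE,
      t(gap_metrics(aligned[idx], week_records$label[idx], thr)),
      transform_fitted = fitted[d])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    time_index = week, device_id = "overall", aligned = FALSE,
    t(gap_metrics(week_records$score, week_records$label, thr)),
    transform_fitted = any(fitted))
  rows[[length(rows) + 1L]] <- data.frame(
    time_index = week, device_id = "overall", aligned = TRUE,
    t(gap_metrics(aligned, week_records$label, thr)),
    transform_fitted = any(fitted))
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  new_buffer <- rbind(buffer,
                      as.data.frame(week_records)[, record_columns])
  # keep only weeks that can still fall inside a future window
  new_buffer <- new_buffer[new_buffer$time_index > week - engine$window_length, ,
                           drop = FALSE]
  engine$buffer <- new_buffer
  engine$transforms <- transforms
  engine$last_time <- week
  list(engine = engine, metrics = metrics)
}

#' Run a deployment scenario with repeated simulation
#'
#' Simulates the full weekly stream defined by `schedule`, runs the streaming
#' engine over it, and repeats the whole simulation `n_reps` times to obtain
#' the mean and 5-95 percentile band of the weekly sensitivity-specificity
#' difference, with and without alignment, per device and overall. Each
#' repetition draws a fresh reference set (from `reference_model`) so that
#' operating-point estimation noise is part of the band. Deterministic under
#' `seed`.
#'
#' @param schedule A [make_schedule()] scenario.
#' @param n_reps Number of simulation repetitions.
#' @param seed Integer seed for the whole run.
#' @param reference_model Domain model that generates the reference sets
#'   (default: the unshifted preset).
#' @param n_reference_cases Cases per reference set (default 1200).
#' @param window_length,min_fit_size Passed to [upa_engine()].
#' @return A `scenario_report`: data.frame with columns `week`, `device_id`
#'   (including `"overall"`), `aligned`, `mean_gap`, `p05`, `p95`, `n_reps`;
#'   the per-rep trajectories are attached as attribute `"reps"`.
#' @export
run_scenario <- function(schedule, n_reps = 50L, seed = 1L,
                         reference_model = preset_domain_model("reference"),
                         n_reference_cases = 1200L,
                         window_length = 2L, min_fit_size = 50L) {
  stopifnot(inherits(schedule, "scenario_schedule"))
  n_reps <- assert_count(n_reps, min = 1L)
  n_reference_cases <- assert_count(n_reference_cases, min = 2L)
  set.seed(seed)
  weeks <- sort(unique(schedule$counts$week))
  per_rep <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    reference <- generate_records(
      reference_model, n_cases = n_reference_cases,
      prevalence = schedule$prevalence,
      images_per_case = schedule$images_per_case,
      device_id = "reference", case_prefix = sprintf("ref_r%04d", rep_i))
    engine <- upa_engine(reference, window_length = window_length,
                         min_fit_size = min_fit_size)
    rows <- vector("list", length(weeks))
    for (wi in seq_along(weeks)) {
      week_records <- generate_week(schedule, weeks[wi])
      stepped <- engine_step(engine, week_records)
      engine <- stepped$engine
      rows[[wi]] <- stepped$metrics
    }
    rep_metrics <- do.call(rbind, rows)
    rep_metrics$rep <- rep_i
    per_rep[[rep_i]] <- rep_metrics
  }
  reps <- do.call(rbind, per_rep)
  key <- interaction(reps$time_index, reps$device_id, reps$aligned, drop = TRUE)
  agg <- do.call(rbind, lapply(split(reps, key), function(g) {
    data.frame(
      week = g$time_index[1L], device_id = g$device_id[1L],
      aligned = g$aligned[1L],
      mean_gap = mean(g$gap, na.rm = TRUE),
      p05 = unname(quantile(g$gap, 0.05, na.rm = TRUE, names = FALSE)),
      p95 = unname(quantile(g$gap, 0.95, na.rm = TRUE, names = FALSE)),
      n_reps = sum(!is.na(g$gap)))
  }))
  agg <- agg[order(agg$device_id, agg$aligned, agg$week), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "reps") <- reps
  attr(agg, "scenario") <- schedule$scenario
  class(agg) <- c("scenario_report", "data.frame")
  agg
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s: %d week(s) x %d series\n",
              attr(x, "scenario") %||% "?", length(unique(x$week)),
              length(unique(paste(x$device_id, x$aligned)))))
  ov <- x[x$device_id == "overall", , drop = FALSE]
  for (al in c(FALSE, TRUE)) {
    g <- ov[ov$aligned == al, , drop = FALSE]
    if (nrow(g)) {
      cat(sprintf("  overall %s alignment: final-week mean SEN-SPC %+.3f, max |mean| %.3f\n",
                  if (al) "with" else "without",
                  g$mean_gap[which.max(g$week)], max(abs(g$mean_gap))))
    }
  }
  invisible(x)
}
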