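#' Build a deployment-scenario schedule
#'
#' A schedule fixes, for every simulated week, how many cases each device
#' (scanner) acquires and which domain model generates its scores. The four
#' shipped scenarios:
#' \describe{
#'   \item{`new_site`}{Static single-week schedule: one shifted device.}
#'   \item{`transition`}{A new scanner B is installed and scanner A gradually
#'     decommissioned: weekly counts cross over linearly from (A: all, B: 0)
#'     to (A: 0, B: all); the weekly total stays constant.}
#'   \item{`addition`}{Scanner B is added alongside A: A's count stays fixed
#'     while B ramps linearly from 0 to A's level, doubling the weekly total
#'     by the end.}
#'   \item{`software_update`}{A single scanner whose image processing is
#'     updated at week `update_week`: from that week on its scores pass
#'     through `update_warp` (a sudden, persistent shift).}
#' }
#'
#' @param scenario One of `"new_site"`, `"transition"`, `"addition"`,
#'   `"software_update"`.
#' @param horizon Number of weeks (>= 4 for the multi-week scenarios;
#'   `new_site` always spans one week).
#' @param cases_per_week Baseline weekly case volume (default 250).
#' @param prevalence Case-level prevalence (default 0.02, screening-like).
#' @param images_per_case Images per case (default 4, two views per breast).
#' @param model_a Domain model of the incumbent device.
#' @param model_b Domain model of the incoming device (scenarios
#'   `new_site`, `transition`, `addition`).
#' @param update_week Week at which the software update lands
#'   (`software_update`; default `floor(horizon / 2)`).
#' @param update_warp Warp applied from `update_week` on (default
#'   [sharpness_update_warp()] with strength 1.5).
#' @return A `scenario_schedule`: `counts` (data.frame `week`, `device_id`,
#'   `n_cases`), per-device models, prevalence and image multiplicity.
#' @examples
#' sch <- make_schedule("transition", horizon = 10)
#' head(sch$counts)
#' @export
make_schedule <- function(scenario = c("new_site", "transition", "addition",
                                       "software_update"),
                          horizon = 20L, cases_per_week = 250L,
                          prevalence = 0.02, images_per_case = 4L,
                          model_a = preset_domain_model("reference"),
                          model_b = preset_domain_model("scanner_shift"),
                          update_week = NULL,
                          update_warp = sharpness_update_warp(1.5)) {
  scenario <- match.arg(scenario)
  cases_per_week <- assert_count(cases_per_week, min = 1L)
  images_per_case <- assert_count(images_per_case, min = 1L)
  if (scenario == "new_site") {
    horizon <- 1L
  } else {
    horizon <- assert_count(horizon, min = 4L)
  }
  weeks <- seq_len(horizon) - 1L

  if (scenario == "new_site") {
    counts <- data.frame(week = 0L, device_id = "scanner_b",
                         n_cases = cases_per_week)
    models <- list(scanner_b = model_b)
    update <- NULL
  } else if (scenario == "transition") {
    b <- as.integer(round(cases_per_week * weeks / (horizon - 1L)))
    counts <- rbind(
      data.frame(week = weeks, device_id = "scanner_a",
                 n_cases = cases_per_week - b),
      data.frame(week = weeks, device_id = "scanner_b", n_cases = b)
    )
    models <- list(scanner_a = model_a, scanner_b = model_b)
    update <- NULL
  } else if (scenario == "addition") {
    b <- as.integer(round(cases_per_week * weeks / (horizon - 1L)))
    counts <- rbind(
      data.frame(week = weeks, device_id = "scanner_a",
                 n_cases = cases_per_week),
      data.frame(week = weeks, device_id = "scanner_b", n_cases = b)
    )
    models <- list(scanner_a = model_a, scanner_b = model_b)
    update <- NULL
  } else { # software_update
    update_week <- assert_count(update_week %||% (horizon %/% 2L), min = 0L)
    counts <- data.frame(week = weeks, device_id = "scanner_a",
                         n_cases = cases_per_week)
    models <- list(scanner_a = model_a)
    update <- list(device_id = "scanner_a", week = update_week,
                   warp = update_warp)
  }
  counts <- counts[order(counts$week, counts$device_id), , drop = FALSE]
  rownames(counts) <- NULL
  structure(
    list(scenario = scenario, horizon = horizon, counts = counts,
         models = models, update = update, prevalence = prevalence,
         images_per_case = images_per_case,
         cases_per_week = cases_per_week),
    class = "scenario_schedule"
  )
}

# Domain model in force for a device at a given week (software updates swap
# the warp from the update week onward).
schedule_model <- function(schedule, device_id, week) {
  model <- schedule$models[[device_id]]
  if (is.null(model)) {
    stop(sprintf("schedule has no model for device '%s'", device_id),
         call. = FALSE)
  }
  upd <- schedule$update
  if (!is.null(upd) && identical(upd$device_id, device_id) &&
      week >= upd$week) {
    model$warp <- upd$warp
  }
  model
}

# One simulated week of records across all scheduled devices; draws from the
# current RNG stream.
generate_week <- function(schedule, week) {
  rows <- schedule$counts[schedule$counts$week == week &
                            schedule$counts$n_cases > 0L, , drop = FALSE]
  parts <- lapply(seq_len(nrow(rows)), function(i) {
    generate_records(
      model = schedule_model(schedule, rows$device_id[i], week),
      n_cases = rows$n_cases[i], prevalence = schedule$prevalence,
      images_per_case = schedule$images_per_case,
      device_id = rows$device_id[i], time_index = week
    )
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("record_set", "data.frame")
  out
}

#' @export
print.scenario_schedule <- function(x, ...) {
  totals <- tapply(x$counts$n_cases, x$counts$week, sum)
  cat(sprintf("<scenario_schedule> %s: %d week(s), devices %s, weekly totals %d-%d cases\n",
              x$scenario, x$horizon,
              paste(names(x$models), collapse = ", "),
              min(totals), max(totals)))
  if (!is.null(x$update)) {
    cat(sprintf("  software update on %s at week %d\n",
                x$update$device_id, x$update$week))
  }
  invisible(x)
}
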