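#' Prediction record sets
#'
#' A record set is the tabular atom of the package: one row per image with the
#' model's continuous prediction score, an optional binary ground-truth label,
#' and grouping metadata. All images of one case (a patient study, typically
#' four mammographic views) share `case_id`, `device_id` and `time_index`.
#'
#' @param records A data.frame with columns `score` (numeric in \[0, 1\]),
#'   `case_id`, `image_id`, `device_id` (coerced to character) and optionally
#'   `label` (0/1 or `NA`) and `time_index` (non-negative integer weeks,
#'   defaulting to 0 for static datasets).
#'
#' @return A `record_set`: a data.frame with the canonical column order
#'   `score, label, case_id, image_id, device_id, time_index` and all
#'   invariants checked.
#'
#' @details Invariants enforced: scores lie in \[0, 1\]; labels, when present,
#'   are 0/1; `(case_id, image_id)` is unique; all rows of a case agree on
#'   `device_id` and `time_index`.
#'
#' @examples
#' rs <- record_set(data.frame(
#'   score = c(0.1, 0.2, 0.8, 0.9), label = c(0, 0, 1, 1),
#'   case_id = c("c1", "c1", "c2", "c2"), image_id = c("i1", "i2", "i3", "i4"),
#'   device_id = "scanner_a"
#' ))
#' prevalence(rs)
#' @export
record_set <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("score", "case_id", "image_id", "device_id")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    score = as.numeric(records$score),
    label = if ("label" %in% names(records)) as.numeric(records$label) else rep(NA_real_, nrow(records)),
    case_id = as.character(records$case_id),
    image_id = as.character(records$image_id),
    device_id = as.character(records$device_id),
    time_index = if ("time_index" %in% names(records)) {
      as.integer(records$time_index)
    } else rep(0L, nrow(records)),
    stringsAsFactors = FALSE
  )
  validate_record_set(out)
  class(out) <- c("record_set", "data.frame")
  out
}

validate_record_set <- function(df) {
  if (nrow(df) == 0L) {
    return(invisible(df))
  }
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
  if (length(bad) > 0L) {
    stop(sprintf("%d row(s) rejected: score outside [0, 1] or missing (rows %s)",
                 length(bad),
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  lab <- df$label[!is.na(df$label)]
  if (length(lab) > 0L && !all(lab %in% c(0, 1))) {
    stop("labels must be 0, 1 or missing", call. = FALSE)
  }
  if (anyNA(df$time_index) || any(df$time_index < 0L)) {
    stop("time_index must be a non-negative integer", call. = FALSE)
  }
  key <- paste(df$case_id, df$image_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (case_id, image_id) pair: %s",
                 df$case_id[which(duplicated(key))[1L]]), call. = FALSE)
  }
  per_case <- paste(df$device_id, df$time_index, sep = "\r")
  if (any(tapply(per_case, df$case_id, function(v) length(unique(v))) > 1L)) {
    stop("all images of a case must share device_id and time_index", call. = FALSE)
  }
  invisible(df)
}

#' @rdname record_set
#' @param x A `record_set`.
#' @export
prevalence <- function(x) {
  stopifnot(inherits(x, "record_set"))
  if (nrow(x) == 0L) stop("cannot compute prevalence of an empty record set", call. = FALSE)
  if (anyNA(x$label)) {
    stop("prevalence requested but some labels are missing", call. = FALSE)
  }
  mean(x$label)
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set> %d images, %d cases, %d device(s), weeks %s\n",
              nrow(x), length(unique(x$case_id)), length(unique(x$device_id)),
              if (nrow(x)) paste(range(x$time_index), collapse = "-") else "-"))
  if (!anyNA(x$label) && nrow(x) > 0L) {
    cat(sprintf("  prevalence (image-wise): %.4f\n", mean(x$label)))
  }
  invisible(x)
}

record_columns <- c("score", "label", "case_id", "image_id", "device_id", "time_index")

#' Read and write prediction record tables
#'
#' CSV (comma-separated, UTF-8, mandatory header) and JSON (array of objects)
#' are supported. Missing labels are written as empty cells; scores are
#' written at full precision because the alignment transform is sensitive to
#' rank order. Reading enforces all `record_set` invariants; out-of-range or
#' non-numeric scores abort with the offending row number so that no row is
#' ever silently dropped.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#'
#' @return `read_records()` returns a [record_set()]; `write_records()`
#'   returns `path` invisibly.
#' @export
read_records <- function(path, format = c("auto", "csv", "json")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0L) raw <- data.frame()
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_record_set())
  }
  required <- c("score", "case_id", "image_id", "device_id")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(raw$score))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1L]
    stop(sprintf("non-numeric score at row %d: '%s'", bad, raw$score[bad]),
         call. = FALSE)
  }
  raw$score <- score
  if ("label" %in% names(raw)) {
    lab <- as.character(raw$label)
    lab[lab == ""] <- NA_character_
    raw$label <- suppressWarnings(as.numeric(lab))
  }
  if ("time_index" %in% names(raw)) {
    ti <- as.character(raw$time_index)
    ti[ti == ""] <- "0"
    raw$time_index <- as.integer(ti)
  }
  record_set(raw)
}

#' @rdname read_records
#' @param rs A [record_set()].
#' @export
write_records <- function(rs, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(rs, "record_set"))
  format <- resolve_format(match.arg(format), path)
  df <- as.data.frame(rs)[, record_columns, drop = FALSE]
  if (format == "csv") {
    # format() would round; write scores via as.character at full precision
    out <- df
    out$score <- vapply(df$score, format_score, character(1L))
    out$label <- ifelse(is.na(df$label), "", as.character(df$label))
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

format_score <- function(x) {
  sprintf("%.17g", x)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}

empty_record_set <- function() {
  record_set(data.frame(score = numeric(0), label = numeric(0),
                        case_id = character(0), image_id = character(0),
                        device_id = character(0), time_index = integer(0),
                        stringsAsFactors = FALSE))
}
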