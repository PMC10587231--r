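# Internal argument checks shared across modules.

assert_scores <- function(x, arg = deparse(substitute(x))) {
  if (length(x) == 0L) {
    stop(sprintf("'%s' must contain at least one score", arg), call. = FALSE)
  }
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be numeric", arg), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' contains missing or non-finite scores", arg), call. = FALSE)
  }
  if (any(x < 0 | x > 1)) {
    bad <- which(x < 0 | x > 1)[1L]
    stop(sprintf("'%s' contains scores outside [0, 1] (first at position %d: %g)",
                 arg, bad, x[bad]), call. = FALSE)
  }
  invisible(x)
}

assert_binary_labels <- function(labels, require_both = TRUE,
                                 arg = deparse(substitute(labels))) {
  if (length(labels) == 0L || anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop(sprintf("'%s' must be a complete vector of 0/1 labels", arg), call. = FALSE)
  }
  if (require_both) {
    if (!any(labels == 1)) {
      stop("labels contain no positives; sensitivity is undefined", call. = FALSE)
    }
    if (!any(labels == 0)) {
      stop("labels contain no negatives; specificity is undefined", call. = FALSE)
    }
  }
  invisible(labels)
}

assert_count <- function(x, min = 1L, arg = deparse(substitute(x))) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", arg, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
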