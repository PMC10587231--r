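#' Empirical cumulative distribution function of prediction scores
#'
#' Right-continuous step function: at any query `x` the value is the fraction
#' of scores less than or equal to `x` — 0 below the minimum, 1 at and above
#' the maximum.
#'
#' @param scores Numeric vector of scores in \[0, 1\].
#' @return A function mapping reals to \[0, 1\].
#' @examples
#' F <- empirical_cdf(c(0.2, 0.4, 0.6, 0.8))
#' F(0.4) # 0.5
#' @export
empirical_cdf <- function(scores) {
  assert_scores(scores, "scores")
  ecdf(scores)
}

#' Fit the prediction-alignment transform
#'
#' Fits a monotone piecewise-linear map from the shifted score domain onto the
#' reference score domain by cumulative-distribution matching (the score-space
#' analogue of histogram matching). Each distinct alignment score `a` becomes
#' a source knot; its empirical CDF level `q = #\{alignment <= a\}/n` is looked
#' up in the reference distribution, and the matched reference quantile at
#' level `q` becomes the target knot. Between knots the map is linear; beyond
#' the outermost knots it continues with the slope of the outermost segment
#' and is clipped to \[0, 1\] on application.
#'
#' Because the map is monotone non-decreasing it never changes the relative
#' order of predictions, so ROC-AUC is identical before and after alignment
#' (exactly so when the scores carry no ties).
#'
#' No labels are used: fitting is entirely unsupervised.
#'
#' @param reference Scores from the reference (in-distribution) domain — the
#'   matching target, typically the validation set used to calibrate the
#'   operating point.
#' @param alignment Unlabelled scores from the shifted domain.
#' @param min_fit_size Minimum number of alignment scores required (default
#'   2); a transform is refused, not degraded, below it.
#'
#' @return An `alignment_transform` with fields `source_knots`,
#'   `target_knots`, `fit_size`, `reference_size`.
#'
#' @details The reference quantile at level `q` interpolates linearly between
#'   order statistics, assigning order statistic `i` of `n` the level `i/n`
#'   (the same convention as [empirical_cdf()]); levels below `1/n` clamp to
#'   the smallest order statistic. Under this convention aligning a set to
#'   itself is exactly the identity at every knot. Tied alignment scores share
#'   a knot and therefore always map to equal outputs.
#'
#' @examples
#' ref <- c(0.1, 0.3, 0.5, 0.7, 0.9)
#' tr <- fit_alignment(ref, ref + 0.05)
#' apply_alignment(tr, 0.35) # 0.3: the location shift is inverted
#' @seealso [apply_alignment()], [detect_shift()]
#' @export
fit_alignment <- function(reference, alignment, min_fit_size = 2L) {
  assert_scores(reference, "reference")
  assert_scores(alignment, "alignment")
  min_fit_size <- assert_count(min_fit_size, min = 2L)
  if (length(alignment) < min_fit_size) {
    stop(sprintf("alignment set has %d score(s); at least %d required",
                 length(alignment), min_fit_size), call. = FALSE)
  }
  src <- sort(unique(alignment))
  if (length(src) < 2L) {
    stop("alignment set has fewer than 2 distinct scores; cannot fit a transform",
         call. = FALSE)
  }
  q <- findInterval(src, sort(alignment)) / length(alignment)
  tgt <- order_statistic_quantile(reference, q)
  structure(
    list(source_knots = src, target_knots = tgt,
         fit_size = length(alignment), reference_size = length(reference)),
    class = "alignment_transform"
  )
}

# Quantile by linear interpolation between order statistics, order statistic
# i of n at level i/n; levels below 1/n clamp to the minimum.
order_statistic_quantile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 1L) {
    return(rep(xs, length(q)))
  }
  levels <- seq_len(n) / n
  approx(levels, xs, xout = pmax(q, levels[1L]),
         method = "linear", rule = 2, ties = "ordered")$y
}

#' Apply a fitted alignment transform to scores
#'
#' Linear interpolation between the transform's knots; outside the knot range
#' the map extends linearly with the outermost segment's slope and the result
#' is clipped to \[0, 1\]. Input scores outside \[0, 1\] are an error, never
#' silently clamped.
#'
#' @param transform An `alignment_transform` from [fit_alignment()].
#' @param scores Scores in \[0, 1\] from the shifted domain.
#' @return Aligned scores, same length and order, in \[0, 1\]; monotone
#'   non-decreasing in the input.
#' @export
apply_alignment <- function(transform, scores) {
  stopifnot(inherits(transform, "alignment_transform"))
  assert_scores(scores, "scores")
  s <- transform$source_knots
  t <- transform$target_knots
  k <- length(s)
  out <- approx(s, t, xout = scores, method = "linear",
                rule = 2, ties = "ordered")$y
  lo <- scores < s[1L]
  hi <- scores > s[k]
  if (any(lo)) {
    slope <- (t[2L] - t[1L]) / (s[2L] - s[1L])
    out[lo] <- t[1L] + (scores[lo] - s[1L]) * slope
  }
  if (any(hi)) {
    slope <- (t[k] - t[k - 1L]) / (s[k] - s[k - 1L])
    out[hi] <- t[k] + (scores[hi] - s[k]) * slope
  }
  pmin(1, pmax(0, out))
}

#' @export
print.alignment_transform <- function(x, ...) {
  cat(sprintf("<alignment_transform> %d knots | fitted on %d alignment scores vs %d reference scores\n",
              length(x$source_knots), x$fit_size, x$reference_size))
  rng <- range(x$source_knots)
  cat(sprintf("  source range [%.4f, %.4f] -> target range [%.4f, %.4f]\n",
              rng[1L], rng[2L], x$target_knots[1L],
              x$target_knots[length(x$target_knots)]))
  invisible(x)
}

#' Detect a distribution shift between reference and incoming scores
#'
#' Two-sample Kolmogorov-Smirnov distance between the empirical score
#' distributions: `sup |ECDF_ref - ECDF_window|`. A shift is flagged when the
#' statistic exceeds `threshold`.
#'
#' @param reference Reference-domain scores.
#' @param window Recent scores from the monitored stream.
#' @param threshold Flagging threshold on the KS statistic (default 0.1).
#' @return A list with `statistic` (in \[0, 1\]), `flagged` and `threshold`.
#' @export
detect_shift <- function(reference, window, threshold = 0.1) {
  assert_scores(reference, "reference")
  assert_scores(window, "window")
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  grid <- sort(unique(c(reference, window)))
  statistic <- max(abs(ecdf(reference)(grid) - ecdf(window)(grid)))
  list(statistic = statistic, flagged = statistic > threshold,
       threshold = threshold)
}

#' Serialise an alignment transform to and from JSON
#'
#' A fitted transform is a small audit-friendly object; the JSON holds
#' `source_knots`, `target_knots`, `fit_size` and `reference_size` at full
#' precision so a shipped transform reproduces bit-identical alignments.
#'
#' @param transform An `alignment_transform`.
#' @param path JSON file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns the `alignment_transform`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "alignment_transform"))
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  tr <- structure(
    list(source_knots = as.numeric(obj$source_knots),
         target_knots = as.numeric(obj$target_knots),
         fit_size = as.integer(obj$fit_size),
         reference_size = as.integer(obj$reference_size)),
    class = "alignment_transform"
  )
  validate_transform(tr)
  tr
}

validate_transform <- function(tr) {
  s <- tr$source_knots
  t <- tr$target_knots
  if (length(s) != length(t) || length(s) < 2L) {
    stop("transform must have equally many source and target knots (>= 2)",
         call. = FALSE)
  }
  if (is.unsorted(s, strictly = TRUE)) {
    stop("source knots must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(t)) {
    stop("target knots must be non-decreasing", call. = FALSE)
  }
  invisible(tr)
}
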