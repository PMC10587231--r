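#' Monotone score warps modelling acquisition shift
#'
#' Acquisition shift (a new scanner, a different staining protocol, an image
#' processing update) is modelled as a strictly increasing warp of the score
#' in \[0, 1\]. A strictly monotone warp changes the score *distribution* —
#' and thereby breaks a pre-calibrated threshold — while preserving the rank
#' order of predictions, hence ROC-AUC: exactly the regime the alignment
#' method assumes.
#'
#' Families:
#' \describe{
#'   \item{`warp_identity()`}{No shift.}
#'   \item{`warp_affine_latent(shift, scale)`}{Affine map on the logit of the
#'     score, `x -> plogis(shift + scale * qlogis(x))` with `scale > 0`. A
#'     negative `shift` models a scanner whose images make the model score
#'     systematically lower.}
#'   \item{`warp_power(gamma)`}{`x -> x^gamma`, `gamma > 0`.}
#'   \item{`sharpness_update_warp(strength)`}{Odds-power warp
#'     `x -> x^(1+s) / (x^(1+s) + (1-x)^(1+s))`, `s >= 0`: identity at
#'     `s = 0`, fixed points at 0 and 1, and pushes scores towards the
#'     extremes — the score-space counterpart of a processing update that
#'     increases image sharpness and makes the model more confident.}
#' }
#'
#' @param shift,scale,gamma,strength Family parameters; see above.
#' @return A `score_warp` object usable in [domain_model()] and
#'   [apply_warp()].
#' @export
warp_identity <- function() {
  new_warp("identity", list())
}

#' @rdname warp_identity
#' @export
warp_affine_latent <- function(shift, scale = 1) {
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift),
            is.numeric(scale), length(scale) == 1L, scale > 0)
  new_warp("affine_latent", list(shift = shift, scale = scale))
}

#' @rdname warp_identity
#' @export
warp_power <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  new_warp("power_score", list(gamma = gamma))
}

#' @rdname warp_identity
#' @export
sharpness_update_warp <- function(strength) {
  if (!is.numeric(strength) || length(strength) != 1L || is.na(strength) ||
      strength < 0) {
    stop("'strength' must be a single non-negative number", call. = FALSE)
  }
  new_warp("sharpness", list(strength = strength))
}

new_warp <- function(family, params) {
  structure(list(family = family, params = params), class = "score_warp")
}

#' @rdname warp_identity
#' @param warp A `score_warp`.
#' @param x Scores in \[0, 1\].
#' @export
apply_warp <- function(warp, x) {
  stopifnot(inherits(warp, "score_warp"))
  assert_scores(x, "x")
  p <- warp$params
  switch(warp$family,
    identity = x,
    affine_latent = plogis(p$shift + p$scale * qlogis(x)),
    power_score = x^p$gamma,
    sharpness = {
      s <- 1 + p$strength
      a <- x^s
      b <- (1 - x)^s
      out <- a / (a + b)
      # 0^s/(0^s + 1^s) and the x = 1 counterpart are exact fixed points
      out[x == 0] <- 0
      out[x == 1] <- 1
      out
    },
    stop(sprintf("unknown warp family '%s'", warp$family), call. = FALSE)
  )
}

#' @export
print.score_warp <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  } else ""
  cat(sprintf("<score_warp> %s(%s)\n", x$family, ps))
  invisible(x)
}

#' Binormal-on-logit score model for one acquisition domain
#'
#' Class-conditional score distributions: a latent decision variable
#' `z ~ Normal(mu_class, sigma)` is squashed through the logistic function
#' and then passed through the domain's acquisition warp,
#' `score = warp(plogis(z))`. The binormal latent gives the closed-form
#' separability `AUC = pnorm((mu_pos - mu_neg) / (sigma * sqrt(2)))`, which
#' any strictly monotone warp leaves unchanged — so warped domains reproduce
#' the regime of AUC generalisation with threshold shift.
#'
#' @param mu_neg,mu_pos Latent means of the negative and positive class
#'   (`mu_pos > mu_neg`).
#' @param sigma Latent standard deviation (> 0), shared by both classes.
#' @param warp A [warp_identity()]-family `score_warp`.
#' @return A `domain_model`.
#' @examples
#' m <- domain_model() # defaults: mu 0/2, sigma 1 -> AUC = pnorm(sqrt(2))
#' binormal_auc(m)
#' @export
domain_model <- function(mu_neg = 0, mu_pos = 2, sigma = 1,
                         warp = warp_identity()) {
  stopifnot(is.numeric(mu_neg), is.numeric(mu_pos), is.numeric(sigma),
            length(mu_neg) == 1L, length(mu_pos) == 1L, length(sigma) == 1L,
            inherits(warp, "score_warp"))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a positive number", call. = FALSE)
  }
  if (!(mu_pos > mu_neg)) {
    stop("'mu_pos' must exceed 'mu_neg' (positives score higher in expectation)",
         call. = FALSE)
  }
  structure(list(mu_neg = mu_neg, mu_pos = mu_pos, sigma = sigma, warp = warp),
            class = "domain_model")
}

#' @rdname domain_model
#' @param model A `domain_model`.
#' @export
binormal_auc <- function(model) {
  stopifnot(inherits(model, "domain_model"))
  pnorm((model$mu_pos - model$mu_neg) / (model$sigma * sqrt(2)))
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model> latent N(%g, %g^2) vs N(%g, %g^2); closed-form AUC %.4f; warp %s\n",
              x$mu_neg, x$sigma, x$mu_pos, x$sigma, binormal_auc(x),
              x$warp$family))
  invisible(x)
}

#' Shipped domain-model presets
#'
#' `"reference"`: the unshifted source domain (identity warp).
#' `"scanner_shift"`: a strong scanner-replacement shift — latent logit shift
#' of -1.5 — whose closed-form balanced operating point breaks by
#' `|SEN - SPC| ~ 0.69` (before-correction Youden ~ 0.30) while AUC is
#' untouched. `"sharpness_update"`: an odds-power sharpening of strength 1.5,
#' breaking the balanced point by `|SEN - SPC| ~ 0.29`.
#'
#' @param name Preset name.
#' @return A `domain_model`.
#' @export
preset_domain_model <- function(name = c("reference", "scanner_shift",
                                         "sharpness_update")) {
  name <- match.arg(name)
  switch(name,
    reference = domain_model(),
    scanner_shift = domain_model(warp = warp_affine_latent(shift = -1.5)),
    sharpness_update = domain_model(warp = sharpness_update_warp(1.5))
  )
}

#' Study-design presets
#'
#' Screening-like and balanced data regimes: `preset_mammography()` mirrors a
#' breast-screening stream (prevalence 0.02, 4 images per case, 250 cases per
#' week); `preset_histopathology()` mirrors a balanced patch-classification
#' set (prevalence 0.5, 1 image per case).
#'
#' @return A list with `model`, `prevalence`, `images_per_case`,
#'   `cases_per_week`.
#' @export
preset_mammography <- function() {
  list(model = preset_domain_model("reference"), prevalence = 0.02,
       images_per_case = 4L, cases_per_week = 250L)
}

#' @rdname preset_mammography
#' @export
preset_histopathology <- function() {
  list(model = preset_domain_model("reference"), prevalence = 0.5,
       images_per_case = 1L, cases_per_week = 250L)
}

#' Generate a synthetic prediction record set
#'
#' Case labels are drawn `Bernoulli(prevalence)`; every image of a case
#' inherits the case label (all four views of a malignant study are positive
#' in the image-wise accounting). Each image receives an independent latent
#' draw `z ~ Normal(mu_class, sigma)` and the score `warp(plogis(z))`.
#' Deterministic under `seed`.
#'
#' @param model A [domain_model()].
#' @param n_cases Number of cases (>= 1).
#' @param prevalence Case-level positive fraction in \[0, 1\].
#' @param images_per_case Images per case (default 1).
#' @param device_id,time_index Metadata stamped on every record.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers that seed once can draw many sets reproducibly).
#' @param case_prefix Prefix for generated case identifiers; defaults to a
#'   device/time-derived prefix that keeps ids unique across weeks.
#' @return A [record_set()].
#' @export
generate_records <- function(model, n_cases, prevalence,
                             images_per_case = 1L, device_id = "device_a",
                             time_index = 0L, seed = NULL,
                             case_prefix = NULL) {
  stopifnot(inherits(model, "domain_model"))
  n_cases <- assert_count(n_cases, min = 1L)
  images_per_case <- assert_count(images_per_case, min = 1L)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("'prevalence' must be a single number in [0, 1]", call. = FALSE)
  }
  time_index <- assert_count(time_index, min = 0L)
  if (!is.null(seed)) set.seed(seed)
  case_prefix <- case_prefix %||% sprintf("%s_t%03d", device_id, time_index)

  case_label <- rbinom(n_cases, 1L, prevalence)
  label <- rep(case_label, each = images_per_case)
  mu <- ifelse(label == 1, model$mu_pos, model$mu_neg)
  z <- rnorm(n_cases * images_per_case, mean = mu, sd = model$sigma)
  score <- apply_warp(model$warp, plogis(z))

  case_id <- rep(sprintf("%s_c%05d", case_prefix, seq_len(n_cases)),
                 each = images_per_case)
  image_id <- paste0(case_id, "_i", rep(seq_len(images_per_case), n_cases))
  record_set(data.frame(
    score = score, label = label, case_id = case_id, image_id = image_id,
    device_id = device_id, time_index = time_index, stringsAsFactors = FALSE
  ))
}
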