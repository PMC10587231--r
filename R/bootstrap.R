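#' Configuration for the new-site bootstrap evaluation
#'
#' @param n_eval_cases Cases drawn per repetition for the evaluation set
#'   (default 2500).
#' @param n_align_cases Cases drawn per repetition, disjoint from the
#'   evaluation draw, to fit the alignment transform (default 1000).
#' @param n_reps Number of repetitions (default 500). Each repetition draws
#'   its evaluation and alignment sets independently — without replacement
#'   within a repetition (the two sets are disjoint by case), with cases
#'   reusable across repetitions.
#' @param seed Integer seed.
#' @return A `bootstrap_config`.
#' @export
bootstrap_config <- function(n_eval_cases = 2500L, n_align_cases = 1000L,
                             n_reps = 500L, seed = 1L) {
  structure(
    list(n_eval_cases = assert_count(n_eval_cases),
         n_align_cases = assert_count(n_align_cases),
         n_reps = assert_count(n_reps),
         seed = assert_count(seed, min = 0L)),
    class = "bootstrap_config"
  )
}

#' New-site deployment evaluation by repeated sampling
#'
#' The scenario: a classifier calibrated at a balanced operating point on
#' reference data is deployed to a site with an acquisition shift. Each
#' repetition draws an evaluation set and a disjoint alignment set (case-level
#' draws; all images of a drawn case are included) from the target domain,
#' fits the alignment transform from the unlabelled alignment scores against
#' the reference scores, and evaluates sensitivity, specificity, ROC-AUC,
#' Youden's index and SEN - SPC at the frozen threshold on the evaluation
#' images, before and after alignment. Results are aggregated over
#' repetitions (mean, s.d., percentiles 5/25/50/75/95).
#'
#' @param target Labelled [record_set()] from the shifted domain.
#' @param reference Reference-domain [record_set()] (scores only are used
#'   for matching).
#' @param op An [operating_point][select_threshold_balanced] frozen on the
#'   reference domain.
#' @param cfg A [bootstrap_config()].
#' @return A `bootstrap_summary`: `summary` data.frame (one row per metric x
#'   before/after), and the per-repetition `reps` data.frame.
#' @export
scenario1_bootstrap <- function(target, reference, op, cfg = bootstrap_config()) {
  stopifnot(inherits(target, "record_set"), inherits(reference, "record_set"),
            inherits(op, "operating_point"), inherits(cfg, "bootstrap_config"))
  if (anyNA(target$label)) {
    stop("the target set must be labelled for evaluation", call. = FALSE)
  }
  case_ids <- unique(target$case_id)
  need <- cfg$n_eval_cases + cfg$n_align_cases
  if (length(case_ids) < need) {
    stop(sprintf("target has %d cases; %d required (%d evaluation + %d alignment)",
                 length(case_ids), need, cfg$n_eval_cases, cfg$n_align_cases),
         call. = FALSE)
  }
  set.seed(cfg$seed)
  case_of_row <- match(target$case_id, case_ids)
  thr <- op$threshold
  ref_scores <- reference$score

  reps <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    drawn <- sample.int(length(case_ids), need, replace = FALSE)
    eval_cases <- drawn[seq_len(cfg$n_eval_cases)]
    align_cases <- drawn[-seq_len(cfg$n_eval_cases)]
    stopifnot(length(intersect(eval_cases, align_cases)) == 0L)
    eval_idx <- case_of_row %in% eval_cases
    align_scores <- target$score[case_of_row %in% align_cases]

    tr <- fit_alignment(ref_scores, align_scores)
    s_before <- target$score[eval_idx]
    s_after <- apply_alignment(tr, s_before)
    lab <- target$label[eval_idx]

    reps[[r]] <- rbind(
      data.frame(rep = r, aligned = FALSE, rep_metrics(s_before, lab, thr)),
      data.frame(rep = r, aligned = TRUE, rep_metrics(s_after, lab, thr))
    )
  }
  reps <- do.call(rbind, reps)
  new_bootstrap_summary(reps, cfg)
}

rep_metrics <- function(scores, labels, threshold) {
  ss <- sen_spc(scores, labels, threshold)
  data.frame(sensitivity = unname(ss[1L]), specificity = unname(ss[2L]),
             auc = roc_auc(scores, labels),
             youden = unname(ss[1L] + ss[2L] - 1),
             sen_spc_gap = unname(ss[1L] - ss[2L]))
}

new_bootstrap_summary <- function(reps, cfg) {
  metric_names <- c("sensitivity", "specificity", "auc", "youden", "sen_spc_gap")
  rows <- list()
  for (al in c(FALSE, TRUE)) {
    g <- reps[reps$aligned == al, , drop = FALSE]
    for (m in metric_names) {
      v <- g[[m]]
      qs <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, aligned = al, mean = mean(v), sd = stats::sd(v),
        p05 = qs[1L], p25 = qs[2L], p50 = qs[3L], p75 = qs[4L], p95 = qs[5L])
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, reps = reps, config = cfg),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %d repetitions (eval %d / align %d cases)\n",
              x$config$n_reps, x$config$n_eval_cases, x$config$n_align_cases))
  s <- x$summary
  for (al in c(FALSE, TRUE)) {
    g <- s[s$aligned == al, , drop = FALSE]
    cat(sprintf("  %s alignment:\n", if (al) "after " else "before"))
    for (i in seq_len(nrow(g))) {
      cat(sprintf("    %-12s mean %+.4f (sd %.4f)  [p05 %+.4f, p95 %+.4f]\n",
                  g$metric[i], g$mean[i], g$sd[i], g$p05[i], g$p95[i]))
    }
  }
  invisible(x)
}

#' Sensitivity of the alignment to the sizes of its input sets
#'
#' Sweeps the alignment-set size at the full reference (the alignment-size
#' analysis) and the reference-set size at a fixed 500-case alignment set
#' (the reference-size analysis), re-running the bootstrap protocol at each
#' grid point.
#'
#' Grid points are coupled by common random numbers: within one repetition
#' every size shares the same evaluation draw, alignment sets are nested
#' subsets of the largest draw, and reference subsets are nested subsets of
#' one permutation. Each grid point's marginal distribution is exactly the
#' repeated-sampling protocol of [scenario1_bootstrap()]; the coupling only
#' stabilises comparisons *across* sizes (the dispersion of the recovered
#' operating point is expected to shrink as the alignment set grows).
#'
#' @inheritParams scenario1_bootstrap
#' @param align_sizes Integer vector of alignment-set sizes in cases
#'   (`NULL` to skip the sweep).
#' @param ref_sizes Integer vector of reference-set sizes in cases (`NULL`
#'   to skip); the alignment set is fixed at `fixed_align_cases`.
#' @param fixed_align_cases Alignment-set size used during the reference-size
#'   sweep (default 500 cases).
#' @return A `size_sensitivity` object: `grid`, a data.frame with one row per
#'   grid point (`sweep`, `size`, the mean/sd/percentiles of the
#'   after-alignment SEN - SPC, and `spread_after` = p95 - p05), plus the
#'   per-repetition `reps` data.frame and the shared before-alignment
#'   summary row.
#' @export
size_sensitivity <- function(target, reference, op,
                             align_sizes = c(250L, 500L, 1000L),
                             ref_sizes = NULL, cfg = bootstrap_config(),
                             fixed_align_cases = 500L) {
  stopifnot(inherits(target, "record_set"), inherits(reference, "record_set"),
            inherits(op, "operating_point"), inherits(cfg, "bootstrap_config"))
  if (anyNA(target$label)) {
    stop("the target set must be labelled for evaluation", call. = FALSE)
  }
  align_sizes <- sort(unique(as.integer(align_sizes)))
  ref_sizes <- if (is.null(ref_sizes)) integer(0) else sort(unique(as.integer(ref_sizes)))
  if (any(c(align_sizes, ref_sizes, fixed_align_cases) < 2L)) {
    stop("all sizes must be at least 2 cases", call. = FALSE)
  }
  case_ids <- unique(target$case_id)
  max_align <- max(c(align_sizes, if (length(ref_sizes)) fixed_align_cases else NULL))
  need <- cfg$n_eval_cases + max_align
  if (length(case_ids) < need) {
    stop(sprintf("target has %d cases; %d required (%d evaluation + %d alignment)",
                 length(case_ids), need, cfg$n_eval_cases, max_align),
         call. = FALSE)
  }
  ref_case_ids <- unique(reference$case_id)
  if (length(ref_sizes) && max(ref_sizes) > length(ref_case_ids)) {
    stop(sprintf("reference has %d cases; %d requested", length(ref_case_ids),
                 max(ref_sizes)), call. = FALSE)
  }
  set.seed(cfg$seed)
  case_of_row <- match(target$case_id, case_ids)
  ref_case_of_row <- match(reference$case_id, ref_case_ids)
  thr <- op$threshold

  rep_rows <- list()
  for (r in seq_len(cfg$n_reps)) {
    drawn <- sample.int(length(case_ids), need, replace = FALSE)
    eval_cases <- drawn[seq_len(cfg$n_eval_cases)]
    align_pool <- drawn[-seq_len(cfg$n_eval_cases)]
    eval_idx <- case_of_row %in% eval_cases
    s_eval <- target$score[eval_idx]
    lab <- target$label[eval_idx]
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      rep = r, sweep = "none", size = NA_integer_, aligned = FALSE,
      rep_metrics(s_eval, lab, thr))
    for (a in align_sizes) {
      align_scores <- target$score[case_of_row %in% align_pool[seq_len(a)]]
      tr <- fit_alignment(reference$score, align_scores)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        rep = r, sweep = "alignment", size = a, aligned = TRUE,
        rep_metrics(apply_alignment(tr, s_eval), lab, thr))
    }
    if (length(ref_sizes)) {
      align_scores <- target$score[case_of_row %in%
                                     align_pool[seq_len(fixed_align_cases)]]
      ref_perm <- sample.int(length(ref_case_ids))
      for (nr in ref_sizes) {
        sub_scores <- reference$score[ref_case_of_row %in% ref_perm[seq_len(nr)]]
        tr <- fit_alignment(sub_scores, align_scores)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          rep = r, sweep = "reference", size = nr, aligned = TRUE,
          rep_metrics(apply_alignment(tr, s_eval), lab, thr))
      }
    }
  }
  reps <- do.call(rbind, rep_rows)
  grid <- do.call(rbind, lapply(
    split(reps[reps$aligned, , drop = FALSE],
          interaction(reps$sweep[reps$aligned], reps$size[reps$aligned],
                      drop = TRUE)),
    function(g) {
      qs <- quantile(g$sen_spc_gap, c(0.05, 0.25, 0.5, 0.75, 0.95),
                     names = FALSE)
      data.frame(sweep = g$sweep[1L], size = g$size[1L],
                 mean_gap_after = mean(g$sen_spc_gap),
                 sd = stats::sd(g$sen_spc_gap),
                 p05 = qs[1L], p25 = qs[2L], p50 = qs[3L], p75 = qs[4L],
                 p95 = qs[5L], spread_after = qs[5L] - qs[1L])
    }))
  grid <- grid[order(grid$sweep, grid$size), , drop = FALSE]
  rownames(grid) <- NULL
  before <- reps[!reps$aligned, , drop = FALSE]
  structure(
    list(grid = grid, reps = reps,
         before = data.frame(mean_gap_before = mean(before$sen_spc_gap),
                             sd = stats::sd(before$sen_spc_gap))),
    class = "size_sensitivity"
  )
}

#' @export
print.size_sensitivity <- function(x, ...) {
  cat(sprintf("<size_sensitivity> before alignment: mean SEN-SPC %+.3f\n",
              x$before$mean_gap_before))
  print(x$grid[, c("sweep", "size", "mean_gap_after", "spread_after")],
        row.names = FALSE)
  invisible(x)
}
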