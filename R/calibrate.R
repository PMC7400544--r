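# Significance-threshold calibration: synthetic two-component mixtures of
# leukocyte-rich (positive) and leukocyte-free (negative) samples, the
# fraction of significant deconvolutions as a function of unknown content,
# loess smoothing, and ROC analysis at fixed unknown-content windows.

#' Build a grid of synthetic positive/negative two-component mixtures
#'
#' For each unknown-content level `w` in `{0, w_step, ..., 1}`, draws `reps`
#' random (positive sample, negative sample) pairs and forms the convex
#' combination `(1 - w) * positive + w * negative`. The full-scale
#' calibration grid is `w_step = 0.001, reps = 200` (200,200 mixtures); the
#' defaults here are a reduced grid sized for interactive use.
#'
#' @param positives Beta tibble of leukocyte-rich samples.
#' @param negatives Beta tibble of leukocyte-free samples (same CpGs).
#' @param w_step Unknown-content increment; must divide 1 evenly.
#' @param reps Mixtures per level.
#' @param seed Integer seed.
#' @return A list of class `md_mixture_grid`: `mixtures` (Beta tibble) and
#'   `truth` (tibble: `sample_id`, `w`, `positive_id`, `negative_id`).
#' @export
build_mixture_grid <- function(positives, negatives, w_step = 0.01,
                               reps = 20, seed = NULL) {
  stopifnot(ncol(positives) > 1L, ncol(negatives) > 1L, reps >= 1)
  n_levels <- 1 / w_step
  if (abs(n_levels - round(n_levels)) > 1e-9) {
    stop("w_step must divide 1 evenly")
  }
  stopifnot(identical(positives$cpg_id, negatives$cpg_id))
  P <- beta_matrix(positives)
  N <- beta_matrix(negatives)
  ws <- seq(0, 1, by = w_step)
  with_seed(seed, {
    total <- length(ws) * reps
    out <- matrix(NA_real_, nrow(P), total)
    truth <- vector("list", total)
    idx <- 0L
    for (w in ws) {
      for (r in seq_len(reps)) {
        idx <- idx + 1L
        pi <- sample(ncol(P), 1)
        ni <- sample(ncol(N), 1)
        out[, idx] <- (1 - w) * P[, pi] + w * N[, ni]
        truth[[idx]] <- tibble::tibble(
          sample_id = sprintf("w%0.4f_r%03d", w, r), w = w,
          positive_id = colnames(P)[pi], negative_id = colnames(N)[ni])
      }
    }
    truth <- dplyr::bind_rows(truth)
    colnames(out) <- truth$sample_id
    mixtures <- tibble::tibble(cpg_id = rownames(P),
                               !!!as.data.frame(out))
    structure(list(mixtures = mixtures, truth = truth, w_step = w_step,
                   reps = reps),
              class = "md_mixture_grid")
  })
}

#' Expected mixture count of a calibration grid
#'
#' `(1/w_step + 1) * reps` mixtures: one batch of `reps` at each level of
#' `w` from 0 to 1 inclusive.
#'
#' @inheritParams build_mixture_grid
#' @return Integer mixture count.
#' @export
mixture_grid_size <- function(w_step, reps) {
  n_levels <- 1 / w_step
  if (abs(n_levels - round(n_levels)) > 1e-9) {
    stop("w_step must divide 1 evenly")
  }
  as.integer((round(n_levels) + 1) * reps)
}

#' Fraction of significant deconvolutions versus unknown content
#'
#' For each threshold, computes the fraction of mixtures at each `w` level
#' whose R2 meets the threshold, fits a loess curve (span 0.25, degree 2)
#' over `w`, and reads the fitted value at `w = 1` off as the estimated
#' false-positive rate (the call rate on pure unknown content).
#'
#' @param results Tibble with columns `w` and `R2` (deconvolution results
#'   joined to the grid truth).
#' @param thresholds R2 thresholds to profile, each in (0, 1).
#' @param span Loess smoothing span (default 0.25).
#' @return A list of class `md_threshold_curve`: `curve` (tibble `threshold`,
#'   `w`, `frac_significant`, `loess_fit`), `fpr` (tibble `threshold`,
#'   `fpr_at_w1`) and `span`.
#' @export
significant_fraction_curve <- function(results, thresholds = seq(0.2, 0.9, by = 0.1),
                                       span = 0.25) {
  stopifnot(all(c("w", "R2") %in% names(results)))
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  curves <- purrr::map(thresholds, function(th) {
    lv <- results |>
      dplyr::group_by(w = .data$w) |>
      dplyr::summarise(frac_significant = mean(.data$R2 >= th),
                       .groups = "drop") |>
      dplyr::mutate(threshold = th)
    if (nrow(lv) >= 20) {   # loess at span 0.25 needs enough w levels
      lo <- stats::loess(frac_significant ~ w, data = lv, span = span,
                         degree = 2, family = "gaussian")
      lv$loess_fit <- stats::predict(lo, lv$w)
    } else {
      lv$loess_fit <- lv$frac_significant
    }
    lv
  })
  curve <- dplyr::bind_rows(curves)
  fpr <- curve |>
    dplyr::group_by(threshold = .data$threshold) |>
    dplyr::summarise(
      fpr_at_w1 = clip01(.data$loess_fit[which.max(.data$w)]),
      .groups = "drop")
  structure(list(curve = curve, fpr = fpr, span = span),
            class = "md_threshold_curve")
}

#' @export
autoplot.md_threshold_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$w, y = .data$frac_significant,
                               colour = factor(.data$threshold))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loess_fit)) +
    ggplot2::labs(x = "unknown content w", y = "fraction significant",
                  colour = "R2 threshold") +
    ggplot2::theme_minimal()
}

#' ROC analysis of a significance score at a fixed unknown content
#'
#' Sweeps a decision threshold over \[0, 1\] and reports sensitivity (on the
#' positive scores, e.g. R2 of mixtures in a +/-2.5% window around a target
#' unknown content) and specificity (on negative scores, e.g. R2 of
#' negative-negative pair mixtures). AUROC is computed by the trapezoid rule
#' and the operating point maximising Youden's J = sensitivity +
#' specificity - 1 is reported.
#'
#' @param scores_pos Numeric scores of true-positive mixtures.
#' @param scores_neg Numeric scores of true-negative mixtures.
#' @param threshold_step Sweep increment (default 0.001).
#' @return A list of class `md_roc`: `roc` (tibble `threshold`,
#'   `sensitivity`, `specificity`), `auroc`, `youden_threshold`, `youden_j`.
#' @export
roc_at_unknown_content <- function(scores_pos, scores_neg,
                                   threshold_step = 0.001) {
  if (!length(scores_pos)) stop("empty positive score window")
  if (!length(scores_neg)) stop("empty negative score window")
  th <- seq(0, 1, by = threshold_step)
  sens <- vapply(th, function(t) mean(scores_pos >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores_neg < t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auroc <- sum(diff(c(0, fpr[ord], 1)) *
                 (c(sens[ord], 1) + c(0, sens[ord])) / 2)
  j <- sens + spec - 1
  best <- which.max(j)
  structure(list(roc = tibble::tibble(threshold = th, sensitivity = sens,
                                      specificity = spec),
                 auroc = auroc, youden_threshold = th[best],
                 youden_j = j[best]),
            class = "md_roc")
}

#' Scores of grid mixtures inside an unknown-content window
#'
#' Selects results whose `w` lies within `center +/- width/2`, the windowing
#' used to evaluate sensitivity at a nominal unknown-content level.
#'
#' @param results Tibble with columns `w` and `R2`.
#' @param center Window center (e.g. 0.3 for 30% unknown content).
#' @param width Total window width (default 0.05, i.e. +/-2.5%).
#' @return Numeric vector of R2 scores in the window.
#' @export
scores_in_window <- function(results, center, width = 0.05) {
  sel <- abs(results$w - center) <= width / 2 + 1e-12
  if (!any(sel)) stop(sprintf("empty window around w = %g", center))
  results$R2[sel]
}
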