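# Per-sample deconvolution pipeline: alpha-grid LTS -> non-negativity ->
# normalisation -> goodness-of-fit metrics -> significance flag.

#' Significance-threshold presets
#'
#' Named R2 thresholds for calling a deconvolution significant: `stringent`
#' (0.5, low false-positive rate) and `lenient` (0.35, higher sensitivity at
#' the cost of more false positives on leukocyte-poor samples).
#' @export
deconv_thresholds <- c(stringent = 0.5, lenient = 0.35)

# Consistency factor of the trimmed scale: E[Z^2 | |Z| <= q] for standard
# normal Z with q = qnorm((1 + alpha)/2), so that S_k/(k * c_alpha) is an
# unbiased variance estimate under Gaussian residuals regardless of alpha.
lts_consistency <- function(alpha) {
  if (alpha >= 1) return(1)
  q <- stats::qnorm((1 + alpha) / 2)
  1 - 2 * q * stats::dnorm(q) / alpha
}

#' Select the LTS trimming fraction on a per-sample alpha grid
#'
#' Fits an LTS regression at each candidate `alpha` and scores it by the
#' consistency-corrected trimmed residual scale
#' \eqn{\hat\sigma(\alpha) = \sqrt{S_k / (k\, c_\alpha)}}, where
#' \eqn{c_\alpha} corrects for keeping only the central \eqn{\alpha}
#' fraction of Gaussian residuals. Under clean residuals this scale is flat
#' in `alpha`; as soon as the retained set is forced to absorb CpGs
#' contaminated by unmodelled content it jumps sharply. The selected `alpha`
#' is therefore the *largest* grid value whose corrected scale is within
#' `scale_tol` of the grid minimum: the least trimming compatible with an
#' uncontaminated retained set. With exactly zero residuals every candidate
#' ties and the largest grid alpha is returned.
#'
#' @inheritParams fit_lts
#' @param alpha_grid Candidate trimming fractions; the default is the nine
#'   values 0.50, 0.55, ..., 0.90.
#' @param scale_tol Relative plateau tolerance (default 1.5): alphas whose
#'   corrected scale exceeds `scale_tol` times the minimum are considered
#'   contaminated. The contamination jump is typically an order of magnitude,
#'   while sampling fluctuation of the scale across nested subsets is well
#'   below 50%, so the selection is insensitive to the exact value.
#' @return A list: `alpha` (selected), `fit` (its [fit_lts()] result),
#'   `fractions` (relative fractions of the selected fit) and `candidates`
#'   (tibble of alpha, corrected scale, and reconstruction RMSE against the
#'   observed profile for every grid point).
#' @export
select_alpha <- function(B, m, alpha_grid = seq(0.5, 0.9, by = 0.05),
                         seed = NULL, n_starts = 500, scale_tol = 1.5) {
  if (!length(alpha_grid)) stop("alpha_grid must not be empty")
  if (any(alpha_grid < 0.5 | alpha_grid > 1)) {
    stop("alpha_grid values must lie in [0.5, 1]")
  }
  alpha_grid <- sort(alpha_grid)
  cand <- purrr::map(alpha_grid, function(a) {
    fit <- fit_lts(B, m, alpha = a, n_starts = n_starts, seed = seed)
    f <- normalize_to_relative(enforce_nonnegativity(fit, B, m))
    list(alpha = a, fit = fit, fractions = f,
         scale = sqrt((fit$objective / fit$k) / lts_consistency(a)),
         rmse = rmse(m, as.numeric(B %*% f)))
  })
  scales <- vapply(cand, `[[`, numeric(1), "scale")
  ok <- which(scales <= min(scales) * scale_tol + 1e-12)
  pick <- ok[length(ok)]                # largest admissible alpha
  list(alpha = alpha_grid[pick], fit = cand[[pick]]$fit,
       fractions = cand[[pick]]$fractions,
       candidates = tibble::tibble(alpha = alpha_grid, scale = scales,
                                   rmse = vapply(cand, `[[`, numeric(1),
                                                 "rmse")))
}

#' Goodness-of-fit metrics for a deconvolution
#'
#' Reconstructs the mixture as \eqn{\tilde m = B \tilde f} and reports:
#' `R1` = Pearson correlation and `RMSE1` = root-mean-square error between
#' the observed and reconstructed profiles over all aligned CpGs, and `R2`,
#' `RMSE2` = the same quantities restricted to the LTS-retained CpG subset.
#' With zero residuals R1 = R2 = 1 and both RMSEs are 0. Zero variance in a
#' correlation argument yields R = 0 with `degenerate = TRUE` rather than an
#' error.
#'
#' @inheritParams fit_llsr
#' @param fractions Relative cell-type fractions (named, summing to 1).
#' @param retained Integer indices of the retained CpG subset.
#' @return One-row tibble: `R1`, `RMSE1`, `R2`, `RMSE2`, `degenerate`.
#' @export
compute_fit_metrics <- function(B, m, fractions, retained) {
  stopifnot(length(retained) >= 1, abs(sum(fractions) - 1) < 1e-6)
  mt <- as.numeric(B %*% fractions[colnames(B)])
  r1 <- safe_pearson(m, mt)
  r2 <- safe_pearson(m[retained], mt[retained])
  tibble::tibble(
    R1 = as.numeric(r1), RMSE1 = rmse(m, mt),
    R2 = as.numeric(r2), RMSE2 = rmse(m[retained], mt[retained]),
    degenerate = isTRUE(attr(r1, "degenerate")) ||
      isTRUE(attr(r2, "degenerate")))
}

# Core per-sample solve shared by deconvolve() and the benchmark harness.
# Returns a one-row tibble of fractions + metrics, or NULL on hard failure.
deconvolve_column <- function(B, m, engine = "lts", alpha = NULL,
                              alpha_grid = seq(0.5, 0.9, by = 0.05),
                              threshold = 0.5, seed = NULL, n_starts = 500) {
  present <- !is.na(m)
  if (sum(present) < ncol(B) + 1L) {
    stop("too few non-missing CpGs for regression")
  }
  Bp <- B[present, , drop = FALSE]
  mp <- m[present]
  if (engine == "lts") {
    if (is.null(alpha)) {
      sel <- select_alpha(Bp, mp, alpha_grid = alpha_grid, seed = seed,
                          n_starts = n_starts)
      fit <- sel$fit
      fractions <- sel$fractions
      chosen_alpha <- sel$alpha
    } else {
      fit <- fit_lts(Bp, mp, alpha = alpha, n_starts = n_starts, seed = seed)
      fractions <- normalize_to_relative(enforce_nonnegativity(fit, Bp, mp))
      chosen_alpha <- alpha
    }
  } else {
    fit <- switch(engine,
      llsr = fit_llsr(Bp, mp),
      qp = fit_qp(Bp, mp),
      rlr = fit_rlr(Bp, mp),
      nusvr = fit_nusvr(Bp, mp),
      stop("unknown engine: ", engine))
    fractions <- normalize_to_relative(enforce_nonnegativity(fit, Bp, mp))
    chosen_alpha <- NA_real_
  }
  met <- compute_fit_metrics(Bp, mp, fractions, fit$retained)
  dplyr::bind_cols(
    tibble::as_tibble_row(fractions),
    met[, c("R1", "RMSE1", "R2", "RMSE2")],
    tibble::tibble(alpha = chosen_alpha, n_cpgs = sum(present),
                   n_retained = length(fit$retained),
                   significant = met$R2 >= threshold))
}

#' Deconvolve a set of bulk methylation profiles
#'
#' The main entry point. Aligns the mixture table with the signature, then for
#' every sample runs the pipeline: LTS over the alpha grid (or a fixed
#' `alpha`, or one of the comparator engines), elimination-based
#' non-negativity, normalisation to relative fractions, goodness-of-fit
#' metrics and the significance flag `R2 >= threshold`. CpGs missing in a
#' sample are dropped from that sample's regression only. Samples that fail
#' outright (e.g. all values missing) are kept as rows with `status =
#' "failed"` so a long run is never lost to one bad column.
#'
#' @param mixture Beta tibble (`cpg_id` + one column per sample), e.g. from
#'   [read_beta_table()].
#' @param signature Signature tibble (`cpg_id` + one column per cell type).
#' @param threshold R2 significance threshold; see [deconv_thresholds].
#' @param engine `"lts"` (default) or one of `"llsr"`, `"qp"`, `"rlr"`,
#'   `"nusvr"` for benchmarking.
#' @param alpha Optional fixed trimming fraction overriding the grid search.
#' @param alpha_grid Candidate alphas for the per-sample search.
#' @param seed Integer seed for the LTS subset search.
#' @param n_starts Elemental starts per LTS fit.
#' @param quiet Suppress the progress message emitted every 100 samples.
#' @return A tibble of class `md_deconv`, one row per sample: `sample_id`,
#'   the relative fraction of each signature cell type, `R1`, `RMSE1`, `R2`,
#'   `RMSE2`, selected `alpha`, CpG counts, `significant` and `status`.
#' @examples
#' prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 120,
#'                                    markers_per_type = 10, seed = 1)
#' sig <- signature_from_profiles(prof)
#' mix <- sig
#' mix$s1 <- as.numeric(beta_matrix(sig) %*% c(0.2, 0.3, 0.5))
#' mix <- mix[, c("cpg_id", "s1")]
#' deconvolve(mix, sig, seed = 1)
#' @export
deconvolve <- function(mixture, signature, threshold = deconv_thresholds[["stringent"]],
                       engine = c("lts", "llsr", "qp", "rlr", "nusvr"),
                       alpha = NULL, alpha_grid = seq(0.5, 0.9, by = 0.05),
                       seed = NULL, n_starts = 500, quiet = TRUE) {
  engine <- match.arg(engine)
  al <- align_features(mixture, signature)
  B <- beta_matrix(al$signature)
  M <- beta_matrix(al$mixture)
  cell_types <- colnames(B)
  samples <- colnames(M)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    res <- tryCatch(
      deconvolve_column(B, M[, i], engine = engine, alpha = alpha,
                        alpha_grid = alpha_grid, threshold = threshold,
                        seed = seed, n_starts = n_starts),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(sample_id = samples[i], status = "failed",
                                  message = conditionMessage(res))
    } else {
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = samples[i]), res,
        tibble::tibble(status = "ok", message = NA_character_))
    }
    if (!quiet && i %% 100 == 0) {
      message(sprintf("deconvolved %d/%d samples", i, length(samples)))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- structure(out, class = c("md_deconv", class(out)),
                   cell_types = cell_types, threshold = threshold,
                   engine = engine)
  out
}

#' @export
tidy.md_deconv <- function(x, ...) {
  cell_types <- attr(x, "cell_types")
  x |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::select("sample_id", dplyr::all_of(cell_types)) |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "fraction")
}

#' @export
glance.md_deconv <- function(x, ...) {
  ok <- dplyr::filter(x, .data$status == "ok")
  tibble::tibble(
    n_samples = nrow(x), n_ok = nrow(ok),
    n_significant = sum(ok$significant),
    threshold = attr(x, "threshold"),
    mean_R2 = mean(ok$R2), mean_RMSE1 = mean(ok$RMSE1),
    engine = attr(x, "engine"))
}

#' Stacked-bar plot of relative cell-type fractions
#'
#' @param object An `md_deconv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.md_deconv <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative fraction", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
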