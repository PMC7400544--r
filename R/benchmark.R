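# Benchmark harness: run the five engines over spike-in grids and compare
# accuracy with per-condition correlation/RMSE summaries and two-way
# ANOVA + Tukey HSD.

#' Simulate a spike-in mixture grid
#'
#' Crosses tumor-content levels with spike fractions: at every
#' `(tumor_frac, spike_frac)` condition, `replicates` mixtures are formed
#' with a random spike cell type each, via [make_spikein_mixture()], plus
#' optional log-normal noise.
#'
#' @inheritParams make_spikein_mixture
#' @param tumor_fracs Unknown-content levels (default `seq(0, 0.9, 0.3)`).
#' @param spike_fracs Spike fractions of the leukocyte compartment
#'   (default `c(0.005, 0.05, 0.1, 0.25, 0.5)`, spanning the 0.5--50% range).
#' @param replicates Mixtures per condition.
#' @param tumor_overlap_frac Marker overlap of each fresh unknown profile.
#' @param lambda Log-normal noise level.
#' @return List with `mixtures` (Beta tibble) and `truth` (tibble with
#'   `sample_id`, `tumor_frac`, `spike_type`, `spike_frac` and per-type
#'   absolute fractions).
#' @export
simulate_spikein_grid <- function(profiles, tumor_fracs = seq(0, 0.9, by = 0.3),
                                  spike_fracs = c(0.005, 0.05, 0.1, 0.25, 0.5),
                                  replicates = 5, tumor_overlap_frac = 0.2,
                                  lambda = 0,
                                  profile_draw = c("replicate", "mean"),
                                  seed = NULL) {
  profile_draw <- match.arg(profile_draw)
  with_seed(seed, {
    cols <- list(); truth <- list()
    i <- 0L
    for (t in tumor_fracs) for (p in spike_fracs) for (r in seq_len(replicates)) {
      i <- i + 1L
      unk <- simulate_unknown_profile(profiles, tumor_overlap_frac)
      st <- sample(profiles$cell_types, 1)
      mx <- make_spikein_mixture(profiles, unk, t, st, p,
                                 profile_draw = profile_draw)
      m <- if (lambda > 0) add_lognormal_noise(mx$mixture, lambda) else mx$mixture
      id <- sprintf("mix%05d", i)
      cols[[id]] <- m
      truth[[id]] <- dplyr::bind_cols(tibble::tibble(sample_id = id), mx$truth)
    }
    list(mixtures = tibble::tibble(cpg_id = profiles$beta$cpg_id, !!!cols),
         truth = dplyr::bind_rows(truth))
  })
}

#' Compare regression engines on mixtures with known composition
#'
#' Applies each engine identically to every mixture and pairs the estimated
#' relative fractions with the ground truth (absolute fractions rescaled to
#' the leukocyte compartment). Engine failures on individual mixtures are
#' recorded and excluded from that engine's summary.
#'
#' @param mixtures Beta tibble of mixtures.
#' @param truth Truth tibble (`sample_id`, `tumor_frac`, per-type absolute
#'   fractions), e.g. from [simulate_spikein_grid()].
#' @param signature Signature tibble.
#' @param engines Engines to compare (default all five).
#' @param seed Seed for the LTS subset search.
#' @param ... Passed to [deconvolve()] (e.g. `alpha_grid`, `n_starts`).
#' @return An `md_benchmark`: `records` (tibble `engine`, `sample_id`,
#'   `tumor_frac`, `cell_type`, `estimate`, `truth`), `summary` (per engine
#'   and tumor level: Pearson `r`, `r2`, `rmse`, `n`), `failures`.
#' @export
run_method_comparison <- function(mixtures, truth, signature,
                                  engines = c("lts", "llsr", "qp", "rlr",
                                              "nusvr"),
                                  seed = NULL, ...) {
  cell_types <- names(signature)[-1]
  stopifnot(all(cell_types %in% names(truth)))
  rel_truth <- truth |>
    dplyr::select("sample_id", "tumor_frac", dplyr::all_of(cell_types)) |>
    tidyr::pivot_longer(dplyr::all_of(cell_types), names_to = "cell_type",
                        values_to = "truth") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(truth = .data$truth / sum(.data$truth)) |>
    dplyr::ungroup()
  records <- list(); failures <- list()
  for (eng in engines) {
    res <- deconvolve(mixtures, signature, engine = eng, seed = seed, ...)
    bad <- dplyr::filter(res, .data$status == "failed")
    if (nrow(bad)) {
      failures[[eng]] <- dplyr::mutate(bad, engine = eng)
    }
    records[[eng]] <- tidy(res) |>
      dplyr::rename(estimate = "fraction") |>
      dplyr::inner_join(rel_truth, by = c("sample_id", "cell_type")) |>
      dplyr::mutate(engine = eng)
  }
  records <- dplyr::bind_rows(records)
  summary <- records |>
    dplyr::group_by(engine = .data$engine, tumor_frac = .data$tumor_frac) |>
    dplyr::summarise(r = stats::cor(.data$estimate, .data$truth),
                     r2 = .data$r[1]^2,
                     rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
                     n = dplyr::n(), .groups = "drop")
  structure(list(records = records, summary = summary,
                 failures = dplyr::bind_rows(failures)),
            class = "md_benchmark")
}

#' @export
glance.md_benchmark <- function(x, ...) {
  x$summary |>
    dplyr::group_by(engine = .data$engine) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), mean_rmse = mean(.data$rmse),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_r2))
}

#' Two-way ANOVA with Tukey HSD over engines
#'
#' Per cell type, fits a fixed-effects ANOVA of the estimated fraction on
#' engine and tumor-content level (both categorical) and reports Tukey
#' honest-significant-difference adjusted p-values for every engine pair.
#'
#' @param records Benchmark `records` tibble (or an `md_benchmark`).
#' @return Tibble: `cell_type`, `comparison`, `diff`, `p_adj`.
#' @export
anova_tukey <- function(records) {
  if (inherits(records, "md_benchmark")) records <- records$records
  if (length(unique(records$engine)) < 2) {
    stop("need at least two engines for pairwise comparison")
  }
  records |>
    dplyr::group_by(cell_type = .data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      df$engine <- factor(df$engine)
      df$tumor_level <- factor(df$tumor_frac)
      fit <- stats::aov(estimate ~ engine + tumor_level, data = df)
      tk <- stats::TukeyHSD(fit, which = "engine")$engine
      tibble::tibble(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"])
    }) |>
    dplyr::ungroup()
}

#' Accuracy-versus-unknown-content plot for an engine comparison
#'
#' @param object An `md_benchmark`.
#' @param ... Unused.
#' @return A ggplot of per-condition r-squared by engine.
#' @export
autoplot.md_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$tumor_frac, y = .data$r2,
                               colour = .data$engine)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "unknown (tumor) content", y = expression(R^2),
                  colour = "engine") +
    ggplot2::theme_minimal()
}
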