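# Signature-matrix construction from purified cell profiles: bridging batch
# correction, missingness filters, sex/contamination filters, pairwise
# differential tests, and condition-number-minimising marker selection.

#' Assemble a purified-profile set
#'
#' @param beta Beta tibble (`cpg_id` + one column per purified sample).
#' @param meta Tibble with columns `sample_id`, `cell_type`, `study`.
#' @return An `md_profiles` object usable by the builder functions.
#' @export
purified_profiles <- function(beta, meta) {
  stopifnot(all(c("sample_id", "cell_type", "study") %in% names(meta)),
            setequal(meta$sample_id, names(beta)[-1]))
  structure(list(beta = beta, meta = meta,
                 cell_types = unique(meta$cell_type)),
            class = "md_profiles")
}

replace_beta <- function(profiles, M) {
  profiles$beta <- tibble::tibble(cpg_id = rownames(M),
                                  !!!as.data.frame(M))
  profiles
}

#' Bridging batch correction across studies
#'
#' Uses a cell type profiled in every study as a bridge: the per-study mean
#' bridge profile is compared with the cross-study aggregate, the difference
#' is the study's correction factor, and that factor is subtracted from
#' every sample of the study. Corrected values are clipped to \[0, 1\]
#' (values below 0 are set to 0, above 1 to 1). Pre-clipping, the per-study
#' bridge means all equal the aggregate exactly; with one study the
#' correction is identically zero.
#'
#' @param profiles An `md_profiles` object.
#' @param bridge_cell_type Name of the bridging cell type (e.g. monocytes).
#' @param clip Clip corrected values to \[0, 1\] (default `TRUE`; disable to
#'   verify the pre-clip identity).
#' @return Corrected `md_profiles`.
#' @export
bridge_batch_correct <- function(profiles, bridge_cell_type, clip = TRUE) {
  meta <- profiles$meta
  M <- beta_matrix(profiles$beta)
  studies <- unique(meta$study)
  bridge_means <- lapply(studies, function(s) {
    ids <- meta$sample_id[meta$study == s & meta$cell_type == bridge_cell_type]
    if (!length(ids)) {
      stop("no '", bridge_cell_type, "' samples in study '", s, "'")
    }
    rowMeans(M[, ids, drop = FALSE], na.rm = TRUE)
  })
  names(bridge_means) <- studies
  aggregate <- Reduce(`+`, bridge_means) / length(bridge_means)
  for (s in studies) {
    correction <- bridge_means[[s]] - aggregate
    ids <- meta$sample_id[meta$study == s]
    M[, ids] <- M[, ids, drop = FALSE] - correction
  }
  if (clip) M[] <- clip01(M)
  replace_beta(profiles, M)
}

#' Drop samples and CpGs with excessive missingness
#'
#' Two fixed-order passes: samples with more than `max_sample_missing`
#' missing CpGs are dropped first, then CpGs missing in more than
#' `max_cpg_missing` of the remaining samples.
#'
#' @param profiles An `md_profiles` object.
#' @param max_sample_missing,max_cpg_missing Missingness ceilings (default
#'   0.10 each).
#' @return Filtered `md_profiles`.
#' @export
filter_samples_and_cpgs <- function(profiles, max_sample_missing = 0.10,
                                    max_cpg_missing = 0.10) {
  M <- beta_matrix(profiles$beta)
  keep_samples <- colMeans(is.na(M)) <= max_sample_missing
  M <- M[, keep_samples, drop = FALSE]
  keep_cpgs <- rowMeans(is.na(M)) <= max_cpg_missing
  M <- M[keep_cpgs, , drop = FALSE]
  if (!ncol(M) || !nrow(M)) stop("missingness filter removed everything")
  profiles$meta <- profiles$meta[profiles$meta$sample_id %in% colnames(M), ]
  replace_beta(profiles, M)
}

#' Remove sex-linked and contamination-prone candidate CpGs
#'
#' Removes (i) CpGs on supplied sex-associated and X/Y probe lists, (ii)
#' CpGs whose mean Beta across a solid-cancer cell-line panel falls below
#' `beta_floor`, and (iii) CpGs below `beta_floor` in *any* nonhematopoietic
#' tissue panel. Because markers are selected for hypomethylation in one
#' leukocyte type, a CpG that is also lowly methylated in tumors or other
#' tissues would let non-leukocyte signal leak into the signature; only CpGs
#' highly methylated everywhere outside the hematopoietic compartment
#' survive as candidates.
#'
#' @param profiles An `md_profiles` object.
#' @param sex_cpgs,xy_cpgs Character vectors of probe IDs to exclude.
#' @param cancer_panel Optional Beta tibble of cancer cell lines.
#' @param tissue_panels Optional list of Beta tibbles, one per
#'   nonhematopoietic tissue panel.
#' @param beta_floor Minimum acceptable panel mean Beta (default 0.8).
#' @return Filtered `md_profiles`.
#' @export
filter_candidate_cpgs <- function(profiles, sex_cpgs = character(),
                                  xy_cpgs = character(),
                                  cancer_panel = NULL,
                                  tissue_panels = list(),
                                  beta_floor = 0.8) {
  drop <- union(sex_cpgs, xy_cpgs)
  low_mean_cpgs <- function(panel) {
    P <- beta_matrix(panel)
    rownames(P)[rowMeans(P, na.rm = TRUE) < beta_floor]
  }
  if (!is.null(cancer_panel)) drop <- union(drop, low_mean_cpgs(cancer_panel))
  for (panel in tissue_panels) drop <- union(drop, low_mean_cpgs(panel))
  keep <- !(profiles$beta$cpg_id %in% drop)
  if (!any(keep)) stop("no candidate CpGs survive the contamination filter")
  profiles$beta <- profiles$beta[keep, , drop = FALSE]
  profiles
}

# Vectorised Welch (unequal-variance) two-sample t-test across CpG rows.
row_welch <- function(M1, M2) {
  n1 <- rowSums(!is.na(M1)); n2 <- rowSums(!is.na(M2))
  m1 <- rowMeans(M1, na.rm = TRUE); m2 <- rowMeans(M2, na.rm = TRUE)
  v1 <- rowSums((M1 - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((M2 - m2)^2, na.rm = TRUE) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  list(p = p, diff = m1 - m2)
}

#' Rank marker candidates by pairwise differential methylation
#'
#' Runs two-sample unequal-variance t-tests per CpG for every unordered
#' cell-type pair plus any named lineage contrasts (group versus group).
#' P-values are Bonferroni-corrected over the global family of
#' (candidate CpGs x contrasts). A CpG enters cell type `t`'s marker list iff
#' every contrast involving `t` is significant at `alpha` after correction
#' *and* its mean Beta in `t` is lower than in every other type
#' (hypomethylated-marker convention). Lists are ranked ascending by the
#' worst (largest) corrected p across the type's contrasts, ties broken by
#' the larger hypomethylation margin. Lineage-contrast lists accept either
#' direction of difference.
#'
#' @param profiles An `md_profiles` object (>= 2 samples per cell type).
#' @param lineage_contrasts Named list; each element is
#'   `list(group1 = <types>, group2 = <types>)`, e.g. the myeloid split
#'   (monocytes/dendritic cells/macrophages versus
#'   neutrophils/eosinophils).
#' @param alpha Corrected significance level (default 0.05).
#' @return An `md_marker_ranking`: per-list ranked tibbles of `cpg_id`,
#'   `worst_p_adj`, `margin`, plus the Bonferroni family size.
#' @export
rank_markers <- function(profiles, lineage_contrasts = list(), alpha = 0.05) {
  meta <- profiles$meta
  M <- beta_matrix(profiles$beta)
  types <- unique(meta$cell_type)
  counts <- table(meta$cell_type)
  if (any(counts < 2)) {
    stop("cell types with < 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  cols_of <- function(tt) M[, meta$sample_id[meta$cell_type %in% tt],
                            drop = FALSE]
  pairs <- utils::combn(types, 2, simplify = FALSE)
  contrasts <- c(
    setNames(lapply(pairs, function(p) list(group1 = p[1], group2 = p[2])),
             vapply(pairs, paste, character(1), collapse = ".vs.")),
    lineage_contrasts)
  tests <- lapply(contrasts, function(ct) {
    row_welch(cols_of(ct$group1), cols_of(ct$group2))
  })
  n_family <- nrow(M) * length(contrasts)
  p_adj <- lapply(tests, function(t) pmin(1, t$p * n_family))
  type_means <- vapply(types, function(t) rowMeans(cols_of(t), na.rm = TRUE),
                       numeric(nrow(M)))
  rank_list <- function(p_mat, d_mat) {
    ok <- rowSums(p_mat < alpha) == ncol(p_mat) &
      rowSums(d_mat < 0) == ncol(d_mat)
    worst <- apply(p_mat, 1, max)
    margin <- apply(-d_mat, 1, min)  # smallest hypomethylation gap
    tibble::tibble(cpg_id = rownames(M)[ok], worst_p_adj = worst[ok],
                   margin = margin[ok]) |>
      dplyr::arrange(.data$worst_p_adj, dplyr::desc(.data$margin))
  }
  lists <- list()
  pair_names <- names(contrasts)[seq_along(pairs)]
  for (t in types) {
    involved <- vapply(pairs, function(p) t %in% p, logical(1))
    p_mat <- do.call(cbind, p_adj[pair_names[involved]])
    # orient differences as (target - other): negative means hypomethylated
    d_mat <- do.call(cbind, lapply(which(involved), function(i) {
      d <- tests[[pair_names[i]]]$diff
      if (pairs[[i]][1] == t) d else -d
    }))
    lists[[t]] <- rank_list(p_mat, d_mat)
  }
  for (nm in names(lineage_contrasts)) {
    p_mat <- cbind(p_adj[[nm]])
    # lineage lists separate two groups; either direction qualifies
    sig <- p_mat[, 1] < alpha
    lists[[nm]] <- tibble::tibble(
      cpg_id = rownames(M)[sig], worst_p_adj = p_mat[sig, 1],
      margin = abs(tests[[nm]]$diff)[sig]) |>
      dplyr::arrange(.data$worst_p_adj, dplyr::desc(.data$margin))
  }
  structure(list(lists = lists, alpha = alpha, n_family = n_family,
                 cell_types = types,
                 lineage_names = names(lineage_contrasts)),
            class = "md_marker_ranking")
}

#' @export
print.md_marker_ranking <- function(x, ...) {
  cat(sprintf("<md_marker_ranking> %d lists | Bonferroni family %d | alpha %g\n",
              length(x$lists), x$n_family, x$alpha))
  for (nm in names(x$lists)) cat(sprintf("  %s: %d CpGs\n", nm,
                                         nrow(x$lists[[nm]])))
  invisible(x)
}

#' Select signature CpGs by minimising the condition number
#'
#' For each candidate count `g` in `g_range`, takes the top `g` CpGs from
#' every marker list (lists shorter than `g` contribute all their entries),
#' deduplicates, builds the cell-type-mean signature matrix over those CpGs,
#' and computes its 2-norm condition number. The signature with the smallest
#' condition number is returned: a low condition number means the cell-type
#' columns are close to orthogonal, so the downstream regression is
#' well-posed.
#'
#' @param ranking An `md_marker_ranking` from [rank_markers()].
#' @param profiles The (corrected, filtered) `md_profiles`.
#' @param g_range Candidate per-list CpG counts (default `20:200`).
#' @return Signature tibble with attributes `g` (selected count),
#'   `condition_number`, and `search` (tibble of `g`, `n_cpgs`, `kappa`).
#' @export
build_signature <- function(ranking, profiles, g_range = 20:200) {
  stopifnot(inherits(ranking, "md_marker_ranking"), length(g_range) >= 1)
  M <- beta_matrix(profiles$beta)
  meta <- profiles$meta
  types <- ranking$cell_types
  type_means <- vapply(types, function(t) {
    rowMeans(M[, meta$sample_id[meta$cell_type == t], drop = FALSE],
             na.rm = TRUE)
  }, numeric(nrow(M)))
  rownames(type_means) <- rownames(M)
  search <- list()
  best <- NULL
  for (g in sort(unique(g_range))) {
    cpgs <- unique(unlist(lapply(ranking$lists, function(l) {
      utils::head(l$cpg_id, g)
    })))
    cpgs <- cpgs[cpgs %in% rownames(type_means)]
    if (length(cpgs) <= length(types)) next
    S <- type_means[cpgs, , drop = FALSE]
    sv <- svd(S, nu = 0, nv = 0)$d
    if (min(sv) < max(sv) * 1e-12) {
      warning("signature at g = ", g, " is numerically singular; skipped")
      next
    }
    kappa <- max(sv) / min(sv)
    search[[length(search) + 1L]] <- tibble::tibble(g = g,
                                                    n_cpgs = length(cpgs),
                                                    kappa = kappa)
    if (is.null(best) || kappa < best$kappa) {
      best <- list(g = g, kappa = kappa, cpgs = cpgs)
    }
  }
  if (is.null(best)) stop("no candidate signature was non-singular")
  sig <- tibble::tibble(cpg_id = best$cpgs,
                        !!!as.data.frame(type_means[best$cpgs, , drop = FALSE]))
  attr(sig, "g") <- best$g
  attr(sig, "condition_number") <- best$kappa
  attr(sig, "search") <- dplyr::bind_rows(search)
  sig
}
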