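# Synthetic-data generators. These emulate the structure of purified
# leukocyte 450k profiles: each cell type owns a disjoint block of marker
# CpGs that are hypomethylated only in that type (low Beta translating to
# cell-type-specific expression), everything else sits near a high baseline.
# Replicate noise acts on the logit scale so draws stay in (0,1) and the
# noise is symmetric around the mean in logit space, as Beta-value replicate
# scatter on arrays roughly is.

#' Simulate purified reference cell-type profiles
#'
#' Generates replicate Beta profiles for `n_cell_types` purified populations.
#' Cell type `i` owns `markers_per_type` marker CpGs at `marker_beta`
#' (hypomethylated) while all other CpGs sit at `baseline_beta`; replicates
#' add logit-normal noise with sd `replicate_sd`. With `n_studies > 1`, each
#' study gets an additive Beta-scale offset (sd `study_offset_sd`) applied to
#' all its samples, exercising the bridging batch correction.
#'
#' @param n_cell_types Number of cell types (default 6, whole-blood scale).
#' @param n_cpgs Total CpGs simulated.
#' @param markers_per_type Marker CpGs per cell type (disjoint blocks).
#' @param reps_per_type Replicate samples per cell type per study.
#' @param baseline_beta High methylation baseline (default 0.85).
#' @param marker_beta Hypomethylated marker level (default 0.10).
#' @param replicate_sd Logit-scale replicate noise sd (default 0.15).
#' @param n_studies Number of simulated studies (default 1).
#' @param study_offset_sd Beta-scale sd of per-study batch offsets.
#' @param cell_types Optional cell-type names.
#' @param seed Integer seed.
#' @return An object of class `md_profiles`: a list with `beta` (Beta tibble,
#'   `cpg_id` + one column per sample), `meta` (tibble `sample_id`,
#'   `cell_type`, `study`), `markers` (tibble `cpg_id`, `marker_for`), and
#'   the generating parameters.
#' @export
simulate_purified_profiles <- function(n_cell_types = 6, n_cpgs = 1000,
                                       markers_per_type = 30,
                                       reps_per_type = 5,
                                       baseline_beta = 0.85,
                                       marker_beta = 0.10,
                                       replicate_sd = 0.15,
                                       n_studies = 1,
                                       study_offset_sd = 0.05,
                                       cell_types = NULL, seed = NULL) {
  if (markers_per_type * n_cell_types > n_cpgs) {
    stop("marker blocks do not fit: markers_per_type * n_cell_types > n_cpgs")
  }
  stopifnot(baseline_beta > 0, baseline_beta < 1,
            marker_beta > 0, marker_beta < 1)
  cell_types <- cell_types %||% paste0("CT", seq_len(n_cell_types))
  stopifnot(length(cell_types) == n_cell_types)
  cpg_ids <- sprintf("cg%06d", seq_len(n_cpgs))
  marker_for <- rep(NA_character_, n_cpgs)
  mu <- matrix(baseline_beta, n_cpgs, n_cell_types,
               dimnames = list(cpg_ids, cell_types))
  for (i in seq_len(n_cell_types)) {
    block <- ((i - 1L) * markers_per_type + 1L):(i * markers_per_type)
    mu[block, i] <- marker_beta
    marker_for[block] <- cell_types[i]
  }
  with_seed(seed, {
    offsets <- if (n_studies > 1) stats::rnorm(n_studies, 0, study_offset_sd)
               else 0
    cols <- list(); meta <- list()
    for (s in seq_len(n_studies)) {
      for (i in seq_len(n_cell_types)) {
        for (r in seq_len(reps_per_type)) {
          id <- sprintf("%s_s%d_r%d", cell_types[i], s, r)
          x <- stats::plogis(stats::qlogis(mu[, i]) +
                               stats::rnorm(n_cpgs, 0, replicate_sd))
          cols[[id]] <- clip01(x + offsets[s])
          meta[[id]] <- tibble::tibble(sample_id = id,
                                       cell_type = cell_types[i],
                                       study = paste0("study", s))
        }
      }
    }
    beta <- tibble::tibble(cpg_id = cpg_ids, !!!cols)
    structure(list(beta = beta, meta = dplyr::bind_rows(meta),
                   markers = tibble::tibble(cpg_id = cpg_ids,
                                            marker_for = marker_for),
                   baseline_beta = baseline_beta, marker_beta = marker_beta,
                   cell_types = cell_types, study_offsets = offsets),
              class = "md_profiles")
  })
}

#' @export
print.md_profiles <- function(x, ...) {
  cat(sprintf("<md_profiles> %d CpGs x %d samples | %d cell types, %d studies\n",
              nrow(x$beta), ncol(x$beta) - 1L, length(unique(x$meta$cell_type)),
              length(unique(x$meta$study))))
  invisible(x)
}

#' Build a cell-type-mean signature from purified profiles
#'
#' Column of cell type `t` = mean Beta across all replicates labelled `t`.
#' By default only marker CpGs enter the signature, mirroring a real
#' reference: a deconvolution signature consists of selected discriminative
#' probes, not baseline CpGs identical across cell types (which carry no
#' composition information and would dominate a trimmed fit).
#'
#' @param profiles An `md_profiles` object (or any list with `beta`/`meta`).
#' @param markers_only Restrict rows to marker CpGs when the profile set
#'   carries marker annotations (default `TRUE`).
#' @return A signature tibble (`cpg_id` + one column per cell type).
#' @export
signature_from_profiles <- function(profiles, markers_only = TRUE) {
  M <- beta_matrix(profiles$beta)
  if (markers_only && !is.null(profiles$markers)) {
    keep <- profiles$markers$cpg_id[!is.na(profiles$markers$marker_for)]
    M <- M[keep, , drop = FALSE]
  }
  types <- unique(profiles$meta$cell_type)
  cols <- lapply(types, function(t) {
    ids <- profiles$meta$sample_id[profiles$meta$cell_type == t]
    rowMeans(M[, ids, drop = FALSE], na.rm = TRUE)
  })
  names(cols) <- types
  tibble::tibble(cpg_id = rownames(M), !!!cols)
}

#' Simulate an unknown (tumor-like) profile absent from the signature
#'
#' The profile sits at the high baseline with independent logit-normal noise
#' and carries no systematic hypomethylation at signature marker CpGs, except
#' at a random `tumor_overlap_frac` of them which are set low — adversarial
#' contamination mimicking a leukocyte-like pattern the trimmed regression
#' must learn to discard.
#'
#' @param profiles The `md_profiles` object defining the CpG/marker layout.
#' @param tumor_overlap_frac Fraction of marker CpGs the unknown profile
#'   perturbs (0 = orthogonal to every signature column, 1 = fully mimicking).
#' @param noise_sd Logit-scale measurement scatter of the unknown profile
#'   (default 0.05). The biological difference between a cancer cell line
#'   and the leukocyte baseline is structural -- concentrated at the overlap
#'   CpGs -- while per-probe array scatter is small, so the default keeps
#'   contamination sparse rather than smearing it over every probe.
#' @param seed Integer seed.
#' @return Named numeric vector of Beta values, one per CpG.
#' @export
simulate_unknown_profile <- function(profiles, tumor_overlap_frac = 0,
                                     noise_sd = 0.05, seed = NULL) {
  stopifnot(tumor_overlap_frac >= 0, tumor_overlap_frac <= 1)
  cpg_ids <- profiles$markers$cpg_id
  n <- length(cpg_ids)
  with_seed(seed, {
    mu <- rep(profiles$baseline_beta, n)
    marker_idx <- which(!is.na(profiles$markers$marker_for))
    n_hit <- round(tumor_overlap_frac * length(marker_idx))
    if (n_hit > 0) {
      hit <- sample(marker_idx, n_hit)
      mu[hit] <- profiles$marker_beta
    }
    x <- stats::plogis(stats::qlogis(mu) + stats::rnorm(n, 0, noise_sd))
    stats::setNames(x, cpg_ids)
  })
}

#' Form a spike-in mixture with known composition
#'
#' The leukocyte compartment gets budget `1 - tumor_frac`; `spike_type`
#' receives `spike_frac` of that budget and the remainder is split across
#' the other cell types by a symmetric Dirichlet(1) draw. One replicate
#' profile per cell type is sampled from `profiles` and combined convexly
#' with the unknown profile, so every mixture entry stays in \[0, 1\].
#'
#' @inheritParams simulate_unknown_profile
#' @param unknown Unknown profile vector (from [simulate_unknown_profile()]).
#' @param tumor_frac Unknown-content fraction `t` in \[0, 0.9\].
#' @param spike_type Cell type whose fraction is controlled.
#' @param spike_frac Spike fraction `p` of the leukocyte compartment, in
#'   \[0.005, 0.5\].
#' @param profile_draw `"replicate"` (default) samples one purified replicate
#'   per cell type, so mixtures carry realistic profile-versus-signature
#'   mismatch; `"mean"` combines the per-type mean profiles, making recovery
#'   exact in the absence of unknown content and noise.
#' @param seed Integer seed.
#' @return List with `mixture` (named Beta vector) and `truth` (one-row
#'   tibble: `tumor_frac`, `spike_type`, `spike_frac`, plus the absolute
#'   fraction of every cell type; all fractions + `tumor_frac` sum to 1).
#' @export
make_spikein_mixture <- function(profiles, unknown, tumor_frac, spike_type,
                                 spike_frac,
                                 profile_draw = c("replicate", "mean"),
                                 seed = NULL) {
  profile_draw <- match.arg(profile_draw)
  if (tumor_frac < 0 || tumor_frac > 0.9) stop("tumor_frac must lie in [0, 0.9]")
  if (spike_frac < 0.005 || spike_frac > 0.5) {
    stop("spike_frac must lie in [0.005, 0.5]")
  }
  types <- profiles$cell_types
  stopifnot(spike_type %in% types)
  with_seed(seed, {
    leuk <- 1 - tumor_frac
    f <- stats::setNames(rep(0, length(types)), types)
    f[spike_type] <- spike_frac * leuk
    others <- setdiff(types, spike_type)
    w <- stats::rgamma(length(others), 1)  # symmetric Dirichlet(1)
    f[others] <- (1 - spike_frac) * leuk * w / sum(w)
    M <- beta_matrix(profiles$beta)
    if (profile_draw == "replicate") {
      basis <- M[, vapply(types, function(t) {
        ids <- profiles$meta$sample_id[profiles$meta$cell_type == t]
        sample(ids, 1)
      }, character(1)), drop = FALSE]
    } else {
      basis <- vapply(types, function(t) {
        ids <- profiles$meta$sample_id[profiles$meta$cell_type == t]
        rowMeans(M[, ids, drop = FALSE])
      }, numeric(nrow(M)))
    }
    mix <- as.numeric(basis %*% f) + tumor_frac * unknown
    truth <- tibble::tibble(tumor_frac = tumor_frac, spike_type = spike_type,
                            spike_frac = spike_frac)
    truth <- dplyr::bind_cols(truth, tibble::as_tibble_row(f))
    list(mixture = stats::setNames(mix, rownames(M)), truth = truth)
  })
}

#' Add multiplicative log-normal noise to a Beta profile
#'
#' Each entry is multiplied by \eqn{2^{\epsilon}} with
#' \eqn{\epsilon \sim N(0, \lambda\sigma)} i.i.d., then clipped to \[0, 1\].
#'
#' @param m Numeric Beta vector.
#' @param lambda Noise level in \[0, 1\].
#' @param sigma Scale so that the sd of \eqn{\epsilon} is `lambda * sigma`
#'   (default 1, mapping `lambda` directly onto the log2 sd).
#' @param seed Integer seed.
#' @return Noisy, clipped Beta vector of the same length.
#' @export
add_lognormal_noise <- function(m, lambda, sigma = 1, seed = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, sigma > 0)
  if (lambda == 0) return(m)
  with_seed(seed, {
    eps <- stats::rnorm(length(m), 0, lambda * sigma)
    clip01(m * 2^eps)
  })
}

#' Simulate a cohort of tumor admixtures with known purity
#'
#' For each sample: purity `q` drawn uniformly from `purity_range`, a fresh
#' unknown profile, a Dirichlet(1) leukocyte composition filling the
#' remaining `1 - q`, and optional log-normal measurement noise. This is the
#' test bed for purity-model training and significance calibration.
#'
#' @inheritParams simulate_unknown_profile
#' @param n_samples Number of mixtures.
#' @param purity_range Range of true tumor purity (default `c(0, 0.9)`).
#' @param lambda Log-normal noise level applied to each mixture.
#' @param seed Integer seed.
#' @return List with `mixtures` (Beta tibble) and `truth` (tibble:
#'   `sample_id`, `purity`, per-cell-type absolute fractions).
#' @export
simulate_tumor_cohort <- function(profiles, n_samples,
                                  purity_range = c(0, 0.9),
                                  tumor_overlap_frac = 0.2,
                                  lambda = 0.05, seed = NULL) {
  types <- profiles$cell_types
  M <- beta_matrix(profiles$beta)
  with_seed(seed, {
    cols <- list(); truth <- list()
    for (i in seq_len(n_samples)) {
      q <- stats::runif(1, purity_range[1], purity_range[2])
      w <- stats::rgamma(length(types), 1)
      f <- stats::setNames((1 - q) * w / sum(w), types)
      unk <- simulate_unknown_profile(profiles, tumor_overlap_frac)
      reps <- vapply(types, function(t) {
        ids <- profiles$meta$sample_id[profiles$meta$cell_type == t]
        sample(ids, 1)
      }, character(1))
      mix <- as.numeric(M[, reps, drop = FALSE] %*% f) + q * unk
      if (lambda > 0) mix <- add_lognormal_noise(mix, lambda)
      id <- sprintf("mix%04d", i)
      cols[[id]] <- mix
      truth[[id]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = id, purity = q),
        tibble::as_tibble_row(f))
    }
    list(mixtures = tibble::tibble(cpg_id = rownames(M), !!!cols),
         truth = dplyr::bind_rows(truth))
  })
}
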