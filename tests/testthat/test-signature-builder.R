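test_that("bridge correction is the identity with one study and exact on several", {
  one <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 90,
                                    markers_per_type = 10, n_studies = 1,
                                    seed = 1)
  corrected <- bridge_batch_correct(one, "CT1")
  expect_equal(beta_matrix(corrected$beta), beta_matrix(one$beta),
               tolerance = 1e-12)

  multi <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 90,
                                      markers_per_type = 10, n_studies = 3,
                                      study_offset_sd = 0.04, seed = 2)
  fixed <- bridge_batch_correct(multi, "CT1", clip = FALSE)
  M <- beta_matrix(fixed$beta)
  meta <- fixed$meta
  study_means <- sapply(unique(meta$study), function(s) {
    ids <- meta$sample_id[meta$study == s & meta$cell_type == "CT1"]
    rowMeans(M[, ids, drop = FALSE])
  })
  aggregate <- rowMeans(study_means)
  for (j in seq_len(ncol(study_means))) {
    expect_equal(study_means[, j], aggregate, tolerance = 1e-12)
  }
})

test_that("bridge correction clips to [0, 1] and requires bridge samples", {
  prof <- simulate_purified_profiles(n_cell_types = 2, n_cpgs = 40,
                                     markers_per_type = 5, n_studies = 2,
                                     seed = 3)
  # force a large offset so correction would push below zero
  M <- beta_matrix(prof$beta)
  s2 <- prof$meta$sample_id[prof$meta$study == "study2"]
  M[, s2] <- pmax(M[, s2] - 0.3, 0)
  prof$beta <- tibble::tibble(cpg_id = rownames(M), !!!as.data.frame(M))
  out <- bridge_batch_correct(prof, "CT1")
  expect_true(all(beta_matrix(out$beta) >= 0))
  expect_true(all(beta_matrix(out$beta) <= 1))
  expect_error(bridge_batch_correct(prof, "CT9"), "no 'CT9' samples")
})

test_that("missingness filter drops samples first, then CpGs, at the 10% boundary", {
  prof <- simulate_purified_profiles(n_cell_types = 2, n_cpgs = 100,
                                     markers_per_type = 10, reps_per_type = 5,
                                     seed = 4)
  M <- beta_matrix(prof$beta)
  # sample 1: 11% missing -> dropped; sample 2: 5% missing -> kept
  M[1:11, 1] <- NA
  M[1:5, 2] <- NA
  # cpg 99: missing in 2 of the 9 surviving samples (22%) -> dropped
  M[99, 3:4] <- NA
  prof$beta <- tibble::tibble(cpg_id = rownames(M), !!!as.data.frame(M))
  out <- filter_samples_and_cpgs(prof)
  kept <- beta_matrix(out$beta)
  expect_identical(ncol(kept), ncol(M) - 1L)
  expect_false(colnames(M)[1] %in% colnames(kept))
  expect_false("cg000099" %in% rownames(kept))
  # cpgs missing only in the dropped sample survive
  expect_true("cg000006" %in% rownames(kept))
  # hand count: cpgs 1-5 are missing in kept sample 2 (1/9 > 10%), cpg 99
  # in two kept samples; 100 - 5 - 1 = 94 survive
  expect_identical(nrow(kept), 94L)
  # idempotence
  again <- filter_samples_and_cpgs(out)
  expect_identical(beta_matrix(again$beta), kept)
})

test_that("contamination filter applies the set algebra of its panels", {
  prof <- simulate_purified_profiles(n_cell_types = 2, n_cpgs = 60,
                                     markers_per_type = 8, seed = 5)
  ids <- prof$beta$cpg_id
  cancer <- tibble::tibble(cpg_id = ids,
                           c1 = rep(0.9, 60), c2 = rep(0.9, 60))
  cancer[5, -1] <- 0.79 / 2 * 2   # mean 0.79 -> removed (boundary)
  cancer[6, -1] <- 0.80           # mean 0.80 -> kept
  tissue <- tibble::tibble(cpg_id = ids, t1 = rep(0.95, 60))
  tissue$t1[10] <- 0.5            # low in one tissue panel -> removed
  out <- filter_candidate_cpgs(prof, sex_cpgs = ids[1], xy_cpgs = ids[2],
                               cancer_panel = cancer,
                               tissue_panels = list(tissue))
  oracle <- setdiff(ids, c(ids[1], ids[2], ids[5], ids[10]))
  expect_identical(out$beta$cpg_id, oracle)
})

test_that("planted markers are ranked for their cell type only", {
  prof <- simulate_purified_profiles(n_cell_types = 4, n_cpgs = 200,
                                     markers_per_type = 10, reps_per_type = 5,
                                     replicate_sd = 0.2, seed = 6)
  rk <- rank_markers(prof)
  truth <- prof$markers
  for (t in prof$cell_types) {
    planted <- truth$cpg_id[!is.na(truth$marker_for) & truth$marker_for == t]
    # the vast majority of planted markers are recovered in the right list
    expect_gt(mean(planted %in% rk$lists[[t]]$cpg_id), 0.8)
    # and no other type's list claims them
    for (o in setdiff(prof$cell_types, t)) {
      expect_false(any(planted %in% rk$lists[[o]]$cpg_id))
    }
  }
  # baseline CpGs (hypomethylated nowhere) never qualify
  base <- truth$cpg_id[is.na(truth$marker_for)]
  for (t in prof$cell_types) {
    expect_false(any(base %in% rk$lists[[t]]$cpg_id))
  }
})

test_that("a CpG hypomethylated in two types or hypermethylated is excluded", {
  prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 60,
                                     markers_per_type = 6, reps_per_type = 6,
                                     replicate_sd = 0.05, seed = 7)
  M <- beta_matrix(prof$beta)
  meta <- prof$meta
  shared <- "cg000050"   # hypomethylated in CT1 AND CT2
  M[shared, meta$sample_id[meta$cell_type %in% c("CT1", "CT2")]] <- 0.08
  hyper <- "cg000051"    # hypermethylated in CT1, strongly significant
  M[hyper, ] <- 0.2
  M[hyper, meta$sample_id[meta$cell_type == "CT1"]] <- 0.95
  prof$beta <- tibble::tibble(cpg_id = rownames(M), !!!as.data.frame(M))
  rk <- rank_markers(prof)
  expect_false(shared %in% rk$lists$CT1$cpg_id)
  expect_false(shared %in% rk$lists$CT2$cpg_id)
  expect_false(hyper %in% rk$lists$CT1$cpg_id)
})

test_that("welch statistics agree with t.test on random rows", {
  set.seed(8)
  M1 <- matrix(runif(50, 0.2, 0.8), 10, 5)
  M2 <- matrix(runif(40, 0.2, 0.8), 10, 4)
  got <- methyldecon:::row_welch(M1, M2)
  for (i in c(1, 4, 9)) {
    tt <- t.test(M1[i, ], M2[i, ])
    expect_equal(got$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(got$diff[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("the reference list geometry yields a 419-row signature", {
  # 11 cell-type lists each contributing 35 CpGs plus a 34-CpG lineage list,
  # all disjoint: 11 * 35 + 34 = 419 rows.
  n_types <- 11
  cpgs <- sprintf("cg%05d", 1:10000)
  lists <- list()
  offset <- 0
  types <- paste0("T", 1:n_types)
  for (t in types) {
    lists[[t]] <- tibble::tibble(cpg_id = cpgs[offset + 1:200],
                                 worst_p_adj = seq_len(200) * 1e-6,
                                 margin = 0.7)
    offset <- offset + 200
  }
  lists[["myeloid"]] <- tibble::tibble(cpg_id = cpgs[offset + 1:34],
                                       worst_p_adj = seq_len(34) * 1e-6,
                                       margin = 0.7)
  ranking <- structure(list(lists = lists, alpha = 0.05, n_family = 1,
                            cell_types = types, lineage_names = "myeloid"),
                       class = "md_marker_ranking")
  picked <- unique(unlist(lapply(ranking$lists,
                                 function(l) head(l$cpg_id, 35))))
  expect_identical(length(picked), 11L * 35L + 34L)
})

test_that("condition-number search favours purer marker structure", {
  # idealized orthogonal markers: kappa approaches 1 as marker beta drops
  make_sig <- function(marker_beta) {
    S <- matrix(0.9, 40, 4)
    for (i in 1:4) S[(i - 1) * 10 + 1:10, i] <- marker_beta
    S
  }
  kappas <- sapply(c(0.5, 0.2, 0.05), function(mb) {
    sv <- svd(make_sig(mb))$d
    max(sv) / min(sv)
  })
  expect_true(all(diff(kappas) < 0))

  prof <- simulate_purified_profiles(n_cell_types = 4, n_cpgs = 200,
                                     markers_per_type = 12, seed = 9)
  rk <- rank_markers(prof)
  sig_one <- build_signature(rk, prof, g_range = 8)
  # single-point grid equals direct construction at g = 8
  direct <- unique(unlist(lapply(rk$lists, function(l) head(l$cpg_id, 8))))
  expect_setequal(sig_one$cpg_id, direct)
  expect_identical(attr(sig_one, "g"), 8)
  sig_best <- build_signature(rk, prof, g_range = c(4, 8, 12))
  expect_lte(attr(sig_best, "condition_number"),
             attr(sig_one, "condition_number") + 1e-9)
})

test_that("a built signature deconvolves held-out synthetic mixtures", {
  prof <- simulate_purified_profiles(n_cell_types = 5, n_cpgs = 400,
                                     markers_per_type = 20, reps_per_type = 6,
                                     n_studies = 2, study_offset_sd = 0.03,
                                     seed = 10)
  prof <- bridge_batch_correct(prof, "CT1")
  rk <- rank_markers(prof)
  sig <- build_signature(rk, prof, g_range = seq(5, 20, by = 5))
  B <- beta_matrix(sig)
  set.seed(11)
  for (i in 1:5) {
    w <- rgamma(5, 1); truth <- setNames(w / sum(w), prof$cell_types)
    mu <- sapply(prof$cell_types, function(t) {
      ids <- prof$meta$sample_id[prof$meta$cell_type == t]
      rowMeans(beta_matrix(prof$beta)[, ids, drop = FALSE])
    })
    m <- as.numeric(mu[sig$cpg_id, ] %*% truth)
    est <- methyldecon:::deconvolve_column(B, m, seed = i, n_starts = 60)
    expect_lt(max(abs(unlist(est[, colnames(B)]) - truth[colnames(B)])), 0.05)
  }
})
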