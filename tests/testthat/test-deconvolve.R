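test_that("select_alpha evaluates the default nine-point grid", {
  prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 150,
                                     markers_per_type = 12, seed = 2)
  B <- beta_matrix(signature_from_profiles(prof))
  m <- exact_mixture(B, c(0.3, 0.3, 0.4))
  sel <- select_alpha(B, m, seed = 1, n_starts = 50)
  expect_identical(sel$candidates$alpha, seq(0.5, 0.9, by = 0.05))
  expect_identical(nrow(sel$candidates), 9L)
  # clean mixture: every candidate fits exactly, tie-break returns 0.90
  expect_equal(sel$alpha, 0.9)
  expect_error(select_alpha(B, m, alpha_grid = numeric()), "empty")
  expect_error(select_alpha(B, m, alpha_grid = c(0.3, 0.6)), "\\[0.5, 1\\]")
})

test_that("contamination confined to 40% of CpGs drives alpha to 0.70 or less", {
  prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 150,
                                     markers_per_type = 12, seed = 2)
  B <- beta_matrix(signature_from_profiles(prof))
  set.seed(5)
  for (i in 1:5) {
    m <- exact_mixture(B, c(0.3, 0.3, 0.4)) + rnorm(nrow(B), 0, 0.004)
    bad <- sample(nrow(B), round(0.4 * nrow(B)))
    m[bad] <- clip01(m[bad] + runif(length(bad), 0.2, 0.5))
    sel <- select_alpha(B, m, seed = i, n_starts = 150)
    expect_lte(sel$alpha, 0.70)
    # agrees with explicit grid evaluation of the same criterion
    grid <- seq(0.5, 0.9, by = 0.05)
    scales <- vapply(grid, function(a) {
      f <- fit_lts(B, m, a, n_starts = 150, seed = i)
      sqrt((f$objective / f$k) / methyldecon:::lts_consistency(a))
    }, numeric(1))
    ok <- which(scales <= min(scales) * 1.5 + 1e-12)
    expect_equal(sel$alpha, grid[ok[length(ok)]])
  }
})

test_that("fit metrics match direct formula evaluation", {
  B <- toy_signature()[1:4, ]
  f <- c(A = 0.6, B = 0.4)
  m <- c(0.35, 0.60, 0.70, 0.50)
  retained <- c(1L, 2L, 4L)
  mt <- as.numeric(B %*% f)
  met <- compute_fit_metrics(B, m, f, retained)
  expect_equal(met$R1, cor(m, mt), tolerance = 1e-12)
  expect_equal(met$RMSE1, sqrt(mean((m - mt)^2)), tolerance = 1e-12)
  expect_equal(met$R2, cor(m[retained], mt[retained]), tolerance = 1e-12)
  expect_equal(met$RMSE2, sqrt(mean((m[retained] - mt[retained])^2)),
               tolerance = 1e-12)
  expect_false(met$degenerate)
  # retained = all rows collapses the subset metrics onto the global ones
  met_all <- compute_fit_metrics(B, m, f, seq_len(nrow(B)))
  expect_equal(met_all$R2, met_all$R1)
  expect_equal(met_all$RMSE2, met_all$RMSE1)
})

test_that("perfect reconstruction gives R = 1 and RMSE = 0; zero variance flags", {
  B <- toy_signature()
  f <- c(A = 0.5, B = 0.5)
  m <- exact_mixture(B, f)
  met <- compute_fit_metrics(B, m, f, 1:4)
  expect_equal(met$R1, 1); expect_equal(met$R2, 1)
  expect_equal(met$RMSE1, 0); expect_equal(met$RMSE2, 0)
  # constant observed profile: correlation undefined -> 0 with flag
  met2 <- compute_fit_metrics(B, rep(0.5, 8), f, 1:8)
  expect_equal(met2$R1, 0)
  expect_true(met2$degenerate)
})

test_that("deconvolve recovers ideal mixtures and flags them significant", {
  prof <- std_profiles()
  sig <- signature_from_profiles(prof)
  B <- beta_matrix(sig)
  set.seed(9)
  w <- rgamma(6, 1); truth <- w / sum(w)
  mix <- tibble::tibble(cpg_id = sig$cpg_id, s1 = exact_mixture(B, truth))
  res <- deconvolve(mix, sig, seed = 1, n_starts = 50)
  expect_lt(max(abs(unlist(res[1, colnames(B)]) - truth)), 1e-6)
  expect_true(res$significant)
  expect_equal(res$R2, 1)
})

test_that("a pure unknown profile is not significant at the stringent threshold", {
  prof <- std_profiles()
  sig <- signature_from_profiles(prof)
  flags <- vapply(1:20, function(i) {
    unk <- simulate_unknown_profile(prof, tumor_overlap_frac = 0, seed = i)
    mix <- tibble::tibble(cpg_id = prof$beta$cpg_id, s1 = unname(unk))
    res <- deconvolve(mix, sig, seed = i, n_starts = 50)
    res$significant
  }, logical(1))
  expect_lt(mean(flags), 0.1)
})

test_that("threshold changes the flag but never the fractions", {
  prof <- std_profiles()
  sig <- signature_from_profiles(prof)
  coh <- simulate_tumor_cohort(prof, 4, purity_range = c(0.5, 0.8), seed = 3)
  strict <- deconvolve(coh$mixtures, sig, threshold = 0.5, seed = 1,
                       n_starts = 50)
  lenient <- deconvolve(coh$mixtures, sig,
                        threshold = deconv_thresholds[["lenient"]],
                        seed = 1, n_starts = 50)
  ct <- attr(strict, "cell_types")
  expect_equal(as.data.frame(strict[, ct]), as.data.frame(lenient[, ct]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(lenient$significant >= strict$significant))
})

test_that("datasets deconvolve sample-wise with failure isolation and determinism", {
  prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 120,
                                     markers_per_type = 10, seed = 3)
  sig <- signature_from_profiles(prof)
  B <- beta_matrix(sig)
  set.seed(4)
  cols <- lapply(1:9, function(i) {
    w <- rgamma(3, 1)
    clip01(exact_mixture(B, w / sum(w)) + rnorm(nrow(B), 0, 0.01))
  })
  names(cols) <- sprintf("s%02d", 1:9)
  mix <- tibble::tibble(cpg_id = sig$cpg_id, !!!cols,
                        s10 = rep(NA_real_, nrow(sig)))
  res <- deconvolve(mix, sig, seed = 7, n_starts = 50)
  expect_identical(res$sample_id, c(names(cols), "s10"))
  expect_identical(sum(res$status == "ok"), 9L)
  expect_identical(res$status[res$sample_id == "s10"], "failed")
  res2 <- deconvolve(mix, sig, seed = 7, n_starts = 50)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("fractions are invariant to positive rescaling of the mixture", {
  prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 120,
                                     markers_per_type = 10, seed = 8)
  sig <- signature_from_profiles(prof)
  B <- beta_matrix(sig)
  set.seed(15)
  for (i in 1:5) {
    w <- rgamma(3, 1)
    m <- clip01(exact_mixture(B, w / sum(w)) + rnorm(nrow(B), 0, 0.01))
    c0 <- 0.5  # scaling down keeps values inside [0,1]
    a <- methyldecon:::deconvolve_column(B, m, seed = i, n_starts = 50)
    b <- methyldecon:::deconvolve_column(B, c0 * m, seed = i, n_starts = 50)
    ct <- colnames(B)
    expect_equal(unlist(a[, ct]), unlist(b[, ct]), tolerance = 1e-6)
    # Pearson-based metrics are invariant to the rescaling; the RMSEs are
    # not (the reconstruction from sum-to-one fractions has fixed scale)
    expect_equal(a$R1, b$R1, tolerance = 1e-6)
    expect_equal(a$R2, b$R2, tolerance = 1e-6)
  }
})

test_that("estimation error grows with unknown content", {
  prof <- std_profiles()
  sig <- signature_from_profiles(prof)
  B <- beta_matrix(sig)
  levels <- c(0, 0.3, 0.6, 0.9)
  set.seed(31)
  mse <- sapply(levels, function(t) {
    errs <- vapply(1:12, function(r) {
      unk <- simulate_unknown_profile(prof, 0.2)
      w <- rgamma(6, 1)
      f <- (1 - t) * w / sum(w)
      m <- clip01(exact_mixture(B, f) + t * unk[rownames(B)])
      est <- methyldecon:::deconvolve_column(B, m, seed = r, n_starts = 80)
      mean((unlist(est[, colnames(B)]) - w / sum(w))^2)
    }, numeric(1))
    mean(errs)
  })
  expect_true(all(diff(mse) >= -1e-6))
})

test_that("tidy/glance/autoplot work on deconvolution results", {
  prof <- simulate_purified_profiles(n_cell_types = 3, n_cpgs = 120,
                                     markers_per_type = 10, seed = 3)
  sig <- signature_from_profiles(prof)
  B <- beta_matrix(sig)
  mix <- tibble::tibble(cpg_id = sig$cpg_id,
                        s1 = exact_mixture(B, c(0.2, 0.3, 0.5)))
  res <- deconvolve(mix, sig, seed = 1, n_starts = 50)
  td <- tidy(res)
  expect_identical(names(td), c("sample_id", "cell_type", "fraction"))
  expect_equal(sum(td$fraction), 1, tolerance = 1e-9)
  gl <- glance(res)
  expect_identical(gl$n_ok, 1L)
  expect_s3_class(autoplot(res), "ggplot")
})
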