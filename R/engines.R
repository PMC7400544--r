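# The five per-sample regression engines. Each takes the aligned signature
# matrix B (CpG x cell type, numeric) and one mixture column m, and returns a
# "md_fit": engine name, per-cell-type coefficients (unconstrained, before
# non-negativity handling), residuals over all n CpGs, the retained CpG row
# indices (all rows except for LTS), and the objective = sum of squared
# residuals over the retained rows.

new_md_fit <- function(engine, coefficients, residuals, retained, objective,
                       hyper = list(), converged = TRUE, extra = list()) {
  structure(
    c(list(engine = engine, coefficients = coefficients,
           residuals = residuals, retained = retained,
           objective = objective, hyper = hyper, converged = converged),
      extra),
    class = c(paste0("md_", engine, "_fit"), "md_fit"))
}

check_design <- function(B, m) {
  stopifnot(is.matrix(B), is.numeric(m))
  if (length(m) != nrow(B)) stop("mixture length does not match signature rows")
  if (is.null(colnames(B))) colnames(B) <- paste0("V", seq_len(ncol(B)))
  if (qr(B)$rank < ncol(B)) {
    stop("signature matrix is rank deficient; cell-type columns must be ",
         "linearly independent")
  }
  B
}

# Plain OLS on a row subset, no intercept (the mixture model m = B f has
# none). Returns named coefficients or NULL when the subset is singular.
ols_coef <- function(B, m, rows = NULL) {
  Bs <- if (is.null(rows)) B else B[rows, , drop = FALSE]
  ms <- if (is.null(rows)) m else m[rows]
  fit <- stats::.lm.fit(Bs, ms)
  cf <- fit$coefficients
  if (anyNA(cf) || fit$rank < ncol(Bs)) return(NULL)
  names(cf) <- colnames(B)
  cf
}

#' Linear least-squares deconvolution fit
#'
#' Ordinary least squares of one mixture profile on the signature matrix,
#' without intercept. Residuals span all CpGs.
#'
#' @param B Numeric CpG-by-cell-type signature matrix (full column rank).
#' @param m Numeric mixture profile, one Beta value per CpG row of `B`.
#' @return An `md_fit` with unconstrained coefficients; use
#'   [enforce_nonnegativity()] and [normalize_to_relative()] to obtain
#'   fractions.
#' @seealso [fit_lts()], [fit_qp()], [fit_rlr()], [fit_nusvr()]
#' @export
fit_llsr <- function(B, m) {
  B <- check_design(B, m)
  cf <- ols_coef(B, m)
  if (is.null(cf)) stop("least-squares fit is singular")
  r <- as.numeric(m - B %*% cf)
  new_md_fit("llsr", cf, r, seq_len(nrow(B)), sum(r^2))
}

#' Non-negative least-squares fit via quadratic programming
#'
#' Global minimiser of \eqn{\|Bf - m\|^2} subject to \eqn{f \ge 0}
#' (no sum-to-one constraint; fractions are normalised afterwards).
#'
#' @inheritParams fit_llsr
#' @return An `md_fit` whose coefficients already satisfy non-negativity.
#' @export
fit_qp <- function(B, m) {
  B <- check_design(B, m)
  D <- crossprod(B)
  d <- crossprod(B, m)
  p <- ncol(B)
  sol <- quadprog::solve.QP(D, d, Amat = diag(p), bvec = rep(0, p))
  cf <- pmax(sol$solution, 0)  # zero out solver round-off below the bound
  names(cf) <- colnames(B)
  r <- as.numeric(m - B %*% cf)
  new_md_fit("qp", cf, r, seq_len(nrow(B)), sum(r^2))
}

#' Huber robust linear regression fit
#'
#' M-estimation with Huber weighting solved by iteratively reweighted least
#' squares: CpGs with large standardised residuals are downweighted as
#' `huber_k / |residual|`, so probes the linear model cannot explain
#' (e.g. tumor-perturbed CpGs) pull less on the coefficients.
#'
#' @inheritParams fit_llsr
#' @param huber_k Huber tuning constant in units of the MAD residual scale
#'   (default 1.345, the conventional 95%-efficiency choice).
#' @param maxit Maximum IRLS iterations (default 200). Non-convergence flags
#'   the fit rather than erroring.
#' @return An `md_fit`; `$hyper$weights` holds the final IRLS weights.
#' @export
fit_rlr <- function(B, m, huber_k = 1.345, maxit = 200) {
  B <- check_design(B, m)
  fit <- MASS::rlm(B, m, psi = MASS::psi.huber, k = huber_k,
                   maxit = maxit, scale.est = "MAD")
  cf <- stats::coef(fit)
  names(cf) <- colnames(B)
  r <- as.numeric(m - B %*% cf)
  new_md_fit("rlr", cf, r, seq_len(nrow(B)), sum(r^2),
             hyper = list(huber_k = huber_k, weights = fit$w),
             converged = isTRUE(fit$converged))
}

#' Nu-support-vector regression fit
#'
#' Linear-kernel nu-SVR on jointly standardised inputs (each signature column
#' and the mixture z-scored; primal weights mapped back to the Beta scale).
#' One model is fitted per value of `nu` and the one whose reconstruction
#' \eqn{B\hat f} has the smallest RMSE against `m` is returned.
#'
#' @inheritParams fit_llsr
#' @param nu_grid Candidate `nu` values; the default `c(0.25, 0.5, 0.75)`
#'   fits the regression to roughly 25/50/75% of the CpGs.
#' @return An `md_fit`; `$hyper$nu` records the selected value.
#' @export
fit_nusvr <- function(B, m, nu_grid = c(0.25, 0.5, 0.75)) {
  B <- check_design(B, m)
  if (!length(nu_grid)) stop("nu_grid must not be empty")
  sd_m <- stats::sd(m)
  sd_B <- apply(B, 2, stats::sd)
  if (sd_m == 0 || any(sd_B == 0)) {
    stop("nu-SVR requires non-constant mixture and signature columns")
  }
  Bs <- scale(B)
  ms <- as.numeric(scale(m))
  best <- NULL
  for (nu in nu_grid) {
    mod <- e1071::svm(Bs, ms, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w_std <- as.numeric(t(mod$coefs) %*% mod$SV)
    cf <- w_std * sd_m / sd_B
    names(cf) <- colnames(B)
    err <- rmse(m, as.numeric(B %*% cf))
    if (is.null(best) || err < best$err) best <- list(nu = nu, cf = cf, err = err)
  }
  r <- as.numeric(m - B %*% best$cf)
  new_md_fit("nusvr", best$cf, r, seq_len(nrow(B)), sum(r^2),
             hyper = list(nu = best$nu, nu_grid = nu_grid))
}

# One concentration step: fit OLS on the current subset, re-rank squared
# residuals over all n CpGs, retain the k smallest (ties broken by lower row
# index via stable ordering). Returns NULL when the subset is singular.
lts_cstep <- function(B, m, rows, k) {
  cf <- ols_coef(B, m, rows)
  if (is.null(cf)) return(NULL)
  r2 <- as.numeric(m - B %*% cf)^2
  ord <- order(r2)                       # stable: equal residuals keep index order
  h <- sort(ord[seq_len(k)])
  list(coef = cf, h = h, obj = sum(r2[h]))
}

#' Least Trimmed Squares deconvolution fit (Fast-LTS)
#'
#' Minimises the sum of the `k` smallest squared residuals,
#' \eqn{S_k = \sum_{j=1}^{k} r_{(j)}^2}, where `k = floor(n * alpha)`; the
#' `n - k` worst-fitting CpGs do not influence the coefficients at all, which
#' is what makes the fit robust to CpGs carrying signal from cellular content
#' absent from the signature. The optimal subset is searched with the
#' Fast-LTS scheme: random elemental starts of size `ncol(B)`, each refined
#' by concentration steps (fit, re-rank residuals, retain the `k` best,
#' refit), with the most promising candidates iterated to convergence. The
#' objective is non-increasing across concentration steps.
#'
#' @inheritParams fit_llsr
#' @param alpha Trimming fraction in \[0.5, 1\]: the fraction of CpGs the
#'   fit may use. `alpha = 1` is exactly the least-squares fit.
#' @param n_starts Number of random elemental starts (default 500).
#' @param seed Integer seed making the subset search reproducible.
#' @param n_keep Candidates kept for full convergence refinement. The
#'   default (`NULL`) refines every start on small problems (n <= 50),
#'   where full refinement is cheap and maximises search completeness, and
#'   shortlists the best 10 on larger ones -- the standard Fast-LTS speedup
#'   sized for signature-scale fits (n of a few hundred).
#' @param prelim_csteps Concentration steps applied to every start before
#'   shortlisting (default 2).
#' @return An `md_fit` with additional fields `alpha`, `k` and `converged`;
#'   `retained` holds the optimal CpG subset of size `k`.
#' @export
fit_lts <- function(B, m, alpha, n_starts = 500, seed = NULL, n_keep = NULL,
                    prelim_csteps = 2) {
  B <- check_design(B, m)
  if (alpha < 0.5 || alpha > 1) stop("alpha must lie in [0.5, 1]")
  n <- nrow(B)
  p <- ncol(B)
  n_keep <- n_keep %||% if (n <= 50) n_starts else 10L
  if (alpha == 1) {
    f <- fit_llsr(B, m)
    return(new_md_fit("lts", f$coefficients, f$residuals, f$retained,
                      f$objective, hyper = list(alpha = 1, n_starts = n_starts),
                      extra = list(alpha = 1, k = as.integer(n), seed = seed)))
  }
  k <- as.integer(floor(n * alpha))
  if (k < p + 1L) {
    stop(sprintf("subset too small for regression: k = %d with %d cell types",
                 k, p))
  }
  best <- with_seed(seed, {
    cands <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      rows <- sample.int(n, p)
      st <- lts_cstep(B, m, rows, k)
      if (is.null(st)) next
      for (i in seq_len(prelim_csteps - 1L)) {
        nx <- lts_cstep(B, m, st$h, k)
        if (is.null(nx) || nx$obj >= st$obj) break
        st <- nx
      }
      cands[[s]] <- st
    }
    cands <- cands[!vapply(cands, is.null, logical(1))]
    if (!length(cands)) stop("all elemental starts were singular")
    objs <- vapply(cands, `[[`, numeric(1), "obj")
    keep <- cands[order(objs)[seq_len(min(n_keep, length(cands)))]]
    best <- NULL
    for (st in keep) {
      repeat {
        nx <- lts_cstep(B, m, st$h, k)
        if (is.null(nx)) break
        stopifnot(nx$obj <= st$obj + 1e-9)  # C-step monotonicity
        if (st$obj - nx$obj < 1e-12) { st <- nx; break }
        st <- nx
      }
      if (is.null(best) || st$obj < best$obj) best <- st
    }
    best
  })
  r <- as.numeric(m - B %*% best$coef)
  new_md_fit("lts", best$coef, r, best$h, best$obj,
             hyper = list(alpha = alpha, n_starts = n_starts),
             extra = list(alpha = alpha, k = k, seed = seed))
}

#' Resolve negative coefficients by elimination and refit
#'
#' Applies the non-negativity rule to an engine fit: while any coefficient is
#' negative, the cell type with the most negative coefficient is removed from
#' the design and the engine's core solve is repeated on the same retained
#' CpG rows (the LTS-optimal subset for LTS fits). Eliminated cell types get
#' coefficient 0. The QP engine is already constrained and passes through;
#' nu-SVR follows its own convention of truncating negatives to zero without
#' a refit.
#'
#' @param fit An `md_fit`.
#' @inheritParams fit_llsr
#' @return Named non-negative coefficient vector over all cell types.
#' @export
enforce_nonnegativity <- function(fit, B, m) {
  stopifnot(inherits(fit, "md_fit"))
  cf <- fit$coefficients
  if (fit$engine %in% c("qp", "nusvr")) {
    return(pmax(cf, 0))
  }
  refit <- switch(fit$engine,
    rlr = function(Bsub, msub) {
      stats::coef(MASS::rlm(Bsub, msub, psi = MASS::psi.huber,
                            k = fit$hyper$huber_k %||% 1.345,
                            maxit = 200, scale.est = "MAD"))
    },
    function(Bsub, msub) ols_coef(Bsub, msub)  # llsr and lts refit by OLS
  )
  rows <- fit$retained
  active <- colnames(B)
  out <- stats::setNames(rep(0, ncol(B)), colnames(B))
  repeat {
    if (min(cf) >= -1e-12) {
      out[active] <- pmax(cf, 0)
      return(out)
    }
    drop_type <- active[which.min(cf)]
    active <- setdiff(active, drop_type)
    if (!length(active)) stop("no admissible cell types: all eliminated")
    cf <- refit(B[rows, active, drop = FALSE], m[rows])
    if (is.null(cf)) stop("refit after elimination is singular")
    cf <- stats::setNames(as.numeric(cf), active)
  }
}

#' Normalise non-negative coefficients to relative fractions
#'
#' @param coefficients Named non-negative coefficient vector.
#' @return Named fractions summing to 1.
#' @export
normalize_to_relative <- function(coefficients) {
  if (any(coefficients < 0)) stop("coefficients must be non-negative")
  tot <- sum(coefficients)
  if (tot <= 0) stop("degenerate deconvolution: all coefficients are zero")
  coefficients / tot
}

#' @export
print.md_fit <- function(x, ...) {
  cat(sprintf("<md_fit> engine: %s | %d CpGs retained of %d | SSR %.4g\n",
              x$engine, length(x$retained), length(x$residuals), x$objective))
  print(round(x$coefficients, 4))
  invisible(x)
}
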