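# Shared fixtures, built in code at test time.

# Small well-conditioned toy signature: 8 CpGs x 2 cell types.
toy_signature <- function() {
  B <- cbind(A = c(0.10, 0.85, 0.80, 0.90, 0.12, 0.88, 0.15, 0.82),
             B = c(0.85, 0.12, 0.88, 0.10, 0.90, 0.15, 0.80, 0.86))
  rownames(B) <- sprintf("cg%02d", seq_len(nrow(B)))
  B
}

# Standard desk-scale purified-profile set reused across files.
std_profiles <- function(seed = 11) {
  simulate_purified_profiles(n_cell_types = 6, n_cpgs = 600,
                             markers_per_type = 30, reps_per_type = 5,
                             seed = seed)
}

# A noise-free mixture column over a signature matrix.
exact_mixture <- function(B, fractions) {
  as.numeric(B %*% fractions)
}

# Exhaustive LTS oracle: minimal sum of squared residuals over every
# k-subset of rows, by direct enumeration (independent of the Fast-LTS
# search path). Returns the best objective and subset.
lts_brute_force <- function(B, m, k) {
  subsets <- utils::combn(nrow(B), k, simplify = FALSE)
  best <- list(obj = Inf, h = NULL)
  for (h in subsets) {
    cf <- tryCatch(qr.solve(B[h, , drop = FALSE], m[h]), error = function(e) NULL)
    if (is.null(cf)) next
    obj <- sum((m[h] - B[h, , drop = FALSE] %*% cf)^2)
    if (obj < best$obj - 1e-15) best <- list(obj = obj, h = h)
  }
  best
}

# Non-negative least squares oracle by enumeration of active constraint
# sets: for every subset of coefficients pinned at zero, solve OLS on the
# rest and keep the feasible solution with the smallest SSR.
nnls_brute_force <- function(B, m) {
  p <- ncol(B)
  best <- list(obj = Inf, cf = NULL)
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) == 0)
    cf <- rep(0, p)
    if (length(free)) {
      sol <- qr.solve(B[, free, drop = FALSE], m)
      if (any(sol < -1e-12)) next
      cf[free] <- sol
    }
    obj <- sum((m - B %*% cf)^2)
    if (obj < best$obj - 1e-15) best <- list(obj = obj, cf = cf)
  }
  best$cf
}
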