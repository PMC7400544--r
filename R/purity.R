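# Tumor-purity estimation: a random-forest regression from deconvolution
# goodness-of-fit metrics + relative fractions to tumor purity, and
# purity-scaling of relative fractions.

#' Extract purity-model features from a deconvolution result
#'
#' The feature schema is the four goodness-of-fit metrics (R1, R2, RMSE1,
#' RMSE2) followed by the relative fraction of every signature cell type, in
#' the signature's column order (15 features for the 11-type reference
#' signature). The rationale: as tumor purity rises, the leukocyte signal a
#' reconstruction can explain falls, so the fit metrics carry purity
#' information even though no tumor signature is modelled.
#'
#' @param deconv An `md_deconv` result tibble from [deconvolve()].
#' @return Tibble: `sample_id` plus the feature columns.
#' @export
purity_features <- function(deconv) {
  cell_types <- attr(deconv, "cell_types")
  stopifnot(!is.null(cell_types))
  deconv |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::select("sample_id", "R1", "R2", "RMSE1", "RMSE2",
                  dplyr::all_of(cell_types))
}

#' Train the random-forest tumor-purity model
#'
#' Fits a random-forest regression of known purity on the deconvolution
#' features, with 500 trees, 5 candidate features per split and a minimum
#' terminal-node size of 5. A k-fold cross-validated Pearson r on the
#' training set is reported alongside.
#'
#' @param features Feature tibble from [purity_features()].
#' @param purity Numeric purity ground truth in \[0, 1\], one per feature row.
#' @param n_trees,mtry,min_node Forest hyperparameters (defaults 500/5/5).
#' @param cv_folds Cross-validation folds for the training-set r (default 5;
#'   0 skips CV).
#' @param seed Integer seed for the forest and fold assignment.
#' @return An `md_purity_model`: the forest, the feature schema, and
#'   `cv_r`, the cross-validated training Pearson correlation.
#' @export
train_purity_model <- function(features, purity, n_trees = 500, mtry = 5,
                               min_node = 5, cv_folds = 5, seed = NULL) {
  X <- as.data.frame(features[, setdiff(names(features), "sample_id")])
  if (nrow(X) < 50) stop("need at least 50 training rows")
  if (anyNA(X)) stop("features must not contain missing values")
  if (length(purity) != nrow(X)) stop("purity length must match feature rows")
  if (any(purity < 0 | purity > 1)) stop("purity values must lie in [0, 1]")
  schema <- names(X)
  mtry <- min(mtry, ncol(X))
  with_seed(seed, {
    forest <- randomForest::randomForest(
      x = X, y = purity, ntree = n_trees, mtry = mtry, nodesize = min_node,
      importance = TRUE)
    cv_r <- NA_real_
    if (cv_folds > 1) {
      fold <- sample(rep_len(seq_len(cv_folds), nrow(X)))
      pred <- numeric(nrow(X))
      for (k in seq_len(cv_folds)) {
        hold <- fold == k
        fk <- randomForest::randomForest(
          x = X[!hold, , drop = FALSE], y = purity[!hold], ntree = n_trees,
          mtry = mtry, nodesize = min_node)
        pred[hold] <- stats::predict(fk, X[hold, , drop = FALSE])
      }
      cv_r <- stats::cor(pred, purity)
    }
    structure(list(forest = forest, schema = schema, cv_r = cv_r,
                   params = list(n_trees = n_trees, mtry = mtry,
                                 min_node = min_node)),
              class = "md_purity_model")
  })
}

#' Predict tumor purity from deconvolution features
#'
#' @param model An `md_purity_model`.
#' @param features Feature tibble matching the training schema.
#' @return Numeric purity estimates clipped to \[0, 1\] (a regression forest
#'   can stray slightly outside the proportion scale), named by sample when
#'   a `sample_id` column is present.
#' @export
predict_purity <- function(model, features) {
  stopifnot(inherits(model, "md_purity_model"))
  X <- as.data.frame(features[, setdiff(names(features), "sample_id")])
  if (!identical(names(X), model$schema)) {
    stop("feature schema mismatch: expected ",
         paste(model$schema, collapse = ", "))
  }
  q <- clip01(as.numeric(stats::predict(model$forest, X)))
  if ("sample_id" %in% names(features)) names(q) <- features$sample_id
  q
}

#' @export
glance.md_purity_model <- function(x, ...) {
  tibble::tibble(n_trees = x$params$n_trees, mtry = x$params$mtry,
                 min_node = x$params$min_node, cv_r = x$cv_r,
                 n_features = length(x$schema))
}

#' @export
tidy.md_purity_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(feature = rownames(imp),
                 pct_inc_mse = imp[, "%IncMSE"],
                 inc_node_purity = imp[, "IncNodePurity"]) |>
    dplyr::arrange(dplyr::desc(.data$pct_inc_mse))
}

#' @export
print.md_purity_model <- function(x, ...) {
  cat(sprintf("<md_purity_model> %d trees, mtry %d, min node %d | CV r = %.3f\n",
              x$params$n_trees, x$params$mtry, x$params$min_node, x$cv_r))
  invisible(x)
}

#' Scale relative fractions by tumor purity
#'
#' Purity-scaled fractions \eqn{\underline{\tilde f} = (1 - q)\tilde f}:
#' the leukocyte compartment shrinks to the non-tumor share of the sample
#' while ratios between cell types are preserved exactly. The output sums to
#' `1 - q`.
#'
#' @param fractions Named relative fractions summing to 1.
#' @param q Tumor purity in \[0, 1\].
#' @return Scaled fractions of the same length.
#' @export
scale_fractions <- function(fractions, q) {
  if (q < 0 || q > 1) stop("purity q must lie in [0, 1]")
  (1 - q) * fractions
}

#' Split samples into stratified halves
#'
#' Random half split stratified by a group label (e.g. cancer type), the
#' protocol used for purity-model training versus held-out evaluation.
#'
#' @param groups Character/factor vector of group labels, one per sample.
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = training half.
#' @export
split_half_stratified <- function(groups, seed = NULL) {
  with_seed(seed, {
    train <- logical(length(groups))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      train[sample(idx, ceiling(length(idx) / 2))] <- TRUE
    }
    train
  })
}
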