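#' Read a CpG-by-sample Beta-value table
#'
#' Reads a tab- or comma-delimited text table of methylation Beta values
#' (the "Level 3" array style: CpG probe IDs in the first column, one column
#' per sample) into a tibble. Values must lie in \[0, 1\]; values straying
#' beyond by at most `tol` (floating-point formatting noise) are clipped,
#' anything further raises an error. Missing cells may be empty or `NA`.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter. Default `NULL` guesses from the extension
#'   (`.csv` is comma, anything else tab).
#' @param tol Out-of-range tolerance before erroring (default `1e-6`).
#' @return A tibble whose first column `cpg_id` holds unique probe IDs and
#'   whose remaining columns are numeric Beta values, one per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("cpg_id\ts1\ts2", "cg01\t0.1\t0.9", "cg02\t0.5\tNA"), tf)
#' read_beta_table(tf)
#' @export
read_beta_table <- function(path, delim = NULL, tol = 1e-6) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(raw) < 2L) stop("expected a CpG ID column plus >=1 sample column")
  names(raw)[1] <- "cpg_id"
  raw$cpg_id <- as.character(raw$cpg_id)
  dup <- unique(raw$cpg_id[duplicated(raw$cpg_id)])
  if (length(dup)) {
    stop("duplicate CpG IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (j in seq(2L, ncol(raw))) {
    col <- raw[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], names(raw)[j], col[bad[1]]))
      }
      col <- num
    }
    raw[[j]] <- assert_beta_range(col, sprintf("column '%s'", names(raw)[j]),
                                  tol = tol)
  }
  tibble::as_tibble(raw)
}

#' Read a CpG-by-cell-type signature matrix
#'
#' Same format as [read_beta_table()] with cell types as columns; missing
#' entries are not allowed in a reference signature.
#'
#' @inheritParams read_beta_table
#' @return A tibble: `cpg_id` plus one numeric column per cell type.
#' @export
read_signature_matrix <- function(path, delim = NULL, tol = 1e-6) {
  sig <- read_beta_table(path, delim = delim, tol = tol)
  if (anyNA(sig)) stop("signature matrix must not contain missing values")
  sig
}

#' Convert a Beta tibble to a numeric matrix
#'
#' @param tbl A tibble as returned by [read_beta_table()].
#' @return Numeric matrix with CpG IDs as rownames.
#' @export
beta_matrix <- function(tbl) {
  stopifnot(names(tbl)[1] == "cpg_id")
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$cpg_id
  storage.mode(m) <- "double"
  m
}

#' Restrict a mixture table and a signature to their shared CpGs
#'
#' Intersects the CpG sets of a mixture Beta table and a signature matrix and
#' returns both restricted to the shared probes, in the signature's row order
#' (deterministic across runs). Missing mixture values are retained here;
#' downstream per-sample regressions drop a sample's missing CpGs from that
#' sample's fit only, which the returned logical mask records.
#'
#' @param mixture Mixture Beta tibble (`cpg_id` + sample columns).
#' @param signature Signature tibble (`cpg_id` + cell-type columns).
#' @return A list with elements `mixture`, `signature` (aligned tibbles) and
#'   `mask` (logical matrix, CpG x sample, `TRUE` where the value is present).
#' @export
align_features <- function(mixture, signature) {
  shared <- intersect(signature$cpg_id, mixture$cpg_id)
  n_types <- ncol(signature) - 1L
  if (length(shared) < n_types + 1L) {
    stop(sprintf("insufficient shared CpGs: %d found, need at least %d",
                 length(shared), n_types + 1L))
  }
  sig <- signature[match(shared, signature$cpg_id), , drop = FALSE]
  mix <- mixture[match(shared, mixture$cpg_id), , drop = FALSE]
  mask <- !is.na(beta_matrix(mix))
  list(mixture = mix, signature = sig, mask = mask)
}

#' Write a deconvolution result table to TSV
#'
#' One row per sample: sample ID, relative fractions, the four goodness-of-fit
#' metrics, the selected trimming fraction alpha, the significance flag and,
#' when purity has been estimated, the purity and purity-scaled fractions.
#' Values round-trip through [read_result_table()] at 1e-12.
#'
#' @param results A deconvolution result tibble (see [deconvolve()]).
#' @param path Output file path.
#' @export
write_result_table <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}
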