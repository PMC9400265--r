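#' PCA of a group x use-category matrix
#'
#' Principal component analysis (SVD via `stats::prcomp`) of the ethnic-group
#' by use-category use-value matrix, used to project groups into a common
#' use-pattern space. Column-centered by default; unit-variance scaling is
#' optional (the UVc columns share units, so covariance PCA is the default).
#' Output is deterministic and sign-stabilized: within each component the
#' largest-magnitude loading is made positive, so results are reproducible
#' across linear-algebra backends.
#'
#' @param mat Numeric matrix (>= 2 rows and >= 2 columns); row names label
#'   groups, column names label categories. Missing entries are zero-filled
#'   with a warning (an absent category is an uncited category).
#' @param center,scale Centering / unit-variance scaling flags.
#' @param k Number of components to keep (default: all).
#' @return A list of class `"ordination_result"`: `scores` (group x
#'   component), `loadings` (category x component, orthonormal columns),
#'   `explained_variance_ratio`, `center`, `scale`.
#' @export
pca_ordination <- function(mat, center = TRUE, scale = FALSE, k = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need a matrix with >= 2 rows and >= 2 columns", call. = FALSE)
  }
  if (anyNA(mat)) {
    warning("missing entries zero-filled (uncited categories)", call. = FALSE)
    mat[is.na(mat)] <- 0
  }
  col_var <- apply(mat, 2, stats::var)
  if (all(col_var == 0)) {
    stop("degenerate input: constant matrix has no principal components",
         call. = FALSE)
  }
  if (scale && any(col_var == 0)) {
    stop("degenerate input: zero-variance column cannot be unit-scaled",
         call. = FALSE)
  }
  fit <- stats::prcomp(mat, center = center, scale. = scale)
  k <- min(k %||% ncol(fit$rotation), ncol(fit$rotation))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(fit$sdev^2)
  structure(
    list(
      scores = scores, loadings = loadings,
      explained_variance_ratio = (fit$sdev^2 / total_var)[seq_len(k)],
      center = center, scale = scale
    ),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("<ordination_result> ", nrow(x$scores), " groups x ",
      nrow(x$loadings), " categories, ", ncol(x$scores),
      " component(s)\n", sep = "")
  evr <- round(100 * x$explained_variance_ratio, 1)
  cat("  variance explained:", paste0(evr, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Extract the UVc block of a group index table for ordination
#'
#' Returns the ethnic-group x category matrix of per-category use values
#' (`UVc_*` columns of the group rows), zero-filling missing entries, ready
#' for [pca_ordination()].
#'
#' @param table A `"group_index_table"` (see [build_group_index_table()]).
#' @param categories Optional character vector of categories to keep (must
#'   exist as `UVc_` columns).
#' @return Numeric matrix with ethnic groups as row names and categories as
#'   column names.
#' @export
project_groups <- function(table, categories = NULL) {
  body <- table[table$row_type == "group", ]
  if (nrow(body) == 0) stop("schema error: empty table", call. = FALSE)
  uvc_cols <- grep("^UVc_", names(body), value = TRUE)
  if (is.null(categories)) {
    categories <- sub("^UVc_", "", uvc_cols)
  } else {
    missing <- setdiff(paste0("UVc_", categories), uvc_cols)
    if (length(missing)) {
      stop("schema error: no UVc column for category: ",
           paste(sub("^UVc_", "", missing), collapse = ", "), call. = FALSE)
    }
  }
  if (length(categories) == 0) {
    stop("schema error: no UVc_ category columns in table", call. = FALSE)
  }
  mat <- as.matrix(body[, paste0("UVc_", categories)])
  mat[is.na(mat)] <- 0
  rownames(mat) <- body$ethnic_group
  colnames(mat) <- categories
  mat
}

#' Write ordination artifacts to TSV
#'
#' Emits `scores.tsv`, `loadings.tsv` and `variance.tsv` into `dir`.
#'
#' @param ordination An `"ordination_result"`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_ordination <- function(ordination, dir) {
  stopifnot(inherits(ordination, "ordination_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    scores = file.path(dir, "scores.tsv"),
    loadings = file.path(dir, "loadings.tsv"),
    variance = file.path(dir, "variance.tsv")
  )
  readr::write_tsv(
    tibble::as_tibble(ordination$scores, rownames = "group"),
    paths["scores"], progress = FALSE
  )
  readr::write_tsv(
    tibble::as_tibble(ordination$loadings, rownames = "category"),
    paths["loadings"], progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(
      component = seq_along(ordination$explained_variance_ratio),
      explained_variance_ratio = ordination$explained_variance_ratio
    ),
    paths["variance"], progress = FALSE
  )
  invisible(paths)
}
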