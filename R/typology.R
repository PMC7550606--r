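# Classification of ARS patches into types: PCA on the five patch
# descriptors, then agglomerative hierarchical clustering (Ward.D2) on
# all five principal-component scores.

PATCH_FEATURES <- c("start_day", "mean_depth_m", "mean_sst_c",
                    "duration_days", "mcp_area_km2")

#' Build the patch feature table
#'
#' Selects the five clustering descriptors of each ARS patch: start day
#' (days since 10 September), mean depth (m), mean SST (degC), duration
#' (days) and minimum-convex-polygon area (km^2). Patches with missing
#' descriptors are dropped with a message.
#'
#' @param phases Metric-filled phase tibble (see [phase_metrics()]),
#'   typically filtered to `kind == "ARS"`.
#' @return A tibble of complete-case feature rows (plus `id`,
#'   `start_time` as identifiers).
#' @export
patch_feature_table <- function(phases) {
  x <- dplyr::filter(phases, .data$kind == "ARS")
  keep <- stats::complete.cases(x[PATCH_FEATURES])
  if (any(!keep))
    message(sum(!keep), " patch(es) dropped for missing descriptors")
  dplyr::select(x[keep, ], "id", "start_time",
                dplyr::all_of(PATCH_FEATURES))
}

#' PCA of the patch feature table
#'
#' Principal components of the column-standardized (z-scored) features —
#' i.e. an eigendecomposition of their correlation matrix, appropriate
#' because the descriptors mix units (days, m, degC, km^2). Components
#' are ordered by decreasing eigenvalue, with the sign convention that
#' each component's largest-magnitude loading is positive.
#'
#' @param table Output of [patch_feature_table()] (at least 3 rows).
#' @return A list of class `patch_pca`: `scores` (n x 5 matrix),
#'   `loadings`, `explained_variance` (eigenvalues, summing to 5), and
#'   the input `table`.
#' @export
pca_patches <- function(table) {
  feats <- as.matrix(table[PATCH_FEATURES])
  if (nrow(feats) < 3) stop("need at least 3 patches for PCA")
  const <- apply(feats, 2, stats::sd) < 1e-12
  if (any(const))
    stop("constant feature column(s): ",
         paste(colnames(feats)[const], collapse = ", "))
  pc <- stats::prcomp(feats, center = TRUE, scale. = TRUE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance = pc$sdev^2, table = table),
            class = "patch_pca")
}

#' Ward clustering of patch PC scores
#'
#' Agglomerative hierarchical clustering with the Ward.D2 criterion
#' (heights on the Euclidean distance scale) on all principal-component
#' scores, cut at `k` groups. Cluster labels are renumbered so that type
#' 1 has the earliest mean `start_day`.
#'
#' @param pca A `patch_pca` object (or a bare score matrix plus a
#'   `start_day` vector via `start_day`).
#' @param k Number of groups; the default 3 follows the common
#'   three-type structure, and `suggest_k()` reports the
#'   largest-relative-height-gap heuristic alongside.
#' @param start_day Optional override of the ordering variable.
#' @return A list of class `patch_clusters`: `assignments` (integer per
#'   patch), `merge_heights` (non-decreasing), `k`, `hclust` (the tree),
#'   `suggested_k`, and the feature `table` with a `type` column.
#' @export
ward_clustering <- function(pca, k = 3, start_day = NULL) {
  scores <- if (inherits(pca, "patch_pca")) pca$scores else as.matrix(pca)
  n <- nrow(scores)
  if (k < 1 || k > n) stop("k must be between 1 and the number of patches")
  if (is.null(start_day) && inherits(pca, "patch_pca"))
    start_day <- pca$table$start_day
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # renumber by ascending mean start day (fallback: first occurrence)
  ord <- if (!is.null(start_day)) {
    order(tapply(start_day, raw, mean))
  } else {
    unique(raw)
  }
  assignments <- match(raw, ord)
  # largest relative jump in merge height suggests where to cut
  gaps <- diff(hc$height) / pmax(utils::head(hc$height, -1), 1e-12)
  suggested_k <- if (length(gaps) >= 1) n - which.max(gaps) else k
  table <- if (inherits(pca, "patch_pca"))
    dplyr::mutate(pca$table, type = assignments) else NULL
  structure(list(assignments = assignments,
                 merge_heights = hc$height, k = k, hclust = hc,
                 suggested_k = suggested_k, table = table),
            class = "patch_clusters")
}

#' Per-type summary of ARS patches
#'
#' Arithmetic mean and standard error of each descriptor per patch type,
#' plus each type's share of all patches (percentages summing to 100).
#'
#' @param clusters A `patch_clusters` object, or an integer assignment
#'   vector (then `table` must be supplied).
#' @param table Feature table matching the assignments.
#' @return A tibble with one row per type: `type`, `n`, `share_pct`, and
#'   `<feature>_mean` / `<feature>_se` columns.
#' @export
summarize_patch_types <- function(clusters, table = NULL) {
  if (inherits(clusters, "patch_clusters")) {
    table <- clusters$table
    assignments <- clusters$assignments
  } else {
    assignments <- clusters
  }
  stopifnot(!is.null(table), length(assignments) == nrow(table))
  table |>
    dplyr::mutate(type = assignments) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(PATCH_FEATURES),
                    list(mean = mean,
                         se = ~ stats::sd(.x) / sqrt(length(.x))))) |>
    dplyr::mutate(share_pct = 100 * .data$n / sum(.data$n),
                  .after = "n")
}

#' @export
print.patch_clusters <- function(x, ...) {
  cat(sprintf("<patch_clusters> %d patches in %d types (suggested k: %d)\n",
              length(x$assignments), x$k, x$suggested_k))
  print(table(type = x$assignments))
  invisible(x)
}
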