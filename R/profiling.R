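#' Z-score selected columns of a table
#'
#' Standardizes each column to mean 0 and sample SD 1. The 18 behavioral
#' variables have incommensurate ranges (hundreds of coin events vs. a
#' handful of shield purchases), so distances on the raw scale would be
#' dominated by the large counts. Constant columns are dropped with a
#' warning.
#'
#' @param table Data.frame.
#' @param columns Columns to standardize (default [kdt_variables()]).
#' @return Data.frame of the standardized columns only.
#' @export
zscore_table <- function(table, columns = kdt_variables()) {
  columns <- intersect(columns, names(table))
  if (nrow(table) < 2L) stop("need at least 2 rows to standardize")
  x <- table[columns]
  s <- vapply(x, stats::sd, 0)
  if (any(s == 0)) {
    warning("constant columns dropped: ",
            paste(columns[s == 0], collapse = ", "))
    x <- x[s > 0]
  }
  as.data.frame(scale(as.matrix(x)))
}

#' Ward-linkage agglomerative clustering on squared Euclidean distances
#'
#' Classic Ward clustering: at each step the two clusters whose merge
#' minimally increases the total within-cluster sum of squares are joined
#' (Lance-Williams recurrence on squared Euclidean distances). Merge heights
#' are reported as the SSE increase of each merge, which is non-decreasing.
#'
#' @param table Data.frame or matrix of numeric rows (n >= 2).
#' @return An `hclust` object with `$height` equal to the per-merge SSE
#'   increase.
#' @export
ward_cluster <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("non-numeric cells in clustering table")
  if (nrow(x) < 2L) stop("need n >= 2 rows")
  hc <- stats::hclust(stats::dist(x)^2, method = "ward.D")
  hc$height <- hc$height / 2  # Lance-Williams Ward heights are twice the SSE increase
  hc
}

#' Choose the number of clusters by silhouette, with K-means confirmation
#'
#' Cuts the Ward dendrogram at every k in `k_range`, computes the mean
#' silhouette width (Euclidean distances), runs seeded K-means at the same k
#' and records its silhouette, and picks the k maximizing the hierarchical
#' silhouette. An agreement flag reports whether K-means prefers the same k.
#'
#' @param table Numeric table the linkage was built from (standardized).
#' @param linkage `hclust` object from [ward_cluster()].
#' @param k_range Candidate cluster counts (default 2:6).
#' @param seed Integer seed for the K-means restarts.
#' @param nstart K-means restarts (default 25).
#' @return Object of class `cluster_solution`: list with `chosen_k`,
#'   `silhouette` (per-k, hierarchical), `kmeans_silhouette`, `labels`
#'   (matrix, one column per k, from the hierarchical cut), `kmeans_labels`,
#'   `agreement`, and `linkage`.
#' @export
choose_k <- function(table, linkage, k_range = 2:6, seed = 1L,
                     nstart = 25L) {
  x <- as.matrix(table)
  n <- nrow(x)
  if (any(k_range < 2L | k_range > n - 1L))
    stop("k_range must lie within [2, n-1]")
  d <- stats::dist(x)
  sil_h <- sil_k <- stats::setNames(rep(NA_real_, length(k_range)),
                                    paste0("k", k_range))
  labels <- matrix(NA_integer_, n, length(k_range),
                   dimnames = list(NULL, paste0("k", k_range)))
  km_labels <- labels
  force(linkage)   # force before seeding
  set.seed(seed)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lab <- stats::cutree(linkage, k = k)
    if (length(unique(lab)) < k) {
      warning("empty cluster at k = ", k, "; skipped")
      next
    }
    labels[, i] <- lab
    sil_h[i] <- mean(cluster::silhouette(lab, d)[, "sil_width"])
    km <- stats::kmeans(x, centers = k, nstart = nstart)
    km_labels[, i] <- km$cluster
    sil_k[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  chosen <- k_range[which.max(sil_h)]
  structure(list(chosen_k = chosen, silhouette = sil_h,
                 kmeans_silhouette = sil_k,
                 labels = labels, kmeans_labels = km_labels,
                 agreement = k_range[which.max(sil_k)] == chosen,
                 k_range = k_range, linkage = linkage),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Ward/silhouette cluster solution: chosen k =", x$chosen_k,
      if (isTRUE(x$agreement)) "(K-means concurs)" else
        "(K-means prefers a different k)", "\n")
  print(round(rbind(hierarchical = x$silhouette,
                    kmeans = x$kmeans_silhouette), 3))
  invisible(x)
}

#' Name behavioral clusters from their mean profiles
#'
#' Rule-based characterization on the cluster means of the 18 KDT
#' variables: the cluster with the lowest combined box-interaction level
#' (touched + accepted, both box kinds) is "risk_avoidant"; among the rest,
#' high engagement with the highest total losses is "useless_risk"; high
#' gains without elevated losses is "useful_risk". With a single cluster the
#' label is "homogeneous". Ties are broken by the total-gains mean (lower
#' mean wins the risk-avoidant label), with a warning.
#'
#' @param table Cohort data.frame holding the 18 KDT variables.
#' @param labels Cluster assignment per row.
#' @return Named character vector: cluster id -> profile name.
#' @export
characterize_clusters <- function(table, labels) {
  ids <- sort(unique(labels))
  if (length(ids) == 1L)
    return(stats::setNames("homogeneous", ids))
  boxv <- c("ambiguous_boxes_touched", "ambiguous_boxes_accepted",
            "risk_boxes_touched", "risk_boxes_accepted")
  agg <- function(v) vapply(ids, function(g)
    mean(rowSums(table[labels == g, v, drop = FALSE])), 0)
  box <- agg(boxv)
  losses <- agg("total_losses")
  gains <- agg("total_gains")
  out <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (any(duplicated(signif(box, 10)))) {
    warning("tied box-engagement profiles; tie broken by total-gains mean")
    box <- box + 1e-9 * gains
  }
  avoid <- which.min(box)
  out[avoid] <- "risk_avoidant"
  rest <- setdiff(seq_along(ids), avoid)
  if (length(rest) == 1L) {
    out[rest] <- if (losses[rest] > losses[avoid]) "useless_risk"
      else "useful_risk"
  } else {
    useless <- rest[which.max(losses[rest])]
    out[useless] <- "useless_risk"
    out[setdiff(rest, useless)] <- "useful_risk"
  }
  out
}

#' Serialize a cluster solution to JSON
#'
#' @param solution A `cluster_solution` from [choose_k()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_solution <- function(solution, path) {
  jsonlite::write_json(
    list(chosen_k = solution$chosen_k,
         agreement = solution$agreement,
         silhouette = as.list(solution$silhouette),
         kmeans_silhouette = as.list(solution$kmeans_silhouette),
         labels = solution$labels[, paste0("k", solution$chosen_k)],
         merge = solution$linkage$merge,
         height = solution$linkage$height),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
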