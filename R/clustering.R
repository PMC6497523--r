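#' Hierarchical clustering of nuclei by shape profile
#'
#' Agglomerative clustering of aligned, fixed-length angle profiles
#' (Euclidean distance, Ward linkage by default), cut into `k` clusters.
#' Profiles share units (degrees), so no per-position standardization is
#' applied. Given identical inputs the result is deterministic.
#'
#' @param x A [fit_profiles()] result or a numeric profile matrix (one row
#'   per nucleus).
#' @param k Number of clusters (`1 <= k <= n`).
#' @param linkage `"ward"` (Ward's minimum variance, on squared Euclidean
#'   distances), `"average"` or `"complete"`.
#' @return An object of class `cluster_result`: list with `labels` (integer
#'   vector), `k`, `tree` (the [stats::hclust()] dendrogram) and `profiles`
#'   (the feature matrix).
#' @export
cluster_profiles <- function(x, k, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  mat <- if (inherits(x, "profile_fit")) x$profiles else as.matrix(x)
  n <- nrow(mat)
  if (k > n) stop("k exceeds the number of nuclei")
  if (k < 1) stop("k must be at least 1")
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  tree <- stats::hclust(stats::dist(mat), method = method)
  labels <- if (k == 1L) rep(1L, n) else unname(stats::cutree(tree, k = k))
  structure(list(labels = labels, k = k, tree = tree, profiles = mat),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d nuclei in %d clusters: %s\n",
              length(x$labels), x$k,
              paste(sprintf("%d (n=%d)", seq_len(x$k),
                            tabulate(x$labels, x$k)), collapse = ", ")))
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  graphics::plot(x$tree, labels = FALSE, main = "Shape-profile dendrogram",
                 ...)
  stats::rect.hclust(x$tree, k = x$k)
  invisible(x)
}

#' Sub-cluster one cluster of an existing result
#'
#' Re-clusters only the members of the chosen cluster into `k2` groups,
#' relabelling them as new clusters appended after the existing ones; all
#' other labels are unchanged. Used for recursive discovery of morphological
#' classes within a heterogeneous cluster.
#'
#' @param result A `cluster_result`.
#' @param cluster The cluster id to split.
#' @param k2 Number of sub-clusters (at most the cluster's size).
#' @param linkage Passed to [cluster_profiles()].
#' @return A new `cluster_result` with `k + k2 - 1` clusters.
#' @export
subcluster <- function(result, cluster, k2, linkage = "ward") {
  stopifnot(inherits(result, "cluster_result"))
  members <- which(result$labels == cluster)
  if (length(members) < k2) stop("cluster ", cluster, " has fewer than k2 members")
  if (k2 == 1L) return(result)
  sub <- cluster_profiles(result$profiles[members, , drop = FALSE], k = k2,
                          linkage = linkage)
  labels <- result$labels
  # sub-cluster 1 keeps the old id; the rest get fresh ids after k
  new_ids <- c(cluster, result$k + seq_len(k2 - 1L))
  labels[members] <- new_ids[sub$labels]
  structure(list(labels = labels, k = result$k + k2 - 1L, tree = result$tree,
                 profiles = result$profiles),
            class = "cluster_result")
}

#' Best-matching label agreement
#'
#' Fraction of observations whose cluster label matches the reference after
#' the optimal one-to-one relabelling (maximized over label permutations;
#' solved exactly by enumeration for up to 8 labels, greedily above).
#'
#' @param labels Integer or factor cluster labels.
#' @param truth Reference labels, same length.
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("label vectors differ in length")
  la <- as.integer(factor(labels))
  tr <- as.integer(factor(truth))
  ka <- max(la); kt <- max(tr)
  k <- max(ka, kt)
  conf <- matrix(0L, k, k)
  for (i in seq_along(la)) conf[la[i], tr[i]] <- conf[la[i], tr[i]] + 1L
  if (k <= 8L) {
    perms <- pracma::perms(seq_len(k))
    best <- max(apply(perms, 1, function(p) {
      sum(conf[cbind(seq_len(k), p)])
    }))
  } else {
    # greedy assignment on the confusion matrix
    best <- 0L
    cf <- conf
    for (step in seq_len(k)) {
      m <- which(cf == max(cf), arr.ind = TRUE)[1, ]
      best <- best + cf[m[1], m[2]]
      cf[m[1], ] <- -1L
      cf[, m[2]] <- -1L
    }
  }
  best / length(la)
}

#' Suggest a cluster count by silhouette score
#'
#' Computes the mean silhouette width for each candidate `k` and returns the
#' candidate maximizing it. Offered as guidance only: the choice of `k` for
#' a real sample is a biological read-out, not an algorithmic rule.
#'
#' @inheritParams cluster_profiles
#' @param k_range Candidate cluster counts.
#' @return Named numeric vector of mean silhouette widths, with the chosen
#'   `k` in attribute `"best_k"`.
#' @export
suggest_k <- function(x, k_range = 2:6, linkage = "ward") {
  mat <- if (inherits(x, "profile_fit")) x$profiles else as.matrix(x)
  d <- as.matrix(stats::dist(mat))
  scores <- vapply(k_range, function(k) {
    lab <- cluster_profiles(mat, k, linkage)$labels
    mean_silhouette(d, lab)
  }, numeric(1))
  names(scores) <- k_range
  structure(scores, best_k = k_range[which.max(scores)])
}

mean_silhouette <- function(d, lab) {
  n <- length(lab)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab == lab[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(g) {
      mean(d[i, lab == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
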