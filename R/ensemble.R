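#' Ensemble of randomly initialized k-means partitions
#'
#' Runs Lloyd's squared-Euclidean k-means `n_init` times on the voxel feature
#' matrix, each run from an independent random centroid initialization
#' (random distinct voxels), iterated to convergence (up to 300 iterations).
#' The ensemble is the basis both for validity-index evaluation (via its best
#' member) and for stability-based consensus labelling.
#'
#' @param features voxels x features matrix (see [build_features()])
#' @param k number of clusters (>= 2, < number of voxels)
#' @param n_init ensemble size (number of random initializations)
#' @param seed integer seed
#' @return object of class `partition_ensemble`: list with `partitions`
#'   (n_init x voxels integer matrix, labels in 1..k), `wss` (total
#'   within-cluster sum of squares per member), `k`
#' @export
kmeans_ensemble <- function(features, k, n_init = 1000L, seed = 1L) {
  features <- as.matrix(features)
  k <- assert_count(k, "k", min = 2L)
  n_init <- assert_count(n_init, "n_init")
  n <- nrow(features)
  if (k >= n) stop("k must be smaller than the number of voxels", call. = FALSE)
  if (sum(apply(features, 2L, stats::var)) == 0) {
    stop("degenerate features: zero variance across voxels", call. = FALSE)
  }
  set.seed(seed)
  partitions <- matrix(NA_integer_, n_init, n)
  wss <- numeric(n_init)
  for (i in seq_len(n_init)) {
    fit <- suppressWarnings(
      stats::kmeans(features, centers = k, iter.max = 300L,
                    nstart = 1L, algorithm = "Lloyd")
    )
    partitions[i, ] <- fit$cluster
    wss[i] <- fit$tot.withinss
  }
  structure(list(partitions = partitions, wss = wss, k = k),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> k=%d, %d members, %d voxels (best WSS %.4g)\n",
              x$k, nrow(x$partitions), ncol(x$partitions), min(x$wss)))
  invisible(x)
}

# best (lowest-WSS) member of an ensemble
best_partition <- function(ensemble) {
  ensemble$partitions[which.min(ensemble$wss), ]
}

# optimal one-to-one relabelling of `part` onto `ref` (max label overlap),
# exact search over the k! permutations (k <= 7)
align_partition <- function(part, ref, k) {
  conf <- table(factor(part, levels = seq_len(k)), factor(ref, levels = seq_len(k)))
  best <- NULL
  best_overlap <- -1L
  for (p in all_perms(k)) {
    ov <- sum(conf[cbind(seq_len(k), p)])
    if (ov > best_overlap) {
      best_overlap <- ov
      best <- p
    }
  }
  best[part]
}

#' Consensus labelling with stability filtering
#'
#' Aligns every ensemble member to a reference partition (the member with the
#' lowest within-cluster sum of squares) by optimal one-to-one label matching,
#' then marks a voxel as stable iff its aligned label is identical in at least
#' `stability_threshold` of the members. Unstable voxels are flagged and
#' excluded from subregion membership (their label is `NA`).
#'
#' @param ensemble a [kmeans_ensemble()] result
#' @param stability_threshold required share of agreeing members in (0, 1];
#'   the default 1 demands strict unanimity across initializations
#' @return object of class `parcellation`: list with `label` (integer or `NA`
#'   per voxel), `stable` (logical), `agreement` (share of members agreeing
#'   with the modal aligned label), `k`
#' @export
consensus_labels <- function(ensemble, stability_threshold = 1.0) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  if (nrow(ensemble$partitions) == 0L) stop("empty ensemble", call. = FALSE)
  stopifnot(stability_threshold > 0, stability_threshold <= 1)
  k <- ensemble$k
  ref <- best_partition(ensemble)
  n <- ncol(ensemble$partitions)
  R <- nrow(ensemble$partitions)
  counts <- matrix(0L, k, n)
  for (i in seq_len(R)) {
    al <- align_partition(ensemble$partitions[i, ], ref, k)
    counts[cbind(al, seq_len(n))] <- counts[cbind(al, seq_len(n))] + 1L
  }
  modal <- max.col(t(counts), ties.method = "first")
  agreement <- counts[cbind(modal, seq_len(n))] / R
  stable <- agreement >= stability_threshold
  label <- ifelse(stable, modal, NA_integer_)
  structure(list(label = as.integer(label), stable = stable,
                 agreement = agreement, k = k),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> k=%d, %d voxels (%d stable)%s\n",
              x$k, length(x$label), sum(x$stable),
              if (!is.null(x$names)) paste0(", named: ",
                                            paste(x$names, collapse = "/")) else ""))
  invisible(x)
}
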