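# Cluster validity indices used in the majority vote over candidate k.
#
# All indices are computed from the feature matrix and a hard partition
# alone. Scalar indices carry their own optimum rule (max or min over k);
# Hartigan and Krzanowski-Lai are defined on the sequence of within-cluster
# sums of squares over successive k and vote through elbow-type rules.

validity_context <- function(X, labels, d = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- max(labels)
  if (is.null(d)) d <- stats::dist(X)
  dm <- as.matrix(d)
  sizes <- tabulate(labels, k)
  centroids <- matrix(0, k, ncol(X))
  for (j in seq_len(k)) {
    centroids[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  gc_ <- colMeans(X)
  # squared distance of each point to its centroid
  d2own <- rowSums((X - centroids[labels, , drop = FALSE])^2)
  W <- sum(d2own)
  totss <- sum(rowSums(sweep(X, 2L, gc_)^2))
  pair <- which(upper.tri(dm), arr.ind = TRUE)
  within_pair <- labels[pair[, 1L]] == labels[pair[, 2L]]
  dpair <- dm[pair]
  list(X = X, labels = labels, k = k, n = n, p = ncol(X), dm = dm,
       sizes = sizes, centroids = centroids, global_centroid = gc_,
       d2own = d2own, W = W, B = totss - W, totss = totss,
       dpair = dpair, within_pair = within_pair)
}

vi_calinski_harabasz <- function(ctx) {
  with(ctx, if (W <= 0 || k <= 1 || n <= k) NA_real_ else
    (B / (k - 1)) / (W / (n - k)))
}

vi_silhouette <- function(ctx) {
  with(ctx, {
    s <- numeric(n)
    for (i in seq_len(n)) {
      own <- labels == labels[i]
      if (sum(own) == 1L) { s[i] <- 0; next }
      a <- sum(dm[i, own]) / (sum(own) - 1L)
      b <- min(vapply(setdiff(seq_len(k), labels[i]), function(j) {
        mean(dm[i, labels == j])
      }, numeric(1)))
      s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    mean(s)
  })
}

vi_davies_bouldin <- function(ctx) {
  with(ctx, {
    S <- vapply(seq_len(k), function(j) {
      mean(sqrt(d2own[labels == j]))
    }, numeric(1))
    M <- as.matrix(stats::dist(centroids))
    if (any(M[upper.tri(M)] == 0)) return(NA_real_)
    mean(vapply(seq_len(k), function(i) {
      max(vapply(setdiff(seq_len(k), i), function(j) (S[i] + S[j]) / M[i, j],
                 numeric(1)))
    }, numeric(1)))
  })
}

vi_dunn <- function(ctx) {
  with(ctx, {
    diam <- max(c(0, dpair[within_pair]))
    if (diam == 0 || !any(!within_pair)) return(NA_real_)
    min(dpair[!within_pair]) / diam
  })
}

vi_c_index <- function(ctx) {
  with(ctx, {
    nw <- sum(within_pair)
    if (nw == 0L) return(NA_real_)
    sw <- sum(dpair[within_pair])
    ds <- sort(dpair)
    smin <- sum(ds[seq_len(nw)])
    smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
    if (smax == smin) return(NA_real_)
    (sw - smin) / (smax - smin)
  })
}

vi_mcclain_rao <- function(ctx) {
  with(ctx, {
    nw <- sum(within_pair)
    nb <- sum(!within_pair)
    if (nw == 0L || nb == 0L) return(NA_real_)
    mb <- sum(dpair[!within_pair]) / nb
    if (mb == 0) return(NA_real_)
    (sum(dpair[within_pair]) / nw) / mb
  })
}

vi_point_biserial <- function(ctx) {
  with(ctx, {
    nw <- sum(within_pair)
    nb <- sum(!within_pair)
    nt <- length(dpair)
    sd_d <- stats::sd(dpair)
    if (nw == 0L || nb == 0L || sd_d == 0) return(NA_real_)
    mw <- mean(dpair[within_pair])
    mb <- mean(dpair[!within_pair])
    (mb - mw) * sqrt(nw * nb / nt^2) / sd_d
  })
}

vi_pbm <- function(ctx) {
  with(ctx, {
    e1 <- sum(sqrt(rowSums(sweep(X, 2L, global_centroid)^2)))
    ek <- sum(sqrt(d2own))
    Dk <- max(stats::dist(centroids))
    if (ek == 0 || Dk == 0) return(NA_real_)
    ((1 / k) * (e1 / ek) * Dk)^2
  })
}

vi_ratkowsky_lance <- function(ctx) {
  with(ctx, {
    tss <- vapply(seq_len(p), function(j) sum((X[, j] - global_centroid[j])^2),
                  numeric(1))
    keep <- tss > 0
    if (!any(keep)) return(NA_real_)
    bss <- vapply(seq_len(p), function(j) {
      sum(sizes * (centroids[, j] - global_centroid[j])^2)
    }, numeric(1))
    mean(sqrt(bss[keep] / tss[keep])) / sqrt(k)
  })
}

vi_xie_beni <- function(ctx) {
  with(ctx, {
    sep <- min(stats::dist(centroids))^2
    if (sep == 0) return(NA_real_)
    W / (n * sep)
  })
}

.VALIDITY_INDICES <- list(
  calinski_harabasz = list(fn = vi_calinski_harabasz, rule = "max"),
  silhouette        = list(fn = vi_silhouette,        rule = "max"),
  davies_bouldin    = list(fn = vi_davies_bouldin,    rule = "min"),
  dunn              = list(fn = vi_dunn,              rule = "max"),
  c_index           = list(fn = vi_c_index,           rule = "min"),
  mcclain_rao       = list(fn = vi_mcclain_rao,       rule = "min"),
  point_biserial    = list(fn = vi_point_biserial,    rule = "max"),
  pbm               = list(fn = vi_pbm,               rule = "max"),
  ratkowsky_lance   = list(fn = vi_ratkowsky_lance,   rule = "max"),
  xie_beni          = list(fn = vi_xie_beni,          rule = "min")
)

#' Compute one cluster validity index on a partition
#'
#' Scalar indices available: Calinski-Harabasz, mean silhouette width,
#' Davies-Bouldin, Dunn, C-index, McClain-Rao, point-biserial, PBM,
#' Ratkowsky-Lance and Xie-Beni. Returns `NA` where the index is undefined
#' for the partition (e.g. coincident centroids, no between-cluster pairs).
#'
#' @param index index name (see Details)
#' @param features voxels x features matrix
#' @param labels integer partition labels in 1..k
#' @return the index value, or `NA` if undefined
#' @export
validity_index <- function(index, features, labels) {
  index <- match.arg(index, names(.VALIDITY_INDICES))
  ctx <- validity_context(features, as.integer(labels))
  .VALIDITY_INDICES[[index]]$fn(ctx)
}

#' Validity-index votes over candidate cluster numbers
#'
#' Evaluates the full index battery on the best (lowest within-cluster sum of
#' squares) ensemble member for every candidate `k` and records each index's
#' vote under its own optimum rule: maximum or minimum over `k` for the ten
#' scalar indices; for Hartigan, the elbow of the statistic
#' `H(k) = (W_k / W_{k+1} - 1) (n - k - 1)` (the `k` with the largest drop
#' `H(k-1) - H(k)`, taking the one-cluster solution's within sum of squares
#' as the total sum of squares); for
#' Krzanowski-Lai, the `k` maximizing `|DIFF_k| / |DIFF_{k+1}|` with
#' `DIFF_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k` (the one-cluster
#' within-cluster sum of squares is the total sum of squares). Indices
#' undefined on some candidate abstain and are logged in the table.
#'
#' @param features voxels x features matrix
#' @param ensembles list of [kmeans_ensemble()] results, one per candidate k
#' @param k_range integer candidate range (default 2:7); must match the
#'   ensembles' k values
#' @return a `vote_table` data.frame with columns `index`, `vote`,
#'   `abstained`; per-k index values are attached as attribute `"values"`
#'   and the W_k sequence as `"wss"`
#' @export
compute_validity_votes <- function(features, ensembles, k_range = 2:7) {
  ks <- vapply(ensembles, function(e) e$k, integer(1))
  if (!identical(sort(as.integer(k_range)), sort(ks))) {
    stop("ensembles do not match `k_range`", call. = FALSE)
  }
  k_range <- sort(as.integer(k_range))
  ensembles <- ensembles[order(ks)]
  X <- as.matrix(features)
  d <- stats::dist(X)
  n <- nrow(X)
  p <- ncol(X)

  scalar_names <- names(.VALIDITY_INDICES)
  values <- matrix(NA_real_, length(scalar_names), length(k_range),
                   dimnames = list(scalar_names, as.character(k_range)))
  wss <- numeric(length(k_range))
  for (j in seq_along(k_range)) {
    part <- best_partition(ensembles[[j]])
    ctx <- validity_context(X, part, d = d)
    wss[j] <- ctx$W
    for (nm in scalar_names) values[nm, j] <- .VALIDITY_INDICES[[nm]]$fn(ctx)
  }

  vote_scalar <- function(vals, rule) {
    ok <- which(is.finite(vals))
    if (!length(ok)) return(NA_integer_)
    v <- vals[ok]
    best <- if (rule == "max") max(v) else min(v)
    k_range[ok[which(abs(v - best) < 1e-12)[1L]]]
  }
  votes <- vapply(scalar_names, function(nm) {
    vote_scalar(values[nm, ], .VALIDITY_INDICES[[nm]]$rule)
  }, integer(1))

  # Hartigan statistic H(k) = (W_k / W_{k+1} - 1)(n - k - 1) over successive
  # k (W_1 = total sum of squares); vote by the elbow rule: the k with the
  # largest drop H(k-1) - H(k), i.e. after which adding clusters stops paying
  hartigan_vote <- NA_integer_
  if (length(k_range) >= 2L && k_range[1L] == 2L) {
    tss <- sum(sweep(X, 2L, colMeans(X))^2)
    w_ext <- c(tss, wss)
    ks_ext <- c(1L, k_range)
    H <- (w_ext[-length(w_ext)] / w_ext[-1L] - 1) *
      (n - ks_ext[-length(ks_ext)] - 1) # H(1), H(2), ..., H(kmax - 1)
    if (length(H) >= 2L) {
      drop_ <- H[-length(H)] - H[-1L] # indexed by k = 2 .. kmax - 1
      ok <- which(is.finite(drop_))
      if (length(ok)) hartigan_vote <- k_range[ok[which.max(drop_[ok])]]
    }
  }

  # Krzanowski-Lai over interior k (needs W_{k-1} and W_{k+1}; W_1 = TSS)
  kl_vote <- NA_integer_
  if (length(k_range) >= 2L && k_range[1L] == 2L) {
    tss <- sum(sweep(X, 2L, colMeans(X))^2)
    w_ext <- c(tss, wss) # W_1, W_2, ..., W_kmax
    ks_ext <- c(1L, k_range)
    diffs <- vapply(seq_along(k_range), function(j) {
      k <- k_range[j]
      (k - 1)^(2 / p) * w_ext[j] - k^(2 / p) * w_ext[j + 1L]
    }, numeric(1))
    if (length(diffs) >= 2L) {
      kl <- abs(diffs[-length(diffs)]) / abs(diffs[-1L])
      ok <- which(is.finite(kl))
      if (length(ok)) kl_vote <- k_range[ok[which.max(kl[ok])]]
    }
  }

  out <- data.frame(
    index = c(scalar_names, "hartigan", "krzanowski_lai"),
    vote = c(unname(votes), hartigan_vote, kl_vote),
    stringsAsFactors = FALSE
  )
  out$abstained <- is.na(out$vote)
  attr(out, "values") <- values
  attr(out, "wss") <- stats::setNames(wss, as.character(k_range))
  class(out) <- c("vote_table", class(out))
  out
}

#' Select the cluster number by majority vote
#'
#' The winning `k` is the modal vote among non-abstaining indices, with ties
#' broken toward the smaller `k`; agreement is the percentage of
#' non-abstaining indices voting for the winner.
#'
#' @param votes a vote table from [compute_validity_votes()]
#' @return list with `k_star` (integer) and `agreement` (percent)
#' @export
select_k <- function(votes) {
  v <- votes$vote[!is.na(votes$vote)]
  if (!length(v)) stop("all validity indices abstained", call. = FALSE)
  tab <- table(v)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k_star <- min(winners)
  list(k_star = k_star, agreement = 100 * sum(v == k_star) / length(v))
}
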