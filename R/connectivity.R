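# clip correlations before atanh so Fisher z stays finite
.Z_CLIP <- 1 - 1e-7

fisher_z <- function(r) atanh(pmin(pmax(r, -.Z_CLIP), .Z_CLIP))

#' Task-wise beta-series correlations between subregions and parcels
#'
#' For each task, Pearson correlations are computed across that task's
#' correct target-condition trials between each subregion's trial series and
#' each cortical parcel's trial series, then Fisher z-transformed (with
#' correlations clipped to +/- (1 - 1e-7) so z stays finite). Cells with a
#' constant series are undefined and flagged missing (`NA`).
#'
#' @param subregion_series trials x 4 matrix (columns ordered as
#'   `ipl_subregions()`), aligned with `table` rows
#' @param parcel_series trials x parcels matrix aligned with `table` rows
#' @param table trial table aligned with the series
#' @param min_trials minimum correct target trials required per task
#' @return object of class `connectivity_tensor`: list with `r`, `z`
#'   (4 x parcels x 3 arrays), `n_trials` per task, and dim metadata
#' @export
taskwise_correlation <- function(subregion_series, parcel_series, table,
                                 min_trials = 5L) {
  subregion_series <- as.matrix(subregion_series)
  parcel_series <- as.matrix(parcel_series)
  stopifnot(nrow(subregion_series) == nrow(table),
            nrow(parcel_series) == nrow(table),
            ncol(subregion_series) == 4L)
  keep <- target_correct_rows(table)
  P <- ncol(parcel_series)
  r <- array(NA_real_, dim = c(4L, P, 3L),
             dimnames = list(.SUBREGIONS, NULL, .TASKS))
  n_trials <- stats::setNames(integer(3L), .TASKS)
  for (tk in .TASKS) {
    rows <- keep[table$task[keep] == tk]
    n_trials[tk] <- length(rows)
    if (length(rows) < min_trials) {
      stop(sprintf("task %s has %d correct target trials (< %d)",
                   tk, length(rows), min_trials), call. = FALSE)
    }
    r[, , tk] <- t(suppressWarnings(
      stats::cor(parcel_series[rows, , drop = FALSE],
                 subregion_series[rows, , drop = FALSE])
    ))
  }
  structure(list(r = r, z = fisher_z(r), n_trials = n_trials,
                 n_parcels = P),
            class = "connectivity_tensor")
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  cat(sprintf("<connectivity_tensor> 4 subregions x %d parcels x 3 tasks\n",
              x$n_parcels))
  if (!is.null(x$p)) {
    cat(sprintf("  %d cells flagged at alpha = %g\n", sum(x$flag, na.rm = TRUE),
                attr(x$flag, "alpha")))
  }
  invisible(x)
}

# task-specific shift statistic: z(task) minus the mean z across tasks
connectivity_statistic <- function(z) {
  sweep(z, c(1L, 2L), apply(z, c(1L, 2L), mean))
}

#' Pooled permutation baseline for task-specific connectivity shifts
#'
#' Builds the empirical null of the shift statistic `z(task) - mean_task z`
#' under the hypothesis that all three tasks induce the same coupling: in
#' each permutation, task labels are shuffled across the correct
#' target-condition trials within each subject (preserving per-task trial
#' counts), correlations are recomputed per permuted task and the statistic
#' is stored per (subregion, parcel, task).
#'
#' @inheritParams taskwise_correlation
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @param shuffle_unit `"subject"` (default) shuffles task labels within each
#'   subject; `"pooled"` shuffles across all trials
#' @return object of class `connectivity_null`: list with `stat` array
#'   (4 x parcels x 3 x n_perm) and `n_perm`
#' @export
permutation_baseline <- function(subregion_series, parcel_series, table,
                                 n_perm = 5000L, seed = 1L,
                                 shuffle_unit = c("subject", "pooled")) {
  shuffle_unit <- match.arg(shuffle_unit)
  n_perm <- assert_count(n_perm, "n_perm", min = 100L)
  subregion_series <- as.matrix(subregion_series)
  parcel_series <- as.matrix(parcel_series)
  keep <- target_correct_rows(table)
  tasks <- table$task[keep]
  if (length(unique(tasks)) < 2L) {
    stop("permutation baseline needs at least two tasks", call. = FALSE)
  }
  subj <- table$subject[keep]
  sub_s <- subregion_series[keep, , drop = FALSE]
  par_s <- parcel_series[keep, , drop = FALSE]
  P <- ncol(par_s)
  set.seed(seed)
  groups <- if (shuffle_unit == "subject") {
    split(seq_along(tasks), subj)
  } else {
    list(seq_along(tasks))
  }
  stat <- array(NA_real_, dim = c(4L, P, 3L, n_perm),
                dimnames = list(.SUBREGIONS, NULL, .TASKS, NULL))
  for (b in seq_len(n_perm)) {
    perm_tasks <- tasks
    for (g in groups) perm_tasks[g] <- tasks[g][sample.int(length(g))]
    z <- array(NA_real_, dim = c(4L, P, 3L))
    for (ti in seq_along(.TASKS)) {
      rows <- which(perm_tasks == .TASKS[ti])
      z[, , ti] <- fisher_z(t(suppressWarnings(
        stats::cor(par_s[rows, , drop = FALSE], sub_s[rows, , drop = FALSE])
      )))
    }
    stat[, , , b] <- connectivity_statistic(z)
  }
  structure(list(stat = stat, n_perm = n_perm, shuffle_unit = shuffle_unit),
            class = "connectivity_null")
}

#' Flag task-specific connectivity shifts against the permutation null
#'
#' The observed statistic per cell is `z(task) - mean_task z`. Two-tailed
#' empirical p-values use the add-one correction
#' `p = (1 + #\{|null| >= |obs|\}) / (1 + n_perm)`; a cell is flagged iff
#' `p < alpha`. No correction across parcels is applied by default;
#' `adjust = "BH"` applies Benjamini-Hochberg across all cells.
#'
#' @param tensor a [taskwise_correlation()] result
#' @param null a [permutation_baseline()] result
#' @param alpha significance level
#' @param adjust `"none"` (default) or `"BH"`
#' @return the tensor with `stat`, `p` and `flag` arrays added
#' @export
significant_shifts <- function(tensor, null, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(tensor, "connectivity_tensor"),
            inherits(null, "connectivity_null"))
  if (!identical(dim(null$stat)[1:3], dim(tensor$z))) {
    stop("null distribution does not match tensor dimensions", call. = FALSE)
  }
  if (anyNA(null$stat)) stop("null distribution contains missing cells", call. = FALSE)
  obs <- connectivity_statistic(tensor$z)
  n_perm <- null$n_perm
  exceed <- apply(abs(null$stat) >=
                    array(abs(obs), dim = dim(null$stat)), c(1L, 2L, 3L), sum)
  p <- (1 + exceed) / (1 + n_perm)
  p[is.na(obs)] <- NA_real_
  p_use <- p
  if (adjust == "BH") {
    p_use <- array(stats::p.adjust(p, method = "BH"), dim = dim(p),
                   dimnames = dimnames(p))
  }
  flag <- !is.na(p_use) & p_use < alpha
  attr(flag, "alpha") <- alpha
  tensor$stat <- obs
  tensor$p <- p
  tensor$p_adjusted <- if (adjust == "BH") p_use else NULL
  tensor$flag <- flag
  tensor
}

#' Aggregate parcel-level connectivity to seven networks
#'
#' Mean Fisher z per (subregion, network, task), in an all-cells variant and
#' a significant-only variant (`NA` where a network has no flagged cell;
#' requires [significant_shifts()] to have been run for that variant).
#'
#' @param tensor a `connectivity_tensor`
#' @param lookup data.frame (`parcel`, `network`) covering every parcel
#' @return list of `all` and (if flags present) `significant`:
#'   4 x 7 x 3 arrays of mean z
#' @export
network_aggregate <- function(tensor, lookup) {
  stopifnot(inherits(tensor, "connectivity_tensor"))
  P <- tensor$n_parcels
  net <- lookup$network[match(seq_len(P), lookup$parcel)]
  if (anyNA(net)) stop("unmapped parcel(s) in network lookup", call. = FALSE)
  if (!all(net %in% .NETWORKS)) stop("unknown network name(s)", call. = FALSE)
  agg <- function(include) {
    out <- array(NA_real_, dim = c(4L, length(.NETWORKS), 3L),
                 dimnames = list(.SUBREGIONS, .NETWORKS, .TASKS))
    for (nw in .NETWORKS) {
      cols <- which(net == nw)
      if (!length(cols)) next
      for (ti in seq_along(.TASKS)) {
        for (si in 1:4) {
          z <- tensor$z[si, cols, ti]
          m <- include[si, cols, ti]
          out[si, nw, ti] <- if (any(m, na.rm = TRUE)) {
            mean(z[which(m)])
          } else NA_real_
        }
      }
    }
    out
  }
  all_mask <- array(TRUE, dim = dim(tensor$z))
  res <- list(all = agg(all_mask))
  if (!is.null(tensor$flag)) res$significant <- agg(tensor$flag)
  res
}

#' Write a connectivity tensor as long-format TSV
#'
#' Columns: subregion, parcel, task, r, z, and (when present) stat, p, flag.
#'
#' @param tensor a `connectivity_tensor`
#' @param path file path
#' @export
write_connectivity_tsv <- function(tensor, path) {
  long <- expand.grid(subregion = .SUBREGIONS,
                      parcel = seq_len(tensor$n_parcels),
                      task = .TASKS, stringsAsFactors = FALSE)
  long$r <- as.vector(tensor$r)
  long$z <- as.vector(tensor$z)
  if (!is.null(tensor$p)) {
    long$stat <- as.vector(tensor$stat)
    long$p <- as.vector(tensor$p)
    long$flag <- as.vector(tensor$flag)
  }
  write_tsv(long, path)
}
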