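# off-diagonal directed connections among the four subregions
ec_connections <- function(include_self = FALSE) {
  g <- expand.grid(source = .SUBREGIONS, target = .SUBREGIONS,
                   stringsAsFactors = FALSE)
  if (!include_self) g <- g[g$source != g$target, , drop = FALSE]
  g <- g[order(match(g$source, .SUBREGIONS), match(g$target, .SUBREGIONS)), ]
  rownames(g) <- NULL
  g
}

# subjects x 3 tasks x connections matrix view of a modulation set
ec_flatten <- function(mods, include_self = FALSE) {
  conn <- ec_connections(include_self)
  n <- dim(mods)[1L]
  out <- array(NA_real_, dim = c(n, 3L, nrow(conn)))
  for (j in seq_len(nrow(conn))) {
    out[, , j] <- mods[, , conn$source[j], conn$target[j]]
  }
  dimnames(out) <- list(dimnames(mods)[[1L]], .TASKS,
                        paste(conn$source, conn$target, sep = "->"))
  out
}

#' Per-connection task contrast statistic
#'
#' For every directed connection, the statistic is the mean over subjects of
#' the parameter under the given task minus the mean of the same parameter
#' under the other two tasks.
#'
#' @param mods a `modulation_set` (see [generate_modulations()] /
#'   [read_modulation_set()])
#' @param task task whose contrast is computed
#' @param include_self include self-connections?
#' @return named numeric vector (one entry per directed connection)
#' @export
task_contrast_statistic <- function(mods, task, include_self = FALSE) {
  task <- match.arg(task, .TASKS)
  if (dim(mods)[1L] < 2L) stop("need >= 2 subjects", call. = FALSE)
  x <- ec_flatten(mods, include_self)
  others <- setdiff(.TASKS, task)
  d <- x[, task, , drop = FALSE] -
    (x[, others[1L], , drop = FALSE] + x[, others[2L], , drop = FALSE]) / 2
  stats::setNames(apply(d, 3L, mean), dimnames(x)[[3L]])
}

#' Random-effects permutation test for task-specific modulations
#'
#' Tests, per task and directed connection, the null hypothesis of no
#' parameter difference between tasks. The observed statistic is the
#' [task_contrast_statistic()]; the null is built by independently permuting
#' each subject's three task assignments (`method = "label_permutation"`,
#' default) or by randomly sign-flipping each subject's contrast
#' (`method = "sign_flip"`) and recomputing the statistic `n_perm` times.
#' A connection is flagged iff its absolute observed statistic exceeds the
#' `percentile`-th percentile of the absolute null; the empirical
#' add-one-corrected p-value is reported alongside so either decision rule
#' can be applied.
#'
#' @param mods a `modulation_set`
#' @param n_perm number of permutations; must be at least
#'   `ceiling(100 / (100 - percentile))` (10000 recommended for the default
#'   percentile)
#' @param percentile percentile of the absolute null used as the threshold
#'   (default 99.9)
#' @param seed integer seed
#' @param method null-construction strategy (see Description)
#' @param include_self test self-connections as well?
#' @return an `ec_test_result` data.frame: `task`, `source`, `target`,
#'   `statistic`, `mean_strength` (group mean parameter under the task),
#'   `threshold`, `p`, `flag`; test metadata in attributes
#' @export
ec_permutation_test <- function(mods, n_perm = 10000L, percentile = 99.9,
                                seed = 1L,
                                method = c("label_permutation", "sign_flip"),
                                include_self = FALSE) {
  method <- match.arg(method)
  stopifnot(percentile > 0, percentile < 100)
  n_perm <- assert_count(n_perm, "n_perm")
  min_n <- ceiling(100 / (100 - percentile) - 1e-6)
  if (n_perm < min_n) {
    stop(sprintf("n_perm = %d too small for percentile %.4g; need >= %d",
                 n_perm, percentile, min_n), call. = FALSE)
  }
  n <- dim(mods)[1L]
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  x <- ec_flatten(mods, include_self)
  C <- dim(x)[3L]
  conn_names <- dimnames(x)[[3L]]

  # per-subject statistic contribution: 1.5 * x[s, t, c] - 0.5 * S[s, c]
  # with S the sum over tasks (invariant under task-label permutation)
  S <- apply(x, c(1L, 3L), sum)            # n x C
  half_meanS <- 0.5 * colMeans(S)          # length C
  # stacked view: rows s + (t-1) * n, columns connections
  Xs <- matrix(aperm(x, c(1L, 2L, 3L)), nrow = n * 3L, ncol = C)

  obs <- vapply(.TASKS, function(tk) task_contrast_statistic(mods, tk, include_self),
                numeric(C))                # C x 3
  set.seed(seed)
  null_abs <- array(NA_real_, dim = c(n_perm, 3L, C))
  if (method == "label_permutation") {
    for (b in seq_len(n_perm)) {
      P <- t(vapply(seq_len(n), function(s) sample.int(3L), integer(3L)))
      for (ti in 1:3) {
        rows <- (P[, ti] - 1L) * n + seq_len(n)
        null_abs[b, ti, ] <- 1.5 * colMeans(Xs[rows, , drop = FALSE]) - half_meanS
      }
    }
  } else {
    # subject-wise contrast vectors per task; flip signs per subject
    d <- array(NA_real_, dim = c(n, 3L, C))
    for (ti in 1:3) d[, ti, ] <- 1.5 * matrix(Xs[(ti - 1L) * n + seq_len(n), ],
                                              n, C) - 0.5 * S
    for (b in seq_len(n_perm)) {
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      for (ti in 1:3) null_abs[b, ti, ] <- colMeans(sgn * d[, ti, ])
    }
  }
  null_abs <- abs(null_abs)

  conn <- ec_connections(include_self)
  out <- do.call(rbind, lapply(seq_along(.TASKS), function(ti) {
    tk <- .TASKS[ti]
    thr <- apply(null_abs[, ti, , drop = FALSE], 3L,
                 stats::quantile, probs = percentile / 100, type = 1L)
    pv <- vapply(seq_len(C), function(j) {
      (1 + sum(null_abs[, ti, j] >= abs(obs[j, tk]))) / (1 + n_perm)
    }, numeric(1))
    strength <- colMeans(matrix(Xs[(ti - 1L) * n + seq_len(n), ], n, C))
    data.frame(task = tk, source = conn$source, target = conn$target,
               statistic = obs[, tk], mean_strength = strength,
               threshold = thr, p = pv,
               flag = abs(obs[, tk]) > thr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "percentile") <- percentile
  attr(out, "method") <- method
  attr(out, "connections") <- conn_names
  class(out) <- c("ec_test_result", class(out))
  out
}

#' Write effective-connectivity test results as TSV
#'
#' Columns mirror a source/target/strength/p table restricted to flagged
#' connections when `significant_only = TRUE`.
#'
#' @param result an `ec_test_result`
#' @param path file path
#' @param significant_only write only flagged connections?
#' @export
write_ec_result <- function(result, path, significant_only = FALSE) {
  df <- as.data.frame(result)
  if (significant_only) df <- df[df$flag, , drop = FALSE]
  write_tsv(df, path)
}
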