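#' Subregion-averaged trial features
#'
#' Averages trial-wise voxel betas over the stable voxels of each of the four
#' subregions (L-ant, L-post, R-ant, R-post), keeping only correct
#' target-condition trials (invalid, word, false belief): control conditions,
#' catch trials and incorrect responses are dropped.
#'
#' @param betas list with elements `left`, `right`: trials x voxels matrices
#'   aligned with `table` rows
#' @param parc list with elements `left`, `right`: named parcellations
#' @param table trial table aligned with the beta matrices
#' @return a data.frame with the trial metadata plus feature columns
#'   `L_ant`, `L_post`, `R_ant`, `R_post`
#' @export
aggregate_subregions <- function(betas, parc, table) {
  stopifnot(is.list(betas), is.list(parc),
            all(c("left", "right") %in% names(betas)),
            all(c("left", "right") %in% names(parc)))
  keep <- target_correct_rows(table)
  out <- table[keep, c("trial_id", "subject", "session", "run", "task",
                       "condition"), drop = FALSE]
  for (h in c("left", "right")) {
    p <- parc[[h]]
    if (is.null(p$names)) stop("parcellation must be named", call. = FALSE)
    b <- as.matrix(betas[[h]])
    stopifnot(nrow(b) == nrow(table))
    for (nm in c("anterior", "posterior")) {
      code <- which(p$names == nm)
      vox <- which(p$stable & p$label == code)
      if (!length(vox)) {
        stop(sprintf("empty subregion: %s %s", h, nm), call. = FALSE)
      }
      col <- paste0(if (h == "left") "L_" else "R_",
                    if (nm == "anterior") "ant" else "post")
      out[[col]] <- rowMeans(b[keep, vox, drop = FALSE])
    }
  }
  out <- out[, c("trial_id", "subject", "session", "run", "task", "condition",
                 .FEATURE_COLS)]
  rownames(out) <- NULL
  out
}

#' Balance trial counts across tasks within subject and run
#'
#' Within each (subject, run), every task is subsampled without replacement
#' to the minimum per-task trial count of that (subject, run). Subsampling is
#' seeded per group (independently of which other groups are present), so the
#' same rows are retained when the table is restricted to a subject subset.
#'
#' @param table a subregion feature table (see [aggregate_subregions()])
#' @param seed integer seed
#' @return the balanced table (row order: subject, run, task, trial id)
#' @export
balance_trials <- function(table, seed) {
  tasks <- intersect(.TASKS, unique(table$task))
  groups <- split(seq_len(nrow(table)), list(table$subject, table$run),
                  drop = TRUE)
  keep <- integer(0)
  for (g in groups) {
    cnt <- table(factor(table$task[g], levels = tasks))
    if (any(cnt == 0L)) {
      miss <- names(cnt)[cnt == 0L][1L]
      stop(sprintf("subject %s run %d has no '%s' trials",
                   table$subject[g[1L]], table$run[g[1L]], miss), call. = FALSE)
    }
    m <- min(cnt)
    set.seed(group_seed(seed, table$subject[g[1L]], table$run[g[1L]]))
    for (tk in tasks) {
      rows <- g[table$task[g] == tk]
      keep <- c(keep, if (length(rows) > m) sort(sample(rows, m)) else rows)
    }
  }
  out <- table[keep, , drop = FALSE]
  out <- out[order(out$subject, out$run, match(out$task, tasks), out$trial_id), ]
  rownames(out) <- NULL
  out
}

#' Confound table for a feature table
#'
#' Numeric confounds derived from the trial metadata: session number, session
#' time (position of the run within its session) and run time (position of
#' the trial within its run), plus the subject identifier.
#'
#' @param table a subregion feature table
#' @return data.frame with columns `subject`, `session`, `session_time`,
#'   `run_time`, aligned row-for-row with `table`
#' @export
confound_table <- function(table) {
  run_time <- stats::ave(seq_len(nrow(table)),
                         table$subject, table$run,
                         FUN = function(i) rank(table$trial_id[i]))
  data.frame(subject = table$subject,
             session = as.numeric(table$session),
             session_time = as.numeric((table$run - 1L) %% 4L + 1L),
             run_time = as.numeric(run_time),
             stringsAsFactors = FALSE)
}

#' Remove confound-explained variation from features
#'
#' The numeric confounds (session number, session time, run time) are
#' regressed out of each feature column by least squares fitted on the
#' training rows only; the fitted coefficients are applied to the test rows,
#' so no test information enters the fit. Zero-variance confound columns are
#' dropped (recorded in attribute `"dropped"`). Subject identity is handled
#' by within-subject mean-centering computed from each subject's own rows,
#' which involves no cross-subject leakage and remains defined for subjects
#' unseen at training time.
#'
#' @param train training feature table (with metadata columns)
#' @param test optional test feature table
#' @param center_subject apply within-subject mean-centering?
#' @return list with residualized `train` and `test` tables; attribute
#'   `"dropped"` on the result lists dropped confound columns
#' @export
deconfound <- function(train, test = NULL, center_subject = TRUE) {
  ctr <- confound_table(train)
  cte <- if (!is.null(test)) confound_table(test)
  num_cols <- c("session", "session_time", "run_time")
  keep_cols <- num_cols[vapply(num_cols, function(cn) stats::var(ctr[[cn]]) > 0,
                               logical(1))]
  dropped <- setdiff(num_cols, keep_cols)
  if (length(dropped)) {
    message("deconfound: dropping zero-variance confound(s): ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep_cols)) {
    Xtr <- cbind(1, as.matrix(ctr[keep_cols]))
    fit <- lapply(.FEATURE_COLS, function(cn) {
      stats::lm.fit(Xtr, train[[cn]])$coefficients
    })
    for (j in seq_along(.FEATURE_COLS)) {
      cn <- .FEATURE_COLS[j]
      beta <- fit[[j]]
      beta[is.na(beta)] <- 0
      train[[cn]] <- train[[cn]] - as.vector(Xtr %*% beta)
      if (!is.null(test)) {
        Xte <- cbind(1, as.matrix(cte[keep_cols]))
        test[[cn]] <- test[[cn]] - as.vector(Xte %*% beta)
      }
    }
  }
  if (center_subject) {
    center <- function(df) {
      for (cn in .FEATURE_COLS) {
        df[[cn]] <- df[[cn]] - stats::ave(df[[cn]], df$subject)
      }
      df
    }
    train <- center(train)
    if (!is.null(test)) test <- center(test)
  }
  out <- list(train = train, test = test)
  attr(out, "dropped") <- dropped
  out
}

#' Run-wise feature standardization
#'
#' Within each (subject, session, run) every feature column is de-meaned to
#' zero and scaled to unit variance using the population (1/n) variance
#' convention, so a two-trial run with values (1, 3) maps to (-1, 1).
#' Zero-variance columns within a run are set to 0 (recorded in attribute
#' `"degenerate_runs"`).
#'
#' @param table a subregion feature table
#' @return the standardized table
#' @export
standardize_runwise <- function(table) {
  degenerate <- character(0)
  grp <- interaction(table$subject, table$session, table$run, drop = TRUE)
  for (cn in .FEATURE_COLS) {
    x <- table[[cn]]
    m <- stats::ave(x, grp)
    v <- stats::ave((x - m)^2, grp) # population variance
    z <- ifelse(v > 0, (x - m) / sqrt(v), 0)
    if (any(v == 0)) degenerate <- c(degenerate, cn)
    table[[cn]] <- z
  }
  if (length(degenerate)) {
    message("standardize_runwise: zero-variance run(s) in ",
            paste(unique(degenerate), collapse = ", "), "; set to 0")
  }
  attr(table, "degenerate_runs") <- unique(degenerate)
  table
}

# one-vs-rest L2 logistic fits; returns 3 x 5 matrix (intercept + 4 weights)
fit_ovr_logistic <- function(table, reg_strength = 1) {
  x <- as.matrix(table[.FEATURE_COLS])
  n <- nrow(x)
  lam <- 1 / (reg_strength * n)
  w <- matrix(NA_real_, 3L, length(.FEATURE_COLS) + 1L,
              dimnames = list(.TASKS, c("intercept", .FEATURE_COLS)))
  for (tk in .TASKS) {
    y <- as.integer(table$task == tk)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lam, standardize = FALSE)
    cf <- as.vector(stats::coef(fit, s = lam))
    w[tk, ] <- cf
  }
  w
}

ovr_predict <- function(weights, table) {
  x <- cbind(1, as.matrix(table[.FEATURE_COLS]))
  scores <- x %*% t(weights)
  # argmax with ties broken by fixed task order (attention < semantics < social)
  .TASKS[apply(scores, 1L, which.max)]
}

#' Leave-one-subject-out task decoding
#'
#' One cross-validation fold per subject. Within each fold the training and
#' held-out data are balanced (per subject and run), deconfounded (numeric
#' confound regression fitted on training rows only; within-subject
#' centering) and standardized run-wise, then three one-vs-rest L2-penalized
#' logistic discriminants are fitted on the training subjects and the held-out
#' subject's trials are assigned to the task with the maximal decision value
#' (ties broken by fixed task order). (Subject, run) cells missing a task
#' entirely are dropped with a message before balancing.
#'
#' @param table a subregion feature table covering >= 3 subjects
#' @param seed integer seed (drives the balancing subsamples)
#' @param reg_strength inverse regularization strength of the L2 logistic
#'   model (penalty `1/(reg_strength * n)` in glmnet's scaling)
#' @return list with `report` (class `cv_report`: overall and per-task
#'   accuracy in percent, 3x3 confusion matrix, chance level, number of test
#'   trials) and `signature` (fold-averaged 3 x 5 weight matrix, intercept
#'   plus one weight per subregion) and `fold_weights`
#' @export
loso_crossvalidate <- function(table, seed = 1L, reg_strength = 1) {
  subjects <- sort(unique(table$subject))
  if (length(subjects) < 3L) {
    stop("leave-one-subject-out requires >= 3 subjects", call. = FALSE)
  }
  tasks_present <- intersect(.TASKS, unique(table$task))
  if (length(tasks_present) < 3L) {
    stop("all three tasks must be present", call. = FALSE)
  }
  # drop (subject, run) cells missing a task entirely
  grp <- split(seq_len(nrow(table)), list(table$subject, table$run), drop = TRUE)
  bad <- vapply(grp, function(g) {
    any(table(factor(table$task[g], levels = .TASKS)) == 0L)
  }, logical(1))
  if (any(bad)) {
    message("loso_crossvalidate: dropping ", sum(bad),
            " (subject, run) cell(s) missing a task")
    table <- table[-unlist(grp[bad]), , drop = FALSE]
    subjects <- sort(unique(table$subject))
  }

  confusion <- matrix(0L, 3L, 3L, dimnames = list(true = .TASKS, pred = .TASKS))
  fold_weights <- vector("list", length(subjects))
  names(fold_weights) <- subjects
  for (s in subjects) {
    train <- table[table$subject != s, , drop = FALSE]
    test <- table[table$subject == s, , drop = FALSE]
    train <- balance_trials(train, seed)
    test <- balance_trials(test, seed)
    dc <- deconfound(train, test)
    train <- standardize_runwise(dc$train)
    test <- standardize_runwise(dc$test)
    w <- fit_ovr_logistic(train, reg_strength = reg_strength)
    fold_weights[[s]] <- w
    pred <- ovr_predict(w, test)
    for (i in seq_len(nrow(test))) {
      confusion[test$task[i], pred[i]] <- confusion[test$task[i], pred[i]] + 1L
    }
  }
  n_test <- sum(confusion)
  overall <- 100 * sum(diag(confusion)) / n_test
  per_task <- 100 * diag(confusion) / rowSums(confusion)
  signature <- Reduce(`+`, fold_weights) / length(fold_weights)
  report <- structure(list(overall_accuracy = overall,
                           per_task_accuracy = per_task,
                           confusion = confusion,
                           chance = 100 / 3,
                           n_test = n_test),
                      class = "cv_report")
  list(report = report, signature = signature, fold_weights = fold_weights)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> overall accuracy %.2f%% (chance %.2f%%), %d test trials\n",
              x$overall_accuracy, x$chance, x$n_test))
  cat("per-task accuracy (%):\n")
  print(round(x$per_task_accuracy, 2))
  cat("confusion matrix (rows = true task):\n")
  print(x$confusion)
  invisible(x)
}
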