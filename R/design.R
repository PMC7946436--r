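#' Generate an event-related trial design for one task
#'
#' Builds the per-run trial table of the three-task study. Each run of the
#' attention task contains 8 invalid, 30 valid and 2 catch trials; each
#' semantics run 20 word and 20 pseudoword trials; each social-cognition run
#' 3 false-belief and 3 true-belief trials. Trial order within a run is
#' pseudo-randomized under `seed`, runs are grouped into sessions of four,
#' and onsets follow a jittered inter-trial interval (truncated Gaussian with
#' task-specific mean; onsets are carried for completeness and are not used by
#' downstream stages). Response correctness is simulated as Bernoulli with a
#' per-condition accuracy; catch trials probe no response and carry `NA`.
#'
#' @param task `"attention"`, `"semantics"` or `"social"`
#' @param n_runs runs per subject (sessions hold four runs each)
#' @param n_subjects number of subjects
#' @param seed integer seed
#' @param accuracy probability of a correct response on non-catch trials
#' @return a `data.frame` (trial table) with columns `trial_id`, `subject`,
#'   `session`, `run`, `task`, `condition`, `correct`, `onset`
#' @export
#' @examples
#' d <- generate_design("attention", n_runs = 1, n_subjects = 1, seed = 1)
#' table(d$condition)
generate_design <- function(task, n_runs, n_subjects, seed, accuracy = 0.95) {
  if (!is.character(task) || length(task) != 1L || !task %in% .TASKS) {
    stop(sprintf("unknown task '%s'; must be one of %s",
                 paste(task, collapse = ","), paste(.TASKS, collapse = ", ")),
         call. = FALSE)
  }
  n_runs <- assert_count(n_runs, "n_runs")
  n_subjects <- assert_count(n_subjects, "n_subjects")
  stopifnot(accuracy >= 0, accuracy <= 1)
  set.seed(seed)

  counts <- .DESIGN_COUNTS[[task]]
  iti <- .ITI[[task]]
  per_run <- rep(names(counts), counts)
  rows <- vector("list", n_subjects * n_runs)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("sub%02d", s)
    for (r in seq_len(n_runs)) {
      cond <- sample(per_run)
      gaps <- pmax(iti["min"], stats::rnorm(length(cond), iti["mean"], iti["sd"]))
      correct <- stats::rbinom(length(cond), 1L, accuracy) == 1L
      correct[cond == "catch"] <- NA
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        subject = subj,
        session = (r - 1L) %/% 4L + 1L,
        run = r,
        task = task,
        condition = cond,
        correct = correct,
        onset = cumsum(gaps),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Generate the full three-task design for a subject sample
#'
#' Calls [generate_design()] once per task, then assembles each run's
#' timeline: the three task blocks are administered consecutively within a
#' run in pseudo-randomized order (separated by a 16 s rest period), onsets
#' are shifted to run time accordingly, and trial ids follow the timeline.
#'
#' @inheritParams generate_design
#' @return a trial table covering all three tasks
#' @export
generate_full_design <- function(n_runs, n_subjects, seed, accuracy = 0.95) {
  parts <- lapply(seq_along(.TASKS), function(i) {
    generate_design(.TASKS[i], n_runs, n_subjects, seed = seed + i, accuracy = accuracy)
  })
  out <- do.call(rbind, parts)
  set.seed(seed)
  rest <- 16
  pieces <- list()
  for (s in sort(unique(out$subject))) {
    for (r in seq_len(n_runs)) {
      block_order <- sample(.TASKS)
      offset <- 0
      for (tk in block_order) {
        rows <- which(out$subject == s & out$run == r & out$task == tk)
        block <- out[rows, , drop = FALSE]
        block$onset <- block$onset + offset
        offset <- max(block$onset) + rest
        pieces[[length(pieces) + 1L]] <- block
      }
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$subject, out$run, out$onset), ]
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read / write a trial table as TSV
#'
#' @param table a trial table as returned by [generate_design()]
#' @param path file path
#' @return `read_trial_table()` returns the trial table; the writer returns
#'   `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  write_tsv(table, path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- read_tsv(path)
  out$correct <- as.logical(out$correct)
  out
}

# rows of a trial table that are correct responses to the target condition
target_correct_rows <- function(table) {
  tgt <- unname(.TARGET[table$task])
  which(table$condition == tgt & !is.na(table$correct) & table$correct)
}
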