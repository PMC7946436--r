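#' Build the voxel-by-feature matrix for parcellation
#'
#' For each voxel, the feature vector holds one entry per (subject, task):
#' the mean trial-wise beta of that subject's correct target-condition trials
#' (target > rest contrast against a zero rest baseline), pooling information
#' across subjects. Incorrect trials and control/catch conditions are
#' excluded.
#'
#' @param betas trials x voxels beta matrix (rows aligned with `table`)
#' @param table trial table aligned with `betas` rows
#' @param target_conditions named character vector mapping task to its target
#'   condition; defaults to the canonical targets
#' @return voxels x features numeric matrix with `subject.task` column names
#' @export
build_features <- function(betas, table, target_conditions = NULL) {
  betas <- as.matrix(betas)
  stopifnot(nrow(betas) == nrow(table))
  tgt <- target_conditions %||% .TARGET
  subjects <- sort(unique(table$subject))
  tasks <- intersect(.TASKS, unique(table$task))
  cols <- list()
  for (s in subjects) {
    for (tk in tasks) {
      rows <- which(table$subject == s & table$task == tk &
                      table$condition == tgt[[tk]] &
                      !is.na(table$correct) & table$correct)
      if (!length(rows)) {
        stop(sprintf("subject %s has no correct '%s' trials in task %s",
                     s, tgt[[tk]], tk), call. = FALSE)
      }
      cols[[paste(s, tk, sep = ".")]] <- colMeans(betas[rows, , drop = FALSE])
    }
  }
  out <- do.call(cbind, cols)
  if (any(!is.finite(out))) stop("non-finite feature values", call. = FALSE)
  out
}
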