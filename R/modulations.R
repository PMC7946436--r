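#' Ground-truth directed modulation matrices
#'
#' Holds, for each task, a 4x4 matrix of directed modulatory coupling
#' strengths among the four IPL subregions (rows = source, columns = target;
#' arbitrary rate units) plus a between-subject sd used when sampling
#' subject-wise matrices.
#'
#' @param B named list of three 4x4 matrices (one per task, names
#'   `ipl_tasks()`), rows/cols ordered as `ipl_subregions()`
#' @param subject_sd between-subject Gaussian sd (>= 0)
#' @return object of class `modulation_truth`
#' @export
modulation_truth <- function(B, subject_sd = 0.5) {
  stopifnot(is.list(B), setequal(names(B), .TASKS))
  B <- B[.TASKS]
  for (tk in .TASKS) {
    m <- as.matrix(B[[tk]])
    stopifnot(all(dim(m) == c(4L, 4L)), all(is.finite(m)))
    dimnames(m) <- list(.SUBREGIONS, .SUBREGIONS)
    B[[tk]] <- m
  }
  if (subject_sd < 0) stop("subject_sd must be >= 0", call. = FALSE)
  structure(list(B = B, subject_sd = subject_sd), class = "modulation_truth")
}

#' Default modulation truth with task-dependent directed coupling
#'
#' The planted group-level matrices reproduce the qualitative (and numeric)
#' pattern of significant task-specific modulations among the four IPL
#' subregions: a sparse configuration for attention, dense interhemispheric
#' facilitation/inhibition for semantics, and predominantly facilitatory
#' influences from the posterior subregions for social cognition. Entries not
#' listed are zero; diagonals are zero.
#'
#' @param subject_sd between-subject sd
#' @return a [modulation_truth()]
#' @export
default_modulation_truth <- function(subject_sd = 0.5) {
  z <- matrix(0, 4, 4, dimnames = list(.SUBREGIONS, .SUBREGIONS))
  set_links <- function(m, links) {
    for (l in links) m[l[[1]], l[[2]]] <- as.numeric(l[[3]])
    m
  }
  B <- list(
    attention = set_links(z, list(
      list("L-ant", "R-post", -1.93),
      list("L-post", "R-ant", 3.01),
      list("R-post", "R-ant", -1.50)
    )),
    semantics = set_links(z, list(
      list("L-ant", "L-post", 1.08),
      list("L-ant", "R-ant", 0.97),
      list("L-ant", "R-post", 1.27),
      list("L-post", "R-ant", 1.26),
      list("R-ant", "L-ant", -1.49),
      list("R-ant", "L-post", -2.45),
      list("R-ant", "R-post", -3.24),
      list("R-post", "R-ant", -0.22)
    )),
    social = set_links(z, list(
      list("L-ant", "R-ant", 0.30),
      list("L-post", "L-ant", 1.23),
      list("L-post", "R-ant", -0.57),
      list("R-post", "L-ant", 1.76),
      list("R-post", "L-post", 1.43),
      list("R-post", "R-ant", 2.13)
    ))
  )
  modulation_truth(B, subject_sd = subject_sd)
}

#' Sample subject-wise modulation matrices around a ground truth
#'
#' Each subject's per-task matrix is the truth matrix plus i.i.d. Gaussian
#' between-subject noise (applied to every directed connection).
#'
#' @param truth a [modulation_truth()]
#' @param n_subjects number of subjects (>= 2; the downstream permutation test
#'   is undefined for fewer)
#' @param seed integer seed
#' @return a `modulation_set`: numeric array `subject x task x source x target`
#'   with dimnames
#' @export
generate_modulations <- function(truth, n_subjects, seed) {
  stopifnot(inherits(truth, "modulation_truth"))
  if (!is.numeric(n_subjects) || n_subjects < 2L) {
    stop("n_subjects must be >= 2 (permutation test undefined otherwise)",
         call. = FALSE)
  }
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 2L)
  set.seed(seed)
  subjects <- sprintf("sub%02d", seq_len(n_subjects))
  out <- array(0, dim = c(n_subjects, 3L, 4L, 4L),
               dimnames = list(subjects, .TASKS, .SUBREGIONS, .SUBREGIONS))
  for (s in seq_len(n_subjects)) {
    for (tk in .TASKS) {
      out[s, tk, , ] <- truth$B[[tk]] +
        matrix(stats::rnorm(16L, 0, truth$subject_sd), 4L, 4L)
    }
  }
  class(out) <- c("modulation_set", class(out))
  out
}

#' Read / write a modulation set as long-format TSV
#'
#' Columns: `subject`, `task`, `source`, `target`, `value`, with subregion
#' names `L-ant`, `L-post`, `R-ant`, `R-post`.
#'
#' @param mods a `modulation_set` array
#' @param path file path
#' @export
write_modulation_set <- function(mods, path) {
  dn <- dimnames(mods)
  long <- expand.grid(subject = dn[[1]], task = dn[[2]],
                      source = dn[[3]], target = dn[[4]],
                      stringsAsFactors = FALSE)
  long$value <- as.vector(mods)
  long <- long[order(long$subject, long$task, long$source, long$target), ]
  write_tsv(long, path)
}

#' @rdname write_modulation_set
#' @export
read_modulation_set <- function(path) {
  long <- read_tsv(path)
  subjects <- sort(unique(long$subject))
  out <- array(NA_real_, dim = c(length(subjects), 3L, 4L, 4L),
               dimnames = list(subjects, .TASKS, .SUBREGIONS, .SUBREGIONS))
  out[cbind(match(long$subject, subjects), match(long$task, .TASKS),
            match(long$source, .SUBREGIONS), match(long$target, .SUBREGIONS))] <-
    long$value
  stopifnot(all(is.finite(out)))
  class(out) <- c("modulation_set", class(out))
  out
}
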