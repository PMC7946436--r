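`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from one master seed
#'
#' Stages of the pipeline are seeded independently so each stage is
#' reproducible in isolation. The split uses a Lehmer step of the master seed
#' plus the stage index, kept inside the 32-bit integer range.
#'
#' @param seed master integer seed
#' @param stage stage index (1-based) or stage name known to the pipeline
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "parcellate", "classify", "connectivity", "ecperm")
  if (is.character(stage)) {
    stage <- match(match.arg(stage, stages), stages)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) %% 44488L) * 48271 + stage) # < 2^31
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# deterministic per-group seed that does not depend on which other groups are
# present (needed so leave-one-subject-out folds reuse identical subsamples)
group_seed <- function(seed, subject, run) {
  s <- sum(utf8ToInt(as.character(subject))) %% 10000L
  as.integer((seed %% 100000L) * 10007L + s * 101L + as.integer(run)) %% 2147483647L
}

# coordinates -> single integer key for set operations on voxel grids
coord_key <- function(coords, shape) {
  (coords[, 1L] - 1L) + shape[1L] * ((coords[, 2L] - 1L) + shape[2L] * (coords[, 3L] - 1L))
}

# all permutations of 1..k (k <= 7 in practice)
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
    }
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
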