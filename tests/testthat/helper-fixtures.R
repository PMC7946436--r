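# Shared fixtures, generated in code at test time.

# tiny planted study: full design + betas + planted-truth parcellations
tiny_study <- function(n_subjects = 4, n_runs = 4, effect_size = 1,
                       noise_sd = 1, subject_sd = 0.5, accuracy = 0.95,
                       shape = c(4, 4, 2), seed = 11) {
  des <- generate_full_design(n_runs, n_subjects, seed = seed,
                              accuracy = accuracy)
  roi <- generate_roi(shape, 0.5, mirrored = TRUE, seed = seed + 1)
  spec <- default_effect_spec(effect_size = effect_size, noise_sd = noise_sd,
                              subject_sd = subject_sd)
  betas <- list(
    left = generate_trial_betas(des, roi$left, roi$labels$left, spec,
                                seed = seed + 2),
    right = generate_trial_betas(des, roi$right, roi$labels$right, spec,
                                 seed = seed + 3)
  )
  parc <- list(
    left = parcellation_from_labels(roi$left, roi$labels$left,
                                    c("anterior", "posterior")),
    right = parcellation_from_labels(roi$right, roi$labels$right,
                                     c("anterior", "posterior"))
  )
  list(design = des, roi = roi, spec = spec, betas = betas, parc = parc)
}

# hand-rolled Pearson correlation (independent of stats::cor)
hand_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# brute-force adjusted Rand index via mclust (independent oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# build a partition_ensemble object directly from a label matrix
manual_ensemble <- function(partitions, k, wss = NULL) {
  structure(list(partitions = partitions,
                 wss = wss %||% rep(1, nrow(partitions)), k = k),
            class = "partition_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
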