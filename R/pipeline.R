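#' Default pipeline configuration
#'
#' Demo-scale study conditions: 10 subjects with 4 runs each, 200 voxels per
#' hemisphere (10 x 5 x 4 grid), 100 cortical parcels and 1000 connectivity
#' permutations, with the analysis defaults of the individual stages
#' (ensemble size 1000, candidate clusters 2..7, unanimity stability
#' threshold, alpha 0.05, effective-connectivity percentile 99.9 with 10000
#' permutations).
#'
#' @return a nested configuration list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    design = list(n_subjects = 10L, n_runs = 4L, accuracy = 0.95),
    roi = list(shape = c(10L, 5L, 4L), anterior_fraction = 0.5,
               mirrored = TRUE, drop_fraction = 0),
    effects = list(effect_size = 1, noise_sd = 1, subject_sd = 0.5,
                   baseline = 0),
    coupling = list(n_parcels = 100L, rho = 0.5, parcels_per_link = 8L),
    modulation = list(subject_sd = 0.5),
    parcellation = list(k_range = 2:7, n_init = 1000L,
                        stability_threshold = 1.0),
    classifier = list(reg_strength = 1),
    connectivity = list(n_perm = 1000L, alpha = 0.05,
                        shuffle_unit = "subject"),
    ecperm = list(n_perm = 10000L, percentile = 99.9,
                  method = "label_permutation")
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Missing fields are filled from [default_config()]; unknown fields and
#' invalid values are rejected with the offending field path.
#'
#' @param config a (possibly partial) configuration list, or `NULL` for the
#'   full defaults
#' @return the normalized configuration
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config()
  config <- config %||% list()
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config field: ", bad[1L], call. = FALSE)
  out <- defaults
  out$seed <- config$seed %||% defaults$seed
  for (sec in setdiff(names(defaults), "seed")) {
    given <- config[[sec]] %||% list()
    if (!is.list(given)) stop(sprintf("config field '%s' must be a list", sec),
                              call. = FALSE)
    bad <- setdiff(names(given), names(defaults[[sec]]))
    if (length(bad)) {
      stop(sprintf("unknown config field: %s.%s", sec, bad[1L]), call. = FALSE)
    }
    out[[sec]] <- utils::modifyList(defaults[[sec]], given)
  }
  fail <- function(path, why) {
    stop(sprintf("invalid config value at %s: %s", path, why), call. = FALSE)
  }
  with(out, {
    if (!is.numeric(seed) || length(seed) != 1L) fail("seed", "must be one number")
    if (design$n_subjects < 1) fail("design.n_subjects", "must be >= 1")
    if (design$n_runs < 1) fail("design.n_runs", "must be >= 1")
    if (design$accuracy < 0 || design$accuracy > 1) {
      fail("design.accuracy", "must lie in [0, 1]")
    }
    if (length(roi$shape) != 3L || any(roi$shape < 1)) {
      fail("roi.shape", "must be three positive integers")
    }
    if (roi$anterior_fraction <= 0 || roi$anterior_fraction >= 1) {
      fail("roi.anterior_fraction", "must lie strictly in (0, 1)")
    }
    if (effects$noise_sd < 0 || effects$subject_sd < 0) {
      fail("effects.noise_sd", "sds must be >= 0")
    }
    if (coupling$n_parcels < 1) fail("coupling.n_parcels", "must be >= 1")
    if (abs(coupling$rho) > 1) fail("coupling.rho", "must lie in [-1, 1]")
    kr <- parcellation$k_range
    if (any(kr < 2) || any(kr != floor(kr)) || is.unsorted(kr)) {
      fail("parcellation.k_range", "must be an ascending integer range >= 2")
    }
    if (parcellation$n_init < 1) fail("parcellation.n_init", "must be >= 1")
    if (parcellation$stability_threshold <= 0 ||
        parcellation$stability_threshold > 1) {
      fail("parcellation.stability_threshold", "must lie in (0, 1]")
    }
    if (classifier$reg_strength <= 0) fail("classifier.reg_strength", "must be > 0")
    if (connectivity$alpha <= 0 || connectivity$alpha >= 1) {
      fail("connectivity.alpha", "must lie strictly in (0, 1)")
    }
    if (connectivity$n_perm < 100) fail("connectivity.n_perm", "must be >= 100")
    if (ecperm$percentile <= 0 || ecperm$percentile >= 100) {
      fail("ecperm.percentile", "must lie strictly in (0, 100)")
    }
    min_n <- ceiling(100 / (100 - ecperm$percentile) - 1e-6)
    if (ecperm$n_perm < min_n) {
      fail("ecperm.n_perm", sprintf("must be >= %d for percentile %.4g",
                                    min_n, ecperm$percentile))
    }
  })
  out$roi$shape <- as.integer(out$roi$shape)
  out$parcellation$k_range <- as.integer(out$parcellation$k_range)
  out
}

#' Simulate a complete synthetic study
#'
#' Generates the full three-task design, left/right ROI masks with planted
#' anterior/posterior labels, trial-wise voxel betas per hemisphere, planted
#' subregion mean series, coupled parcel series and subject-wise modulation
#' matrices, all under one validated configuration.
#'
#' @param config a configuration (see [validate_config()])
#' @param seed overrides the stage seed (defaults to
#'   `stage_seed(config$seed, "simulate")`)
#' @return list with `design`, `roi`, `betas` (left/right), `planted_series`,
#'   `parcel_series`, `coupling`, `modulations`, `effect_spec`
#' @export
simulate_study <- function(config = NULL, seed = NULL) {
  config <- validate_config(config)
  seed <- seed %||% stage_seed(config$seed, "simulate")
  d <- config$design
  design <- generate_full_design(d$n_runs, d$n_subjects, seed = seed,
                                 accuracy = d$accuracy)
  roi <- generate_roi(config$roi$shape, config$roi$anterior_fraction,
                      mirrored = config$roi$mirrored, seed = seed + 1L,
                      drop_fraction = config$roi$drop_fraction)
  spec <- default_effect_spec(effect_size = config$effects$effect_size,
                              noise_sd = config$effects$noise_sd,
                              subject_sd = config$effects$subject_sd,
                              baseline = config$effects$baseline)
  betas <- list(
    left = generate_trial_betas(design, roi$left, roi$labels$left, spec,
                                seed = seed + 2L),
    right = generate_trial_betas(design, roi$right, roi$labels$right, spec,
                                 seed = seed + 3L)
  )
  planted_series <- cbind(
    L_ant = rowMeans(betas$left[, roi$labels$left == 1L, drop = FALSE]),
    L_post = rowMeans(betas$left[, roi$labels$left == 2L, drop = FALSE]),
    R_ant = rowMeans(betas$right[, roi$labels$right == 1L, drop = FALSE]),
    R_post = rowMeans(betas$right[, roi$labels$right == 2L, drop = FALSE])
  )
  coupling <- default_coupling_spec(n_parcels = config$coupling$n_parcels,
                                    rho = config$coupling$rho,
                                    parcels_per_link = config$coupling$parcels_per_link)
  parcel_series <- generate_parcel_betas(design, planted_series, coupling,
                                         seed = seed + 4L)
  truth <- default_modulation_truth(subject_sd = config$modulation$subject_sd)
  modulations <- generate_modulations(truth, n_subjects = max(2L, d$n_subjects),
                                      seed = seed + 5L)
  list(design = design, roi = roi, betas = betas,
       planted_series = planted_series, parcel_series = parcel_series,
       coupling = coupling, modulations = modulations, effect_spec = spec,
       modulation_truth = truth)
}

#' Parcellate one hemisphere end-to-end
#'
#' Features -> per-k ensembles -> validity votes -> majority k -> consensus
#' labels with stability filtering -> anatomical naming.
#'
#' @param betas trials x voxels matrix for one hemisphere
#' @param design aligned trial table
#' @param mask the hemisphere's [roi_mask()]
#' @param k_range candidate cluster numbers
#' @param n_init ensemble size per k
#' @param stability_threshold consensus stability threshold
#' @param seed integer seed
#' @return list with `parcellation` (named), `votes`, `k_star`, `agreement`
#' @export
parcellate_hemisphere <- function(betas, design, mask, k_range = 2:7,
                                  n_init = 1000L, stability_threshold = 1.0,
                                  seed = 1L) {
  features <- build_features(betas, design)
  ensembles <- lapply(seq_along(k_range), function(i) {
    kmeans_ensemble(features, k_range[i], n_init = n_init, seed = seed + i)
  })
  votes <- compute_validity_votes(features, ensembles, k_range)
  sel <- select_k(votes)
  ens <- ensembles[[match(sel$k_star, k_range)]]
  parc <- consensus_labels(ens, stability_threshold = stability_threshold)
  parc <- name_subregions(parc, mask)
  list(parcellation = parc, votes = votes, k_star = sel$k_star,
       agreement = sel$agreement)
}

pipeline_stages <- c("simulate", "parcellate", "classify", "connectivity",
                     "ecperm")

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> parcellate -> classify -> connectivity -> ecperm), writing
#' each stage's outputs under `out_dir` as TSV/JSON/NIfTI plus a run manifest
#' (`manifest.json`: config and its hash, per-stage seeds and wall times,
#' package version, warnings). When an upstream stage is not selected its
#' artifacts are reloaded from `out_dir`; a missing artifact is an error
#' naming the file. Identical config and seed give identical stage outputs.
#'
#' @param config configuration list (see [validate_config()])
#' @param out_dir output directory (created if needed)
#' @param stages character vector of stages, or `"all"`
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config = NULL, out_dir, stages = "all") {
  config <- validate_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  need <- function(f) {
    if (!file.exists(pth(f))) {
      stop(sprintf("missing upstream artifact '%s' in %s", f, out_dir),
           call. = FALSE)
    }
    pth(f)
  }
  manifest <- list(config = config, package = "iplparc",
                   version = as.character(utils::packageVersion("iplparc")),
                   seeds = list(), timing = list(), warnings = list())
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  env <- new.env(parent = emptyenv())
  timer <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    manifest$timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  load_sim <- function() {
    if (!is.null(env$sim)) return(env$sim)
    design <- read_trial_table(need("design.tsv"))
    left <- read_mask_nifti(need("roi_left.nii.gz"), "left")
    right <- read_mask_nifti(need("roi_right.nii.gz"), "right")
    env$sim <- list(
      design = design,
      roi = list(left = left$mask, right = right$mask,
                 labels = list(left = left$labels, right = right$labels)),
      betas = list(left = as.matrix(read_tsv(need("betas_left.tsv"))),
                   right = as.matrix(read_tsv(need("betas_right.tsv")))),
      parcel_series = as.matrix(read_tsv(need("parcel_series.tsv"))),
      coupling = default_coupling_spec(
        n_parcels = config$coupling$n_parcels,
        rho = config$coupling$rho,
        parcels_per_link = config$coupling$parcels_per_link),
      modulations = read_modulation_set(need("modulations.tsv"))
    )
    env$sim
  }
  load_parc <- function() {
    if (!is.null(env$parc)) return(env$parc)
    l <- read_mask_nifti(need("parcellation_left.nii.gz"), "left")
    r <- read_mask_nifti(need("parcellation_right.nii.gz"), "right")
    as_parc <- function(m) {
      parcellation_from_labels(m$mask, m$labels,
                               names = c("anterior", "posterior"))
    }
    env$parc <- list(left = as_parc(l), right = as_parc(r))
    env$parc
  }

  if ("simulate" %in% stages) {
    sd_sim <- stage_seed(config$seed, "simulate")
    manifest$seeds$simulate <- sd_sim
    timer("simulate", {
      sim <- simulate_study(config, seed = sd_sim)
      env$sim <- sim
      write_trial_table(sim$design, pth("design.tsv"))
      write_mask_nifti(sim$roi$left, pth("roi_left.nii.gz"),
                       labels = sim$roi$labels$left)
      write_mask_nifti(sim$roi$right, pth("roi_right.nii.gz"),
                       labels = sim$roi$labels$right)
      write_tsv(as.data.frame(sim$betas$left), pth("betas_left.tsv"))
      write_tsv(as.data.frame(sim$betas$right), pth("betas_right.tsv"))
      write_tsv(as.data.frame(sim$parcel_series), pth("parcel_series.tsv"))
      write_tsv(sim$coupling$networks, pth("parcel_networks.tsv"))
      write_modulation_set(sim$modulations, pth("modulations.tsv"))
    })
  }
  if ("parcellate" %in% stages) {
    sd_parc <- stage_seed(config$seed, "parcellate")
    manifest$seeds$parcellate <- sd_parc
    timer("parcellate", {
      sim <- load_sim()
      pc <- config$parcellation
      res <- list(
        left = parcellate_hemisphere(sim$betas$left, sim$design, sim$roi$left,
                                     k_range = pc$k_range, n_init = pc$n_init,
                                     stability_threshold = pc$stability_threshold,
                                     seed = sd_parc),
        right = parcellate_hemisphere(sim$betas$right, sim$design,
                                      sim$roi$right,
                                      k_range = pc$k_range, n_init = pc$n_init,
                                      stability_threshold = pc$stability_threshold,
                                      seed = sd_parc + 100L)
      )
      env$parc <- list(left = res$left$parcellation,
                       right = res$right$parcellation)
      write_parcellation_nifti(res$left$parcellation,
                               pth("parcellation_left.nii.gz"))
      write_parcellation_nifti(res$right$parcellation,
                               pth("parcellation_right.nii.gz"))
      summ <- rbind(summary(res$left$parcellation),
                    summary(res$right$parcellation))
      write_tsv(summ, pth("parcellation_summary.tsv"))
      votes <- rbind(cbind(hemisphere = "left",
                           as.data.frame(res$left$votes)),
                     cbind(hemisphere = "right",
                           as.data.frame(res$right$votes)))
      write_tsv(votes, pth("votes.tsv"))
      cong <- hemispheric_congruency(res$left$parcellation,
                                     res$right$parcellation)
      jsonlite::write_json(
        list(k_star = list(left = res$left$k_star, right = res$right$k_star),
             agreement = list(left = res$left$agreement,
                              right = res$right$agreement),
             congruency = cong),
        pth("parcellation_report.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  if ("classify" %in% stages) {
    sd_cls <- stage_seed(config$seed, "classify")
    manifest$seeds$classify <- sd_cls
    timer("classify", {
      sim <- load_sim()
      parc <- load_parc()
      feats <- aggregate_subregions(sim$betas, parc, sim$design)
      cv <- loso_crossvalidate(feats, seed = sd_cls,
                               reg_strength = config$classifier$reg_strength)
      jsonlite::write_json(
        list(overall_accuracy = cv$report$overall_accuracy,
             per_task_accuracy = as.list(cv$report$per_task_accuracy),
             chance = cv$report$chance, n_test = cv$report$n_test,
             confusion = cv$report$confusion),
        pth("cv_report.json"), auto_unbox = TRUE, digits = NA)
      sig <- as.data.frame(cv$signature)
      sig <- cbind(task = rownames(sig), sig)
      write_tsv(sig, pth("signature.tsv"))
    })
  }
  if ("connectivity" %in% stages) {
    sd_con <- stage_seed(config$seed, "connectivity")
    manifest$seeds$connectivity <- sd_con
    timer("connectivity", {
      sim <- load_sim()
      parc <- load_parc()
      series <- subregion_series(sim$betas, parc)
      tensor <- taskwise_correlation(series, sim$parcel_series, sim$design)
      null <- permutation_baseline(series, sim$parcel_series, sim$design,
                                   n_perm = config$connectivity$n_perm,
                                   seed = sd_con,
                                   shuffle_unit = config$connectivity$shuffle_unit)
      tensor <- significant_shifts(tensor, null,
                                   alpha = config$connectivity$alpha)
      write_connectivity_tsv(tensor, pth("connectivity.tsv"))
      nets <- network_aggregate(tensor, sim$coupling$networks)
      long <- expand.grid(subregion = .SUBREGIONS, network = .NETWORKS,
                          task = .TASKS, stringsAsFactors = FALSE)
      long$mean_z_all <- as.vector(nets$all)
      long$mean_z_significant <- as.vector(nets$significant)
      write_tsv(long, pth("network_summary.tsv"))
    })
  }
  if ("ecperm" %in% stages) {
    sd_ec <- stage_seed(config$seed, "ecperm")
    manifest$seeds$ecperm <- sd_ec
    timer("ecperm", {
      sim <- load_sim()
      res <- ec_permutation_test(sim$modulations,
                                 n_perm = config$ecperm$n_perm,
                                 percentile = config$ecperm$percentile,
                                 seed = sd_ec,
                                 method = config$ecperm$method)
      write_ec_result(res, pth("ec_results.tsv"))
      write_ec_result(res, pth("ec_significant.tsv"), significant_only = TRUE)
    })
  }
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}

#' Subregion mean series over all trials
#'
#' Row means of the stable voxels of each named subregion, for every trial
#' (no condition filtering; downstream correlation stages filter themselves).
#'
#' @param betas list with `left`/`right` trial x voxel matrices
#' @param parc list with `left`/`right` named parcellations
#' @return trials x 4 matrix, columns ordered as `ipl_subregions()`
#' @export
subregion_series <- function(betas, parc) {
  cols <- list()
  for (h in c("left", "right")) {
    p <- parc[[h]]
    b <- as.matrix(betas[[h]])
    for (nm in c("anterior", "posterior")) {
      code <- which(p$names == nm)
      vox <- which(p$stable & p$label == code)
      if (!length(vox)) stop(sprintf("empty subregion: %s %s", h, nm),
                             call. = FALSE)
      cols[[paste0(if (h == "left") "L_" else "R_",
                   if (nm == "anterior") "ant" else "post")]] <-
        rowMeans(b[, vox, drop = FALSE])
    }
  }
  do.call(cbind, cols)[, .FEATURE_COLS]
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a configuration list
#' @param path file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
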