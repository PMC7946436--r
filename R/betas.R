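#' Effect specification for synthetic trial-wise activity
#'
#' Encodes the planted activity model for voxel-level beta generation:
#' a baseline level, a per-(task, condition, hemisphere, subregion) mean
#' activity shift, an i.i.d. Gaussian voxel/trial noise sd, and a Gaussian
#' between-subject offset sd.
#'
#' @param effects data.frame with columns `task`, `condition`, `hemisphere`,
#'   `subregion` (1 = anterior, 2 = posterior) and `effect` (beta units)
#' @param noise_sd trial/voxel noise sd (>= 0)
#' @param subject_sd between-subject offset sd (>= 0)
#' @param baseline baseline activity level
#' @return an object of class `effect_spec`
#' @export
effect_spec <- function(effects, noise_sd = 1, subject_sd = 0.5, baseline = 0) {
  need <- c("task", "condition", "hemisphere", "subregion", "effect")
  if (!all(need %in% names(effects))) {
    stop("`effects` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (noise_sd < 0 || subject_sd < 0) stop("sds must be >= 0", call. = FALSE)
  structure(list(effects = effects, noise_sd = noise_sd,
                 subject_sd = subject_sd, baseline = baseline),
            class = "effect_spec")
}

#' Default planted specialization pattern
#'
#' The qualitative task-specialization pattern used throughout the synthetic
#' study conditions: the attention target condition (invalid) raises activity
#' in the right anterior subregion, the semantics target (word) in the left
#' anterior subregion, and the social target (false belief) in both posterior
#' subregions. All control/catch conditions and all other cells are zero.
#'
#' @param effect_size planted mean shift in beta units
#' @inheritParams effect_spec
#' @return an `effect_spec` covering every (task, condition, hemisphere,
#'   subregion) combination
#' @export
default_effect_spec <- function(effect_size = 1, noise_sd = 1, subject_sd = 0.5,
                                baseline = 0) {
  grid <- do.call(rbind, lapply(.TASKS, function(tk) {
    expand.grid(task = tk, condition = .CONDITIONS[[tk]],
                hemisphere = c("left", "right"), subregion = 1:2,
                stringsAsFactors = FALSE)
  }))
  grid$effect <- 0
  planted <- list(
    c("attention", "invalid", "right", 1),
    c("semantics", "word", "left", 1),
    c("social", "false_belief", "left", 2),
    c("social", "false_belief", "right", 2)
  )
  for (p in planted) {
    hit <- grid$task == p[1] & grid$condition == p[2] &
      grid$hemisphere == p[3] & grid$subregion == as.integer(p[4])
    grid$effect[hit] <- effect_size
  }
  effect_spec(grid, noise_sd = noise_sd, subject_sd = subject_sd,
              baseline = baseline)
}

#' Generate trial-wise voxel activity for one hemisphere
#'
#' Emulates single-trial beta estimates over an ROI: each value is
#' `baseline + subject offset + planted effect + Gaussian noise`, where the
#' planted effect depends on the trial's (task, condition), the mask's
#' hemisphere and the voxel's planted subregion label.
#'
#' @param design trial table ([generate_design()] or [generate_full_design()])
#' @param roi an [roi_mask()] for one hemisphere
#' @param labels integer planted subregion labels aligned with `roi` voxels
#' @param spec an [effect_spec()] covering all (task, condition) pairs present
#' @param seed integer seed
#' @return a trials x voxels numeric matrix with the trial table rows attached
#'   as attribute `"design"` and the mask as `"mask"`
#' @export
generate_trial_betas <- function(design, roi, labels, spec, seed) {
  stopifnot(inherits(roi, "roi_mask"), inherits(spec, "effect_spec"))
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(roi$coords))
  eff <- spec$effects[spec$effects$hemisphere == roi$hemisphere, , drop = FALSE]

  pairs <- unique(design[, c("task", "condition")])
  for (i in seq_len(nrow(pairs))) {
    hit <- eff$task == pairs$task[i] & eff$condition == pairs$condition[i]
    if (sum(hit) == 0L) {
      stop(sprintf("effect spec has no entry for (%s, %s) in hemisphere %s",
                   pairs$task[i], pairs$condition[i], roi$hemisphere),
           call. = FALSE)
    }
  }
  set.seed(seed)
  n <- nrow(design)
  v <- nrow(roi$coords)
  subjects <- sort(unique(design$subject))
  offsets <- stats::rnorm(length(subjects), 0, spec$subject_sd)
  names(offsets) <- subjects

  # per-trial, per-subregion effect lookup
  eff_key <- paste(eff$task, eff$condition, eff$subregion, sep = "\r")
  eff_map <- stats::setNames(eff$effect, eff_key)
  shift <- matrix(0, n, v)
  for (lab in sort(unique(labels))) {
    key <- paste(design$task, design$condition, lab, sep = "\r")
    e <- eff_map[key]
    e[is.na(e)] <- 0
    shift[, labels == lab] <- e
  }
  out <- spec$baseline + offsets[design$subject] + shift +
    matrix(stats::rnorm(n * v, 0, spec$noise_sd), n, v)
  dimnames(out) <- NULL
  attr(out, "design") <- design
  attr(out, "mask") <- roi
  out
}

#' Coupling specification for synthetic parcel activity
#'
#' Describes which cortical parcels are coupled to which IPL subregion during
#' which task, with what target Pearson correlation, plus the parcel-to-network
#' lookup used for seven-network aggregation.
#'
#' @param entries data.frame with columns `task`, `subregion` (name among
#'   `ipl_subregions()`), `parcel` (integer index) and `rho` in \[-1, 1\];
#'   may have zero rows for a fully null configuration
#' @param n_parcels total number of parcels (default 400)
#' @param networks optional data.frame (`parcel`, `network`) mapping every
#'   parcel to one of the seven networks; default cycles through the networks
#' @return an object of class `coupling_spec`
#' @export
coupling_spec <- function(entries = NULL, n_parcels = 400L, networks = NULL) {
  n_parcels <- assert_count(n_parcels, "n_parcels")
  if (is.null(entries)) {
    entries <- data.frame(task = character(), subregion = character(),
                          parcel = integer(), rho = numeric())
  }
  need <- c("task", "subregion", "parcel", "rho")
  stopifnot(all(need %in% names(entries)))
  if (nrow(entries)) {
    if (any(abs(entries$rho) > 1)) stop("|rho| must be <= 1", call. = FALSE)
    if (any(entries$parcel < 1L | entries$parcel > n_parcels)) {
      stop("parcel index out of range 1..", n_parcels, call. = FALSE)
    }
    stopifnot(all(entries$task %in% .TASKS), all(entries$subregion %in% .SUBREGIONS))
  }
  if (is.null(networks)) {
    networks <- data.frame(parcel = seq_len(n_parcels),
                           network = rep_len(.NETWORKS, n_parcels))
  }
  stopifnot(all(seq_len(n_parcels) %in% networks$parcel))
  structure(list(entries = entries, n_parcels = n_parcels, networks = networks),
            class = "coupling_spec")
}

#' Default task-specific coupling configuration
#'
#' Plants moderate task-dependent coupling echoing the qualitative pattern of
#' the study: during attention the right anterior subregion couples with
#' visual/dorsal-attention parcels, during semantics the left anterior
#' subregion with dorsal-attention/default-mode parcels, and during social
#' cognition both posterior subregions with default-mode parcels.
#'
#' @param n_parcels total parcel count
#' @param rho planted Pearson correlation
#' @param parcels_per_link number of parcels coupled per (task, subregion)
#' @return a [coupling_spec()]
#' @export
default_coupling_spec <- function(n_parcels = 400L, rho = 0.5,
                                  parcels_per_link = 8L) {
  base <- coupling_spec(NULL, n_parcels = n_parcels)
  nets <- base$networks
  used <- integer(0)
  pick <- function(nm, n) {
    ids <- setdiff(nets$parcel[nets$network %in% nm], used)
    if (length(ids) < n) { # small atlases: spill into any unused network
      ids <- c(ids, setdiff(nets$parcel, c(used, ids)))
    }
    ids <- ids[seq_len(min(n, length(ids)))]
    if (!length(ids)) stop("too few parcels for the default coupling pattern",
                           call. = FALSE)
    used <<- c(used, ids)
    ids
  }
  entries <- rbind(
    data.frame(task = "attention", subregion = "R-ant",
               parcel = pick(c("VIS", "DAN"), parcels_per_link), rho = rho),
    data.frame(task = "semantics", subregion = "L-ant",
               parcel = pick(c("DAN", "DMN"), parcels_per_link), rho = rho),
    data.frame(task = "social", subregion = "L-post",
               parcel = pick("DMN", parcels_per_link), rho = rho),
    data.frame(task = "social", subregion = "R-post",
               parcel = pick("DMN", parcels_per_link), rho = rho)
  )
  coupling_spec(entries, n_parcels = n_parcels, networks = base$networks)
}

#' Generate trial-wise parcel activity coupled to subregion series
#'
#' Every parcel starts as unit Gaussian noise across trials. For each planted
#' coupling entry, on the trials of the specified task the parcel value is
#' replaced by `rho * standardized subregion value + sqrt(1 - rho^2) * noise`,
#' so the population correlation with the subregion series on those trials is
#' `rho`; other trials and unplanted parcels remain pure noise.
#'
#' @param design trial table aligned with `subregion_series` rows
#' @param subregion_series trials x 4 matrix of subregion activities (columns
#'   ordered as `ipl_subregions()`)
#' @param spec a [coupling_spec()]
#' @param seed integer seed
#' @return trials x parcels numeric matrix
#' @export
generate_parcel_betas <- function(design, subregion_series, spec, seed) {
  stopifnot(inherits(spec, "coupling_spec"))
  subregion_series <- as.matrix(subregion_series)
  stopifnot(nrow(subregion_series) == nrow(design),
            ncol(subregion_series) == 4L)
  set.seed(seed)
  n <- nrow(design)
  out <- matrix(stats::rnorm(n * spec$n_parcels), n, spec$n_parcels)
  e <- spec$entries
  for (i in seq_len(nrow(e))) {
    rows <- which(design$task == e$task[i])
    if (!length(rows)) next
    s <- subregion_series[rows, match(e$subregion[i], .SUBREGIONS)]
    sdev <- stats::sd(s)
    z <- if (sdev > 0) (s - mean(s)) / sdev else rep(0, length(s))
    out[rows, e$parcel[i]] <- e$rho[i] * z +
      sqrt(1 - e$rho[i]^2) * stats::rnorm(length(rows))
  }
  out
}
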