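planted_parcellation <- function(hemisphere = "left", shape = c(4, 6, 2),
                                 frac = 0.5, drop = 0, seed = 51,
                                 mirrored = TRUE) {
  roi <- generate_roi(shape, frac, mirrored = mirrored, seed = seed,
                      drop_fraction = drop)
  list(roi = roi,
       left = parcellation_from_labels(roi$left, roi$labels$left,
                                       c("anterior", "posterior")),
       right = parcellation_from_labels(roi$right, roi$labels$right,
                                        c("anterior", "posterior")))
}

test_that("subregion names follow the anterior-posterior center of mass", {
  roi <- generate_roi(c(4, 6, 2), 0.5, seed = 1)
  # unnamed consensus-style parcellation with swapped codes: code 2 anterior
  lab <- ifelse(roi$labels$left == 1L, 2L, 1L)
  parc <- structure(list(label = lab, stable = rep(TRUE, length(lab)),
                         agreement = rep(1, length(lab)), k = 2L),
                    class = "parcellation")
  named <- name_subregions(parc, roi$left)
  expect_equal(named$names, c("posterior", "anterior"))
  # the anterior cluster's mm center is anterior to (greater y than) the other
  expect_gt(named$centers_mm["anterior", 2], named$centers_mm["posterior", 2])
  # names match planted truth through the summary table
  s <- summary(named)
  expect_setequal(s$subregion, c("anterior", "posterior"))
  expect_equal(sum(s$n_voxels), length(lab))
})

test_that("equal anterior-posterior centers are rejected as degenerate", {
  mask <- roi_mask(as.matrix(expand.grid(1:4, 1:2, 1)), c(4, 2, 1), "left")
  # clusters split along x: identical y centers
  lab <- ifelse(mask$coords[, 1] <= 2, 1L, 2L)
  parc <- structure(list(label = lab, stable = rep(TRUE, 8),
                         agreement = rep(1, 8), k = 2L),
                    class = "parcellation")
  expect_error(name_subregions(parc, mask), "degenerate")
})

test_that("mirrored planted parcellations are fully congruent", {
  p <- planted_parcellation(drop = 0.2)
  cong <- hemispheric_congruency(p$left, p$right)
  expect_equal(unname(cong$overlap_pct["left"]), 100)
  expect_equal(unname(cong$overlap_pct["right"]), 100)
  expect_equal(cong$concordance_pct, 100)
  expect_true(all(cong$per_subregion_pct == 100))
})

test_that("independently generated hemispheres overlap partially", {
  p <- planted_parcellation(drop = 0.3, mirrored = FALSE)
  cong <- hemispheric_congruency(p$left, p$right)
  expect_lt(cong$overlap_pct["left"], 100)
  expect_gt(cong$overlap_pct["left"], 0)
  # labels depend only on the anterior-posterior plane: shared voxels agree
  expect_equal(cong$concordance_pct, 100)
})

test_that("congruency on a constructed 20-voxel fixture gives 75% overlap, 80% concordance", {
  shape <- c(2, 10, 1)
  # left mask: all 20 voxels; labels: anterior = y > 5
  grid <- as.matrix(expand.grid(1:2, 1:10, 1))
  left <- parcellation_from_labels(roi_mask(grid, shape, "left"),
                                   ifelse(grid[, 2] > 5, 1L, 2L),
                                   c("anterior", "posterior"))
  # right mask: 15 of the 20 mirrored positions (drop 5), 3 labels flipped
  keep <- setdiff(seq_len(20), c(1, 4, 9, 16, 20))
  rg <- grid[keep, , drop = FALSE]
  rg[, 1] <- shape[1] + 1L - rg[, 1] # so the flip maps back onto the left grid
  lab_r <- ifelse(rg[, 2] > 5, 1L, 2L)
  lab_r[c(2, 7, 11)] <- 3L - lab_r[c(2, 7, 11)] # three discordant voxels
  ord <- order((rg[, 1] - 1) + shape[1] * ((rg[, 2] - 1)))
  right <- parcellation_from_labels(roi_mask(rg[ord, ], shape, "right"),
                                    lab_r[ord], c("anterior", "posterior"))
  cong <- hemispheric_congruency(left, right)
  expect_equal(unname(cong$overlap_pct["left"]), 75)
  expect_equal(unname(cong$overlap_pct["right"]), 100)
  expect_equal(cong$concordance_pct, 80)
})

test_that("disjoint masks give zero overlap and undefined concordance", {
  shape <- c(4, 2, 1)
  g1 <- as.matrix(expand.grid(1:2, 1:2, 1))
  g2 <- as.matrix(expand.grid(1:2, 1:2, 1)) # flips onto x in 3:4
  left <- parcellation_from_labels(roi_mask(g1, shape, "left"),
                                   rep(1:2, each = 2),
                                   c("anterior", "posterior"))
  right <- parcellation_from_labels(roi_mask(g2, shape, "right"),
                                    rep(1:2, each = 2),
                                    c("anterior", "posterior"))
  cong <- hemispheric_congruency(left, right)
  expect_equal(unname(cong$overlap_pct["left"]), 0)
  expect_true(is.na(cong$concordance_pct))
})

test_that("shape mismatches are rejected", {
  p1 <- planted_parcellation(shape = c(4, 6, 2))
  p2 <- planted_parcellation(shape = c(4, 6, 3))
  expect_error(hemispheric_congruency(p1$left, p2$right), "shapes differ")
})

test_that("named parcellations round-trip through NIfTI label volumes", {
  p <- planted_parcellation(drop = 0.15)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_parcellation_nifti(p$left, path)
  back <- read_mask_nifti(path, "left")
  expect_equal(back$mask$coords, p$left$mask$coords)
  # anterior voxels coded 1, posterior 2
  expect_equal(back$labels, p$roi$labels$left)
})

test_that("end-to-end parcellation recovers the planted two-subregion split", {
  st <- tiny_study(n_subjects = 4, n_runs = 4, effect_size = 1.2,
                   noise_sd = 1, shape = c(6, 6, 3), seed = 52)
  ph <- parcellate_hemisphere(st$betas$right, st$design, st$roi$right,
                              k_range = 2:5, n_init = 25, seed = 53)
  expect_equal(ph$k_star, 2L)
  stable <- ph$parcellation$stable
  # consensus labels match planted truth (codes aligned via names)
  planted_names <- ifelse(st$roi$labels$right == 1, "anterior", "posterior")
  got_names <- ph$parcellation$names[ph$parcellation$label[stable]]
  expect_gte(ari(got_names, planted_names[stable]), 0.9)
  expect_gte(mean(stable), 0.8)
})
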