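make_series <- function(n_subjects = 2, n_runs = 2, n_parcels = 20, seed = 41,
                        accuracy = 1) {
  des <- generate_full_design(n_runs, n_subjects, seed = seed,
                              accuracy = accuracy)
  n <- nrow(des)
  set.seed(seed + 1)
  list(design = des,
       sub = matrix(rnorm(n * 4), n, 4),
       par = matrix(rnorm(n * n_parcels), n, n_parcels))
}

test_that("identical and negated series give clipped unit correlations", {
  s <- make_series()
  s$par[, 1] <- s$sub[, 2]
  s$par[, 2] <- -s$sub[, 2]
  tensor <- taskwise_correlation(s$sub, s$par, s$design)
  for (tk in ipl_tasks()) {
    expect_equal(tensor$r["L-post", 1, tk], 1, tolerance = 1e-12)
    expect_equal(tensor$r["L-post", 2, tk], -1, tolerance = 1e-12)
    expect_equal(tensor$z["L-post", 1, tk], atanh(1 - 1e-7))
  }
})

test_that("correlations equal a hand-computed Pearson value on printed vectors", {
  x <- c(0.2, -1.1, 0.5, 2.0, -0.3, 0.9)
  y <- c(1.0, -0.4, 0.1, 1.5, 0.2, 0.6)
  des <- data.frame(trial_id = 1:18, subject = "s1", session = 1, run = 1,
                    task = rep(ipl_tasks(), each = 6),
                    condition = rep(c("invalid", "word", "false_belief"),
                                    each = 6),
                    correct = TRUE, onset = 1:18)
  sub <- matrix(rep(x, 3 * 4), 18, 4)
  par <- matrix(rep(y, 3), 18, 1)
  tensor <- taskwise_correlation(sub, par, des, min_trials = 5)
  # independent oracle: centered cross-product formula
  for (tk in ipl_tasks()) {
    expect_equal(tensor$r["L-ant", 1, tk], hand_pearson(x, y),
                 tolerance = 1e-12)
  }
})

test_that("constant series yield missing cells, short tasks are rejected", {
  s <- make_series()
  s$par[, 3] <- 5
  tensor <- taskwise_correlation(s$sub, s$par, s$design)
  expect_true(all(is.na(tensor$r[, 3, ])))
  des1 <- s$design[s$design$task == "attention", ]
  expect_error(
    taskwise_correlation(s$sub[s$design$task == "attention", ],
                         s$par[s$design$task == "attention", ], des1),
    "correct target trials"
  )
})

test_that("the permutation null is centered and rejects single-task input", {
  s <- make_series(seed = 43)
  null <- permutation_baseline(s$sub, s$par, s$design, n_perm = 150, seed = 2)
  # statistic sums to zero over tasks by construction; mean near zero
  expect_lt(abs(mean(null$stat)), 0.01)
  sums <- apply(null$stat, c(1, 2, 4), sum)
  expect_lt(max(abs(sums)), 1e-10)
  des_a <- s$design[s$design$task == "attention", ]
  expect_error(
    permutation_baseline(s$sub[s$design$task == "attention", ],
                         s$par[s$design$task == "attention", ], des_a,
                         n_perm = 150, seed = 2),
    "two tasks"
  )
})

test_that("empirical p-values follow the add-one formula and flag rule", {
  s <- make_series(seed = 44, n_parcels = 2)
  tensor <- taskwise_correlation(s$sub, s$par, s$design)
  obs <- iplparc:::connectivity_statistic(tensor$z)
  # craft a null where every draw exceeds cell (1,1,1): p = (1+n)/(1+n)
  n_perm <- 4999
  stat <- array(0, dim = c(4, 2, 3, n_perm))
  stat[1, 1, 1, ] <- abs(obs[1, 1, 1]) + 1
  null <- structure(list(stat = stat, n_perm = n_perm,
                         shuffle_unit = "subject"),
                    class = "connectivity_null")
  res <- significant_shifts(tensor, null, alpha = 0.05)
  expect_equal(res$p[1, 1, 1], 1)
  expect_false(res$flag[1, 1, 1])
  # every other cell: obs exceeds all null draws -> p = 1/5000
  expect_equal(res$p[2, 1, 1], 1 / 5000)
  expect_true(res$flag[2, 1, 1])
})

test_that("a planted task-specific coupling is detected with high power", {
  hits <- vapply(1:10, function(sd0) {
    des <- generate_design("semantics", n_runs = 9, n_subjects = 1,
                           seed = sd0, accuracy = 1) # 360 trials
    des <- rbind(des,
                 generate_design("attention", n_runs = 3, n_subjects = 1,
                                 seed = sd0 + 50, accuracy = 1),
                 generate_design("social", n_runs = 12, n_subjects = 1,
                                 seed = sd0 + 100, accuracy = 1))
    des$trial_id <- seq_len(nrow(des))
    n <- nrow(des)
    set.seed(sd0 + 200)
    sub <- matrix(rnorm(n * 4), n, 4)
    cs <- coupling_spec(data.frame(task = "semantics", subregion = "L-ant",
                                   parcel = 1L, rho = 0.6), n_parcels = 5L)
    par <- generate_parcel_betas(des, sub, cs, seed = sd0 + 300)
    tensor <- taskwise_correlation(sub, par, des)
    null <- permutation_baseline(sub, par, des, n_perm = 199,
                                 seed = sd0 + 400)
    res <- significant_shifts(tensor, null, alpha = 0.05)
    isTRUE(res$flag["L-ant", 1, "semantics"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("network aggregation equals a brute-force group-by recomputation", {
  s <- make_series(seed = 45, n_parcels = 21)
  tensor <- taskwise_correlation(s$sub, s$par, s$design)
  lookup <- data.frame(parcel = 1:21,
                       network = rep(ipl_networks(), each = 3))
  nets <- network_aggregate(tensor, lookup)
  for (nw in ipl_networks()) {
    cols <- lookup$parcel[lookup$network == nw]
    for (tk in ipl_tasks()) {
      for (sr in ipl_subregions()) {
        expect_equal(nets$all[sr, nw, tk], mean(tensor$z[sr, cols, tk]),
                     tolerance = 1e-12)
      }
    }
  }
  # constant z propagates; single-network elevation isolates
  t2 <- tensor
  t2$z[] <- 0.7
  expect_true(all(abs(network_aggregate(t2, lookup)$all - 0.7) < 1e-12))
  t3 <- tensor
  t3$z[] <- 0
  t3$z[, lookup$parcel[lookup$network == "DMN"], ] <- 1
  n3 <- network_aggregate(t3, lookup)$all
  expect_true(all(n3[, "DMN", ] == 1))
  expect_true(all(n3[, setdiff(ipl_networks(), "DMN"), ] == 0))
  # unmapped parcel rejected
  expect_error(network_aggregate(tensor, lookup[-1, ]), "unmapped")
})

test_that("flags are invariant to parcel reordering", {
  s <- make_series(seed = 46, n_parcels = 10)
  tensor <- taskwise_correlation(s$sub, s$par, s$design)
  null <- permutation_baseline(s$sub, s$par, s$design, n_perm = 120, seed = 3)
  res <- significant_shifts(tensor, null, alpha = 0.2)
  perm <- c(4, 1, 10, 3, 2, 9, 5, 8, 7, 6)
  tensor_p <- taskwise_correlation(s$sub, s$par[, perm], s$design)
  null_p <- permutation_baseline(s$sub, s$par[, perm], s$design,
                                 n_perm = 120, seed = 3)
  res_p <- significant_shifts(tensor_p, null_p, alpha = 0.2)
  expect_equal(res_p$flag[, , ], res$flag[, perm, ])
  # Fisher z is monotone in r
  rs <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(diff(atanh(rs)) > 0))
})
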