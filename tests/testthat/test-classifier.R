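test_that("subregion aggregation averages stable voxels and filters trials", {
  st <- tiny_study(n_subjects = 2, n_runs = 4, noise_sd = 0, subject_sd = 0,
                   accuracy = 1)
  # constant value in L-ant voxels: column constant
  bl <- st$betas$left
  bl[, st$roi$labels$left == 1] <- 2.0
  ft <- aggregate_subregions(list(left = bl, right = st$betas$right),
                             st$parc, st$design)
  expect_true(all(ft$L_ant == 2.0))
  expect_true(all(ft$condition %in% c("invalid", "word", "false_belief")))

  # a 3-voxel subregion with values 1, 2, 6 on one trial averages to 3
  grid <- as.matrix(expand.grid(1:3, 1:2, 1))
  mask <- roi_mask(grid, c(3, 2, 1), "left")
  labels <- ifelse(grid[, 2] == 2, 1L, 2L) # y = 2 is anterior
  parc1 <- list(
    left = parcellation_from_labels(mask, labels, c("anterior", "posterior")),
    right = parcellation_from_labels(roi_mask(grid, c(3, 2, 1), "right"),
                                     labels, c("anterior", "posterior"))
  )
  des1 <- data.frame(trial_id = 1L, subject = "s1", session = 1L, run = 1L,
                     task = "social", condition = "false_belief",
                     correct = TRUE, onset = 0)
  b_left <- matrix(0, 1, 6)
  b_left[1, labels == 1] <- c(1, 2, 6)
  ft1 <- aggregate_subregions(list(left = b_left, right = matrix(0, 1, 6)),
                              parc1, des1)
  expect_equal(ft1$L_ant, 3)

  # one incorrect trial: exactly one fewer row
  des2 <- st$design
  tgt <- which(des2$condition == "invalid" & des2$correct)
  des2$correct[tgt[1]] <- FALSE
  ft2 <- aggregate_subregions(st$betas, st$parc, des2)
  expect_equal(nrow(ft2), nrow(ft) - 1)
})

test_that("balancing subsamples every task to the per-run minimum", {
  st <- tiny_study(n_subjects = 2, n_runs = 2, accuracy = 1, seed = 21)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  b <- balance_trials(ft, seed = 5)
  # design counts per run: invalid 8, word 20, false_belief 3 -> min 3
  cnt <- table(b$subject, b$run, b$task)
  expect_true(all(cnt == 3))
  # brute-force recomputation of retained counts per (subject, run)
  for (s in unique(ft$subject)) {
    for (r in unique(ft$run)) {
      m <- min(table(ft$task[ft$subject == s & ft$run == r]))
      got <- table(b$task[b$subject == s & b$run == r])
      expect_true(all(got == m))
      # retained ids are a subset of the available ids
      expect_true(all(b$trial_id[b$subject == s & b$run == r] %in%
                        ft$trial_id[ft$subject == s & ft$run == r]))
    }
  }
  # already balanced input is returned unchanged up to order
  b2 <- balance_trials(b, seed = 9)
  expect_setequal(b2$trial_id, b$trial_id)
  # a missing task is rejected naming the cell
  ft3 <- ft[!(ft$subject == "sub01" & ft$run == 1 & ft$task == "social"), ]
  expect_error(balance_trials(ft3, seed = 1), "sub01 run 1.*social")
})

test_that("balancing of one subject does not depend on other subjects present", {
  st <- tiny_study(n_subjects = 3, n_runs = 2, seed = 22)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  all_b <- balance_trials(ft, seed = 7)
  solo <- balance_trials(ft[ft$subject == "sub02", ], seed = 7)
  expect_identical(sort(solo$trial_id),
                   sort(all_b$trial_id[all_b$subject == "sub02"]))
})

test_that("deconfounding projects out training-fitted numeric confounds", {
  st <- tiny_study(n_subjects = 3, n_runs = 8, noise_sd = 0, subject_sd = 0,
                   accuracy = 1, seed = 23)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  # make features exactly linear in session number
  cf <- confound_table(ft)
  for (cn in c("L_ant", "L_post", "R_ant", "R_post")) {
    ft[[cn]] <- 2 * cf$session + 1
  }
  dc <- suppressMessages(deconfound(ft, center_subject = FALSE))
  expect_lt(max(abs(dc$train$L_ant)), 1e-10)
})

test_that("deconfound residuals equal hand-computed least squares on a toy table", {
  toy <- data.frame(
    trial_id = 1:6, subject = "s1", session = c(1, 1, 1, 1, 2, 2),
    run = c(1, 1, 2, 2, 5, 5), task = rep(c("attention", "semantics",
                                            "social"), 2),
    condition = "x",
    L_ant = c(0.3, 1.2, -0.5, 2.0, 0.7, -1.1),
    L_post = c(1.0, 0.2, 0.4, -0.3, 0.8, 0.1),
    R_ant = c(-0.2, 0.5, 1.5, 0.3, -0.6, 0.9),
    R_post = c(0.0, 0.7, -0.9, 1.1, 0.4, -0.2)
  )
  cf <- confound_table(toy)
  X <- cbind(1, cf$session, cf$session_time, cf$run_time)
  dc <- deconfound(toy, center_subject = FALSE)
  for (cn in c("L_ant", "L_post", "R_ant", "R_post")) {
    beta <- solve(t(X) %*% X, t(X) %*% toy[[cn]]) # normal equations oracle
    resid <- toy[[cn]] - as.vector(X %*% beta)
    expect_equal(dc$train[[cn]], resid, tolerance = 1e-10)
  }
})

test_that("zero-variance confounds are dropped with a message", {
  st <- tiny_study(n_subjects = 3, n_runs = 2, seed = 24) # single session
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  expect_message(dc <- deconfound(ft), "session")
  expect_equal(attr(dc, "dropped"), "session")
})

test_that("run-wise standardization uses the population-variance convention", {
  tb <- data.frame(trial_id = 1:2, subject = "s1", session = 1, run = 1,
                   task = c("attention", "semantics"), condition = "x",
                   L_ant = c(1, 3), L_post = c(0, 2), R_ant = c(-1, 1),
                   R_post = c(4, 8))
  out <- standardize_runwise(tb)
  expect_equal(out$L_ant, c(-1, 1))
  expect_equal(out$R_post, c(-1, 1))
  # idempotence
  out2 <- standardize_runwise(out)
  expect_equal(out2$L_ant, out$L_ant, tolerance = 1e-12)
  # 5-row run matches an independent recomputation
  tb5 <- data.frame(trial_id = 1:5, subject = "s1", session = 1, run = 1,
                    task = "attention", condition = "x",
                    L_ant = c(2, 4, 4, 7, 8), L_post = rnorm(5),
                    R_ant = rnorm(5), R_post = rnorm(5))
  o5 <- standardize_runwise(tb5)
  x <- tb5$L_ant
  expect_equal(o5$L_ant, (x - mean(x)) / sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-12)
  # zero-variance column within a run is set to zero, with a message
  tb0 <- tb; tb0$L_post <- c(5, 5)
  expect_message(o0 <- standardize_runwise(tb0), "zero-variance")
  expect_equal(o0$L_post, c(0, 0))
})

test_that("decoding is nearly perfect when planted effects dominate noise", {
  st <- tiny_study(n_subjects = 10, n_runs = 4, effect_size = 1,
                   noise_sd = 0.2, seed = 25)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  cv <- suppressMessages(loso_crossvalidate(ft, seed = 26))
  expect_gte(cv$report$overall_accuracy, 95)
  expect_equal(sum(cv$report$confusion), cv$report$n_test)
})

test_that("the fold-averaged signature recovers the planted sign pattern", {
  hits <- vapply(1:10, function(sd0) {
    st <- tiny_study(n_subjects = 5, n_runs = 4, effect_size = 1,
                     noise_sd = 0.5, seed = 100 + sd0)
    ft <- aggregate_subregions(st$betas, st$parc, st$design)
    cv <- suppressMessages(loso_crossvalidate(ft, seed = sd0))
    sig <- cv$signature
    sig["attention", "R_ant"] > 0 && sig["semantics", "L_ant"] > 0 &&
      sig["social", "L_post"] > 0 && sig["social", "R_post"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fold weights are reproducible without the held-out subject (no leakage)", {
  st <- tiny_study(n_subjects = 4, n_runs = 2, seed = 27)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  cv <- suppressMessages(loso_crossvalidate(ft, seed = 28))
  # refit fold for sub03 using only the training subjects' rows
  train <- ft[ft$subject != "sub03", ]
  train <- balance_trials(train, 28)
  dc <- suppressMessages(deconfound(train))
  train <- standardize_runwise(dc$train)
  w <- iplparc:::fit_ovr_logistic(train, reg_strength = 1)
  expect_identical(w, cv$fold_weights[["sub03"]])
})

test_that("task-label permutation drives accuracy to chance", {
  st <- tiny_study(n_subjects = 5, n_runs = 2, effect_size = 1,
                   noise_sd = 0.3, seed = 29)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  set.seed(30)
  accs <- vapply(1:10, function(i) {
    p <- ft
    # permute task labels within (subject, run) so the design stays balanced
    for (s in unique(p$subject)) for (r in unique(p$run)) {
      rows <- which(p$subject == s & p$run == r)
      p$task[rows] <- sample(p$task[rows])
    }
    suppressMessages(loso_crossvalidate(p, seed = i))$report$overall_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 3), 8)
})

test_that("fewer than three subjects is rejected", {
  st <- tiny_study(n_subjects = 2, n_runs = 2, seed = 31)
  ft <- aggregate_subregions(st$betas, st$parc, st$design)
  expect_error(loso_crossvalidate(ft, seed = 1), ">= 3 subjects")
})
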