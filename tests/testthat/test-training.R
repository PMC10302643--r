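test_that("splitDataset partitions with the documented rounding", {
  w <- tinyWorld(nLig = 17, nSub = 20, seed = 7)
  expect_equal(nrow(w$reactions), 340L)
  sp <- splitDataset(w$reactions, seed = 3)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 204L, val = 68L, test = 68L))
  # disjoint partition whose union is the input
  key <- function(df) paste(df$ligand_id, df$substituent)
  all <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_equal(sort(all), sort(key(w$reactions)))
  expect_equal(anyDuplicated(all), 0L)
  # 10 rows under (0.6, 0.2, 0.2) give (6, 2, 2)
  sp10 <- splitDataset(w$reactions[1:10, ], seed = 5)
  expect_equal(unname(vapply(sp10, nrow, integer(1))), c(6L, 2L, 2L))
  # reproducible per seed
  sp2 <- splitDataset(w$reactions, seed = 3)
  expect_identical(sp$train$ligand_id, sp2$train$ligand_id)
  expect_error(splitDataset(w$reactions[1:4, ]), "fewer than 5")
})

test_that("checkTermination applies the stated thresholds exactly", {
  cfg <- trainConfig()
  # strictly decreasing losses: large changes, no sign flips
  expect_equal(checkTermination(seq(20, 15, by = -0.5), cfg), "continue")
  # alternating +0.5/-0.5: 100% flips, mean |change| = 0.5 > 0.2
  osc <- 10 + c(0, cumsum(rep(c(0.5, -0.5), 5)))
  expect_equal(checkTermination(osc, cfg), "rejected")
  # constant losses: mean |change| = 0 < 1e-4
  expect_equal(checkTermination(rep(2, 11), cfg), "converged")
  # too few losses: always continue
  expect_equal(checkTermination(rep(c(1, 9), 4), cfg), "continue")
  # boundary: flips at exactly 8/9 with magnitude just above the threshold
  d <- c(0.21, -0.21, 0.21, -0.21, 0.21, -0.21, 0.21, -0.21, 0.21, 0.21)
  expect_equal(checkTermination(5 + cumsum(c(0, d)), cfg), "rejected")
  d2 <- d; d2[10] <- -d2[10]; d2[9] <- d2[9]   # 7/9 flips -> continue
  d2 <- c(0.21, -0.21, 0.21, -0.21, 0.21, -0.21, 0.21, 0.21, 0.21, 0.21)
  expect_equal(checkTermination(5 + cumsum(c(0, d2)), cfg), "continue")
  # purity: repeated evaluation of the same window gives the same answer
  expect_identical(checkTermination(osc, cfg), checkTermination(osc, cfg))
})

test_that("trainTwoStage runs the two-stage protocol end to end", {
  w <- tinyWorld(nLig = 4, nSub = 6, seed = 13,
                 truth = generativeTruth(noise_sd = 0, seed = 15))
  sp <- splitDataset(w$reactions, seed = 14)
  cfg <- trainConfig(learning_rate = 0.002, max_epochs = 400, seed = 42)
  r <- trainTwoStage(sp$train, sp$val, w$trees, w$subs$table, cfg)
  expect_s4_class(r, "TrainResult")
  expect_true(r@status %in% c("completed", "converged_early",
                              "rejected_fluctuation",
                              "stage1_cutoff_not_reached"))
  expect_true(length(r@lossHistory) > 0)
  # non-negativity projections hold after training
  expect_true(all(r@model@head@wH2 >= 0))
  expect_true(all(r@model@head@wFinal >= 0))
  # max_epochs = 0: untrained params returned, metrics still computed
  r0 <- trainTwoStage(sp$train, sp$val, w$trees, w$subs$table,
                      trainConfig(max_epochs = 0L, seed = 42))
  expect_equal(r0@status, "completed")
  expect_equal(r0@epochsRun, 0L)
  expect_length(r0@lossHistory, 0L)
  expect_true(is.finite(r0@valR2))
  # same config and seed reproduce the same fit
  r2 <- trainTwoStage(sp$train, sp$val, w$trees, w$subs$table, cfg)
  expect_identical(r@model@head@wFinal, r2@model@head@wFinal)
  expect_identical(r@lossHistory, r2@lossHistory)
})

test_that("noiseless separable toy trains to a tight free-energy fit", {
  # 2 ligands x 10 substituents, no noise: the additive truth is exactly
  # representable, so a healthy run ends with a small dG error
  trees <- generateLigandSet(2, branchingLaw = c("Me", "tBu"), seed = 2)
  subs <- generateSubstituentSet(10, seed = 3)
  ds <- generateReactionDataset(trees, subs$substrates,
                                generativeTruth(noise_sd = 0, seed = 4))
  sp <- splitDataset(ds$reactions, seed = 5)
  fits <- lapply(1:6, function(i)
    trainTwoStage(sp$train, sp$val, trees, subs$table,
                  trainConfig(learning_rate = 0.002, max_epochs = 5000,
                              seed = 60 + i)))
  dGerr <- vapply(fits, function(r) {
    p <- predictReactions(r@model, sp$train, trees, subs$table)
    mean(abs(p$dG_total - eyringEnergyFromRate(sp$train$k_obs)))
  }, numeric(1))
  expect_lt(min(dGerr), 0.1)
})

test_that("selection filters by both thresholds and keeps the top ten", {
  mk <- function(r2, mae, status = "completed") {
    new("TrainResult", model = list(), status = status,
        lossHistory = numeric(), stageSwitch = NA_integer_,
        epochsRun = 1L, valR2 = r2, valMae = mae, config = list())
  }
  # 15 qualifiers: exactly the 10 largest validation R^2 survive
  res <- lapply(seq(0.81, 0.95, by = 0.01), function(r) mk(r, 0.5))
  ens <- selectAndEnsemble(res)
  expect_length(ensembleMembers(ens), 10L)
  r2s <- vapply(ensembleMembers(ens), function(m) m@valR2, numeric(1))
  expect_equal(r2s, sort(seq(0.86, 0.95, by = 0.01), decreasing = TRUE))
  # good R^2 but failing MAE arm is excluded
  expect_error(selectAndEnsemble(list(mk(0.9, 2.0))), "empty ensemble")
  # fluctuation-rejected runs never enter selection
  expect_error(selectAndEnsemble(list(mk(0.95, 0.1,
                                         "rejected_fluctuation"))),
               "empty ensemble")
  # construction enforces the thresholds
  expect_error(new("ModelEnsemble", members = list(mk(0.5, 0.5)),
                   r2Threshold = 0.8, maeThreshold = 1.5))
})

test_that("ensemble predictions average the member predictions", {
  w <- tinyWorld(nLig = 3, nSub = 4, seed = 23)
  sp <- splitDataset(w$reactions, seed = 24)
  r <- trainTwoStage(sp$train, sp$val, w$trees, w$subs$table,
                     trainConfig(max_epochs = 0L, seed = 5))
  r@valR2 <- 0.9; r@valMae <- 0.1    # force qualification of the stub
  ens <- new("ModelEnsemble", members = list(r, r), r2Threshold = 0.8,
             maeThreshold = 1.5)
  pe <- predictEnsemble(ens, sp$val, w$trees, w$subs$table)
  ps <- predictReactions(r@model, sp$val, w$trees, w$subs$table)
  # identical members: the mean equals the member prediction
  expect_equal(pe$k_pred, ps$k_pred)
  expect_equal(pe$dG_L, ps$dG_L)
})

test_that("cross-validation keeps a constant test fold across 4 runs", {
  w <- tinyWorld(nLig = 17, nSub = 20, seed = 33)
  plan <- cvPlan(w$reactions, nFolds = 5, seed = 9)
  expect_equal(as.integer(table(plan$fold)), rep(68L, 5))
  expect_length(plan$runs, 4L)
  tests <- lapply(plan$runs, `[[`, "test")
  for (j in 2:4) expect_identical(tests[[j]], tests[[1]])
  vals <- lapply(plan$runs, `[[`, "val")
  # each run validates on a distinct fold from S1-S4
  expect_equal(anyDuplicated(vapply(vals, function(v) v[1], integer(1))), 0L)
  for (rn in plan$runs) {
    expect_length(intersect(rn$train, rn$val), 0L)
    expect_length(intersect(rn$train, rn$test), 0L)
    expect_equal(sort(c(rn$train, rn$val, rn$test)), seq_len(340L))
  }
  expect_identical(cvPlan(w$reactions, 5, seed = 9)$fold, plan$fold)
})

test_that("hyperparameter search scores by validation R^2", {
  w <- tinyWorld(nLig = 3, nSub = 4, seed = 43)
  sp <- splitDataset(w$reactions, seed = 44)
  # degenerate one-point space: returned without training twice
  tune1 <- tuneHyperparameters(list(learning_rate = 0.002), budget = 5,
                               sp$train, sp$val, w$trees, w$subs$table,
                               config = trainConfig(max_epochs = 10L),
                               seed = 2)
  expect_equal(nrow(tune1$log), 1L)
  expect_equal(tune1$best$learning_rate, 0.002)
  # budget 1 samples a single configuration
  tune2 <- tuneHyperparameters(list(learning_rate = c(0.001, 0.002),
                                    iterations = c(3L, 4L)),
                               budget = 1, sp$train, sp$val, w$trees,
                               w$subs$table,
                               config = trainConfig(max_epochs = 10L),
                               seed = 3)
  expect_equal(nrow(tune2$log), 1L)
  expect_error(tuneHyperparameters(list(learning_rate = 0.001), budget = 0,
                                   sp$train, sp$val, w$trees, w$subs$table),
               "budget")
})
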