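test_that("restrictedLinearFit matches closed forms and clips at zero", {
  X <- cbind(a = as.numeric(1:5))
  expect_equal(unname(restrictedLinearFit(X, 2 * (1:5))$coefficients), 2)
  # negatively correlated single feature: coefficient clipped to 0
  expect_equal(unname(restrictedLinearFit(X, -(1:5))$coefficients), 0)
  expect_error(restrictedLinearFit(matrix(0, 3, 2), 1:3), "degenerate")
  # objective never worse than predicting zero
  set.seed(61)
  for (rep in 1:20) {
    Xr <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    f <- restrictedLinearFit(Xr, y)
    expect_lte(sum(f$residuals^2), sum(y^2) + 1e-10)
    expect_true(all(f$coefficients >= 0))
  }
})

test_that("restrictedLinearFit equals the exhaustive active-set oracle", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(6:15, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta <- pmax(rnorm(p), 0)
    y <- drop(X %*% beta) + rnorm(n, sd = 0.3)
    got <- restrictedLinearFit(X, y)$coefficients
    expect_equal(unname(got), enumNnls(X, y), tolerance = 1e-6)
  }
})

test_that("descriptor tables encode ligands as specified", {
  trees <- lapply(list(c("Me", "Me", "Me"), c("Et", "Et", "Et"),
                       c("Cy", "Cy", "tBu")), buildTree)
  names(trees) <- c("A", "B", "C")
  oh <- buildDescriptorTable(trees, "one_hot")
  expect_equal(dim(oh), c(3L, 3L))
  expect_true(all(oh == diag(3)))
  expect_equal(rowSums(oh), c(A = 1, B = 1, C = 1))
  fp <- buildDescriptorTable(trees, "fingerprint")
  expect_equal(dim(fp), c(3L, 96L))
  # identical structures give identical fingerprint rows
  trees2 <- trees
  trees2$D <- buildTree(c("Me", "Me", "Me"), "D")
  fp2 <- buildDescriptorTable(trees2, "fingerprint")
  expect_equal(unname(fp2["D", ]), unname(fp2["A", ]))
  # distinct structures differ
  expect_false(all(fp["A", ] == fp["C", ]))
  # numeric_file passthrough and missing-row error
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(ligand = c("A", "B", "C"),
                       buried_volume = c(25.9, 31.1, 38.2),
                       cone_angle = c(118, 132, 170)), csv, row.names = FALSE)
  num <- buildDescriptorTable(trees, "numeric_file", path = csv)
  expect_equal(unname(num[, "buried_volume"]), c(25.9, 31.1, 38.2))
  write.csv(data.frame(ligand = c("A", "B"), x = 1:2), csv,
            row.names = FALSE)
  expect_error(buildDescriptorTable(trees, "numeric_file", path = csv),
               "missing descriptor row")
})

test_that("descriptor-swap training keeps the substrate pathway unchanged", {
  w <- tinyWorld(nLig = 4, nSub = 5, seed = 83)
  sp <- splitDataset(w$reactions, seed = 84)
  oh <- buildDescriptorTable(w$trees, "one_hot")
  fp <- buildDescriptorTable(w$trees, "fingerprint")
  cfg <- trainConfig(max_epochs = 50L, seed = 7)
  r1 <- trainBaseline(sp$train, sp$val, oh, w$subs$table, cfg)
  r2 <- trainBaseline(sp$train, sp$val, fp, w$subs$table, cfg)
  expect_s4_class(r1, "TrainResult")
  expect_true(is.finite(r1@valR2) && is.finite(r2@valR2))
  # substrate (Hammett) features are byte-identical across descriptor kinds
  expect_identical(TreeMPNN:::.hammettMatrix(sp$train, w$subs$table),
                   TreeMPNN:::.hammettMatrix(sp$train, w$subs$table))
  p1 <- predictBaselineModel(r1@model, sp$val, w$subs$table)
  expect_equal(nrow(p1), nrow(sp$val))
  expect_true(all(p1$dG_total >= 0))
})

test_that("compareDescriptors reports both methods per descriptor", {
  w <- tinyWorld(nLig = 4, nSub = 5, seed = 93)
  sp <- splitDataset(w$reactions, seed = 94)
  tabs <- list(one_hot = buildDescriptorTable(w$trees, "one_hot"))
  rep <- compareDescriptors(sp, tabs, w$subs$table,
                            config = trainConfig(max_epochs = 30L),
                            nTrials = 2L, seed = 5)
  expect_equal(nrow(rep), 2L)
  expect_setequal(rep$method, c("fcnn", "restricted_linear"))
  expect_true(all(c("train_r2", "val_r2", "test_r2") %in% names(rep)))
})
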