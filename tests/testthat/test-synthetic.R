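test_that("generated ligand sets span a bulk gradient reproducibly", {
  # minimal pair: pure trimethyl- and pure tri-tert-butylphosphine analogues
  two <- generateLigandSet(2, branchingLaw = c("Me", "tBu"), seed = 1)
  expect_equal(unname(vapply(two, stericProxy, integer(1))), c(3L, 12L))
  full <- generateLigandSet(17, seed = 5)
  s <- vapply(full, stericProxy, integer(1))
  expect_gte(length(unique(s)), 3L)
  # reproducible per seed; every tree canonicalizes and encodes cleanly
  full2 <- generateLigandSet(17, seed = 5)
  expect_equal(lapply(full, treeEdges), lapply(full2, treeEdges))
  tpl <- buildTemplate(full)
  for (tr in full) expect_s4_class(encodeGraph(tr, tpl), "AlignedGraph")
  expect_error(generateLigandSet(1), "at least 2")
  expect_error(generateLigandSet(3, branchingLaw = c("Me", "Qx")),
               "impossible branching law")
})

test_that("reaction datasets follow the additive generative truth", {
  trees <- generateLigandSet(17, seed = 7)
  subs <- generateSubstituentSet(20, seed = 8)
  expect_true(all(abs(subs$substrates$sigma) <= 0.8))
  # full factorial 17 x 20 = 340 rows
  ds <- generateReactionDataset(trees, subs$substrates,
                                generativeTruth(seed = 9))
  expect_equal(nrow(ds$reactions), 340L)
  expect_true(all(ds$reactions$k_obs > 0))
  # noiseless data: Eyring back-conversion reproduces the additive truth
  ds0 <- generateReactionDataset(trees, subs$substrates,
                                 generativeTruth(noise_sd = 0, seed = 9))
  back <- eyringEnergyFromRate(ds0$reactions$k_obs, 298.15)
  expect_equal(back, ds0$truth$dG_L_true + ds0$truth$dG_LS_true,
               tolerance = 1e-10)
  # larger sigma_eff at fixed ligand: smaller dG_LS*, larger k
  one <- ds0$truth$ligand_id == ds0$truth$ligand_id[1]
  ord <- order(ds0$truth$sigma_eff[one])
  expect_true(all(diff(ds0$truth$dG_LS_true[one][ord]) <= 0))
  expect_true(all(diff(ds0$reactions$k_obs[one][ord]) >= 0))
})

test_that("noiseless truth features are recovered by restricted regression", {
  # regressing the true dG on (1, -s, -sigma) style features recovers the
  # generative slopes when no clipping is active
  trees <- generateLigandSet(8, seed = 17)
  subs <- generateSubstituentSet(10, seed = 18)
  tr <- generativeTruth(noise_sd = 0, seed = 19)
  ds <- generateReactionDataset(trees, subs$substrates, tr)
  dG <- ds$truth$dG_L_true + ds$truth$dG_LS_true
  X <- cbind(intercept = 1, negS = -ds$truth$s, negSigma = ds$truth$sigma_eff * -1)
  f <- restrictedLinearFit(X, dG)
  expect_equal(unname(f$coefficients[["intercept"]]), tr$a0 + tr$b0,
               tolerance = 1e-6)
  expect_equal(unname(f$coefficients[["negS"]]), tr$a1 - tr$b1,
               tolerance = 1e-6)
  expect_equal(unname(f$coefficients[["negSigma"]]), tr$b2, tolerance = 1e-6)
})

test_that("dataset statistics are stable per seed", {
  trees <- generateLigandSet(6, seed = 27)
  subs <- generateSubstituentSet(8, seed = 28)
  a <- generateReactionDataset(trees, subs$substrates,
                               generativeTruth(seed = 29))
  b <- generateReactionDataset(trees, subs$substrates,
                               generativeTruth(seed = 29))
  expect_identical(a$reactions$k_obs, b$reactions$k_obs)
  expect_identical(a$truth, b$truth)
})
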