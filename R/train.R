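#' @include AllClasses.R energy.R mpnn.R
#' @useDynLib TreeMPNN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run expr under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

.lrGrid <- c(0.0005, 0.001, 0.002, 0.005)
.cutoffGrid <- c(5.0, 6.0, 7.0)

#' Training configuration
#'
#' Assembles and validates the hyperparameters of the two-stage protocol.
#' Grid-valued fields (`learning_rate`, `d_m`, `iterations`,
#' `stage1_cutoff`) must come from their stated grids unless
#' `allowNonGrid = TRUE`.
#'
#' @param learning_rate Adam learning rate, from \{0.0005, 0.001, 0.002,
#'   0.005\}.
#' @param d_m message dimension, 2-4.
#' @param iterations message-passing iterations, 3-5.
#' @param batch_size samples per gradient step (default 10).
#' @param max_epochs epoch cap (default 10000).
#' @param stage1_cutoff free-energy MAE (kcal/mol) below which stage 1 ends;
#'   from \{5, 6, 7\}.
#' @param fluct_window trailing window of loss changes inspected by the
#'   termination rule (default 10).
#' @param fluct_scope series the termination rule monitors: `"epoch"`
#'   (default; the per-epoch mean training loss) or `"batch"` (every raw
#'   batch loss). Raw batch losses of shuffled batches carry composition
#'   noise whose consecutive differences flip sign with probability 2/3,
#'   which makes the sign-flip rejection fire on healthy runs; see the
#'   methods vignette.
#' @param fluct_sign_frac fraction of consecutive change pairs that must flip
#'   sign to reject (default 0.8).
#' @param fluct_mag mean absolute change that must be exceeded to reject
#'   (default 0.2).
#' @param converge_tol mean absolute change below which the run is declared
#'   converged (default 1e-4).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param T reaction temperature in kelvin for Eyring conversions.
#' @param l2_strength L2 regularization on the two sigmoid units.
#' @param w_final_range range of the uniform initialization of the two final
#'   scale weights, kcal/mol (see [newEnergyHead()]).
#' @param update_activation `"linear"` (default) or `"leaky"`: whether the
#'   message-passing update output passes through the leaky ReLU as well as
#'   the messages; see [MpnnParams-class].
#' @param k_scale rate-constant unit used by the stage-2 loss, the selection
#'   MAE and the fluctuation/convergence thresholds: `"auto"` (default)
#'   divides by the arithmetic mean of the training rate constants, i.e.
#'   stage 2 works on relative rates as kinetic screens report them; a
#'   numeric value divides by that value (1 = raw input units). Validation
#'   R^2 is scale-free and unaffected.
#' @param allowNonGrid permit off-grid values for the grid-valued fields.
#' @return a named list of class `TrainConfig`.
#' @export
trainConfig <- function(learning_rate = 0.002, d_m = 3L, iterations = 4L,
                        batch_size = 10L, max_epochs = 10000L,
                        stage1_cutoff = 5.0, fluct_window = 10L,
                        fluct_scope = c("epoch", "batch"),
                        fluct_sign_frac = 0.8, fluct_mag = 0.2,
                        converge_tol = 1e-4, seed = 1L, T = 298.15,
                        l2_strength = 1e-4, k_scale = "auto",
                        update_activation = c("linear", "leaky"),
                        w_final_range = c(15, 30),
                        allowNonGrid = FALSE) {
  fluct_scope <- match.arg(fluct_scope)
  update_activation <- match.arg(update_activation)
  cfg <- list(learning_rate = learning_rate, d_m = as.integer(d_m),
              iterations = as.integer(iterations),
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              stage1_cutoff = stage1_cutoff,
              fluct_window = as.integer(fluct_window),
              fluct_scope = fluct_scope,
              fluct_sign_frac = fluct_sign_frac, fluct_mag = fluct_mag,
              converge_tol = converge_tol, seed = as.integer(seed), T = T,
              l2_strength = l2_strength, k_scale = k_scale,
              update_activation = update_activation,
              w_final_range = w_final_range)
  if (!allowNonGrid) {
    if (!learning_rate %in% .lrGrid)
      stop("learning_rate must come from {0.0005, 0.001, 0.002, 0.005}")
    if (!cfg$d_m %in% 2:4) stop("d_m must be 2, 3 or 4")
    if (!cfg$iterations %in% 3:5) stop("iterations must be 3, 4 or 5")
    if (!stage1_cutoff %in% .cutoffGrid)
      stop("stage1_cutoff must come from {5, 6, 7} kcal/mol")
  }
  if (cfg$batch_size < 1L || cfg$max_epochs < 0L)
    stop("batch_size must be >= 1 and max_epochs >= 0")
  class(cfg) <- c("TrainConfig", "list")
  cfg
}

#' Random train/validation/test partition
#'
#' Sizes are `floor(n * fraction)` with the remainder distributed to the
#' groups with the largest fractional parts (earlier group on ties), so 340
#' reactions under (0.6, 0.2, 0.2) give (204, 68, 68).
#'
#' @param reactions reaction data.frame.
#' @param fractions three fractions summing to 1.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list with `train`, `val`, `test` data.frames (disjoint, union =
#'   input).
#' @export
splitDataset <- function(reactions, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- nrow(reactions)
  if (n < 5L) stop("refusing to split fewer than 5 reactions")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- raw - sizes
    give <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  idx <- .withSeed(seed, sample.int(n))
  ends <- cumsum(sizes)
  list(train = reactions[idx[seq_len(ends[1])], , drop = FALSE],
       val = reactions[idx[(ends[1] + 1):ends[2]], , drop = FALSE],
       test = reactions[idx[(ends[2] + 1):ends[3]], , drop = FALSE])
}

#' Batch-loss termination rule
#'
#' Inspects the trailing window of batch losses: with at least
#' `fluct_window + 1` losses, the `fluct_window` consecutive changes are
#' computed; the run is `"rejected"` when at least `fluct_sign_frac` of the
#' comparable consecutive change pairs flip sign and the mean absolute change
#' exceeds `fluct_mag`, `"converged"` when the mean absolute change falls
#' below `converge_tol`, otherwise `"continue"`. A pure function of its
#' window.
#'
#' @param recentLosses numeric vector of the most recent batch losses (the
#'   last `fluct_window + 1` are used; fewer means `"continue"`).
#' @param config a [trainConfig()].
#' @return `"continue"`, `"converged"` or `"rejected"`.
#' @examples
#' cfg <- trainConfig()
#' checkTermination(seq(10, 5, by = -0.5), cfg)          # continue
#' checkTermination(10 + c(0, cumsum(rep(c(0.5, -0.5), 5))), cfg)  # rejected
#' checkTermination(rep(2, 11), cfg)                     # converged
#' @export
checkTermination <- function(recentLosses, config = trainConfig()) {
  w <- config$fluct_window
  if (length(recentLosses) < w + 1L) return("continue")
  tail_ <- recentLosses[(length(recentLosses) - w):length(recentLosses)]
  d <- diff(tail_)
  meanAbs <- mean(abs(d))
  flips <- sum(d[-1] * d[-length(d)] < 0)
  if (flips / (w - 1L) >= config$fluct_sign_frac && meanAbs > config$fluct_mag)
    return("rejected")
  if (meanAbs < config$converge_tol) return("converged")
  "continue"
}

# encode a named list of trees against a template into the C++ graph layout
.graphPayload <- function(trees, template) {
  lapply(trees, function(tr) {
    g <- encodeGraph(tr, template)
    el <- .directedEdges(g)
    list(recv = as.integer(el$recv), send = as.integer(el$send),
         e = as.numeric(el$e), h0 = as.numeric(.initialStates(g)))
  })
}

.hammettMatrix <- function(reactions, hammett) {
  H <- t(mapply(encodeSubstrate, reactions$substituent, reactions$position,
                MoreArgs = list(table = hammett)))
  rownames(H) <- NULL
  H
}

.r2 <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Train one model with the two-stage protocol
#'
#' Stage 1 regresses predicted activation free energies against the
#' Eyring-converted experimental energies (MAE loss, kcal/mol) until the
#' batch loss drops below `stage1_cutoff`; the remaining epochs form stage 2,
#' which regresses predicted rate constants against the experimental ones.
#' Adam is used throughout with the fluctuation/convergence termination rule
#' applied per batch within each stage; the non-negativity constraints on the
#' readout are enforced by projection after every step. Validation metrics
#' (R^2 and MAE, both in rate-constant space) are attached to the result.
#'
#' @param train,val reaction data.frames (see [readReactionTable()]).
#' @param trees named list of [LigandTree-class] covering every ligand.
#' @param hammett a `HammettTable` covering every substituent.
#' @param config a [trainConfig()]; `config$seed` controls both weight
#'   initialization and batch shuffling.
#' @param template optional frozen [GraphTemplate-class]; defaults to the
#'   template spanned by `trees`.
#' @return a [TrainResult-class].
#' @export
trainTwoStage <- function(train, val, trees, hammett, config = trainConfig(),
                          template = NULL) {
  if (is.null(template)) template <- buildTemplate(trees)
  ligIds <- names(trees)
  miss <- setdiff(unique(c(train$ligand_id, val$ligand_id)), ligIds)
  if (length(miss))
    stop(sprintf("no tree for ligand(s): %s", paste(miss, collapse = ", ")))
  n <- totalSlots(template)
  trainTrees <- trees[unique(train$ligand_id)]
  init <- .withSeed(config$seed, {
    mpnn <- newMpnnParams(config$d_m, config$iterations,
                          updateLeaky = config$update_activation == "leaky")
    # per-slot RMS of the initial GNN outputs keeps the sigmoid logits O(1)
    G0 <- t(vapply(trainTrees, function(tr)
      runMpnn(encodeGraph(tr, template), mpnn), numeric(n)))
    list(mpnn = mpnn,
         head = newEnergyHead(n, l2 = config$l2_strength,
                              wFinalRange = config$w_final_range,
                              inputScale = sqrt(colMeans(G0^2))))
  })
  graphs <- .graphPayload(trees, template)
  kScale <- .kScale(config, train$k_obs)
  fit <- .trainCore(
    graphs = unname(graphs), desc = matrix(0, 0, 0), useGnn = TRUE,
    ligidx = match(train$ligand_id, ligIds),
    sig = .hammettMatrix(train, hammett),
    dGobs = eyringEnergyFromRate(train$k_obs, config$T),
    kobs = train$k_obs / kScale,
    Wm = init$mpnn@Wm, Wu = init$mpnn@Wu,
    wH1 = init$head@wH1, wH2 = init$head@wH2,
    wF = as.numeric(init$head@wFinal),
    cfg = c(config, list(leaky_slope = init$mpnn@leakySlope,
                         update_leaky = as.integer(init$mpnn@updateLeaky),
                         fluct_per_batch =
                           as.integer(config$fluct_scope == "batch"),
                         RT = .Rkcal * config$T,
                         eyring_prefactor = .kB * config$T / .hP / kScale)),
    seed = config$seed)
  model <- new("RateModel", template = template,
               mpnn = new("MpnnParams", Wm = fit$Wm, Wu = as.numeric(fit$Wu),
                          iterations = config$iterations,
                          leakySlope = init$mpnn@leakySlope,
                          updateLeaky = init$mpnn@updateLeaky),
               head = new("EnergyHead", wH1 = as.numeric(fit$wH1),
                          wH2 = as.numeric(fit$wH2),
                          wFinal = setNames(as.numeric(fit$wFinal),
                                            c("LS", "L")),
                          l2 = config$l2_strength),
               temperature = config$T)
  pv <- predictReactions(model, val, trees, hammett)
  new("TrainResult", model = model, status = fit$status,
      lossHistory = as.numeric(fit$loss),
      stageSwitch = as.integer(fit$stageSwitch),
      epochsRun = as.integer(fit$epochsRun),
      valR2 = .r2(val$k_obs, pv$k_pred),
      valMae = mean(abs(pv$k_pred - val$k_obs)) / kScale,
      config = c(unclass(config), list(k_scale_used = kScale)))
}

# resolve the stage-2 rate unit (see trainConfig)
.kScale <- function(config, kTrain) {
  ks <- config$k_scale
  if (is.null(ks) || identical(ks, "auto")) mean(kTrain) else as.numeric(ks)
}

# member prediction dispatch shared by ensembles and reports
.memberPredict <- function(result, reactions, trees, hammett) {
  m <- result@model
  if (is(m, "RateModel")) predictReactions(m, reactions, trees, hammett)
  else predictBaselineModel(m, reactions, hammett)
}

#' Filter, rank and ensemble training runs
#'
#' Drops fluctuation-rejected runs, keeps those with validation R^2 above and
#' validation MAE below the thresholds, sorts by validation R^2 and retains at
#' most `maxMembers`.
#'
#' @param results list of [TrainResult-class] objects.
#' @param r2Threshold validation R^2 threshold (default 0.8).
#' @param maeThreshold validation MAE threshold (default 1.5).
#' @param maxMembers ensemble size cap (default 10).
#' @return a [ModelEnsemble-class].
#' @export
selectAndEnsemble <- function(results, r2Threshold = 0.8, maeThreshold = 1.5,
                              maxMembers = 10L) {
  if (!length(results)) stop("no training results supplied")
  ok <- vapply(results, function(r)
    r@status != "rejected_fluctuation" && is.finite(r@valR2) &&
      r@valR2 > r2Threshold && r@valMae < maeThreshold, logical(1))
  qual <- results[ok]
  if (!length(qual))
    stop(sprintf(
      paste0("empty ensemble: no run met val R^2 > %g and val MAE < %g; ",
             "run more trials or revisit the hyperparameters"),
      r2Threshold, maeThreshold))
  r2 <- vapply(qual, function(r) r@valR2, numeric(1))
  qual <- qual[order(-r2)][seq_len(min(maxMembers, length(qual)))]
  new("ModelEnsemble", members = qual, r2Threshold = r2Threshold,
      maeThreshold = maeThreshold)
}

#' Ensemble prediction
#'
#' Arithmetic mean of the member predictions in rate-constant space, with the
#' free-energy components averaged alongside for reporting. Per-member values
#' are returned as attribute `"members"` for distribution summaries.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param reactions reaction data.frame.
#' @param trees named list of [LigandTree-class] (ignored by descriptor-swap
#'   baselines).
#' @param hammett a `HammettTable`.
#' @return `reactions` with averaged `dG_LS`, `dG_L`, `dG_total`, `k_pred`
#'   columns appended.
#' @export
predictEnsemble <- function(ensemble, reactions, trees,
                            hammett = readHammettTable()) {
  per <- lapply(ensemble@members, .memberPredict, reactions = reactions,
                trees = trees, hammett = hammett)
  avg <- function(col) rowMeans(vapply(per, function(p) p[[col]],
                                       numeric(nrow(reactions))))
  out <- cbind(reactions,
               data.frame(dG_LS = avg("dG_LS"), dG_L = avg("dG_L"),
                          dG_total = avg("dG_total"), k_pred = avg("k_pred")),
               row.names = NULL)
  attr(out, "members") <- per
  out
}

#' Train many runs and select the ensemble
#'
#' Convenience loop: `nTrials` two-stage runs with per-trial seeds derived
#' from `seed`, followed by [selectAndEnsemble()].
#'
#' @inheritParams trainTwoStage
#' @param nTrials number of training runs.
#' @param seed base seed; trial `i` uses `seed * 1000 + i` (kept below 2^31).
#' @param r2Threshold,maeThreshold selection thresholds.
#' @return list with `ensemble` ([ModelEnsemble-class]) and `results` (all
#'   runs, including rejected ones).
#' @export
trainEnsemble <- function(train, val, trees, hammett, config = trainConfig(),
                          nTrials = 30L, seed = 1L, template = NULL,
                          r2Threshold = 0.8, maeThreshold = 1.5) {
  if (is.null(template)) template <- buildTemplate(trees)
  results <- lapply(seq_len(nTrials), function(i) {
    cfg <- config
    cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    trainTwoStage(train, val, trees, hammett, cfg, template)
  })
  list(ensemble = selectAndEnsemble(results, r2Threshold, maeThreshold),
       results = results)
}

#' Fixed-test-set cross-validation plan
#'
#' Partitions the reactions into `nFolds` equal-sized folds; the last fold is
#' the constant test set and each of the remaining folds serves once as the
#' validation set, the others as training. For 340 reactions and 5 folds this
#' yields folds of 68 and 4 runs.
#'
#' @param reactions reaction data.frame.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed; identical seeds give identical fold assignment.
#' @return list with `fold` (integer assignment per row) and `runs` (list of
#'   `nFolds - 1` lists with `train`, `val`, `test` row indices).
#' @export
cvPlan <- function(reactions, nFolds = 5L, seed = 1L) {
  n <- nrow(reactions)
  if (n < nFolds) stop("dataset smaller than the number of folds")
  sizes <- rep(floor(n / nFolds), nFolds)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  idx <- .withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[idx] <- rep(seq_len(nFolds), times = sizes)
  runs <- lapply(seq_len(nFolds - 1L), function(j) {
    list(train = which(!fold %in% c(j, nFolds)),
         val = which(fold == j),
         test = which(fold == nFolds))
  })
  list(fold = fold, runs = runs)
}

#' Fixed-test-set k-fold cross-validation
#'
#' Executes the [cvPlan()]: for each run, trains an ensemble on three folds,
#' validates on the rotating fold and evaluates on the constant test fold.
#'
#' @inheritParams trainEnsemble
#' @param nFolds number of folds (default 5).
#' @return list with `metrics` (data.frame: run, val_r2, test_r2, members),
#'   `means` (averaged val/test R^2) and `plan`.
#' @export
crossValidate <- function(reactions, trees, hammett, config = trainConfig(),
                          nFolds = 5L, seed = 1L, nTrials = 30L,
                          r2Threshold = 0.8, maeThreshold = 1.5) {
  plan <- cvPlan(reactions, nFolds, seed)
  template <- buildTemplate(trees)
  rows <- lapply(seq_along(plan$runs), function(j) {
    rn <- plan$runs[[j]]
    fit <- trainEnsemble(reactions[rn$train, , drop = FALSE],
                         reactions[rn$val, , drop = FALSE],
                         trees, hammett, config, nTrials,
                         seed = seed + j, template = template,
                         r2Threshold = r2Threshold,
                         maeThreshold = maeThreshold)
    test <- reactions[rn$test, , drop = FALSE]
    pt <- predictEnsemble(fit$ensemble, test, trees, hammett)
    data.frame(run = j,
               val_r2 = max(vapply(fit$ensemble@members,
                                   function(m) m@valR2, numeric(1))),
               test_r2 = .r2(test$k_obs, pt$k_pred),
               members = length(fit$ensemble@members))
  })
  metrics <- do.call(rbind, rows)
  list(metrics = metrics,
       means = c(val_r2 = mean(metrics$val_r2),
                 test_r2 = mean(metrics$test_r2)),
       plan = plan)
}

#' Hyperparameter search over the stated grids
#'
#' Evaluates sampled configurations by validation R^2 of a single two-stage
#' run each (exhaustive when the budget covers the whole grid; otherwise a
#' random subset without replacement).
#'
#' @inheritParams trainTwoStage
#' @param space named list of candidate values, e.g.
#'   `list(learning_rate = c(0.001, 0.002), d_m = 3, iterations = 3:4)`;
#'   omitted fields keep the `config` defaults.
#' @param budget maximum number of configurations trained.
#' @param seed seed for sampling and per-trial training seeds.
#' @return list with `best` (a [trainConfig()]), `log` (data.frame of trials)
#'   and `results` (the [TrainResult-class] objects).
#' @export
tuneHyperparameters <- function(space, budget, train, val, trees, hammett,
                                config = trainConfig(), seed = 1L,
                                template = NULL) {
  if (budget < 1L) stop("budget must be at least 1")
  if (is.null(template)) template <- buildTemplate(trees)
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  if (!nrow(grid)) stop("empty search space")
  pick <- if (budget >= nrow(grid)) seq_len(nrow(grid)) else
    .withSeed(seed, sample.int(nrow(grid), budget))
  results <- vector("list", length(pick))
  log <- vector("list", length(pick))
  for (t in seq_along(pick)) {
    cfg <- config
    for (f in names(grid)) cfg[[f]] <- grid[[f]][pick[t]]
    cfg$seed <- as.integer((seed * 1000L + t) %% .Machine$integer.max)
    cfg <- do.call(trainConfig, cfg[names(formals(trainConfig))[
      names(formals(trainConfig)) %in% names(cfg)]])
    results[[t]] <- trainTwoStage(train, val, trees, hammett, cfg, template)
    log[[t]] <- data.frame(trial = t, grid[pick[t], , drop = FALSE],
                           val_r2 = results[[t]]@valR2,
                           status = results[[t]]@status,
                           row.names = NULL)
  }
  log <- do.call(rbind, log)
  best <- which.max(ifelse(vapply(results, function(r)
    r@status == "rejected_fluctuation", logical(1)), -Inf, log$val_r2))
  bestCfg <- config
  for (f in names(grid)) bestCfg[[f]] <- grid[[f]][pick[best]]
  list(best = do.call(trainConfig, bestCfg[names(formals(trainConfig))[
    names(formals(trainConfig)) %in% names(bestCfg)]]),
    log = log, results = results)
}
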