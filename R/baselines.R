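#' @include AllClasses.R train.R
NULL

#' Non-negative linear regression with zero intercept
#'
#' Least-squares fit of `y ~ X` with all coefficients constrained to be
#' non-negative and no intercept (Lawson-Hanson active-set algorithm). This is
#' the restricted linear regression used to compare ligand descriptors on an
#' equal footing: the final layer of the rate model alone.
#'
#' @param X numeric feature matrix (rows = reactions).
#' @param y numeric response (observed rate constants).
#' @param tol active-set tolerance on the dual vector.
#' @param maxIter iteration cap.
#' @return list with `coefficients` (length `ncol(X)`, all `>= 0`), `fitted`
#'   and `residuals`.
#' @examples
#' X <- cbind(a = 1:5)
#' restrictedLinearFit(X, 2 * (1:5))$coefficients   # 2
#' restrictedLinearFit(X, -(1:5))$coefficients      # clipped to 0
#' @export
restrictedLinearFit <- function(X, y, tol = 1e-10, maxIter = 10L * ncol(X)) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("degenerate design: no feature columns")
  if (all(X == 0)) stop("degenerate design: all-zero feature matrix")
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  p <- ncol(X)
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(X, y - X %*% x))
  iter <- 0L
  scale <- max(abs(w), 1)
  while (any(!passive & w > tol * scale) && iter < maxIter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      P <- which(passive)
      z[P] <- qr.coef(qr(X[, P, drop = FALSE]), y)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(p); break }
    }
    w <- drop(crossprod(X, y - X %*% x))
  }
  fitted <- drop(X %*% x)
  list(coefficients = setNames(pmax(x, 0), colnames(X)), fitted = fitted,
       residuals = y - fitted)
}

# deterministic 31-ary string hash kept inside double-safe integer range
.strHash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

# Wl-style iterated neighborhood labels of a ligand tree (root included),
# hashed into count bins per radius. A simplified stand-in for multiple
# molecular fingerprint features; documented as an approximation.
.treeFingerprint <- function(tree, radii = 1:3, nbits = 32L) {
  n <- nrow(tree@nodes)
  adj <- .adjacency(n, tree@edges)
  lab <- c("P", tree@nodes$element)            # index 1 = root
  counts <- numeric(nbits * length(radii))
  for (r in seq_along(radii)) {
    nxt <- character(n + 1L)
    for (v in 0:n) {
      nb <- adj[[v + 1L]]
      token <- if (is.null(nb)) character() else
        sort(paste0(nb[, 2], ":", lab[nb[, 1] + 1L]))
      nxt[v + 1L] <- paste0(lab[v + 1L], "|", paste(token, collapse = ","))
    }
    lab <- nxt
    for (v in 0:n) {
      bin <- (.strHash(lab[v + 1L]) %% nbits) + (r - 1L) * nbits + 1L
      counts[bin] <- counts[bin] + 1
    }
  }
  counts
}

#' Build a ligand descriptor table for the descriptor-swap baselines
#'
#' Alternative ligand featurizations that replace the GNN output states:
#' identity-style one-hot encodings, hashed circular substructure-count
#' fingerprints (radii 1-3, a simplified multiple-fingerprint-features
#' scheme), or user-supplied numeric columns such as buried volumes and cone
#' angles (input data only; never computed here).
#'
#' @param trees named list of [LigandTree-class] objects.
#' @param kind `"one_hot"`, `"fingerprint"` or `"numeric_file"`.
#' @param path CSV path for `kind = "numeric_file"`; schema `ligand,
#'   feature1, feature2, ...`.
#' @param nbits bins per radius for `kind = "fingerprint"` (default 32).
#' @return numeric matrix with one row per ligand (rownames = ligand ids) and
#'   attribute `kind`.
#' @export
buildDescriptorTable <- function(trees,
                                 kind = c("one_hot", "fingerprint",
                                          "numeric_file"),
                                 path = NULL, nbits = 32L) {
  kind <- match.arg(kind)
  ids <- names(trees)
  tab <- switch(kind,
    one_hot = {
      m <- diag(length(ids))
      colnames(m) <- ids
      m
    },
    fingerprint = t(vapply(trees, .treeFingerprint,
                           numeric(3L * nbits), nbits = nbits)),
    numeric_file = {
      if (is.null(path)) stop("numeric_file descriptors need a path")
      df <- read.csv(path, stringsAsFactors = FALSE)
      if (!"ligand" %in% names(df))
        stop("numeric_file must have a 'ligand' column")
      row <- match(ids, df$ligand)
      if (anyNA(row))
        stop(sprintf("missing descriptor row for ligand(s): %s",
                     paste(ids[is.na(row)], collapse = ", ")))
      as.matrix(df[row, setdiff(names(df), "ligand"), drop = FALSE])
    })
  rownames(tab) <- ids
  attr(tab, "kind") <- kind
  tab
}

#' Train a descriptor-swap baseline model
#'
#' The architecture with the GNN layer removed: the ligand descriptor row
#' feeds the two-head readout directly; substrate Hammett features and the
#' two-stage protocol are byte-identical to the full model.
#'
#' @inheritParams trainTwoStage
#' @param descriptors matrix from [buildDescriptorTable()].
#' @return a [TrainResult-class] whose `model` is a `BaselineModel` list.
#' @export
trainBaseline <- function(train, val, descriptors, hammett,
                          config = trainConfig()) {
  ids <- rownames(descriptors)
  miss <- setdiff(unique(c(train$ligand_id, val$ligand_id)), ids)
  if (length(miss))
    stop(sprintf("no descriptor row for ligand(s): %s",
                 paste(miss, collapse = ", ")))
  p <- ncol(descriptors)
  init <- .withSeed(config$seed, newEnergyHead(
    p, l2 = config$l2_strength, wFinalRange = config$w_final_range,
    inputScale = sqrt(colMeans(descriptors[unique(train$ligand_id), ,
                                           drop = FALSE]^2))))
  kScale <- .kScale(config, train$k_obs)
  fit <- .trainCore(
    graphs = list(), desc = as.matrix(descriptors), useGnn = FALSE,
    ligidx = match(train$ligand_id, ids),
    sig = .hammettMatrix(train, hammett),
    dGobs = eyringEnergyFromRate(train$k_obs, config$T),
    kobs = train$k_obs / kScale,
    Wm = matrix(0, 2, 3), Wu = numeric(3),
    wH1 = init@wH1, wH2 = init@wH2, wF = as.numeric(init@wFinal),
    cfg = c(config, list(leaky_slope = 0.01, update_leaky = 1L,
                         fluct_per_batch =
                           as.integer(config$fluct_scope == "batch"),
                         RT = .Rkcal * config$T,
                         eyring_prefactor = .kB * config$T / .hP / kScale)),
    seed = config$seed)
  model <- structure(
    list(descriptors = as.matrix(descriptors),
         head = new("EnergyHead", wH1 = as.numeric(fit$wH1),
                    wH2 = as.numeric(fit$wH2),
                    wFinal = setNames(as.numeric(fit$wFinal), c("LS", "L")),
                    l2 = config$l2_strength),
         temperature = config$T),
    class = "BaselineModel")
  pv <- predictBaselineModel(model, val, hammett)
  new("TrainResult", model = model, status = fit$status,
      lossHistory = as.numeric(fit$loss),
      stageSwitch = as.integer(fit$stageSwitch),
      epochsRun = as.integer(fit$epochsRun),
      valR2 = .r2(val$k_obs, pv$k_pred),
      valMae = mean(abs(pv$k_pred - val$k_obs)) / kScale,
      config = c(unclass(config), list(k_scale_used = kScale)))
}

#' Predict reactions with a descriptor-swap baseline model
#'
#' @param model a `BaselineModel` from [trainBaseline()].
#' @param reactions reaction data.frame.
#' @param hammett a `HammettTable`.
#' @return `reactions` with the [energyForward()] columns appended.
#' @export
predictBaselineModel <- function(model, reactions,
                                 hammett = readHammettTable()) {
  G <- model$descriptors[reactions$ligand_id, , drop = FALSE]
  H <- .hammettMatrix(reactions, hammett)
  cbind(reactions, energyForward(G, H, model$head, model$temperature),
        row.names = NULL)
}

#' Descriptor comparison table
#'
#' Scores each descriptor table with both baseline methods: (a) the two-head
#' readout trained with the two-stage protocol (GNN removed) and (b) the
#' restricted linear regression against the rate constant, always with the
#' unchanged Hammett substrate features alongside. Reported metric is R^2 in
#' rate-constant space per split.
#'
#' @param splits list with `train`, `val`, `test` reaction data.frames (see
#'   [splitDataset()]).
#' @param descriptorTables named list of matrices from
#'   [buildDescriptorTable()].
#' @param hammett a `HammettTable`.
#' @param config a [trainConfig()] for the neural method.
#' @param nTrials training runs per descriptor for the neural method (best
#'   validation R^2 reported).
#' @param seed base seed.
#' @return data.frame: descriptor, method, train_r2, val_r2, test_r2.
#' @export
compareDescriptors <- function(splits, descriptorTables, hammett,
                               config = trainConfig(), nTrials = 5L,
                               seed = 1L) {
  rows <- list()
  for (nm in names(descriptorTables)) {
    D <- descriptorTables[[nm]]
    runs <- lapply(seq_len(nTrials), function(i) {
      cfg <- config
      cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
      trainBaseline(splits$train, splits$val, D, hammett, cfg)
    })
    ok <- vapply(runs, function(r)
      r@status != "rejected_fluctuation" && is.finite(r@valR2), logical(1))
    scored <- if (any(ok)) runs[ok] else runs
    best <- scored[[which.max(vapply(scored, function(r) r@valR2,
                                     numeric(1)))]]
    r2s <- vapply(splits, function(sp) {
      p <- predictBaselineModel(best@model, sp, hammett)
      .r2(sp$k_obs, p$k_pred)
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(descriptor = nm, method = "fcnn", train_r2 = r2s[["train"]],
                 val_r2 = r2s[["val"]], test_r2 = r2s[["test"]])
    feat <- function(sp) cbind(.hammettMatrix(sp, hammett),
                               D[sp$ligand_id, , drop = FALSE])
    fitLin <- restrictedLinearFit(feat(splits$train), splits$train$k_obs)
    r2l <- vapply(splits, function(sp)
      .r2(sp$k_obs, drop(feat(sp) %*% fitLin$coefficients)), numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(descriptor = nm, method = "restricted_linear",
                 train_r2 = r2l[["train"]], val_r2 = r2l[["val"]],
                 test_r2 = r2l[["test"]])
  }
  do.call(rbind, rows)
}
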