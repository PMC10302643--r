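#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm runif setNames quantile median cor sd
#' @importFrom utils read.csv write.csv head
NULL

#' Phosphorus-rooted layered ligand tree
#'
#' A trivalent phosphine ligand represented as a tree radiating from the
#' phosphorus atom. Hydrogens are suppressed; every node is a carbon atom whose
#' `layer` is its bond-count distance from the root. Ring closures are kept as
#' extra edges between nodes of equal or adjacent layers; no node duplication
#' is used. After [canonicalize()] each node additionally carries a `path`
#' string (priority ranks per layer, e.g. `"2.1.3"`) that defines its position
#' in the canonical layout.
#'
#' @slot name ligand label.
#' @slot nodes data.frame with columns `id` (integer, 1..n after build),
#'   `element` (currently always `"C"`), `layer` (integer >= 1) and `path`
#'   (character, `NA` until canonicalized).
#' @slot edges data.frame with columns `i`, `j` (integer node ids, `0` denotes
#'   the phosphorus root) and `order` (1, 1.5 or 2).
#' @slot canonical logical flag set by [canonicalize()].
#' @seealso [buildTree()], [canonicalize()], [encodeGraph()]
#' @export
setClass("LigandTree",
         representation(name = "character", nodes = "data.frame",
                        edges = "data.frame", canonical = "logical"))

setValidity("LigandTree", function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "element", "layer", "path") %in% names(nd)))
    msg <- c(msg, "nodes must have columns id, element, layer, path")
  if (!all(c("i", "j", "order") %in% names(ed)))
    msg <- c(msg, "edges must have columns i, j, order")
  if (nrow(nd)) {
    if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
    if (any(nd$layer < 1L)) msg <- c(msg, "layers must be >= 1")
    if (!all(nd$element == "C"))
      msg <- c(msg, "only carbon nodes are supported")
  }
  if (nrow(ed)) {
    ids <- c(0L, nd$id)
    if (!all(ed$i %in% ids) || !all(ed$j %in% ids))
      msg <- c(msg, "edge endpoints must reference the root (0) or node ids")
    if (!all(ed$order %in% c(1, 1.5, 2)))
      msg <- c(msg, "bond orders must be 1, 1.5 or 2")
  }
  if (length(msg)) msg else TRUE
})

#' Fixed slot template over a ligand set
#'
#' The per-position maximum branching pattern across a collection of canonical
#' ligand trees. Each slot is identified by its canonical path; slots are
#' ordered layer-major then priority-minor so that every ligand in the
#' generating set encodes to an equal-length vector.
#'
#' @slot paths character vector of canonical slot paths, in slot order.
#' @seealso [buildTemplate()], [encodeGraph()]
#' @export
setClass("GraphTemplate", representation(paths = "character"))

setValidity("GraphTemplate", function(object) {
  p <- object@paths
  if (!length(p)) return("template must have at least one slot")
  if (anyDuplicated(p)) return("slot paths must be unique")
  TRUE
})

#' Aligned Boolean graph encoding of a ligand
#'
#' Fixed-length encoding of a canonical [LigandTree-class] against a
#' [GraphTemplate-class]: a Boolean presence vector over the template slots
#' plus a symmetric bond-order matrix over the slots together with the
#' always-present phosphorus root (matrix row/column 1).
#'
#' @slot ligand ligand label.
#' @slot presence numeric vector of 0/1, one entry per template slot.
#' @slot edgeOrder symmetric numeric matrix of dimension
#'   `(totalSlots + 1) x (totalSlots + 1)` with entries in \{0, 1, 1.5, 2\};
#'   index 1 is the phosphorus root.
#' @seealso [encodeGraph()], [runMpnn()]
#' @export
setClass("AlignedGraph",
         representation(ligand = "character", presence = "numeric",
                        edgeOrder = "matrix"))

setValidity("AlignedGraph", function(object) {
  msg <- character()
  n <- length(object@presence)
  E <- object@edgeOrder
  if (!all(object@presence %in% c(0, 1)))
    msg <- c(msg, "presence must be Boolean (0/1)")
  if (!all(dim(E) == n + 1L))
    msg <- c(msg, "edgeOrder must be (totalSlots+1) square")
  else {
    if (!isTRUE(all.equal(E, t(E)))) msg <- c(msg, "edgeOrder must be symmetric")
    if (any(diag(E) != 0)) msg <- c(msg, "edgeOrder diagonal must be zero")
    if (!all(E %in% c(0, 1, 1.5, 2)))
      msg <- c(msg, "edge orders must be 0, 1, 1.5 or 2")
    pres <- c(1, object@presence)   # root always present
    bad <- which(E > 0, arr.ind = TRUE)
    if (nrow(bad) && any(pres[bad[, 1]] == 0 | pres[bad[, 2]] == 0))
      msg <- c(msg, "edges may only join present slots")
  }
  if (length(msg)) msg else TRUE
})

#' Bias-free weight-tied message-passing parameters
#'
#' Parameters of the GNN layer: a linear message map from the concatenation
#' `(h_i, h_j, e_ij)` to a message of dimension `dm`, and a linear update map
#' from `(h_i, m_i)` back to a scalar hidden state. The same weights are
#' applied at every iteration; there are no bias terms, so the all-zero state
#' is a fixed point and vacant edgeless slots stay exactly zero. The message
#' map is followed by a leaky ReLU; the update map is linear by default
#' (`updateLeaky` controls whether it is activated too).
#'
#' @slot Wm message weights, a `dm x 3` matrix.
#' @slot Wu update weights, a numeric vector of length `1 + dm`.
#' @slot iterations number of message-passing iterations (3-5).
#' @slot leakySlope negative-branch slope of the leaky ReLU (0.01).
#' @slot updateLeaky whether the update output is also passed through the
#'   leaky ReLU (`FALSE`: linear update, hidden states may be negative at
#'   full scale). The training protocol specifies the activation for the GNN
#'   layer without saying whether it covers the update function; see the
#'   methods vignette for the sensitivity analysis behind the default.
#' @seealso [newMpnnParams()], [runMpnn()]
#' @export
setClass("MpnnParams",
         representation(Wm = "matrix", Wu = "numeric", iterations = "integer",
                        leakySlope = "numeric", updateLeaky = "logical"))

setValidity("MpnnParams", function(object) {
  msg <- character()
  dm <- nrow(object@Wm)
  if (ncol(object@Wm) != 3L) msg <- c(msg, "Wm must have 3 columns (h_i, h_j, e_ij)")
  if (!dm %in% 2:4) msg <- c(msg, "message dimension must be 2, 3 or 4")
  if (length(object@Wu) != 1L + dm)
    msg <- c(msg, "Wu must have length 1 + message dimension")
  if (!object@iterations %in% 3:5) msg <- c(msg, "iterations must be 3, 4 or 5")
  if (object@leakySlope < 0 || object@leakySlope >= 1)
    msg <- c(msg, "leakySlope must lie in [0, 1)")
  if (!all(is.finite(object@Wm)) || !all(is.finite(object@Wu)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Constrained two-head free-energy readout
#'
#' The readout that decomposes the activation free energy. A sigmoid unit over
#' the concatenated Hammett vector and GNN output states gives the
#' ligand-substrate hidden state; a second sigmoid unit with non-negative
#' weights over the GNN output states alone gives the ligand-only hidden
#' state. Two non-negative final weights scale the hidden states into
#' `dG_LS` and `dG_L` (kcal/mol); no layer has a bias.
#'
#' @slot wH1 weights of the ligand-substrate unit, length `2 + totalSlots`
#'   (the two Hammett entries first); L2-regularized, unconstrained sign.
#' @slot wH2 weights of the ligand-only unit, length `totalSlots`;
#'   L2-regularized and non-negative.
#' @slot wFinal two non-negative scalars `c(LS, L)` scaling the hidden states.
#' @slot l2 L2 regularization strength applied to `wH1` and `wH2`.
#' @seealso [newEnergyHead()], [energyForward()]
#' @export
setClass("EnergyHead",
         representation(wH1 = "numeric", wH2 = "numeric", wFinal = "numeric",
                        l2 = "numeric"))

setValidity("EnergyHead", function(object) {
  msg <- character()
  if (length(object@wH1) != length(object@wH2) + 2L)
    msg <- c(msg, "wH1 must be 2 entries longer than wH2 (Hammett block)")
  if (length(object@wFinal) != 2L) msg <- c(msg, "wFinal must have length 2")
  if (any(object@wH2 < 0)) msg <- c(msg, "wH2 must be non-negative")
  if (any(object@wFinal < 0)) msg <- c(msg, "wFinal must be non-negative")
  if (object@l2 < 0) msg <- c(msg, "l2 must be non-negative")
  if (!all(is.finite(c(object@wH1, object@wH2, object@wFinal))))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Full rate-constant prediction model
#'
#' Bundles the frozen slot template, the message-passing parameters, the
#' two-head energy readout and the reaction temperature into one predictor.
#'
#' @slot template the [GraphTemplate-class] the model was trained against.
#' @slot mpnn [MpnnParams-class].
#' @slot head [EnergyHead-class]; its weight lengths must match the template.
#' @slot temperature reaction temperature in kelvin used for Eyring
#'   conversions.
#' @seealso [trainTwoStage()], [predictReactions()]
#' @export
setClass("RateModel",
         representation(template = "GraphTemplate", mpnn = "MpnnParams",
                        head = "EnergyHead", temperature = "numeric"))

setValidity("RateModel", function(object) {
  n <- length(object@template@paths)
  if (length(object@head@wH2) != n)
    return("head dimensions do not match template slot count")
  if (object@temperature <= 0) return("temperature must be positive (kelvin)")
  TRUE
})

#' Result of one two-stage training run
#'
#' @slot model the trained [RateModel-class] (or descriptor-swap equivalent;
#'   see [trainBaseline()]).
#' @slot status one of `"completed"`, `"converged_early"`,
#'   `"rejected_fluctuation"`, `"stage1_cutoff_not_reached"`.
#' @slot lossHistory per-batch training losses (stage-dependent units).
#' @slot stageSwitch batch index at which stage 2 began (`NA` if never).
#' @slot epochsRun number of epochs actually executed.
#' @slot valR2 coefficient of determination on the validation split, in
#'   rate-constant space.
#' @slot valMae mean absolute error on the validation split, in rate-constant
#'   space.
#' @slot config the [trainConfig()] list used.
#' @export
setClass("TrainResult",
         representation(model = "ANY", status = "character",
                        lossHistory = "numeric", stageSwitch = "integer",
                        epochsRun = "integer", valR2 = "numeric",
                        valMae = "numeric", config = "list"))

setValidity("TrainResult", function(object) {
  ok <- c("completed", "converged_early", "rejected_fluctuation",
          "stage1_cutoff_not_reached")
  if (!object@status %in% ok)
    return(sprintf("status must be one of: %s", paste(ok, collapse = ", ")))
  TRUE
})

#' Threshold-gated model ensemble
#'
#' Up to ten training runs, each passing the validation thresholds
#' (R^2 > `r2Threshold`, MAE < `maeThreshold`), kept in decreasing order of
#' validation R^2. The ensemble prediction is the arithmetic mean of member
#' predictions in rate-constant space, with the energy components averaged
#' alongside for reporting.
#'
#' @slot members list of [TrainResult-class] objects.
#' @slot r2Threshold validation R^2 threshold used at selection.
#' @slot maeThreshold validation MAE threshold used at selection.
#' @seealso [selectAndEnsemble()], [predictEnsemble()]
#' @export
setClass("ModelEnsemble",
         representation(members = "list", r2Threshold = "numeric",
                        maeThreshold = "numeric"))

setValidity("ModelEnsemble", function(object) {
  if (!length(object@members)) return("ensemble must have at least one member")
  if (length(object@members) > 10L) return("ensemble keeps at most 10 members")
  for (m in object@members) {
    if (!is(m, "TrainResult")) return("members must be TrainResult objects")
    if (!(m@valR2 > object@r2Threshold && m@valMae < object@maeThreshold))
      return("every member must satisfy both validation thresholds")
  }
  TRUE
})
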