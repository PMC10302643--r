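#' @include AllClasses.R
NULL

#' Canonicalize a ligand tree
#'
#' Orders sibling branches within every layer by a CIP-like hierarchical
#' digraph comparison (higher priority first) and assigns each node a unique
#' canonical path. The output is independent of the input node ordering;
#' truly identical branches keep their input order, which cannot affect any
#' downstream encoding.
#'
#' @param tree a [LigandTree-class].
#' @return a canonical [LigandTree-class] with nodes renumbered in slot order
#'   and `path` filled in.
#' @examples
#' tr <- canonicalize(buildTree(phosphineSpec("PMe3", c("Me", "Me", "Me"))))
#' treeNodes(tr)$path
#' @export
setGeneric("canonicalize", function(tree) standardGeneric("canonicalize"))

#' Ligand name accessor
#' @param x a [LigandTree-class] or [AlignedGraph-class].
#' @return character label.
#' @export
setGeneric("ligandName", function(x) standardGeneric("ligandName"))

#' Node table accessor
#' @param x a [LigandTree-class].
#' @return data.frame of nodes (id, element, layer, path).
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' Edge table accessor
#' @param x a [LigandTree-class].
#' @return data.frame of edges (i, j, order); `0` denotes the phosphorus root.
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' Steric bulk proxy of a ligand tree
#'
#' Counts the nodes in the first `maxLayer` layers; used by the synthetic
#' generator as the ground-truth steric descriptor and convenient for sorting
#' ligands by bulk near the metal center.
#'
#' @param x a [LigandTree-class].
#' @param maxLayer outermost layer counted (default 3).
#' @return integer node count.
#' @export
setGeneric("stericProxy", function(x, maxLayer = 3L) standardGeneric("stericProxy"))

#' Total slot count of a template or aligned graph
#' @param x a [GraphTemplate-class] or [AlignedGraph-class].
#' @return integer number of slots (the phosphorus root is not a slot).
#' @export
setGeneric("totalSlots", function(x) standardGeneric("totalSlots"))

#' Slot path accessor
#' @param x a [GraphTemplate-class].
#' @return character vector of canonical slot paths in slot order.
#' @export
setGeneric("templatePaths", function(x) standardGeneric("templatePaths"))

#' Boolean presence vector of an aligned graph
#' @param x an [AlignedGraph-class].
#' @return numeric 0/1 vector over template slots.
#' @export
setGeneric("nodePresence", function(x) standardGeneric("nodePresence"))

#' Bond-order matrix of an aligned graph
#' @param x an [AlignedGraph-class].
#' @return symmetric numeric matrix over root + slots.
#' @export
setGeneric("edgeOrder", function(x) standardGeneric("edgeOrder"))

#' Ensemble member accessor
#' @param x a [ModelEnsemble-class].
#' @return list of [TrainResult-class] members, best validation R^2 first.
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))

setMethod("ligandName", "LigandTree", function(x) x@name)
setMethod("ligandName", "AlignedGraph", function(x) x@ligand)
setMethod("treeNodes", "LigandTree", function(x) x@nodes)
setMethod("treeEdges", "LigandTree", function(x) x@edges)
setMethod("stericProxy", "LigandTree", function(x, maxLayer = 3L)
  sum(x@nodes$layer <= maxLayer))
setMethod("totalSlots", "GraphTemplate", function(x) length(x@paths))
setMethod("totalSlots", "AlignedGraph", function(x) length(x@presence))
setMethod("templatePaths", "GraphTemplate", function(x) x@paths)
setMethod("nodePresence", "AlignedGraph", function(x) x@presence)
setMethod("edgeOrder", "AlignedGraph", function(x) x@edgeOrder)
setMethod("ensembleMembers", "ModelEnsemble", function(x) x@members)

setMethod("show", "LigandTree", function(object) {
  cat(sprintf("LigandTree '%s': %d carbon nodes over %d layers%s\n",
              object@name, nrow(object@nodes),
              if (nrow(object@nodes)) max(object@nodes$layer) else 0L,
              if (object@canonical) " (canonical)" else ""))
  lay <- table(factor(object@nodes$layer,
                      levels = seq_len(max(c(object@nodes$layer, 1L)))))
  cat("  nodes per layer:", paste(as.integer(lay), collapse = " "), "\n")
  nring <- sum(object@edges$i != 0L) - sum(object@nodes$layer > 1L)
  cat(sprintf("  %d edges (%d ring closures)\n", nrow(object@edges),
              max(0L, nring)))
})

setMethod("show", "GraphTemplate", function(object) {
  lay <- lengths(regmatches(object@paths, gregexpr(".", object@paths,
                                                   fixed = TRUE))) + 1L
  cat(sprintf("GraphTemplate: %d slots over %d layers\n",
              length(object@paths), max(lay)))
  cat("  slots per layer:",
      paste(as.integer(table(factor(lay, levels = seq_len(max(lay))))),
            collapse = " "), "\n")
})

setMethod("show", "AlignedGraph", function(object) {
  cat(sprintf("AlignedGraph '%s': %d/%d slots occupied, %d bonds\n",
              object@ligand, sum(object@presence), length(object@presence),
              sum(object@edgeOrder[upper.tri(object@edgeOrder)] > 0)))
})

setMethod("show", "MpnnParams", function(object) {
  cat(sprintf(
    "MpnnParams: message dim %d, %d iterations, leaky slope %g, no bias\n",
    nrow(object@Wm), object@iterations, object@leakySlope))
})

setMethod("show", "EnergyHead", function(object) {
  cat(sprintf(
    "EnergyHead: %d slots; wFinal = (LS %.3g, L %.3g), l2 = %g\n",
    length(object@wH2), object@wFinal[1], object@wFinal[2], object@l2))
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel: %d-slot template, T = %.2f K\n",
              length(object@template@paths), object@temperature))
  show(object@mpnn)
  show(object@head)
})

setMethod("show", "TrainResult", function(object) {
  cat(sprintf(
    "TrainResult: status %s after %d epochs; val R^2 = %.3f, val MAE = %.3g\n",
    object@status, object@epochsRun, object@valR2, object@valMae))
})

setMethod("show", "ModelEnsemble", function(object) {
  r2 <- vapply(object@members, function(m) m@valR2, numeric(1))
  cat(sprintf(
    "ModelEnsemble: %d members (val R^2 %.3f .. %.3f; thresholds R^2 > %g, MAE < %g)\n",
    length(object@members), max(r2), min(r2), object@r2Threshold,
    object@maeThreshold))
})
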