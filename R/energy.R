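#' @include AllClasses.R
NULL

# physical constants (CODATA 2018 exact values); energies kcal/mol, T kelvin
.kB <- 1.380649e-23        # J/K
.hP <- 6.62607015e-34      # J s
.Rkcal <- 8.314462618 / 4184   # kcal mol^-1 K^-1

#' Physical constants used in the Eyring conversions
#'
#' @return named list with Boltzmann's constant `kB` (J/K), Planck's constant
#'   `h` (J s) and the gas constant `R` (kcal mol^-1 K^-1).
#' @export
eyringConstants <- function() list(kB = .kB, h = .hP, R = .Rkcal)

#' Convert an activation free energy to a rate constant
#'
#' Eyring equation `k = (kB T / h) exp(-Ea / (R T))` with `Ea` in kcal/mol.
#' Strictly decreasing in `Ea` and positive for every finite barrier.
#'
#' @param Ea activation free energy, kcal/mol (vectorized).
#' @param T absolute temperature, kelvin.
#' @return rate constant(s), 1/s.
#' @examples
#' eyringRateFromEnergy(0, 298.15)          # kB T / h
#' eyringRateFromEnergy(20, 298.15)
#' @export
eyringRateFromEnergy <- function(Ea, T = 298.15) {
  if (any(!is.finite(Ea))) stop("domain error: Ea must be finite")
  if (any(T <= 0)) stop("domain error: T must be positive")
  (.kB * T / .hP) * exp(-Ea / (.Rkcal * T))
}

#' Convert a rate constant to an activation free energy
#'
#' Inverse Eyring relation `Ea = R T log(kB T / (h k))`, kcal/mol. Exact
#' algebraic inverse of [eyringRateFromEnergy()].
#'
#' @param k rate constant(s), must be positive.
#' @param T absolute temperature, kelvin.
#' @return activation free energy in kcal/mol.
#' @export
eyringEnergyFromRate <- function(k, T = 298.15) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("domain error: k must be positive and finite")
  if (any(T <= 0)) stop("domain error: T must be positive")
  .Rkcal * T * log(.kB * T / (.hP * k))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Construct a two-head energy readout
#'
#' @param nSlots template slot count the readout must match.
#' @param l2 L2 regularization strength for `wH1` and `wH2`.
#' @param init `"random"` (Glorot-style for the sigmoid units; final weights
#'   uniform on the kcal/mol barrier scale, see the methods vignette) or
#'   `"zero"`.
#' @param wFinalRange range of the uniform initialization of the two final
#'   scale weights, kcal/mol. The default spans the activation free energies
#'   that correspond to rates measurable on laboratory timescales at ambient
#'   temperature, so initial predictions start on the physical barrier scale.
#' @param inputScale optional per-slot RMS of the readout inputs (the GNN
#'   output states or descriptor columns over the training ligands). Sigmoid
#'   unit weights are divided by it so the initial logits are O(1) regardless
#'   of the hidden-state magnitudes the message passing produces; without
#'   this the sigmoids start saturated and gradients vanish.
#' @return an [EnergyHead-class].
#' @export
newEnergyHead <- function(nSlots, l2 = 1e-4, init = c("random", "zero"),
                          wFinalRange = c(15, 30), inputScale = NULL) {
  init <- match.arg(init)
  if (is.null(inputScale)) inputScale <- rep(1, nSlots)
  ok <- is.finite(inputScale) & inputScale > 0
  inputScale[!ok] <- if (any(ok)) max(1e-3, stats::median(inputScale[ok]))
                     else 1
  if (init == "random") {
    wH1 <- rnorm(nSlots + 2L, sd = 1 / sqrt(nSlots + 2L)) /
      c(0.5, 0.5, inputScale)
    wH2 <- abs(rnorm(nSlots, sd = 1 / sqrt(nSlots))) / inputScale
    wFinal <- runif(2L, wFinalRange[1], wFinalRange[2])
  } else {
    wH1 <- numeric(nSlots + 2L); wH2 <- numeric(nSlots); wFinal <- c(0, 0)
  }
  new("EnergyHead", wH1 = wH1, wH2 = wH2,
      wFinal = setNames(wFinal, c("LS", "L")), l2 = l2)
}

#' Decomposed free-energy forward pass
#'
#' Computes the two sigmoid hidden states and scales them into the additive
#' decomposition: `dG_LS = wFinal["LS"] * sigmoid(wH1 . c(hammett, gnnOut))`,
#' `dG_L = wFinal["L"] * sigmoid(wH2 . gnnOut)`, `dG_total = dG_LS + dG_L`,
#' and the Eyring-predicted rate constant at temperature `T`. Refuses to run
#' if the non-negativity constraints on `wH2`/`wFinal` are violated.
#'
#' @param gnnOut GNN output states (vector or matrix with one row per
#'   reaction), length/cols = `length(head@wH2)`.
#' @param hammett Hammett vector `c(sigma_meta, sigma_para)` (or matrix with
#'   one row per reaction).
#' @param head an [EnergyHead-class].
#' @param T temperature, kelvin.
#' @return data.frame with columns `dG_LS`, `dG_L`, `dG_total`, `k_pred`, `T`
#'   (kcal/mol, 1/s, kelvin), one row per reaction.
#' @examples
#' head <- newEnergyHead(3, init = "zero")
#' head@wFinal[] <- c(10, 8)
#' energyForward(c(0, 0, 0), c(0, 0), head)   # sigmoid(0) = 0.5 each
#' @export
energyForward <- function(gnnOut, hammett, head, T = 298.15) {
  if (any(head@wH2 < 0) || any(head@wFinal < 0))
    stop("constraint error: non-negative weights violated in EnergyHead")
  G <- if (is.matrix(gnnOut)) gnnOut else matrix(gnnOut, nrow = 1)
  H <- if (is.matrix(hammett)) hammett else matrix(hammett, nrow = 1,
                                                   ncol = 2, byrow = TRUE)
  if (ncol(G) != length(head@wH2))
    stop(sprintf("shape error: gnnOut has %d columns, head expects %d",
                 ncol(G), length(head@wH2)))
  if (nrow(H) == 1L && nrow(G) > 1L) H <- H[rep(1L, nrow(G)), , drop = FALSE]
  hLS <- .sigmoid(drop(cbind(H, G) %*% head@wH1))
  hL <- .sigmoid(drop(G %*% head@wH2))
  dG_LS <- head@wFinal[["LS"]] * hLS
  dG_L <- head@wFinal[["L"]] * hL
  dG <- dG_LS + dG_L
  data.frame(dG_LS = dG_LS, dG_L = dG_L, dG_total = dG,
             k_pred = eyringRateFromEnergy(dG, T), T = T)
}

#' Predict reactions with a trained model
#'
#' Runs the full forward pipeline (aligned-graph encoding, message passing,
#' two-head readout, Eyring conversion) over a reaction table.
#'
#' @param model a [RateModel-class].
#' @param reactions data.frame with columns `ligand_id`, `substituent`,
#'   `position` (see [readReactionTable()]).
#' @param trees named list of [LigandTree-class] objects covering every
#'   `ligand_id`.
#' @param hammett a `HammettTable`; defaults to the bundled table.
#' @return `reactions` with the [energyForward()] columns appended.
#' @export
predictReactions <- function(model, reactions, trees,
                             hammett = readHammettTable()) {
  miss <- setdiff(unique(reactions$ligand_id), names(trees))
  if (length(miss))
    stop(sprintf("no tree for ligand(s): %s", paste(miss, collapse = ", ")))
  gOut <- gnnOutputs(model, trees)
  G <- gOut[reactions$ligand_id, , drop = FALSE]
  H <- t(mapply(encodeSubstrate, reactions$substituent, reactions$position,
                MoreArgs = list(table = hammett)))
  cbind(reactions,
        energyForward(G, H, model@head, model@temperature),
        row.names = NULL)
}

#' Per-ligand GNN output states under a model
#'
#' @param model a [RateModel-class] (its frozen template is used).
#' @param trees named list of [LigandTree-class] objects.
#' @return numeric matrix, one row per ligand, `totalSlots` columns.
#' @export
gnnOutputs <- function(model, trees) {
  out <- t(vapply(trees, function(tr)
    runMpnn(encodeGraph(tr, model@template), model@mpnn),
    numeric(length(model@template@paths))))
  rownames(out) <- names(trees)
  out
}
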