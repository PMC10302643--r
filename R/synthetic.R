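#' @include AllClasses.R ligandTree.R energy.R
NULL

#' Generative ground truth for synthetic reaction datasets
#'
#' Additive free-energy model used by [generateReactionDataset()]:
#' `dG_L* = max(0, a0 - a1 * s)` (bulkier ligands lower the ligand-only
#' barrier) and `dG_LS* = max(0, b0 + b1 * s - b2 * sigma_eff)` (bulk crowds
#' the cooperative term slightly; electron-withdrawing substituents lower
#' it), with `s` the node count in layers 1-3 and `sigma_eff` the sum of the
#' two Hammett entries (one of which is always zero for mono-substituted
#' substrates). Gaussian noise of sd `noise_sd` is added to the total free
#' energy before Eyring conversion. Defaults keep `dG_LS` generally larger
#' than `dG_L`; see the methods vignette.
#'
#' @param a0,a1 ligand-term intercept and steric slope, kcal/mol (per node).
#' @param b0,b1,b2 interaction-term intercept, steric slope and Hammett
#'   slope, kcal/mol.
#' @param noise_sd free-energy noise sd, kcal/mol.
#' @param T temperature, kelvin.
#' @param seed integer seed for the noise draw.
#' @return a named list of class `GenerativeTruth`.
#' @export
generativeTruth <- function(a0 = 12, a1 = 0.3, b0 = 14, b1 = 0.1, b2 = 2.0,
                            noise_sd = 0.05, T = 298.15, seed = 1L) {
  tr <- list(a0 = a0, a1 = a1, b0 = b0, b1 = b1, b2 = b2,
             noise_sd = noise_sd, T = T, seed = as.integer(seed))
  if (noise_sd < 0 || T <= 0) stop("noise_sd must be >= 0 and T > 0")
  class(tr) <- c("GenerativeTruth", "list")
  tr
}

#' Generate a ligand set spanning a bulk gradient
#'
#' Emits `nLigands` trialkyl/arylalkyl phosphine trees whose steric proxies
#' (node counts in layers 1-3) sweep from the smallest to the largest
#' substituent in the branching law. The first ligand is always the pure
#' triple of the smallest substituent and the last the pure triple of the
#' largest; intermediate ligands take their primary substituent along the
#' gradient and draw the other two from the pool below it.
#'
#' @param nLigands number of ligands (>= 2).
#' @param branchingLaw character vector of substituent names from
#'   [substituentNames()], ordered from least to most bulky.
#' @param seed integer seed; identical seeds give identical trees.
#' @return named list of [LigandTree-class] objects (`SL01`, `SL02`, ...).
#' @examples
#' trees <- generateLigandSet(2, branchingLaw = c("Me", "tBu"), seed = 1)
#' vapply(trees, stericProxy, integer(1))   # 3 and 12
#' @export
generateLigandSet <- function(nLigands,
                              branchingLaw = c("Me", "Et", "iPr", "nBu",
                                               "tBu", "Cy", "Bn", "Ad"),
                              seed = 1L) {
  if (nLigands < 2L) stop("need at least 2 ligands")
  unknown <- setdiff(branchingLaw, substituentNames())
  if (length(unknown))
    stop(sprintf("impossible branching law: unknown substituent(s) %s",
                 paste(unknown, collapse = ", ")))
  np <- length(branchingLaw)
  if (np < 2L) stop("impossible branching law: need >= 2 substituent sizes")
  primary <- round(seq(1L, np, length.out = nLigands))
  .withSeed(seed, {
    trees <- lapply(seq_len(nLigands), function(i) {
      subs <- if (i == 1L) rep(branchingLaw[1L], 3L)
              else if (i == nLigands) rep(branchingLaw[np], 3L)
              else c(branchingLaw[primary[i]],
                     sample(branchingLaw[seq_len(primary[i])], 2L,
                            replace = TRUE))
      buildTree(subs, name = sprintf("SL%02d", i))
    })
    setNames(trees, vapply(trees, ligandName, character(1)))
  })
}

#' Generate a synthetic substituent panel
#'
#' Substituents `X01..Xnn` with Hammett constants drawn uniformly from
#' [-0.8, 0.8] and a random meta/para position each, mirroring the
#' composition of a mono-substituted aryl bromide screen. Returns both the
#' substrate assignments and a `HammettTable` covering them (each synthetic
#' substituent gets the same constant at both positions; only the assigned
#' one is ever used).
#'
#' @param nSubstituents panel size (default 20).
#' @param sigmaRange range of the uniform sigma draw.
#' @param seed integer seed.
#' @return list with `substrates` (data.frame: substituent, position, sigma)
#'   and `table` (a `HammettTable`).
#' @export
generateSubstituentSet <- function(nSubstituents = 20L,
                                   sigmaRange = c(-0.8, 0.8), seed = 1L) {
  .withSeed(seed, {
    sigma <- runif(nSubstituents, sigmaRange[1], sigmaRange[2])
    position <- sample(c("meta", "para"), nSubstituents, replace = TRUE)
    substrates <- data.frame(
      substituent = sprintf("X%02d", seq_len(nSubstituents)),
      position = position, sigma = sigma, stringsAsFactors = FALSE)
    tab <- data.frame(
      substituent = c("H", substrates$substituent),
      sigma_meta = c(0, sigma), sigma_para = c(0, sigma))
    class(tab) <- c("HammettTable", "data.frame")
    list(substrates = substrates, table = tab)
  })
}

#' Generate a full-factorial synthetic reaction dataset
#'
#' Crosses every ligand with every substituent, computes the additive
#' ground-truth free energies of the [generativeTruth()] model, adds Gaussian
#' noise to the total and converts to rate constants with the Eyring equation
#' at the truth temperature. The truth components are recorded per row so
#' parameter-recovery tests can compare fitted decompositions against the
#' generative ones.
#'
#' @param trees named list of [LigandTree-class] objects.
#' @param substrates data.frame with columns `substituent`, `position`,
#'   `sigma` (see [generateSubstituentSet()]).
#' @param truth a [generativeTruth()].
#' @return list with `reactions` (ligand_id, substituent, position, k_obs,
#'   temperature_K) and `truth` (the same rows plus s, sigma_eff, dG_L_true,
#'   dG_LS_true, dG_true, noise).
#' @examples
#' trees <- generateLigandSet(3, seed = 1)
#' subs <- generateSubstituentSet(4, seed = 2)
#' ds <- generateReactionDataset(trees, subs$substrates, generativeTruth())
#' nrow(ds$reactions)   # 12
#' @export
generateReactionDataset <- function(trees, substrates,
                                    truth = generativeTruth()) {
  if (!all(is.finite(substrates$sigma))) stop("sigma values must be finite")
  s <- vapply(trees, stericProxy, integer(1))
  grid <- expand.grid(ligand_id = names(trees),
                      sub = seq_len(nrow(substrates)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sigEff <- substrates$sigma[grid$sub]
  sRow <- s[grid$ligand_id]
  dG_L <- pmax(0, truth$a0 - truth$a1 * sRow)
  dG_LS <- pmax(0, truth$b0 + truth$b1 * sRow - truth$b2 * sigEff)
  noise <- .withSeed(truth$seed, rnorm(nrow(grid), 0, truth$noise_sd))
  dG <- dG_L + dG_LS + noise
  reactions <- data.frame(
    ligand_id = grid$ligand_id,
    substituent = substrates$substituent[grid$sub],
    position = substrates$position[grid$sub],
    k_obs = eyringRateFromEnergy(dG, truth$T),
    temperature_K = truth$T, stringsAsFactors = FALSE)
  truthTab <- cbind(reactions[c("ligand_id", "substituent", "position")],
                    data.frame(s = unname(sRow), sigma_eff = sigEff,
                               dG_L_true = unname(dG_L),
                               dG_LS_true = unname(dG_LS),
                               dG_true = unname(dG_L + dG_LS),
                               noise = noise))
  list(reactions = reactions, truth = truthTab)
}
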