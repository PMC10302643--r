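#' @include AllClasses.R train.R
NULL

.reactionCols <- c("ligand_id", "substituent", "position", "k_obs",
                   "temperature_K")

.validateReactions <- function(df, where = "reaction table") {
  miss <- setdiff(.reactionCols, names(df))
  if (length(miss))
    stop(sprintf("schema error in %s: missing column(s) %s", where,
                 paste(miss, collapse = ", ")))
  bad <- which(!is.finite(df$k_obs) | df$k_obs <= 0)
  if (length(bad))
    stop(sprintf("validation error in %s: non-positive k_obs in row %s",
                 where, paste(bad, collapse = ", ")))
  bad <- which(!df$position %in% c("meta", "para"))
  if (length(bad))
    stop(sprintf("validation error in %s: invalid position in row %s",
                 where, paste(bad, collapse = ", ")))
  bad <- which(!is.finite(df$temperature_K) | df$temperature_K <= 0)
  if (length(bad))
    stop(sprintf("validation error in %s: non-positive temperature in row %s",
                 where, paste(bad, collapse = ", ")))
  df
}

#' Read a reaction table
#'
#' CSV schema: `ligand_id, substituent, position, k_obs, temperature_K`.
#' Rows are validated (positive rate constants and temperatures, meta/para
#' positions) with offending row numbers reported.
#'
#' @param path CSV file.
#' @return validated data.frame with a `row` column attached for error
#'   reporting.
#' @export
readReactionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .validateReactions(df, sprintf("'%s'", path))
  df$row <- seq_len(nrow(df))
  df
}

#' Write a reaction table
#'
#' @param reactions reaction data.frame (validated before writing).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeReactionTable <- function(reactions, path) {
  reactions <- .validateReactions(reactions)
  write.csv(reactions[.reactionCols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write prediction and decomposition reports
#'
#' Emits two CSVs into `outDir`: `predictions.csv` with the per-reaction
#' ensemble-mean rate constant and free-energy components, and
#' `ligand_dG_L_summary.csv` with the distribution (min, q1, median, q3, max)
#' of the ligand-only free energy across the ensemble members per ligand,
#' sorted by ascending median — the tabular equivalent of the boxplot
#' display of the selected parameter sets.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param reactions reaction data.frame.
#' @param trees named list of [LigandTree-class] (ignored for baselines).
#' @param hammett a `HammettTable`.
#' @param outDir output directory, created if missing.
#' @return named character vector of the files written, invisibly.
#' @export
writeReport <- function(ensemble, reactions, trees,
                        hammett = readHammettTable(), outDir = ".") {
  if (!is(ensemble, "ModelEnsemble")) stop("ensemble must be a ModelEnsemble")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pred <- predictEnsemble(ensemble, reactions, trees, hammett)
  members <- attr(pred, "members")
  predPath <- file.path(outDir, "predictions.csv")
  write.csv(pred[c(.reactionCols[.reactionCols %in% names(pred)],
                   "dG_L", "dG_LS", "dG_total", "k_pred")],
            predPath, row.names = FALSE, quote = FALSE)
  # dG_L depends only on the ligand: one value per ligand per member
  ligands <- unique(reactions$ligand_id)
  perMember <- vapply(members, function(p)
    vapply(ligands, function(l)
      mean(p$dG_L[reactions$ligand_id == l]), numeric(1)),
    numeric(length(ligands)))
  perMember <- matrix(perMember, nrow = length(ligands),
                      dimnames = list(ligands, NULL))
  qs <- t(apply(perMember, 1, quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
                names = FALSE))
  summ <- data.frame(ligand_id = ligands, min = qs[, 1], q1 = qs[, 2],
                     median = qs[, 3], q3 = qs[, 4], max = qs[, 5])
  summ <- summ[order(summ$median), ]
  sumPath <- file.path(outDir, "ligand_dG_L_summary.csv")
  write.csv(summ, sumPath, row.names = FALSE, quote = FALSE)
  invisible(c(predictions = predPath, ligand_summary = sumPath))
}
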