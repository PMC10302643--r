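#' @include AllClasses.R train.R
NULL

.modelToList <- function(model) {
  if (is(model, "RateModel")) {
    list(kind = "mpnn",
         template = model@template@paths,
         Wm = as.numeric(model@mpnn@Wm), dm = nrow(model@mpnn@Wm),
         Wu = model@mpnn@Wu,
         iterations = model@mpnn@iterations,
         leakySlope = model@mpnn@leakySlope,
         updateLeaky = model@mpnn@updateLeaky,
         wH1 = model@head@wH1, wH2 = model@head@wH2,
         wFinal = as.numeric(model@head@wFinal), l2 = model@head@l2,
         temperature = model@temperature)
  } else {
    list(kind = "descriptor",
         ligands = rownames(model$descriptors),
         descriptors = as.numeric(model$descriptors),
         p = ncol(model$descriptors),
         wH1 = model$head@wH1, wH2 = model$head@wH2,
         wFinal = as.numeric(model$head@wFinal), l2 = model$head@l2,
         temperature = model$temperature)
  }
}

.modelFromList <- function(x) {
  if (x$kind == "mpnn") {
    new("RateModel",
        template = new("GraphTemplate", paths = unlist(x$template)),
        mpnn = new("MpnnParams",
                   Wm = matrix(unlist(x$Wm), x$dm, 3L),
                   Wu = unlist(x$Wu), iterations = as.integer(x$iterations),
                   leakySlope = x$leakySlope,
                   updateLeaky = isTRUE(x$updateLeaky)),
        head = new("EnergyHead", wH1 = unlist(x$wH1), wH2 = unlist(x$wH2),
                   wFinal = setNames(unlist(x$wFinal), c("LS", "L")),
                   l2 = x$l2),
        temperature = x$temperature)
  } else {
    lig <- unlist(x$ligands)
    structure(
      list(descriptors = matrix(unlist(x$descriptors), length(lig),
                                x$p, dimnames = list(lig, NULL)),
           head = new("EnergyHead", wH1 = unlist(x$wH1),
                      wH2 = unlist(x$wH2),
                      wFinal = setNames(unlist(x$wFinal), c("LS", "L")),
                      l2 = x$l2),
           temperature = x$temperature),
      class = "BaselineModel")
  }
}

#' Serialize a trained model to JSON
#'
#' Flat named-array archive: every weight tensor is stored as a plain numeric
#' array under its name (`Wm` row-major by column, `Wu`, `wH1`, `wH2`,
#' `wFinal`) together with the slot template, iteration count, activation
#' settings and temperature, so the file is readable outside R.
#'
#' @param model a [RateModel-class] or `BaselineModel`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @seealso [readRateModel()], [writeEnsemble()]
#' @export
writeRateModel <- function(model, path) {
  jsonlite::write_json(.modelToList(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deserialize a trained model from JSON
#'
#' @param path file written by [writeRateModel()].
#' @return a [RateModel-class] or `BaselineModel`.
#' @export
readRateModel <- function(path) {
  .modelFromList(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Serialize a model ensemble to JSON
#'
#' Stores each member's parameter archive together with its validation
#' metrics, termination status and training configuration; per-batch loss
#' histories are not persisted.
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(ensemble, path) {
  payload <- list(
    r2Threshold = ensemble@r2Threshold,
    maeThreshold = ensemble@maeThreshold,
    members = lapply(ensemble@members, function(m)
      list(model = .modelToList(m@model), status = m@status,
           valR2 = m@valR2, valMae = m@valMae,
           config = m@config[!vapply(m@config, is.null, logical(1))])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Deserialize a model ensemble from JSON
#'
#' @param path file written by [writeEnsemble()].
#' @return a [ModelEnsemble-class] (members carry empty loss histories).
#' @export
readEnsemble <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  members <- lapply(x$members, function(m)
    new("TrainResult", model = .modelFromList(m$model), status = m$status,
        lossHistory = numeric(), stageSwitch = NA_integer_,
        epochsRun = NA_integer_, valR2 = m$valR2, valMae = m$valMae,
        config = m$config))
  new("ModelEnsemble", members = members, r2Threshold = x$r2Threshold,
      maeThreshold = x$maeThreshold)
}

#' Read a training configuration from JSON
#'
#' The file holds any subset of [trainConfig()]'s fields; omitted fields keep
#' their defaults and unknown fields are rejected.
#'
#' @param path JSON file.
#' @param ... overrides applied on top of the file's values.
#' @return a [trainConfig()].
#' @export
readTrainConfig <- function(path, ...) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  over <- list(...)
  x[names(over)] <- over
  known <- names(formals(trainConfig))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  do.call(trainConfig, x)
}

#' Write a training configuration to JSON
#'
#' @param config a [trainConfig()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTrainConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
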