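#' Accessors for the core classes
#'
#' `simX`, `simY`, `causalIndices`, `effectWeights` and `simConfig` extract
#' the covariate matrix, outcome, ground-truth causal set, effect sizes and
#' configuration of a [SimulatedDataset-class]. `rankedFeatures`,
#' `selectionScores`, `tunedParams` and `boTrace` extract the ranking,
#' per-feature scores, tuned hyper-parameters and tuning history of a
#' [SelectionResult-class]. `bestPoint`, `bestObjective` and `evaluations`
#' extract the optimum and history of a [BOTrace-class].
#'
#' @param object an object of the respective class.
#' @return the extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("simX", function(object) standardGeneric("simX"))
#' @rdname accessors
#' @export
setMethod("simX", "SimulatedDataset", function(object) object@X)

#' @rdname accessors
#' @export
setGeneric("simY", function(object) standardGeneric("simY"))
#' @rdname accessors
#' @export
setMethod("simY", "SimulatedDataset", function(object) object@y)

#' @rdname accessors
#' @export
setGeneric("causalIndices", function(object) standardGeneric("causalIndices"))
#' @rdname accessors
#' @export
setMethod("causalIndices", "SimulatedDataset", function(object) object@causalIndices)

#' @rdname accessors
#' @export
setGeneric("effectWeights", function(object) standardGeneric("effectWeights"))
#' @rdname accessors
#' @export
setMethod("effectWeights", "SimulatedDataset", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))
#' @rdname accessors
#' @export
setMethod("simConfig", "SimulatedDataset", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("rankedFeatures", function(object) standardGeneric("rankedFeatures"))
#' @rdname accessors
#' @export
setMethod("rankedFeatures", "SelectionResult", function(object) object@rankedIndices)

#' @rdname accessors
#' @export
setGeneric("selectionScores", function(object) standardGeneric("selectionScores"))
#' @rdname accessors
#' @export
setMethod("selectionScores", "SelectionResult", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("tunedParams", function(object) standardGeneric("tunedParams"))
#' @rdname accessors
#' @export
setMethod("tunedParams", "SelectionResult", function(object) object@hyperparams)

#' @rdname accessors
#' @export
setGeneric("boTrace", function(object) standardGeneric("boTrace"))
#' @rdname accessors
#' @export
setMethod("boTrace", "SelectionResult", function(object) object@trace)

#' @rdname accessors
#' @export
setGeneric("bestPoint", function(object) standardGeneric("bestPoint"))
#' @rdname accessors
#' @export
setMethod("bestPoint", "BOTrace", function(object) object@bestPoint)

#' @rdname accessors
#' @export
setGeneric("bestObjective", function(object) standardGeneric("bestObjective"))
#' @rdname accessors
#' @export
setMethod("bestObjective", "BOTrace", function(object) object@bestObjective)

#' @rdname accessors
#' @export
setGeneric("evaluations", function(object) standardGeneric("evaluations"))
#' @rdname accessors
#' @export
setMethod("evaluations", "BOTrace", function(object) object@evaluations)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: n =", object@n, ", p =", object@p,
      ", p0 =", object@p0, "\n",
      " effect model:", object@effectModel,
      "| outcome:", object@outcomeType,
      "| noise sd:", object@noiseSd,
      "| seed:", object@seed, "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cfg <- object@config
  cat("SimulatedDataset:", cfg@n, "samples x", cfg@p, "features,",
      cfg@p0, "causal (", cfg@effectModel, "/", cfg@outcomeType, ")\n")
})

setMethod("show", "HyperParameterSpace", function(object) {
  cat("HyperParameterSpace with", nrow(object@parameters), "parameter(s):\n")
  print(object@parameters, row.names = FALSE)
})

setMethod("show", "BOTrace", function(object) {
  cat("BOTrace:", nrow(object@evaluations), "evaluations (",
      object@nIterations, "iterations ), kappa =", object@kappa, "\n",
      " best objective:", format(object@bestObjective), "at",
      paste(names(object@bestPoint),
            vapply(object@bestPoint, function(v) format(v, digits = 4), ""),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", object@tuner, "-tuned", object@method, "ranking of",
      length(object@rankedIndices), "features (requested",
      object@nRequested, ")\n")
  k <- min(5L, length(object@rankedIndices))
  if (k) cat(" top:", paste(object@rankedIndices[seq_len(k)], collapse = " "), "\n")
})
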