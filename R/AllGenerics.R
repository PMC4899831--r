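#' @include AllClasses.R
NULL

#' Accessors for PatientSimRec objects
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortExtracts", function(x, ...) standardGeneric("cohortExtracts"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("generatorConfig", function(x, ...) standardGeneric("generatorConfig"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x, ...) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignment", function(x, ...) standardGeneric("clusterAssignment"))

#' @rdname accessors
#' @export
setGeneric("clusterCentroids", function(x, ...) standardGeneric("clusterCentroids"))

#' @rdname accessors
#' @export
setGeneric("clusterPlans", function(x, ...) standardGeneric("clusterPlans"))

#' @rdname accessors
#' @export
setGeneric("sizeFractions", function(x, ...) standardGeneric("sizeFractions"))

#' @rdname accessors
#' @export
setGeneric("mergeLog", function(x, ...) standardGeneric("mergeLog"))

#' @rdname accessors
#' @export
setGeneric("metricMatrix", function(x, ...) standardGeneric("metricMatrix"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x, ...) standardGeneric("nClusters"))

setMethod("cohortExtracts", "SyntheticCohort", function(x, ...) x@extracts)
setMethod("groundTruth", "SyntheticCohort", function(x, ...) x@groundTruth)
setMethod("generatorConfig", "SyntheticCohort", function(x, ...) x@config)
setMethod("featureNames", "EncodingSchema", function(x, ...) x@featureNames)
setMethod("clusterAssignment", "ClusteringResult", function(x, ...) x@assignment)
setMethod("clusterCentroids", "ClusteringResult", function(x, ...) x@centroids)
setMethod("clusterPlans", "ClusteringResult", function(x, ...) x@labelPlans)
setMethod("sizeFractions", "ClusteringResult", function(x, ...) x@sizeFractions)
setMethod("mergeLog", "ClusteringResult", function(x, ...) x@mergeLog)
setMethod("metricMatrix", "SPSDMatrix", function(x, ...) x@matrix)
setMethod("nClusters", "ClusteringResult", function(x, ...) nrow(x@centroids))

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  patients: %d  seed: %d\n", object@nPatients, object@seed))
  cat(sprintf("  continuous variables: %d  comorbidities: %d  plans: %d\n",
              nrow(object@continuousSpecs),
              length(object@comorbidityPrevalences),
              length(object@planFrequencies)))
  cat(sprintf("  responder rate: %.2f  latent groups: %d  separation: %.1f SD\n",
              object@responderRate, object@nLatentGroups,
              object@groupSeparation))
  cat(sprintf("  plan-group coupling: %.2f  plan-match effect: %.2f\n",
              object@planGroupCoupling, object@planMatchEffect))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients (seed %d)\n",
              nrow(object@extracts$patients), object@config@seed))
  cat(sprintf("  extracts: %s\n", paste(names(object@extracts), collapse = ", ")))
  cat(sprintf("  planted eligible: %d / %d\n",
              sum(object@groundTruth$planted_eligible),
              nrow(object@groundTruth)))
})

setMethod("show", "EncodingSchema", function(object) {
  cat(sprintf("EncodingSchema: d = %d features (%d continuous, %d one-hot, %d flags)\n",
              length(object@featureNames), nrow(object@continuous),
              length(object@featureNames) - nrow(object@continuous) -
                length(object@flags),
              length(object@flags)))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult (%s): %d clusters over %d patients\n",
              object@method, nrow(object@centroids), length(object@assignment)))
  sz <- sort(object@sizeFractions, decreasing = TRUE)
  cat(sprintf("  size fractions: %s\n",
              paste(sprintf("%.3f", sz), collapse = " ")))
  if (nrow(object@mergeLog) > 0)
    cat(sprintf("  merges performed: %d\n", nrow(object@mergeLog)))
})

setMethod("show", "SPSDMatrix", function(object) {
  cat(sprintf("SPSDMatrix %dx%d (%s, lambda = %.2f)\n",
              nrow(object@matrix), ncol(object@matrix), object@provenance,
              object@shrinkageLambda))
})
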