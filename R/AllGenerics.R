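#' Planted truth of a simulated study
#'
#' @param object a [SimulatedStudy-class].
#' @return the list of planted truths recorded by the generator.
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "SimulatedStudy", function(object) object@truth)

#' Configuration of a simulated study
#'
#' @param object a [SimulatedStudy-class].
#' @return the [SimConfig-class] used to generate the study.
#' @export
setGeneric("simConfigOf", function(object) standardGeneric("simConfigOf"))

#' @rdname simConfigOf
#' @export
setMethod("simConfigOf", "SimulatedStudy", function(object) object@config)

#' Differential protein abundance between genotype groups
#'
#' @param object a [ProteomicsExperiment-class] or a long-format
#'   data.frame of replicate quantifications.
#' @param ... further arguments passed to methods.
#' @return a data.frame of per-protein, per-fraction results; see the
#'   method documentation.
#' @export
setGeneric("differentialAbundance",
           function(object, ...) standardGeneric("differentialAbundance"))
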