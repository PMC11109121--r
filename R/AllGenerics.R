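#' Accessors for Cohort objects
#'
#' @param object a [Cohort-class].
#' @return \code{patients()}, \code{adjudications()} and
#'   \code{screeningCalls()} return the corresponding data.frame;
#'   \code{nPatients()} the number of patients.
#' @name cohort-accessors
#' @aliases patients adjudications screeningCalls nPatients
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))

#' @rdname cohort-accessors
#' @export
setGeneric("adjudications", function(object) standardGeneric("adjudications"))

#' @rdname cohort-accessors
#' @export
setGeneric("screeningCalls", function(object) standardGeneric("screeningCalls"))

#' @rdname cohort-accessors
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))

#' Predicted viability of a fitted dose-response curve
#'
#' @param object a [FourPL-class] fit.
#' @param conc numeric vector of concentrations (uM), all > 0.
#' @return numeric vector of predicted viability fractions (unclipped).
#' @export
setGeneric("predictViability",
           function(object, conc) standardGeneric("predictViability"))

#' Diagnostic metrics of a confusion matrix
#'
#' \code{sensitivity()} is the true-positive rate over clinically sensitive
#' patients, \code{specificity()} the true-negative rate over clinically
#' resistant patients, both as percentages in [0, 100]. \code{accuracy()}
#' is the overall fraction correct (percent) over evaluable patients. A zero
#' denominator raises an undefined-metric error.
#'
#' @param object a [ConfusionMatrix-class].
#' @return numeric scalar, percent (not rounded; round only for reporting).
#' @name concordance-metrics
#' @aliases sensitivity specificity accuracy
NULL

#' @rdname concordance-metrics
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname concordance-metrics
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname concordance-metrics
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
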