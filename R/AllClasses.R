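#' @import methods
NULL

#' Clinical cohort with adjudicated drug responses
#'
#' Container for one screening cohort: one row per patient in
#' \code{patients}, one row per patient x drug line in \code{adjudications}
#' (RECIST label plus the derived sensitive/resistant/not-evaluable
#' adjudication), and optionally the organoid screening calls in
#' \code{screeningCalls} (one row per patient x drug x index mode).
#'
#' @slot patients data.frame with columns \code{patient_id}, \code{sex},
#'   \code{age}, \code{smoking}, \code{stage_at_sampling}, \code{mutations}
#'   (semicolon-joined tokens).
#' @slot adjudications data.frame with columns \code{patient_id},
#'   \code{drug}, \code{line}, \code{recist_label}, \code{tumor_change_pct},
#'   \code{notes}, \code{adjudicated}.
#' @slot screeningCalls data.frame with columns \code{patient_id},
#'   \code{drug}, \code{mode}, \code{call} (may have zero rows).
#'
#' @seealso [loadCohort()], [adjudicate()], [buildConfusion()]
#' @export
setClass("Cohort",
  representation(
    patients       = "data.frame",
    adjudications  = "data.frame",
    screeningCalls = "data.frame"
  )
)

setValidity("Cohort", function(object) {
  p <- object@patients
  a <- object@adjudications
  s <- object@screeningCalls
  msgs <- character()
  need_p <- c("patient_id", "sex", "age", "smoking", "stage_at_sampling",
              "mutations")
  if (!all(need_p %in% names(p)))
    msgs <- c(msgs, paste("patients lacks columns:",
                          paste(setdiff(need_p, names(p)), collapse = ", ")))
  else {
    if (anyDuplicated(p$patient_id))
      msgs <- c(msgs, "duplicate patient_id in patients")
    if (nrow(p) && any(!is.finite(p$age) | p$age <= 0))
      msgs <- c(msgs, "age must be > 0")
  }
  need_a <- c("patient_id", "drug", "recist_label", "tumor_change_pct",
              "adjudicated")
  if (!all(need_a %in% names(a)))
    msgs <- c(msgs, paste("adjudications lacks columns:",
                          paste(setdiff(need_a, names(a)), collapse = ", ")))
  else if (nrow(a)) {
    if (!all(a$patient_id %in% p$patient_id))
      msgs <- c(msgs, "adjudication for unknown patient_id")
    if (anyDuplicated(a[, c("patient_id", "drug")]))
      msgs <- c(msgs, "duplicate (patient_id, drug) adjudication")
    bad <- setdiff(a$adjudicated, c("sensitive", "resistant", "not_evaluable"))
    if (length(bad))
      msgs <- c(msgs, paste("invalid adjudication label:",
                            paste(bad, collapse = ", ")))
  }
  if (nrow(s)) {
    need_s <- c("patient_id", "drug", "mode", "call")
    if (!all(need_s %in% names(s)))
      msgs <- c(msgs, paste("screeningCalls lacks columns:",
                            paste(setdiff(need_s, names(s)), collapse = ", ")))
    else if (!all(s$call %in% c("sensitive", "resistant")))
      msgs <- c(msgs, "screening call must be sensitive/resistant")
  }
  if (length(msgs)) msgs else TRUE
})

#' One patient x drug dilution series with replicate readouts
#'
#' Raw ATP-luminescence readouts for one organoid line exposed to one drug
#' over a descending concentration series, plus the vehicle (DMSO) control
#' wells that define 100\% viability.
#'
#' @slot patientId character scalar.
#' @slot drug character scalar.
#' @slot concentrations numeric, micromolar, strictly decreasing.
#' @slot replicates list of numeric vectors, one per concentration, each the
#'   raw readouts of the technical replicates at that dose.
#' @slot dmsoReadouts numeric, raw readouts of the DMSO control wells.
#'
#' @seealso [profilesFromPlate()], [normalizeViability()], [fitFourPL()]
#' @export
setClass("DoseResponseProfile",
  representation(
    patientId      = "character",
    drug           = "character",
    concentrations = "numeric",
    replicates     = "list",
    dmsoReadouts   = "numeric"
  )
)

setValidity("DoseResponseProfile", function(object) {
  msgs <- character()
  cc <- object@concentrations
  if (length(object@patientId) != 1L || length(object@drug) != 1L)
    msgs <- c(msgs, "patientId and drug must be scalars")
  if (length(cc) < 1L || any(!is.finite(cc)) || any(cc <= 0))
    msgs <- c(msgs, "concentrations must be positive and finite")
  if (length(cc) > 1L && any(diff(cc) >= 0))
    msgs <- c(msgs, "concentrations must be strictly decreasing")
  if (length(object@replicates) != length(cc))
    msgs <- c(msgs, "one replicate vector required per concentration")
  else if (any(vapply(object@replicates, length, 1L) < 1L))
    msgs <- c(msgs, "every concentration needs >= 1 replicate readout")
  if (length(object@dmsoReadouts) < 1L)
    msgs <- c(msgs, "dmsoReadouts must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' Parameters of the decreasing four-parameter logistic (4PL)
#' \deqn{v(c) = bottom + \frac{top - bottom}{1 + 10^{hill\,(\log_{10} c - \log_{10} EC_{50})}}}
#' so that viability falls from \code{top} towards \code{bottom} as the
#' concentration increases (\code{hill > 0}).
#'
#' @slot top,bottom viability fractions (asymptotes).
#' @slot log10EC50 log10 of the inflection concentration, log10(uM).
#' @slot hill positive slope factor.
#' @slot converged did the optimizer report convergence.
#' @slot fallbackUsed set when no trustworthy fit was obtained (optimizer
#'   failure, flat or non-monotone data); downstream AUC then uses the
#'   trapezoid on observed means instead of the curve.
#'
#' @seealso [fitFourPL()], [computeAUC()], [predictViability()]
#' @export
setClass("FourPL",
  representation(
    top          = "numeric",
    bottom       = "numeric",
    log10EC50    = "numeric",
    hill         = "numeric",
    converged    = "logical",
    fallbackUsed = "logical"
  ),
  prototype(top = NA_real_, bottom = NA_real_, log10EC50 = NA_real_,
            hill = NA_real_, converged = FALSE, fallbackUsed = FALSE)
)

setValidity("FourPL", function(object) {
  msgs <- character()
  if (!object@fallbackUsed) {
    if (!is.finite(object@top) || !is.finite(object@bottom) ||
        !is.finite(object@log10EC50) || !is.finite(object@hill))
      msgs <- c(msgs, "non-finite parameters in a non-fallback fit")
    else {
      if (object@bottom < 0 || object@bottom > object@top)
        msgs <- c(msgs, "need 0 <= bottom <= top")
      if (object@hill <= 0)
        msgs <- c(msgs, "hill must be > 0 (decreasing-curve convention)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Confusion matrix of organoid calls against clinical labels
#'
#' 2x2 counts for one drug and one index mode. Clinically sensitive patients
#' called sensitive are true positives; clinically resistant patients called
#' resistant are true negatives. Patients whose clinical response is not
#' evaluable (or who lack an adjudication) are counted in \code{excluded}
#' and never enter the denominators.
#'
#' @slot tp,fn,tn,fp,excluded non-negative integer counts.
#' @slot drug,mode character labels carried along for reporting.
#'
#' @seealso [buildConfusion()], [sensitivity()], [specificity()]
#' @export
setClass("ConfusionMatrix",
  representation(
    tp = "integer", fn = "integer", tn = "integer", fp = "integer",
    excluded = "integer", drug = "character", mode = "character"
  ),
  prototype(tp = 0L, fn = 0L, tn = 0L, fp = 0L, excluded = 0L,
            drug = NA_character_, mode = NA_character_)
)

setValidity("ConfusionMatrix", function(object) {
  cnt <- c(object@tp, object@fn, object@tn, object@fp, object@excluded)
  if (any(is.na(cnt)) || any(cnt < 0L)) "counts must be non-negative" else TRUE
})
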