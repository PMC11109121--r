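## Concordance of organoid calls with adjudicated clinical labels.

#' Build a confusion matrix of organoid calls vs clinical labels
#'
#' Joins the organoid calls for one drug with the adjudicated clinical
#' labels by patient. Clinically sensitive and called sensitive counts as a
#' true positive; clinically resistant and called resistant as a true
#' negative. Patients adjudicated not-evaluable are excluded; a call with no
#' matching adjudication is excluded with a warning.
#'
#' @param calls data.frame with columns \code{patient_id} and \code{call}
#'   ("sensitive"/"resistant"); if it has a \code{drug} column it is
#'   filtered to \code{drug} first.
#' @param adjudications data.frame with \code{patient_id}, \code{drug} and
#'   \code{adjudicated} (as in [adjudications()] of a [Cohort-class]).
#' @param drug drug whose calls are evaluated.
#' @param clinical_drug drug name(s) to match in the adjudications; defaults
#'   to \code{drug}. Useful when the clinical line was a same-class agent
#'   (e.g. evaluating an osimertinib screen against a lazertinib response,
#'   both third-generation EGFR-TKIs).
#' @param mode label stored on the result for reporting.
#' @return a [ConfusionMatrix-class].
#' @export
buildConfusion <- function(calls, adjudications, drug,
                           clinical_drug = drug, mode = NA_character_) {
  stopifnot(all(c("patient_id", "call") %in% names(calls)))
  if ("drug" %in% names(calls)) calls <- calls[calls$drug == drug, ]
  adj <- adjudications[adjudications$drug %in% clinical_drug, ]
  tp <- fn <- tn <- fp <- excl <- 0L
  for (i in seq_len(nrow(calls))) {
    pid <- calls$patient_id[i]
    lab <- adj$adjudicated[adj$patient_id == pid]
    if (length(lab) == 0L) {
      warning("no clinical adjudication for patient ", pid,
              " (drug ", drug, "); excluded", call. = FALSE)
      excl <- excl + 1L
      next
    }
    lab <- lab[1]
    if (lab == "not_evaluable") { excl <- excl + 1L; next }
    cl <- calls$call[i]
    if (lab == "sensitive") {
      if (cl == "sensitive") tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (cl == "resistant") tn <- tn + 1L else fp <- fp + 1L
    }
  }
  methods::new("ConfusionMatrix", tp = tp, fn = fn, tn = tn, fp = fp,
               excluded = excl, drug = drug, mode = mode)
}

#' @rdname concordance-metrics
#' @export
setMethod("sensitivity", "ConfusionMatrix", function(object) {
  d <- object@tp + object@fn
  if (d == 0L) stop("undefined metric: no clinically sensitive patients")
  100 * object@tp / d
})

#' @rdname concordance-metrics
#' @export
setMethod("specificity", "ConfusionMatrix", function(object) {
  d <- object@tn + object@fp
  if (d == 0L) stop("undefined metric: no clinically resistant patients")
  100 * object@tn / d
})

#' @rdname concordance-metrics
#' @export
setMethod("accuracy", "ConfusionMatrix", function(object) {
  d <- object@tp + object@fn + object@tn + object@fp
  if (d == 0L) stop("undefined metric: no evaluable patients")
  100 * (object@tp + object@tn) / d
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix [%s%s]: tp=%d fn=%d tn=%d fp=%d excluded=%d\n",
              object@drug,
              if (is.na(object@mode)) "" else paste0(", ", object@mode),
              object@tp, object@fn, object@tn, object@fp, object@excluded))
  invisible(NULL)
})

.discordant <- function(calls, adjudications, drug, clinical_drug) {
  if ("drug" %in% names(calls)) calls <- calls[calls$drug == drug, ]
  adj <- adjudications[adjudications$drug %in% clinical_drug &
                         adjudications$adjudicated != "not_evaluable", ]
  m <- merge(calls[, c("patient_id", "call")],
             adj[, c("patient_id", "adjudicated")], by = "patient_id")
  sort(m$patient_id[m$call != m$adjudicated])
}

#' Head-to-head comparison of AUC-only and CODRP calls
#'
#' Evaluates both index modes against the same adjudicated clinical labels
#' and reports, per mode, the confusion matrix, sensitivity/specificity and
#' the list of clinically discordant patients, plus the metric deltas
#' (CODRP minus AUC-only).
#'
#' @param calls data.frame with columns \code{patient_id, drug, mode, call}
#'   (modes "codrp" and "auc"), e.g. [screeningCalls()] of the packaged
#'   cohort or calls derived from [computeIndices()].
#' @param adjudications adjudication data.frame (see [buildConfusion()]).
#' @param drug drug to compare.
#' @param clinical_drug see [buildConfusion()].
#' @return list with elements \code{codrp}, \code{auc} (each: confusion,
#'   sensitivity_pct, specificity_pct, discordant) and \code{delta}
#'   (sensitivity_pct, specificity_pct).
#' @export
compareIndices <- function(calls, adjudications, drug,
                           clinical_drug = drug) {
  stopifnot(all(c("patient_id", "drug", "mode", "call") %in% names(calls)))
  one <- function(mode) {
    sub <- calls[calls$mode == mode, ]
    if (!nrow(sub[sub$drug == drug, ]))
      stop("no '", mode, "'-mode calls for drug ", drug)
    cm <- buildConfusion(sub, adjudications, drug, clinical_drug, mode)
    list(confusion = cm,
         sensitivity_pct = sensitivity(cm),
         specificity_pct = specificity(cm),
         discordant = .discordant(sub, adjudications, drug, clinical_drug))
  }
  res <- list(codrp = one("codrp"), auc = one("auc"))
  res$delta <- list(
    sensitivity_pct = res$codrp$sensitivity_pct - res$auc$sensitivity_pct,
    specificity_pct = res$codrp$specificity_pct - res$auc$specificity_pct)
  res
}

#' Concordance report over drugs and modes
#'
#' Machine-readable summary (ready for JSON serialisation): per drug x mode
#' the confusion counts, raw and reporting-rounded metrics (one decimal),
#' and the discordant patient ids.
#'
#' @param calls calls data.frame (\code{patient_id, drug, mode, call}).
#' @param adjudications adjudication data.frame.
#' @param drug_map named list mapping each screened drug to the clinical
#'   drug name(s) it is evaluated against; defaults to identity over the
#'   drugs present in \code{calls}.
#' @return nested list keyed by drug then mode.
#' @export
concordanceReport <- function(calls, adjudications, drug_map = NULL) {
  if (is.null(drug_map)) {
    drugs <- unique(calls$drug)
    drug_map <- stats::setNames(as.list(drugs), drugs)
  }
  out <- list()
  for (drg in names(drug_map)) {
    out[[drg]] <- list()
    for (md in unique(calls$mode[calls$drug == drg])) {
      sub <- calls[calls$mode == md, ]
      cm <- buildConfusion(sub, adjudications, drg, drug_map[[drg]], md)
      sens <- tryCatch(sensitivity(cm), error = function(e) NA_real_)
      spec <- tryCatch(specificity(cm), error = function(e) NA_real_)
      out[[drg]][[md]] <- list(
        counts = list(tp = cm@tp, fn = cm@fn, tn = cm@tn, fp = cm@fp,
                      excluded = cm@excluded),
        sensitivity_pct = sens, specificity_pct = spec,
        sensitivity_pct_reported = round(sens, 1),
        specificity_pct_reported = round(spec, 1),
        discordant = .discordant(sub, adjudications, drg, drug_map[[drg]]))
    }
  }
  out
}
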