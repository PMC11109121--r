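## Scoring core: growth rate, cohort Z-scores, AUC index, CODRP index,
## sensitive/resistant classification.

#' Organoid growth rate from mean live areas
#'
#' Relative increase of the mean live-organoid area between the first and
#' third day of drug exposure: \code{(day3 - day1) / day1}. Negative values
#' mean shrinkage. This is a property of the sample, measured on vehicle
#' wells, not of any drug.
#'
#' @param mean_area_day1,mean_area_day3 mean areas (same units, e.g. um^2);
#'   day-1 areas must be > 0. Vectorised.
#' @return dimensionless growth rates.
#' @examples
#' growthRate(100, 300)   # 2
#' @export
growthRate <- function(mean_area_day1, mean_area_day3) {
  if (any(!is.finite(mean_area_day1)) || any(mean_area_day1 <= 0))
    stop("mean_area_day1 must be finite and > 0")
  (mean_area_day3 - mean_area_day1) / mean_area_day1
}

#' Read a per-patient growth table
#'
#' @param path CSV with columns \code{patient_id, mean_area_day1,
#'   mean_area_day3}.
#' @return data.frame with those columns plus \code{growth_rate}.
#' @export
readGrowth <- function(path) {
  if (!file.exists(path)) stop("growth table not found: ", path)
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "mean_area_day1", "mean_area_day3")
  if (!all(need %in% names(g)))
    stop("growth table schema error; missing column(s): ",
         paste(setdiff(need, names(g)), collapse = ", "))
  g$patient_id <- as.character(g$patient_id)
  g$growth_rate <- growthRate(g$mean_area_day1, g$mean_area_day3)
  g
}

#' Cohort Z-score
#'
#' \code{(x - mean(x)) / sd(x)} with the sample (n - 1) standard deviation by
#' default; population SD is available for sensitivity checks. This is the
#' standardisation behind both the AUC index (the Z-scored AUC of one drug
#' across the cohort) and the CODRP index.
#'
#' @param x numeric, length >= 2.
#' @param sd_mode "sample" (n - 1, default) or "population".
#' @param what label used in error messages to name the offending column.
#' @return Z-scores; mean 0 and (sample) SD 1 by construction.
#' @export
zscore <- function(x, sd_mode = c("sample", "population"), what = "values") {
  sd_mode <- match.arg(sd_mode)
  if (length(x) < 2L) stop("zscore needs n >= 2 for ", what)
  if (any(!is.finite(x))) stop("non-finite ", what, " in zscore")
  m <- mean(x)
  s <- if (sd_mode == "sample") stats::sd(x)
       else sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0)
    stop("zero variance in ", what, "; Z-score undefined")
  (x - m) / s
}

#' Distance from the drug-sensitivity reference point
#'
#' The CODRP composite places each patient at (Z of growth rate, Z of AUC)
#' and measures the Euclidean distance from the reference point
#' (reference_z, reference_z). The default reference -4.5 is an extreme
#' lower tail of the standard normal (an idealised maximally sensitive,
#' slow-growing sample); resistance increases with distance from it, so both
#' a larger AUC and a faster growth rate push a patient outward.
#'
#' @param z_growth,z_auc cohort Z-scores (vectorised).
#' @param reference_z reference coordinate, default -4.5 (must be < 0).
#' @return non-negative distances.
#' @examples
#' codrpDistance(0, 0)          # 4.5 * sqrt(2)
#' codrpDistance(-4.5, -4.5)    # 0
#' @export
codrpDistance <- function(z_growth, z_auc, reference_z = -4.5) {
  if (any(!is.finite(z_growth)) || any(!is.finite(z_auc)))
    stop("non-finite Z-score input")
  if (!is.finite(reference_z) || reference_z >= 0)
    stop("reference_z must be finite and < 0")
  sqrt((z_growth - reference_z)^2 + (z_auc - reference_z)^2)
}

#' Classify an index Z-score at a fixed cutoff
#'
#' Values at or below the cutoff are sensitive, above it resistant. The tie
#' at the cutoff is classified sensitive (inclusive rule) so results are
#' deterministic. The default cutoff -0.17 is the published operating point
#' and is stored as a constant, not re-derived.
#'
#' @param index_z finite Z-scores (CODRP Z or AUC Z).
#' @param cutoff Z-units threshold, default -0.17.
#' @return character vector over \{"sensitive", "resistant"\}.
#' @export
classifyCall <- function(index_z, cutoff = -0.17) {
  if (any(!is.finite(index_z))) stop("non-finite index_z")
  ifelse(index_z <= cutoff, "sensitive", "resistant")
}

## Relative tolerance below which the cohort growth-rate spread is treated
## as zero: measured areas carry nowhere near 8 significant digits, so a
## spread this small is numerically meaningless and the composite reduces to
## the AUC index (see codrpIndex).
.GROWTH_VAR_TOL <- 1e-8

#' Compute AUC and CODRP indices for one cohort
#'
#' Per drug (Z-scoring is always per metric and per drug within one cohort,
#' never pooled across drugs): Z-scores the AUCs (the AUC index) and the
#' growth rates, forms each patient's [codrpDistance()] from the reference
#' point, Z-scores those distances across the cohort (the CODRP index), and
#' classifies both indices at the cutoff.
#'
#' If the cohort's growth rates are constant up to numerical noise
#' (\code{sd <= 1e-8 * max(abs(mean), 1)}) the growth term carries no
#' information and the CODRP index is defined to reduce exactly to the AUC
#' index; a warning notes the degenerate cohort.
#'
#' @param records data.frame with columns \code{patient_id, drug, auc,
#'   growth_rate}; >= 2 patients per drug.
#' @param reference_z reference coordinate, default -4.5.
#' @param cutoff classification threshold, default -0.17.
#' @param sd_mode passed to [zscore()].
#' @return the input with added columns \code{z_auc, z_growth,
#'   codrp_distance, codrp_z, call_codrp, call_auc}.
#' @export
codrpIndex <- function(records, reference_z = -4.5, cutoff = -0.17,
                       sd_mode = "sample") {
  need <- c("patient_id", "drug", "auc", "growth_rate")
  stopifnot(all(need %in% names(records)))
  parts <- split(records, records$drug)
  parts <- lapply(parts, function(d) {
    if (nrow(d) < 2L)
      stop("need >= 2 patients per drug for Z-scoring (drug ", d$drug[1], ")")
    d$z_auc <- zscore(d$auc, sd_mode, what = paste0("auc[", d$drug[1], "]"))
    g <- d$growth_rate
    if (any(!is.finite(g))) stop("non-finite growth_rate")
    if (stats::sd(g) <= .GROWTH_VAR_TOL * max(abs(mean(g)), 1)) {
      warning("growth-rate spread below tolerance for drug ", d$drug[1],
              "; CODRP index reduces to the AUC index", call. = FALSE)
      d$z_growth <- 0
      d$codrp_distance <- codrpDistance(0, d$z_auc, reference_z)
      d$codrp_z <- d$z_auc
    } else {
      d$z_growth <- zscore(g, sd_mode,
                           what = paste0("growth_rate[", d$drug[1], "]"))
      d$codrp_distance <- codrpDistance(d$z_growth, d$z_auc, reference_z)
      d$codrp_z <- zscore(d$codrp_distance, sd_mode,
                          what = paste0("codrp_distance[", d$drug[1], "]"))
    }
    d$call_codrp <- classifyCall(d$codrp_z, cutoff)
    d$call_auc <- classifyCall(d$z_auc, cutoff)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' End-to-end index table from plate and growth tables
#'
#' Convenience wrapper: [screenAUC()] on the plate, join of the per-patient
#' growth rates, then [codrpIndex()]. The \code{call} column reflects the
#' requested mode ("codrp" or "auc_only"); both mode-specific call columns
#' are always present.
#'
#' @param plate plate data.frame ([readPlate()] schema).
#' @param growth growth data.frame ([readGrowth()] schema, or any frame with
#'   \code{patient_id} and \code{growth_rate}).
#' @param mode "codrp" (default) or "auc_only".
#' @param reference_z,cutoff,sd_mode see [codrpIndex()].
#' @return one row per patient x drug with AUC, Z-scores, CODRP index and
#'   calls.
#' @export
computeIndices <- function(plate, growth, mode = c("codrp", "auc_only"),
                           reference_z = -4.5, cutoff = -0.17,
                           sd_mode = "sample") {
  mode <- match.arg(mode)
  aucs <- screenAUC(plate)
  if (!"growth_rate" %in% names(growth)) {
    need <- c("patient_id", "mean_area_day1", "mean_area_day3")
    stopifnot(all(need %in% names(growth)))
    growth$growth_rate <- growthRate(growth$mean_area_day1,
                                     growth$mean_area_day3)
  }
  rec <- merge(aucs, growth[, c("patient_id", "growth_rate")],
               by = "patient_id", sort = FALSE)
  if (nrow(rec) < nrow(aucs))
    stop("growth table lacks growth rates for some screened patients")
  idx <- codrpIndex(rec, reference_z, cutoff, sd_mode)
  idx$call <- if (mode == "codrp") idx$call_codrp else idx$call_auc
  idx
}
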