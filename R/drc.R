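## Dose-response core: dilution design, DMSO normalisation, 4PL fitting,
## normalised AUC.

#' Serial dilution series
#'
#' The screening design is a descending geometric dilution series, by default
#' seven three-fold steps from 50 uM (plus a separate DMSO control well that
#' is not part of the series).
#'
#' @param top_conc highest concentration, uM (> 0).
#' @param fold dilution factor between consecutive doses (> 1).
#' @param n_points number of doses (>= 2).
#' @return numeric vector of length \code{n_points}, strictly decreasing.
#' @examples
#' makeDilutionSeries(50, 3, 7)
#' @export
makeDilutionSeries <- function(top_conc = 50, fold = 3, n_points = 7) {
  if (!is.finite(top_conc) || top_conc <= 0)
    stop("top_conc must be > 0")
  if (!is.finite(fold) || fold <= 1)
    stop("fold must be > 1")
  if (!is.finite(n_points) || n_points < 2)
    stop("n_points must be >= 2")
  top_conc / fold^(seq_len(n_points) - 1)
}

#' Read a long-format plate table
#'
#' @param path CSV with columns \code{patient_id, drug, conc_uM, replicate,
#'   readout}; \code{conc_uM == 0} encodes the DMSO control wells. Readouts
#'   are arbitrary-unit luminescence.
#' @return validated data.frame with those columns.
#' @export
readPlate <- function(path) {
  if (!file.exists(path)) stop("plate table not found: ", path)
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "drug", "conc_uM", "replicate", "readout")
  if (!all(need %in% names(p)))
    stop("plate table schema error; missing column(s): ",
         paste(setdiff(need, names(p)), collapse = ", "))
  p$patient_id <- as.character(p$patient_id)
  p$drug <- as.character(p$drug)
  if (any(!is.finite(p$conc_uM)) || any(p$conc_uM < 0))
    stop("conc_uM must be finite and >= 0 (0 = DMSO control)")
  if (any(!is.finite(p$readout)))
    stop("non-finite readout in plate table")
  p[, need]
}

#' Split a plate table into per-(patient, drug) dose-response profiles
#'
#' @param plate data.frame as returned by [readPlate()].
#' @return list of [DoseResponseProfile-class], one per patient x drug
#'   combination present. DMSO control wells (\code{conc_uM == 0}) of a
#'   patient are shared across that patient's drugs.
#' @export
profilesFromPlate <- function(plate) {
  need <- c("patient_id", "drug", "conc_uM", "replicate", "readout")
  stopifnot(all(need %in% names(plate)))
  ctrl <- plate[plate$conc_uM == 0, ]
  trt <- plate[plate$conc_uM > 0, ]
  keys <- unique(trt[, c("patient_id", "drug")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    pid <- keys$patient_id[i]; drg <- keys$drug[i]
    sub <- trt[trt$patient_id == pid & trt$drug == drg, ]
    concs <- sort(unique(sub$conc_uM), decreasing = TRUE)
    reps <- lapply(concs, function(cc) sub$readout[sub$conc_uM == cc])
    dm <- ctrl$readout[ctrl$patient_id == pid &
                         (ctrl$drug == drg | ctrl$drug == "DMSO")]
    out[[i]] <- methods::new("DoseResponseProfile", patientId = pid,
                             drug = drg, concentrations = concs,
                             replicates = reps, dmsoReadouts = dm)
  }
  names(out) <- paste(keys$patient_id, keys$drug, sep = ".")
  out
}

#' Normalise replicate readouts to the DMSO control
#'
#' Viability at each dose is the arithmetic mean of the technical replicates
#' divided by the mean of the DMSO control readouts. Values are >= 0 and may
#' exceed 1 (stimulation / noise); they are only clipped later, inside the
#' AUC integral.
#'
#' @param profile a [DoseResponseProfile-class].
#' @return named numeric vector of mean viability fractions, one per
#'   concentration (names = concentration in uM, descending).
#' @export
normalizeViability <- function(profile) {
  stopifnot(methods::is(profile, "DoseResponseProfile"))
  ctrl <- mean(profile@dmsoReadouts)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control error: DMSO mean readout must be > 0")
  v <- vapply(profile@replicates, mean, 1.0) / ctrl
  names(v) <- format(profile@concentrations, trim = TRUE)
  v
}

#' Four-parameter logistic viability
#'
#' The decreasing 4PL used throughout:
#' \code{bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10_ec50)))}.
#' Exported because it doubles as the generating curve of the synthetic-data
#' module.
#'
#' @param conc concentrations, uM (> 0).
#' @param top,bottom,log10_ec50,hill curve parameters.
#' @return viability fractions.
#' @export
fourPLViability <- function(conc, top, bottom, log10_ec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10_ec50)))
}

## Monotone tolerance: largest allowed upward excursion (viability fraction)
## along ascending dose before the data are declared non-monotone and the
## trapezoid fallback is used. Generous relative to the ~0.06 SD of a
## triplicate mean at 10% replicate CV.
.NONMONO_TOL <- 0.25
## Below this range of mean viabilities the curve is flat (no dose effect)
## and a 4PL is unidentifiable; fall back to the trapezoid.
.FLAT_TOL <- 0.05

#' Fit a four-parameter logistic dose-response curve
#'
#' Box-constrained Levenberg-Marquardt least squares of the decreasing 4PL
#' on the per-dose mean viabilities. Constraints: \code{bottom} in [0, 1],
#' \code{top} in [0.5, 1.5], \code{hill} in (0, 10], \code{log10_ec50}
#' within the tested grid plus/minus one decade. Starting values come from
#' the raw curve (top = max mean, bottom = min mean, EC50 = dose nearest the
#' half-range). If the optimizer fails, the data are flat, or they rise with
#' dose beyond tolerance, \code{fallbackUsed} is set and downstream AUC uses
#' the trapezoid on the observed means.
#'
#' @param concentrations numeric, uM, >= 4 distinct values for a full fit.
#' @param viabilities per-dose mean viability fractions (same length).
#' @return a [FourPL-class].
#' @examples
#' cc <- makeDilutionSeries(50, 3, 7)
#' v <- fourPLViability(cc, 1, 0, 0.5, 1)
#' fitFourPL(cc, v)
#' @export
fitFourPL <- function(concentrations, viabilities) {
  if (length(concentrations) != length(viabilities))
    stop("concentrations and viabilities must have equal length")
  keep <- is.finite(concentrations) & is.finite(viabilities) &
    concentrations > 0
  concentrations <- concentrations[keep]
  viabilities <- viabilities[keep]
  if (length(unique(concentrations)) < 2L)
    stop("need >= 2 distinct concentrations")

  ord <- order(concentrations)            # ascending dose
  lc <- log10(concentrations[ord])
  v <- viabilities[ord]

  fallback <- function(conv) methods::new("FourPL", converged = conv,
                                          fallbackUsed = TRUE)
  if (length(unique(lc)) < 4L) return(fallback(FALSE))
  if (diff(range(v)) < .FLAT_TOL) return(fallback(FALSE))
  ## largest upward excursion along ascending dose
  if (max(v - cummin(v)) > .NONMONO_TOL) return(fallback(FALSE))

  top0 <- min(max(max(v), 0.5), 1.5)
  bot0 <- min(max(min(v), 0), min(1, top0))
  half <- (top0 + bot0) / 2
  le0 <- lc[which.min(abs(v - half))]
  lo <- c(top = 0.5, bottom = 0, le = min(lc) - 1, hill = 1e-6)
  hi <- c(top = 1.5, bottom = 1, le = max(lc) + 1, hill = 10)
  start <- c(top = top0, bottom = min(bot0, 1),
             le = min(max(le0, lo[["le"]]), hi[["le"]]), hill = 1)

  resid_fn <- function(p)
    v - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
           (1 + 10^(p[["hill"]] * (lc - p[["le"]]))))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lo, upper = hi, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:3)) return(fallback(FALSE))
  cf <- fit$par
  if (any(!is.finite(cf)) || cf[["bottom"]] > cf[["top"]])
    return(fallback(FALSE))
  methods::new("FourPL", top = cf[["top"]], bottom = cf[["bottom"]],
               log10EC50 = cf[["le"]], hill = cf[["hill"]],
               converged = TRUE, fallbackUsed = FALSE)
}

#' @rdname predictViability
#' @export
setMethod("predictViability", "FourPL", function(object, conc) {
  if (object@fallbackUsed)
    stop("fallback fit has no curve; use the observed means")
  fourPLViability(conc, object@top, object@bottom, object@log10EC50,
                  object@hill)
})

setMethod("show", "FourPL", function(object) {
  if (object@fallbackUsed) {
    cat("FourPL: fallback (no trustworthy fit); AUC uses raw trapezoid\n")
  } else {
    cat(sprintf(
      "FourPL: top=%.4g bottom=%.4g log10EC50=%.4g hill=%.4g (%s)\n",
      object@top, object@bottom, object@log10EC50, object@hill,
      if (object@converged) "converged" else "not converged"))
  }
  invisible(NULL)
})

#' Normalised area under the dose-response curve
#'
#' AUC is the mean viability over the tested log10-concentration range:
#' \deqn{AUC = \frac{1}{\log_{10}c_{max} - \log_{10}c_{min}}
#'   \int_{\log_{10}c_{min}}^{\log_{10}c_{max}} \tilde v(x)\,dx}
#' with \eqn{\tilde v} the viability clipped to [0, 1] before integration,
#' so AUC is dimensionless in [0, 1]; 1 means no drug effect anywhere on the
#' grid (fully resistant) and 0 complete kill. A fitted curve is integrated
#' by adaptive quadrature; for a fallback fit the trapezoid rule is applied
#' to the clipped observed means.
#'
#' @param fit a [FourPL-class] (possibly a fallback).
#' @param concentrations tested concentrations, uM; must span > 0 decades.
#' @param viabilities observed per-dose mean viabilities; required when
#'   \code{fit} is a fallback.
#' @return list with \code{auc} (in [0, 1]) and \code{method}
#'   ("fitted_curve" or "trapezoid_raw").
#' @export
computeAUC <- function(fit, concentrations, viabilities = NULL) {
  keep <- is.finite(concentrations) & concentrations > 0
  concentrations <- concentrations[keep]
  if (length(unique(concentrations)) < 2L)
    stop("AUC needs >= 2 distinct concentrations")
  lmin <- log10(min(concentrations))
  lmax <- log10(max(concentrations))

  if (methods::is(fit, "FourPL") && !fit@fallbackUsed) {
    f <- function(x) pmin(pmax(predictViability(fit, 10^x), 0), 1)
    val <- stats::integrate(f, lmin, lmax, rel.tol = 1e-10,
                            subdivisions = 500L)$value / (lmax - lmin)
    return(list(auc = val, method = "fitted_curve"))
  }
  if (is.null(viabilities))
    stop("fallback AUC needs the observed viabilities")
  viabilities <- viabilities[keep]
  ord <- order(concentrations)
  x <- log10(concentrations[ord])
  y <- pmin(pmax(viabilities[ord], 0), 1)
  val <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2) / (lmax - lmin)
  list(auc = val, method = "trapezoid_raw")
}

#' Closed-form AUC of a unit-amplitude 4PL
#'
#' For \code{top = 1, bottom = 0} the normalised log10-axis AUC has the
#' antiderivative \eqn{x - \log_{10}(1 + 10^{h(x - m)})/h}, used by the
#' synthetic-data module for fast noiseless AUCs (no clipping is needed since
#' the curve lies strictly inside (0, 1)).
#'
#' @param log10_ec50,hill curve parameters (vectorised over both).
#' @param lmin,lmax integration limits on the log10 axis.
#' @return AUC values in (0, 1).
#' @export
aucFourPL <- function(log10_ec50, hill, lmin, lmax) {
  anti <- function(x) {
    z <- hill * (x - log10_ec50)
    ## log10(1 + 10^z), overflow-safe for large |z|
    l1p <- ifelse(z > 30, z, log1p(10^z) / log(10))
    x - l1p / hill
  }
  (anti(lmax) - anti(lmin)) / (lmax - lmin)
}

#' Fit and summarise every profile on a plate
#'
#' Runs [normalizeViability()], [fitFourPL()] and [computeAUC()] over each
#' patient x drug profile of a long-format plate table.
#'
#' @param plate data.frame as returned by [readPlate()].
#' @return data.frame with one row per profile: \code{patient_id, drug, auc,
#'   method, converged, top, bottom, log10_ec50, hill}.
#' @export
screenAUC <- function(plate) {
  profs <- profilesFromPlate(plate)
  rows <- lapply(profs, function(pr) {
    v <- normalizeViability(pr)
    fit <- fitFourPL(pr@concentrations, v)
    a <- computeAUC(fit, pr@concentrations, v)
    data.frame(patient_id = pr@patientId, drug = pr@drug, auc = a$auc,
               method = a$method, converged = fit@converged,
               top = fit@top, bottom = fit@bottom,
               log10_ec50 = fit@log10EC50, hill = fit@hill,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
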