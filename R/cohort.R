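## Clinical cohort readers, RECIST adjudication, accessors.

.RECIST_LEVELS <- c("PR", "PD", "SD", "NE")

.CLINICAL_COLS <- c("patient_id", "sex", "age", "smoking",
                    "stage_at_sampling", "mutations", "drug", "line",
                    "recist_label", "tumor_change_pct", "notes")

#' Map a RECIST label to a binary drug-response adjudication
#'
#' Clinical response is read off the RECIST 1.1 label of the drug line that
#' was active at organoid sampling: a partial response (PR) is sensitive and
#' progressive disease (PD) is resistant. Stable disease (SD) is split on the
#' recorded tumor size change — any documented decrease counts as a clinical
#' response (sensitive), any increase as resistance; SD without a recorded
#' change, and NE, are not evaluable and are excluded from concordance
#' denominators.
#'
#' @param recist_label character vector with values in PR, PD, SD, NE.
#' @param tumor_change_pct signed percent change in tumor size (negative =
#'   shrinkage), \code{NA} when not recorded. Recycled against
#'   \code{recist_label}.
#' @param notes ignored by the rule; accepted so adjudication calls can carry
#'   the free-text rationale alongside.
#' @return character vector over \{"sensitive", "resistant",
#'   "not_evaluable"\}. The rule is a pure function of its inputs.
#' @examples
#' adjudicate("PR")                 # "sensitive"
#' adjudicate("SD", -10)            # "sensitive"  (documented shrinkage)
#' adjudicate("NE")                 # "not_evaluable"
#' @export
adjudicate <- function(recist_label, tumor_change_pct = NA_real_,
                       notes = "") {
  recist_label <- as.character(recist_label)
  bad <- setdiff(unique(recist_label), .RECIST_LEVELS)
  if (length(bad))
    stop("unknown RECIST label token(s): ", paste(bad, collapse = ", "))
  n <- length(recist_label)
  change <- rep_len(as.numeric(tumor_change_pct), n)
  out <- character(n)
  out[recist_label == "PR"] <- "sensitive"
  out[recist_label == "PD"] <- "resistant"
  out[recist_label == "NE"] <- "not_evaluable"
  sd_i <- recist_label == "SD"
  out[sd_i & !is.na(change) & change < 0] <- "sensitive"
  out[sd_i & !is.na(change) & change > 0] <- "resistant"
  out[sd_i & (is.na(change) | change == 0)] <- "not_evaluable"
  out
}

#' Load a clinical cohort table (and optional organoid screening calls)
#'
#' Reads the long-format clinical CSV (one row per patient x drug line; the
#' per-patient demographic columns are repeated on every row and deduplicated
#' here), applies [adjudicate()] to every drug line, and returns a validated
#' [Cohort-class]. Malformed rows are reported with their row numbers.
#'
#' @param clinical_csv path to a CSV with columns \code{patient_id, sex, age,
#'   smoking, stage_at_sampling, mutations, drug, line, recist_label,
#'   tumor_change_pct, notes} (UTF-8, comma-separated, "." decimal).
#' @param screening_csv optional path to a CSV of organoid screening calls
#'   with columns \code{patient_id, drug, mode, call}.
#' @return a [Cohort-class].
#' @examples
#' coh <- loadCohort(codrpExample("clinical.csv"),
#'                   codrpExample("screening.csv"))
#' nPatients(coh)
#' @export
loadCohort <- function(clinical_csv, screening_csv = NULL) {
  if (!file.exists(clinical_csv))
    stop("clinical table not found: ", clinical_csv)
  raw <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.CLINICAL_COLS, names(raw))
  if (length(missing_cols))
    stop("clinical table schema error; missing column(s): ",
         paste(missing_cols, collapse = ", "))

  if (nrow(raw) == 0L) {
    return(methods::new("Cohort",
      patients = data.frame(patient_id = character(), sex = character(),
                            age = numeric(), smoking = character(),
                            stage_at_sampling = character(),
                            mutations = character(),
                            stringsAsFactors = FALSE),
      adjudications = data.frame(patient_id = character(), drug = character(),
                                 line = numeric(), recist_label = character(),
                                 tumor_change_pct = numeric(),
                                 notes = character(), adjudicated = character(),
                                 stringsAsFactors = FALSE),
      screeningCalls = .readScreening(screening_csv)))
  }

  age <- suppressWarnings(as.numeric(raw$age))
  chg <- suppressWarnings(as.numeric(ifelse(raw$tumor_change_pct == "",
                                            NA, raw$tumor_change_pct)))
  badrow <- which(raw$patient_id == "" | is.na(age) | age <= 0 |
                    !(raw$recist_label %in% .RECIST_LEVELS))
  if (length(badrow))
    stop("malformed clinical row(s) (1-based, excluding header): ",
         paste(badrow, collapse = ", "))

  first <- !duplicated(raw$patient_id)
  pats <- data.frame(patient_id = raw$patient_id[first],
                     sex = raw$sex[first],
                     age = age[first],
                     smoking = raw$smoking[first],
                     stage_at_sampling = raw$stage_at_sampling[first],
                     mutations = raw$mutations[first],
                     stringsAsFactors = FALSE)
  adj <- data.frame(patient_id = raw$patient_id,
                    drug = raw$drug,
                    line = suppressWarnings(as.numeric(raw$line)),
                    recist_label = raw$recist_label,
                    tumor_change_pct = chg,
                    notes = raw$notes,
                    stringsAsFactors = FALSE)
  dup <- duplicated(adj[, c("patient_id", "drug")])
  if (any(dup))
    stop("duplicate (patient, drug) adjudication row(s): ",
         paste(which(dup), collapse = ", "))
  adj$adjudicated <- adjudicate(adj$recist_label, adj$tumor_change_pct)

  methods::new("Cohort", patients = pats, adjudications = adj,
               screeningCalls = .readScreening(screening_csv))
}

.readScreening <- function(path) {
  empty <- data.frame(patient_id = character(), drug = character(),
                      mode = character(), call = character(),
                      stringsAsFactors = FALSE)
  if (is.null(path)) return(empty)
  if (!file.exists(path)) stop("screening table not found: ", path)
  s <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("patient_id", "drug", "mode", "call")
  if (!all(need %in% names(s)))
    stop("screening table schema error; missing column(s): ",
         paste(setdiff(need, names(s)), collapse = ", "))
  if (nrow(s) == 0L) return(empty)
  s[, need]
}

#' Write a cohort back to the clinical CSV schema
#'
#' Inverse of [loadCohort()]: re-joins the per-patient columns onto every
#' drug line and writes the same column set, so that
#' \code{writeCohort(loadCohort(f), g)} reproduces \code{f} up to column
#' order.
#'
#' @param cohort a [Cohort-class].
#' @param clinical_csv output path.
#' @return the path, invisibly.
#' @export
writeCohort <- function(cohort, clinical_csv) {
  stopifnot(methods::is(cohort, "Cohort"))
  a <- cohort@adjudications
  p <- cohort@patients
  m <- cbind(a, p[match(a$patient_id, p$patient_id),
                  setdiff(names(p), "patient_id"), drop = FALSE])
  out <- m[, .CLINICAL_COLS]
  out$tumor_change_pct <- ifelse(is.na(out$tumor_change_pct), "",
                                 format(out$tumor_change_pct,
                                        trim = TRUE, scientific = FALSE))
  utils::write.csv(out, clinical_csv, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(clinical_csv)
}

#' Path to a packaged example/fixture file
#'
#' The package ships the clinical characteristics and treatment-response
#' tables of the 14-patient EGFR-mutant NSCLC cohort (transcribed from the
#' published study tables) plus the organoid screening calls, as plain CSV.
#'
#' @param file file name under the package's \code{extdata}, e.g.
#'   \code{"clinical.csv"} or \code{"screening.csv"}; with no argument,
#'   lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
codrpExample <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "codrp")))
  path <- system.file("extdata", file, package = "codrp")
  if (path == "") stop("no packaged file named ", file)
  path
}

#' @rdname cohort-accessors
#' @export
setMethod("patients", "Cohort", function(object) object@patients)

#' @rdname cohort-accessors
#' @export
setMethod("adjudications", "Cohort", function(object) object@adjudications)

#' @rdname cohort-accessors
#' @export
setMethod("screeningCalls", "Cohort", function(object) object@screeningCalls)

#' @rdname cohort-accessors
#' @export
setMethod("nPatients", "Cohort", function(object) nrow(object@patients))

setMethod("show", "Cohort", function(object) {
  cat("Cohort:", nrow(object@patients), "patients,",
      nrow(object@adjudications), "adjudicated drug lines")
  if (nrow(object@screeningCalls))
    cat(",", nrow(object@screeningCalls), "screening calls")
  cat("\n")
  if (nrow(object@adjudications)) {
    tab <- table(object@adjudications$drug, object@adjudications$adjudicated)
    print(tab)
  }
  invisible(NULL)
})
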