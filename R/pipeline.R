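## Pipeline orchestration: YAML run configuration, end-to-end run, report.
## A thin command-line wrapper over these functions ships in
## inst/scripts/codrp.R.

.configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

#' Load and validate a pipeline run configuration
#'
#' The YAML file has an \code{inputs:} block (paths \code{clinical} and
#' optionally \code{screening}, \code{plate}, \code{growth}) or a
#' \code{sim:} block ([simConfig()] fields) -- exactly one of the two -- plus
#' an optional \code{index:} block (\code{reference_z}, \code{cutoff},
#' \code{sd_mode}), \code{mode} (codrp / auc_only / both), \code{out_dir}
#' and \code{seed}.
#'
#' @param path YAML file.
#' @param seed optional override of the file's seed.
#' @return validated config list.
#' @export
loadRunConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$sim)
  if (has_inputs == has_sim)
    stop("config must contain exactly one of 'inputs' and 'sim'")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$mode <- match.arg(cfg$mode %||% "codrp",
                        c("codrp", "auc_only", "both"))
  idx <- cfg$index %||% list()
  cfg$index <- list(reference_z = idx$reference_z %||% -4.5,
                    cutoff = idx$cutoff %||% -0.17,
                    sd_mode = idx$sd_mode %||% "sample")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline on files
#'
#' When \code{plate} and \code{growth} are given, indices and calls are
#' computed from the raw screen; otherwise the organoid calls are taken from
#' the screening-call table of the clinical cohort. If a clinical table is
#' present, a concordance report against the adjudicated labels is written.
#' Outputs (\code{indices.csv}, \code{concordance.json}) are stamped with an
#' md5 hash of the effective configuration, so re-running identical inputs
#' reproduces them byte-identically.
#'
#' @param out_dir output directory (created if needed).
#' @param clinical,screening,plate,growth input CSV paths (see
#'   [loadCohort()], [readPlate()], [readGrowth()]).
#' @param mode "codrp", "auc_only" or "both" (both = compare the modes).
#' @param index list with \code{reference_z}, \code{cutoff}, \code{sd_mode}.
#' @param drug_map see [concordanceReport()].
#' @return invisibly, a list with the computed pieces (\code{indices},
#'   \code{calls}, \code{report}, \code{config_hash}).
#' @export
runPipeline <- function(out_dir, clinical = NULL, screening = NULL,
                        plate = NULL, growth = NULL, mode = "codrp",
                        index = list(), drug_map = NULL) {
  mode <- match.arg(mode, c("codrp", "auc_only", "both"))
  ref <- index$reference_z %||% -4.5
  cut <- index$cutoff %||% -0.17
  sdm <- index$sd_mode %||% "sample"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- .configHash(list(clinical = clinical, screening = screening,
                           plate = plate, growth = growth, mode = mode,
                           reference_z = ref, cutoff = cut, sd_mode = sdm))

  indices <- NULL
  calls <- NULL
  if (!is.null(plate)) {
    if (is.null(growth) && mode != "auc_only")
      stop("missing input: growth table is required in CODRP mode")
    plate_df <- readPlate(plate)
    if (!is.null(growth)) {
      growth_df <- readGrowth(growth)
      indices <- computeIndices(plate_df, growth_df,
                                mode = if (mode == "auc_only") "auc_only"
                                       else "codrp",
                                reference_z = ref, cutoff = cut,
                                sd_mode = sdm)
      calls <- rbind(
        data.frame(patient_id = indices$patient_id, drug = indices$drug,
                   mode = "codrp", call = indices$call_codrp,
                   stringsAsFactors = FALSE),
        data.frame(patient_id = indices$patient_id, drug = indices$drug,
                   mode = "auc", call = indices$call_auc,
                   stringsAsFactors = FALSE))
    } else {
      aucs <- screenAUC(plate_df)
      aucs$z_auc <- NA_real_
      for (d in unique(aucs$drug)) {
        sel <- aucs$drug == d
        aucs$z_auc[sel] <- zscore(aucs$auc[sel], sd_mode = sdm,
                                  what = paste0("auc[", d, "]"))
      }
      aucs$call <- classifyCall(aucs$z_auc, cut)
      indices <- aucs
      calls <- data.frame(patient_id = aucs$patient_id, drug = aucs$drug,
                          mode = "auc", call = aucs$call,
                          stringsAsFactors = FALSE)
    }
    indices$config_hash <- hash
    utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
  }

  report <- NULL
  if (!is.null(clinical)) {
    coh <- loadCohort(clinical, screening)
    if (is.null(calls)) {
      calls <- screeningCalls(coh)
      if (!nrow(calls))
        stop("missing input: no plate/growth data and no screening calls")
    }
    use_modes <- switch(mode, codrp = "codrp", auc_only = "auc",
                        both = c("codrp", "auc"))
    calls_use <- calls[calls$mode %in% use_modes, ]
    report <- concordanceReport(calls_use, adjudications(coh), drug_map)
    jsonlite::write_json(list(config_hash = hash, mode = mode,
                              drugs = report),
                         file.path(out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(indices = indices, calls = calls, report = report,
                 config_hash = hash))
}

#' Pipeline subcommands
#'
#' Function equivalents of the command-line subcommands:
#' \code{cmdSimulate()} writes the simulated fixture files of a \code{sim:}
#' config block, \code{cmdRun()} executes [runPipeline()] from a config, and
#' \code{cmdReport()} prints a human-readable summary of a completed run
#' directory.
#'
#' @param config a list from [loadRunConfig()].
#' @return \code{cmdSimulate}: the simulation result (invisibly);
#'   \code{cmdRun}: the pipeline result (invisibly); \code{cmdReport}: the
#'   parsed report (invisibly).
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmdSimulate <- function(config) {
  if (is.null(config$sim)) stop("config has no 'sim' block")
  sim_args <- config$sim
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  sc <- do.call(simConfig, sim_args)
  out_dir <- config$out_dir %||% "."
  invisible(simulateCohort(sc, dir = out_dir))
}

#' @rdname pipeline-commands
#' @export
cmdRun <- function(config) {
  out_dir <- config$out_dir %||% "."
  if (!is.null(config$sim)) {
    sim <- cmdSimulate(config)
    inputs <- list(clinical = file.path(out_dir, "clinical.csv"),
                   plate = file.path(out_dir, "plate.csv"),
                   growth = file.path(out_dir, "growth.csv"))
  } else inputs <- config$inputs
  for (nm in names(inputs))
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]]))
      stop("missing input '", nm, "': ", inputs[[nm]])
  runPipeline(out_dir, clinical = inputs$clinical,
              screening = inputs$screening, plate = inputs$plate,
              growth = inputs$growth, mode = config$mode %||% "codrp",
              index = config$index %||% list(),
              drug_map = config$drug_map)
}

#' @rdname pipeline-commands
#' @param run_dir directory containing the outputs of [cmdRun()].
#' @export
cmdReport <- function(run_dir) {
  jf <- file.path(run_dir, "concordance.json")
  idxf <- file.path(run_dir, "indices.csv")
  rep <- NULL
  if (file.exists(jf)) {
    rep <- jsonlite::read_json(jf)
    cat("Concordance report (config", rep$config_hash, ")\n")
    for (drg in names(rep$drugs)) {
      for (md in names(rep$drugs[[drg]])) {
        r <- rep$drugs[[drg]][[md]]
        cat(sprintf(
          " %s [%s]: tp=%d fn=%d tn=%d fp=%d excl=%d | sens %.1f%% spec %.1f%%\n",
          drg, md, r$counts$tp, r$counts$fn, r$counts$tn, r$counts$fp,
          r$counts$excluded,
          r$sensitivity_pct %||% NA, r$specificity_pct %||% NA))
        if (length(r$discordant))
          cat("   discordant:", paste(unlist(r$discordant), collapse = ", "),
              "\n")
      }
    }
  }
  if (file.exists(idxf)) {
    idx <- utils::read.csv(idxf, stringsAsFactors = FALSE)
    cat("Indices:", nrow(idx), "patient x drug records\n")
  }
  if (is.null(rep) && !file.exists(idxf))
    stop("no pipeline outputs found in ", run_dir)
  invisible(rep)
}
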