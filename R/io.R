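# NONMEM-style dataset I/O, the end-to-end pipeline, and a small CLI.
#
# Dataset layout: CSV with header ID, TIME, AMT, DV, EVID, MDV, WT, PAR
# (case-insensitive). EVID 1 = dosing row (AMT in mg, DV missing), EVID 0 =
# observation row (DV in ng/mL unless MDV = 1). TIME in hours from each
# subject's first record; WT and PAR constant within subject.

TDM_COLUMNS <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "WT", "PAR")

#' Write subjects to a NONMEM-style CSV
#'
#' @param dataset List of `subject_record`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tdm <- function(dataset, path) {
  rows <- lapply(dataset, function(s) {
    d <- data.frame(ID = s$id, TIME = s$doses$time, AMT = s$doses$amount,
                    DV = NA_real_, EVID = 1L, MDV = 1L)
    o <- data.frame(ID = s$id, TIME = s$obs$time, AMT = NA_real_,
                    DV = s$obs$dv, EVID = 0L,
                    MDV = ifelse(is.na(s$obs$dv), 1L, 0L))
    x <- rbind(d, o)
    x <- x[order(x$TIME, -x$EVID), ]   # doses before observations at ties
    x$WT <- s$covariates$weight
    x$PAR <- s$covariates$par
    x
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a NONMEM-style TDM dataset
#'
#' Validates the schema: required columns, at least one dose before each
#' subject's first observation, non-decreasing TIME within subject, and
#' constant WT/PAR within subject. Violations raise errors naming the
#' offending row or subject.
#'
#' @param path CSV file with columns ID, TIME, AMT, DV, EVID, MDV, WT, PAR
#'   (case-insensitive header).
#' @return A `tdm_cohort` (list of `subject_record`s). Observations with
#'   MDV = 1 are dropped.
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  missing_cols <- setdiff(TDM_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw$.row <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (any(bad <- !(raw$EVID %in% c(0, 1)))) {
    stop(sprintf("row %d: EVID must be 0 or 1", raw$.row[bad][1]),
         call. = FALSE)
  }
  if (any(bad <- raw$EVID == 1 & (is.na(raw$AMT) | raw$AMT <= 0))) {
    stop(sprintf("row %d: dosing row needs a positive AMT", raw$.row[bad][1]),
         call. = FALSE)
  }
  if (any(bad <- !is.na(raw$TIME) & raw$TIME < 0)) {
    stop(sprintf("row %d: negative TIME", raw$.row[bad][1]), call. = FALSE)
  }
  subjects <- list()
  for (id in unique(raw$ID)) {
    d <- raw[raw$ID == id, ]
    if (is.unsorted(d$TIME)) {
      stop(sprintf("subject %s: TIME not non-decreasing (row %d)",
                   id, d$.row[which(diff(d$TIME) < 0)[1] + 1]), call. = FALSE)
    }
    if (length(unique(d$WT)) != 1 || length(unique(d$PAR)) != 1) {
      stop(sprintf("subject %s: WT and PAR must be constant within subject",
                   id), call. = FALSE)
    }
    if (!d$PAR[1] %in% c(0, 1)) {
      stop(sprintf("subject %s: PAR must be 0 or 1", id), call. = FALSE)
    }
    doses <- d[d$EVID == 1, ]
    obs <- d[d$EVID == 0 & d$MDV == 0, ]
    if (nrow(doses) == 0) {
      stop(sprintf("subject %s has no dosing records", id), call. = FALSE)
    }
    if (nrow(obs) > 0 && min(obs$TIME) <= min(doses$TIME)) {
      stop(sprintf("subject %s: observation at or before the first dose (row %d)",
                   id, obs$.row[which.min(obs$TIME)]), call. = FALSE)
    }
    if (any(is.na(obs$DV))) {
      stop(sprintf("subject %s: DV missing on an MDV=0 observation row", id),
           call. = FALSE)
    }
    subjects[[length(subjects) + 1]] <- structure(
      list(id = id,
           covariates = subject_covariates(weight = d$WT[1], par = d$PAR[1]),
           doses = data.frame(time = doses$TIME, amount = doses$AMT),
           obs = data.frame(time = obs$TIME, dv = obs$DV)),
      class = "subject_record")
  }
  structure(subjects, class = "tdm_cohort")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (draw a synthetic
#' cohort and observations), `fit` (NLME estimation), `validate` (GOF table,
#' VPC, bootstrap) and `pta` (PTA grid plus the four recommendation
#' slices). Each stochastic stage derives its seed from `config$seed` and
#' logs it; artifacts are written under `config$out_dir` as CSV/JSON.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{stages}{character subset of `c("simulate", "fit", "validate",
#'       "pta")`; default all.}
#'     \item{dataset}{path to a TDM CSV; required unless `"simulate"` is a
#'       stage.}
#'     \item{design}{arguments for [cohort_design()] (simulate stage).}
#'     \item{model}{arguments for [pop_params()]; the generating/initial
#'       model. May also be a path to a model-config JSON.}
#'     \item{seed}{master integer seed (default 1).}
#'     \item{out_dir}{output directory (default `"."`).}
#'     \item{n_bootstrap, n_sim_vpc, n_virtual}{stage sizes; defaults 200,
#'       500, 1000.}
#'   }
#' @param quiet Suppress progress messages.
#' @return A list of stage results (invisibly also written to `out_dir`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  stages <- config$stages %||% c("simulate", "fit", "validate", "pta")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  model <- if (is.character(config$model)) {
    read_model_config(config$model)
  } else {
    do.call(pop_params, as.list(config$model %||% list()))
  }
  results <- list(seed = seed, model = model)

  if ("simulate" %in% stages) {
    design <- do.call(cohort_design, as.list(config$design %||% list()))
    say("[simulate] drawing cohort of %d subjects (seed %d)",
        design$n_subjects, seed)
    cohort <- draw_cohort(design, seed = seed)
    dataset <- simulate_dataset(cohort, model, seed = seed + 1L)
    write_tdm(dataset, file.path(out_dir, "dataset.csv"))
    results$dataset <- dataset
  } else {
    if (is.null(config$dataset)) {
      stop("config must name a `dataset` when the simulate stage is skipped",
           call. = FALSE)
    }
    say("[load] reading %s", config$dataset)
    results$dataset <- read_tdm(config$dataset)
  }

  if ("fit" %in% stages) {
    say("[fit] estimating population parameters (%d subjects)",
        length(results$dataset))
    fit <- pk_fit(results$dataset, init = model,
                  fixed = config$fixed %||% "ka")
    results$fit <- fit
    report <- list(
      converged = fit$converged, ofv = fit$ofv,
      n_subjects = fit$n_subjects, n_observations = fit$n_observations,
      estimates = stats::setNames(
        lapply(fit$free_params, function(nm) get_param(fit$estimates, nm)),
        fit$free_params),
      se = as.list(fit$se), rse_pct = as.list(fit$rse_pct),
      ebe = as.list(fit$ebe))
    jsonlite::write_json(report, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_model_config(fit$estimates, file.path(out_dir, "final_model.json"))
  }

  model_for_sim <- if (!is.null(results$fit)) results$fit$estimates else model
  fit_obj <- results$fit %||% as_fit(results$dataset, model_for_sim)

  if ("validate" %in% stages) {
    say("[validate] GOF table, VPC, bootstrap (seed %d)", seed + 2L)
    gof <- gof_table(fit_obj, results$dataset)
    utils::write.csv(gof, file.path(out_dir, "gof.csv"), row.names = FALSE)
    v <- vpc(fit_obj, results$dataset,
             n_sim = as.integer(config$n_sim_vpc %||% 500L), seed = seed + 2L)
    utils::write.csv(as.data.frame(v), file.path(out_dir, "vpc.csv"),
                     row.names = FALSE)
    results$gof <- gof
    results$vpc <- v
    if (length(fit_obj$free_params) > 0) {
      bs <- bootstrap_model(results$dataset, fit_obj,
                            n_resamples = as.integer(config$n_bootstrap %||% 200L),
                            seed = seed + 3L)
      utils::write.csv(as.data.frame(bs), file.path(out_dir, "bootstrap.csv"),
                       row.names = FALSE)
      results$bootstrap <- bs
    }
  }

  if ("pta" %in% stages) {
    n_virtual <- as.integer(config$n_virtual %||% 1000L)
    say("[pta] simulating the dose grid (%d virtual patients/cell, seed %d)",
        n_virtual, seed + 4L)
    grid <- pta_grid(pop = model_for_sim, n_virtual = n_virtual,
                     seed = seed + 4L)
    utils::write.csv(as.data.frame(grid), file.path(out_dir, "pta_grid.csv"),
                     row.names = FALSE)
    recs <- list()
    for (freq in c("qd", "bid")) {
      for (p in c(0, 1)) {
        rec <- recommend_dose(grid, freq, p, pop = model_for_sim,
                              n_virtual = n_virtual, seed = seed + 4L)
        rec_df <- as.data.frame(rec)
        rec_df$frequency <- freq
        rec_df$par <- p
        recs[[paste(freq, p)]] <- rec_df
      }
    }
    rec_all <- do.call(rbind, recs)
    rownames(rec_all) <- NULL
    utils::write.csv(rec_all, file.path(out_dir, "recommendations.csv"),
                     row.names = FALSE)
    results$pta <- grid
    results$recommendations <- rec_all
  }
  say("[done] artifacts in %s", normalizePath(out_dir))
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate-cohort`, `fit`, `validate`, `pta`, `recommend`,
#' `run-all`. Each accepts `--config <json>`, `--seed <int>` and
#' `--out <dir>`; flags override the config file. Intended to be called
#' from an `Rscript` wrapper:
#' `Rscript -e 'olanzpk::pk_cli()' run-all --seed 1 --out out/`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return The [run_pipeline()] result, invisibly.
#' @export
pk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: <cmd> [--config config.json] [--seed N] [--out DIR]",
    "  cmd: simulate-cohort | fit | validate | pta | recommend | run-all",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(NULL))
  }
  cmd <- args[1]
  stage_map <- list(
    "simulate-cohort" = "simulate",
    "fit" = "fit",
    "validate" = "validate",
    "pta" = "pta",
    "recommend" = "pta",
    "run-all" = c("simulate", "fit", "validate", "pta"))
  if (!cmd %in% names(stage_map)) {
    stop(sprintf("unknown subcommand `%s`\n%s", cmd, usage), call. = FALSE)
  }
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!rest[i] %in% c("--config", "--seed", "--out")) {
      stop(sprintf("unknown option `%s`\n%s", rest[i], usage), call. = FALSE)
    }
    if (i == length(rest)) stop(sprintf("option %s needs a value", rest[i]),
                                call. = FALSE)
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  config <- if (!is.null(opts$config)) {
    jsonlite::read_json(opts$config, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    list()
  }
  config$stages <- stage_map[[cmd]]
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) config$out_dir <- opts$out
  invisible(run_pipeline(config))
}
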