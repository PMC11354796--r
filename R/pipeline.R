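#' Pipeline configuration
#'
#' @param vif_threshold VIF threshold for recursive metabolite
#'   elimination (> 1; default 3).
#' @param selection_alpha Wald p-value threshold for metabolite selection
#'   into the score (default 0.10).
#' @param maxstat_quantiles admissible cutpoint band as cohort
#'   proportions (default `c(0.10, 0.90)`).
#' @param cutpoint_endpoint endpoint defining the maxstat cutpoint,
#'   `"DFS"` (default) or `"OS"`.
#' @param forced_covariates clinical columns forced into the Cox design
#'   and never removed by the VIF recursion (default HER-2 and hormonal
#'   receptor status).
#' @param seed integer seed recorded in the run manifest.
#' @param output_dir where [run_pipeline()] writes its artifacts
#'   (`NULL` = no files).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(vif_threshold = 3,
                            selection_alpha = 0.10,
                            maxstat_quantiles = c(0.10, 0.90),
                            cutpoint_endpoint = c("DFS", "OS"),
                            forced_covariates = c("her2",
                                                  "hormonal_receptor"),
                            seed = 1L,
                            output_dir = NULL) {
  cutpoint_endpoint <- match.arg(cutpoint_endpoint)
  check_number(vif_threshold, "vif_threshold", 1, strict_lower = TRUE)
  check_number(selection_alpha, "selection_alpha", 0, 1,
               strict_lower = TRUE)
  if (selection_alpha >= 1) stop_input("'selection_alpha' must be < 1")
  q <- maxstat_quantiles
  if (length(q) != 2L || any(q <= 0) || any(q >= 1) || q[1L] >= q[2L]) {
    stop_input("'maxstat_quantiles' must be ordered, strictly inside (0,1)")
  }
  structure(list(vif_threshold = vif_threshold,
                 selection_alpha = selection_alpha,
                 maxstat_quantiles = q,
                 cutpoint_endpoint = cutpoint_endpoint,
                 forced_covariates = as.character(forced_covariates),
                 seed = as.integer(check_number(seed, "seed")),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline or cohort configuration file
#'
#' YAML or JSON with the [pipeline_config()] / [cohort_config()] field
#' names verbatim; unknown fields are an error.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @param type `"pipeline"` or `"cohort"`.
#' @return The corresponding validated config object.
#' @export
read_config <- function(path, type = c("pipeline", "cohort")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_input("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  builder <- if (type == "pipeline") pipeline_config else cohort_config
  if (!is.null(vals$true_beta)) vals$true_beta <- unlist(vals$true_beta)
  if (!is.null(vals$maxstat_quantiles)) {
    vals$maxstat_quantiles <- unlist(vals$maxstat_quantiles)
  }
  unknown <- setdiff(names(vals), names(formals(builder)))
  if (length(unknown)) {
    stop_input("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(builder, vals)
}

#' Read and validate the four pipeline input files
#'
#' Expects RFC-4180 CSV with a header row and `patient_id` as first
#' column: `before.csv` / `after.csv` (one column per metabolite, strictly
#' positive concentrations), `clinical.csv` (covariates including the
#' forced Cox covariates) and `outcomes.csv` (`dfs_time`, `dfs_event`,
#' `os_time`, `os_event`). Patient identifiers are reconciled across the
#' files; mismatches, duplicate ids, non-positive times and non-numeric
#' concentrations are validation errors naming the offending row/column.
#'
#' @param before_path,after_path,clinical_path,outcomes_path file paths.
#' @param forced_covariates clinical columns that must be present (0/1
#'   coded).
#' @return List with `before`, `after` ([metabolite_table()]s),
#'   `clinical` (data frame), `dfs`, `os` ([survival_outcome()]s).
#' @export
read_inputs <- function(before_path, after_path, clinical_path,
                        outcomes_path,
                        forced_covariates = c("her2", "hormonal_receptor")) {
  read_one <- function(path) {
    if (!file.exists(path)) stop_input("input file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (!"patient_id" %in% names(df)) {
      stop_input(path, ": missing 'patient_id' column")
    }
    if (anyDuplicated(df$patient_id)) {
      stop_input(path, ": duplicate patient ids: ",
                 paste(unique(df$patient_id[duplicated(df$patient_id)]),
                       collapse = ", "))
    }
    df
  }
  conc_table <- function(path, timepoint) {
    df <- read_one(path)
    mets <- setdiff(names(df), "patient_id")
    if (!length(mets)) stop_input(path, ": no metabolite columns")
    vals <- as.matrix(df[mets])
    if (!is.numeric(vals)) {
      bad <- mets[!vapply(df[mets], is.numeric, logical(1))][1L]
      stop_input(path, ": non-numeric concentration column '", bad, "'")
    }
    rownames(vals) <- df$patient_id
    metabolite_table(vals, timepoint = timepoint)
  }
  before <- conc_table(before_path, "before")
  after <- conc_table(after_path, "after")
  clinical <- read_one(clinical_path)
  miss <- setdiff(forced_covariates, names(clinical))
  if (length(miss)) {
    stop_input(clinical_path, ": missing forced covariate column(s): ",
               paste(miss, collapse = ", "))
  }
  oc <- read_one(outcomes_path)
  need <- c("dfs_time", "dfs_event", "os_time", "os_event")
  miss <- setdiff(need, names(oc))
  if (length(miss)) {
    stop_input(outcomes_path, ": missing column(s): ",
               paste(miss, collapse = ", "))
  }
  dfs <- survival_outcome(oc$patient_id, oc$dfs_time, oc$dfs_event, "DFS")
  os <- survival_outcome(oc$patient_id, oc$os_time, oc$os_event, "OS")

  ids <- rownames(before$values)
  for (other in list(rownames(after$values), clinical$patient_id,
                     oc$patient_id)) {
    extra <- length(setdiff(other, ids)) + length(setdiff(ids, other))
    if (!setequal(other, ids)) {
      stop_input("patient ids are not identical across input files (",
                 extra, " mismatching id(s))")
    }
  }
  clinical <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(before = before, after = after, clinical = clinical,
       dfs = align_outcome(dfs, ids), os = align_outcome(os, ids))
}

#' Run the full fold-change survival pipeline
#'
#' Executes, in order: sum normalization and paired log fold changes;
#' recursive VIF-guided multivariate Cox modelling of DFS (forced
#' clinical covariates included); selection of metabolites at the
#' configured alpha; MRSS computation; maxstat cutpoint and low/high risk
#' stratification; overall and stage-stratified Kaplan-Meier / log-rank
#' analyses of both endpoints; age/stage-adjusted Cox models; and the
#' cohort characteristics tables. When `config$output_dir` is set, every
#' result table is written as CSV plus a JSON run manifest; the run is
#' deterministic given inputs and configuration.
#'
#' An empty selection (no metabolite below `selection_alpha`) is a
#' graceful stop: the bundle is returned with
#' `status = "empty_selection"` and the artifacts computed up to that
#' point.
#'
#' @param inputs a list as returned by [read_inputs()] or a
#'   `synthetic_cohort` from [generate_cohort()].
#' @param config a [pipeline_config()].
#' @return A result bundle (list) with elements `status`, `fold_changes`,
#'   `vif`, `selection`, `mrss`, `km`, `logrank`, `stage_km`,
#'   `adjusted`, `characteristics`, `manifest`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop_input("'config' must be a pipeline_config")
  }
  if (inherits(inputs, "synthetic_cohort")) {
    inputs <- list(before = inputs$before, after = inputs$after,
                   clinical = inputs$clinical, dfs = inputs$dfs,
                   os = inputs$os)
  }
  need <- c("before", "after", "clinical", "dfs", "os")
  if (!all(need %in% names(inputs))) {
    stop_input("'inputs' needs elements: ",
               paste(setdiff(need, names(inputs)), collapse = ", "))
  }
  out_dir <- config$output_dir
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_csv_lossless(df, file.path(out_dir, file))
    }
  }

  fc <- paired_log_fold_change(sum_normalize(inputs$before),
                               sum_normalize(inputs$after))
  ids <- rownames(fc$log_fc)
  clinical <- inputs$clinical[match(ids, inputs$clinical$patient_id), ,
                              drop = FALSE]
  dfs <- align_outcome(inputs$dfs, ids)
  os <- align_outcome(inputs$os, ids)
  emit(cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
             as.data.frame(fc$log_fc, check.names = FALSE)),
       "fold_changes.csv")

  miss <- setdiff(config$forced_covariates, names(clinical))
  if (length(miss)) {
    stop_input("clinical table is missing forced covariate(s): ",
               paste(miss, collapse = ", "))
  }
  forced <- as.matrix(clinical[config$forced_covariates])
  rownames(forced) <- ids

  rv <- recursive_vif_cox(fc, forced, dfs,
                          threshold = config$vif_threshold)
  emit(vif_trace_table(rv$trace), "vif_trace.csv")
  final_vif <- rv$trace$iterations[[length(rv$trace$iterations)]]$vif
  removed <- vapply(rv$trace$iterations, function(it) it$removed,
                    character(1))
  removed <- removed[!is.na(removed)]
  fm <- cox_table(rv$fit)
  fm$vif <- unname(final_vif[fm$covariate])
  fm <- fm[c("covariate", "vif", "hr", "ci_lower", "ci_upper", "p")]
  if (length(removed)) {
    fm <- rbind(fm, data.frame(covariate = removed,
                               vif = NA_real_, hr = NA_real_,
                               ci_lower = NA_real_, ci_upper = NA_real_,
                               p = NA_real_))
    fm$note <- ifelse(fm$covariate %in% removed,
                      paste0("VIF > ", config$vif_threshold), "")
  } else {
    fm$note <- ""
  }
  emit(fm, "final_model.csv")

  selection <- select_significant(rv$fit, alpha = config$selection_alpha)
  bundle <- list(status = "ok", fold_changes = fc, vif = rv,
                 selection = selection, config = config)
  manifest <- list(
    package = "metabosurv",
    version = as.character(utils::packageVersion("metabosurv")),
    seed = config$seed,
    config = config[setdiff(names(config), "output_dir")],
    n_patients = length(ids),
    n_events_dfs = sum(dfs$event),
    n_events_os = sum(os$event),
    n_vif_cycles = rv$trace$n_removed,
    n_metabolites_surviving = length(rv$trace$surviving_metabolites),
    n_selected = nrow(selection)
  )
  write_manifest <- function() {
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  if (!nrow(selection)) {
    message("no metabolite below alpha = ", config$selection_alpha,
            "; stopping before score construction")
    bundle$status <- "empty_selection"
    manifest$status <- "empty_selection"
    bundle$manifest <- manifest
    write_manifest()
    return(bundle)
  }

  cut_outcome <- if (config$cutpoint_endpoint == "DFS") dfs else os
  mrss <- mrss_stratify(fc, selection, cut_outcome,
                        quantile_range = config$maxstat_quantiles)
  risk <- mrss$risk_label
  emit(data.frame(patient_id = ids, score = unname(mrss$score),
                  risk_label = as.character(risk),
                  stringsAsFactors = FALSE),
       "mrss_scores.csv")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(cutpoint = mrss$cutpoint, max_statistic = mrss$max_statistic,
           candidate_range = mrss$candidate_range,
           adjusted_p = mrss$maxstat$adjusted_p,
           n_low = sum(risk == "low"), n_high = sum(risk == "high")),
      file.path(out_dir, "cutpoint.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  km <- list(); logrank <- list(); stage_km <- list()
  for (ep in c("DFS", "OS")) {
    oc <- if (ep == "DFS") dfs else os
    km[[ep]] <- km_estimate(oc, risk)
    logrank[[ep]] <- logrank_test(oc, risk)
    stage_km[[ep]] <- suppressWarnings(
      stage_stratified_km(risk, clinical$stage, oc))
    emit(do.call(rbind, lapply(names(km[[ep]]), function(g) {
      cv <- km[[ep]][[g]]
      data.frame(group = g, time = cv$time, n_risk = cv$n_risk,
                 n_event = cv$n_event, survival = cv$survival)
    })), paste0("km_", tolower(ep), ".csv"))
    emit(do.call(rbind, lapply(names(stage_km[[ep]]$km), function(g) {
      cv <- stage_km[[ep]]$km[[g]]
      data.frame(group = g, time = cv$time, n_risk = cv$n_risk,
                 n_event = cv$n_event, survival = cv$survival)
    })), paste0("km_", tolower(ep), "_by_stage.csv"))
  }

  adjusted <- adjusted_models(risk, clinical, dfs, os)
  emit(adjusted$table, "table4.csv")

  patient_chars <- intersect(c("age_group", "stage", "menopause",
                               "previous_pregnancy", "bmi_category"),
                             names(clinical))
  char_clin <- clinical
  char_clin$relapse <- ifelse(dfs$event == 1, "Yes", "No")
  char_clin$death <- ifelse(os$event == 1, "Yes", "No")
  characteristics <- build_characteristics_table(
    char_clin, risk, c(patient_chars, "relapse", "death"))
  emit(characteristics, "table2.csv")
  tumor_chars <- intersect(c("her2", "hormonal_receptor"), names(clinical))
  tumor_tab <- NULL
  if (length(tumor_chars)) {
    tumor_tab <- build_characteristics_table(clinical, risk, tumor_chars)
    emit(tumor_tab, "table3.csv")
  }

  manifest$status <- "ok"
  manifest$cutpoint <- mrss$cutpoint
  manifest$n_high_risk <- sum(risk == "high")
  bundle <- c(bundle, list(mrss = mrss, km = km, logrank = logrank,
                           stage_km = stage_km, adjusted = adjusted,
                           characteristics = characteristics,
                           tumor_characteristics = tumor_tab))
  bundle$manifest <- manifest
  write_manifest()
  bundle
}
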