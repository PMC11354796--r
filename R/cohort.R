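#' Standard 35-metabolite serum NMR panel
#'
#' The default metabolite panel: 35 metabolites routinely quantified from
#' 1H NMR serum spectra.
#'
#' @return Character vector of 35 metabolite names.
#' @export
serum_nmr_panel <- function() {
  c("Alanine", "Arginine", "Ascorbate", "Asparagine", "Aspartate",
    "Betaine", "Carnitine", "Choline", "Citrate", "Creatine",
    "Creatinine", "Formate", "Glucose", "Glutamate", "Glutamine",
    "Glycerol", "Glycine", "Histidine", "Isoleucine", "Lactate",
    "Leucine", "Lysine", "Methionine", "myo-Inositol",
    "N,N-Dimethylglycine", "Pantothenate", "Phenylalanine", "Proline",
    "Serine", "sn-Glycero-3-phosphocholine", "Taurine", "Threonine",
    "Tyrosine", "Urea", "Valine")
}

default_true_beta <- function() {
  c(Histidine = log(0.32), Lactate = log(0.32),
    Serine = log(5.06), Taurine = log(2.51))
}

default_clinical_margins <- function() {
  list(
    age_lt50 = 0.43,
    stage = c(I = 0.05, II = 0.60, III = 0.275, IV = 0.075),
    her2_positive = 0.425,
    hormonal_receptor_positive = 0.7375,
    menopause = 0.55,
    previous_pregnancy = 0.9125,
    bmi = c(`normal weight` = 0.30, overweight = 0.2625, obese = 0.4375)
  )
}

# default latent-factor loading matrix. For the canonical serum panel
# with 3 factors the blocks follow metabolic pathways whose serum levels
# co-vary strongly (essential/branched-chain amino acids; one-carbon /
# methylamine metabolism; energy/waste products). For other panels the
# non-signal metabolites are split evenly across the factors.
default_factor_loadings <- function(metabolite_names, n_latent_factors,
                                    signal = character(0)) {
  m <- length(metabolite_names)
  L <- matrix(0, m, n_latent_factors,
              dimnames = list(metabolite_names, NULL))
  canonical <- list(
    c("Isoleucine", "Leucine", "Lysine", "Methionine", "Threonine",
      "Tyrosine", "Valine"),
    c("Betaine", "Carnitine", "Glycine", "Formate"),
    c("Glucose", "Urea")
  )
  if (n_latent_factors == 3L &&
      all(unlist(canonical) %in% metabolite_names)) {
    for (q in 1:3) L[canonical[[q]], q] <- 1
    return(L)
  }
  pool <- setdiff(metabolite_names, signal)
  k <- min(length(pool), max(2L * n_latent_factors, round(0.37 * m)))
  chosen <- pool[seq_len(k)]
  for (i in seq_along(chosen)) {
    L[chosen[i], ((i - 1L) %% n_latent_factors) + 1L] <- 1
  }
  L
}

#' Configuration of a synthetic paired-metabolomics cohort
#'
#' Parameters of the generative model used by [generate_cohort()]:
#' log-normal concentrations driven by latent Gaussian factors (planted
#' collinearity among the fold changes), and proportional-hazards
#' exponential event times driven by a designated set of signal
#' metabolites' log fold changes.
#'
#' @param n_patients cohort size (>= 2; default 80).
#' @param metabolite_names metabolite panel (default
#'   [serum_nmr_panel()]).
#' @param n_latent_factors number of shared latent factors inducing
#'   fold-change collinearity (default 3).
#' @param factor_loading_scale multiplier on the factor loadings; 0 gives
#'   an (asymptotically) orthogonal design (default 1).
#' @param true_beta named vector of log-hazard coefficients per unit log
#'   fold change; names must be metabolites of the panel. Default: the
#'   four-signal pattern with two protective and two harmful metabolites.
#' @param baseline_hazard_rate baseline relapse hazard per month
#'   (default 0.0095, about 42% relapse by 60 months at zero linear
#'   predictor).
#' @param censor_time_months administrative censoring time (default 60).
#' @param fatal_fraction fraction of relapses that progress to death
#'   (default 0.8).
#' @param post_relapse_rate hazard per month of death after relapse
#'   (default 1/12, i.e. mean 12 months from relapse to death).
#' @param logfc_noise_sd idiosyncratic (per-metabolite) standard
#'   deviation of the log fold change (default 0.3).
#' @param clinical_margins category probabilities for the simulated
#'   clinical covariates (see [default_clinical_margins()]); clinical
#'   covariates are drawn independently of the metabolites.
#' @param seed integer seed; one global seed feeds per-stage substreams
#'   so every table is reproducible.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 80L,
                          metabolite_names = serum_nmr_panel(),
                          n_latent_factors = 3L,
                          factor_loading_scale = 1,
                          true_beta = default_true_beta(),
                          baseline_hazard_rate = 0.0095,
                          censor_time_months = 60,
                          fatal_fraction = 0.8,
                          post_relapse_rate = 1 / 12,
                          logfc_noise_sd = 0.3,
                          clinical_margins = default_clinical_margins(),
                          seed = 1L) {
  n_patients <- as.integer(check_number(n_patients, "n_patients", 2))
  metabolite_names <- as.character(metabolite_names)
  if (anyDuplicated(metabolite_names)) {
    stop_input("duplicate metabolite names")
  }
  n_latent_factors <- as.integer(check_number(n_latent_factors,
                                              "n_latent_factors", 1))
  check_number(factor_loading_scale, "factor_loading_scale", 0)
  if (length(true_beta)) {
    if (is.null(names(true_beta)) || !is.numeric(true_beta)) {
      stop_input("'true_beta' must be a named numeric vector")
    }
    unknown <- setdiff(names(true_beta), metabolite_names)
    if (length(unknown)) {
      stop_input("unknown metabolite(s) in true_beta: ",
                 paste(unknown, collapse = ", "))
    }
  }
  check_number(baseline_hazard_rate, "baseline_hazard_rate", 0,
               strict_lower = TRUE)
  check_number(censor_time_months, "censor_time_months", 0,
               strict_lower = TRUE)
  check_number(fatal_fraction, "fatal_fraction", 0, 1)
  check_number(post_relapse_rate, "post_relapse_rate", 0,
               strict_lower = TRUE)
  check_number(logfc_noise_sd, "logfc_noise_sd", 0, strict_lower = TRUE)
  seed <- as.integer(check_number(seed, "seed"))
  structure(list(n_patients = n_patients,
                 metabolite_names = metabolite_names,
                 n_latent_factors = n_latent_factors,
                 factor_loading_scale = factor_loading_scale,
                 true_beta = true_beta,
                 baseline_hazard_rate = baseline_hazard_rate,
                 censor_time_months = censor_time_months,
                 fatal_fraction = fatal_fraction,
                 post_relapse_rate = post_relapse_rate,
                 logfc_noise_sd = logfc_noise_sd,
                 clinical_margins = clinical_margins,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic paired-metabolomics survival cohort
#'
#' Simulates the statistical structure the analysis pipeline assumes,
#' with known ground truth:
#'
#' * Before-treatment log concentrations are Gaussian around
#'   metabolite-specific baselines; the treatment-induced change of each
#'   log concentration is a latent-factor term (shared factors create
#'   strong pairwise correlation among designated metabolite blocks, the
#'   planted collinearity that the VIF recursion must detect) plus a
#'   metabolite-specific mean shift and independent noise. Concentrations
#'   are exponentiated, so they are strictly positive by construction.
#' * The latent relapse (DFS) time is exponential with hazard
#'   `baseline_hazard_rate * exp(sum_m true_beta[m] * logFC[i, m])`,
#'   where `logFC` is the sum-normalized paired log fold change exactly
#'   as the preprocessing module computes it.
#' * The death (OS) time adds an exponential post-relapse increment for a
#'   `fatal_fraction` of relapsers. Both endpoints are administratively
#'   censored at `censor_time_months`.
#' * Clinical covariates are drawn independently of the metabolites from
#'   the configured category margins.
#'
#' The same configuration and seed always produce an identical cohort.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: `before`, `after`
#'   ([metabolite_table()]s), `clinical` (data frame), `dfs`, `os`
#'   ([survival_outcome()]s), and `truth` (generating parameters: full
#'   `true_beta`, per-patient linear predictor, scaled factor loadings,
#'   latent event times).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_input("'config' must be a cohort_config")
  }
  n <- config$n_patients
  mets <- config$metabolite_names
  m <- length(mets)
  ids <- sprintf("P%03d", seq_len(n))

  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  # metabolite-level parameters: baseline abundance and treatment shift
  set.seed(seeds[1L])
  mu <- stats::runif(m, log(0.05), log(3))
  drift <- stats::rnorm(m, 0, 0.1)
  loadings <- default_factor_loadings(mets, config$n_latent_factors,
                                      signal = names(config$true_beta)) *
    config$factor_loading_scale

  # paired concentrations
  set.seed(seeds[2L])
  logB <- matrix(mu, n, m, byrow = TRUE) +
    matrix(stats::rnorm(n * m, 0, 0.35), n, m)
  f <- matrix(stats::rnorm(n * config$n_latent_factors), n)
  delta <- f %*% t(loadings) +
    matrix(drift, n, m, byrow = TRUE) +
    matrix(stats::rnorm(n * m, 0, config$logfc_noise_sd), n, m)
  logA <- logB + delta
  dimnames(logB) <- dimnames(logA) <- list(ids, mets)
  before <- metabolite_table(exp(logB), timepoint = "before")
  after <- metabolite_table(exp(logA), timepoint = "after")

  # ground-truth linear predictor uses the pipeline's own covariates
  fc <- paired_log_fold_change(sum_normalize(before), sum_normalize(after))
  beta_full <- stats::setNames(numeric(m), mets)
  beta_full[names(config$true_beta)] <- config$true_beta
  lp <- drop(fc$log_fc %*% beta_full)

  # clinical covariates, independent of the metabolites
  set.seed(seeds[3L])
  mg <- config$clinical_margins
  draw <- function(levels, prob) {
    sample(levels, n, replace = TRUE, prob = prob)
  }
  clinical <- data.frame(
    patient_id = ids,
    age_group = draw(c("<50", ">=50"), c(mg$age_lt50, 1 - mg$age_lt50)),
    stage = draw(names(mg$stage), mg$stage),
    her2 = draw(c(1L, 0L), c(mg$her2_positive, 1 - mg$her2_positive)),
    hormonal_receptor = draw(c(1L, 0L),
                             c(mg$hormonal_receptor_positive,
                               1 - mg$hormonal_receptor_positive)),
    menopause = draw(c("Yes", "No"), c(mg$menopause, 1 - mg$menopause)),
    previous_pregnancy = draw(c("Yes", "No"),
                              c(mg$previous_pregnancy,
                                1 - mg$previous_pregnancy)),
    bmi_category = draw(names(mg$bmi), mg$bmi),
    stringsAsFactors = FALSE
  )

  # proportional-hazards event times with administrative censoring
  set.seed(seeds[4L])
  cens <- config$censor_time_months
  relapse_t <- stats::rexp(n, rate = config$baseline_hazard_rate * exp(lp))
  dfs_event <- as.numeric(relapse_t <= cens)
  dfs_time <- pmin(relapse_t, cens)
  fatal <- stats::rbinom(n, 1L, config$fatal_fraction)
  death_t <- relapse_t + stats::rexp(n, rate = config$post_relapse_rate)
  os_event <- as.numeric(fatal == 1L & death_t <= cens)
  os_time <- ifelse(os_event == 1, death_t, cens)

  structure(list(
    before = before, after = after, clinical = clinical,
    dfs = survival_outcome(ids, dfs_time, dfs_event, "DFS"),
    os = survival_outcome(ids, os_time, os_event, "OS"),
    truth = list(true_beta = beta_full, linear_predictor = lp,
                 factor_loadings = loadings, latent_relapse_time = relapse_t,
                 latent_death_time = death_t, fatal = fatal),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n = ", x$config$n_patients, ", ",
      length(x$config$metabolite_names), " metabolites; relapses = ",
      sum(x$dfs$event), ", deaths = ", sum(x$os$event), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `before.csv`, `after.csv`, `clinical.csv` and `outcomes.csv`
#' (columns `patient_id`, `dfs_time`, `dfs_event`, `os_time`,
#' `os_event`) in the pipeline input dialect. Doubles are serialized
#' losslessly, so the files round-trip exactly through [read_inputs()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
cohort_to_csv <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop_input("'cohort' must be a synthetic_cohort")
  }
  if (!is.character(directory) || length(directory) != 1L ||
      !nzchar(directory)) {
    stop_input("'directory' must be a non-empty path")
  }
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
  }
  conc_df <- function(tab) {
    cbind(data.frame(patient_id = rownames(tab$values),
                     stringsAsFactors = FALSE),
          as.data.frame(tab$values, check.names = FALSE))
  }
  paths <- file.path(directory, c("before.csv", "after.csv",
                                  "clinical.csv", "outcomes.csv"))
  write_csv_lossless(conc_df(cohort$before), paths[1L])
  write_csv_lossless(conc_df(cohort$after), paths[2L])
  write_csv_lossless(cohort$clinical, paths[3L])
  write_csv_lossless(data.frame(
    patient_id = cohort$dfs$patient_id,
    dfs_time = cohort$dfs$time, dfs_event = cohort$dfs$event,
    os_time = cohort$os$time, os_event = cohort$os$event,
    stringsAsFactors = FALSE
  ), paths[4L])
  invisible(paths)
}
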