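#' Configuration for the end-to-end pipeline
#'
#' @param generator A [generator_config()] (ignored when \code{trials_csv}
#'   and \code{scores_csv} point at real data).
#' @param sampler A [sampler_config()].
#' @param trials_csv,scores_csv Optional paths to existing CSVs; when NULL a
#'   synthetic study is generated.
#' @param run_reliability Logical; run the odd-even split-half stage (doubles
#'   the number of diffusion fits).
#' @param reliability_iter Iteration budget for the half-fits.
#' @param seed Global seed; overrides the generator and sampler seeds.
#' @return A \code{pipeline_config} object.
#' @export
pipeline_config <- function(generator = generator_config(),
                            sampler = sampler_config(),
                            trials_csv = NULL, scores_csv = NULL,
                            run_reliability = TRUE,
                            reliability_iter = 1000, seed = 1) {
  generator$seed <- as.integer(seed)
  sampler$seed <- as.integer(seed)
  structure(list(generator = generator, sampler = sampler,
                 trials_csv = trials_csv, scores_csv = scores_csv,
                 run_reliability = run_reliability,
                 reliability_iter = as.integer(reliability_iter),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) -> preprocess -> diffusion fits per
#' participant and condition -> optional split-half reliability ->
#' descriptive statistics -> SEM Models 1 (baseline) and 2 (angry), with
#' indirect effects for the drift-to-isolation chains.  Every stage is a
#' pure function of its inputs and the global seed, so reruns are
#' byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param verbose Logical; log stage progress.
#' @return A report list with every stage's output.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  if (is.null(cfg$trials_csv)) {
    say("stage simulate: n = %d participants, %d trials/run, seed %d",
        cfg$generator$n_participants, cfg$generator$trials_per_run, cfg$seed)
    study <- simulate_study(cfg$generator)
    trials <- study$trials
    trials$rt <- trials$rt_ms / 1000
    scores_true <- study$scores
    truth <- study$truth
  } else {
    say("stage load: %s", cfg$trials_csv)
    trials <- read_trials(cfg$trials_csv)
    scores_true <- if (!is.null(cfg$scores_csv)) read.csv(cfg$scores_csv)
      else NULL
    truth <- NULL
  }

  say("stage preprocess")
  prep <- preprocess_trials(trials)
  say("  retained %d/%d trials; excluded participants: %s",
      nrow(prep$trials), nrow(trials),
      if (length(prep$excluded)) paste(prep$excluded, collapse = ", ")
      else "none")

  say("stage fit-ddm: %d participant-conditions",
      nrow(unique(prep$trials[, c("participant_id", "run")])))
  fits <- fit_ddm_all(prep$trials, cfg$sampler)

  reliability <- NULL
  if (cfg$run_reliability) {
    say("stage reliability (odd-even split)")
    rel_cfg <- cfg$sampler
    rel_cfg$n_iter <- cfg$reliability_iter
    rel_cfg$burn_in <- cfg$reliability_iter %/% 2
    reliability <- split_half_reliability(prep$trials, rel_cfg)
  }

  # assemble the score table with fitted point estimates
  wide <- stats::reshape(fits[, c("participant_id", "run", "v", "t0")],
                         direction = "wide", idvar = "participant_id",
                         timevar = "run", sep = "_")
  names(wide) <- sub("^(v|t0)\\.", "\\1_", names(wide))
  scores <- scores_true
  if (!is.null(scores)) {
    keep <- setdiff(names(scores),
                    c("t0_baseline", "t0_angry", "v_baseline", "v_angry"))
    scores <- merge(scores[, keep], wide, by = "participant_id")
  } else {
    scores <- wide
  }

  say("stage stats")
  corr_vars <- intersect(c("t0_baseline", "t0_angry", "v_baseline",
                           "v_angry", "AIHQ_BS", "DACOBS_AB", "PENN_ER40",
                           "MiniPONS", "RMET", "Hinting", "PSI", "OSI"),
                         names(scores))
  correlations <- zero_order_correlations(scores[, corr_vars])
  contrasts <- if (all(c("t0_baseline", "t0_angry", "v_baseline",
                         "v_angry") %in% names(scores)))
    condition_contrasts(scores) else NULL

  sem_fits <- list()
  indirect <- list()
  if (all(model_overt()$observed %in% names(scores)) &&
      nrow(scores) > length(model_ddm("baseline")$observed) + 2) {
    say("stage sem: overt two-factor model")
    sem_fits$overt <- fit_ml(model_overt(), scores)
    for (cond in c("baseline", "angry")) {
      mname <- if (cond == "baseline") "model1" else "model2"
      say("stage sem: %s (%s condition)", mname, cond)
      spec <- model_ddm(cond)
      sem_fits[[mname]] <- fit_ml(spec, scores)
      vvar <- paste0("v_", cond)
      t0var <- paste0("t0_", cond)
      indirect[[mname]] <- indirect_effects(
        sem_fits[[mname]],
        list(c(vvar, "SCC", "OSI"), c(t0var, "SCC", "OSI"),
             c(t0var, "SCB", "PSI")))
    }
  }

  report <- list(
    schema = "driftsem-report-1",
    seed = cfg$seed,
    n_participants = length(unique(trials$participant_id)),
    preprocess = list(report = prep$report, excluded = prep$excluded),
    ddm_fits = fits,
    reliability = reliability,
    scores = scores,
    truth = truth,
    correlations = correlations,
    contrasts = contrasts,
    sem = sem_fits,
    indirect = indirect,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(fits, file.path(out_dir, "ddm_params.csv"), row.names = FALSE)
    write.csv(scores, file.path(out_dir, "scores_fitted.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Machine-readable summary of a pipeline report
#'
#' @param report Output of [run_pipeline()].
#' @return A nested list safe to serialize as JSON.
#' @export
report_summary <- function(report) {
  semsum <- lapply(report$sem, function(f)
    list(chi_square = f$chi_square, df = f$df, p_value = f$p_value,
         cfi = f$cfi, rmsea = f$rmsea, n = f$n,
         r_squared = as.list(f$r_squared)))
  list(schema = report$schema, seed = report$seed,
       n_participants = report$n_participants,
       excluded = report$preprocess$excluded,
       mpsf_max = max(report$ddm_fits$mpsf),
       all_converged = all(report$ddm_fits$converged),
       contrasts = report$contrasts,
       icc = if (!is.null(report$reliability)) report$reliability$icc,
       sem = semsum)
}
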