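#' Configuration for the synthetic dot-probe study generator
#'
#' Defines the full generative model a synthetic study is drawn from: a
#' bivariate standard-normal latent layer (social cognitive capacity SCC and
#' social cognitive bias SCB), participant-level diffusion-model parameters
#' for the two task conditions (baseline: neutral-neutral faces; angry:
#' neutral-angry faces) coupled to the latents, observed indicators loading
#' on the latents, and the two isolation outcomes (perceived social
#' isolation PSI, objective social isolation OSI) produced by structural
#' paths from the latents and the shared diffusion traits.
#'
#' Couplings and paths are on the standardized (correlation) scale: latents
#' and the participant-level diffusion traits have unit variance, so every
#' coupling, loading and structural path is directly a standardized
#' coefficient of the generating model.
#'
#' @param n_participants Number of participants.
#' @param trials_per_run Trials per run/condition (default 160, the task's
#'   run length).
#' @param seed Integer seed; fully determines every generated table.
#' @param latent_cor Correlation between SCC and SCB.
#' @param latent_loadings Named vector of standardized loadings for the six
#'   indicators (SCC: MiniPONS, PENN_ER40, RMET, Hinting; SCB: DACOBS_AB,
#'   AIHQ_BS).
#' @param structural_paths Named vector of standardized structural paths,
#'   names of the form \code{"predictor->outcome"}; predictors may be SCC,
#'   SCB, t0, v (the condition-shared diffusion traits), outcomes PSI, OSI.
#' @param residual_cor Residual correlation between PSI and OSI.
#' @param residual_sds Optional named vector overriding indicator residual
#'   SDs; default \code{sqrt(1 - loading^2)} (unit-variance indicators).
#' @param ddm_population_means List with elements \code{baseline} and
#'   \code{angry}, each a [ddm_params()] of population means.
#' @param ddm_population_sds Matrix (5 x 2, rows v,a,t0,st0,sv; columns
#'   baseline, angry) of population SDs, or a named vector recycled over
#'   conditions.
#' @param ddm_cross_condition_cor Named vector: correlation of each
#'   parameter's participant-level deviation across the two conditions.
#' @param ddm_latent_coupling Named vector, names \code{"param~latent"}
#'   (e.g. \code{"v~SCC"}): standardized coupling of the condition-shared
#'   diffusion trait to a latent.
#' @param rt_deadline Seconds; simulated responses slower than this are
#'   recorded as non-responses ("none").
#' @return A \code{generator_config} object.
#' @export
generator_config <- function(n_participants = 271,
                             trials_per_run = 160,
                             seed = 1,
                             latent_cor = -0.32,
                             latent_loadings = c(MiniPONS = 0.60,
                                                 PENN_ER40 = 0.55,
                                                 RMET = 0.50,
                                                 Hinting = 0.40,
                                                 DACOBS_AB = 0.65,
                                                 AIHQ_BS = 0.60),
                             structural_paths = c("SCB->PSI" = 0.56,
                                                  "SCC->PSI" = 0.00,
                                                  "SCB->OSI" = 0.31,
                                                  "SCC->OSI" = -0.26,
                                                  "t0->PSI" = -0.16),
                             residual_cor = 0.45,
                             residual_sds = NULL,
                             ddm_population_means = list(
                               baseline = ddm_params(v = 4.098, a = 1.0,
                                                     t0 = 0.347, st0 = 0.15,
                                                     sv = 0.8),
                               angry = ddm_params(v = 4.003, a = 1.0,
                                                  t0 = 0.343, st0 = 0.15,
                                                  sv = 0.8)),
                             ddm_population_sds = cbind(
                               baseline = c(v = 0.443, a = 0.15, t0 = 0.039,
                                            st0 = 0.04, sv = 0.25),
                               angry = c(v = 0.483, a = 0.15, t0 = 0.039,
                                         st0 = 0.04, sv = 0.25)),
                             ddm_cross_condition_cor = c(v = 0.758, a = 0.85,
                                                         t0 = 0.738,
                                                         st0 = 0.5, sv = 0.5),
                             ddm_latent_coupling = c("v~SCC" = 0.33,
                                                     "t0~SCB" = 0.20),
                             rt_deadline = 1.5) {
  stopifnot(n_participants >= 1, trials_per_run >= 1)
  if (abs(latent_cor) >= 1)
    stop("latent covariance matrix is not positive definite", call. = FALSE)
  if (is.null(dim(ddm_population_sds)))
    ddm_population_sds <- cbind(baseline = ddm_population_sds,
                                angry = ddm_population_sds)
  if (any(ddm_population_sds < 0)) stop("SDs must be nonnegative", call. = FALSE)
  pnames <- c("v", "a", "t0", "st0", "sv")
  stopifnot(all(pnames %in% rownames(ddm_population_sds)),
            all(pnames %in% names(ddm_cross_condition_cor)))
  for (m in ddm_population_means) validate_ddm_params(m)
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    trials_per_run = as.integer(trials_per_run),
    seed = as.integer(seed),
    latent_cor = latent_cor,
    latent_loadings = latent_loadings,
    structural_paths = structural_paths,
    residual_cor = residual_cor,
    residual_sds = residual_sds,
    ddm_population_means = ddm_population_means,
    ddm_population_sds = ddm_population_sds[pnames, , drop = FALSE],
    ddm_cross_condition_cor = ddm_cross_condition_cor[pnames],
    ddm_latent_coupling = ddm_latent_coupling,
    rt_deadline = rt_deadline), class = "generator_config")
  # shared-trait construction must leave nonnegative unique variance, and the
  # outcome layer nonnegative residual variance
  for (p in pnames) {
    cc <- coupling_vector(cfg, p)
    if (drop(t(cc) %*% latent_R(cfg) %*% cc) > 1 + 1e-12)
      stop("latent coupling for ", p, " exceeds unit variance", call. = FALSE)
  }
  sysv <- outcome_systematic_var(cfg)
  if (any(sysv >= 1))
    stop("structural paths imply nonpositive outcome residual variance",
         call. = FALSE)
  cfg
}

latent_R <- function(cfg) {
  matrix(c(1, cfg$latent_cor, cfg$latent_cor, 1), 2, 2,
         dimnames = list(c("SCC", "SCB"), c("SCC", "SCB")))
}

coupling_vector <- function(cfg, param) {
  cc <- c(SCC = 0, SCB = 0)
  nm <- names(cfg$ddm_latent_coupling)
  for (i in seq_along(nm)) {
    parts <- strsplit(nm[i], "~", fixed = TRUE)[[1]]
    if (parts[1] == param) cc[parts[2]] <- cfg$ddm_latent_coupling[i]
  }
  cc
}

path_value <- function(cfg, predictor, outcome) {
  key <- paste0(predictor, "->", outcome)
  if (key %in% names(cfg$structural_paths)) unname(cfg$structural_paths[key]) else 0
}

# Covariance matrix of the standardized predictors (SCC, SCB, t0 trait, v
# trait) implied by the generating model.
predictor_cov <- function(cfg) {
  R <- latent_R(cfg)
  ct0 <- coupling_vector(cfg, "t0")
  cv <- coupling_vector(cfg, "v")
  S <- matrix(0, 4, 4, dimnames = list(c("SCC", "SCB", "t0", "v"),
                                       c("SCC", "SCB", "t0", "v")))
  S[1:2, 1:2] <- R
  S["t0", c("SCC", "SCB")] <- S[c("SCC", "SCB"), "t0"] <- R %*% ct0
  S["v", c("SCC", "SCB")] <- S[c("SCC", "SCB"), "v"] <- R %*% cv
  S["t0", "t0"] <- S["v", "v"] <- 1
  S["t0", "v"] <- S["v", "t0"] <- drop(t(ct0) %*% R %*% cv)
  S
}

outcome_systematic_var <- function(cfg) {
  S <- predictor_cov(cfg)
  out <- c(PSI = 0, OSI = 0)
  for (o in names(out)) {
    b <- vapply(rownames(S), function(pr) path_value(cfg, pr, o), 0)
    out[o] <- drop(t(b) %*% S %*% b)
  }
  out
}

#' Draw per-participant latent scores and true diffusion parameters
#'
#' For each participant, SCC and SCB are drawn from a bivariate standard
#' normal.  Each diffusion parameter has a unit-variance condition-shared
#' trait (a linear combination of the latents plus unique noise) and
#' condition-specific deviations whose cross-condition correlation is set by
#' the config; parameter values are population mean + SD * deviation.
#' Draws violating \code{t0 - st0/2 > 0.05} or \code{a > 0.2} are redrawn up
#' to 1000 times, then clipped, so the likelihood is always well defined.
#'
#' @param cfg A [generator_config()].
#' @return A data.frame with one row per participant: \code{participant_id},
#'   latent scores \code{SCC}, \code{SCB}, shared traits \code{z_v} ...
#'   \code{z_sv}, and true parameters \code{v_baseline} ... \code{sv_angry}.
#' @export
generate_participant_params <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_participants
  pnames <- c("v", "a", "t0", "st0", "sv")
  withr_seed(cfg$seed, {
    R <- latent_R(cfg)
    L <- chol(R)
    lat <- matrix(rnorm(2 * n), n, 2) %*% L
    colnames(lat) <- c("SCC", "SCB")
    out <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                      SCC = lat[, "SCC"], SCB = lat[, "SCB"])
    for (p in pnames) {
      cc <- coupling_vector(cfg, p)
      explained <- drop(t(cc) %*% R %*% cc)
      shared <- drop(lat %*% cc) + sqrt(max(0, 1 - explained)) * rnorm(n)
      rho <- cfg$ddm_cross_condition_cor[p]
      out[[paste0("z_", p)]] <- shared
      for (cond in c("baseline", "angry")) {
        dev <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
        mu <- cfg$ddm_population_means[[cond]][[p]]
        sdv <- cfg$ddm_population_sds[p, cond]
        out[[paste0(p, "_", cond)]] <- mu + sdv * dev
      }
    }
    # enforce parameter validity: redraw condition deviations, then clip
    for (cond in c("baseline", "angry")) {
      acol <- paste0("a_", cond)
      t0col <- paste0("t0_", cond)
      st0col <- paste0("st0_", cond)
      svcol <- paste0("sv_", cond)
      for (i in seq_len(n)) {
        ok <- function() {
          out[i, acol] > 0.2 && out[i, st0col] >= 0 && out[i, svcol] >= 0 &&
            out[i, t0col] - out[i, st0col] / 2 > 0.05
        }
        tries <- 0
        while (!ok() && tries < 1000) {
          for (p in pnames) {
            rho <- cfg$ddm_cross_condition_cor[p]
            dev <- sqrt(rho) * out[i, paste0("z_", p)] +
              sqrt(1 - rho) * rnorm(1)
            out[i, paste0(p, "_", cond)] <-
              cfg$ddm_population_means[[cond]][[p]] +
              cfg$ddm_population_sds[p, cond] * dev
          }
          tries <- tries + 1
        }
        if (!ok()) {
          out[i, acol] <- max(out[i, acol], 0.21)
          out[i, svcol] <- max(out[i, svcol], 0)
          out[i, st0col] <- max(out[i, st0col], 0)
          out[i, st0col] <- min(out[i, st0col],
                                2 * (out[i, t0col] - 0.051))
          if (out[i, t0col] - out[i, st0col] / 2 <= 0.05) {
            out[i, st0col] <- 0
            out[i, t0col] <- max(out[i, t0col], 0.051)
          }
        }
      }
    }
    out
  })
}

# evaluate expr with a temporary RNG state seeded at seed
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate dot-probe trials for one parameter set
#'
#' Thin wrapper over [simulate_ddm()] returning trial records in the task's
#' layout (trial index, RT, correct/incorrect), with responses slower than
#' the deadline recorded as non-responses.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials.
#' @param seed Integer seed.
#' @param rt_deadline Non-response threshold in seconds.
#' @return Data.frame: \code{trial_index}, \code{rt} (s, NA for none),
#'   \code{response} in \{correct, incorrect, none\}.
#' @export
generate_trials <- function(params, n, seed, rt_deadline = 1.5) {
  sim <- simulate_ddm(n, params, seed)
  response <- ifelse(sim$correct, "correct", "incorrect")
  none <- sim$rt > rt_deadline
  response[none] <- "none"
  sim$rt[none] <- NA_real_
  data.frame(trial_index = seq_len(n), rt = sim$rt, response = response)
}

#' Generate the participant-level score table (and item-level matrices)
#'
#' Observed indicators are loading x latent + Gaussian residual, rescaled to
#' realistic questionnaire means/SDs.  PSI and OSI are built from the
#' structural paths applied to SCC, SCB and the shared diffusion traits,
#' plus correlated residuals scaled so both outcomes have unit variance
#' before rescaling.  Item-level matrices (UCLA-R: 20 items, SNS: 6 items)
#' come from a one-factor model per questionnaire with the standardized
#' outcome as the factor.
#'
#' @param cfg A [generator_config()].
#' @param participant_params Output of [generate_participant_params()].
#' @param items Logical; also generate item-level matrices.
#' @return List with \code{scores} (the score table, including the true
#'   diffusion t0/v per condition), and if requested \code{items_ucla},
#'   \code{items_sns}.
#' @export
generate_scores <- function(cfg, participant_params, items = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  pp <- participant_params
  n <- nrow(pp)
  lam <- cfg$latent_loadings
  ind_latent <- c(MiniPONS = "SCC", PENN_ER40 = "SCC", RMET = "SCC",
                  Hinting = "SCC", DACOBS_AB = "SCB", AIHQ_BS = "SCB")
  missing_l <- setdiff(names(ind_latent), names(lam))
  if (length(missing_l))
    stop("missing loadings for: ", paste(missing_l, collapse = ", "),
         call. = FALSE)
  # realistic raw scales (mean, sd) for the indicators and totals
  scales <- list(PENN_ER40 = c(82, 8), MiniPONS = c(47.2, 4),
                 RMET = c(26.1, 3.3), Hinting = c(17, 2.2),
                 AIHQ_BS = c(2.7, 0.6), DACOBS_AB = c(22.9, 6.1),
                 PSI = c(40, 12), OSI = c(12, 6))
  withr_seed(cfg$seed + 1L, {
    std <- data.frame(row.names = seq_len(n))
    for (ind in names(ind_latent)) {
      rs <- if (!is.null(cfg$residual_sds) && ind %in% names(cfg$residual_sds))
        cfg$residual_sds[ind] else sqrt(max(0, 1 - lam[ind]^2))
      std[[ind]] <- lam[ind] * pp[[ind_latent[ind]]] + rs * rnorm(n)
    }
    sysv <- outcome_systematic_var(cfg)
    rvar <- 1 - sysv
    rsd <- sqrt(rvar)
    Rres <- matrix(c(1, cfg$residual_cor, cfg$residual_cor, 1), 2, 2)
    eres <- matrix(rnorm(2 * n), n, 2) %*% chol(Rres)
    preds <- cbind(SCC = pp$SCC, SCB = pp$SCB, t0 = pp$z_t0, v = pp$z_v)
    for (k in 1:2) {
      o <- c("PSI", "OSI")[k]
      b <- vapply(colnames(preds), function(pr) path_value(cfg, pr, o), 0)
      std[[o]] <- drop(preds %*% b) + rsd[o] * eres[, k]
    }
    scores <- data.frame(participant_id = pp$participant_id)
    for (v in names(scales))
      scores[[v]] <- scales[[v]][1] + scales[[v]][2] * std[[v]]
    scores$t0_baseline <- pp$t0_baseline
    scores$t0_angry <- pp$t0_angry
    scores$v_baseline <- pp$v_baseline
    scores$v_angry <- pp$v_angry
    out <- list(scores = scores)
    if (items) {
      gen_items <- function(factor_std, k, loading, center, slope, lo, hi) {
        m <- matrix(0, n, k)
        for (j in seq_len(k)) {
          x <- loading * factor_std + sqrt(1 - loading^2) * rnorm(n)
          m[, j] <- pmin(pmax(center + slope * x, lo), hi)
        }
        m
      }
      # loadings chosen to reproduce alpha ~ .94 (UCLA-R) and ~ .84 (SNS)
      out$items_ucla <- gen_items(std$PSI, 20, 0.66, 2.5, 0.7, 1, 4)
      out$items_sns <- gen_items(-std$OSI, 6, 0.68, 2.5, 1.2, 0, 5)
      colnames(out$items_ucla) <- paste0("ucla_", 1:20)
      colnames(out$items_sns) <- paste0("sns_", 1:6)
    }
    out
  })
}

#' Simulate a complete synthetic dot-probe study
#'
#' Draws participant parameters, simulates trial-level data for both runs,
#' and builds the score table.  The returned trial table uses the on-disk
#' layout (RT in ms, run labels baseline/angry).
#'
#' @param cfg A [generator_config()].
#' @param items Logical; also generate item-level questionnaire matrices.
#' @return List: \code{trials} (trial table), \code{scores} (score table),
#'   \code{truth} (participant-level generating values), and optional item
#'   matrices.
#' @export
simulate_study <- function(cfg, items = TRUE) {
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = items)
  seeds <- withr_seed(cfg$seed + 2L,
                      matrix(sample.int(.Machine$integer.max - 1,
                                        nrow(pp) * 2), ncol = 2))
  trials <- vector("list", nrow(pp) * 2)
  k <- 0
  for (i in seq_len(nrow(pp))) {
    for (ci in 1:2) {
      cond <- c("baseline", "angry")[ci]
      par <- ddm_params(v = pp[i, paste0("v_", cond)],
                        a = pp[i, paste0("a_", cond)],
                        t0 = pp[i, paste0("t0_", cond)],
                        st0 = pp[i, paste0("st0_", cond)],
                        sv = pp[i, paste0("sv_", cond)])
      tr <- generate_trials(par, cfg$trials_per_run, seeds[i, ci],
                            rt_deadline = cfg$rt_deadline)
      k <- k + 1
      trials[[k]] <- data.frame(participant_id = pp$participant_id[i],
                                run = cond, trial_index = tr$trial_index,
                                rt_ms = tr$rt * 1000, response = tr$response)
    }
  }
  list(trials = do.call(rbind, trials), scores = sc$scores, truth = pp,
       items_ucla = sc$items_ucla, items_sns = sc$items_sns)
}

#' Write a simulated study to CSV files
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (trials, scores, truth).
#' @export
write_study_csv <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             scores = file.path(dir, "scores.csv"),
             truth = file.path(dir, "truth.csv"))
  write.csv(study$trials, paths["trials"], row.names = FALSE)
  write.csv(study$scores, paths["scores"], row.names = FALSE)
  write.csv(study$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
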