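test_that("degrees of freedom: overt model 16, extended models 24, saturated 0", {
  expect_equal(count_df(model_overt()), 16L)
  expect_equal(count_df(model_ddm("baseline")), 24L)
  expect_equal(count_df(model_ddm("angry")), 24L)
  # saturated: three observed exogenous variables, all variances and
  # covariances free -> 3 + 3 parameters = 6 moments
  sat <- sem_model(covariances = list(c("x", "y"), c("x", "z"),
                                      c("y", "z")))
  expect_equal(count_df(sat), 0L)
})

test_that("df equals moments minus the optimizer's free-parameter count", {
  for (spec in list(model_overt(), model_ddm("angry"))) {
    p <- length(spec$observed)
    expect_equal(count_df(spec),
                 as.integer(p * (p + 1) / 2 - sum(spec$par_table$free)))
  }
})

test_that("data simulated exactly from the model's implied covariance fit perfectly", {
  Sigma <- overt_population_cov()
  dat <- data_with_cov(400, Sigma, seed = 3)
  fit <- fit_ml(model_overt(), dat)
  expect_lt(fit$chi_square, 1e-4)
  expect_equal(fit$cfi, 1)
  expect_lt(fit$rmsea, 1e-4)
  # free parameters recover the generating values
  expect_equal(unname(sem_coef(fit, "SCC=~PENN_ER40")["est"]), 0.9,
               tolerance = 1e-4)
  expect_equal(unname(sem_coef(fit, "PSI~SCB")["est"]), 0.8,
               tolerance = 1e-4)
  expect_equal(unname(sem_coef(fit, "OSI~SCC")["est"]), -0.5,
               tolerance = 1e-4)
  expect_equal(unname(sem_coef(fit, "SCC~~SCB")["est"]), -0.2,
               tolerance = 1e-4)
  # implied covariance at the optimum is symmetric positive definite
  ev <- eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(fit$Sigma, t(fit$Sigma), tolerance = 1e-10)
})

test_that("standardized paths are recovered from a large generated study", {
  # generating model restricted to the overt layer (no diffusion-to-outcome
  # paths or couplings) so the fitted model is correctly specified and the
  # config values are the exact standardized truth
  cfg <- generator_config(n_participants = 2000, seed = 5,
                          structural_paths = c("SCB->PSI" = 0.56,
                                               "SCC->PSI" = 0.00,
                                               "SCB->OSI" = 0.31,
                                               "SCC->OSI" = -0.26),
                          ddm_latent_coupling = c("v~SCC" = 0))
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = FALSE)$scores
  fit <- fit_ml(model_overt(), sc)
  truth <- c("PSI~SCB" = 0.56, "PSI~SCC" = 0.00, "OSI~SCB" = 0.31,
             "OSI~SCC" = -0.26, "SCC~~SCB" = -0.32)
  for (lab in names(truth))
    expect_lt(abs(sem_coef(fit, lab, std = TRUE)["est"] - truth[lab]),
              0.05)
  # loadings too
  for (ind in c("MiniPONS", "PENN_ER40", "RMET", "Hinting")) {
    expect_lt(abs(sem_coef(fit, paste0("SCC=~", ind), std = TRUE)["est"] -
                    cfg$latent_loadings[ind]), 0.05)
  }
})

test_that("both optimizers reach the same discrepancy minimum", {
  cfg <- generator_config(n_participants = 600, seed = 19)
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = FALSE)$scores
  f1 <- fit_ml(model_ddm("baseline"), sc)
  f2 <- fit_ml(model_ddm("baseline"), sc, optimizer = "BFGS")
  expect_lt(abs(f1$F_min - f2$F_min), 1e-4)
  expect_lt(max(abs(f1$par_table$std - f2$par_table$std)), 1e-3)
})

test_that("standardized and unstandardized solutions imply the same chi-square", {
  cfg <- generator_config(n_participants = 500, seed = 23)
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = FALSE)$scores
  fit_raw <- fit_ml(model_overt(), sc)
  sc_std <- sc
  for (v in model_overt()$observed) sc_std[[v]] <- as.numeric(scale(sc[[v]]))
  fit_std <- fit_ml(model_overt(), sc_std)
  expect_equal(fit_raw$chi_square, fit_std$chi_square, tolerance = 1e-5)
  expect_equal(fit_raw$cfi, fit_std$cfi, tolerance = 1e-7)
})

test_that("indirect effects follow the delta-method arithmetic", {
  # a = 0.5, b = 0.4, Var = 0.01 each, zero covariance
  se_expected <- sqrt(0.4^2 * 0.01 + 0.5^2 * 0.01)
  # build a minimal fake fit exercising the published formula
  tab <- data.frame(type = c("regression", "regression"),
                    lhs = c("M", "Y"), op = "~", rhs = c("X", "M"),
                    free = TRUE, value = NA, est = c(0.5, 0.4),
                    se = 0.1, z = NA, p = NA, std = c(0.5, 0.4))
  tab$label <- paste0(tab$lhs, "~", tab$rhs)
  fit <- structure(list(par_table = tab, vcov = diag(0.01, 2)),
                   class = "sem_fit")
  ie <- indirect_effects(fit, list(c("X", "M", "Y")))
  expect_equal(ie$est, 0.2)
  expect_equal(ie$se, se_expected, tolerance = 1e-12)
  # a zero segment zeroes the product
  fit$par_table$est[1] <- 0
  ie0 <- indirect_effects(fit, list(c("X", "M", "Y")))
  expect_equal(ie0$est, 0)
  expect_error(indirect_effects(fit, list(c("X", "Q", "Y"))), "absent")
})

test_that("delta-method SE agrees with a bootstrap on a synthetic study", {
  cfg <- generator_config(n_participants = 500, seed = 37)
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = FALSE)$scores
  fit <- fit_ml(model_ddm("baseline"), sc)
  ie <- indirect_effects(fit, list(c("v_baseline", "SCC", "OSI")))
  set.seed(41)
  reps <- 200
  boot <- replicate(reps, {
    idx <- sample.int(nrow(sc), replace = TRUE)
    f <- tryCatch(fit_ml(model_ddm("baseline"), sc[idx, ]),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f)) NA_real_
    else indirect_effects(f, list(c("v_baseline", "SCC", "OSI")))$est
  })
  boot_se <- sd(boot, na.rm = TRUE)
  expect_lt(abs(ie$se - boot_se) / boot_se, 0.30)
})

test_that("suppression is flagged only for opposite-signed significant effects", {
  mkfit <- function(a, b, direct, se = 0.02) {
    tab <- data.frame(type = "regression", lhs = c("M", "Y", "Y"), op = "~",
                      rhs = c("X", "M", "X"), free = TRUE, value = NA,
                      est = c(a, b, direct), se = se, z = NA, p = NA,
                      std = c(a, b, direct))
    tab$z <- tab$est / tab$se
    tab$p <- 2 * pnorm(-abs(tab$z))
    tab$label <- paste0(tab$lhs, "~", tab$rhs)
    structure(list(par_table = tab, vcov = diag(se^2, 3)),
              class = "sem_fit")
  }
  res <- detect_suppression(mkfit(0.7, 0.2, -0.18), "X", "Y", "M")
  expect_true(res$suppression)
  expect_equal(res$total, -0.18 + 0.14, tolerance = 1e-12)
  expect_false(detect_suppression(mkfit(0.7, 0.2, 0.18),
                                  "X", "Y", "M")$suppression)
  expect_false(detect_suppression(mkfit(0.7, 0.2, -0.001, se = 0.5),
                                  "X", "Y", "M")$suppression)
})
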