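test_that("degenerate config collapses every participant onto the population means", {
  cfg <- generator_config(n_participants = 5, seed = 1,
                          ddm_population_sds = c(v = 0, a = 0, t0 = 0,
                                                 st0 = 0, sv = 0),
                          ddm_latent_coupling = c("v~SCC" = 0))
  pp <- generate_participant_params(cfg)
  expect_true(all(pp$v_baseline == 4.098))
  expect_true(all(pp$t0_angry == 0.343))
  expect_true(all(pp$a_baseline == 1.0))
})

test_that("generation is bit-identical under the same seed", {
  cfg <- generator_config(n_participants = 8, trials_per_run = 30, seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$truth, s2$truth)
})

test_that("latent coupling reproduces its closed-form correlation", {
  # with a single coupling c and uncorrelated latents, the generating
  # algebra gives corr(param, latent) = sqrt(rho_cross) * c
  cfg <- generator_config(n_participants = 2000, seed = 13, latent_cor = 0,
                          ddm_latent_coupling = c("v~SCC" = 0.5),
                          ddm_cross_condition_cor = c(v = 1, a = 0.85,
                                                      t0 = 0.738, st0 = 0.5,
                                                      sv = 0.5))
  pp <- generate_participant_params(cfg)
  expect_lt(abs(cor(pp$v_baseline, pp$SCC) - 0.5), 0.05)
  # cross-condition correlation knob is honoured
  expect_lt(abs(cor(pp$t0_baseline, pp$t0_angry) - 0.738), 0.05)
})

test_that("all generated parameter sets satisfy the likelihood-support constraints", {
  cfg <- generator_config(n_participants = 200, seed = 3,
                          ddm_population_sds = c(v = 1, a = 0.5, t0 = 0.15,
                                                 st0 = 0.15, sv = 0.5))
  pp <- generate_participant_params(cfg)
  for (cond in c("baseline", "angry")) {
    expect_true(all(pp[[paste0("a_", cond)]] > 0.2))
    expect_true(all(pp[[paste0("t0_", cond)]] -
                      pp[[paste0("st0_", cond)]] / 2 > 0.05))
    expect_true(all(pp[[paste0("st0_", cond)]] >= 0))
    expect_true(all(pp[[paste0("sv_", cond)]] >= 0))
  }
})

test_that("score construction matches the generating covariance algebra", {
  # lighter residuals make the forced correlations visible at modest n
  cfg <- generator_config(n_participants = 5000, seed = 29,
                          structural_paths = c("SCB->PSI" = 0.6))
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = FALSE)$scores
  # regression of standardized PSI on standardized SCB ~ 0.6
  b <- coef(lm(scale(sc$PSI) ~ scale(pp$SCB)))[2]
  expect_lt(abs(b - 0.6), 0.05)
  # indicator correlation forced by the loadings: r = l1 * l2 for a shared
  # latent with unit variance
  r_obs <- cor(sc$MiniPONS, sc$PENN_ER40)
  r_exp <- cfg$latent_loadings["MiniPONS"] * cfg$latent_loadings["PENN_ER40"]
  expect_lt(abs(r_obs - r_exp), 0.05)
})

test_that("noiseless indicators hit the loading-forced correlations exactly", {
  cfg <- generator_config(n_participants = 400, seed = 31,
                          residual_sds = c(MiniPONS = 0, PENN_ER40 = 0,
                                           RMET = 0, Hinting = 0,
                                           DACOBS_AB = 0, AIHQ_BS = 0))
  pp <- generate_participant_params(cfg)
  sc <- generate_scores(cfg, pp, items = FALSE)$scores
  expect_equal(cor(sc$MiniPONS, sc$PENN_ER40), 1, tolerance = 1e-10)
  expect_equal(cor(sc$DACOBS_AB, sc$AIHQ_BS), 1, tolerance = 1e-10)
})

test_that("item-level matrices reproduce the questionnaire reliabilities", {
  cfg <- generator_config(n_participants = 3000, seed = 17)
  pp <- generate_participant_params(cfg)
  out <- generate_scores(cfg, pp, items = TRUE)
  expect_equal(dim(out$items_ucla), c(3000, 20))
  expect_equal(dim(out$items_sns), c(3000, 6))
  expect_equal(cronbach_alpha(out$items_ucla), 0.94, tolerance = 0.03)
  expect_equal(cronbach_alpha(out$items_sns), 0.84, tolerance = 0.04)
})

test_that("missing loadings raise a configuration error", {
  cfg <- generator_config(n_participants = 10, seed = 1)
  cfg$latent_loadings <- cfg$latent_loadings[-1]
  pp <- generate_participant_params(cfg)
  expect_error(generate_scores(cfg, pp), "missing loadings")
})

test_that("trial tables have the task layout and deadline-censored responses", {
  cfg <- generator_config(n_participants = 3, trials_per_run = 40, seed = 9)
  st <- simulate_study(cfg)
  expect_setequal(unique(st$trials$run), c("baseline", "angry"))
  expect_equal(nrow(st$trials), 3 * 2 * 40)
  expect_setequal(setdiff(c("participant_id", "run", "trial_index",
                            "rt_ms", "response"), names(st$trials)),
                  character(0))
  none <- st$trials$response == "none"
  expect_true(all(is.na(st$trials$rt_ms[none])))
  expect_true(all(st$trials$rt_ms[!none] > 200 * 0))  # positive RTs
})

test_that("an over-strong latent coupling is rejected at construction", {
  expect_error(generator_config(ddm_latent_coupling = c("v~SCC" = 1.2)),
               "unit variance")
  expect_error(generator_config(latent_cor = 1.0), "positive definite")
})
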