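#' Declarative structural equation model specification
#'
#' Builds a path-model specification from a measurement part (latents and
#' their indicators), structural regressions, and covariance terms.  The
#' first loading of every latent is fixed to 1 for identification; every
#' variable receives a free (residual) variance; observed variables that
#' never appear as an outcome are treated as exogenous, with free variances
#' and, between every pair of them, a free covariance (exogenous variables
#' are modeled as correlated by default).
#'
#' @param latents Named list: latent name -> character vector of indicator
#'   names (>= 2 each).
#' @param regressions Named list: outcome -> character vector of predictors.
#' @param covariances List of length-2 character vectors: pairs of variables
#'   with a free (residual) covariance.
#' @return A \code{sem_spec} object with the internal parameter table.
#' @examples
#' spec <- model_overt()
#' count_df(spec)
#' @export
sem_model <- function(latents = list(), regressions = list(),
                      covariances = list()) {
  stopifnot(is.list(latents), is.list(regressions), is.list(covariances))
  for (l in latents)
    if (length(l) < 2) stop("every latent needs >= 2 indicators", call. = FALSE)
  lat_names <- names(latents)
  indicators <- unlist(latents, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("an indicator may load on one latent only", call. = FALSE)
  reg_vars <- unique(c(names(regressions), unlist(regressions)))
  cov_vars <- unique(unlist(covariances))
  observed <- unique(c(indicators,
                       setdiff(c(reg_vars, cov_vars), lat_names)))
  vars <- c(observed, lat_names)
  outcomes <- names(regressions)
  exo_obs <- setdiff(observed, c(indicators, outcomes))

  par <- list()
  add <- function(type, lhs, op, rhs, free, value = NA_real_) {
    par[[length(par) + 1]] <<- data.frame(type = type, lhs = lhs, op = op,
                                          rhs = rhs, free = free,
                                          value = value)
  }
  for (l in lat_names) {
    inds <- latents[[l]]
    add("loading", l, "=~", inds[1], FALSE, 1)
    for (ind in inds[-1]) add("loading", l, "=~", ind, TRUE)
  }
  for (o in outcomes)
    for (pr in regressions[[o]]) add("regression", o, "~", pr, TRUE)
  for (v in vars) add("variance", v, "~~", v, TRUE)
  for (cv in covariances) {
    stopifnot(length(cv) == 2)
    add("covariance", cv[1], "~~", cv[2], TRUE)
  }
  if (length(exo_obs) > 1) {
    for (i in seq_len(length(exo_obs) - 1))
      for (j in seq(i + 1, length(exo_obs))) {
        pair <- c(exo_obs[i], exo_obs[j])
        already <- any(vapply(covariances, function(cv)
          setequal(cv, pair), TRUE))
        if (!already) add("covariance", pair[1], "~~", pair[2], TRUE)
      }
  }
  tab <- do.call(rbind, par)
  tab$label <- paste0(tab$lhs, tab$op, tab$rhs)
  spec <- structure(list(latents = latents, regressions = regressions,
                         covariances = covariances, observed = observed,
                         lat_names = lat_names, vars = vars,
                         exogenous_observed = exo_obs, par_table = tab),
                    class = "sem_spec")
  if (count_df(spec) < 0)
    stop("model not identified: negative degrees of freedom", call. = FALSE)
  spec
}

#' Degrees of freedom of a model specification
#'
#' Sample moments \code{p(p+1)/2} minus the number of free parameters.
#'
#' @param spec A [sem_model()] specification.
#' @param p Number of observed variables (defaults to the spec's own count).
#' @return Integer degrees of freedom.
#' @export
count_df <- function(spec, p = length(spec$observed)) {
  stopifnot(inherits(spec, "sem_spec"))
  as.integer(p * (p + 1) / 2 - sum(spec$par_table$free))
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("SEM specification: %d observed, %d latent, %d free parameters, df = %d\n",
              length(x$observed), length(x$lat_names),
              sum(x$par_table$free), count_df(x)))
  invisible(x)
}

#' Two-factor model of social cognition and social isolation
#'
#' Latent social cognitive capacity (SCC: MiniPONS, PENN_ER40, RMET,
#' Hinting) and social cognitive bias (SCB: DACOBS_AB, AIHQ_BS), correlated,
#' both regressed onto observed PSI and OSI with a PSI-OSI residual
#' covariance; 8 observed variables, 16 df.
#'
#' @return A \code{sem_spec}.
#' @export
model_overt <- function() {
  sem_model(
    latents = list(SCC = c("MiniPONS", "PENN_ER40", "RMET", "Hinting"),
                   SCB = c("DACOBS_AB", "AIHQ_BS")),
    regressions = list(PSI = c("SCC", "SCB"), OSI = c("SCC", "SCB")),
    covariances = list(c("SCC", "SCB"), c("PSI", "OSI")))
}

#' Extended model with diffusion parameters as exogenous predictors
#'
#' Adds the condition's nondecision time and drift rate as correlated
#' observed exogenous variables with paths to SCC, SCB, PSI and OSI;
#' 10 observed variables, 24 df.  Model 1 uses the baseline condition's
#' estimates, Model 2 the angry condition's.
#'
#' @param condition "baseline" (Model 1) or "angry" (Model 2).
#' @return A \code{sem_spec}.
#' @export
model_ddm <- function(condition = c("baseline", "angry")) {
  condition <- match.arg(condition)
  t0v <- paste0("t0_", condition)
  vv <- paste0("v_", condition)
  sem_model(
    latents = list(SCC = c("MiniPONS", "PENN_ER40", "RMET", "Hinting"),
                   SCB = c("DACOBS_AB", "AIHQ_BS")),
    regressions = list(SCC = c(t0v, vv), SCB = c(t0v, vv),
                       PSI = c("SCC", "SCB", t0v, vv),
                       OSI = c("SCC", "SCB", t0v, vv)),
    covariances = list(c("SCC", "SCB"), c("PSI", "OSI")))
}

# ---- internal: RAM matrices and the ML discrepancy ----

ram_matrices <- function(spec, theta) {
  vars <- spec$vars
  nv <- length(vars)
  A <- S <- matrix(0, nv, nv, dimnames = list(vars, vars))
  tab <- spec$par_table
  k <- 0
  for (i in seq_len(nrow(tab))) {
    val <- if (tab$free[i]) { k <- k + 1; theta[k] } else tab$value[i]
    if (tab$type[i] == "loading") A[tab$rhs[i], tab$lhs[i]] <- val
    else if (tab$type[i] == "regression") A[tab$lhs[i], tab$rhs[i]] <- val
    else if (tab$type[i] == "variance") S[tab$lhs[i], tab$lhs[i]] <- val
    else { S[tab$lhs[i], tab$rhs[i]] <- val; S[tab$rhs[i], tab$lhs[i]] <- val }
  }
  list(A = A, S = S)
}

implied_cov <- function(spec, theta) {
  m <- ram_matrices(spec, theta)
  nv <- length(spec$vars)
  IA <- solve(diag(nv) - m$A)
  C <- IA %*% m$S %*% t(IA)
  dimnames(C) <- list(spec$vars, spec$vars)
  C
}

start_values <- function(spec, S) {
  tab <- spec$par_table
  first_ind <- vapply(spec$lat_names, function(l) spec$latents[[l]][1], "")
  names(first_ind) <- spec$lat_names
  th <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    if (!tab$free[i]) next
    v <- switch(tab$type[i],
      loading = 1,
      regression = 0,
      covariance = 0,
      variance = {
        vn <- tab$lhs[i]
        if (vn %in% spec$observed) S[vn, vn] / 2
        else S[first_ind[vn], first_ind[vn]] / 2
      })
    th <- c(th, v)
  }
  th
}

ml_discrepancy <- function(spec, S, logdetS) {
  p <- length(spec$observed)
  obs <- spec$observed
  function(theta) {
    Sig <- tryCatch(implied_cov(spec, theta)[obs, obs],
                    error = function(e) NULL)
    if (is.null(Sig) || any(!is.finite(Sig))) return(1e10)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    f <- logdet + sum(diag(S %*% chol2inv(ch))) - logdetS - p
    if (!is.finite(f)) return(1e10)
    f
  }
}

num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hp <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hp
    xm <- x; xm[j] <- xm[j] - hp
    J[, j] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' \deqn{F = \log|\Sigma(\theta)| + tr(S \Sigma(\theta)^{-1}) - \log|S| - p}
#' by quasi-Newton iteration from a deterministic start (loadings 1, paths
#' and covariances 0, variances at half the observed variances).  The
#' chi-square statistic is \code{(n - 1) F} at the minimum; RMSEA and CFI
#' follow the usual definitions with the independence baseline; standard
#' errors come from the inverse expected information; the standardized
#' solution rescales by model-implied SDs.
#'
#' @param spec A [sem_model()] specification.
#' @param data Data.frame containing all observed variables (complete cases
#'   are used).
#' @param optimizer "nlminb" (default) or "BFGS" (used as an independent
#'   cross-check in tests).
#' @return A \code{sem_fit} object: parameter table with estimates, SEs,
#'   z, p and standardized estimates; \code{chi_square}, \code{df},
#'   \code{p_value}, \code{cfi}, \code{rmsea}, \code{r_squared}, \code{n},
#'   \code{F_min}, \code{vcov}, \code{heywood} flag.
#' @export
fit_ml <- function(spec, data, optimizer = c("nlminb", "BFGS")) {
  stopifnot(inherits(spec, "sem_spec"))
  optimizer <- match.arg(optimizer)
  miss <- setdiff(spec$observed, names(data))
  if (length(miss))
    stop("data lacks observed variables: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- data[, spec$observed, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  p <- length(spec$observed)
  if (n <= p) stop("need n > number of observed variables", call. = FALSE)
  Sraw <- cov(X)
  # optimize on SD-standardized variables (well-conditioned); the fit is
  # invariant and estimates are mapped back to the raw metric afterwards
  s_obs <- sqrt(diag(Sraw))
  S <- diag(1 / s_obs) %*% Sraw %*% diag(1 / s_obs)
  dimnames(S) <- dimnames(Sraw)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance not positive definite", call. = FALSE))
  logdetS <- 2 * sum(log(diag(chS)))
  obj <- ml_discrepancy(spec, S, logdetS)
  th0 <- start_values(spec, S)
  if (optimizer == "nlminb") {
    opt <- nlminb(th0, obj, control = list(iter.max = 1000, eval.max = 2000))
    theta <- opt$par; fmin <- opt$objective
  } else {
    opt <- optim(th0, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    theta <- opt$par; fmin <- opt$value
  }
  grad <- drop(num_jacobian(obj, theta))
  if (fmin >= 1e9 || max(abs(grad)) > 1e-3 * max(1, abs(fmin)) + 1e-4)
    warning(sprintf("possible non-convergence (gradient norm %.2e)",
                    max(abs(grad))), call. = FALSE)

  tab <- spec$par_table
  tab$est <- NA_real_
  tab$est[!tab$free] <- tab$value[!tab$free]
  tab$est[tab$free] <- theta

  # expected information: I_ij = (n-1)/2 tr(Sig^-1 dSig_i Sig^-1 dSig_j)
  obs <- spec$observed
  Sig <- implied_cov(spec, theta)[obs, obs]
  Siginv <- solve(Sig)
  vecSig <- function(th) as.vector(implied_cov(spec, th)[obs, obs])
  J <- num_jacobian(vecSig, theta)
  pre <- Siginv %x% Siginv
  info <- (n - 1) / 2 * t(J) %*% pre %*% J
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, length(theta), length(theta)))

  # standardized solution from the model-implied covariance of all variables
  Call <- implied_cov(spec, theta)
  sds <- sqrt(pmax(diag(Call), 0))
  std <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lhs <- tab$lhs[i]; rhs <- tab$rhs[i]
    std[i] <- switch(tab$type[i],
      loading = tab$est[i] * sds[lhs] / sds[rhs],
      regression = tab$est[i] * sds[rhs] / sds[lhs],
      variance = tab$est[i] / Call[lhs, lhs],
      covariance = tab$est[i] / (sds[lhs] * sds[rhs]))
  }
  tab$std <- std

  # map estimates, SEs and vcov back to the raw metric: every variable has a
  # scale (observed: sample SD; latent: SD of its scale-setting indicator)
  scale_of <- c(s_obs, vapply(spec$lat_names,
                              function(l) s_obs[spec$latents[[l]][1]], 0))
  names(scale_of) <- c(names(s_obs), spec$lat_names)
  gfac <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    lhs <- tab$lhs[i]; rhs <- tab$rhs[i]
    gfac[i] <- switch(tab$type[i],
      loading = scale_of[rhs] / scale_of[lhs],
      regression = scale_of[lhs] / scale_of[rhs],
      variance = scale_of[lhs]^2,
      covariance = scale_of[lhs] * scale_of[rhs])
  }
  tab$est <- tab$est * gfac
  g_free <- gfac[tab$free]
  vc <- diag(g_free, length(g_free)) %*% vc %*% diag(g_free, length(g_free))
  se <- sqrt(pmax(diag(vc), 0))
  tab$se <- NA_real_
  tab$se[tab$free] <- se
  tab$z <- tab$est / tab$se
  tab$p <- 2 * pnorm(-abs(tab$z))
  Sig <- diag(s_obs) %*% Sig %*% diag(s_obs)
  dimnames(Sig) <- list(obs, obs)
  # independence-baseline discrepancy (scale-invariant; computed on the
  # standardized metric where diag(S) = 1)
  fb <- sum(log(diag(S))) - logdetS
  S <- Sraw

  chi2 <- (n - 1) * fmin
  df <- count_df(spec)
  pval <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else 0
  chi2_b <- (n - 1) * fb
  df_b <- p * (p - 1) / 2
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom

  endo <- unique(names(spec$regressions))
  r2 <- vapply(endo, function(v) {
    i <- which(tab$type == "variance" & tab$lhs == v)
    1 - tab$std[i]
  }, 0)
  heywood <- any(tab$est[tab$type == "variance"] < 0)
  if (heywood)
    warning("Heywood case: negative residual variance", call. = FALSE)

  structure(list(spec = spec, par_table = tab, theta = tab$est[tab$free],
                 chi_square = chi2, df = df, p_value = pval, cfi = cfi,
                 rmsea = rmsea, r_squared = r2, n = n, F_min = fmin,
                 S = S, Sigma = Sig, vcov = vc, gradient = grad,
                 heywood = heywood, optimizer = optimizer),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SEM fit (n = %d): chi-square(%d) = %.2f, p = %.3f, CFI = %.3f, RMSEA = %.3f\n",
              x$n, x$df, x$chi_square, x$p_value, x$cfi, x$rmsea))
  tab <- x$par_table[, c("label", "est", "se", "z", "p", "std")]
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  if (length(x$r_squared)) {
    cat("R-squared:\n")
    print(round(x$r_squared, digits))
  }
  invisible(x)
}

#' Extract a path coefficient from a fit
#'
#' @param fit A \code{sem_fit}.
#' @param label Parameter label, e.g. \code{"PSI~SCB"}.
#' @param std Logical; return the standardized estimate.
#' @return Named numeric: est, se, z, p.
#' @export
sem_coef <- function(fit, label, std = FALSE) {
  i <- match(label, fit$par_table$label)
  if (is.na(i)) stop("no parameter ", label, call. = FALSE)
  row <- fit$par_table[i, ]
  c(est = if (std) row$std else row$est, se = row$se, z = row$z, p = row$p)
}

#' Indirect effects by the product-of-coefficients method
#'
#' For each chain predictor -> mediator -> outcome, the estimate is the
#' product of the two path coefficients; its standard error follows the
#' delta method
#' \deqn{SE = \sqrt{b^2 Var(a) + a^2 Var(b) + 2ab\,Cov(a, b)}}
#' and the two-sided p-value comes from the normal z.  Standardized
#' estimates are products of the standardized paths.
#'
#' @param fit A \code{sem_fit}.
#' @param paths List of length-3 character vectors
#'   \code{c(predictor, mediator, outcome)}.
#' @return Data.frame with est, se, z, p and std per chain.
#' @export
indirect_effects <- function(fit, paths) {
  free_idx <- which(fit$par_table$free)
  rows <- lapply(paths, function(ch) {
    stopifnot(length(ch) == 3)
    la <- paste0(ch[2], "~", ch[1])
    lb <- paste0(ch[3], "~", ch[2])
    ia <- match(la, fit$par_table$label)
    ib <- match(lb, fit$par_table$label)
    if (is.na(ia) || is.na(ib))
      stop("path absent from model: ", if (is.na(ia)) la else lb,
           call. = FALSE)
    a <- fit$par_table$est[ia]; b <- fit$par_table$est[ib]
    ka <- match(ia, free_idx); kb <- match(ib, free_idx)
    va <- fit$vcov[ka, ka]; vb <- fit$vcov[kb, kb]
    cab <- fit$vcov[ka, kb]
    se <- sqrt(b^2 * va + a^2 * vb + 2 * a * b * cab)
    z <- (a * b) / se
    data.frame(predictor = ch[1], mediator = ch[2], outcome = ch[3],
               est = a * b, se = se, z = z, p = 2 * pnorm(-abs(z)),
               std = fit$par_table$std[ia] * fit$par_table$std[ib])
  })
  do.call(rbind, rows)
}

#' Detect a suppression effect
#'
#' Flags suppression when the direct path and the indirect chain through
#' the mediator have opposite signs and both are significant at
#' \code{alpha}; reports total = direct + indirect.
#'
#' @param fit A \code{sem_fit}.
#' @param predictor,outcome,mediator Variable names.
#' @param alpha Significance level.
#' @return List: \code{suppression}, \code{direct}, \code{indirect},
#'   \code{total}, \code{reason}.
#' @export
detect_suppression <- function(fit, predictor, outcome, mediator,
                               alpha = 0.05) {
  direct <- sem_coef(fit, paste0(outcome, "~", predictor))
  ind <- indirect_effects(fit, list(c(predictor, mediator, outcome)))
  opp <- sign(direct["est"]) != sign(ind$est) && direct["est"] != 0 &&
    ind$est != 0
  sig <- direct["p"] < alpha && ind$p < alpha
  reason <- if (!opp) "direct and indirect effects share a sign"
    else if (!sig) "direct or indirect effect not significant"
    else "opposite-signed significant direct and indirect effects"
  list(suppression = unname(opp && sig),
       direct = unname(direct["est"]), indirect = ind$est,
       total = unname(direct["est"]) + ind$est, reason = reason)
}
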