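#' Configuration for the differential-evolution MCMC sampler
#'
#' Defaults follow common DE-MCMC practice for a 5-dimensional posterior:
#' 15 chains (3 per parameter), 2000 iterations with the first 1000
#' discarded, scale factor gamma = 2.38/sqrt(2d), and uniform jitter of
#' half-width 0.001 added to every proposal.  Priors are bounded uniforms;
#' the joint support additionally requires \code{t0 - st0/2 > 0.05} so the
#' likelihood stays well defined.
#'
#' @param n_chains Number of interacting chains (>= 2 x number of
#'   parameters).
#' @param n_iter Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param gamma Scale of the difference-vector proposal.
#' @param gamma1_prob Probability of a full-difference (gamma = 1)
#'   mode-jumping proposal, part of the original DE-MC scheme; lets outlier
#'   chains relocate onto the converged population in one move.
#' @param jitter_half_width Half-width of the uniform proposal jitter.
#' @param seed Integer seed for the whole run.
#' @param priors Named list of \code{c(lower, upper)} bounds for v, a, t0,
#'   st0, sv.
#' @return A \code{sampler_config} object.
#' @export
sampler_config <- function(n_chains = 15, n_iter = 2000, burn_in = 1000,
                           gamma = 2.38 / sqrt(2 * 5), gamma1_prob = 0.1,
                           jitter_half_width = 0.001, seed = 1,
                           priors = list(v = c(-10, 10), a = c(0.2, 5),
                                         t0 = c(0.05, 1.0), st0 = c(0, 0.5),
                                         sv = c(0, 5))) {
  stopifnot(n_chains >= 2 * 5, burn_in < n_iter, n_iter >= 2,
            gamma > 0, jitter_half_width >= 0,
            gamma1_prob >= 0, gamma1_prob <= 1)
  stopifnot(all(c("v", "a", "t0", "st0", "sv") %in% names(priors)))
  for (b in priors) stopifnot(length(b) == 2, b[1] < b[2])
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 gamma = gamma, gamma1_prob = gamma1_prob,
                 jitter_half_width = jitter_half_width,
                 seed = as.integer(seed), priors = priors),
            class = "sampler_config")
}

param_names_ddm <- function() c("v", "a", "t0", "st0", "sv")

in_support <- function(theta, priors) {
  for (j in seq_along(param_names_ddm())) {
    b <- priors[[param_names_ddm()[j]]]
    if (theta[j] < b[1] || theta[j] > b[2]) return(FALSE)
  }
  theta[3] - theta[4] / 2 > 0.05
}

draw_from_prior <- function(priors) {
  repeat {
    theta <- vapply(param_names_ddm(),
                    function(p) runif(1, priors[[p]][1], priors[[p]][2]), 0)
    if (theta[3] - theta[4] / 2 > 0.05) return(theta)
  }
}

#' Run the DE-MCMC sampler on one participant-condition data set
#'
#' Proposals for chain k are \code{current_k + gamma * (chain_m - chain_n) +
#' Uniform(-eps, eps)} with m, n distinct chains other than k, accepted by a
#' Metropolis step on the log posterior (diffusion likelihood plus flat
#' bounded priors).  Out-of-support proposals are rejected outright.  The
#' run is fully reproducible under the config seed.
#'
#' @param rt Vector of reaction times (s) of the filtered trials.
#' @param correct Logical vector of response correctness.
#' @param cfg A [sampler_config()].
#' @param log_target Optional replacement for the DDM log-likelihood,
#'   a \code{function(theta)} on the 5-vector (v, a, t0, st0, sv); used for
#'   sampler validation against analytic targets.
#' @param min_trials Guard: minimum number of trials required.
#' @return A \code{chain_set} object: \code{samples} (chains x iterations x
#'   5 array), \code{log_posterior} (chains x iterations), \code{accepted}
#'   counts per chain, \code{burn_in}, and \code{degenerate} flag (TRUE when
#'   all responses fall on one boundary).
#' @export
run_demc <- function(rt, correct, cfg = sampler_config(), log_target = NULL,
                     min_trials = 40) {
  stopifnot(inherits(cfg, "sampler_config"))
  if (is.null(log_target)) {
    if (length(rt) < min_trials)
      stop("too few trials (", length(rt), " < ", min_trials, ")",
           call. = FALSE)
    ll <- function(theta)
      ddm_loglik_cpp(rt, correct, theta[1], theta[2], theta[3], theta[4],
                     theta[5], 1e-29)
    degenerate <- length(unique(correct)) < 2
  } else {
    ll <- log_target
    degenerate <- FALSE
  }
  d <- 5L
  m <- cfg$n_chains
  pri <- cfg$priors
  withr_seed(cfg$seed, {
    # start each chain at the best of a small pool of prior draws: starts
    # stay independent and overdispersed, but a chain is very unlikely to
    # begin inside a negligible-mass local basin it could never leave with
    # difference-vector proposals (the DE-MC outlier-chain failure mode)
    theta <- matrix(0, m, d)
    lp <- numeric(m)
    for (i in seq_len(m)) {
      best <- draw_from_prior(pri)
      best_lp <- ll(best)
      for (tries in seq_len(24)) {
        cand <- draw_from_prior(pri)
        cand_lp <- ll(cand)
        if (cand_lp > best_lp) { best <- cand; best_lp <- cand_lp }
      }
      theta[i, ] <- best
      lp[i] <- best_lp
    }
    samples <- array(NA_real_, c(m, cfg$n_iter, d),
                     dimnames = list(NULL, NULL, param_names_ddm()))
    lp_trace <- matrix(NA_real_, m, cfg$n_iter)
    accepted <- integer(m)
    eps <- cfg$jitter_half_width
    for (it in seq_len(cfg$n_iter)) {
      for (k in seq_len(m)) {
        others <- sample(setdiff(seq_len(m), k), 2)
        g <- if (runif(1) < cfg$gamma1_prob) 1 else cfg$gamma
        prop <- theta[k, ] + g * (theta[others[1], ] -
                                    theta[others[2], ]) +
          runif(d, -eps, eps)
        if (in_support(prop, pri)) {
          lp_prop <- ll(prop)
          if (log(runif(1)) < lp_prop - lp[k]) {
            theta[k, ] <- prop
            lp[k] <- lp_prop
            accepted[k] <- accepted[k] + 1L
          }
        }
      }
      samples[, it, ] <- theta
      lp_trace[, it] <- lp
    }
    structure(list(samples = samples, log_posterior = lp_trace,
                   accepted = accepted, burn_in = cfg$burn_in,
                   n_trials = length(rt), degenerate = degenerate),
              class = "chain_set")
  })
}

#' @export
print.chain_set <- function(x, ...) {
  dm <- dim(x$samples)
  cat(sprintf("DE-MCMC chain set: %d chains x %d iterations x %d parameters (burn-in %d)\n",
              dm[1], dm[2], dm[3], x$burn_in))
  cat(sprintf("mean acceptance rate: %.2f\n", mean(x$accepted) / dm[2]))
  invisible(x)
}

post_burn <- function(chains) {
  it <- seq(chains$burn_in + 1L, dim(chains$samples)[2])
  chains$samples[, it, , drop = FALSE]
}

#' Multivariate potential scale reduction factor
#'
#' Brooks-Gelman convergence diagnostic on the post-burn-in samples: with
#' W the mean within-chain covariance and B/n the covariance of the chain
#' means, MPSF^2 = (n-1)/n + (m+1)/m * lambda_1, where lambda_1 is the
#' largest eigenvalue of W^-1 B/n.  Univariate PSRFs use the same formula
#' per parameter, so the 1-parameter case reduces exactly.  Values are
#' floored at 1 (the raw formula dips to sqrt((n-1)/n) when chains agree
#' perfectly).
#'
#' @param chains A \code{chain_set}, or an array chains x iterations x
#'   parameters of retained samples.
#' @param threshold Convergence criterion on the MPSF (default 1.15).
#' @return A \code{convergence_report}: \code{mpsf}, \code{psrf} (named per
#'   parameter), \code{converged}, \code{threshold}.
#' @export
compute_mpsf <- function(chains, threshold = 1.15) {
  x <- if (inherits(chains, "chain_set")) post_burn(chains) else chains
  stopifnot(length(dim(x)) == 3)
  m <- dim(x)[1]; n <- dim(x)[2]; d <- dim(x)[3]
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  if (n < 10) stop("need at least 10 retained iterations", call. = FALSE)
  means <- apply(x, c(1, 3), mean)                    # m x d
  W <- matrix(0, d, d)
  for (k in seq_len(m)) W <- W + cov(matrix(x[k, , ], n, d))
  W <- W / m
  Bn <- cov(matrix(means, m, d))                      # B / n
  solW <- tryCatch(solve(W, Bn), error = function(e)
    stop("singular within-chain covariance: ", conditionMessage(e),
         call. = FALSE))
  lambda1 <- max(Re(eigen(solW, only.values = TRUE)$values))
  mpsf <- sqrt(max(1, (n - 1) / n + (m + 1) / m * lambda1))
  psrf <- sqrt(pmax(1, (n - 1) / n + (m + 1) / m * diag(Bn) / diag(W)))
  names(psrf) <- dimnames(x)[[3]] %||% paste0("p", seq_len(d))
  structure(list(mpsf = mpsf, psrf = psrf,
                 converged = mpsf < threshold, threshold = threshold),
            class = "convergence_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("MPSF = %.4f (%s, threshold %.2f)\n", x$mpsf,
              if (x$converged) "converged" else "NOT converged", x$threshold))
  print(round(x$psrf, 4))
  invisible(x)
}

#' Posterior-mean point estimates from a chain set
#'
#' Per-parameter means over the post-burn-in samples pooled across chains.
#' If the chains fail the MPSF criterion a warning is attached but the
#' estimate is still returned.
#'
#' @param chains A \code{chain_set}.
#' @param check_convergence Logical; warn when MPSF >= 1.15.
#' @return A [ddm_params()] object with attribute \code{"mpsf"}.
#' @export
point_estimates <- function(chains, check_convergence = TRUE) {
  x <- post_burn(chains)
  est <- apply(x, 3, mean)
  conv <- tryCatch(compute_mpsf(chains), error = function(e)
    list(mpsf = NA_real_, converged = NA))
  if (check_convergence && isFALSE(conv$converged))
    warning(sprintf("chains not converged (MPSF = %.3f)", conv$mpsf),
            call. = FALSE)
  out <- ddm_params(v = est["v"], a = est["a"], t0 = est["t0"],
                    st0 = est["st0"], sv = est["sv"])
  attr(out, "mpsf") <- conv$mpsf
  out
}

#' Fit the diffusion model to every participant and condition
#'
#' Runs [run_demc()] independently per participant x condition on filtered
#' trials and extracts posterior-mean point estimates plus convergence
#' diagnostics.
#'
#' @param trials Filtered trial data.frame (columns \code{participant_id},
#'   \code{run}, \code{rt} in seconds, \code{response}).
#' @param cfg A [sampler_config()]; each fit derives its own seed from it.
#' @param min_trials Minimum trials per fit.
#' @param max_retries A fit failing the MPSF criterion is re-run with fresh
#'   chains (deterministically derived seed) up to this many times; the
#'   final diagnostic is reported either way.
#' @return Data.frame, one row per participant x condition: point estimates
#'   \code{v}, \code{a}, \code{t0}, \code{st0}, \code{sv}, \code{mpsf},
#'   \code{n_trials}, \code{retries}, \code{converged}.
#' @export
fit_ddm_all <- function(trials, cfg = sampler_config(), min_trials = 40,
                        max_retries = 2) {
  key <- unique(trials[, c("participant_id", "run")])
  rows <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    sub <- trials[trials$participant_id == key$participant_id[i] &
                    trials$run == key$run[i], ]
    attempt <- 0
    repeat {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + 7919L * i + 104729L * attempt
      ch <- run_demc(sub$rt, sub$response == "correct", cfg_i,
                     min_trials = min_trials)
      est <- suppressWarnings(point_estimates(ch, check_convergence = FALSE))
      mpsf <- attr(est, "mpsf")
      if (isTRUE(mpsf < 1.15) || attempt >= max_retries) break
      attempt <- attempt + 1
    }
    rows[[i]] <- data.frame(participant_id = key$participant_id[i],
                            run = key$run[i], v = est$v, a = est$a,
                            t0 = est$t0, st0 = est$st0, sv = est$sv,
                            mpsf = mpsf,
                            n_trials = length(sub$rt), retries = attempt,
                            converged = isTRUE(mpsf < 1.15))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
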