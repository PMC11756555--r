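# Shared fixtures built in code at test time.

# small trial table with known exclusion outcomes
toy_trials <- function() {
  data.frame(participant_id = "P001", run = "baseline",
             trial_index = 1:5,
             rt = c(0.15, NA, 0.30, 0.31, 0.32),
             response = c("correct", "none", "correct", "incorrect",
                          "correct"))
}

# data whose sample covariance equals a target matrix exactly
data_with_cov <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  X <- Z %*% chol(Sigma)
  colnames(X) <- colnames(Sigma)
  as.data.frame(X)
}

# population covariance implied by the overt two-factor model at given
# parameter values, assembled by hand (independent of the package's RAM code)
overt_population_cov <- function(lam = c(MiniPONS = 1, PENN_ER40 = 0.9,
                                         RMET = 0.8, Hinting = 0.7,
                                         DACOBS_AB = 1, AIHQ_BS = 0.85),
                                 psi = c(SCC = 0.5, SCB = 0.6),
                                 psi_cov = -0.2,
                                 beta = matrix(c(0.1, 0.8, -0.5, 0.4), 2, 2,
                                   byrow = TRUE,
                                   dimnames = list(c("PSI", "OSI"),
                                                   c("SCC", "SCB"))),
                                 theta_ind = 0.5, theta_out = c(0.6, 0.7),
                                 theta_out_cov = 0.25) {
  Phi <- matrix(c(psi["SCC"], psi_cov, psi_cov, psi["SCB"]), 2, 2)
  L <- matrix(0, 6, 2)
  L[1:4, 1] <- lam[1:4]
  L[5:6, 2] <- lam[5:6]
  Syy <- L %*% Phi %*% t(L) + diag(theta_ind, 6)
  Syo <- L %*% Phi %*% t(beta)
  Soo <- beta %*% Phi %*% t(beta) +
    matrix(c(theta_out[1], theta_out_cov, theta_out_cov, theta_out[2]), 2, 2)
  S <- rbind(cbind(Syy, Syo), cbind(t(Syo), Soo))
  nm <- c(names(lam), "PSI", "OSI")
  dimnames(S) <- list(nm, nm)
  S
}
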