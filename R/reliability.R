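#' Split trials into odd- and even-indexed halves
#'
#' Parity is taken on the original (pre-filter) trial index, so filtering
#' gaps do not shift trials between halves and the two halves always
#' partition the input exactly.
#'
#' @param trials Data.frame with a \code{trial_index} column.
#' @return List with elements \code{odd} and \code{even}.
#' @export
split_odd_even <- function(trials) {
  odd <- trials$trial_index %% 2 == 1
  list(odd = trials[odd, , drop = FALSE],
       even = trials[!odd, , drop = FALSE])
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation from the two-way ANOVA decomposition:
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with n targets (rows) and k raters/halves (columns).
#'
#' @param m Numeric matrix, participants x measurements (>= 3 rows, >= 2
#'   columns, no missing cells).
#' @return Scalar ICC(2,1).
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 rows and >= 2 columns", call. = FALSE)
  grand <- mean(m)
  if (all(abs(m - grand) < 1e-300))
    stop("zero total variance", call. = FALSE)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Odd-even split-half reliability of diffusion point estimates
#'
#' Splits each participant-condition's filtered trials by trial-index
#' parity, fits the diffusion model to each half, and computes ICC(2,1)
#' across participants between the two halves for each parameter and
#' condition.
#'
#' @param trials Filtered trial data.frame.
#' @param cfg A [sampler_config()]; the half-fits inherit it (callers
#'   typically pass a reduced iteration budget).
#' @param parameters Which parameters to report ICCs for.
#' @param min_trials Minimum trials per half-fit.
#' @return List: \code{estimates} (per participant x condition x half) and
#'   \code{icc}, a data.frame with columns \code{run}, \code{parameter},
#'   \code{icc}, \code{n}.
#' @export
split_half_reliability <- function(trials, cfg = sampler_config(),
                                   parameters = c("v", "t0"),
                                   min_trials = 20) {
  halves <- split_odd_even(trials)
  ests <- list()
  for (h in c("odd", "even")) {
    e <- fit_ddm_all(halves[[h]], cfg, min_trials = min_trials)
    e$half <- h
    ests[[h]] <- e
  }
  est <- do.call(rbind, ests)
  rownames(est) <- NULL
  iccs <- list()
  for (run in unique(est$run)) {
    for (p in parameters) {
      wide <- merge(ests$odd[ests$odd$run == run, c("participant_id", p)],
                    ests$even[ests$even$run == run, c("participant_id", p)],
                    by = "participant_id", suffixes = c("_odd", "_even"))
      if (nrow(wide) >= 3) {
        iccs[[paste(run, p)]] <- data.frame(
          run = run, parameter = p,
          icc = icc_2_1(as.matrix(wide[, -1])), n = nrow(wide))
      }
    }
  }
  list(estimates = est, icc = do.call(rbind, c(iccs, make.row.names = FALSE)))
}
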