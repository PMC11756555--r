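#' Zero-order Pearson correlations with two-sided p-values
#'
#' Pairwise complete cases; p-values from the t transform with n - 2
#' degrees of freedom.  Pairs with a zero-variance member are flagged NA.
#'
#' @param table Data.frame of numeric columns (non-numeric columns are
#'   dropped).
#' @return List of matrices \code{r}, \code{p}, \code{n}.
#' @export
zero_order_correlations <- function(table) {
  num <- table[vapply(table, is.numeric, TRUE)]
  if (nrow(num) < 4) stop("need >= 4 rows", call. = FALSE)
  k <- ncol(num)
  r <- p <- nm <- matrix(NA_real_, k, k,
                         dimnames = list(names(num), names(num)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cc <- stats::complete.cases(num[[i]], num[[j]])
      n <- sum(cc)
      nm[i, j] <- n
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (n < 4 || sd(num[[i]][cc]) == 0 || sd(num[[j]][cc]) == 0) next
      rij <- cor(num[[i]][cc], num[[j]][cc])
      r[i, j] <- rij
      tstat <- rij * sqrt((n - 2) / (1 - rij^2))
      p[i, j] <- 2 * pt(-abs(tstat), n - 2)
    }
  }
  list(r = r, p = p, n = nm)
}

#' Paired-samples t-test
#'
#' \code{t = mean(d) / (sd(d)/sqrt(n))} on the differences d = x - y, with
#' n - 1 degrees of freedom and a two-sided p-value.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @return List: \code{t}, \code{df}, \code{p}, \code{mean_x},
#'   \code{mean_y}, \code{sd_x}, \code{sd_y}, \code{mean_diff}.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  d <- x - y
  if (sd(d) == 0)
    stop("zero variance of differences", call. = FALSE)
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), n - 1),
       mean_x = mean(x), mean_y = mean(y), sd_x = sd(x), sd_y = sd(y),
       mean_diff = mean(d))
}

#' Cronbach's alpha
#'
#' \code{alpha = k/(k-1) * (1 - sum(item variances) / variance(total))}
#' with sample (n - 1) variances on complete cases.
#'
#' @param items Numeric matrix or data.frame, participants x items (>= 3
#'   rows, >= 2 items).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) stop("need >= 2 items and >= 3 rows", call. = FALSE)
  vt <- var(rowSums(m))
  if (vt == 0) stop("zero total variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

#' Power of the Pearson correlation test (Fisher-z approximation)
#'
#' \code{power = Phi(atanh(r) * sqrt(n - 3) - z_{1 - alpha/2})} for the
#' two-sided test (the vanishing opposite tail is ignored);
#' \code{solve_detectable_r()} inverts it for the smallest detectable
#' correlation by root finding.
#'
#' @param n Sample size (> 3).
#' @param r True correlation (0 < r < 1).
#' @param alpha Significance level.
#' @param tail "two" or "one".
#' @return Power in (0, 1).
#' @export
power_correlation <- function(n, r, alpha = 0.05, tail = c("two", "one")) {
  tail <- match.arg(tail)
  stopifnot(n > 3, r > 0, r < 1, alpha > 0, alpha < 1)
  zcrit <- if (tail == "two") qnorm(1 - alpha / 2) else qnorm(1 - alpha)
  pnorm(atanh(r) * sqrt(n - 3) - zcrit)
}

#' @rdname power_correlation
#' @param power Target power.
#' @export
solve_detectable_r <- function(n, power = 0.80, alpha = 0.05,
                               tail = c("two", "one")) {
  tail <- match.arg(tail)
  f <- function(r) power_correlation(n, r, alpha, tail) - power
  if (f(1 - 1e-12) < 0)
    stop("power unattainable at this sample size", call. = FALSE)
  uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-10)$root
}

#' Condition contrasts for the diffusion parameters
#'
#' Paired t-tests comparing baseline and angry conditions for t0 and v.
#'
#' @param scores Score table with \code{t0_baseline}, \code{t0_angry},
#'   \code{v_baseline}, \code{v_angry}.
#' @return Data.frame with one row per parameter.
#' @export
condition_contrasts <- function(scores) {
  rows <- lapply(c("t0", "v"), function(p) {
    ct <- paired_t(scores[[paste0(p, "_baseline")]],
                   scores[[paste0(p, "_angry")]])
    data.frame(parameter = p, t = ct$t, df = ct$df, p_value = ct$p,
               mean_baseline = ct$mean_x, sd_baseline = ct$sd_x,
               mean_angry = ct$mean_y, sd_angry = ct$sd_y)
  })
  do.call(rbind, rows)
}
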