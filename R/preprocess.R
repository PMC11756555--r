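#' Read a trial-level CSV
#'
#' Expects columns \code{participant_id}, \code{run} (baseline/angry),
#' \code{trial_index}, \code{rt_ms}, \code{response} (correct/incorrect/
#' none).  RTs are converted to seconds internally.
#'
#' @param path CSV path.
#' @return Data.frame with \code{rt} in seconds added.
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "run", "trial_index", "rt_ms", "response")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trial CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr$rt <- tr$rt_ms / 1000
  tr
}

#' Apply the trial-level exclusion rules
#'
#' Removes, in one pass and in this order: (1) trials without a response;
#' (2) responses faster than 200 ms; (3) reaction times outside mean plus or
#' minus 2 SD, where the mean and SD are computed per participant within
#' condition on the trials surviving the first two rules.  The 2-SD window
#' is closed: values exactly at the limits are retained, and when SD is 0
#' only values equal to the mean are retained.
#'
#' @param trials Data.frame with columns \code{participant_id}, \code{run},
#'   \code{trial_index}, \code{rt} (seconds, NA for non-response) and
#'   \code{response}.
#' @param fast_cutoff Seconds; responses strictly faster are excluded.
#' @param sd_mult Width of the trimming window in SD units.
#' @return List: \code{trials} (retained rows) and \code{report}, a
#'   data.frame per participant x condition with counts \code{n_input},
#'   \code{n_no_response}, \code{n_fast}, \code{n_outlier},
#'   \code{n_retained} (which always sum to \code{n_input}).
#' @export
filter_trials <- function(trials, fast_cutoff = 0.200, sd_mult = 2) {
  if (nrow(trials) == 0) {
    rep0 <- data.frame(participant_id = character(), run = character(),
                       n_input = integer(), n_no_response = integer(),
                       n_fast = integer(), n_outlier = integer(),
                       n_retained = integer())
    return(list(trials = trials, report = rep0))
  }
  key <- interaction(trials$participant_id, trials$run, drop = TRUE)
  keep <- logical(nrow(trials))
  reps <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    sub <- trials[idx, ]
    none <- sub$response == "none" | is.na(sub$rt)
    fast <- !none & sub$rt < fast_cutoff
    surv <- !none & !fast
    out <- logical(length(idx))
    if (any(surv)) {
      m <- mean(sub$rt[surv])
      s <- sd(sub$rt[surv])
      if (!is.finite(s)) s <- 0
      out <- surv & (sub$rt < m - sd_mult * s | sub$rt > m + sd_mult * s)
    }
    retained <- surv & !out
    keep[idx[retained]] <- TRUE
    reps[[g]] <- data.frame(participant_id = sub$participant_id[1],
                            run = sub$run[1],
                            n_input = length(idx),
                            n_no_response = sum(none),
                            n_fast = sum(fast),
                            n_outlier = sum(out),
                            n_retained = sum(retained))
  }
  report <- do.call(rbind, reps)
  rownames(report) <- NULL
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Exclude participants with an insufficient response rate
#'
#' The response rate is the proportion of presented trials (both runs, before
#' any filtering) with any response.  Participants whose rate is strictly
#' below the threshold are dropped entirely.
#'
#' @param trials Raw (pre-filter) trial data.frame.
#' @param threshold Minimum response rate (default 0.5; the rule is strictly
#'   "below").
#' @return List: \code{trials} without the excluded participants, and
#'   \code{excluded}, the dropped participant ids.
#' @export
exclude_participants <- function(trials, threshold = 0.5) {
  if (nrow(trials) == 0) return(list(trials = trials, excluded = character()))
  responded <- trials$response != "none" & !is.na(trials$rt)
  rate <- tapply(responded, trials$participant_id, mean)
  excluded <- names(rate)[rate < threshold]
  list(trials = trials[!(trials$participant_id %in% excluded), , drop = FALSE],
       excluded = excluded)
}

#' Full preprocessing stage
#'
#' Participant-level exclusion on the raw data, then trial-level filtering.
#'
#' @param trials Raw trial data.frame (with \code{rt} in seconds).
#' @inheritParams filter_trials
#' @return List: \code{trials}, \code{report}, \code{excluded}.
#' @export
preprocess_trials <- function(trials, fast_cutoff = 0.200, sd_mult = 2) {
  ex <- exclude_participants(trials)
  fl <- filter_trials(ex$trials, fast_cutoff = fast_cutoff, sd_mult = sd_mult)
  list(trials = fl$trials, report = fl$report, excluded = ex$excluded)
}
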