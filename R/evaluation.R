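# Model-versus-behavior statistics: learning curves, mean residual sum of
# squares, BIC, and transfer-of-learning metrics.

#' Mean residual sum of squares between two curves
#'
#' `sum((y - p)^2) / n` over paired curve values; the summary used to compare
#' a model's learning curve with a reference (e.g. human) curve.
#'
#' @param model,reference Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
mean_rss <- function(model, reference) {
  if (length(model) != length(reference)) stop("curve length mismatch")
  if (length(model) == 0L) stop("curves must be non-empty")
  mean((model - reference)^2)
}

#' Bayesian Information Criterion from a residual sum of squares
#'
#' `BIC = n ln(RSS/n) + k ln(n)` with `k` the number of fitted parameters
#' (0 for all agents here, since every parameter is held at its default).
#' With `k = 0`, BIC is a strictly monotone transform of RSS at fixed `n`,
#' so rankings by RSS and by BIC agree.
#'
#' @param rss Residual sum of squares, `>= 0`.
#' @param n Number of residuals, `>= 1`.
#' @param k_params Count of fitted parameters, `>= 0`.
#' @return Scalar BIC; `-Inf` (with a warning) when `rss` is exactly 0.
#' @export
bic <- function(rss, n, k_params = 0) {
  if (rss < 0 || n < 1 || k_params < 0) stop("invalid BIC inputs")
  if (rss == 0) {
    warning("rss is 0; BIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + k_params * log(n)
}

#' Transfer-of-learning metrics for one phase
#'
#' For a per-trial reward sequence split into phases: jumpstart is the mean of
#' the first `j` rewards after the phase boundary (initial performance on the
#' new task), asymptotic is the mean of the final three rewards (end-of-phase
#' performance), and episodic is the mean over the whole phase. All three are
#' convex combinations of the rewards, hence bounded by their range.
#'
#' @param rewards Numeric vector of per-trial rewards for the whole run.
#' @param boundaries Integer vector of phase start indices (first phase starts
#'   at 1); phase `p` spans `boundaries[p] .. boundaries[p+1] - 1`.
#' @param j Number of initial trials in the jumpstart average (default 3).
#' @return A data.frame with one row per phase: `phase`, `jumpstart`,
#'   `episodic`, `asymptotic`.
#' @export
transfer_metrics <- function(rewards, boundaries, j = 3L) {
  ends <- c(boundaries[-1L] - 1L, length(rewards))
  out <- lapply(seq_along(boundaries), function(p) {
    seg <- rewards[boundaries[p]:ends[p]]
    if (length(seg) < max(j, 3L)) stop("phase shorter than metric windows")
    data.frame(phase = p,
               jumpstart = mean(seg[seq_len(j)]),
               episodic = mean(seg),
               asymptotic = mean(seg[(length(seg) - 2L):length(seg)]))
  })
  do.call(rbind, out)
}

#' Learning curve aligned on trial-within-episode
#'
#' Averages the correct-choice indicator at each within-episode trial index
#' across episodes and runs, with a normal-approximation 95% confidence band
#' clipped to the unit interval.
#'
#' @param records A trial-record data.frame with columns `trial` (within
#'   episode) and `correct` (0/1).
#' @param max_trial Truncate the curve at this index (default: indices present
#'   in every episode are kept, i.e. up to the shortest episode).
#' @return A data.frame: `trial_index`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
learning_curve <- function(records, max_trial = NULL) {
  if (is.null(records) || nrow(records) == 0L) stop("empty record stream")
  if (is.null(max_trial)) {
    per_ep <- tapply(records$trial, interaction(records$run, records$episode,
                                                drop = TRUE), max)
    max_trial <- min(per_ep)
  }
  idx <- seq_len(max_trial)
  rows <- lapply(idx, function(i) {
    x <- records$correct[records$trial == i]
    m <- mean(x)
    se <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    data.frame(trial_index = i, mean = m,
               ci_lo = max(0, m - 1.96 * se),
               ci_hi = min(1, m + 1.96 * se), n = length(x))
  })
  do.call(rbind, rows)
}

#' Ablation comparison report
#'
#' One row per agent kind: mean residual sum of squares of the agent's curve
#' against the reference curve, the corresponding BIC (`k = 0` fitted
#' parameters), and a 95% confidence interval on the mean squared residual.
#' Rows are sorted by agent name for stable output.
#'
#' @param curves Named list of numeric model curves (one per agent kind).
#' @param reference Numeric reference curve of the same length.
#' @param k_params Fitted-parameter count passed to [bic()].
#' @return A data.frame: `agent`, `n`, `mean_rss`, `bic`, `ci_lo`, `ci_hi`.
#' @export
ablation_report <- function(curves, reference, k_params = 0) {
  if (is.null(names(curves)) || any(names(curves) == ""))
    stop("curves must be a named list")
  lens <- vapply(curves, length, integer(1))
  if (any(lens != length(reference))) stop("misaligned curves")
  out <- lapply(sort(names(curves)), function(a) {
    sq <- (curves[[a]] - reference)^2
    n <- length(sq)
    m <- mean(sq)
    se <- if (n > 1L) stats::sd(sq) / sqrt(n) else 0
    data.frame(agent = a, n = n, mean_rss = m,
               bic = suppressWarnings(bic(sum(sq), n, k_params)),
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
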