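# Step 2: water-yield-ratio disturbance via a structural break in the
# double-mass curve (cumulative Q against cumulative P) at the fire date,
# tested with Chow's F statistic. The break position is *fixed* at the fire
# date rather than searched, so the single-split F distribution applies --
# deliberately different from step 1's max-selection-corrected scan.

#' Double-mass curve
#'
#' Running sums of monthly flow against running sums of monthly
#' precipitation. If flow is proportional to precipitation the curve is a
#' straight line through the origin; a slope break marks a change in the
#' water-yield ratio Q/P.
#'
#' @param q,p Equal-length, time-aligned non-negative monthly series.
#' @return Data frame with `P_cum`, `Q_cum`. If total precipitation is
#'   zero the curve is degenerate (vertical accumulation) and a warning is
#'   raised.
#' @export
double_mass_curve <- function(q, p) {
  stop_if(length(q) != length(p), "q and p must be the same length")
  stop_if(any(q < 0) || any(p < 0), "q and p must be non-negative")
  if (sum(p) == 0) warning("total precipitation is zero: degenerate curve")
  data.frame(P_cum = cumsum(p), Q_cum = cumsum(q))
}

#' Chow test for a structural break at a known position
#'
#' Fits ordinary least squares (intercept + slope, `K = 2` regressors) to
#' the pooled double-mass pairs and to the two segments split at
#' `break_index` (last point of the first segment), and computes
#' `F = [(SSE0 - (SSE1 + SSE2))/K] / [(SSE1 + SSE2)/(n - 2K)]` with
#' p-value from the `F(K, n - 2K)` distribution.
#'
#' @param dmc Output of [double_mass_curve()] (or any data frame with
#'   `P_cum`, `Q_cum`).
#' @param break_index Index of the last point of the first segment.
#' @param alpha Significance level for the break decision.
#' @return A `chow_result` list: `SSE0`, `SSE1`, `SSE2`, `K`, `n`, `F`,
#'   `p_value`, `alpha`, `break_detected`, and `note` for degenerate
#'   perfect-fit cases.
#' @export
chow_test <- function(dmc, break_index, alpha = 0.05) {
  k <- 2L
  n <- nrow(dmc)
  stop_if(break_index < k + 1 || n - break_index < k + 1,
          "each segment needs at least K + 1 = 3 points")
  sse <- function(d) sum(lm(Q_cum ~ P_cum, data = d)$residuals ^ 2)
  sse0 <- sse(dmc)
  sse1 <- sse(dmc[seq_len(break_index), ])
  sse2 <- sse(dmc[(break_index + 1):n, ])
  note <- NULL
  if (sse1 + sse2 <= .Machine$double.eps * sse0 && sse0 > 0) {
    f <- Inf; p <- 0
    note <- "segments fit perfectly while the pooled model does not"
  } else if (sse0 <= 0) {
    f <- 0; p <- 1
    note <- "all models fit perfectly: no break"
  } else {
    f <- ((sse0 - (sse1 + sse2)) / k) / ((sse1 + sse2) / (n - 2 * k))
    f <- max(f, 0)
    p <- pf(f, k, n - 2 * k, lower.tail = FALSE)
  }
  structure(list(SSE0 = sse0, SSE1 = sse1, SSE2 = sse2, K = k, n = n,
                 F = f, p_value = p, alpha = alpha,
                 break_detected = p < alpha, break_index = break_index,
                 note = note,
                 meta = "OLS on cumulative series; no autocorrelation correction"),
            class = "chow_result")
}

#' Step-2 decision: was the water-yield ratio disturbed at the fire date?
#'
#' Builds the 120-month double-mass curve (60 months each side of the fire
#' month) and applies [chow_test()] with the break placed at the fire date.
#'
#' @param monthly Monthly data frame with `P_mm` and `Q_mm`.
#' @param fire_date Fire date.
#' @param alpha Significance level.
#' @return A `chow_result`; `break_detected` is the rejection of the
#'   no-yield-change null.
#' @export
test_yield_disturbance <- function(monthly, fire_date, alpha = 0.05) {
  idx <- window_indices(monthly$date, fire_date)
  rows <- c(idx$pre, idx$post)
  dmc <- double_mass_curve(monthly$Q_mm[rows], monthly$P_mm[rows])
  chow_test(dmc, break_index = length(idx$pre), alpha = alpha)
}

#' @export
print.chow_result <- function(x, ...) {
  cat(sprintf("<chow_result> F(%d, %d) = %.3f, p = %.4g: break %sdetected at index %d\n",
              x$K, x$n - 2 * x$K, x$F, x$p_value,
              if (x$break_detected) "" else "not ", x$break_index))
  invisible(x)
}
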