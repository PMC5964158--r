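# Agreement statistics between sulcus traces and repeated placements.

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures. Rows are
#' targets, columns are raters/methods.
#'
#' @param x n x k matrix of measurements.
#' @return ICC in \[-1, 1\].
#' @export
icc21 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) return(1)   # all measurements identical
  (msr - mse) / denom
}

#' Agreement between an automatic and a manual sulcus trace
#'
#' Point counts may differ: every automatic point is matched to its nearest
#' manual point ("nearest points" matching). Distances are Euclidean; the
#' ICC(2,1) is computed on the matched coordinate pairs with the three
#' coordinates pooled.
#'
#' @param auto,manual `sulcus_trace` objects (or n x 3 matrices).
#' @return a `trace_agreement`: `mean_dist_mm`, `sd_dist_mm`, `icc`.
#' @export
trace_agreement <- function(auto, manual) {
  a <- if (inherits(auto, "sulcus_trace")) auto$points else as_points(auto)
  m <- if (inherits(manual, "sulcus_trace")) manual$points else as_points(manual)
  nn <- FNN::get.knnx(m, a, k = 1)
  matched <- m[nn$nn.index[, 1], , drop = FALSE]
  d <- nn$nn.dist[, 1]
  icc <- icc21(cbind(as.vector(a), as.vector(matched)))
  structure(list(mean_dist_mm = mean(d), sd_dist_mm = stats::sd(d), icc = icc),
            class = "trace_agreement")
}

#' @export
print.trace_agreement <- function(x, ...) {
  cat(sprintf("<trace_agreement> %.2f +/- %.2f mm, ICC %.4f\n",
              x$mean_dist_mm, x$sd_dist_mm, x$icc))
  invisible(x)
}

# core one-way repeated-measures ANOVA on a subjects x conditions matrix
rm_anova_matrix <- function(y, factor_name = "condition") {
  y <- as.matrix(y)
  s <- nrow(y); c <- ncol(y)
  if (s < 2 || c < 2) stop_repe("need >= 2 subjects and >= 2 conditions", "repe_input_error")
  grand <- mean(y)
  ss_cond <- s * sum((colMeans(y) - grand)^2)
  ss_subj <- c * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1L
  df2 <- (c - 1L) * (s - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err <= 0) { if (ms_cond <= 0) 0 else Inf } else ms_cond / ms_err
  data.frame(factor = factor_name, F = f, df_num = df1, df_den = df2,
             p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' One-way repeated-measures ANOVA on a positioning-delta table
#'
#' Tests for a systematic displacement across conditions (e.g. the
#' repetition differences Rep2-1 ... Rep5-1): a significant condition
#' effect flags a systematic positioning error. Input is either a
#' subjects x conditions matrix (one F test) or a long, balanced
#' data.frame with columns `subject`, `condition`, `axis`, `delta`
#' (one F test per axis).
#'
#' @param deltas matrix or long data.frame (see above).
#' @param factor_name label for the within-subject factor.
#' @return data.frame with columns `factor`, `F`, `df_num`, `df_den`, `p`
#'   (one row per axis for long input).
#' @export
rm_anova <- function(deltas, factor_name = "positioning_error") {
  if (is.matrix(deltas) || (is.data.frame(deltas) && is.null(deltas$axis)))
    return(rm_anova_matrix(deltas, factor_name))
  need <- c("subject", "condition", "axis", "delta")
  if (!all(need %in% names(deltas)))
    stop_repe("long input needs subject/condition/axis/delta columns", "repe_input_error")
  out <- NULL
  for (ax in unique(deltas$axis)) {
    df <- deltas[deltas$axis == ax, ]
    tab <- table(df$subject, df$condition)
    if (any(tab != 1L)) stop_repe("unbalanced delta table", "repe_input_error")
    y <- stats::xtabs(delta ~ subject + condition, df)
    r <- rm_anova_matrix(as.matrix(y), paste0(factor_name, ":", ax))
    out <- rbind(out, r)
  }
  out
}
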