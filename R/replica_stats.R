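# Replica-level aggregation of per-frame metrics ------------------------------

#' Per-replica metric time series
#'
#' @param values ordered numeric metric values.
#' @param times matching time stamps (ps).
#' @param system_label,replica_label,metric_name identifying labels.
#' @export
metric_series <- function(values, times = seq_along(values) - 1,
                          system_label = "system", replica_label = "Equ1",
                          metric_name = "metric") {
  if (length(values) != length(times))
    stop("values and times must have equal length")
  structure(list(system_label = system_label, replica_label = replica_label,
                 metric_name = metric_name,
                 values = as.numeric(values), times = as.numeric(times)),
            class = "metric_series")
}

#' Drop the leading equilibration part of a series
#'
#' Removes the first `ceiling(fraction * n)` points.
#'
#' @param series a `metric_series` (or plain numeric vector).
#' @param fraction in [0, 1).
#' @export
discard_equilibration <- function(series, fraction = 0.2) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (is.numeric(series)) {
    n <- length(series)
    return(series[seq_len(n) > ceiling(fraction * n)])
  }
  n <- length(series$values)
  keep <- seq_len(n) > ceiling(fraction * n)
  series$values <- series$values[keep]
  series$times <- series$times[keep]
  series
}

#' Histogram + kernel-density summary of pooled metric values
#'
#' The density uses Silverman's rule-of-thumb bandwidth on a fixed grid and
#' is renormalized to integrate to 1 on that grid. Modes are density maxima
#' whose height exceeds a prominence floor (fraction of the peak density),
#' so a clean bimodal pooled distribution reports 2 modes. Constant input
#' yields a degenerate-distribution flag and no KDE.
#'
#' @param values pooled numeric values (>= 2).
#' @param n_grid density grid size.
#' @param prominence_floor minimum mode height as a fraction of the peak.
#' @return list: `histogram` (from [graphics::hist()] machinery, counts
#'   only), `density` data.frame (x, y) or NULL, `n_modes`, `degenerate`.
#' @export
distribution_summary <- function(values, n_grid = 512,
                                 prominence_floor = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  h <- graphics::hist(values, plot = FALSE)
  if (stats::sd(values) == 0) {
    return(list(histogram = h, density = NULL, n_modes = 1L,
                degenerate = TRUE))
  }
  d <- stats::density(values, bw = "nrd0", n = n_grid)
  dx <- diff(d$x[1:2])
  y <- d$y / (sum(d$y) * dx)              # renormalize on the grid
  interior <- 2:(length(y) - 1)
  is_max <- y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]
  modes <- interior[is_max]
  modes <- modes[y[modes] >= prominence_floor * max(y)]
  list(histogram = h, density = data.frame(x = d$x, y = y),
       n_modes = length(modes), degenerate = FALSE)
}

#' Welch two-sample comparison with significance stars
#'
#' Two-sided Welch t-test on per-replica means (the unit of replication is
#' the simulation run, not the frame, avoiding frame autocorrelation).
#' Stars: "*" for 0.01 <= p < 0.05, "**" for p < 0.01.
#'
#' @param a,b numeric vectors of per-replica means (>= 2 each).
#' @param label_a,label_b group labels.
#' @return list (class `comparison_result`): group labels, `t_statistic`,
#'   `df`, `p_value`, `stars`.
#' @export
compare_groups <- function(a, b, label_a = "A", label_b = "B") {
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicas per group")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se2 <- va + vb
  if (se2 == 0) {
    t_stat <- 0; df <- length(a) + length(b) - 2; p <- 1
  } else {
    t_stat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(group_a = label_a, group_b = label_b,
                 t_statistic = t_stat, df = df, p_value = p,
                 stars = p_stars(p)),
            class = "comparison_result")
}

p_stars <- function(p) if (p < 0.01) "**" else if (p < 0.05) "*" else ""

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s: t = %.3f (df %.2f), p = %.4g %s\n",
              x$group_a, x$group_b, x$t_statistic, x$df, x$p_value,
              x$stars))
  invisible(x)
}
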