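#' Autocorrelation profile and stationarity verdict
#'
#' Sample autocorrelation (biased, denominator-n, mean-centered estimator —
#' the conventional correlogram as computed by [stats::acf()]) with two-sided
#' white-noise bounds +/- z_{0.975}/sqrt(n). A series is called stationary
#' when at most 5% of the lags 1..`max_lag` fall outside the bound: a flat
#' in-bound correlogram means the autocovariance depends on the interval, not
#' on time, which is the working assumption behind trend testing on these
#' series.
#'
#' @param series ordered numeric values, length >= `max_lag` + 2.
#' @param max_lag highest lag to evaluate (>= 1).
#' @param series_id optional identifier carried into the result.
#' @return object of class `acf_result`: list with `lags` (0..max_lag),
#'   `acf`, `bound`, `n_significant_lags`, `stationary_verdict`, `series_id`.
#' @export
acf_profile <- function(series, max_lag = min(20L, length(series) - 2L),
                        series_id = NA_character_) {
  n <- length(series)
  if (max_lag < 1) stop("`max_lag` must be >= 1", call. = FALSE)
  if (n < max_lag + 2) stop("series too short for requested lags", call. = FALSE)
  if (stats::var(series) == 0) {
    stop("constant series: autocorrelation undefined", call. = FALSE)
  }
  rho <- drop(stats::acf(series, lag.max = max_lag, plot = FALSE,
                         demean = TRUE)$acf)
  bound <- stats::qnorm(0.975) / sqrt(n)
  sig <- abs(rho[-1]) > bound
  structure(list(series_id = series_id,
                 lags = 0:max_lag,
                 acf = rho,
                 bound = bound,
                 n_significant_lags = sum(sig),
                 stationary_verdict = mean(sig) <= 0.05),
            class = "acf_result")
}

#' Mann-Kendall trend test
#'
#' Nonparametric trend test on the signs of all pairwise differences:
#' S = sum over i<j of sign(x_j - x_i); Var(S) uses the tie correction
#' \[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)\]/18 over tie groups of size t; the
#' standardized statistic applies a continuity correction
#' (Z = (S-1)/sqrt(Var) for S>0, (S+1)/sqrt(Var) for S<0, 0 at S=0) and the
#' p-value is two-sided normal.
#'
#' @param series ordered numeric values, n >= 4.
#' @param alpha significance level used only to label `direction`.
#' @param series_id optional identifier.
#' @return object of class `trend_result`: list with `S`, `varS`, `Z`, `p`,
#'   `direction` (one of `"increasing"`, `"decreasing"`, `"none"`), `n`,
#'   `series_id`.
#' @export
mann_kendall <- function(series, alpha = 0.05, series_id = NA_character_) {
  n <- length(series)
  if (n < 4) stop("Mann-Kendall needs n >= 4", call. = FALSE)
  d <- outer(series, series, "-") # d[i, j] = x_i - x_j
  S <- sum(sign(d[lower.tri(d)])) # i > j: sign(x_j - x_i) summed over j < i
  ties <- table(series)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  p <- if (varS == 0) 1 else 2 * stats::pnorm(-abs(Z))
  direction <- if (p <= alpha && S > 0) "increasing"
    else if (p <= alpha && S < 0) "decreasing" else "none"
  structure(list(series_id = series_id, n = n, S = S, varS = varS,
                 Z = Z, p = min(p, 1), direction = direction),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %.0f, Var(S) = %.3f, Z = %.3f, p = %.4f (%s)\n",
              x$S, x$varS, x$Z, x$p, x$direction))
  invisible(x)
}

#' Select a subject's core OTUs
#'
#' Core OTUs are those detected (count > 0) at strictly more than half of the
#' subject's time points.
#'
#' @param table an [otu_table()].
#' @param subject subject id.
#' @return character vector of core OTU ids.
#' @export
select_core_otus <- function(table, subject) {
  stopifnot(inherits(table, "otu_table"))
  keep <- table$metadata$subject == subject
  if (!any(keep)) stop("unknown subject: ", subject, call. = FALSE)
  if (sum(keep) < 2) stop("subject has fewer than 2 time points", call. = FALSE)
  sub <- table$counts[, table$metadata$sample_id[keep], drop = FALSE]
  present <- rowSums(sub > 0)
  rownames(sub)[present > ncol(sub) / 2]
}

#' Horizon-graph transform of a time series
#'
#' Mean-centers the series and divides it into bands whose width is the mean
#' absolute deviation from the mean; each point is assigned a band index
#' (ceil(|centered| / width)) and a sign, ready for mirrored horizon-band
#' rendering.
#'
#' @param series numeric, length >= 2, non-constant.
#' @return list with `centered`, `band_width` (the MAD), `band` (integer
#'   index per point) and `sign` (-1, 0, 1 per point).
#' @export
horizon_transform <- function(series) {
  if (length(series) < 2) stop("need at least 2 points", call. = FALSE)
  centered <- series - mean(series)
  width <- mean(abs(centered))
  if (width == 0) stop("constant series: zero mean absolute deviation",
                       call. = FALSE)
  list(centered = centered,
       band_width = width,
       band = as.integer(ceiling(abs(centered) / width)),
       sign = sign(centered))
}

#' Trend-test a panel of series over a time window
#'
#' Applies [mann_kendall()] to each column of a time x series matrix,
#' optionally restricted to a contiguous window of rows (the outside-to-inside
#' stretch of the study, typically).
#'
#' @param series_matrix time x series numeric matrix with column names.
#' @param window integer vector of row indices (default: all rows).
#' @return data.frame with one row per series: `series`, `n`, `S`, `varS`,
#'   `Z`, `p`, `direction`.
#' @export
trend_panel <- function(series_matrix, window = seq_len(nrow(series_matrix))) {
  stopifnot(is.matrix(series_matrix))
  m <- series_matrix[window, , drop = FALSE]
  res <- lapply(colnames(m), function(id) {
    r <- mann_kendall(m[, id], series_id = id)
    data.frame(series = id, n = r$n, S = r$S, varS = r$varS, Z = r$Z,
               p = r$p, direction = r$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
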