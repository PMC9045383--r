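#' Fractional (total-sum) normalization of one subject's series
#'
#' Step (i) of the reference-community normalization: within a subject,
#' convert each time point's counts to fractional abundances summing to 1.
#'
#' @param table an [otu_table()].
#' @param subject subject id present in the metadata.
#' @return numeric matrix, time points (rows, ordered by `time_point`) x OTUs.
#' @export
fractional_normalize <- function(table, subject) {
  stopifnot(inherits(table, "otu_table"))
  meta <- table$metadata
  keep <- meta$subject == subject
  if (!any(keep)) stop("unknown subject: ", subject, call. = FALSE)
  if (sum(keep) < 2) stop("subject has fewer than 2 time points", call. = FALSE)
  ord <- order(meta$time_point[keep])
  ids <- meta$sample_id[keep][ord]
  m <- t(table$counts[, ids, drop = FALSE])
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ", paste(ids[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  m / totals
}

#' Select highly abundant OTUs by cumulative median abundance
#'
#' Step (ii): rank OTUs by their median-across-time fractional abundance and
#' keep the smallest prefix whose medians cumulatively reach `threshold` of
#' the summed medians (default 90% of median time-point reads).
#'
#' @param fractions time x OTU fraction matrix (rows sum to 1).
#' @param threshold cumulative fraction in (0, 1].
#' @return character vector of selected OTU ids.
#' @export
select_abundant_otus <- function(fractions, threshold = 0.90) {
  if (!is.matrix(fractions) || nrow(fractions) == 0 || ncol(fractions) == 0) {
    stop("empty abundance matrix", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  med <- apply(fractions, 2, stats::median)
  ord <- order(med, decreasing = TRUE)
  cum <- cumsum(med[ord])
  total <- cum[length(cum)]
  # a tiny slack keeps threshold = 1 from tipping past the last nonzero
  # median through floating-point undershoot
  k <- which(cum >= threshold * total - 1e-12)[1]
  colnames(fractions)[ord[seq_len(k)]]
}

#' Jensen-Shannon distance between two compositions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the distance is bounded in \[0, 1\]. `0 * log(0)` is taken as 0.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1
#'   (tolerance 1e-9).
#' @return distance in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("negative component", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("inputs must each sum to 1", call. = FALSE)
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  d2 <- (kl(p, m) + kl(q, m)) / 2
  sqrt(max(d2, 0))
}

#' Weighted median
#'
#' Smallest value (in sorted order) whose cumulative weight reaches half the
#' total weight.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, same length, not all zero.
#' @return scalar weighted median.
#' @export
weighted_median <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch", call. = FALSE)
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
  ord <- order(values)
  cw <- cumsum(weights[ord])
  values[ord][which(cw >= sum(weights) / 2)[1]]
}

#' Reference-community normalization of a compositional time series
#'
#' Step (iii): each time point is rescaled toward a reference community built
#' from the *other* time points with similar community structure. For focal
#' time point t, similarity to every other time point u is the
#' Jensen-Shannon distance j(t, u) computed over the abundant-OTU
#' subcomposition; time-point weights are (1 - j)^2; the reference value of
#' each abundant OTU is the weighted median of its fractions over u != t; the
#' scale factor of t is the median, over abundant OTUs with nonzero focal
#' fraction, of reference/focal ratios; all OTU fractions at t are multiplied
#' by that factor. This damps the compositional ripple a single-taxon bloom
#' imposes on every other taxon's fraction.
#'
#' @param fractions time x OTU fraction matrix (rows sum to 1), >= 3 rows.
#' @param abundant character vector of abundant OTU ids (subset of columns).
#' @param subject optional subject id carried through for bookkeeping.
#' @return object of class `normalized_series`: list with `abundances`
#'   (time x OTU, rescaled), `fractions` (the step-(i) input), `abundant_otus`,
#'   `scale_factors`, `reference` (time x abundant OTU matrix), `subject`.
#' @export
reference_normalize <- function(fractions, abundant, subject = NA_character_) {
  if (nrow(fractions) < 3) stop("need at least 3 time points", call. = FALSE)
  if (length(abundant) == 0) stop("empty abundant OTU set", call. = FALSE)
  if (!all(abundant %in% colnames(fractions))) {
    stop("abundant OTUs absent from matrix: ",
         paste(setdiff(abundant, colnames(fractions)), collapse = ", "),
         call. = FALSE)
  }
  n_t <- nrow(fractions)
  ab <- fractions[, abundant, drop = FALSE]
  dead <- rowSums(ab) == 0
  if (any(dead)) {
    stop("all abundant OTUs are zero at time point ",
         paste(rownames(fractions)[dead] %||% which(dead), collapse = ", "),
         call. = FALSE)
  }
  # abundant-OTU subcompositions, renormalized to the simplex for the JSD
  ab_comp <- ab / rowSums(ab)
  scale_factors <- numeric(n_t)
  reference <- matrix(NA_real_, n_t, length(abundant),
                      dimnames = list(rownames(fractions), abundant))
  for (t in seq_len(n_t)) {
    if (all(ab[t, ] == 0)) {
      stop("all abundant OTUs are zero at time point ",
           rownames(fractions)[t] %||% t, call. = FALSE)
    }
    others <- setdiff(seq_len(n_t), t)
    j <- vapply(others, function(u) jsd(ab_comp[t, ], ab_comp[u, ]),
                numeric(1))
    w <- (1 - j)^2
    ref_t <- vapply(seq_along(abundant), function(k) {
      weighted_median(ab[others, k], w)
    }, numeric(1))
    reference[t, ] <- ref_t
    nz <- ab[t, ] > 0
    scale_factors[t] <- stats::median(ref_t[nz] / ab[t, nz])
  }
  structure(list(abundances = fractions * scale_factors,
                 fractions = fractions,
                 abundant_otus = abundant,
                 scale_factors = scale_factors,
                 reference = reference,
                 subject = subject),
            class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf(
    "normalized_series: %d time points x %d OTUs (%d abundant), subject %s\n",
    nrow(x$abundances), ncol(x$abundances), length(x$abundant_otus),
    x$subject))
  cat("scale factors: ", paste(sprintf("%.3f", x$scale_factors),
                               collapse = " "), "\n")
  invisible(x)
}

#' Full three-step normalization for one subject
#'
#' Convenience wrapper running [fractional_normalize()],
#' [select_abundant_otus()] and [reference_normalize()].
#'
#' @inheritParams fractional_normalize
#' @inheritParams select_abundant_otus
#' @return a `normalized_series`.
#' @export
normalize_subject <- function(table, subject, threshold = 0.90) {
  fr <- fractional_normalize(table, subject)
  ab <- select_abundant_otus(fr, threshold)
  reference_normalize(fr, ab, subject = subject)
}
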