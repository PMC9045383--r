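#' PCA of sample abundance profiles
#'
#' Column-mean-centered principal component analysis (no unit scaling) of a
#' samples x OTU fraction matrix, via [stats::prcomp()].
#'
#' @param abundances samples x OTU numeric matrix (>= 2 rows).
#' @param n_components number of components to retain;
#'   must be <= min(samples - 1, OTUs).
#' @return object of class `pca_model`: list with `scores` (samples x
#'   components), `loadings`, `explained` (variance fractions, descending).
#' @export
pca_profiles <- function(abundances, n_components = NULL) {
  stopifnot(is.matrix(abundances))
  n <- nrow(abundances)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  cap <- min(n - 1, ncol(abundances))
  if (is.null(n_components)) n_components <- cap
  if (n_components > cap) {
    stop(sprintf("n_components must be <= %d (min(samples - 1, OTUs))", cap),
         call. = FALSE)
  }
  fit <- stats::prcomp(abundances, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x[, keep, drop = FALSE],
                 loadings = fit$rotation[, keep, drop = FALSE],
                 center = fit$center,
                 explained = explained[keep]),
            class = "pca_model")
}

#' Group separation on principal-component scores
#'
#' Statistical separation of labelled groups in PC space: Mahalanobis
#' distances between group means under the pooled within-group covariance
#' (ridge-regularized), an overall one-way MANOVA (Wilks' lambda with Rao's F
#' approximation, via [stats::manova()]), pairwise two-group Hotelling T^2
#' tests with Bonferroni adjustment, and a single-linkage dendrogram over the
#' group-mean distance matrix.
#'
#' @param scores samples x PCs numeric matrix.
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_pcs number of leading PCs to use; capped at
#'   min(`n_pcs`, available PCs, samples - groups - 1) to keep the pooled
#'   covariance invertible.
#' @return object of class `group_separation`: list with `groups`,
#'   `mahalanobis` (distance matrix between group means), `wilks`,
#'   `approx_F`, `df`, `p`, `pairwise` (Hotelling T^2 data.frame), `hclust`
#'   (single-linkage tree), `n_pcs_used`.
#' @export
group_separation <- function(scores, labels, n_pcs = 25) {
  stopifnot(is.matrix(scores))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2)) stop("every group needs >= 2 samples",
                                   call. = FALSE)
  n <- nrow(scores)
  d <- min(n_pcs, ncol(scores), n - k - 1)
  if (d < 1) stop("too few samples for any usable PC", call. = FALSE)
  x <- scores[, seq_len(d), drop = FALSE]

  # pooled within-group covariance with a light ridge for numerical safety
  pooled <- matrix(0, d, d)
  for (g in groups) {
    xg <- x[labels == g, , drop = FALSE]
    pooled <- pooled + stats::cov(xg) * (nrow(xg) - 1)
  }
  pooled <- pooled / (n - k)
  # ridge small enough that Mahalanobis distances stay invariant to joint
  # invertible transforms well below 1e-6
  pooled <- pooled + diag(1e-10 * sum(diag(pooled)) / d, d)
  pinv <- solve(pooled)

  means <- do.call(rbind, lapply(groups, function(g) {
    colMeans(x[labels == g, , drop = FALSE])
  }))
  rownames(means) <- groups
  md <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      delta <- means[i, ] - means[j, ]
      md[i, j] <- md[j, i] <- sqrt(drop(delta %*% pinv %*% delta))
    }
  }

  fit <- stats::manova(x ~ factor(labels))
  wk <- summary(fit, test = "Wilks")$stats
  pairwise <- hotelling_pairwise(x, labels, groups)
  hc <- stats::hclust(stats::as.dist(md), method = "single")

  structure(list(groups = groups,
                 mahalanobis = md,
                 wilks = wk[1, "Wilks"],
                 approx_F = wk[1, "approx F"],
                 df = wk[1, c("num Df", "den Df")],
                 p = wk[1, "Pr(>F)"],
                 pairwise = pairwise,
                 hclust = hc,
                 n_pcs_used = d,
                 statistic = "Wilks"),
            class = "group_separation")
}

# two-group Hotelling T^2 with F transform, Bonferroni-adjusted over pairs
hotelling_pairwise <- function(x, labels, groups) {
  combos <- utils::combn(groups, 2)
  d <- ncol(x)
  res <- apply(combos, 2, function(ab) {
    xa <- x[labels == ab[1], , drop = FALSE]
    xb <- x[labels == ab[2], , drop = FALSE]
    na <- nrow(xa); nb <- nrow(xb)
    sp <- (stats::cov(xa) * (na - 1) + stats::cov(xb) * (nb - 1)) / (na + nb - 2)
    sp <- sp + diag(1e-8 * sum(diag(sp)) / d, d)
    delta <- colMeans(xa) - colMeans(xb)
    t2 <- (na * nb) / (na + nb) * drop(delta %*% solve(sp) %*% delta)
    df2 <- na + nb - d - 1
    if (df2 < 1) return(c(t2 = t2, p = NA_real_))
    f <- t2 * df2 / ((na + nb - 2) * d)
    c(t2 = t2, p = stats::pf(f, d, df2, lower.tail = FALSE))
  })
  data.frame(group_a = combos[1, ], group_b = combos[2, ],
             T2 = res["t2", ], p = res["p", ],
             p_adjusted = pmin(stats::p.adjust(res["p", ], "bonferroni"), 1),
             stringsAsFactors = FALSE)
}

#' @export
print.group_separation <- function(x, ...) {
  cat(sprintf(
    "group separation (%d groups, %d PCs): Wilks = %.4f, F = %.3f, p = %.3g\n",
    length(x$groups), x$n_pcs_used, x$wilks, x$approx_F, x$p))
  invisible(x)
}
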