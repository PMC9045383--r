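#' Spearman rank correlation with t-approximation p-value
#'
#' rho on average ranks (via [stats::cor()]); two-sided p-value from the
#' t-distribution approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom, which is the standard choice at the short series
#' lengths (n ~ 10-18) this pipeline works with.
#'
#' @param x,y numeric vectors of equal length, n >= 4, neither constant.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values via [stats::p.adjust()] (method `"BH"`); monotone in rank
#' order and capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Genus-cytokine co-occurrence network for one subject
#'
#' Builds the inside-enclosure co-occurrence network of one subject: genera
#' are filtered to mean relative abundance above `abundance_threshold` across
#' the subject's inside-phase samples; every genus-genus, genus-cytokine and
#' cytokine-cytokine pair is rank-correlated across those time points; edges
#' are kept when |rho| >= `rho_threshold`. Raw p-values drive the
#' `significant` flag (p <= 0.05); BH-adjusted q-values are always attached
#' as well.
#'
#' @param table an [otu_table()] (OTU level).
#' @param taxonomy a `taxonomy_map`.
#' @param cytokines cytokine data.frame (`sample_id` + one column per
#'   cytokine) covering the subject's inside-phase samples.
#' @param subject subject id with >= 4 inside-phase time points.
#' @param abundance_threshold minimum mean relative abundance for a genus
#'   (default 0.01, i.e. 1%).
#' @param rho_threshold minimum |rho| for an edge (default 0.5).
#' @return object of class `co_network`: list with `nodes` (data.frame:
#'   `node`, `type`, `mean_level`) and `edges` (data.frame: `node_a`,
#'   `node_b`, `rho`, `p`, `q`, `sign`, `significant`).
#' @export
build_network <- function(table, taxonomy, cytokines, subject,
                          abundance_threshold = 0.01, rho_threshold = 0.5) {
  stopifnot(inherits(table, "otu_table"))
  meta <- table$metadata
  keep <- meta$subject == subject & meta$environment == "inside"
  ids <- meta$sample_id[keep][order(meta$time_point[keep])]
  ids <- intersect(ids, cytokines$sample_id)
  if (length(ids) < 4) {
    stop("subject needs >= 4 inside-phase samples with cytokine data",
         call. = FALSE)
  }
  genus_tab <- aggregate_to_rank(table, taxonomy, "genus")
  fr <- t(genus_tab$counts[, ids, drop = FALSE])
  fr <- fr / rowSums(fr)
  fr <- fr[, colnames(fr) != "unclassified", drop = FALSE]
  mean_ab <- colMeans(fr)
  genera <- colnames(fr)[mean_ab > abundance_threshold]
  if (!length(genera)) {
    stop("no genus exceeds mean relative abundance ", abundance_threshold,
         call. = FALSE)
  }
  cyt <- cytokines[match(ids, cytokines$sample_id), , drop = FALSE]
  cyt_names <- setdiff(names(cyt), "sample_id")
  panel <- cbind(fr[, genera, drop = FALSE],
                 as.matrix(cyt[, cyt_names, drop = FALSE]))
  node_type <- c(rep("genus", length(genera)),
                 rep("cytokine", length(cyt_names)))
  nodes <- data.frame(node = colnames(panel), type = node_type,
                      mean_level = colMeans(panel), stringsAsFactors = FALSE,
                      row.names = NULL)

  combos <- utils::combn(ncol(panel), 2)
  usable <- apply(combos, 2, function(ij) {
    stats::var(panel[, ij[1]]) > 0 && stats::var(panel[, ij[2]]) > 0
  })
  combos <- combos[, usable, drop = FALSE]
  cors <- apply(combos, 2, function(ij) {
    r <- spearman_cor(panel[, ij[1]], panel[, ij[2]])
    c(rho = r$rho, p = r$p)
  })
  q <- fdr_adjust(cors["p", ])
  edges <- data.frame(node_a = colnames(panel)[combos[1, ]],
                      node_b = colnames(panel)[combos[2, ]],
                      rho = cors["rho", ], p = cors["p", ], q = q,
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[abs(edges$rho) >= rho_threshold, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  edges$significant <- edges$p <= 0.05
  rownames(edges) <- NULL
  structure(list(subject = subject, nodes = nodes, edges = edges,
                 samples = ids,
                 abundance_threshold = abundance_threshold,
                 rho_threshold = rho_threshold),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network (subject %s): %d nodes (%d genera, %d cytokines), %d edges\n",
              x$subject, nrow(x$nodes), sum(x$nodes$type == "genus"),
              sum(x$nodes$type == "cytokine"), nrow(x$edges)))
  invisible(x)
}
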