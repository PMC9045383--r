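#' Per-sample alpha diversity
#'
#' Shannon index (natural log, on fractional abundances, via
#' [vegan::diversity()]) or observed OTU richness.
#'
#' @param table an [otu_table()].
#' @param metric `"shannon"` or `"observed_otus"`.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "observed_otus")) {
  stopifnot(inherits(table, "otu_table"))
  metric <- match.arg(metric)
  m <- t(table$counts) # samples x OTUs, vegan orientation
  if (metric == "shannon") {
    vegan::diversity(m, index = "shannon")
  } else {
    rowSums(m > 0)
  }
}

# edge x leaf incidence: which tip fractions flow through each branch.
# Computed once per tree and reused for whole-matrix UniFrac.
branch_leaf_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    children[[p]] <- c(children[[p]], tree$edge[e, 2])
  }
  inc <- matrix(0, nrow(tree$edge), n_tip,
                dimnames = list(NULL, tree$tip.label))
  # postorder: children before parents, so descendant sets accumulate
  desc <- vector("list", n_node)
  for (v in seq_len(n_tip)) desc[[v]] <- v
  tree_po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree_po$edge))) {
    child <- tree_po$edge[e, 2]
    if (child > n_tip) {
      desc[[child]] <- unlist(desc[children[[child]]])
    }
  }
  for (e in seq_len(nrow(tree$edge))) {
    inc[e, desc[[tree$edge[e, 2]]]] <- 1
  }
  inc
}

#' Weighted UniFrac distance between two communities
#'
#' Branch-length-weighted sum of abundance-flow differences: with P_b and Q_b
#' the fractions of each sample descending through branch b,
#' raw = sum_b len_b * |P_b - Q_b|; the normalized variant divides by
#' sum_b len_b * (P_b + Q_b), bounding the distance in \[0, 1\].
#'
#' @param p,q compositions summing to 1, named by (or ordered as) the tree's
#'   leaf labels.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param normalized divide by the total abundance-weighted branch length
#'   (default TRUE).
#' @return scalar distance.
#' @export
weighted_unifrac <- function(p, q, tree, normalized = TRUE) {
  p <- align_to_leaves(p, tree)
  q <- align_to_leaves(q, tree)
  inc <- branch_leaf_incidence(tree)
  P <- drop(inc %*% p)
  Q <- drop(inc %*% q)
  raw <- sum(tree$edge.length * abs(P - Q))
  if (!normalized) return(raw)
  denom <- sum(tree$edge.length * (P + Q))
  if (denom == 0) return(0)
  raw / denom
}

align_to_leaves <- function(x, tree) {
  leaves <- tree$tip.label
  if (!is.null(names(x))) {
    missing <- setdiff(names(x), leaves)
    if (length(missing)) {
      stop("composition entries not on the tree: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    full <- stats::setNames(numeric(length(leaves)), leaves)
    full[names(x)] <- x
    x <- full
  } else if (length(x) != length(leaves)) {
    stop("unnamed composition length differs from leaf count", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) stop("composition must sum to 1", call. = FALSE)
  unname(x)
}

#' All-pairs weighted UniFrac distance matrix
#'
#' @param table an [otu_table()] whose OTU ids are leaves of `tree`.
#' @param tree rooted [ape::phylo].
#' @param normalized see [weighted_unifrac()].
#' @return object of class `dist_matrix`: list with `d` (symmetric matrix,
#'   zero diagonal), `ids`, `metric`.
#' @export
unifrac_matrix <- function(table, tree, normalized = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  missing <- setdiff(rownames(table$counts), tree$tip.label)
  if (length(missing)) {
    stop("OTUs not on the tree: ", paste(utils::head(missing, 5),
                                         collapse = ", "), call. = FALSE)
  }
  fr <- t(table$counts) / colSums(table$counts) # samples x OTUs
  inc <- branch_leaf_incidence(tree)[, rownames(table$counts), drop = FALSE]
  flow <- inc %*% t(fr) # branches x samples
  n <- ncol(flow)
  d <- matrix(0, n, n, dimnames = list(colnames(table$counts),
                                       colnames(table$counts)))
  len <- tree$edge.length
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      raw <- sum(len * abs(flow[, i] - flow[, j]))
      if (normalized) {
        denom <- sum(len * (flow[, i] + flow[, j]))
        raw <- if (denom == 0) 0 else raw / denom
      }
      d[i, j] <- d[j, i] <- raw
    }
  }
  structure(list(d = d, ids = colnames(d),
                 metric = if (normalized) "weighted_unifrac_normalized"
                          else "weighted_unifrac"),
            class = "dist_matrix")
}

#' Between-subject distances within a stratum
#'
#' Pools all pairwise distances between samples of *distinct* subjects that
#' share a time point (or an experimental phase). These are the violin-plot
#' populations behind the convergence comparison.
#'
#' @param dm a `dist_matrix` (see [unifrac_matrix()]).
#' @param metadata metadata data.frame covering the matrix ids.
#' @param by `"time_point"` or `"phase"`.
#' @return data.frame with `stratum`, `sample_i`, `sample_j`, `subject_i`,
#'   `subject_j`, `distance`.
#' @export
between_subject_distances <- function(dm, metadata, by = c("phase", "time_point")) {
  by <- match.arg(by)
  stopifnot(inherits(dm, "dist_matrix"))
  meta <- metadata[match(dm$ids, metadata$sample_id), ]
  out <- list()
  for (stratum in unique(meta[[by]])) {
    idx <- which(meta[[by]] == stratum)
    if (length(unique(meta$subject[idx])) < 2) {
      warning("stratum ", stratum, " has fewer than 2 subjects; skipped")
      next
    }
    pairs <- utils::combn(idx, 2)
    keep <- meta$subject[pairs[1, ]] != meta$subject[pairs[2, ]]
    pairs <- pairs[, keep, drop = FALSE]
    out[[as.character(stratum)]] <- data.frame(
      stratum = stratum,
      sample_i = dm$ids[pairs[1, ]],
      sample_j = dm$ids[pairs[2, ]],
      subject_i = meta$subject[pairs[1, ]],
      subject_j = meta$subject[pairs[2, ]],
      distance = dm$d[cbind(pairs[1, ], pairs[2, ])],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Permutation-calibrated convergence test across experimental phases
#'
#' Tests whether between-subject community distances differ across the three
#' experimental phases, pooling all between-subject sample pairs whose two
#' time points fall in the same phase. The observed statistic is the
#' (tie-uncorrected) Kruskal-Wallis H over the pooled pairs; its reference
#' distribution is obtained by permuting the phase labels *of time points*
#' and regrouping the pairs, because the pooled pairwise distances are
#' pseudo-replicated — every distance at a time point shares samples with
#' five others — and the chi-square reference would reject a true null far
#' too often. Time points are the exchangeable unit under the null of no
#' phase effect.
#'
#' @param dm a `dist_matrix` over the cohort samples.
#' @param metadata metadata data.frame covering the matrix ids.
#' @param n_perm number of permutations (default 999).
#' @param seed seed for the permutation draw.
#' @return list with `H` (observed), `p` (permutation p-value), `medians`
#'   (per-phase median between-subject distance), `n_pairs` (pairs pooled
#'   per phase), `n_perm`.
#' @export
convergence_test <- function(dm, metadata, n_perm = 999, seed = 1) {
  stopifnot(inherits(dm, "dist_matrix"))
  m <- metadata[match(dm$ids, metadata$sample_id), ]
  pr <- utils::combn(seq_along(dm$ids), 2)
  keep <- m$subject[pr[1, ]] != m$subject[pr[2, ]]
  pr <- pr[, keep, drop = FALSE]
  d <- dm$d[cbind(pr[1, ], pr[2, ])]
  tp1 <- m$time_point[pr[1, ]]
  tp2 <- m$time_point[pr[2, ]]
  utp <- sort(unique(m$time_point))
  phase_of_tp <- m$phase[match(utp, m$time_point)]
  h_stat <- function(ph) {
    p1 <- ph[match(tp1, utp)]
    p2 <- ph[match(tp2, utp)]
    inc <- p1 == p2
    g <- p1[inc]
    rr <- rank(d[inc])
    n <- length(rr)
    rg <- tapply(rr, g, sum)
    ng <- tapply(rr, g, length)
    (12 / (n * (n + 1))) * sum(rg^2 / ng) - 3 * (n + 1)
  }
  h0 <- h_stat(phase_of_tp)
  hp <- with_seed(seed, {
    replicate(n_perm, h_stat(sample(phase_of_tp)))
  })
  inc <- phase_of_tp[match(tp1, utp)] == phase_of_tp[match(tp2, utp)]
  g <- phase_of_tp[match(tp1, utp)][inc]
  list(H = h0,
       p = (1 + sum(hp >= h0)) / (n_perm + 1),
       medians = tapply(d[inc], g, stats::median),
       n_pairs = as.vector(table(g)),
       n_perm = n_perm)
}

#' Kruskal-Wallis comparison of grouped values with pairwise follow-up
#'
#' Overall rank-sum test (tie-corrected H, chi-square on k-1 df, via
#' [stats::kruskal.test()]) plus all pairwise two-group tests with Bonferroni
#' adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each nonempty).
#' @param grouping label describing what the groups are.
#' @return object of class `group_test`: list with `grouping`, `H`, `df`,
#'   `p`, `pairwise` (data.frame: group_a, group_b, p, p_adjusted),
#'   `medians`.
#' @export
kruskal_wallis_groups <- function(groups, grouping = "group") {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) {
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  kw <- stats::kruskal.test(groups)
  combos <- utils::combn(names(groups), 2)
  praw <- apply(combos, 2, function(ab) {
    stats::kruskal.test(groups[ab])$p.value
  })
  pairwise <- data.frame(group_a = combos[1, ], group_b = combos[2, ],
                         p = praw,
                         p_adjusted = stats::p.adjust(praw, "bonferroni"),
                         stringsAsFactors = FALSE)
  structure(list(grouping = grouping,
                 H = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p = kw$p.value,
                 pairwise = pairwise,
                 medians = vapply(groups, stats::median, numeric(1))),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (%s): H = %.4f, df = %d, p = %.4g\n",
              x$grouping, x$H, x$df, x$p))
  invisible(x)
}
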