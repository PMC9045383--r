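#' EM source tracking of one sink community
#'
#' Estimates the mixing proportions alpha of a sink sample over a set of
#' known source communities plus an "unknown" component, under a multinomial
#' mixture: the sink's taxon distribution is modelled as
#' sum_k alpha_k beta_k + alpha_unknown beta_unknown, with beta_k the
#' source relative-abundance profiles. This is an expectation-maximization
#' analogue of FEAST-style microbial source tracking, suited to the
#' sources-and-sinks design where a few environmental samples (e.g. habitat
#' air) are candidate origins for many host-associated samples.
#'
#' The EM ascends the joint penalized likelihood of the observed source
#' counts (multinomial draws from their beta_k) and the sink counts (a
#' multinomial draw from the mixture). Source profiles are latent: each
#' M-step re-estimates beta_k from the source's own smoothed counts plus
#' the sink counts assigned to it, so sink sampling noise can be soaked up
#' by small source-profile adjustments. The unknown profile starts uniform
#' and is re-estimated each M-step from the sink counts assigned to the
#' unknown plus a uniform Dirichlet prior: without the prior the model is
#' unidentifiable (a free unknown profile reproduces the sink exactly at
#' any mixing proportion). With it, the unknown claims taxa the sources
#' cannot explain, but cannot profitably absorb source-covered mass. The
#' estimator is accurate when the sources jointly account for most of the
#' sink; when the true unknown share is dominant it is conservative,
#' attributing less to the sources than the truth (see the methods
#' vignette).
#'
#' @param sink nonnegative count vector over taxa.
#' @param sources list of count vectors over the same taxa (or a taxa x
#'   sources count matrix, one column per source), each with positive total.
#' @param max_iter maximum EM iterations (default 1000).
#' @param tol convergence threshold on max |delta alpha| (default 1e-6).
#' @param pseudocount smoothing added to each source taxon count before
#'   normalization (default 1).
#' @param unknown_prior_strength total pseudocount mass of the uniform
#'   Dirichlet prior on the unknown profile, as a fraction of the sink
#'   depth (default 0.2).
#' @param sink_id optional identifier.
#' @return object of class `source_estimate`: list with `proportions` (named
#'   vector over sources + `"unknown"`, summing to 1), `loglik_trace` (the
#'   penalized objective per iteration, nondecreasing), `iterations`,
#'   `converged`, `unknown_dist`, `sink_id`.
#' @export
em_source_track <- function(sink, sources, max_iter = 1000, tol = 1e-6,
                            pseudocount = 1, unknown_prior_strength = 0.2,
                            sink_id = NA_character_) {
  if (is.matrix(sources)) {
    sources <- stats::setNames(
      lapply(seq_len(ncol(sources)), function(i) sources[, i]),
      colnames(sources) %||% paste0("source", seq_len(ncol(sources))))
  }
  if (is.null(names(sources))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  n_taxa <- length(sink)
  if (any(vapply(sources, length, integer(1)) != n_taxa)) {
    stop("taxa mismatch between sink and sources", call. = FALSE)
  }
  if (sum(sink) <= 0) stop("sink has zero total count", call. = FALSE)
  if (any(vapply(sources, sum, numeric(1)) <= 0)) {
    stop("source with zero total count", call. = FALSE)
  }
  k <- length(sources)
  src <- vapply(sources, function(s) as.numeric(s) + pseudocount,
                numeric(n_taxa)) # taxa x k, smoothed observed source counts
  beta <- sweep(src, 2, colSums(src), "/")
  beta_u <- rep(1 / n_taxa, n_taxa)
  alpha <- rep(1 / (k + 1), k + 1)
  x <- as.numeric(sink)
  N <- sum(x)
  anchor <- rep(unknown_prior_strength * N / n_taxa, n_taxa)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    B <- cbind(beta, unknown = beta_u) # taxa x (k+1)
    mix <- drop(B %*% alpha)
    # penalized observed-data objective: source draws + sink mixture draw
    # + uniform Dirichlet prior on the unknown profile
    ll_src <- sum(vapply(seq_len(k), function(j) {
      sum(src[, j] * log(beta[, j]))
    }, numeric(1)))
    ll_u <- sum(anchor * log(beta_u))
    loglik <- c(loglik, ll_src + ll_u + sum(x[x > 0] * log(mix[x > 0])))
    # E-step: responsibility of each component for each sink taxon
    r <- t(t(B) * alpha) / mix # taxa x (k+1); rows sum to 1 where mix > 0
    r[mix == 0, ] <- 1 / (k + 1)
    assigned <- x * r # expected sink counts per component
    # M-step: alpha from assigned mass; source profiles from their own
    # counts plus assigned sink counts; unknown from its assigned counts
    # plus the uniform anchor
    alpha_new <- colSums(assigned) / N
    sb <- src + assigned[, seq_len(k), drop = FALSE]
    beta <- sweep(sb, 2, colSums(sb), "/")
    bu <- assigned[, k + 1] + anchor
    beta_u <- bu / sum(bu)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }
  names(alpha) <- c(names(sources), "unknown")
  structure(list(sink_id = sink_id,
                 proportions = alpha,
                 loglik_trace = loglik,
                 iterations = iter,
                 converged = converged,
                 unknown_dist = beta_u,
                 sink_depth = N),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("source_estimate (%s): %s after %d iterations\n",
              x$sink_id,
              paste(sprintf("%s = %.3f", names(x$proportions),
                            x$proportions), collapse = ", "),
              x$iterations))
  invisible(x)
}

#' Source attribution across a cohort of sink samples
#'
#' Runs [em_source_track()] for every sink sample in an OTU table against the
#' named source samples, and reports per-source mean proportions over sinks.
#'
#' @param table an [otu_table()] containing both source and sink samples.
#' @param source_ids,sink_ids disjoint character vectors of sample ids.
#' @param ... passed to [em_source_track()].
#' @return list with `estimates` (one `source_estimate` per sink),
#'   `proportions` (sinks x components matrix) and `mean_proportions`.
#' @export
attribute_cohort <- function(table, source_ids, sink_ids, ...) {
  stopifnot(inherits(table, "otu_table"))
  if (length(intersect(source_ids, sink_ids))) {
    stop("source and sink ids overlap: ",
         paste(intersect(source_ids, sink_ids), collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(c(source_ids, sink_ids), colnames(table$counts))
  if (length(absent)) {
    stop("samples absent from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sources <- lapply(source_ids, function(id) table$counts[, id])
  names(sources) <- source_ids
  estimates <- lapply(sink_ids, function(id) {
    em_source_track(table$counts[, id], sources, sink_id = id, ...)
  })
  names(estimates) <- sink_ids
  prop <- do.call(rbind, lapply(estimates, `[[`, "proportions"))
  list(estimates = estimates,
       proportions = prop,
       mean_proportions = colMeans(prop))
}

#' Taxa shared between two sample groups at a rank
#'
#' Taxa (aggregated to `rank`) with nonzero count in at least one sample of
#' *both* groups — the Venn-overlap set between, e.g., air and saliva
#' communities.
#'
#' @param table an [otu_table()].
#' @param taxonomy a `taxonomy_map`.
#' @param group_a,group_b nonempty character vectors of sample ids.
#' @param rank taxonomic rank (default `"genus"`).
#' @return character vector of shared taxon labels (excluding
#'   `"unclassified"`).
#' @export
shared_taxa <- function(table, taxonomy, group_a, group_b, rank = "genus") {
  if (!length(group_a) || !length(group_b)) {
    stop("empty sample group", call. = FALSE)
  }
  agg <- aggregate_to_rank(table, taxonomy, rank)
  present <- function(ids) {
    rownames(agg$counts)[rowSums(agg$counts[, ids, drop = FALSE] > 0) > 0]
  }
  setdiff(intersect(present(group_a), present(group_b)), "unclassified")
}
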