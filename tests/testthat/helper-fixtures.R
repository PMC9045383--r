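# shared fixtures and independent oracles, all built in code

tiny_metadata <- function(sample_ids, subjects, time_points,
                          phases = rep(1L, length(sample_ids))) {
  data.frame(sample_id = sample_ids, subject = subjects,
             time_point = time_points, phase = phases,
             environment = ifelse(phases == 2, "inside", "outside"),
             gender = "M", stringsAsFactors = FALSE)
}

tiny_table <- function() {
  counts <- matrix(c(2L, 2L, 0L,
                     1L, 3L, 4L,
                     5L, 0L, 5L,
                     2L, 2L, 2L), nrow = 3,
                   dimnames = list(c("OTU1", "OTU2", "OTU3"),
                                   c("A_t1", "A_t2", "B_t1", "B_t2")))
  otu_table(counts, tiny_metadata(colnames(counts),
                                  c("A", "A", "B", "B"),
                                  c(1L, 2L, 1L, 2L)))
}

# one small cohort reused across tests (memoized per session)
.fixture_env <- new.env()
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(cohort_spec(n_otus = 120, seed = 7))
  }
  .fixture_env$cohort
}

# --- independent oracles -------------------------------------------------

# Jensen-Shannon distance straight from the KL definition, base 2
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}

# Mann-Kendall S by exhaustive double loop
oracle_mk_s <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

# tie-corrected Var(S) from the tie-group definition
oracle_mk_vars <- function(x) {
  n <- length(x)
  t <- as.numeric(table(x))
  (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
}

# Benjamini-Hochberg step-up written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# weighted UniFrac by explicit per-branch descendant search (no shared code
# with the package's incidence-matrix path)
oracle_wunifrac <- function(p, q, tree, normalized = TRUE) {
  n_tip <- length(tree$tip.label)
  descend_tips <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descend_tips))
  }
  raw <- 0
  denom <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- descend_tips(tree$edge[e, 2])
    pb <- sum(p[tree$tip.label[tips]])
    qb <- sum(q[tree$tip.label[tips]])
    raw <- raw + tree$edge.length[e] * abs(pb - qb)
    denom <- denom + tree$edge.length[e] * (pb + qb)
  }
  if (!normalized) raw else if (denom == 0) 0 else raw / denom
}

# minimum spanning tree edge weights by Prim's algorithm
oracle_mst_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  weights <- numeric(0)
  while (sum(in_tree) < n) {
    best <- Inf
    best_j <- NA
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        if (d[i, j] < best) {
          best <- d[i, j]
          best_j <- j
        }
      }
    }
    in_tree[best_j] <- TRUE
    weights <- c(weights, best)
  }
  sort(weights)
}

random_composition <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
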