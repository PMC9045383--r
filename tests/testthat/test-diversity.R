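test_that("alpha diversity has its closed forms", {
  counts <- cbind(one = c(5, 0, 0), even = c(4, 4, 4), two = c(1, 1, 0))
  rownames(counts) <- paste0("o", 1:3)
  tab <- otu_table(counts, tiny_metadata(colnames(counts), rep("A", 3), 1:3))
  sh <- alpha_diversity(tab, "shannon")
  expect_equal(unname(sh["one"]), 0)
  expect_equal(unname(sh["even"]), log(3))
  obs <- alpha_diversity(tab, "observed_otus")
  expect_equal(unname(obs["two"]), 2)
})

test_that("weighted UniFrac reproduces hand-computed trees", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(weighted_unifrac(c(A = 1, B = 0), c(A = 0, B = 1), two,
                                normalized = FALSE), 2)
  expect_equal(weighted_unifrac(c(A = 1, B = 0), c(A = 0, B = 1), two,
                                normalized = TRUE), 1)
  expect_equal(weighted_unifrac(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5),
                                two), 0)

  three <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")
  # shared internal branch carries full weight for both samples and cancels
  expect_equal(weighted_unifrac(c(A = 0, B = 1, C = 0),
                                c(A = 0, B = 0, C = 1), three,
                                normalized = FALSE), 1.0)
  expect_error(weighted_unifrac(c(A = 1, Z = 0), c(A = 0, Z = 1), two),
               "not on the tree")
})

test_that("weighted UniFrac agrees with per-branch accumulation on random trees", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("L", seq_len(n))
    p <- setNames(random_composition(n), tree$tip.label)
    q <- setNames(random_composition(n), tree$tip.label)
    for (norm in c(TRUE, FALSE)) {
      expect_equal(weighted_unifrac(p, q, tree, normalized = norm),
                   oracle_wunifrac(p, q, tree, normalized = norm),
                   tolerance = 1e-9)
    }
    expect_lte(weighted_unifrac(p, q, tree, normalized = TRUE), 1 + 1e-12)
  }
})

test_that("the distance matrix mirrors pairwise weighted UniFrac", {
  co <- small_cohort()
  sub <- co$otu_table
  ids <- sub$metadata$sample_id[1:5]
  tab <- otu_table(sub$counts[, ids], sub$metadata[1:5, ])
  dm <- unifrac_matrix(tab, co$tree)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 5))
  p <- tab$counts[, 1] / sum(tab$counts[, 1])
  q <- tab$counts[, 3] / sum(tab$counts[, 3])
  expect_equal(dm$d[1, 3], weighted_unifrac(p, q, co$tree), tolerance = 1e-12)
})

test_that("between-subject distances count the expected pairs", {
  co <- small_cohort()
  dm <- unifrac_matrix(co$otu_table, co$tree)
  bt <- between_subject_distances(dm, co$otu_table$metadata,
                                  by = "time_point")
  # 4 subjects at each time point -> choose(4,2) = 6 pairs
  expect_true(all(table(bt$stratum) == 6))
  expect_true(all(bt$subject_i != bt$subject_j))

  bp <- between_subject_distances(dm, co$otu_table$metadata, by = "phase")
  # phase pools all its time points' between-subject pairs (cross-time too)
  n2 <- sum(co$otu_table$metadata$phase == 2)
  per_subj <- n2 / 4
  expect_equal(sum(bp$stratum == 2),
               choose(4, 2) * per_subj * per_subj)
})

test_that("kruskal_wallis_groups reproduces the rank-sum hand example", {
  kw <- kruskal_wallis_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)

  same <- kruskal_wallis_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$H, 0, tolerance = 1e-9)

  three <- kruskal_wallis_groups(list(a = rnorm(5), b = rnorm(5),
                                      c = rnorm(5)))
  expect_equal(nrow(three$pairwise), 3)
  expect_true(all(three$pairwise$p_adjusted >= three$pairwise$p))
  expect_true(all(three$pairwise$p_adjusted <= 1))
  expect_error(kruskal_wallis_groups(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis_groups(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("phase convergence is detected and its null is calibrated", {
  co <- generate_cohort(cohort_spec(shared_weight_inside = 0.5, seed = 1))
  dm <- unifrac_matrix(co$otu_table, co$tree)
  ct <- convergence_test(dm, co$otu_table$metadata, seed = 1)
  expect_lt(ct$p, 0.05)
  expect_equal(unname(which.min(ct$medians)), 2)

  # a handful of null cohorts: mostly non-significant
  rej <- vapply(1:8, function(s) {
    co0 <- generate_cohort(cohort_spec(shared_weight_inside = 0,
                                       seed = 600 + s))
    dm0 <- unifrac_matrix(co0$otu_table, co0$tree)
    convergence_test(dm0, co0$otu_table$metadata, n_perm = 199,
                     seed = s)$p < 0.05
  }, logical(1))
  expect_lte(sum(rej), 2)
})
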