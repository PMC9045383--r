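test_that("fractional normalization puts every time point on the simplex", {
  tab <- tiny_table()
  fr <- fractional_normalize(tab, "A")
  expect_equal(unname(fr["A_t1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(rowSums(fr)), rep(1, 2), tolerance = 1e-9)
  expect_error(fractional_normalize(tab, "Z"), "unknown subject")

  counts <- matrix(c(1, 1, 0, 0, 2, 2), 2,
                   dimnames = list(c("o1", "o2"), c("s1", "s2", "s3")))
  expect_error(otu_table(counts, tiny_metadata(colnames(counts),
                                               rep("A", 3), 1:3)),
               "zero total")
})

test_that("abundant-OTU selection takes the smallest sufficient prefix", {
  fr <- matrix(rep(c(0.6, 0.3, 0.1), each = 3), nrow = 3,
               dimnames = list(NULL, c("big", "mid", "small")))
  expect_equal(select_abundant_otus(fr, 0.90), c("big", "mid"))
  expect_equal(select_abundant_otus(fr, 1.0), c("big", "mid", "small"))

  # zero-median OTUs never enter at threshold 1
  fr2 <- cbind(fr, zero = 0)
  expect_setequal(select_abundant_otus(fr2, 1.0), c("big", "mid", "small"))

  single <- matrix(1, 3, 1, dimnames = list(NULL, "only"))
  expect_equal(select_abundant_otus(single), "only")
  expect_error(select_abundant_otus(fr, 0), "threshold")
})

test_that("jsd matches the KL-based definition and its closed forms", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), oracle_jsd(c(0.5, 0.5), c(1, 0)),
               tolerance = 1e-12)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), sqrt(0.31127812), tolerance = 1e-6)

  set.seed(42)
  for (i in 1:25) {
    p <- random_composition(8)
    q <- random_composition(8)
    expect_equal(jsd(p, q), oracle_jsd(p, q), tolerance = 1e-12)
  }
  expect_error(jsd(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(jsd(c(0.7, 0.7), c(0.5, 0.5)), "sum to 1")
})

test_that("jsd is a bounded metric on random composition triples", {
  set.seed(1)
  for (i in 1:100) {
    p <- random_composition(6)
    q <- random_composition(6)
    r <- random_composition(6)
    dpq <- jsd(p, q)
    expect_gte(dpq, 0)
    expect_lte(dpq, 1)
    expect_equal(dpq, jsd(q, p), tolerance = 1e-12)
    expect_lte(dpq, jsd(p, r) + jsd(r, q) + 1e-9)
  }
})

test_that("weighted median follows the cumulative-weight rule", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(1, 10), c(0.9, 0.1)), 1)
  expect_equal(weighted_median(c(10, 1), c(0.1, 0.9)), 1)
  expect_equal(weighted_median(5, 2), 5)
  expect_error(weighted_median(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_median(c(1, 2), 1), "length")
})

test_that("a constant series is a fixed point of reference normalization", {
  fr <- matrix(rep(c(0.5, 0.3, 0.2), each = 4), 4,
               dimnames = list(NULL, c("a", "b", "c")))
  ns <- reference_normalize(fr, c("a", "b", "c"))
  expect_equal(ns$scale_factors, rep(1, 4))
  expect_equal(ns$abundances, fr)
  expect_error(reference_normalize(fr[1:2, ], c("a", "b")), "3 time points")
})

test_that("reference normalization ignores OTU labels and time order", {
  set.seed(8)
  co <- small_cohort()
  fr <- fractional_normalize(co$otu_table, "A")
  ab <- select_abundant_otus(fr)
  ns <- reference_normalize(fr, ab)

  # relabel OTUs
  perm <- sample(ncol(fr))
  fr2 <- fr[, perm]
  colnames(fr2) <- paste0("X", colnames(fr)[perm])
  ns2 <- reference_normalize(fr2, paste0("X", ab))
  expect_equal(unname(ns2$scale_factors), unname(ns$scale_factors),
               tolerance = 1e-12)

  # permute non-focal time points: focal row keeps its scale factor
  ord <- c(1, sample(2:nrow(fr)))
  ns3 <- reference_normalize(fr[ord, ], ab)
  expect_equal(ns3$scale_factors[1], ns$scale_factors[1], tolerance = 1e-12)
})

test_that("most similar time points dominate the reference weights", {
  # three time points: t2 nearly equals t1, t3 is far away; the reference
  # for t1 must sit at t2's value, not between t2 and t3
  fr <- rbind(c(0.50, 0.30, 0.20),
              c(0.51, 0.30, 0.19),
              c(0.10, 0.10, 0.80))
  colnames(fr) <- c("a", "b", "c")
  ns <- reference_normalize(fr, c("a", "b", "c"))
  expect_equal(unname(ns$reference[1, ]), unname(fr[2, ]))
})

test_that("reference normalization undoes a single-taxon bloom", {
  co <- generate_cohort(cohort_spec(seed = 0, shared_weight_inside = 0))
  tab <- co$otu_table
  fr0 <- fractional_normalize(tab, "A")
  ab <- select_abundant_otus(fr0)
  spike <- names(sort(colMeans(fr0), decreasing = TRUE))[1]
  t_spike <- 9
  tab2 <- tab
  sid <- tab$metadata$sample_id[tab$metadata$subject == "A" &
                                  tab$metadata$time_point == t_spike]
  tab2$counts[spike, sid] <- tab2$counts[spike, sid] * 10
  fr1 <- fractional_normalize(tab2, "A")
  ns1 <- reference_normalize(fr1, ab)
  others <- setdiff(ab, spike)
  err_frac <- mean(abs(log(fr1[t_spike, others] / fr0[t_spike, others])))
  err_ref <- mean(abs(log(ns1$abundances[t_spike, others] /
                            fr0[t_spike, others])))
  expect_lt(err_ref, err_frac)
  # unspiked abundant OTUs come back close to their pre-spike values
  expect_lt(err_ref, 0.1)
})

test_that("all-zero abundant rows at a time point are rejected by name", {
  fr <- rbind(c(0.5, 0.5, 0), c(0, 0, 1), c(0.4, 0.4, 0.2))
  colnames(fr) <- c("a", "b", "c")
  rownames(fr) <- c("t1", "t2", "t3")
  expect_error(reference_normalize(fr, c("a", "b")), "t2")
})
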