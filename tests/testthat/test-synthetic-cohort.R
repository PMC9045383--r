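test_that("cohort generation is deterministic and validates its spec", {
  spec <- cohort_spec(n_otus = 60, seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$otu_table$counts, c2$otu_table$counts)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))
  expect_identical(c1$cytokines, c2$cytokines)
  expect_identical(c1$air_sources, c2$air_sources)

  expect_error(cohort_spec(shared_weight_inside = 1.2), "shared_weight_inside")
  expect_error(cohort_spec(ar1_phi = 1), "ar1_phi")
  expect_error(cohort_spec(depth_mean = 0), "depth_mean")
  expect_error(cohort_spec(n_timepoints_per_phase = c(3, 3)),
               "n_timepoints_per_phase")
})

test_that("every OTU is a tree leaf and every sample has metadata", {
  co <- small_cohort()
  expect_setequal(rownames(co$otu_table$counts), co$tree$tip.label)
  expect_setequal(colnames(co$otu_table$counts),
                  co$otu_table$metadata$sample_id)
  expect_setequal(rownames(co$otu_table$counts), co$taxonomy$otu_id)
  tpp <- co$spec$n_timepoints_per_phase
  expect_equal(ncol(co$otu_table$counts), co$spec$n_subjects * sum(tpp))
  expect_equal(unname(table(co$otu_table$metadata$phase)[2]),
               co$spec$n_subjects * tpp[2])
})

test_that("shared-environment weight draws inside-phase samples together", {
  mean_inside_jsd <- function(w) {
    co <- generate_cohort(cohort_spec(shared_weight_inside = w, seed = 0))
    fr <- t(co$otu_table$counts) / colSums(co$otu_table$counts)
    meta <- co$otu_table$metadata
    inside <- meta$sample_id[meta$environment == "inside"]
    pairs <- utils::combn(inside, 2)
    keep <- meta$subject[match(pairs[1, ], meta$sample_id)] !=
      meta$subject[match(pairs[2, ], meta$sample_id)]
    mean(apply(pairs[, keep], 2, function(ij) jsd(fr[ij[1], ], fr[ij[2], ])))
  }
  js <- vapply(c(0, 0.25, 0.5, 0.75), mean_inside_jsd, numeric(1))
  expect_true(all(diff(js) < 0))
})

test_that("trend taxa rise on the composition scale", {
  co <- generate_cohort(cohort_spec(
    n_otus = 80, seed = 3, shared_weight_inside = 0, noise_sd = 0.05,
    ar1_phi = 0, trend_taxa = data.frame(otu = "OTU0001", slope = 0.01)))
  fr <- fractional_normalize(co$otu_table, "A")
  mk <- mann_kendall(fr[, "OTU0001"])
  expect_equal(mk$direction, "increasing")
})

test_that("random trees have the right shape and are seed-stable", {
  tr <- generate_tree(2, seed = 5)
  expect_equal(length(tr$tip.label), 2)
  expect_true(all(tr$edge.length > 0))
  tr200 <- generate_tree(200, seed = 5)
  expect_equal(length(tr200$tip.label), 200)
  expect_equal(tr200$Nnode, 199)
  expect_identical(ape::write.tree(generate_tree(50, seed = 9)),
                   ape::write.tree(generate_tree(50, seed = 9)))
  expect_error(generate_tree(1), "n_otus")
})

test_that("air/sink fixture stores truth and validates proportions", {
  g <- generate_air_and_sink(c(0.4, 0.3, 0.1), 0.2, depth = 20000, seed = 4)
  expect_equal(unname(g$truth), c(0.4, 0.3, 0.1, 0.2))
  expect_equal(sum(g$sink), 20000)
  expect_equal(ncol(g$sources), 3)
  expect_error(generate_air_and_sink(c(0.5, 0.2), 0.2, seed = 1),
               "sum to 1|must equal 1")

  # single-source sink matches that source up to multinomial noise
  g1 <- generate_air_and_sink(c(1, 0, 0), 0, depth = 50000, seed = 6)
  sink_fr <- g1$sink / sum(g1$sink)
  expect_lt(max(abs(sink_fr - g1$source_compositions[, 1])), 0.02)
})

test_that("noise-free cytokine links give perfect rank correlation", {
  links <- data.frame(cytokine = c("TNF-a", "IL-10"),
                      genus = c("Rothia", "Prevotella"),
                      sign = c(1, -1), noise_sd = 0)
  co <- generate_cohort(cohort_spec(seed = 2, cytokine_links = links))
  genus <- aggregate_to_rank(co$otu_table, co$taxonomy, "genus")
  fr <- t(genus$counts) / colSums(genus$counts)
  meta <- co$otu_table$metadata
  for (s in unique(meta$subject)) {
    ids <- meta$sample_id[meta$subject == s]
    expect_equal(cor(fr[ids, "Rothia"], co$cytokines[["TNF-a"]][
      match(ids, co$cytokines$sample_id)], method = "spearman"), 1)
    expect_equal(cor(fr[ids, "Prevotella"], co$cytokines[["IL-10"]][
      match(ids, co$cytokines$sample_id)], method = "spearman"), -1)
  }
  expect_error(
    generate_cohort(cohort_spec(seed = 2, cytokine_links = data.frame(
      cytokine = "IL-6", genus = "NoSuchGenus", sign = 1, noise_sd = 0))),
    "unknown genus")
})

test_that("cohort artifacts write as text and round-trip", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_otu_table(paths["otu_table"], paths["metadata"])
  expect_identical(back$counts, co$otu_table$counts)
  tr <- read_tree(paths["tree"])
  expect_setequal(tr$tip.label, co$tree$tip.label)
  tax <- read_taxonomy(paths["taxonomy"])
  expect_identical(tax$genus[match(co$taxonomy$otu_id, tax$otu_id)],
                   co$taxonomy$genus)
  cy <- read_cytokines(paths["cytokines"])
  expect_equal(cy[["IL-6"]], co$cytokines[["IL-6"]])
})
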