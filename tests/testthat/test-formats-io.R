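test_that("OTU table round-trips through TSV unchanged", {
  tab <- tiny_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f, metadata_path = m)
  back <- read_otu_table(f, m)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$metadata$subject, tab$metadata$subject)
  expect_identical(back$metadata$time_point, tab$metadata$time_point)
})

test_that("count parsing errors name the offending cell", {
  meta <- tiny_metadata(c("s1", "s2"), c("A", "A"), 1:2)
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, m)
  writeLines(c("#OTU ID\ts1\ts2", "OTU1\t3\t-1", "OTU2\t1\t2"), f)
  expect_error(read_otu_table(f, m), "negative count.*OTU1.*s2")
  writeLines(c("#OTU ID\ts1\ts2", "OTU1\t3\tx", "OTU2\t1\t2"), f)
  expect_error(read_otu_table(f, m), "non-numeric.*OTU1.*s2")
})

test_that("samples missing from metadata are rejected by name", {
  counts <- matrix(1:4, 2, dimnames = list(c("o1", "o2"), c("s1", "s2")))
  meta <- tiny_metadata("s1", "A", 1L)
  expect_error(otu_table(counts, meta), "missing from metadata.*s2")
})

test_that("gzip-compressed tables are read transparently", {
  tab <- tiny_table()
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  m <- withr::local_tempfile(fileext = ".tsv")
  con <- gzfile(f, "wt")
  writeLines(c(paste(c("#OTU ID", colnames(tab$counts)), collapse = "\t"),
               paste(rownames(tab$counts),
                     apply(tab$counts, 1, paste, collapse = "\t"),
                     sep = "\t")), con)
  close(con)
  write_metadata(tab$metadata, m)
  expect_identical(read_otu_table(f, m)$counts, tab$counts)
})

test_that("newick reading validates structure and sums path lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", f)
  tr <- read_tree(f)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(sort(tr$edge.length), c(1, 1))

  writeLines("(A:1,(B:0.5,C:0.5):0.5):0;", f)
  tr <- read_tree(f)
  expect_equal(length(tr$tip.label), 3)
  # leaf-to-root path of B: 0.5 + 0.5
  b <- which(tr$tip.label == "B")
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[b], 1.0)

  writeLines("((A,B", f)
  expect_error(read_tree(f), "parse error")
})

test_that("missing branch lengths default to zero with a warning", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", f)
  expect_warning(tr <- read_tree(f), "branch lengths")
  expect_true(all(tr$edge.length == 0))
})

test_that("taxonomy lineages parse ranks and fail loudly on unknown ids", {
  tax <- microstasis:::parse_taxonomy(
    c("o1", "o2"),
    c("k__Bacteria;p__Firmicutes;c__;o__;f__;g__Streptococcus",
      "k__Bacteria;p__Proteobacteria;c__;o__;f__;g__"))
  expect_equal(taxon_at_rank(tax, "o1", "genus"), "Streptococcus")
  expect_true(is.na(taxon_at_rank(tax, "o2", "genus")))
  expect_equal(taxon_at_rank(tax, c("o2", "o1"), "phylum"),
               c("Proteobacteria", "Firmicutes"))
  expect_error(taxon_at_rank(tax, "o3", "genus"), "unknown OTU")
})

test_that("rank aggregation sums clade members and conserves column totals", {
  tab <- tiny_table()
  tax <- microstasis:::parse_taxonomy(
    rownames(tab$counts),
    c("k__B;p__P1;c__;o__;f__;g__G1",
      "k__B;p__P1;c__;o__;f__;g__G1",
      "k__B;p__P2;c__;o__;f__;g__"))
  agg <- aggregate_to_rank(tab, tax, "genus")
  expect_equal(agg$counts["G1", "A_t1"],
               sum(tab$counts[c("OTU1", "OTU2"), "A_t1"]))
  expect_true("unclassified" %in% rownames(agg$counts))
  expect_equal(colSums(agg$counts), colSums(tab$counts))
  phy <- aggregate_to_rank(tab, tax, "phylum")
  expect_equal(colSums(phy$counts), colSums(tab$counts))
  expect_error(aggregate_to_rank(tab, tax, "species"))
})

test_that("cytokine tables reject negative concentrations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tIL-6", "s1\t-0.5"), f)
  expect_error(read_cytokines(f), "negative")
  writeLines(c("sample_id\tIL-6", "s1\t0.5"), f)
  expect_equal(read_cytokines(f)[["IL-6"]], 0.5)
})
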