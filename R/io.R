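#' OTU count table with sample metadata
#'
#' Constructs the pipeline's root container: an integer count matrix (OTUs as
#' rows, samples as columns) tied to a per-sample metadata table. All
#' downstream stages (normalization, trend tests, diversity, source tracking,
#' networks) consume this object.
#'
#' @param counts numeric matrix of nonnegative integer counts, OTUs x samples,
#'   with unique rownames (OTU ids) and colnames (sample ids).
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `subject`, `time_point`, `phase`, `environment`, `gender`.
#' @return an object of class `otu_table`: a list with elements `counts` and
#'   `metadata` (rownames = sample ids, ordered as the count columns).
#' @export
otu_table <- function(counts, metadata) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs OTU rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative or missing count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (any(colSums(counts) <= 0)) {
    stop("samples with zero total count: ",
         paste(colnames(counts)[colSums(counts) <= 0], collapse = ", "),
         call. = FALSE)
  }
  meta <- as.data.frame(metadata)
  required <- c("sample_id", "subject", "time_point", "phase",
                "environment", "gender")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  orphans <- setdiff(colnames(counts), meta$sample_id)
  if (length(orphans)) {
    stop("samples in counts missing from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$sample_id), required]
  rownames(meta) <- meta$sample_id
  structure(list(counts = counts, metadata = meta), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %d subjects\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$subject))))
  invisible(x)
}

# open a path as a text connection, transparently handling gzip
open_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an OTU count table and its metadata
#'
#' Reads the classic tab-separated dialect: first column `#OTU ID`, one column
#' per sample. Leading comment lines (`#` not followed by `OTU ID`) are
#' skipped. Gzip-compressed input is accepted.
#'
#' @param path OTU table TSV (optionally .gz).
#' @param metadata_path metadata TSV with columns `sample_id`, `subject`,
#'   `time_point`, `phase`, `environment`, `gender`.
#' @return validated [otu_table()].
#' @export
read_otu_table <- function(path, metadata_path) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  header_i <- grep("^#OTU ID\t", lines)[1]
  if (is.na(header_i)) stop("no '#OTU ID' header row in ", path, call. = FALSE)
  lines <- lines[header_i:length(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  otu_ids <- vapply(body, `[[`, character(1), 1L)
  counts <- matrix(NA_real_, length(otu_ids), length(sample_ids),
                   dimnames = list(otu_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(header)) {
      stop(sprintf("row for OTU '%s' has %d fields, expected %d",
                   otu_ids[i], length(row), length(header)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("non-numeric count at OTU '%s', sample '%s': '%s'",
                   otu_ids[i], sample_ids[j], row[j + 1L]), call. = FALSE)
    }
    if (any(vals < 0)) {
      j <- which(vals < 0)[1]
      stop(sprintf("negative count at OTU '%s', sample '%s'",
                   otu_ids[i], sample_ids[j]), call. = FALSE)
    }
    counts[i, ] <- vals
  }
  if (all(counts == round(counts)) && max(counts) < .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  }
  otu_table(counts, read_metadata(metadata_path))
}

#' Write an OTU table (and optionally its metadata) to TSV
#'
#' @param x an [otu_table()].
#' @param path output TSV path for the counts.
#' @param metadata_path optional output path for the metadata TSV.
#' @param comment optional comment lines written (prefixed `# `) above the
#'   header, e.g. a seed/config stamp.
#' @export
write_otu_table <- function(x, path, metadata_path = NULL, comment = NULL) {
  stopifnot(inherits(x, "otu_table"))
  header <- paste(c("#OTU ID", colnames(x$counts)), collapse = "\t")
  rows <- paste(rownames(x$counts),
                apply(x$counts, 1, paste, collapse = "\t"), sep = "\t")
  pre <- if (length(comment)) paste0("# ", comment) else character()
  writeLines(c(pre, header, rows), path)
  if (!is.null(metadata_path)) write_metadata(x$metadata, metadata_path)
  invisible(path)
}

#' Read a sample metadata table
#' @param path TSV with columns `sample_id`, `subject`, `time_point`,
#'   `phase`, `environment`, `gender`. Gzip accepted.
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  meta <- utils::read.delim(con, stringsAsFactors = FALSE, comment.char = "")
  meta$time_point <- as.integer(meta$time_point)
  meta$phase <- as.integer(meta$phase)
  meta
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxonomy map
#'
#' Lineages use the Silva/Greengenes convention
#' `k__...;p__...;c__...;o__...;f__...;g__...`. Unknown ranks may be empty
#' (`g__`). Lookups on the returned object fail loudly for unknown OTU ids
#' via [taxon_at_rank()].
#'
#' @param path two-column TSV `otu_id`, `lineage`. Gzip accepted.
#' @return data.frame with columns `otu_id`, `lineage`, and one column per
#'   rank `kingdom` ... `genus`, class `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, stringsAsFactors = FALSE)
  parse_taxonomy(tab$otu_id, tab$lineage)
}

rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__")

parse_taxonomy <- function(otu_id, lineage) {
  stopifnot(length(otu_id) == length(lineage))
  parts <- strsplit(lineage, ";", fixed = TRUE)
  if (any(lengths(parts) > 7)) {
    stop("lineage with more than 7 ranks for: ",
         otu_id[which(lengths(parts) > 7)[1]], call. = FALSE)
  }
  out <- data.frame(otu_id = otu_id, lineage = lineage,
                    stringsAsFactors = FALSE)
  for (rk in names(rank_prefixes)) {
    pre <- rank_prefixes[[rk]]
    out[[rk]] <- vapply(parts, function(p) {
      hit <- trimws(p[startsWith(trimws(p), pre)])
      if (length(hit) == 0) return(NA_character_)
      val <- sub(pre, "", hit[1], fixed = TRUE)
      if (nzchar(val)) val else NA_character_
    }, character(1))
  }
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' @rdname read_taxonomy
#' @param taxonomy a `taxonomy_map`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("otu_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the taxon label of OTUs at a rank
#' @param taxonomy a `taxonomy_map`.
#' @param otu_ids character vector; every id must be present in the map.
#' @param rank one of `phylum`, `class`, `order`, `family`, `genus`.
#' @return character vector of labels, `NA` where the rank is unassigned.
#' @export
taxon_at_rank <- function(taxonomy, otu_ids, rank) {
  rank <- match.arg(rank, names(rank_prefixes))
  idx <- match(otu_ids, taxonomy$otu_id)
  if (anyNA(idx)) {
    stop("unknown OTU ids in taxonomy lookup: ",
         paste(otu_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  taxonomy[[rank]][idx]
}

#' Read a rooted phylogenetic tree from newick
#'
#' Wraps [ape::read.tree()]; validates rootedness and unique leaf labels.
#' Missing branch lengths default to 0 with a warning so the omission is
#' visible without discarding topology.
#'
#' @param path newick file (gzip accepted).
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  con <- open_input(path)
  txt <- paste(readLines(con), collapse = "")
  close(con)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("newick parse error in ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length))) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Read / write a cytokine concentration table
#' @param path TSV with `sample_id` then one column per cytokine
#'   (nonnegative assay concentrations). Gzip accepted.
#' @return data.frame, one row per sample.
#' @export
read_cytokines <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative cytokine concentration in ", path, call. = FALSE)
  }
  tab
}

#' @rdname read_cytokines
#' @param cytokines cytokine data.frame.
#' @export
write_cytokines <- function(cytokines, path) {
  utils::write.table(cytokines, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts over OTUs sharing the same label at `rank`; OTUs without a
#' label at that rank are pooled into an `unclassified` row. Per-sample column
#' sums are conserved exactly.
#'
#' @param table an [otu_table()].
#' @param taxonomy a `taxonomy_map` covering every OTU in `table`.
#' @param rank one of `phylum`, `class`, `order`, `family`, `genus`.
#' @return an [otu_table()] whose rows are taxa at `rank`.
#' @export
aggregate_to_rank <- function(table, taxonomy, rank) {
  stopifnot(inherits(table, "otu_table"))
  labels <- taxon_at_rank(taxonomy, rownames(table$counts), rank)
  labels[is.na(labels)] <- "unclassified"
  agg <- rowsum(table$counts, group = labels)
  otu_table(agg, table$metadata)
}
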