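#' Specification of a synthetic longitudinal cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults emulate the study design the pipeline targets: 4 subjects (two
#' male, two female) sampled across three phases — outside, inside a shared
#' closed habitat, outside again — with subject-specific baseline
#' communities, a common-environment component whose weight rises inside the
#' habitat, heavy-tailed microbiome-like abundance profiles, and log-normal
#' sequencing depths.
#'
#' @param n_subjects number of subjects (default 4).
#' @param n_timepoints_per_phase integer vector of three counts
#'   (outside / inside / outside), default c(4, 10, 4).
#' @param n_otus number of OTUs (default 200).
#' @param depth_mean mean sequencing depth in reads per sample
#'   (default 30000).
#' @param depth_cv coefficient of variation of depth (default 0.3).
#' @param shared_weight_inside mixing weight in \[0, 1\] of the common
#'   community for inside-phase samples (default 0.3); outside-phase samples
#'   have weight 0.
#' @param trend_taxa optional data.frame with columns `otu` and `slope`
#'   (relative-abundance units per time step) of taxa given linear trends.
#' @param ar1_phi lag-1 autocorrelation of the log-abundance residuals,
#'   |phi| < 1 (default 0.2).
#' @param noise_sd marginal SD of the log-abundance residuals (default 0.25);
#'   the session-to-session wobble around each subject's base community,
#'   kept below the typical between-subject separation so individuals remain
#'   distinguishable, as they are in real salivary cohorts.
#' @param n_air_sources number of habitat air source communities (default 3).
#' @param air_in_shared fraction in \[0, 1\] of the shared inside-habitat
#'   component that derives from the mean air community (default 0.5):
#'   inside the enclosure, part of what the subjects converge toward is the
#'   recirculated air microbiota, so air-to-saliva source tracking has a
#'   real signal to find.
#' @param cytokine_links optional data.frame with columns `cytokine`,
#'   `genus`, `sign` (+1/-1), `noise_sd` describing monotone genus-cytokine
#'   couplings; cytokines not listed are independent noise.
#' @param cytokine_names assay panel (default the five-cytokine immune
#'   panel IL-1b, IL-6, IL-10, TNF-a, IFN-g).
#' @param seed integer seed; identical specs with identical seeds produce
#'   byte-identical artifacts.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 4,
                        n_timepoints_per_phase = c(4, 10, 4),
                        n_otus = 200,
                        depth_mean = 30000,
                        depth_cv = 0.3,
                        shared_weight_inside = 0.3,
                        trend_taxa = NULL,
                        ar1_phi = 0.2,
                        noise_sd = 0.25,
                        n_air_sources = 3,
                        air_in_shared = 0.5,
                        cytokine_links = NULL,
                        cytokine_names = c("IL-1b", "IL-6", "IL-10",
                                           "TNF-a", "IFN-g"),
                        seed = 1) {
  if (n_subjects < 1) stop_field("n_subjects", "must be >= 1")
  if (length(n_timepoints_per_phase) != 3 ||
      any(n_timepoints_per_phase < 1)) {
    stop_field("n_timepoints_per_phase", "must be three positive counts")
  }
  if (n_otus < 2) stop_field("n_otus", "must be >= 2")
  if (depth_mean <= 0) stop_field("depth_mean", "must be > 0")
  if (depth_cv < 0) stop_field("depth_cv", "must be >= 0")
  if (shared_weight_inside < 0 || shared_weight_inside > 1) {
    stop_field("shared_weight_inside", "must lie in [0, 1]")
  }
  if (abs(ar1_phi) >= 1) stop_field("ar1_phi", "must satisfy |phi| < 1")
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (n_air_sources < 0) stop_field("n_air_sources", "must be >= 0")
  if (air_in_shared < 0 || air_in_shared > 1) {
    stop_field("air_in_shared", "must lie in [0, 1]")
  }
  if (!is.null(trend_taxa)) {
    if (!all(c("otu", "slope") %in% names(trend_taxa))) {
      stop_field("trend_taxa", "needs columns `otu` and `slope`")
    }
  }
  if (!is.null(cytokine_links)) {
    need <- c("cytokine", "genus", "sign", "noise_sd")
    if (!all(need %in% names(cytokine_links))) {
      stop_field("cytokine_links",
                 "needs columns cytokine, genus, sign, noise_sd")
    }
    if (!all(cytokine_links$sign %in% c(-1, 1))) {
      stop_field("cytokine_links", "sign must be +1 or -1")
    }
  }
  structure(list(n_subjects = n_subjects,
                 n_timepoints_per_phase = as.integer(n_timepoints_per_phase),
                 n_otus = as.integer(n_otus),
                 depth_mean = depth_mean,
                 depth_cv = depth_cv,
                 shared_weight_inside = shared_weight_inside,
                 trend_taxa = trend_taxa,
                 ar1_phi = ar1_phi,
                 noise_sd = noise_sd,
                 n_air_sources = as.integer(n_air_sources),
                 air_in_shared = air_in_shared,
                 cytokine_links = cytokine_links,
                 cytokine_names = cytokine_names,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

otu_ids_for <- function(n) sprintf("OTU%04d", seq_len(n))

#' Generate a random rooted binary tree over synthetic OTUs
#'
#' Wraps [ape::rtree()] (rooted, binary, uniform branch lengths in (0, 1\]),
#' relabelling tips to the cohort's OTU ids. Stands in for a reference
#' phylogeny so UniFrac-based analyses are exercised end to end.
#'
#' @param n_otus number of leaves (>= 2).
#' @param seed integer seed; same seed gives an identical newick string.
#' @return rooted [ape::phylo] with `n_otus` leaves and positive branch
#'   lengths.
#' @export
generate_tree <- function(n_otus, seed = 1) {
  if (n_otus < 2) stop_field("n_otus", "must be >= 2")
  with_seed(seed, {
    tree <- ape::rtree(n_otus, rooted = TRUE,
                       br = function(n) stats::runif(n, 0.05, 1))
    # rtree labels tips in random order; rebind to canonical ids in tip order
    tree$tip.label <- otu_ids_for(n_otus)[order(as.integer(
      sub("t", "", tree$tip.label)))]
    tree
  })
}

# six dominant oral phyla and common salivary genera give the synthetic
# taxonomy a realistic vocabulary; extra clades get generic labels
synthetic_phyla <- c("Actinobacteria", "Bacteroidetes", "Firmicutes",
                     "Fusobacteria", "Proteobacteria", "Spirochaetes")
synthetic_genera <- c("Rothia", "Actinomyces", "Prevotella", "Porphyromonas",
                      "Streptococcus", "Veillonella", "Gemella",
                      "Fusobacterium", "Leptotrichia", "Neisseria",
                      "Haemophilus", "Treponema")

# contiguous blocks of tree leaves form genera; blocks of genera form phyla,
# so genus-level aggregation sums coherent clades
synthetic_taxonomy <- function(tree, genus_size = 8) {
  # tips in order of appearance along the cladewise edge list, so a block of
  # consecutive tips is a contiguous stretch of the tree
  tip_order <- tree$edge[tree$edge[, 2] <= length(tree$tip.label), 2]
  tips <- tree$tip.label[tip_order]
  n <- length(tips)
  n_gen <- max(1L, ceiling(n / genus_size))
  genus_idx <- rep(seq_len(n_gen), each = genus_size, length.out = n)
  gnames <- c(synthetic_genera,
              sprintf("Genus%02d", seq_len(max(0, n_gen - length(synthetic_genera)))))
  gnames <- gnames[seq_len(n_gen)]
  phy_of_gen <- rep(seq_along(synthetic_phyla), length.out = n_gen)
  lineage <- sprintf("k__Bacteria;p__%s;c__;o__;f__;g__%s",
                     synthetic_phyla[phy_of_gen[genus_idx]],
                     gnames[genus_idx])
  parse_taxonomy(tips, lineage)[match(sort(tips), tips), ]
}

#' Generate a seeded synthetic cohort
#'
#' Produces the full artifact set the pipeline consumes: OTU counts with
#' metadata, a rooted tree, a taxonomy map, habitat air source communities
#' and a cytokine panel, plus a truth record sufficient to score recovery.
#'
#' For subject s at time t the expected composition is
#' `(1 - w_t) * base_s + w_t * shared`, with `w_t = shared_weight_inside`
#' for inside-phase samples and 0 otherwise. Optional per-taxon linear trends
#' are added on the composition scale and renormalized; an AR(1) process on
#' log-abundance residuals adds stationary session-to-session variation;
#' counts are drawn multinomially at a log-normal depth.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `otu_table`,
#'   `tree`, `taxonomy`, `cytokines`, `air_sources` (taxa x sources count
#'   matrix), `truth` (generating parameters), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n_otus <- spec$n_otus
    otus <- otu_ids_for(n_otus)
    tree <- ape::rtree(n_otus, rooted = TRUE,
                       br = function(n) stats::runif(n, 0.05, 1))
    tree$tip.label <- otus[order(as.integer(sub("t", "", tree$tip.label)))]
    taxonomy <- synthetic_taxonomy(tree)

    # hierarchical heavy-tailed concentration profile: genus-level weights
    # (log-normal, sd 1.5) spread over member OTUs (log-normal, sd 1), so a
    # handful of genera dominate the community the way Streptococcus,
    # Prevotella, Neisseria and Rothia dominate saliva
    genus_of <- taxonomy$genus[match(otus, taxonomy$otu_id)]
    genus_levels <- unique(genus_of)
    genus_w <- exp(stats::rnorm(length(genus_levels), 0, 1.5))
    conc <- genus_w[match(genus_of, genus_levels)] *
      exp(stats::rnorm(n_otus, 0, 1))
    base <- t(vapply(seq_len(spec$n_subjects),
                     function(s) rdirichlet(conc), numeric(n_otus)))
    shared <- rdirichlet(conc)

    # habitat air: a common backbone with stage-specific variation; part of
    # the shared inside-habitat component derives from the mean air profile
    air_comps <- NULL
    if (spec$n_air_sources > 0) {
      air_common <- stats::rnorm(n_otus, 0, 1.5)
      air_comps <- vapply(seq_len(spec$n_air_sources), function(k) {
        own <- stats::rnorm(n_otus, 0, 1.5)
        rdirichlet(exp(0.5 * air_common + sqrt(0.75) * own) * 2)
      }, numeric(n_otus))
      shared <- (1 - spec$air_in_shared) * shared +
        spec$air_in_shared * rowMeans(air_comps)
    }

    tpp <- spec$n_timepoints_per_phase
    n_t <- sum(tpp)
    phase <- rep(1:3, times = tpp)
    env <- ifelse(phase == 2, "inside", "outside")
    w <- ifelse(phase == 2, spec$shared_weight_inside, 0)
    subjects <- LETTERS[seq_len(spec$n_subjects)]
    gender <- rep(c("M", "M", "F", "F"), length.out = spec$n_subjects)

    sdlog <- sqrt(log(1 + spec$depth_cv^2))
    meanlog <- log(spec$depth_mean) - sdlog^2 / 2
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1_phi^2)

    counts <- matrix(0L, n_otus, spec$n_subjects * n_t,
                     dimnames = list(otus, character(spec$n_subjects * n_t)))
    meta <- vector("list", spec$n_subjects)
    col <- 0
    for (s in seq_len(spec$n_subjects)) {
      eps <- matrix(0, n_t, n_otus)
      eps[1, ] <- stats::rnorm(n_otus, 0, spec$noise_sd)
      if (n_t > 1) {
        for (t in 2:n_t) {
          eps[t, ] <- spec$ar1_phi * eps[t - 1, ] +
            stats::rnorm(n_otus, 0, innov_sd)
        }
      }
      for (t in seq_len(n_t)) {
        comp <- (1 - w[t]) * base[s, ] + w[t] * shared
        if (!is.null(spec$trend_taxa)) {
          idx <- match(spec$trend_taxa$otu, otus)
          if (anyNA(idx)) {
            stop_field("trend_taxa", paste("unknown OTU:",
                       spec$trend_taxa$otu[is.na(idx)][1]))
          }
          comp[idx] <- pmax(comp[idx] + spec$trend_taxa$slope * (t - 1), 0)
        }
        comp <- comp * exp(eps[t, ])
        comp <- comp / sum(comp)
        depth <- max(100L, round(stats::rlnorm(1, meanlog, sdlog)))
        col <- col + 1
        counts[, col] <- stats::rmultinom(1, depth, comp)
        colnames(counts)[col] <- sprintf("%s_t%02d", subjects[s], t)
      }
      meta[[s]] <- data.frame(
        sample_id = sprintf("%s_t%02d", subjects[s], seq_len(n_t)),
        subject = subjects[s], time_point = seq_len(n_t), phase = phase,
        environment = env, gender = gender[s], stringsAsFactors = FALSE)
    }
    metadata <- do.call(rbind, meta)
    table <- otu_table(counts, metadata)

    air <- NULL
    if (spec$n_air_sources > 0) {
      air <- vapply(seq_len(spec$n_air_sources), function(k) {
        depth <- max(100L, round(stats::rlnorm(1, meanlog, sdlog)))
        as.numeric(stats::rmultinom(1, depth, air_comps[, k]))
      }, numeric(n_otus))
      dimnames(air) <- list(otus, paste0("Air", seq_len(spec$n_air_sources)))
    }

    cohort <- structure(list(otu_table = table, tree = tree,
                             taxonomy = taxonomy, cytokines = NULL,
                             air_sources = air,
                             truth = list(
                               shared_weight = w,
                               shared_community = shared,
                               base_communities = base,
                               air_compositions = air_comps,
                               air_in_shared = spec$air_in_shared,
                               trend_taxa = spec$trend_taxa,
                               cytokine_links = spec$cytokine_links),
                             spec = spec),
                        class = "synthetic_cohort")
    cohort$cytokines <- generate_cytokines(cohort, spec$cytokine_links,
                                           seed = spec$seed + 1,
                                           cytokine_names = spec$cytokine_names)
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d OTUs x %d samples, %d air sources, seed %d\n",
    nrow(x$otu_table$counts), ncol(x$otu_table$counts),
    if (is.null(x$air_sources)) 0 else ncol(x$air_sources), x$spec$seed))
  invisible(x)
}

#' Generate air source communities and a mixed sink
#'
#' Standalone sources-and-sinks fixture for the source-tracking module. The
#' source communities share a common habitat backbone with stage-specific
#' variation (air sampled from one habitat at different times: related but
#' clearly distinct); the novel "unknown" community has its own independent
#' heavy-tailed profile, as it stands for an environment no source was
#' sampled from. The sink is drawn multinomially from
#' `sum_k mix_k * source_k + unknown_frac * novel`; the truth proportions
#' are stored for recovery scoring.
#'
#' @param mix nonnegative source proportions.
#' @param unknown_frac proportion from the novel community;
#'   `sum(mix) + unknown_frac` must equal 1 (tolerance 1e-9).
#' @param depth sink sequencing depth (reads).
#' @param n_taxa community size (default 200).
#' @param source_depth depth of the observed source counts (default `depth`).
#' @param seed integer seed.
#' @return list with `sources` (taxa x sources count matrix), `sink` (count
#'   vector), `truth` (named proportions incl. `unknown`),
#'   `source_compositions`, `unknown_composition`.
#' @export
generate_air_and_sink <- function(mix, unknown_frac, depth = 50000,
                                  n_taxa = 200, source_depth = depth,
                                  seed = 1) {
  if (any(mix < 0) || unknown_frac < 0) {
    stop_field("mix", "proportions must be nonnegative")
  }
  if (abs(sum(mix) + unknown_frac - 1) > 1e-9) {
    stop_field("mix", "sum(mix) + unknown_frac must equal 1")
  }
  with_seed(seed, {
    k <- length(mix)
    common <- stats::rnorm(n_taxa, 0, 1.5)
    comps <- vapply(seq_len(k), function(i) {
      own <- stats::rnorm(n_taxa, 0, 1.5)
      rdirichlet(exp(0.5 * common + sqrt(0.75) * own) * 2)
    }, numeric(n_taxa))
    novel <- rdirichlet(exp(stats::rnorm(n_taxa, 0, 1.5)) * 2)
    sink_comp <- drop(comps %*% mix) + unknown_frac * novel
    sources <- vapply(seq_len(k), function(i) {
      as.numeric(stats::rmultinom(1, source_depth, comps[, i]))
    }, numeric(n_taxa))
    taxa <- otu_ids_for(n_taxa)
    dimnames(sources) <- list(taxa, paste0("Air", seq_len(k)))
    sink <- as.numeric(stats::rmultinom(1, depth, sink_comp))
    names(sink) <- taxa
    list(sources = sources, sink = sink,
         truth = stats::setNames(c(mix, unknown_frac),
                                 c(colnames(sources), "unknown")),
         source_compositions = comps, unknown_composition = novel)
  })
}

#' Generate a cytokine panel linked to genus abundances
#'
#' Each linked cytokine is a strictly monotone function of its genus'
#' relative abundance within each subject (exponentiated subject-wise
#' standardized abundance, so concentrations stay positive) with Gaussian
#' noise of the stated SD added on the latent scale; `sign = -1` links are
#' monotone decreasing. Standardization is per subject because the
#' co-occurrence analyses are per subject: the stated noise SD is then
#' relative to a unit-SD signal in every subject's own series. Cytokines
#' without a link are iid log-normal noise.
#'
#' @param cohort a `synthetic_cohort` (with `otu_table` and `taxonomy`).
#' @param links data.frame with columns `cytokine`, `genus`, `sign`,
#'   `noise_sd` (noise SD on the latent scale, where the signal has SD 1),
#'   or NULL for an all-noise panel.
#' @param seed integer seed.
#' @param cytokine_names panel column names.
#' @return data.frame: `sample_id` plus one nonnegative column per cytokine.
#' @export
generate_cytokines <- function(cohort, links = NULL, seed = 1,
                               cytokine_names = c("IL-1b", "IL-6", "IL-10",
                                                  "TNF-a", "IFN-g")) {
  table <- cohort$otu_table
  taxonomy <- cohort$taxonomy
  if (!is.null(links)) {
    unknown <- setdiff(links$genus, taxonomy$genus)
    if (length(unknown)) {
      stop("unknown genus id(s) in cytokine links: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cytokine_names <- union(cytokine_names, links$cytokine)
  }
  genus_tab <- aggregate_to_rank(table, taxonomy, "genus")
  fr <- t(genus_tab$counts) / colSums(genus_tab$counts)
  ids <- table$metadata$sample_id
  with_seed(seed, {
    out <- data.frame(sample_id = ids, stringsAsFactors = FALSE,
                      check.names = FALSE)
    for (cy in cytokine_names) {
      link <- if (!is.null(links)) links[links$cytokine == cy, ] else NULL
      if (!is.null(link) && nrow(link)) {
        g <- fr[ids, link$genus[1]]
        subj <- table$metadata$subject[match(ids, table$metadata$sample_id)]
        z <- stats::ave(g, subj, FUN = function(v) {
          if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
        })
        latent <- link$sign[1] * z +
          stats::rnorm(length(z), 0, link$noise_sd[1])
      } else {
        latent <- stats::rnorm(length(ids), 0, 1)
      }
      out[[cy]] <- exp(latent) # positive assay-scale concentration
    }
    out
  })
}

#' Merge air source samples into the cohort's OTU table
#'
#' Returns one [otu_table()] holding both saliva and air samples (air samples
#' get subject `"Air"`, phase 2, environment `"inside"`), the layout the
#' source-tracking stage consumes.
#'
#' @param cohort a `synthetic_cohort` with air sources.
#' @return an [otu_table()].
#' @export
cohort_with_air <- function(cohort) {
  if (is.null(cohort$air_sources)) stop("cohort has no air sources",
                                        call. = FALSE)
  air <- cohort$air_sources
  counts <- cbind(cohort$otu_table$counts, air)
  meta <- rbind(cohort$otu_table$metadata,
                data.frame(sample_id = colnames(air), subject = "Air",
                           time_point = seq_len(ncol(air)), phase = 2L,
                           environment = "inside", gender = "NA",
                           stringsAsFactors = FALSE))
  otu_table(counts, meta)
}

#' Write every cohort artifact to a directory
#'
#' Writes the OTU table, metadata, taxonomy, newick tree, cytokine table,
#' air source counts and a key-value truth record as plain text files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param comment optional comment stamp for the OTU table header.
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir, comment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu_table = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             tree = file.path(dir, "tree.nwk"),
             cytokines = file.path(dir, "cytokines.tsv"),
             air = file.path(dir, "air_sources.tsv"),
             truth = file.path(dir, "truth.txt"))
  write_otu_table(cohort$otu_table, paths["otu_table"],
                  metadata_path = paths["metadata"], comment = comment)
  write_taxonomy(cohort$taxonomy, paths["taxonomy"])
  ape::write.tree(cohort$tree, paths["tree"])
  write_cytokines(cohort$cytokines, paths["cytokines"])
  if (!is.null(cohort$air_sources)) {
    air_lines <- c(paste(c("#OTU ID", colnames(cohort$air_sources)),
                         collapse = "\t"),
                   paste(rownames(cohort$air_sources),
                         apply(cohort$air_sources, 1, paste, collapse = "\t"),
                         sep = "\t"))
    writeLines(air_lines, paths["air"])
  }
  truth <- cohort$truth
  kv <- c(sprintf("seed\t%d", cohort$spec$seed),
          sprintf("shared_weight_inside\t%g",
                  cohort$spec$shared_weight_inside),
          sprintf("shared_weight_by_sample\t%s",
                  paste(truth$shared_weight, collapse = ",")),
          if (!is.null(truth$trend_taxa)) {
            sprintf("trend\t%s\t%g", truth$trend_taxa$otu,
                    truth$trend_taxa$slope)
          },
          if (!is.null(truth$cytokine_links)) {
            sprintf("cytokine_link\t%s\t%s\t%d\t%g",
                    truth$cytokine_links$cytokine,
                    truth$cytokine_links$genus,
                    as.integer(truth$cytokine_links$sign),
                    truth$cytokine_links$noise_sd)
          })
  writeLines(kv, paths["truth"])
  invisible(paths)
}
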