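#' Default pipeline configuration
#'
#' Returns the bundled demo configuration: a synthetic cohort mirroring the
#' target study design (4 subjects, three phases, shared habitat component
#' inside, 3 air sources, linked cytokines) followed by every analysis stage.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed single integer driving every stochastic stage.
#' @return nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = "pipeline_out", seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "refnorm", "trends", "diversity", "ordination",
               "sourcetrack", "network"),
    cohort = list(n_subjects = 4, n_timepoints_per_phase = c(4, 10, 4),
                  n_otus = 200, depth_mean = 30000, depth_cv = 0.3,
                  shared_weight_inside = 0.3, ar1_phi = 0.2, noise_sd = 0.25,
                  n_air_sources = 3,
                  cytokine_links = data.frame(
                    cytokine = c("TNF-a", "IL-10", "IL-1b"),
                    genus = c("Rothia", "Prevotella", "Streptococcus"),
                    sign = c(1, -1, 1),
                    noise_sd = c(0.4, 0.4, 0.4),
                    stringsAsFactors = FALSE)),
    refnorm = list(threshold = 0.90),
    trends = list(rank = "phylum", window = NULL),
    diversity = list(normalized = TRUE, alpha_metric = "shannon"),
    ordination = list(n_pcs = 25, group = "subject"),
    network = list(min_abundance = 0.01, min_rho = 0.5)
  )
}

# TSV writer stamping seed + config hash into a leading comment line
write_tsv_stamped <- function(df, path, stamp) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_info <- function(...) message(sprintf("[microstasis] %s", sprintf(...)))

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> reference normalization -> trend/stationarity
#' tests -> weighted UniFrac convergence analysis -> PCA/MANOVA group
#' separation -> air-to-saliva source tracking -> co-occurrence networks.
#' Each stage writes TSV outputs stamped with the seed and a configuration
#' fingerprint; a stage failure aborts the stages downstream of it. Reruns
#' with the same config and seed are bitwise identical.
#'
#' @param config nested list as from [default_pipeline_config()], or a path
#'   to a YAML file with the same structure.
#' @return invisibly, a list with the stage report (data.frame), the cohort,
#'   and per-stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  if (is.data.frame(config$cohort$cytokine_links) == FALSE &&
      !is.null(config$cohort$cytokine_links)) {
    config$cohort$cytokine_links <-
      as.data.frame(config$cohort$cytokine_links, stringsAsFactors = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hashed <- config[setdiff(names(config), "out_dir")] # paths don't alter results
  stamp <- sprintf("seed=%d config=fnv1a:%s", config$seed,
                   fnv1a_hash(paste(deparse(hashed), collapse = "")))
  report <- list()
  results <- list()
  note <- function(stage, status, detail = "") {
    log_info("%s: %s %s", stage, status, detail)
    report[[stage]] <<- data.frame(stage = stage, status = status,
                                   detail = detail, stringsAsFactors = FALSE)
  }
  aborted <- FALSE
  run_stage <- function(stage, fun) {
    if (!(stage %in% config$stages)) {
      note(stage, "skipped", "disabled in config")
      return(invisible(NULL))
    }
    if (aborted) {
      note(stage, "aborted", "upstream stage failed")
      return(invisible(NULL))
    }
    tryCatch(fun(), error = function(e) {
      aborted <<- TRUE
      note(stage, "failed", conditionMessage(e))
    })
  }

  cohort <- NULL
  run_stage("simulate", function() {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    cohort <<- generate_cohort(spec)
    write_cohort(cohort, config$out_dir, comment = stamp)
    note("simulate", "ok",
         sprintf("%d OTUs x %d samples", nrow(cohort$otu_table$counts),
                 ncol(cohort$otu_table$counts)))
  })
  if (is.null(cohort)) {
    rep_df <- do.call(rbind, report)
    write_tsv_stamped(rep_df, file.path(config$out_dir, "report.tsv"), stamp)
    stop("pipeline aborted at stage: simulate", call. = FALSE)
  }
  table <- cohort$otu_table
  subjects <- setdiff(unique(table$metadata$subject), "Air")

  norm <- list()
  run_stage("refnorm", function() {
    for (s in subjects) {
      ns <- normalize_subject(table, s, config$refnorm$threshold)
      norm[[s]] <<- ns
      out <- data.frame(time_point = seq_len(nrow(ns$abundances)),
                        scale_factor = ns$scale_factors,
                        ns$abundances, check.names = FALSE)
      write_tsv_stamped(out, file.path(config$out_dir,
                                       sprintf("normalized_%s.tsv", s)), stamp)
    }
    note("refnorm", "ok", sprintf("%d subjects, threshold %.2f",
                                  length(subjects), config$refnorm$threshold))
  })

  run_stage("trends", function() {
    agg <- aggregate_to_rank(table, cohort$taxonomy, config$trends$rank)
    rows <- list()
    for (s in subjects) {
      fr <- fractional_normalize(agg, s)
      meta_s <- table$metadata[table$metadata$subject == s, ]
      window <- config$trends$window %||%
        which(sort(meta_s$time_point) <= max(meta_s$time_point[meta_s$phase <= 2]))
      tp <- trend_panel(fr, window = window)
      acfs <- lapply(colnames(fr), function(id) {
        if (stats::var(fr[, id]) == 0) return(NULL)
        a <- acf_profile(fr[, id], series_id = id)
        data.frame(series = id, n_significant_lags = a$n_significant_lags,
                   stationary = a$stationary_verdict)
      })
      tp$subject <- s
      tp <- merge(tp, do.call(rbind, acfs), by = "series", all.x = TRUE)
      rows[[s]] <- tp
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$subject, out$series), ]
    write_tsv_stamped(out, file.path(config$out_dir, "trends.tsv"), stamp)
    results$trends <<- out
    note("trends", "ok", sprintf("%d series tested", nrow(out)))
  })

  run_stage("diversity", function() {
    if (is.null(cohort$tree)) {
      note("diversity", "skipped", "no tree available")
      return(invisible(NULL))
    }
    alpha <- alpha_diversity(table, config$diversity$alpha_metric)
    dm <- unifrac_matrix(table, cohort$tree,
                         normalized = config$diversity$normalized)
    bsd <- between_subject_distances(dm, table$metadata, by = "phase")
    kw <- convergence_test(dm, table$metadata, seed = config$seed)
    write_tsv_stamped(data.frame(sample_id = names(alpha), alpha = alpha),
                      file.path(config$out_dir, "alpha.tsv"), stamp)
    write_tsv_stamped(data.frame(sample_id = rownames(dm$d), dm$d,
                                 check.names = FALSE),
                      file.path(config$out_dir, "unifrac.tsv"), stamp)
    write_tsv_stamped(bsd, file.path(config$out_dir,
                                     "between_subject_distances.tsv"), stamp)
    write_tsv_stamped(data.frame(grouping = "phase", H = kw$H, p = kw$p,
                                 n_perm = kw$n_perm,
                                 median_phase1 = kw$medians[[1]],
                                 median_phase2 = kw$medians[[2]],
                                 median_phase3 = kw$medians[[3]]),
                      file.path(config$out_dir, "convergence_kw.tsv"), stamp)
    results$convergence <<- list(kw = kw, distances = bsd)
    note("diversity", "ok",
         sprintf("phase KW H = %.3f, perm p = %.3g", kw$H, kw$p))
  })

  run_stage("ordination", function() {
    fr <- t(table$counts) / colSums(table$counts)
    pca <- pca_profiles(fr)
    labels <- table$metadata[[config$ordination$group]]
    sep <- group_separation(pca$scores, labels,
                            n_pcs = config$ordination$n_pcs)
    write_tsv_stamped(data.frame(sample_id = rownames(pca$scores),
                                 pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                            drop = FALSE]),
                      file.path(config$out_dir, "pca_scores.tsv"), stamp)
    write_tsv_stamped(data.frame(group = rownames(sep$mahalanobis),
                                 sep$mahalanobis, check.names = FALSE),
                      file.path(config$out_dir, "mahalanobis.tsv"), stamp)
    write_tsv_stamped(sep$pairwise,
                      file.path(config$out_dir, "separation_pairwise.tsv"),
                      stamp)
    results$separation <<- sep
    note("ordination", "ok", sprintf("Wilks p = %.3g on %d PCs", sep$p,
                                     sep$n_pcs_used))
  })

  run_stage("sourcetrack", function() {
    if (is.null(cohort$air_sources)) {
      note("sourcetrack", "skipped", "no air sources")
      return(invisible(NULL))
    }
    merged <- cohort_with_air(cohort)
    sinks <- table$metadata$sample_id[table$metadata$environment == "inside"]
    att <- attribute_cohort(merged, colnames(cohort$air_sources), sinks)
    out <- data.frame(sink = rownames(att$proportions), att$proportions,
                      check.names = FALSE)
    write_tsv_stamped(out, file.path(config$out_dir, "attribution.tsv"),
                      stamp)
    results$attribution <<- att
    note("sourcetrack", "ok",
         sprintf("mean air-attributed total = %.3f",
                 1 - att$mean_proportions[["unknown"]]))
  })

  run_stage("network", function() {
    if (is.null(cohort$cytokines)) {
      note("network", "skipped", "no cytokine table")
      return(invisible(NULL))
    }
    nets <- list()
    for (s in subjects) {
      net <- build_network(table, cohort$taxonomy, cohort$cytokines, s,
                           abundance_threshold = config$network$min_abundance,
                           rho_threshold = config$network$min_rho)
      nets[[s]] <- net
      edges <- net$edges
      if (nrow(edges)) edges$subject <- s
      write_tsv_stamped(edges,
                        file.path(config$out_dir,
                                  sprintf("network_%s.tsv", s)), stamp)
    }
    results$networks <<- nets
    note("network", "ok",
         sprintf("edges per subject: %s",
                 paste(vapply(nets, function(n) nrow(n$edges), integer(1)),
                       collapse = "/")))
  })

  rep_df <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  write_tsv_stamped(rep_df, file.path(config$out_dir, "report.tsv"), stamp)
  if (aborted) {
    failed <- rep_df$stage[rep_df$status == "failed"][1]
    stop("pipeline aborted at stage: ", failed, call. = FALSE)
  }
  invisible(list(report = rep_df, cohort = cohort, normalized = norm,
                 results = results, stamp = stamp))
}
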