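# Pipeline orchestration: simulate -> call -> classify -> accessibility ->
# motifs -> genesets -> profiles, with deterministic versioned outputs.

#' Default pipeline configuration
#'
#' @param scenario Scenario configuration for the simulation stage
#'   (default [default_landscape_config()]).
#' @return Nested configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(scenario = default_landscape_config()) {
  list(
    simulate = TRUE,
    scenario = scenario,
    events = list(q_bind = 0.001, q_diff = 0.01, window = 200L, step = 50L,
                  min_category = 500L, top_n = 10000L, merge_radius = 100L),
    accessibility = list(bin = 50L, p_thresh = 1e-3, merge_gap = 200L,
                         min_len = 200L, window = 2000L),
    motifs = list(n_null = 20000L, n_query = 1000L, null_length = 100L,
                  fdr_target = 0.1, within = 50L, n_background = 10000L),
    genesets = list(lfc_thresh = 2, alpha = 0.01, baseline = "progenitor"),
    profiles = list(union_radius = 50L, heatmap_window = 1000L,
                    heatmap_bin = 100L, heatmap_floor = 5,
                    heatmap_percentile = 85),
    outputs = list(write_tag_libraries = FALSE))
}

#' Validate a pipeline configuration
#'
#' Structural validation performed before any computation: required sections
#' must exist, and in file-input mode every referenced tag/genome file must
#' exist.
#'
#' @param config Configuration list or path to a YAML file.
#' @return The validated configuration (invisibly usable).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML file path")
  for (sec in c("events", "accessibility", "motifs"))
    if (is.null(config[[sec]])) stop("config missing section: ", sec)
  if (isTRUE(config$simulate)) {
    if (is.null(config$scenario)) stop("config missing section: scenario")
  } else {
    files <- config$files
    if (is.null(files)) stop("config missing section: files (or simulate: true)")
    if (is.null(files$genome_fasta)) stop("config missing files$genome_fasta")
    req <- c(files$genome_fasta, unlist(files$chip), files$input,
             unlist(files$atac_prior), unlist(files$atac_post))
    missing <- req[!file.exists(req)]
    if (length(missing) > 0L)
      stop("required input file not found: ", missing[1L])
  }
  config
}

# deterministic TSV writer with parameter header comments
.write_tsv <- function(dt, path, params = NULL) {
  con <- file(path, "w")
  if (!is.null(params))
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(x) paste(format(x), collapse = ","),
                             "")), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = !is.null(params),
                     col.names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: `simulate` (or load configured tag files), `events` (per-TF
#' calling), `classify`, `accessibility` (domains, per-category densities,
#' domain-overlap fractions, prior-vs-post change), `motifs` (background
#' training, threshold calibration, per-category hit rates and
#' over-representation), `genesets` (set construction and category
#' association), `profiles` (top-site union, PCA, heatmap bounds).  Every
#' stage writes deterministic TSV/BED outputs plus a machine-readable
#' run log recording seeds and parameters.
#'
#' @param config Configuration list or YAML path (default
#'   [default_pipeline_config()]).
#' @param outdir Output directory (created).
#' @param seed Master seed; stage seeds derive from it.
#' @param stages Character vector of stages to run (default all).
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir,
                         seed = 1L,
                         stages = c("simulate", "events", "classify",
                                    "accessibility", "motifs", "genesets",
                                    "profiles")) {
  config <- validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  log <- list(seed = seed, stages = stages)
  res <- list()

  ## --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    scen <- simulate_scenario(config$scenario, seed = seed)
    g <- scen$genome
    chip <- scen$chip
    input <- scen$input
    atac_prior <- scen$atac_prior
    atac_post <- scen$atac_post
    expr <- scen$expression
    truth <- scen$truth
    .write_tsv(truth$sites, file.path(outdir, "truth_sites.tsv"),
               params = list(seed = seed))
    .write_tsv(truth$domains, file.path(outdir, "truth_domains.tsv"),
               params = list(seed = seed))
    if (isTRUE(config$outputs$write_tag_libraries)) {
      for (tf in names(chip))
        for (i in seq_along(chip[[tf]]))
          write_tags(chip[[tf]][[i]],
                     file.path(outdir, sprintf("tags_%s_rep%d.bed", tf, i)))
    }
  } else {
    f <- config$files
    g <- load_fasta(f$genome_fasta)
    chip <- lapply(f$chip, function(paths)
      lapply(paths, load_tags, genome = g))
    input <- if (!is.null(f$input)) load_tags(f$input, genome = g) else NULL
    atac_prior <- lapply(f$atac_prior, load_tags, genome = g)
    atac_post <- if (!is.null(f$atac_post))
      lapply(f$atac_post, load_tags, genome = g) else NULL
    expr <- NULL
    if (!is.null(f$expression))
      expr <- list(records = data.table::fread(f$expression),
                   genes = data.table::fread(f$gene_models))
    truth <- NULL
  }
  res$genome <- g
  tf_names <- names(chip)

  ecfg <- do.call(event_config, config$events[
    intersect(names(config$events), names(formals(event_config)))])

  ## --- events -------------------------------------------------------------
  events <- NULL
  if ("events" %in% stages || "classify" %in% stages ||
      "profiles" %in% stages) {
    events <- lapply(chip, function(libs) call_events(libs, input, g, ecfg))
    names(events) <- tf_names
    for (tf in tf_names) {
      .write_tsv(events[[tf]], file.path(outdir, paste0("events_", tf, ".tsv")),
                 params = list(stage = "events", tf = tf,
                               q_bind = ecfg$q_bind, window = ecfg$window))
      write_events_bed(events[[tf]],
                       file.path(outdir, paste0("events_", tf, ".bed")))
    }
    res$events <- events
  }

  ## --- classify -----------------------------------------------------------
  cls <- NULL
  if ("classify" %in% stages) {
    cls <- classify_sites(events, chip, input, g, ecfg)
    .write_tsv(cls$sites, file.path(outdir, "site_categories.tsv"),
               params = list(stage = "classify", q_diff = ecfg$q_diff,
                             phi = signif(cls$phi, 6)))
    .write_tsv(cls$categories, file.path(outdir, "category_counts.tsv"),
               params = list(stage = "classify",
                             min_category = ecfg$min_category))
    res$classify <- cls
  }

  ## --- accessibility ------------------------------------------------------
  if ("accessibility" %in% stages && length(atac_prior) > 0) {
    acfg <- config$accessibility
    domains <- call_domains(atac_prior, g, bin = acfg$bin,
                            p_thresh = acfg$p_thresh,
                            merge_gap = acfg$merge_gap,
                            min_len = acfg$min_len)
    .write_tsv(domains, file.path(outdir, "accessible_domains.tsv"),
               params = list(stage = "accessibility", bin = acfg$bin,
                             p_thresh = acfg$p_thresh))
    access <- list(domains = domains)
    if (!is.null(cls) && nrow(cls$sites) > 0L) {
      sd <- site_density(cls$sites, atac_prior, window = acfg$window)
      dens <- data.table::data.table(cls$sites[, .(chrom, summit, label)],
                                     density = sd$densities$density)
      frac <- dens[, .(fraction_in_domains =
                         fraction_in_domains(.SD, domains),
                       median_density = stats::median(density), n = .N),
                   by = label]
      .write_tsv(dens, file.path(outdir, "site_prior_density.tsv"),
                 params = list(stage = "accessibility", window = acfg$window))
      .write_tsv(frac, file.path(outdir, "category_accessibility.tsv"),
                 params = list(stage = "accessibility"))
      access$site_density <- dens
      access$category_summary <- frac
      if (!is.null(atac_post)) {
        st <- data.table::copy(cls$sites[, .(chrom, summit, label)])
        data.table::setnames(st, "label", "category")
        ch <- accessibility_change(st, atac_prior, atac_post,
                                   window = acfg$window)
        .write_tsv(ch$by_category,
                   file.path(outdir, "accessibility_change.tsv"),
                   params = list(stage = "accessibility"))
        access$change <- ch
      }
    }
    res$accessibility <- access
  }

  ## --- motifs -------------------------------------------------------------
  if ("motifs" %in% stages && !is.null(cls) && nrow(cls$sites) > 0L) {
    mcfg <- config$motifs
    bg <- train_background(g, order = 2L)
    nulls <- sample_sequences(bg, mcfg$n_null, length = mcfg$null_length,
                              seed = seed + 101L)
    motif_models <- if (!is.null(config$scenario))
      config$scenario$motifs else default_motif_models()
    bg_windows <- sample_genome_windows(g, mcfg$n_background,
                                        mcfg$null_length, seed = seed + 103L)
    hit_rows <- list()
    for (mname in names(motif_models)) {
      sm <- score_motif(motif_models[[mname]], bg)
      # query: consensus instances embedded in background sequence
      set.seed(seed + 102L)
      qseq <- sample_sequences(bg, mcfg$n_query, length = mcfg$null_length)
      ins <- sample_motif_instances(motif_models[[mname]], mcfg$n_query)
      at <- (mcfg$null_length - motif_models[[mname]]$width) %/% 2L
      qseq <- paste0(substr(qseq, 1L, at), ins,
                     substr(qseq, at + motif_models[[mname]]$width + 1L,
                            mcfg$null_length))
      sm <- calibrate_threshold(sm, qseq, nulls,
                                fdr_target = mcfg$fdr_target)
      if (!is.finite(sm$threshold)) next
      for (lab in setdiff(unique(cls$sites$label), "unclassified/minor")) {
        pk <- cls$sites[label == lab]
        ph <- peaks_with_hits(pk, g, sm, within = mcfg$within)
        ov <- overrepresentation(ph$flagged, g, sm,
                                 background_seqs = bg_windows)
        hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
          motif = mname, category = lab, threshold = sm$threshold,
          hit_rate = mean(ph$flagged), background_rate = ov$rate_background,
          ratio = ov$ratio, p = ov$p)
      }
    }
    motif_report <- data.table::rbindlist(hit_rows)
    .write_tsv(motif_report, file.path(outdir, "motif_enrichment.tsv"),
               params = list(stage = "motifs", fdr_target = mcfg$fdr_target,
                             n_null = mcfg$n_null))
    res$motifs <- motif_report
  }

  ## --- genesets -----------------------------------------------------------
  if ("genesets" %in% stages && !is.null(expr) && !is.null(cls) &&
      nrow(cls$sites) > 0L) {
    gcfg <- config$genesets
    sets <- build_gene_sets(expr$records, tf_names,
                            baseline = gcfg$baseline,
                            lfc_thresh = gcfg$lfc_thresh, alpha = gcfg$alpha)
    set_dt <- data.table::rbindlist(lapply(names(sets), function(nm)
      if (length(sets[[nm]]))
        data.table::data.table(gene_set = nm, gene = sets[[nm]])))
    .write_tsv(set_dt, file.path(outdir, "gene_sets.tsv"),
               params = list(stage = "genesets", lfc_thresh = gcfg$lfc_thresh,
                             alpha = gcfg$alpha))
    assoc <- association_matrix(cls$sites, sets, expr$genes)
    .write_tsv(assoc, file.path(outdir, "category_geneset_association.tsv"),
               params = list(stage = "genesets"))
    res$genesets <- list(sets = sets, association = assoc)
  }

  ## --- profiles -----------------------------------------------------------
  if ("profiles" %in% stages && !is.null(events)) {
    pcfg <- config$profiles
    uni <- union_top_sites(events, n = ecfg$top_n,
                           merge_radius = pcfg$union_radius)
    .write_tsv(uni, file.path(outdir, "union_top_sites.tsv"),
               params = list(stage = "profiles", top_n = ecfg$top_n))
    libs_flat <- list()
    for (tf in tf_names)
      for (i in seq_along(chip[[tf]]))
        libs_flat[[paste0(tf, "_rep", i)]] <- chip[[tf]][[i]]
    if (nrow(uni) >= 2L && length(libs_flat) >= 2L) {
      cm <- count_matrix(uni, libs_flat, window = ecfg$window)
      pca <- pca_profiles(cm)
      .write_tsv(data.table::data.table(
        experiment = rownames(pca$scores),
        data.table::as.data.table(pca$scores)),
        file.path(outdir, "pca_scores.tsv"),
        params = list(stage = "profiles"))
      .write_tsv(data.table::data.table(pc = seq_along(pca$var_frac),
                                        var_frac = pca$var_frac),
                 file.path(outdir, "pca_variance.tsv"),
                 params = list(stage = "profiles"))
      res$profiles <- list(union = uni, pca = pca)
    }
    hm <- heatmap_matrix(events[[1L]], chip[[1L]], g,
                         window = pcfg$heatmap_window,
                         bin = pcfg$heatmap_bin,
                         floor = pcfg$heatmap_floor,
                         percentile = pcfg$heatmap_percentile)
    .write_tsv(data.table::data.table(bound = c("min", "max"),
                                      value = hm$bounds),
               file.path(outdir, "heatmap_bounds.tsv"),
               params = list(stage = "profiles",
                             percentile = pcfg$heatmap_percentile))
    res$heatmap <- hm
  }

  log$parameters <- list(events = config$events,
                         accessibility = config$accessibility,
                         motifs = config$motifs)
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(res)
}
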