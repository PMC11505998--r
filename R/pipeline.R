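#' Default end-to-end pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]: one block per
#' stage with its tunable parameters. Stage blocks validate before any stage
#' runs; unknown stage names are rejected.
#'
#' @return named list of stage parameter blocks.
#' @export
default_run_config <- function() {
  list(
    stages = c("simulate", "gr", "synergy", "assays", "tgi", "trajectory"),
    simulate = list(
      cell_lines = c("lineA", "lineB"),
      drugs = c("gedatolisib", "alpelisib"),
      gr_params = list(
        "lineA:gedatolisib" = list(gr_inf = -0.5, gec50 = 20, hill = 1),
        "lineA:alpelisib" = list(gr_inf = 0.2, gec50 = 800, hill = 1.2),
        "lineB:gedatolisib" = list(gr_inf = -0.2, gec50 = 60, hill = 1),
        "lineB:alpelisib" = list(gr_inf = 0.4, gec50 = 2000, hill = 1)),
      doubling_time_h = c(lineA = 24, lineB = 40),
      noise_cv = 0.05,
      combo = list(dm_a = 100, m_a = 1.2, dm_b = 400, m_b = 1,
                   interaction = 0.6, noise_cv = 0.02),
      xeno = list(
        arms = list(
          list(name = "vehicle", n_mice = 10, growth_rate_per_day = 0.08,
               treatment_effect = 0),
          list(name = "gedatolisib", n_mice = 10, growth_rate_per_day = 0.08,
               treatment_effect = 0.05),
          list(name = "combination", n_mice = 10, growth_rate_per_day = 0.08,
               treatment_effect = 0.075)),
        v0_mm3 = 150, noise_cv = 0.1),
      cohort = list(n_samples = 300, n_genes = 2000, n_batches = 3,
                    frac_loaded = 0.1, loading = 0.8, batch_shift_sd = 0.3,
                    survival_link = 1, censor_rate = 0.3),
      assay = list(n_events = 20000, live_frac = 0.9, edu_frac_ctrl = 0.5,
                   edu_frac_treated = 0.15, mfi_shift = 0.3,
                   ct_effects = c(PGR = -1))),
    gr = list(background = 0),
    synergy = list(additive_tol = 0.05),
    assays = list(control = "DMSO", target = "PGR",
                  control_condition = "control"),
    tgi = list(day = 28, control_arm = "vehicle"),
    trajectory = list(n_top_iqr = 2000, n_pc = 5, seed_cluster = "G1",
                      n_draws = 20, n_perm = 200, dsc_perm = 200)
  )
}

validate_config <- function(config) {
  known <- c("simulate", "gr", "synergy", "assays", "tgi", "trajectory")
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    stop("unknown stage name(s) in config$stages: ", paste(bad, collapse = ", "))
  }
  for (st in config$stages) {
    if (is.null(config[[st]])) stop("missing parameter block for stage: ", st)
  }
  invisible(TRUE)
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the synthetic end-to-end pipeline
#'
#' Chains simulate -> analyze for each selected stage in dependency order:
#' every analysis stage reads the TSV files written by the simulate stage (or
#' by a previous run in the same output directory), writes its result tables,
#' and the driver records a JSON manifest (stage seeds, parameters, output
#' checksums). Identical config + seed produces checksum-identical outputs.
#' One global seed fans out to per-stage child seeds by stable hashing of the
#' stage name, so stages draw decoupled random streams.
#'
#' @param config configuration list, see [default_run_config()].
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed.
#' @return the run manifest (named list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, seed = 1) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list(),
                   skipped = setdiff(c("simulate", "gr", "synergy", "assays",
                                       "tgi", "trajectory"), config$stages))
  record <- function(stage, outputs, extra = NULL) {
    manifest$stages[[stage]] <<- c(list(seed = child_seed(seed, stage),
                                        outputs = as.list(md5_of(outputs))),
                                   extra)
  }
  path <- function(...) file.path(out_dir, ...)

  if ("simulate" %in% config$stages) {
    sc <- config$simulate
    s_seed <- child_seed(seed, "simulate")
    spec <- plate_spec(cell_lines = sc$cell_lines, drugs = sc$drugs,
                       doubling_time_h = sc$doubling_time_h,
                       gr_params = sc$gr_params, noise_cv = sc$noise_cv,
                       seed = s_seed)
    plates <- gen_dose_response(spec)
    write_tsv(plates, path("plates.tsv"))

    cb <- sc$combo
    ladder <- c(25, 50, 100, 200, 400, 800)
    doses <- rbind(data.frame(dose_a = ladder, dose_b = 0),
                   data.frame(dose_a = 0, dose_b = ladder * 4),
                   data.frame(dose_a = ladder, dose_b = ladder * 4))
    combo <- gen_combination(cb$dm_a, cb$m_a, cb$dm_b, cb$m_b,
                             cb$interaction, doses, noise_cv = cb$noise_cv,
                             seed = child_seed(seed, "simulate.combo"))
    write_tsv(combo, path("combination.tsv"))

    xn <- sc$xeno
    xeno <- gen_xenograft(xn$arms, v0_mm3 = xn$v0_mm3,
                          noise_cv = xn$noise_cv,
                          seed = child_seed(seed, "simulate.xeno"))
    write_tsv(xeno, path("xenograft.tsv"))

    ch <- sc$cohort
    n_loaded <- round(ch$frac_loaded * ch$n_genes)
    loadings <- c(rep(ch$loading, ceiling(n_loaded / 2)),
                  rep(-ch$loading, floor(n_loaded / 2)),
                  rep(0, ch$n_genes - n_loaded))
    cspec <- cohort_spec(n_samples = ch$n_samples, n_genes = ch$n_genes,
                         n_batches = ch$n_batches,
                         module_loadings = loadings,
                         batch_shift_sd = ch$batch_shift_sd,
                         survival_link = ch$survival_link,
                         censor_rate = ch$censor_rate,
                         seed = child_seed(seed, "simulate.cohort"))
    cohort <- gen_expression_cohort(cspec)
    counts_df <- data.frame(gene = rownames(cohort$counts), cohort$counts,
                            check.names = FALSE)
    write_tsv(counts_df, path("counts.tsv"))
    write_tsv(cohort$metadata, path("metadata.tsv"))
    write_tsv(cohort$annotation, path("annotation.tsv"))
    jsonlite::write_json(
      list(pseudotime = cohort$truth$pseudotime,
           loadings = cohort$truth$loadings),
      path("cohort_truth.json"), auto_unbox = TRUE, digits = NA)

    as_ <- sc$assay
    panel <- gen_assay_panel(n_events = as_$n_events,
                             live_frac = as_$live_frac,
                             edu_frac_ctrl = as_$edu_frac_ctrl,
                             edu_frac_treated = as_$edu_frac_treated,
                             mfi_shift = as_$mfi_shift,
                             ct_effects = as_$ct_effects,
                             seed = child_seed(seed, "simulate.assay"))
    write_tsv(panel$events, path("flow_events.tsv"))
    write_tsv(panel$ct, path("ct_table.tsv"))
    jsonlite::write_json(as.list(panel$unstained), path("unstained.json"),
                         auto_unbox = TRUE, digits = NA)
    record("simulate",
           path(c("plates.tsv", "combination.tsv", "xenograft.tsv",
                  "counts.tsv", "metadata.tsv", "annotation.tsv",
                  "cohort_truth.json", "flow_events.tsv", "ct_table.tsv",
                  "unstained.json")))
  }

  if ("gr" %in% config$stages) {
    plates <- read_tsv(path("plates.tsv"),
                       required = c("cell_line", "drug", "conc_nM",
                                    "replicate", "signal_t0", "signal_t",
                                    "duration_h"))
    res <- gr_analysis(plates, background = config$gr$background)
    write_tsv(res$gr_table, path("gr_table.tsv"))
    write_tsv(res$metrics, path("gr_metrics.tsv"))
    record("gr", path(c("gr_table.tsv", "gr_metrics.tsv")))
  }

  if ("synergy" %in% config$stages) {
    combo <- read_tsv(path("combination.tsv"),
                      required = c("dose_a", "dose_b", "fa"))
    res <- synergy_analysis(combo, additive_tol = config$synergy$additive_tol)
    write_tsv(res$ci, path("combination_index.tsv"))
    jsonlite::write_json(list(fit_a = unclass(res$fit_a),
                              fit_b = unclass(res$fit_b)),
                         path("median_effect_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    record("synergy", path(c("combination_index.tsv",
                             "median_effect_fits.json")))
  }

  if ("assays" %in% config$stages) {
    events <- read_tsv(path("flow_events.tsv"),
                       required = c("condition", "viability_dye", "edu",
                                    "prps6", "p4ebp1"))
    unstained <- unlist(jsonlite::read_json(path("unstained.json")))
    fs <- flow_summarize(events, unstained, control = config$assays$control)
    fs$pct_inhibition_edu <- as.numeric(percent_inhibition(fs$norm_edu))
    fs$pct_inhibition_prps6 <- as.numeric(percent_inhibition(fs$norm_prps6))
    fs$pct_inhibition_p4ebp1 <- as.numeric(percent_inhibition(fs$norm_p4ebp1))
    write_tsv(fs, path("flow_summary.tsv"))
    ct <- read_tsv(path("ct_table.tsv"),
                   required = c("sample", "condition", "gene", "ct"))
    dd <- ddct_expression(ct, target = config$assays$target,
                          control_condition = config$assays$control_condition)
    write_tsv(dd, path("ddct.tsv"))
    record("assays", path(c("flow_summary.tsv", "ddct.tsv")))
  }

  if ("tgi" %in% config$stages) {
    xeno <- read_tsv(path("xenograft.tsv"),
                     required = c("animal", "arm", "day", "length_mm",
                                  "width_mm", "body_weight_g"))
    tg <- tgi(xeno, day = config$tgi$day,
              control_arm = config$tgi$control_arm)
    write_tsv(tg, path("tgi.tsv"))
    write_tsv(efficacy_summary(xeno), path("arm_summary.tsv"))
    bw <- body_weight_change(xeno)
    write_tsv(bw, path("body_weight.tsv"))
    gc <- group_compare(xeno, day = config$tgi$day,
                        control_arm = config$tgi$control_arm)
    stats_tab <- cbind(data.frame(test = "one-way ANOVA"), gc$anova)
    write_tsv(stats_tab, path("group_stats.tsv"))
    write_tsv(gc$pairwise, path("pairwise_stats.tsv"))
    record("tgi", path(c("tgi.tsv", "arm_summary.tsv", "body_weight.tsv",
                         "group_stats.tsv", "pairwise_stats.tsv")))
  }

  if ("trajectory" %in% config$stages) {
    tp <- config$trajectory
    t_seed <- child_seed(seed, "trajectory")
    counts_df <- read_tsv(path("counts.tsv"))
    counts <- as.matrix(counts_df[, -1, drop = FALSE])
    rownames(counts) <- counts_df$gene
    meta <- read_tsv(path("metadata.tsv"),
                     required = c("sample", "grade", "batch", "survival_time",
                                  "event"))
    annot <- read_tsv(path("annotation.tsv"), required = c("gene", "biotype"))
    norm <- preprocess_counts(counts, annot)
    d0 <- dsc(norm, meta$batch, n_perm = tp$dsc_perm,
              seed = child_seed(seed, "trajectory.dsc0"))
    adj <- remove_batch(norm, meta$batch, covariate = meta$grade)
    d1 <- dsc(adj, meta$batch, n_perm = tp$dsc_perm,
              seed = child_seed(seed, "trajectory.dsc1"))
    emb <- pca_embed(adj, n_top_iqr = tp$n_top_iqr, n_pc = tp$n_pc)
    traj <- infer_trajectory(emb$embedding, meta$grade,
                             seed_cluster = tp$seed_cluster)
    pt_tab <- data.frame(sample = meta$sample,
                         pseudotime = unname(traj$pseudotime))
    write_tsv(pt_tab, path("pseudotime.tsv"))
    corr <- pseudotime_correlation(adj, traj$pseudotime, n_draws = tp$n_draws,
                                   seed = child_seed(seed, "trajectory.corr"))
    write_tsv(corr, path("pseudotime_correlation.tsv"))
    gmt_path <- path("gene_sets.gmt")
    gene_sets <- if (file.exists(gmt_path)) read_gmt(gmt_path) else {
      # default QC sets: the most positively / negatively correlated genes
      oc <- corr[order(corr$median_r), ]
      list(top_positive = utils::tail(oc$gene, 50),
           top_negative = utils::head(oc$gene, 50))
    }
    stats_vec <- stats::setNames(corr$median_r, corr$gene)
    enr <- gsea_preranked(stats_vec, gene_sets, n_perm = tp$n_perm,
                          seed = child_seed(seed, "trajectory.gsea"))
    write_tsv(enr, path("enrichment.tsv"))
    top_gene <- corr$gene[which.max(abs(corr$median_r))]
    km <- km_twogroup(adj[top_gene, ], meta$survival_time, meta$event)
    jsonlite::write_json(
      list(dsc_before = d0$dsc, dsc_after = d1$dsc,
           dsc_p_before = d0$p_perm,
           variance_explained_5pc = sum(emb$variance_explained[1:5]),
           pseudotime_range = c(0, max(traj$pseudotime)),
           km_gene = top_gene, km_chisq = km$chisq, km_p = km$p),
      path("trajectory_report.json"), auto_unbox = TRUE, digits = NA)
    record("trajectory",
           path(c("pseudotime.tsv", "pseudotime_correlation.tsv",
                  "enrichment.tsv", "trajectory_report.json")))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
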