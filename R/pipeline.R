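# Pipeline orchestration: a single nested run configuration (YAML in and
# out), stage execution in dependency order, and a machine-readable run
# summary with file hashes. All randomness derives from the one global
# seed; the generator and the GSEA permutation null use documented
# fixed offsets from it so each stage is independently reproducible.

#' Default run configuration
#'
#' The reference synthetic-study configuration: simulate with the
#' [simulation_config()] defaults, then run target calling (p < 1e-8,
#' fold > 4, 100 kb window, |log2FC| > 2), chromatin-state annotation
#' (flank 2 kb), differential-signal aggregation (flank 5 kb, pseudocount
#' 0.1, loss threshold -0.5), enrichment (1000 permutations) and
#' stratified survival (all / RAS-driven / RAS-activated, TP53-LOF
#' required in the RAS contexts).
#'
#' @param seed global integer seed
#' @param workdir directory for simulated inputs and stage outputs
#' @return nested configuration list of class `run_config`
#' @export
default_run_config <- function(seed, workdir) {
  structure(list(
    seed = as.integer(seed),
    workdir = workdir,
    simulate = TRUE,
    simulation = list(),  # overrides for simulation_config()
    genome = list(n_chroms = 4L, chrom_length = 105.5e6, bin_size = 50L),
    targets = list(p_threshold = 1e-8, fold_threshold = 4, window = 100000,
                   up_lfc = 2, down_lfc = -2),
    chromstate = list(flank = 2000, bin = 50,
                      bivalent_group = bivalent_polycomb_states()),
    signal = list(flank = 5000, pseudocount = 0.1, loss_threshold = -0.5,
                  loss_max_gap = 2L, loss_min_width = 500),
    enrich = list(n_perm = 1000L, weight_exponent = 1.0),
    survival = list()
  ), class = "run_config")
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop_fmt("unknown configuration key(s)%s: %s",
             if (nzchar(path)) paste0(" under ", path) else "",
             paste(extra, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Values omitted from the file take the [default_run_config()] defaults;
#' unknown keys are rejected. `seed` and `workdir` must be present in the
#' file or supplied here.
#'
#' @param path YAML file
#' @param seed,workdir override/supply the global seed and work directory
#' @return a `run_config`
#' @export
read_run_config <- function(path, seed = NULL, workdir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  if (!is.null(workdir)) raw$workdir <- workdir
  if (is.null(raw$seed)) stop_fmt("run configuration needs a seed")
  if (is.null(raw$workdir)) stop_fmt("run configuration needs a workdir")
  ref <- default_run_config(raw$seed, raw$workdir)
  # simulation overrides are validated by simulation_config() itself
  ref$simulation <- raw$simulation %||% list()
  check_config_keys(raw[setdiff(names(raw), "simulation")], unclass(ref))
  structure(merge_config(unclass(ref), raw), class = "run_config")
}

resolve_sim_config <- function(config) {
  args <- config$simulation
  args$seed <- config$seed
  args$n_chroms <- args$n_chroms %||% config$genome$n_chroms
  args$chrom_length <- args$chrom_length %||% config$genome$chrom_length
  args$bin_size <- args$bin_size %||% config$genome$bin_size
  do.call(simulation_config, args)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> targets -> chromstate -> signal -> enrich ->
#' survival on one configuration, writing every stage's tables under
#' `workdir` plus a resolved copy of the configuration
#' (`run_config.yaml`) and a machine-readable `run_summary.json` whose
#' numbers (peak and target counts, bivalent group fractions, enrichment
#' scores, log-rank p per context) and per-file hashes summarise the run.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config a `run_config` (see [default_run_config()] /
#'   [read_run_config()])
#' @return the run summary, invisibly (also written as JSON)
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  wd <- config$workdir
  data_dir <- file.path(wd, "data")
  out_dir <- file.path(wd, "results")
  dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(wd, "run_config.yaml"))

  sim_cfg <- resolve_sim_config(config)
  if (isTRUE(config$simulate)) {
    stage_msg("simulate", "seed %d -> %s", config$seed, data_dir)
    simulate_study(sim_cfg, data_dir)
  }
  layout <- sim_layout(sim_cfg)

  stage_msg("targets", "reading inputs")
  genes <- read_gene_annotation(file.path(data_dir, "genes.gtf"), "gtf")
  peaks <- read_narrowpeak(file.path(data_dir, "peaks.narrowPeak"))
  expr <- read_expression(file.path(data_dir, "expression.tsv"))
  tg <- config$targets
  tc <- call_targets(peaks, genes, expr, p_threshold = tg$p_threshold,
                     fold_threshold = tg$fold_threshold, window = tg$window,
                     up_lfc = tg$up_lfc, down_lfc = tg$down_lfc)
  write_tsv(tc$targets, file.path(out_dir, "targets.tsv"))
  write_tsv(tc$assignment, file.path(out_dir, "assignment.tsv"))
  write_tsv(tc$peak_labels, file.path(out_dir, "peak_labels.tsv"))
  write_tsv(tc$distance_hist, file.path(out_dir, "distance_hist.tsv"))
  n_act <- sum(tc$targets$class == "activated")
  n_rep <- sum(tc$targets$class == "repressed")
  stage_msg("targets", "%d high-confidence peaks; %d activated, %d repressed targets",
            nrow(tc$hc_peaks), n_act, n_rep)

  stage_msg("chromstate", "annotating anchors")
  seg <- read_segmentation(file.path(data_dir, "segmentation.bed"))
  groups <- anchor_groups(genes, tc$targets, tc$hc_peaks, tc$peak_labels)
  cs <- config$chromstate
  frac_rows <- list()
  group_fractions <- list()
  for (nm in names(groups)) {
    if (!nrow(groups[[nm]])) next
    sf <- state_fractions(groups[[nm]], seg, cs$bivalent_group)
    group_fractions[[nm]] <- sf$group_fraction
    frac_rows[[nm]] <- data.frame(group = nm, n_anchors = sf$n_anchors,
                                  sf$table, stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, frac_rows), file.path(out_dir, "state_fractions.tsv"))
  prof_rows <- list()
  for (nm in c("activated_tss", "repressed_tss")) {
    if (!nrow(groups[[nm]])) next
    pr <- positional_state_profile(groups[[nm]], seg, layout,
                                   flank = cs$flank, bin = cs$bin)
    long <- data.frame(group = nm,
                       offset = rep(pr$offsets, ncol(pr$matrix)),
                       state = rep(colnames(pr$matrix), each = length(pr$offsets)),
                       fraction = as.vector(pr$matrix), stringsAsFactors = FALSE)
    prof_rows[[nm]] <- long[long$fraction > 0, , drop = FALSE]
  }
  write_tsv(do.call(rbind, prof_rows), file.path(out_dir, "state_profile.tsv"))

  stage_msg("signal", "log2-ratio metaprofiles")
  sg <- config$signal
  marks <- c("h3k4me3", "h3k27me3", "ezh2")
  meta_rows <- list()
  profile_center <- list()
  loss <- list()
  for (mark in marks) {
    a <- read_bedgraph(file.path(data_dir, sprintf("coverage_%s_oc2.bedGraph", mark)),
                       layout, config$genome$bin_size)
    b <- read_bedgraph(file.path(data_dir, sprintf("coverage_%s_ddbd.bedGraph", mark)),
                       layout, config$genome$bin_size)
    ratio <- log2_ratio_track(a, b, pseudocount = sg$pseudocount)
    rm(a, b)
    for (nm in c("activating_summits", "repressive_summits",
                 "activated_tss", "repressed_tss")) {
      if (!nrow(groups[[nm]])) next
      mp <- metaprofile(ratio, groups[[nm]], flank = sg$flank, anchor_group = nm)
      meta_rows[[paste(mark, nm)]] <-
        data.frame(mark = mark, group = nm, offset = mp$offsets,
                   mean_log2fc = mp$mean, n_anchors = mp$n_anchors,
                   stringsAsFactors = FALSE)
      ctr <- abs(mp$offsets) <= 500
      profile_center[[paste0(mark, ".", nm)]] <- mean(mp$mean[ctr])
    }
    if (mark %in% c("h3k27me3", "ezh2")) {
      lr <- call_loss_regions(ratio, threshold = sg$loss_threshold,
                              max_gap = sg$loss_max_gap,
                              min_width = sg$loss_min_width)
      loss[[mark]] <- lr
      write_tsv(lr, file.path(out_dir, sprintf("loss_regions_%s.bed", mark)))
    }
    rm(ratio)
  }
  write_tsv(do.call(rbind, meta_rows), file.path(out_dir, "metaprofiles.tsv"))
  loss_jaccard <- interval_jaccard(loss$h3k27me3, loss$ezh2)
  stage_msg("signal", "H3K27me3/EZH2 loss-region Jaccard = %.3f", loss_jaccard)

  stage_msg("enrich", "hypergeometric overlaps and preranked GSEA")
  sets <- read_gmt(file.path(data_dir, "gene_sets.gmt"))
  ranked <- rank_by_log2fc(expr)
  up_genes <- expr$gene_id[expr$is_significant & expr$log2fc > 0]
  ov <- overlap_table(up_genes, sets, expr$gene_id)
  write_tsv(ov, file.path(out_dir, "overlap_table.tsv"))
  en <- config$enrich
  gsea_rows <- lapply(seq_along(sets), function(i) {
    res <- gsea_permutation(ranked, sets[[i]], n_perm = en$n_perm,
                            seed = config$seed + 1000L + i,
                            weight_exponent = en$weight_exponent)
    data.frame(set = names(sets)[i], size = res$set_size, es = res$es,
               nes = res$nes, nominal_p = res$nominal_p,
               n_perm = res$n_permutations, stringsAsFactors = FALSE)
  })
  gsea_tab <- do.call(rbind, gsea_rows)
  write_tsv(gsea_tab, file.path(out_dir, "gsea_results.tsv"))

  stage_msg("survival", "stratified log-rank per context")
  cohort <- read_cohort(file.path(data_dir, "cohort.tsv"))
  surv_specs <- list(all = list(context = "all", tp53 = FALSE),
                     ras_driven_tp53 = list(context = "ras_driven", tp53 = TRUE),
                     ras_activated_tp53 = list(context = "ras_activated", tp53 = TRUE))
  surv_rows <- list()
  km_rows <- list()
  for (nm in names(surv_specs)) {
    sp <- surv_specs[[nm]]
    rs <- run_stratified_survival(cohort, context = sp$context,
                                  require_tp53_lof = sp$tp53)
    surv_rows[[nm]] <- data.frame(analysis = nm, context = sp$context,
                                  require_tp53_lof = sp$tp53, n = rs$n,
                                  chi_square = rs$logrank$chi_square,
                                  p_value = rs$logrank$p_value,
                                  stringsAsFactors = FALSE)
    for (stratum in c("high", "low")) {
      cv <- if (stratum == "high") rs$curve_high else rs$curve_low
      if (!nrow(cv)) next
      km_rows[[paste(nm, stratum)]] <- data.frame(analysis = nm,
                                                  stratum = stratum, cv,
                                                  stringsAsFactors = FALSE)
    }
  }
  surv_tab <- do.call(rbind, surv_rows)
  write_tsv(surv_tab, file.path(out_dir, "logrank.tsv"))
  write_tsv(do.call(rbind, km_rows), file.path(out_dir, "km_curves.tsv"))

  out_files <- sort(list.files(out_dir, full.names = TRUE))
  summary <- list(
    seed = config$seed,
    counts = list(n_peaks = nrow(peaks), n_high_confidence = nrow(tc$hc_peaks),
                  n_activated_targets = n_act, n_repressed_targets = n_rep,
                  n_genes = nrow(genes), n_patients = nrow(cohort)),
    group_fractions = group_fractions,
    signal_center_means = profile_center,
    loss_region_jaccard = loss_jaccard,
    gsea = setNames(lapply(seq_len(nrow(gsea_tab)), function(i)
      list(es = gsea_tab$es[i], nes = gsea_tab$nes[i],
           nominal_p = gsea_tab$nominal_p[i])), gsea_tab$set),
    logrank_p = setNames(as.list(surv_tab$p_value), surv_tab$analysis),
    file_hashes = setNames(as.list(unname(tools::md5sum(out_files))),
                           basename(out_files)))
  jsonlite::write_json(summary, file.path(wd, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(summary)
}
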