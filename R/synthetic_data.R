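# Synthetic-study generator: a complete desk-scale study -- genome, gene
# annotation, chromatin-state segmentation, scored binding peaks,
# two-condition histone/EZH2 coverage, differential expression, gene-set
# collection and a survival cohort -- with planted, recoverable effects
# and a ground-truth manifest.
#
# Every file is a deterministic function of (config, seed): each
# generation step draws from its own derived seed (seed + fixed offset)
# so stages are reproducible independently of one another, and all
# numeric output goes through a fixed text formatting.

SEED_OFF <- c(genes = 11L, segmentation = 23L, peaks = 37L, expression = 53L,
              coverage = 71L, cohort = 101L, gene_sets = 131L)

#' Build a simulation configuration
#'
#' Defaults define the reference synthetic study: 2,000 genes on a 4 x
#' 105.5 Mb genome with 300 activated and 107 repressed planted targets,
#' bivalent/Polycomb TSS probability 0.40 for activated targets vs 0.10
#' background, planted log2 effects +1 (H3K4me3) and -1 (H3K27me3, EZH2)
#' within 500 bp of activating summits, and a 1,200-patient cohort in
#' which a hazard ratio of 2.5 applies only to RAS-driven, TP53-LOF
#' patients in the upper expression quartile.
#'
#' @param seed integer seed (mandatory); all stage seeds derive from it
#' @param n_chroms,chrom_length genome shape
#' @param bin_size coverage bin width (bp)
#' @param n_genes total genes; must fit the non-ambiguity spacing
#' @param n_activated_targets,n_repressed_targets planted target counts
#' @param p_bivalent_given_activated,p_bivalent_background probability
#'   that a TSS state is drawn from the bivalent/Polycomb group
#' @param peak_summit_sd SD (bp) of summit placement around the TSS
#' @param n_decoy_peaks peaks that fail the high-confidence filter
#' @param planted_h3k4me3_log2fc,planted_h3k27me3_log2fc,planted_ezh2_log2fc
#'   multiplicative effects (log2 units) at activating summits in the
#'   overexpression condition
#' @param background_shape,background_scale Gamma law of per-bin coverage
#' @param coverage_flank emit coverage this far (bp) around anchors
#' @param effect_halfwidth planted-effect half-window (bp)
#' @param n_patients,frac_ras_driven,frac_ras_activated_extra,frac_tp53_lof
#'   cohort composition (RAS-driven patients are also RAS-activated;
#'   `frac_ras_activated_extra` adds patients altered only in the
#'   non-driven RAS-pathway genes)
#' @param hazard_ratio_high_expression planted hazard ratio
#' @param censoring_rate expected fraction of censored baseline patients
#' @param baseline_hazard events per day
#' @param n_random_gene_sets extra random sets in the GMT
#' @return a validated list of class `simulation_config`
#' @export
simulation_config <- function(seed,
                              n_chroms = 4L,
                              chrom_length = 105.5e6,
                              bin_size = 50L,
                              n_genes = 2000L,
                              n_activated_targets = 300L,
                              n_repressed_targets = 107L,
                              p_bivalent_given_activated = 0.40,
                              p_bivalent_background = 0.10,
                              peak_summit_sd = 40000,
                              n_decoy_peaks = 600L,
                              planted_h3k4me3_log2fc = 1.0,
                              planted_h3k27me3_log2fc = -1.0,
                              planted_ezh2_log2fc = -1.0,
                              background_shape = 50,
                              background_scale = 0.5,
                              coverage_flank = 6000,
                              effect_halfwidth = 500,
                              n_patients = 1200L,
                              frac_ras_driven = 0.30,
                              frac_ras_activated_extra = 0.15,
                              frac_tp53_lof = 0.40,
                              hazard_ratio_high_expression = 2.5,
                              censoring_rate = 0.15,
                              baseline_hazard = 1 / 1000,
                              n_random_gene_sets = 5L) {
  if (missing(seed)) stop_fmt("a seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, bin_size = as.integer(bin_size),
              n_genes = as.integer(n_genes),
              n_activated_targets = as.integer(n_activated_targets),
              n_repressed_targets = as.integer(n_repressed_targets),
              p_bivalent_given_activated = p_bivalent_given_activated,
              p_bivalent_background = p_bivalent_background,
              peak_summit_sd = peak_summit_sd,
              n_decoy_peaks = as.integer(n_decoy_peaks),
              planted_h3k4me3_log2fc = planted_h3k4me3_log2fc,
              planted_h3k27me3_log2fc = planted_h3k27me3_log2fc,
              planted_ezh2_log2fc = planted_ezh2_log2fc,
              background_shape = background_shape,
              background_scale = background_scale,
              coverage_flank = coverage_flank,
              effect_halfwidth = effect_halfwidth,
              n_patients = as.integer(n_patients),
              frac_ras_driven = frac_ras_driven,
              frac_ras_activated_extra = frac_ras_activated_extra,
              frac_tp53_lof = frac_tp53_lof,
              hazard_ratio_high_expression = hazard_ratio_high_expression,
              censoring_rate = censoring_rate,
              baseline_hazard = baseline_hazard,
              n_random_gene_sets = as.integer(n_random_gene_sets))
  probs <- c(cfg$p_bivalent_given_activated, cfg$p_bivalent_background,
             cfg$frac_ras_driven, cfg$frac_ras_activated_extra,
             cfg$frac_tp53_lof, cfg$censoring_rate)
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must be in [0, 1]")
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$n_patients, cfg$bin_size)
  if (any(counts <= 0)) stop_fmt("counts must be positive")
  if (cfg$n_activated_targets + cfg$n_repressed_targets > cfg$n_genes)
    stop_fmt("more targets than genes")
  if (cfg$hazard_ratio_high_expression <= 0) stop_fmt("hazard ratio must be > 0")
  structure(cfg, class = "simulation_config")
}

sim_layout <- function(config) {
  genome_layout(paste0("chr", seq_len(config$n_chroms)),
                rep(config$chrom_length, config$n_chroms))
}

# TSS grid: genes sit on a regular spacing with small jitter; the spacing
# keeps any summit within 100 kb of its own TSS strictly more than 100 kb
# from every other TSS, so the peak -> gene truth is unique.
GENE_SPACING <- 210000
GENE_MARGIN <- 110000
TSS_JITTER <- 5000

sim_genes <- function(config) {
  slots_per_chrom <- floor((config$chrom_length - 2 * GENE_MARGIN) / GENE_SPACING) + 1
  if (config$n_genes > slots_per_chrom * config$n_chroms)
    stop_fmt(paste("genes too dense for the 100 kb non-ambiguity spacing:",
                   "%d genes but only %d slots; increase chrom_length or n_chroms"),
             config$n_genes, slots_per_chrom * config$n_chroms)
  set.seed(config$seed + SEED_OFF[["genes"]])
  chrom_i <- rep(seq_len(config$n_chroms), length.out = config$n_genes)
  chrom_i <- sort(chrom_i)
  slot <- unlist(lapply(table(chrom_i), seq_len), use.names = FALSE)
  tss <- GENE_MARGIN + (slot - 1) * GENE_SPACING +
    sample(-TSS_JITTER:TSS_JITTER, config$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  len <- sample(2000:20000, config$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - len + 1)
  end <- ifelse(strand == "+", tss + len, tss + 1)
  # planted classes
  cls <- rep("null", config$n_genes)
  ord <- sample.int(config$n_genes)
  cls[ord[seq_len(config$n_activated_targets)]] <- "activated"
  cls[ord[config$n_activated_targets + seq_len(config$n_repressed_targets)]] <- "repressed"
  df <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                   chrom = paste0("chr", chrom_i),
                   start = start, end = end, strand = strand, tss = tss,
                   class = cls, stringsAsFactors = FALSE)
  df
}

BIV_TSS_STATES <- c("TssBiv", "ReprPC")
ACTIVE_TSS_STATES <- c("TssA", "TssAFlnk", "Tx")

draw_tss_state <- function(n, p_biv) {
  biv <- runif(n) < p_biv
  st <- character(n)
  st[biv] <- sample(BIV_TSS_STATES, sum(biv), replace = TRUE, prob = c(0.6, 0.4))
  st[!biv] <- sample(ACTIVE_TSS_STATES, sum(!biv), replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
  st
}

sim_peaks <- function(config, genes) {
  set.seed(config$seed + SEED_OFF[["peaks"]])
  tg <- genes[genes$class != "null", , drop = FALSE]
  n_t <- nrow(tg)
  # summit displacement, truncated so every summit stays within the window
  # (95 kb leaves margin inside the 100 kb ball after grid snapping)
  d <- round(rnorm(n_t, 0, config$peak_summit_sd))
  while (any(bad <- abs(d) > 95000))
    d[bad] <- round(rnorm(sum(bad), 0, config$peak_summit_sd))
  summit <- floor((tg$tss + d) / 50) * 50 + 25  # snap to bin centres
  half1 <- sample(150:400, n_t, replace = TRUE)
  half2 <- sample(150:400, n_t, replace = TRUE)
  nlp <- pmax(8 + rexp(n_t, 1 / 4), 8.1)
  fold <- pmax(4 + rexp(n_t, 1 / 6), 4.1)
  true_pk <- data.frame(chrom = tg$chrom, start = summit - half1,
                        end = summit + half2, summit = summit,
                        fold_enrichment = fold, neg_log10_p = nlp,
                        label = ifelse(tg$class == "activated", "activating",
                                       "repressive"),
                        target_gene = tg$gene_id, stringsAsFactors = FALSE)
  # decoys: each fails p, fold, or both, by a margin of at least 0.1
  n_d <- config$n_decoy_peaks
  if (n_d > 0) {
    dc_chrom <- paste0("chr", sample.int(config$n_chroms, n_d, replace = TRUE))
    dc_summit <- floor(runif(n_d, 50000, config$chrom_length - 50000) / 50) * 50 + 25
    kind <- rep_len(c("low_p", "low_fold", "both"), n_d)
    dc_nlp <- ifelse(kind == "low_fold", 8 + rexp(n_d, 1 / 4), runif(n_d, 1, 7.9))
    dc_fold <- ifelse(kind == "low_p", 4 + rexp(n_d, 1 / 6), runif(n_d, 0.5, 3.9))
    dh1 <- sample(150:400, n_d, replace = TRUE)
    dh2 <- sample(150:400, n_d, replace = TRUE)
    decoy <- data.frame(chrom = dc_chrom, start = dc_summit - dh1,
                        end = dc_summit + dh2, summit = dc_summit,
                        fold_enrichment = dc_fold, neg_log10_p = dc_nlp,
                        label = "decoy", target_gene = NA_character_,
                        stringsAsFactors = FALSE)
    pk <- rbind(true_pk, decoy)
  } else {
    pk <- true_pk
  }
  pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
  pk$peak_id <- sprintf("P%04d", seq_len(nrow(pk)))
  pk$score <- round(10 * pk$neg_log10_p)
  pk$strand <- "."
  pk$neg_log10_q <- pmax(pk$neg_log10_p - 0.5, 0)
  rownames(pk) <- NULL
  pk
}

sim_segmentation <- function(config, genes, peaks) {
  set.seed(config$seed + SEED_OFF[["segmentation"]])
  tss_state <- draw_tss_state(nrow(genes),
                              ifelse(genes$class == "activated",
                                     config$p_bivalent_given_activated,
                                     config$p_bivalent_background))
  segs <- data.frame(chrom = genes$chrom, start = genes$tss - 1000,
                     end = genes$tss + 1000, state = tss_state,
                     stringsAsFactors = FALSE)
  # summit-level states for true peaks far enough from their own TSS
  tp <- peaks[peaks$label %in% c("activating", "repressive"), , drop = FALSE]
  gt <- genes$tss[match(tp$target_gene, genes$gene_id)]
  far <- abs(tp$summit - gt) > 1600
  tp <- tp[far, , drop = FALSE]
  if (nrow(tp)) {
    p_biv <- ifelse(tp$label == "activating", 0.35, config$p_bivalent_background)
    biv <- runif(nrow(tp)) < p_biv
    st <- character(nrow(tp))
    st[biv] <- sample(c("ReprPC", "TssBiv"), sum(biv), replace = TRUE,
                      prob = c(0.7, 0.3))
    st[!biv] <- sample(c("Quies", "Enh", "TxWk"), sum(!biv), replace = TRUE,
                       prob = c(0.5, 0.3, 0.2))
    segs <- rbind(segs, data.frame(chrom = tp$chrom, start = tp$summit - 500,
                                   end = tp$summit + 500, state = st,
                                   stringsAsFactors = FALSE))
  }
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  # fill gaps with Quies so state fractions always sum to 1 without gaps
  filled <- lapply(paste0("chr", seq_len(config$n_chroms)), function(cn) {
    s <- segs[segs$chrom == cn, , drop = FALSE]
    bounds <- c(0, as.vector(rbind(s$start, s$end)), config$chrom_length)
    starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    fill <- data.frame(chrom = cn, start = starts[keep], end = ends[keep],
                       state = "Quies", stringsAsFactors = FALSE)
    out <- rbind(s, fill)
    out[order(out$start), , drop = FALSE]
  })
  seg_df <- do.call(rbind, filled)
  rownames(seg_df) <- NULL
  list(segments = seg_df, tss_state = tss_state)
}

sim_expression <- function(config, genes) {
  set.seed(config$seed + SEED_OFF[["expression"]])
  n <- nrow(genes)
  lfc <- rnorm(n, 0, 0.7)
  sig <- runif(n) < 0.05
  act <- genes$class == "activated"
  rep_ <- genes$class == "repressed"
  draw_trunc <- function(n, mean, lo = -Inf, hi = Inf) {
    x <- rnorm(n, mean, 0.5)
    while (any(bad <- x <= lo | x >= hi)) x[bad] <- rnorm(sum(bad), mean, 0.5)
    x
  }
  # margin 0.1 beyond the classification threshold keeps truth recoverable
  lfc[act] <- draw_trunc(sum(act), 3, lo = 2.1)
  lfc[rep_] <- draw_trunc(sum(rep_), -3, hi = -2.1)
  sig[act | rep_] <- TRUE
  data.frame(gene_id = genes$gene_id, log2fc = lfc, is_significant = sig,
             stringsAsFactors = FALSE)
}

sim_gene_sets <- function(config, genes) {
  set.seed(config$seed + SEED_OFF[["gene_sets"]])
  sets <- list(PLANTED_ACTIVATED_TARGETS = genes$gene_id[genes$class == "activated"],
               PLANTED_REPRESSED_TARGETS = genes$gene_id[genes$class == "repressed"])
  for (i in seq_len(config$n_random_gene_sets)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sort(sample(genes$gene_id, min(sample(50:200, 1), nrow(genes) %/% 2)))
  }
  attr(sets, "description") <- setNames(rep("synthetic", length(sets)), names(sets))
  sets
}

# Coverage bin sets: windows around every true-peak summit and every
# gene TSS (promoter-proximal signal exists genome-wide, so the planted
# effect is a small fraction of total library mass). Returns, per
# chromosome, sorted unique 0-based bin indices.
coverage_bins <- function(config, genes, peaks) {
  bs <- config$bin_size
  fl <- config$coverage_flank
  anchors <- rbind(
    data.frame(chrom = peaks$chrom[peaks$label != "decoy"],
               pos = peaks$summit[peaks$label != "decoy"]),
    data.frame(chrom = genes$chrom, pos = genes$tss))
  out <- list()
  for (cn in paste0("chr", seq_len(config$n_chroms))) {
    a <- anchors[anchors$chrom == cn, , drop = FALSE]
    if (!nrow(a)) { out[[cn]] <- integer() ; next }
    b1 <- floor(pmax(a$pos - fl, 0) / bs)
    b2 <- floor((pmin(a$pos + fl, config$chrom_length) - 1) / bs)
    bins <- unlist(mapply(seq.int, b1, b2, SIMPLIFY = FALSE), use.names = FALSE)
    out[[cn]] <- sort(unique(bins))
  }
  out
}

# Bins carrying the planted multiplicative effect: centres within
# effect_halfwidth of an activating summit.
effect_bins <- function(config, peaks) {
  bs <- config$bin_size
  hw <- config$effect_halfwidth
  s <- peaks[peaks$label == "activating", , drop = FALSE]
  out <- list()
  for (cn in unique(s$chrom)) {
    su <- s$summit[s$chrom == cn]
    k <- floor(hw / bs)
    bins <- unlist(lapply(su, function(x) {
      ctr <- floor(x / bs)  # summit sits at this bin's centre (grid-snapped)
      (ctr - k):(ctr + k)
    }), use.names = FALSE)
    # keep bins whose centre is truly within the half-width
    ctrs <- bins * bs + bs / 2
    sumrep <- rep(su, each = 2 * k + 1)
    out[[cn]] <- sort(unique(bins[abs(ctrs - sumrep) <= hw]))
  }
  out
}

sim_coverage <- function(config, genes, peaks, outdir) {
  bins <- coverage_bins(config, genes, peaks)
  eff <- effect_bins(config, peaks)
  effects <- c(h3k4me3 = config$planted_h3k4me3_log2fc,
               h3k27me3 = config$planted_h3k27me3_log2fc,
               ezh2 = config$planted_ezh2_log2fc)
  conds <- c("oc2", "ddbd")
  paths <- character()
  idx <- 0L
  for (mark in names(effects)) {
    for (cond in conds) {
      idx <- idx + 1L
      set.seed(config$seed + SEED_OFF[["coverage"]] + idx)
      path <- file.path(outdir, sprintf("coverage_%s_%s.bedGraph", mark, cond))
      con <- file(path, "w")
      for (cn in names(bins)) {
        b <- bins[[cn]]
        if (!length(b)) next
        v <- rgamma(length(b), shape = config$background_shape,
                    scale = config$background_scale)
        if (cond == "oc2" && length(eff[[cn]]))
          v[b %in% eff[[cn]]] <- v[b %in% eff[[cn]]] * 2^effects[[mark]]
        writeLines(sprintf("%s\t%d\t%d\t%s", cn, b * config$bin_size,
                           (b + 1L) * config$bin_size, num_chr(v, 10L)), con)
      }
      close(con)
      paths[sprintf("%s_%s", mark, cond)] <- path
    }
  }
  paths
}

#' Simulate a patient cohort with a context-confined survival effect
#'
#' Patients carry oncogenic-alteration flags for the RAS-pathway
#' classification genes and a TP53 loss-of-function flag; expression is
#' log-normal; survival is exponential, with the hazard multiplied by
#' `hazard_ratio_high_expression` only for patients who are RAS-driven
#' AND TP53-LOF AND in the upper expression quartile of that subgroup.
#' Censoring is independent exponential.
#'
#' @param config a [simulation_config()]
#' @return cohort data.frame (see [read_cohort()] for the schema) with a
#'   `manifest` attribute recording each patient's planted subgroup,
#'   stratum and risk flag
#' @export
simulate_cohort <- function(config) {
  if (config$n_patients < 8)
    stop_fmt("n_patients must be at least 8 for quartile stratification")
  set.seed(config$seed + SEED_OFF[["cohort"]])
  n <- config$n_patients
  gl <- ras_gene_lists()
  u <- runif(n)
  subgroup <- ifelse(u < config$frac_ras_driven, "ras_driven",
                     ifelse(u < config$frac_ras_driven + config$frac_ras_activated_extra,
                            "ras_activated_only", "none"))
  flags <- matrix(FALSE, n, length(gl$ras_activated),
                  dimnames = list(NULL, gl$ras_activated))
  drv <- which(subgroup == "ras_driven")
  if (length(drv)) {
    g <- ifelse(runif(length(drv)) < 0.7, "KRAS",
                sample(c("NRAS", "HRAS", "RIT1", "NF1"), length(drv), replace = TRUE))
    flags[cbind(drv, match(g, colnames(flags)))] <- TRUE
  }
  act <- which(subgroup == "ras_activated_only")
  if (length(act)) {
    g <- sample(c("EGFR", "ERBB2", "MET", "BRAF", "MAP2K1"), length(act),
                replace = TRUE, prob = c(0.5, 0.1, 0.1, 0.2, 0.1))
    flags[cbind(act, match(g, colnames(flags)))] <- TRUE
  }
  tp53 <- runif(n) < config$frac_tp53_lof
  expr <- stats::rlnorm(n, meanlog = 2, sdlog = 0.7)
  ctx <- subgroup == "ras_driven" & tp53
  risk <- rep(FALSE, n)
  stratum <- rep(NA_character_, n)
  if (any(ctx)) {
    q3 <- as.numeric(quantile(expr[ctx], 0.75, type = 7))
    stratum[ctx] <- ifelse(expr[ctx] >= q3, "high", "low")
    risk <- ctx & expr >= q3
  }
  rate <- config$baseline_hazard *
    ifelse(risk, config$hazard_ratio_high_expression, 1)
  t_event <- rexp(n, rate)
  cr <- config$censoring_rate
  if (cr > 0) {
    mu <- config$baseline_hazard * cr / (1 - cr)
    t_cens <- rexp(n, mu)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  cohort <- data.frame(sample_id = sprintf("PT%04d", seq_len(n)),
                       expression = expr, tp53_lof = tp53,
                       time = round(time, 2), event = event,
                       stringsAsFactors = FALSE)
  for (g in colnames(flags)) cohort[[paste0("alt_", g)]] <- flags[, g]
  attr(cohort, "manifest") <- data.frame(sample_id = cohort$sample_id,
                                         subgroup = subgroup,
                                         tp53_lof = tp53,
                                         stratum = stratum,
                                         planted_risk = risk,
                                         stringsAsFactors = FALSE)
  cohort
}

#' Simulate a complete synthetic study
#'
#' Writes, under `outdir`: `genes.gtf`, `segmentation.bed`,
#' `peaks.narrowPeak`, six `coverage_<mark>_<cond>.bedGraph` files
#' (H3K4me3/H3K27me3/EZH2 x overexpression `oc2` vs DNA-binding-dead
#' control `ddbd`), `expression.tsv`, `gene_sets.gmt` (first set = the
#' planted activated targets), `cohort.tsv` and `manifest.json`. The same
#' config and seed always reproduce byte-identical files.
#'
#' @param config a [simulation_config()]
#' @param outdir output directory (created if needed)
#' @return the ground-truth manifest (list), invisibly; also written as
#'   JSON alongside the data
#' @export
simulate_study <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genes <- sim_genes(config)
  peaks <- sim_peaks(config, genes)
  seg <- sim_segmentation(config, genes, peaks)
  expr <- sim_expression(config, genes)
  sets <- sim_gene_sets(config, genes)
  cohort <- simulate_cohort(config)

  gt <- genes[c("gene_id", "chrom", "start", "end", "strand", "tss")]
  class(gt) <- c("gene_table", "data.frame")
  write_gene_annotation(gt, file.path(outdir, "genes.gtf"))
  write_segmentation(list(segments = seg$segments, alphabet = roadmap15_states()),
                     file.path(outdir, "segmentation.bed"))
  pk <- peaks[c("peak_id", "chrom", "start", "end", "score", "strand",
                "fold_enrichment", "neg_log10_p", "neg_log10_q", "summit")]
  class(pk) <- c("peak_set", "data.frame")
  write_narrowpeak(pk, file.path(outdir, "peaks.narrowPeak"))
  cov_paths <- sim_coverage(config, genes, peaks, outdir)
  write_expression(expr, file.path(outdir, "expression.tsv"))
  write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
  write_cohort(cohort, file.path(outdir, "cohort.tsv"))

  manifest <- list(
    config = unclass(config),
    genes = data.frame(gene_id = genes$gene_id, class = genes$class,
                       tss_state = seg$tss_state,
                       tss_bivalent = seg$tss_state %in% bivalent_polycomb_states(),
                       stringsAsFactors = FALSE),
    peaks = data.frame(peak_id = peaks$peak_id, label = peaks$label,
                       target_gene = peaks$target_gene, summit = peaks$summit,
                       stringsAsFactors = FALSE),
    patients = attr(cohort, "manifest"),
    files = c(genes = "genes.gtf", segmentation = "segmentation.bed",
              peaks = "peaks.narrowPeak", expression = "expression.tsv",
              gene_sets = "gene_sets.gmt", cohort = "cohort.tsv",
              setNames(basename(cov_paths), paste0("coverage_", names(cov_paths)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", na = "null")
  invisible(manifest)
}
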