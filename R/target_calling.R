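# High-confidence peak filtering, summit-to-TSS assignment, target
# classification and peak labelling.
#
# Conventions: all three thresholds (p, fold enrichment, |log2FC|) are
# strict inequalities; the assignment window test is a closed ball
# |summit - tss| <= window; p-values are compared in -log10 space.

#' Filter peaks to the high-confidence set
#'
#' Keeps peaks with `neg_log10_p > -log10(p_threshold)` AND
#' `fold_enrichment > fold_threshold`, both strict, preserving input
#' order. Idempotent; the output is always a subset of the input.
#'
#' @param peaks a `peak_set`
#' @param p_threshold p-value threshold (default 1e-8)
#' @param fold_threshold fold-enrichment threshold (default 4)
#' @return the filtered `peak_set`
#' @export
filter_high_confidence <- function(peaks, p_threshold = 1e-8, fold_threshold = 4) {
  if (p_threshold <= 0 || fold_threshold <= 0) stop_fmt("thresholds must be > 0")
  keep <- peaks$neg_log10_p > -log10(p_threshold) &
    peaks$fold_enrichment > fold_threshold
  new_peak_set(peaks[keep, , drop = FALSE])
}

#' Assign peaks to genes within a TSS window
#'
#' Emits one row per (peak, gene) pair with `|summit - tss| <= window`
#' (closed ball; distances are summit-to-TSS). `signed_distance` is
#' strand-oriented: `summit - tss` for `+` genes and `tss - summit` for
#' `-` genes, so positive means downstream of the TSS. A peak may pair
#' with several genes and vice versa.
#'
#' @param peaks a `peak_set`
#' @param genes a `gene_table`
#' @param window half-width of the assignment window in bp (default 1e5)
#' @return data.frame with `peak_id`, `gene_id`, `signed_distance`
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 100000) {
  if (window <= 0) stop_fmt("window must be > 0")
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      signed_distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(genes)) return(empty)
  res <- vector("list", length(unique(genes$chrom)))
  k <- 0L
  for (cn in unique(genes$chrom)) {
    g <- genes[genes$chrom == cn, , drop = FALSE]
    p <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (!nrow(p)) next
    og <- order(g$tss)
    g <- g[og, , drop = FALSE]
    # for each peak, genes with tss in [summit - window, summit + window]
    lo <- findInterval(p$summit - window, g$tss, left.open = TRUE) + 1L
    hi <- findInterval(p$summit + window, g$tss)
    n_hit <- pmax(hi - lo + 1L, 0L)
    if (!sum(n_hit)) next
    pi <- rep.int(seq_len(nrow(p)), n_hit)
    gi <- unlist(lapply(which(n_hit > 0L), function(i) lo[i]:hi[i]), use.names = FALSE)
    raw <- p$summit[pi] - g$tss[gi]
    sd_ <- ifelse(g$strand[gi] == "+", raw, -raw)
    k <- k + 1L
    res[[k]] <- data.frame(peak_id = p$peak_id[pi], gene_id = g$gene_id[gi],
                           signed_distance = sd_, stringsAsFactors = FALSE)
  }
  if (!k) return(empty)
  out <- do.call(rbind, res[seq_len(k)])
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify genes as activated or repressed targets
#'
#' A gene is an *activated* target when it has at least one assigned
#' high-confidence peak, is flagged significant, and has
#' `log2fc > up_lfc` (strict); *repressed* symmetrically with
#' `log2fc < down_lfc`; otherwise `none`. Assigned genes missing from the
#' expression table are classed `none` with a warning.
#'
#' @param assignment output of [assign_peaks_to_genes()] run on the
#'   high-confidence peak set
#' @param expression data.frame with `gene_id`, `log2fc`, `is_significant`
#' @param up_lfc log2FC threshold for activation (default 2)
#' @param down_lfc log2FC threshold for repression (default -2)
#' @return data.frame with `gene_id`, `class`
#'   (`activated`/`repressed`/`none`), `n_peaks`, `peak_ids`
#'   (comma-separated), `min_abs_distance`; one row per assigned gene
#' @export
classify_targets <- function(assignment, expression, up_lfc = 2, down_lfc = -2) {
  if (up_lfc <= down_lfc) stop_fmt("up_lfc must exceed down_lfc")
  if (!nrow(assignment)) {
    return(data.frame(gene_id = character(), class = character(),
                      n_peaks = integer(), peak_ids = character(),
                      min_abs_distance = numeric(), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(assignment)
  per_gene <- dt[, list(n_peaks = .N,
                        peak_ids = paste(sort(unique(peak_id)), collapse = ","),
                        min_abs_distance = min(abs(signed_distance))),
                 by = "gene_id"]
  per_gene <- as.data.frame(per_gene)
  m <- match(per_gene$gene_id, expression$gene_id)
  missing <- is.na(m)
  if (any(missing))
    warn_fmt("%d assigned gene(s) missing from expression table; classed 'none'",
             sum(missing))
  lfc <- expression$log2fc[m]
  sig <- expression$is_significant[m]
  cls <- rep("none", nrow(per_gene))
  cls[!missing & sig & lfc > up_lfc] <- "activated"
  cls[!missing & sig & lfc < down_lfc] <- "repressed"
  out <- data.frame(gene_id = per_gene$gene_id, class = cls,
                    n_peaks = per_gene$n_peaks, peak_ids = per_gene$peak_ids,
                    min_abs_distance = per_gene$min_abs_distance,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label peaks as activating, repressive, ambiguous or unassigned
#'
#' A peak is *activating* when every target-classed gene it is assigned to
#' is activated, *repressive* when every one is repressed, *ambiguous*
#' when both classes occur among its genes, and *unassigned* when none of
#' its assigned genes is a target.
#'
#' @param peaks the `peak_set` the assignment was computed from
#' @param assignment output of [assign_peaks_to_genes()]
#' @param targets output of [classify_targets()]
#' @return data.frame with `peak_id`, `label`
#' @export
label_peaks <- function(peaks, assignment, targets) {
  lab <- rep("unassigned", nrow(peaks))
  if (nrow(assignment)) {
    cls <- targets$class[match(assignment$gene_id, targets$gene_id)]
    act <- unique(assignment$peak_id[!is.na(cls) & cls == "activated"])
    rep_ <- unique(assignment$peak_id[!is.na(cls) & cls == "repressed"])
    lab[peaks$peak_id %in% act] <- "activating"
    lab[peaks$peak_id %in% rep_] <- "repressive"
    lab[peaks$peak_id %in% intersect(act, rep_)] <- "ambiguous"
  }
  data.frame(peak_id = peaks$peak_id, label = lab, stringsAsFactors = FALSE)
}

#' Distance-to-TSS histogram over peak-gene assignments
#'
#' Histogram of `|signed_distance|` with half-open bins
#' `[e1, e2), [e2, e3), ...`; the last bin is closed on the right so a
#' distance exactly at the window edge is counted.
#'
#' @param assignment output of [assign_peaks_to_genes()]
#' @param bin_edges ascending bp edges starting at 0
#'   (default `c(0, 5000, 50000, 100000)`)
#' @return data.frame with `bin` (label), `lower`, `upper`, `count`,
#'   `fraction`
#' @export
distance_distribution <- function(assignment, bin_edges = c(0, 5000, 50000, 100000)) {
  if (is.unsorted(bin_edges, strictly = TRUE) || bin_edges[1] != 0)
    stop_fmt("bin_edges must be strictly ascending and start at 0")
  d <- abs(assignment$signed_distance)
  if (length(d) && any(d > bin_edges[length(bin_edges)]))
    stop_fmt("distance beyond last bin edge")
  nb <- length(bin_edges) - 1L
  idx <- findInterval(d, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin = sprintf("[%g,%g%s", bin_edges[-length(bin_edges)],
                           bin_edges[-1], c(rep(")", nb - 1L), "]")),
             lower = bin_edges[-length(bin_edges)], upper = bin_edges[-1],
             count = counts,
             fraction = if (length(d)) counts / length(d) else rep(NA_real_, nb),
             stringsAsFactors = FALSE)
}

#' Run the full target-calling stage
#'
#' Convenience wrapper: high-confidence filter, assignment, target
#' classification, peak labels and the distance histogram in one call.
#'
#' @inheritParams filter_high_confidence
#' @inheritParams assign_peaks_to_genes
#' @inheritParams classify_targets
#' @param expression differential-expression data.frame
#' @return list with `hc_peaks`, `assignment`, `targets`, `peak_labels`,
#'   `distance_hist`
#' @export
call_targets <- function(peaks, genes, expression, p_threshold = 1e-8,
                         fold_threshold = 4, window = 100000,
                         up_lfc = 2, down_lfc = -2) {
  hc <- filter_high_confidence(peaks, p_threshold, fold_threshold)
  asn <- assign_peaks_to_genes(hc, genes, window)
  tg <- classify_targets(asn, expression, up_lfc, down_lfc)
  list(hc_peaks = hc,
       assignment = asn,
       targets = tg,
       peak_labels = label_peaks(hc, asn, tg),
       distance_hist = distance_distribution(asn, c(0, 5000, 50000, window)))
}
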