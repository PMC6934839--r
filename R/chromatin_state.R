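# Chromatin-state annotation of anchors (TSSs, peak summits): point
# queries against a segmentation, per-state fraction tables with a
# bivalent/Polycomb group summary, and positional state-composition
# profiles around anchors.

#' State at a single genomic position
#'
#' @param seg a `state_segmentation`
#' @param chrom chromosome name
#' @param pos 0-based position
#' @return state label, or `"Unannotated"` when the position falls in a
#'   gap of the segmentation
#' @export
state_at <- function(seg, chrom, pos) {
  states_at(seg, chrom, pos)[1]
}

#' Vectorised state lookup
#'
#' @param seg a `state_segmentation`
#' @param chrom chromosome names (recycled if length 1)
#' @param pos 0-based positions
#' @return character vector of state labels (`"Unannotated"` for gaps)
#' @export
states_at <- function(seg, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  s <- seg$segments
  known <- unique(s$chrom)
  bad <- setdiff(unique(chrom), known)
  if (length(bad))
    stop_fmt("chromosome(s) absent from segmentation: %s", paste(bad, collapse = ", "))
  out <- rep("Unannotated", length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    sc <- s[s$chrom == cn, , drop = FALSE]  # already sorted
    i <- findInterval(pos[sel], sc$start)
    hit <- i >= 1L & pos[sel] < sc$end[pmax(i, 1L)]
    out[sel][hit] <- sc$state[i[hit]]
  }
  out
}

#' Per-state fractions at a set of anchors
#'
#' Counts the chromatin state at each single anchor base and summarises
#' the fraction of anchors falling in a configurable bivalent/Polycomb
#' state group. Fractions (including `"Unannotated"`) sum to 1.
#'
#' @param anchors data.frame with `chrom`, `pos` (0-based anchor base;
#'   a TSS or a peak summit)
#' @param seg a `state_segmentation`
#' @param bivalent_group states counted into `group_fraction`
#'   (default [bivalent_polycomb_states()])
#' @return list with `table` (data.frame `state`, `count`, `fraction`,
#'   all alphabet states plus `"Unannotated"`), `group_fraction`,
#'   `n_anchors`
#' @export
state_fractions <- function(anchors, seg, bivalent_group = bivalent_polycomb_states()) {
  if (!nrow(anchors)) stop_fmt("no anchors given")
  st <- states_at(seg, anchors$chrom, anchors$pos)
  levels <- c(seg$alphabet, "Unannotated")
  counts <- table(factor(st, levels = levels))
  frac <- as.numeric(counts) / length(st)
  tab <- data.frame(state = levels, count = as.integer(counts), fraction = frac,
                    stringsAsFactors = FALSE)
  list(table = tab,
       group_fraction = sum(frac[levels %in% bivalent_group]),
       n_anchors = length(st))
}

#' Positional state-composition profile around anchors
#'
#' For each offset bin spanning `[-flank, +flank)` around the anchors
#' (strand-oriented when a `strand` column is present: negative offsets
#' are upstream), the fraction of anchors whose state at
#' `anchor + offset` is each label. Anchors whose full window would leave
#' the chromosome are dropped; the number dropped is reported.
#'
#' @param anchors data.frame with `chrom`, `pos` and optionally `strand`
#'   (summit anchors have no strand and are taken as `+`)
#' @param seg a `state_segmentation`
#' @param layout a `genome_layout` (for edge-dropping)
#' @param flank half-window in bp, a multiple of `bin` (default 2000)
#' @param bin offset bin width in bp (default 50); the state is queried at
#'   the centre base of each offset bin
#' @return list with `offsets` (bin-centre offsets in bp), `matrix`
#'   (offsets x states, rows sum to 1), `n_anchors`, `n_dropped`
#' @export
positional_state_profile <- function(anchors, seg, layout, flank = 2000, bin = 50) {
  if (flank %% bin != 0) stop_fmt("flank must be a multiple of bin")
  strand <- anchors$strand %||% rep("+", nrow(anchors))
  keep <- anchors$pos - flank >= 0 &
    anchors$pos + flank < layout$chrom_lengths[anchors$chrom]
  n_dropped <- sum(!keep)
  if (n_dropped) warn_fmt("%d anchor(s) dropped at chromosome edges", n_dropped)
  a <- anchors[keep, , drop = FALSE]
  strand <- strand[keep]
  if (!nrow(a)) stop_fmt("all anchors dropped at chromosome edges")
  offs <- seq(-flank, flank - bin, by = bin) + bin / 2  # bin centres
  levels <- c(seg$alphabet, "Unannotated")
  mat <- matrix(0, nrow = length(offs), ncol = length(levels),
                dimnames = list(NULL, levels))
  sgn <- ifelse(strand == "-", -1, 1)
  for (j in seq_along(offs)) {
    pos <- round(a$pos + sgn * offs[j])
    st <- states_at(seg, a$chrom, pos)
    cnt <- table(factor(st, levels = levels))
    mat[j, ] <- as.numeric(cnt) / nrow(a)
  }
  list(offsets = offs, matrix = mat, n_anchors = nrow(a), n_dropped = n_dropped)
}

#' Anchor tables for the standard groups of a target-calling run
#'
#' Builds the anchor sets whose chromatin context the pipeline reports:
#' TSSs of activated targets, repressed targets, all targets and all
#' genes, plus summits of activating and repressive peaks (ambiguous
#' peaks are excluded from the summit groups).
#'
#' @param genes a `gene_table`
#' @param targets output of [classify_targets()]
#' @param hc_peaks high-confidence `peak_set`
#' @param peak_labels output of [label_peaks()]
#' @return named list of anchor data.frames (`chrom`, `pos`, and `strand`
#'   for TSS groups)
#' @export
anchor_groups <- function(genes, targets, hc_peaks, peak_labels) {
  tss <- function(ids) {
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
    data.frame(chrom = g$chrom, pos = g$tss, strand = g$strand,
               name = g$gene_id, stringsAsFactors = FALSE)
  }
  summit <- function(lab) {
    p <- hc_peaks[hc_peaks$peak_id %in%
                    peak_labels$peak_id[peak_labels$label == lab], , drop = FALSE]
    data.frame(chrom = p$chrom, pos = p$summit, name = p$peak_id,
               stringsAsFactors = FALSE)
  }
  act <- targets$gene_id[targets$class == "activated"]
  rep_ <- targets$gene_id[targets$class == "repressed"]
  list(activated_tss = tss(act),
       repressed_tss = tss(rep_),
       target_tss = tss(c(act, rep_)),
       nontarget_tss = tss(setdiff(genes$gene_id, c(act, rep_))),
       all_gene_tss = tss(genes$gene_id),
       activating_summits = summit("activating"),
       repressive_summits = summit("repressive"))
}
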