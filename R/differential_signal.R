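# Differential histone-signal analysis: CPM-style library scaling,
# per-bin log2-ratio tracks between two conditions, metaprofiles and
# per-anchor heatmap matrices around anchors, and signal-loss region
# calling on log2-ratio tracks.

track_compatible <- function(a, b) {
  identical(names(a$values), names(b$values)) &&
    a$bin_size == b$bin_size &&
    all(lengths(a$values) == lengths(b$values))
}

#' Per-bin log2 ratio of two coverage tracks
#'
#' Each track is first scaled to counts-per-million equivalents
#' (`value * 1e6 / total_signal`), then the per-bin ratio
#' `log2((a' + c) / (b' + c))` is taken with pseudocount `c`. Scaling
#' makes the ratio invariant to global library-size factors;
#' antisymmetry holds exactly: `log2_ratio_track(a, b) ==
#' -log2_ratio_track(b, a)` for the same pseudocount.
#'
#' @param a,b `coverage_track`s on the same layout and bin size
#' @param pseudocount added to both scaled signals (default 1.0)
#' @return a `coverage_track` flagged as log2-ratio
#' @export
log2_ratio_track <- function(a, b, pseudocount = 1.0) {
  if (!track_compatible(a, b)) stop_fmt("tracks have mismatched layout or bin size")
  if (a$is_log2 || b$is_log2) stop_fmt("inputs must be raw (non-ratio) tracks")
  ta <- track_total(a)
  tb <- track_total(b)
  if (ta <= 0 || tb <= 0) stop_fmt("zero total signal in input track")
  sa <- 1e6 / ta
  sb <- 1e6 / tb
  vals <- mapply(function(va, vb) log2((va * sa + pseudocount) / (vb * sb + pseudocount)),
                 a$values, b$values, SIMPLIFY = FALSE)
  new_coverage_track(vals, a$layout, a$bin_size, is_log2 = TRUE)
}

# Per-anchor matrix of track values over strand-oriented offset bins.
# Anchors whose window leaves the chromosome are dropped.
extract_anchor_rows <- function(track, anchors, flank, keep) {
  bs <- track$bin_size
  nb <- as.integer(2 * flank / bs)
  a <- anchors[keep, , drop = FALSE]
  strand <- (anchors$strand %||% rep("+", nrow(anchors)))[keep]
  mat <- matrix(NA_real_, nrow = nrow(a), ncol = nb)
  for (cn in unique(a$chrom)) {
    sel <- which(a$chrom == cn)
    v <- track$values[[cn]]
    for (i in sel) {
      b0 <- floor((a$pos[i] - flank) / bs)
      row <- v[(b0 + 1L):(b0 + nb)]
      if (strand[i] == "-") row <- rev(row)
      mat[i, ] <- row
    }
  }
  rownames(mat) <- a$name %||% NULL
  mat
}

anchor_keep <- function(track, anchors, flank) {
  if (flank %% track$bin_size != 0) stop_fmt("flank must be a multiple of the bin size")
  lens <- track$layout$chrom_lengths[anchors$chrom]
  anchors$pos - flank >= 0 & anchors$pos + flank <= lens
}

#' Mean signal metaprofile around anchors
#'
#' Averages a (typically log2-ratio) track over strand-oriented windows
#' `[-flank, +flank)` centred on the anchors, one value per track bin.
#' Anchors whose window would leave the chromosome are dropped with a
#' warning.
#'
#' @param track a `coverage_track` (usually from [log2_ratio_track()])
#' @param anchors data.frame with `chrom`, `pos`, optional `strand`
#' @param flank half-window in bp, multiple of the track bin size
#'   (default 5000)
#' @param anchor_group label stored with the result
#' @return list with `offsets` (bin-centre offsets), `mean` (per-offset
#'   mean), `n_anchors`, `anchor_group`
#' @export
metaprofile <- function(track, anchors, flank = 5000, anchor_group = "anchors") {
  if (!nrow(anchors)) stop_fmt("no anchors given")
  keep <- anchor_keep(track, anchors, flank)
  if (any(!keep)) warn_fmt("%d anchor(s) dropped at chromosome edges", sum(!keep))
  if (!any(keep)) stop_fmt("all anchors dropped at chromosome edges")
  mat <- extract_anchor_rows(track, anchors, flank, keep)
  bs <- track$bin_size
  list(offsets = seq(-flank, flank - bs, by = bs) + bs / 2,
       mean = colMeans(mat),
       n_anchors = nrow(mat),
       anchor_group = anchor_group)
}

#' Per-anchor signal matrix (heatmap substrate)
#'
#' One row per anchor, one column per offset bin; column means reproduce
#' the metaprofile of the same anchors. Optionally sorted by row mean
#' ascending (ties broken by anchor name so the order is independent of
#' input order).
#'
#' @inheritParams metaprofile
#' @param sort_by `"mean"` (row mean ascending) or `"none"` (input order)
#' @return list with `offsets`, `matrix`, `anchor_names`, `n_dropped`
#' @export
anchor_matrix <- function(track, anchors, flank = 5000, sort_by = c("mean", "none")) {
  sort_by <- match.arg(sort_by)
  if (!nrow(anchors)) stop_fmt("no anchors given")
  keep <- anchor_keep(track, anchors, flank)
  if (any(!keep)) warn_fmt("%d anchor(s) dropped at chromosome edges", sum(!keep))
  if (!any(keep)) stop_fmt("all anchors dropped at chromosome edges")
  mat <- extract_anchor_rows(track, anchors, flank, keep)
  if (sort_by == "mean") {
    key <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
    mat <- mat[order(rowMeans(mat), key), , drop = FALSE]
  }
  bs <- track$bin_size
  list(offsets = seq(-flank, flank - bs, by = bs) + bs / 2,
       matrix = mat,
       anchor_names = rownames(mat),
       n_dropped = sum(!keep))
}

#' Call signal-loss regions on a log2-ratio track
#'
#' Maximal runs of bins at or below `threshold`, merging runs separated
#' by at most `max_gap` bins and keeping merged regions of width at least
#' `min_width` bp. The track must be a log2-ratio track.
#'
#' @param track a log2-ratio `coverage_track`
#' @param threshold log2-ratio at/below which a bin counts as loss
#'   (default -1.0)
#' @param max_gap maximum number of above-threshold bins bridged when
#'   merging adjacent runs (default 2)
#' @param min_width minimum region width in bp (default 500)
#' @return data.frame in BED order: `chrom`, `start`, `end`
#' @export
call_loss_regions <- function(track, threshold = -1.0, max_gap = 2L, min_width = 500) {
  if (!track$is_log2) stop_fmt("loss regions are called on log2-ratio tracks")
  bs <- track$bin_size
  out <- list()
  for (cn in names(track$values)) {
    low <- track$values[[cn]] <= threshold
    if (!any(low)) next
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by <= max_gap bins
    if (nrow(runs) > 1L) {
      gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
      grp <- cumsum(c(0L, gap > max_gap))
      runs <- data.frame(start = tapply(runs$start, grp, min),
                         end = tapply(runs$end, grp, max))
    }
    width <- (runs$end - runs$start + 1L) * bs
    runs <- runs[width >= min_width, , drop = FALSE]
    if (!nrow(runs)) next
    out[[cn]] <- data.frame(chrom = cn, start = (runs$start - 1L) * bs,
                            end = pmin(runs$end * bs, track$layout$chrom_lengths[[cn]]),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Jaccard index of two interval sets
#'
#' Base-pair Jaccard: intersection length over union length of the two
#' (internally merged) interval sets; used e.g. to quantify
#' co-localisation of EZH2-loss and H3K27me3-loss regions.
#'
#' @param a,b data.frames with `chrom`, `start`, `end`
#' @return scalar in `[0, 1]` (`NA` when both sets are empty)
#' @export
interval_jaccard <- function(a, b) {
  merge_one <- function(df) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    split(df, df$chrom)
  }
  cov_len <- function(df) {
    if (!nrow(df)) return(0)
    sum(df$end - df$start)
  }
  inter_len <- function(da, db) {
    if (!nrow(da) || !nrow(db)) return(0)
    tot <- 0
    j <- 1L
    for (i in seq_len(nrow(da))) {
      while (j <= nrow(db) && db$end[j] <= da$start[i]) j <- j + 1L
      k <- j
      while (k <= nrow(db) && db$start[k] < da$end[i]) {
        tot <- tot + min(da$end[i], db$end[k]) - max(da$start[i], db$start[k])
        k <- k + 1L
      }
    }
    tot
  }
  la <- merge_one(a)
  lb <- merge_one(b)
  chroms <- union(names(la), names(lb))
  inter <- sum(vapply(chroms, function(cn) {
    da <- la[[cn]]
    db <- lb[[cn]]
    if (is.null(da) || is.null(db)) 0 else inter_len(da, db)
  }, numeric(1)))
  total_a <- sum(vapply(la, cov_len, numeric(1)))
  total_b <- sum(vapply(lb, cov_len, numeric(1)))
  uni <- total_a + total_b - inter
  if (uni == 0) return(NA_real_)
  inter / uni
}
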