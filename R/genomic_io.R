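# Domain containers and readers/writers for the genomic formats the
# pipeline touches: GTF/BED gene annotation, ENCODE narrowPeak, 4-column
# ChromHMM-style segmentation BED, bedGraph coverage, and GMT gene sets.
#
# All intervals are 0-based half-open internally (BED convention); GTF is
# converted on read (1-based closed starts minus one).

#' Roadmap 15-state chromatin-state alphabet
#'
#' The state labels of the 15-state Roadmap Epigenomics ChromHMM model, the
#' default vocabulary for segmentations. `"Unannotated"` is reserved for
#' genomic gaps and is always accepted in addition to the alphabet.
#' @return character vector of 15 state labels
#' @export
roadmap15_states <- function() {
  c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh", "ZNF.Rpts",
    "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

#' Default bivalent/Polycomb state group
#'
#' States counted as "bivalent or Polycomb-repressed" when summarising
#' chromatin context at TSSs and peak summits: the three bivalent states
#' plus strong and weak Polycomb repression.
#' @return character vector of 5 state labels
#' @export
bivalent_polycomb_states <- function() {
  c("TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk")
}

#' Construct a genome layout
#'
#' An ordered set of chromosome names and lengths; the coordinate backbone
#' every other container is validated against.
#'
#' @param chrom_names character vector of unique chromosome names
#' @param chrom_lengths positive integer lengths in bp, one per chromosome
#' @return object of class `genome_layout` with fields `chrom_names`,
#'   `chrom_lengths` (named)
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names)) stop_fmt("duplicate chromosome names")
  if (length(chrom_lengths) != length(chrom_names))
    stop_fmt("chrom_names and chrom_lengths differ in length")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop_fmt("chromosome lengths must be positive")
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = setNames(chrom_lengths, chrom_names)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %.3g Mb total\n",
              length(x$chrom_names), sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

layout_check_chrom <- function(layout, chrom) {
  bad <- setdiff(unique(chrom), layout$chrom_names)
  if (length(bad)) stop_fmt("unknown chromosome(s): %s", paste(bad, collapse = ", "))
  invisible(TRUE)
}

## ---- gene annotation ------------------------------------------------------

new_gene_table <- function(df) {
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "tss") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop_fmt("duplicate gene_id in gene table")
  if (any(df$start >= df$end)) stop_fmt("gene with start >= end")
  if (!all(df$strand %in% c("+", "-"))) stop_fmt("strand must be '+' or '-'")
  plus <- df$strand == "+"
  if (any(df$tss[plus] != df$start[plus]) ||
      any(df$tss[!plus] != df$end[!plus] - 1))
    stop_fmt("tss inconsistent with strand convention")
  invisible(df)
}

parse_gtf_attr <- function(attr, key) {
  pat <- paste0(key, ' "([^"]*)"')
  m <- regmatches(attr, regexec(pat, attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Read gene annotation from GTF or BED6
#'
#' Produces one record per gene with a single derived TSS. For multi-
#' transcript GTF genes the TSS is the 5'-most transcript start on the
#' gene's strand: `min(start)` for `+` genes, `max(end) - 1` for `-` genes
#' (0-based; the TSS is the last covered base of a minus-strand gene, so it
#' always lies inside the gene interval). GTF coordinates (1-based closed)
#' are converted to 0-based half-open on read.
#'
#' @param path file path
#' @param format `"gtf"` (rows with feature `gene` and/or `transcript`) or
#'   `"bed"` (BED6: chrom, start, end, name, score, strand)
#' @return a `gene_table` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, sorted by (chrom, start)
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- new_gene_table(data.frame(gene_id = character(), chrom = character(),
                                     start = numeric(), end = numeric(),
                                     strand = character(), tss = numeric(),
                                     stringsAsFactors = FALSE))
  if (!length(lines)) return(empty)

  if (format == "bed") {
    fl <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fl)
    if (any(nf < 6L))
      stop_fmt("malformed BED6 row at line %d (needs 6 fields)", which(nf < 6L)[1])
    df <- data.frame(gene_id = vapply(fl, `[`, "", 4L),
                     chrom   = vapply(fl, `[`, "", 1L),
                     start   = as.numeric(vapply(fl, `[`, "", 2L)),
                     end     = as.numeric(vapply(fl, `[`, "", 3L)),
                     strand  = vapply(fl, `[`, "", 6L),
                     stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end))
      stop_fmt("malformed BED coordinates at line %d", which(is.na(df$start) | is.na(df$end))[1])
    if (anyDuplicated(df$gene_id)) stop_fmt("duplicate gene_id in BED annotation")
    df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
    return(new_gene_table(validate_gene_table(df)))
  }

  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf < 9L))
    stop_fmt("malformed GTF row at line %d (needs 9 fields)", which(nf < 9L)[1])
  feat <- vapply(fl, `[`, "", 3L)
  keep <- feat %in% c("gene", "transcript")
  fl <- fl[keep]
  if (!length(fl)) return(empty)
  feat <- feat[keep]
  chrom  <- vapply(fl, `[`, "", 1L)
  start1 <- as.numeric(vapply(fl, `[`, "", 4L))
  end1   <- as.numeric(vapply(fl, `[`, "", 5L))
  strand <- vapply(fl, `[`, "", 7L)
  gid    <- parse_gtf_attr(vapply(fl, `[`, "", 9L), "gene_id")
  if (anyNA(gid)) stop_fmt("GTF row without gene_id attribute (line %d of kept rows)",
                           which(is.na(gid))[1])
  if (anyNA(start1) || anyNA(end1)) stop_fmt("malformed GTF coordinates")
  start <- start1 - 1  # 1-based closed -> 0-based half-open
  end <- end1

  # strand conflicts are hard errors
  st_by_gene <- tapply(strand, gid, unique)
  conflicted <- names(st_by_gene)[lengths(st_by_gene) > 1L]
  if (length(conflicted))
    stop_fmt("gene_id with conflicting strand: %s", paste(conflicted, collapse = ", "))

  # Prefer transcript rows for TSS derivation; fall back to the gene row.
  use <- if (any(feat == "transcript")) feat == "transcript" else rep(TRUE, length(feat))
  dt <- data.table::data.table(gene_id = gid[use], chrom = chrom[use],
                               start = start[use], end = end[use],
                               strand = strand[use])
  agg <- dt[, list(chrom = chrom[1L], start = min(start), end = max(end),
                   strand = strand[1L]), by = "gene_id"]
  df <- as.data.frame(agg)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  new_gene_table(validate_gene_table(df))
}

#' Write gene annotation as GTF (gene features)
#'
#' Inverse of [read_gene_annotation()] for single-isoform tables: one
#' `gene` row per record, converting back to 1-based closed coordinates.
#'
#' @param genes a `gene_table`
#' @param path output path
#' @param source source field for column 2
#' @return `path`, invisibly
#' @export
write_gene_annotation <- function(genes, path, source = "bivalentscan") {
  rows <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                  genes$chrom, source, as.integer(genes$start + 1),
                  as.integer(genes$end), genes$strand, genes$gene_id)
  writeLines(rows, path)
  invisible(path)
}

## ---- narrowPeak -----------------------------------------------------------

new_peak_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read an ENCODE narrowPeak file
#'
#' BED6+4: chrom, start, end, name, score, strand, signalValue, pValue
#' (as -log10), qValue (as -log10), summit offset from start. The summit
#' offset `-1` (unknown, as emitted by MACS2 without `--call-summits`)
#' falls back to the interval midpoint `start + floor((end-start)/2)`.
#' `fold_enrichment` is taken from signalValue and `neg_log10_p` from
#' column 8.
#'
#' @param path file path
#' @return a `peak_set` data.frame with columns `peak_id`, `chrom`,
#'   `start`, `end`, `score`, `strand`, `fold_enrichment`, `neg_log10_p`,
#'   `neg_log10_q`, `summit` (absolute bp)
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(new_peak_set(data.frame(peak_id = character(), chrom = character(),
                                   start = numeric(), end = numeric(),
                                   score = numeric(), strand = character(),
                                   fold_enrichment = numeric(),
                                   neg_log10_p = numeric(),
                                   neg_log10_q = numeric(),
                                   summit = numeric(), stringsAsFactors = FALSE)))
  }
  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf != 10L))
    stop_fmt("malformed narrowPeak row at line %d (needs 10 fields)", which(nf != 10L)[1])
  g <- function(i) vapply(fl, `[`, "", i)
  df <- data.frame(peak_id = g(4L), chrom = g(1L),
                   start = as.numeric(g(2L)), end = as.numeric(g(3L)),
                   score = as.numeric(g(5L)), strand = g(6L),
                   fold_enrichment = as.numeric(g(7L)),
                   neg_log10_p = as.numeric(g(8L)),
                   neg_log10_q = as.numeric(g(9L)),
                   offset = as.numeric(g(10L)), stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad)) stop_fmt("narrowPeak row %d has end <= start", bad[1])
  bad <- which(df$offset >= df$end - df$start)
  if (length(bad)) stop_fmt("narrowPeak row %d has summit offset beyond interval", bad[1])
  bad <- which(df$offset < -1)
  if (length(bad)) stop_fmt("narrowPeak row %d has summit offset < -1", bad[1])
  if (any(df$neg_log10_p < 0)) stop_fmt("negative -log10 p in narrowPeak")
  if (any(df$fold_enrichment < 0)) stop_fmt("negative fold enrichment in narrowPeak")
  df$summit <- ifelse(df$offset == -1,
                      df$start + floor((df$end - df$start) / 2),
                      df$start + df$offset)
  df$offset <- NULL
  new_peak_set(df)
}

#' Write a peak set as ENCODE narrowPeak
#'
#' Inverse of [read_narrowpeak()]; the summit is re-expressed as an offset
#' from the interval start.
#'
#' @param peaks a `peak_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_narrowpeak <- function(peaks, path) {
  rows <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%d",
                  peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                  peaks$peak_id, num_chr(peaks$score), peaks$strand,
                  num_chr(peaks$fold_enrichment), num_chr(peaks$neg_log10_p),
                  num_chr(peaks$neg_log10_q),
                  as.integer(peaks$summit - peaks$start))
  writeLines(rows, path)
  invisible(path)
}

## ---- chromatin-state segmentation ----------------------------------------

new_segmentation <- function(df, alphabet) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(segments = df, alphabet = alphabet), class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("state_segmentation: %d segments, %d-state alphabet\n",
              nrow(x$segments), length(x$alphabet)))
  invisible(x)
}

#' Read a ChromHMM-style segmentation BED
#'
#' 4-column BED (chrom, start, end, state). Segments on each chromosome
#' must be non-overlapping; gaps are permitted and are treated as the
#' reserved state `"Unannotated"` by downstream queries.
#'
#' @param path file path
#' @param alphabet allowed state labels (default the 15-state Roadmap set)
#' @return a `state_segmentation` object (fields `segments`, `alphabet`)
#' @export
read_segmentation <- function(path, alphabet = roadmap15_states()) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     state = character(), stringsAsFactors = FALSE)
    return(new_segmentation(df, alphabet))
  }
  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf < 4L))
    stop_fmt("malformed segmentation row at line %d (needs 4 fields)", which(nf < 4L)[1])
  df <- data.frame(chrom = vapply(fl, `[`, "", 1L),
                   start = as.numeric(vapply(fl, `[`, "", 2L)),
                   end   = as.numeric(vapply(fl, `[`, "", 3L)),
                   state = vapply(fl, `[`, "", 4L), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop_fmt("segmentation row with start >= end")
  bad <- setdiff(unique(df$state), alphabet)
  if (length(bad)) stop_fmt("unknown state label(s): %s", paste(bad, collapse = ", "))
  seg <- new_segmentation(df, alphabet)
  s <- seg$segments
  ov <- s$chrom[-1] == s$chrom[-nrow(s)] & s$start[-1] < s$end[-nrow(s)]
  if (nrow(s) > 1 && any(ov))
    stop_fmt("overlapping segments on %s near %d", s$chrom[-1][ov][1],
             as.integer(s$start[-1][ov][1]))
  seg
}

#' Write a segmentation as 4-column BED
#' @param seg a `state_segmentation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_segmentation <- function(seg, path) {
  s <- seg$segments
  writeLines(sprintf("%s\t%d\t%d\t%s", s$chrom, as.integer(s$start),
                     as.integer(s$end), s$state), path)
  invisible(path)
}

## ---- coverage tracks ------------------------------------------------------

new_coverage_track <- function(values, layout, bin_size, is_log2 = FALSE) {
  structure(list(values = values, layout = layout, bin_size = bin_size,
                 is_log2 = is_log2), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: bin %d bp, %d chromosome(s), total signal %.4g%s\n",
              x$bin_size, length(x$values), track_total(x),
              if (x$is_log2) " [log2-ratio]" else ""))
  invisible(x)
}

n_bins <- function(layout, bin_size) ceiling(layout$chrom_lengths / bin_size)

track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

#' Read a bedGraph file into a fixed-bin coverage track
#'
#' Each output bin holds the length-weighted mean of the bedGraph values
#' over the bin, with uncovered bases contributing 0 (equivalently: the
#' bin's total value-mass divided by `bin_size`). Intervals may be
#' unsorted and may span bin boundaries; mass is conserved exactly:
#' `sum(bins) * bin_size == sum(value * length)`.
#'
#' @param path file path
#' @param layout a `genome_layout`
#' @param bin_size bin width in bp
#' @return a `coverage_track` (per-chromosome numeric vectors of length
#'   `ceiling(chrom_length / bin_size)`)
#' @export
read_bedgraph <- function(path, layout, bin_size = 50L) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  stopifnot(bin_size >= 1)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1, numeric = 2:4))
  layout_check_chrom(layout, dt$chrom)
  vals <- lapply(layout$chrom_names, function(cn) {
    numeric(ceiling(layout$chrom_lengths[[cn]] / bin_size))
  })
  names(vals) <- layout$chrom_names
  if (nrow(dt)) {
    if (any(dt$end <= dt$start)) stop_fmt("bedGraph interval with end <= start")
    over <- dt$end > layout$chrom_lengths[dt$chrom]
    if (any(over))
      stop_fmt("bedGraph interval beyond chromosome length on %s", dt$chrom[over][1])
    for (cn in unique(dt$chrom)) {
      d <- dt[dt$chrom == cn]
      acc <- vals[[cn]]
      b1 <- floor(d$start / bin_size)
      b2 <- floor((d$end - 1) / bin_size)
      same <- b1 == b2
      if (any(same)) {
        add <- rowsum((d$value * (d$end - d$start))[same], b1[same])
        idx <- as.integer(rownames(add)) + 1L
        acc[idx] <- acc[idx] + add[, 1]
      }
      if (any(!same)) {
        for (i in which(!same)) {
          bins <- b1[i]:b2[i]
          lo <- pmax(d$start[i], bins * bin_size)
          hi <- pmin(d$end[i], (bins + 1) * bin_size)
          acc[bins + 1L] <- acc[bins + 1L] + d$value[i] * (hi - lo)
        }
      }
      vals[[cn]] <- acc
    }
    vals <- lapply(vals, function(v) v / bin_size)
  }
  new_coverage_track(vals, layout, as.integer(bin_size))
}

#' Write a coverage track as bedGraph
#'
#' One row per non-zero bin (log2-ratio tracks keep explicit zeros only if
#' `keep_zero = TRUE`); adjacent equal-valued bins are not merged so the
#' file is a faithful per-bin dump.
#'
#' @param track a `coverage_track`
#' @param path output path
#' @param keep_zero write zero-valued bins too
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    idx <- if (keep_zero) seq_along(v) else which(v != 0)
    if (!length(idx)) next
    start <- (idx - 1) * bs
    end <- pmin(idx * bs, track$layout$chrom_lengths[[cn]])
    writeLines(sprintf("%s\t%d\t%d\t%s", cn, as.integer(start),
                       as.integer(end), num_chr(v[idx], 10L)), con)
  }
  invisible(path)
}

## ---- expression tables ----------------------------------------------------

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `is_significant`
#' (0/1 or TRUE/FALSE). Gene ids must be unique.
#'
#' @param path file path
#' @return data.frame with those three columns
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "log2fc", "is_significant")
  if (!all(need %in% names(df)))
    stop_fmt("expression table must have columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  df$is_significant <- as.logical(df$is_significant)
  if (anyDuplicated(df$gene_id)) stop_fmt("duplicate gene_id in expression table")
  if (any(!is.finite(df$log2fc))) stop_fmt("non-finite log2fc in expression table")
  df
}

#' Write a differential-expression table
#' @param expr data.frame with `gene_id`, `log2fc`, `is_significant`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(gene_id = expr$gene_id, log2fc = expr$log2fc,
                    is_significant = as.integer(expr$is_significant))
  write_tsv(out, path)
}

## ---- GMT gene sets --------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then members. Duplicate
#' members within a set are dropped (first occurrence kept); duplicate set
#' names or empty member lists are errors.
#'
#' @param path file path
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (length(fl) && any(nf < 3L))
    stop_fmt("GMT line %d has no members", which(nf < 3L)[1])
  nm <- vapply(fl, `[`, "", 1L)
  if (anyDuplicated(nm)) stop_fmt("duplicate gene-set name: %s", nm[duplicated(nm)][1])
  sets <- lapply(fl, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fl, `[`, "", 2L), nm)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gmt()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("na", length(sets)), names(sets))
  rows <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
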