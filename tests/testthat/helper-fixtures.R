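# Shared fixture builders. Everything is generated in code; file-based
# fixtures are written to tempfiles at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small peak set built through the narrowPeak reader so tests exercise
# the same constructor users do.
make_peaks <- function(chrom, start, end, summit_offset, fold, nlp,
                       q = nlp - 0.5, id = NULL) {
  n <- length(start)
  id <- id %||% sprintf("pk%d", seq_len(n))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%g\t%g\t%g\t%d",
                   chrom, as.integer(start), as.integer(end), id, fold, nlp, q,
                   as.integer(summit_offset))
  read_narrowpeak(write_lines_tmp(lines, ".narrowPeak"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_genes <- function(chrom, start, end, strand, id = NULL) {
  n <- length(start)
  id <- id %||% sprintf("g%d", seq_len(n))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, as.integer(start),
                   as.integer(end), id, strand)
  read_gene_annotation(write_lines_tmp(lines, ".bed"), "bed")
}

make_segmentation <- function(chrom, start, end, state,
                              alphabet = roadmap15_states()) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, start, end, state)
  read_segmentation(write_lines_tmp(lines, ".bed"), alphabet)
}

make_track <- function(values_by_chrom, bin_size = 50) {
  lens <- vapply(values_by_chrom, function(v) length(v) * bin_size, numeric(1))
  layout <- genome_layout(names(values_by_chrom), lens)
  lines <- unlist(lapply(names(values_by_chrom), function(cn) {
    v <- values_by_chrom[[cn]]
    sprintf("%s\t%d\t%d\t%.10g", cn, (seq_along(v) - 1L) * bin_size,
            seq_along(v) * bin_size, v)
  }), use.names = FALSE)
  read_bedgraph(write_lines_tmp(lines, ".bedGraph"), layout, bin_size)
}

# Small synthetic study shared across test files, simulated once.
small_sim_env <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(small_sim_env$res)) {
    dir <- file.path(tempdir(), "bvs_small_sim")
    cfg <- simulation_config(seed = 42, n_chroms = 2, chrom_length = 22e6,
                             n_genes = 180, n_activated_targets = 40,
                             n_repressed_targets = 15, n_decoy_peaks = 80,
                             n_patients = 250)
    manifest <- simulate_study(cfg, dir)
    small_sim_env$res <- list(dir = dir, cfg = cfg, manifest = manifest)
  }
  small_sim_env$res
}

# Independent brute-force oracle for the GSEA running score: literal
# per-position loop, no shared code with the implementation.
gsea_es_oracle <- function(scores, is_hit, p = 1) {
  N <- length(scores)
  nh <- sum(is_hit)
  nr <- sum(abs(scores[is_hit])^p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      cur <- cur + (if (nr > 0) abs(scores[i])^p / nr else 1 / nh)
    } else {
      cur <- cur - 1 / (N - nh)
    }
    run[i] <- cur
  }
  best <- 0
  es <- 0
  for (i in seq_len(N)) {
    if (abs(run[i]) > best) {
      best <- abs(run[i])
      es <- run[i]
    }
  }
  es
}

# All-pairs brute-force oracle for peak -> gene assignment.
assign_oracle <- function(peaks, genes, window = 100000) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- peaks$summit[i] - genes$tss[j]
      if (abs(d) <= window) {
        rows[[length(rows) + 1L]] <-
          data.frame(peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
                     signed_distance = if (genes$strand[j] == "+") d else -d,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      signed_distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
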