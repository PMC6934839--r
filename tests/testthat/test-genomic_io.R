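test_that("gene annotation reader derives strand-aware TSSs", {
  empty <- read_gene_annotation(write_lines_tmp(character(), ".bed"), "bed")
  expect_equal(nrow(empty), 0)

  g <- make_genes("chr1", 100L, 500L, "-")
  expect_equal(g$tss, 499)

  # two transcripts per gene: TSS is the 5'-most transcript start
  gtf <- c(
    'chr1\tsrc\ttranscript\t101\t500\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\ttranscript\t151\t900\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\ttranscript\t2001\t3000\t.\t-\t.\tgene_id "gB";',
    'chr1\tsrc\ttranscript\t2501\t3600\t.\t-\t.\tgene_id "gB";',
    'chr2\tsrc\ttranscript\t51\t200\t.\t+\t.\tgene_id "gC";')
  gt <- read_gene_annotation(write_lines_tmp(gtf, ".gtf"), "gtf")
  # hand-computed: gA + strand, min start 101 -> 0-based 100;
  # gB - strand, max end 3600 -> tss 3599; gC start 51 -> 50
  expect_equal(gt$tss[gt$gene_id == "gA"], 100)
  expect_equal(gt$gene_id[order(gt$chrom, gt$start)], gt$gene_id)  # sorted
  expect_equal(gt$tss[gt$gene_id == "gB"], 3599)
  expect_equal(gt$start[gt$gene_id == "gB"], 2000)
  expect_equal(gt$end[gt$gene_id == "gB"], 3600)
  expect_equal(gt$tss[gt$gene_id == "gC"], 50)

  # conflicting strand for one gene_id is a hard error
  bad <- c('chr1\tsrc\ttranscript\t1\t10\t.\t+\t.\tgene_id "gX";',
           'chr1\tsrc\ttranscript\t20\t30\t.\t-\t.\tgene_id "gX";')
  expect_error(read_gene_annotation(write_lines_tmp(bad, ".gtf"), "gtf"),
               "conflicting strand")
})

test_that("gtf round-trip through the writer is the identity", {
  s <- small_study()
  gt <- read_gene_annotation(file.path(s$dir, "genes.gtf"), "gtf")
  p2 <- tempfile(fileext = ".gtf")
  write_gene_annotation(gt, p2)
  expect_equal(read_gene_annotation(p2, "gtf"), gt)
})

test_that("narrowPeak reader maps fields and handles unknown summits", {
  p <- make_peaks("chr1", 100L, 200L, 50L, fold = 12.0, nlp = 9.5, q = 8.1)
  expect_equal(p$summit, 150)
  expect_equal(p$neg_log10_p, 9.5)
  expect_equal(p$fold_enrichment, 12.0)

  # offset -1 falls back to the interval midpoint
  p <- make_peaks("chr1", 100L, 251L, -1L, fold = 5, nlp = 9)
  expect_equal(p$summit, 100 + floor(151 / 2))

  expect_error(make_peaks("chr1", 200L, 200L, 0L, 5, 9), "end <= start")
  expect_error(make_peaks("chr1", 100L, 200L, 100L, 5, 9), "offset")
})

test_that("narrowPeak write/read round-trips byte-for-byte", {
  set.seed(11)
  n <- 10
  start <- sort(sample.int(1e6, n))
  lines <- sprintf("chr%d\t%d\t%d\tp%d\t%d\t.\t%g\t%g\t%g\t%d",
                   rep(1:2, length.out = n), start, start + 300 + seq_len(n),
                   seq_len(n), sample.int(1000, n), round(runif(n, 4, 30), 2),
                   round(runif(n, 8, 60), 2), round(runif(n, 6, 50), 2),
                   sample.int(200, n))
  f <- write_lines_tmp(lines, ".narrowPeak")
  pk <- read_narrowpeak(f)
  f2 <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("segmentation reader enforces the state alphabet and no overlap", {
  seg <- make_segmentation("chr1", c(0L, 100L), c(100L, 200L), c("TssA", "ReprPC"))
  expect_equal(nrow(seg$segments), 2)
  expect_equal(seg$segments$state, c("TssA", "ReprPC"))

  expect_error(make_segmentation("chr1", c(0L, 50L), c(100L, 150L),
                                 c("TssA", "TssA")), "overlapping")
  expect_error(make_segmentation("chr1", 0L, 100L, "NotAState"), "NotAState")

  # round trip
  f <- tempfile(fileext = ".bed")
  write_segmentation(seg, f)
  expect_equal(read_segmentation(f)$segments, seg$segments)
})

test_that("state_at agrees with a linear scan on a random segmentation", {
  set.seed(5)
  n <- 1000
  bounds <- sort(sample.int(2e6, 2 * n))
  starts <- bounds[seq(1, 2 * n, 2)]
  ends <- bounds[seq(2, 2 * n, 2)]
  keep <- ends > starts
  states <- sample(roadmap15_states(), sum(keep), replace = TRUE)
  seg <- make_segmentation("chr1", starts[keep], ends[keep], states)
  pos <- sample.int(2e6, 200) - 1L
  linear <- vapply(pos, function(p) {
    s <- seg$segments
    hit <- which(s$start <= p & p < s$end)
    if (length(hit)) s$state[hit] else "Unannotated"
  }, character(1))
  expect_equal(states_at(seg, "chr1", pos), linear)
  expect_error(state_at(seg, "chrX", 10), "chrX")
})

test_that("bedGraph binning is a length-weighted mean and conserves mass", {
  layout <- genome_layout("chr1", 1000)
  # constant value over the whole chromosome
  t1 <- read_bedgraph(write_lines_tmp("chr1\t0\t1000\t4", ".bedGraph"), layout, 50)
  expect_true(all(t1$values$chr1 == 4))
  # partial interval: bin0 fully covered, bin1 half covered
  t2 <- read_bedgraph(write_lines_tmp("chr1\t0\t75\t4", ".bedGraph"), layout, 50)
  expect_equal(t2$values$chr1[1:2], c(4, 2))
  expect_true(all(t2$values$chr1[-(1:2)] == 0))
  # beyond chromosome end
  expect_error(read_bedgraph(write_lines_tmp("chr1\t900\t1100\t1", ".bedGraph"),
                             layout, 50), "beyond")
})

test_that("random bedGraphs match a per-base brute-force expansion", {
  set.seed(7)
  layout <- genome_layout(c("c1", "c2"), c(5000, 3000))
  n <- 500
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  len <- layout$chrom_lengths[chrom]
  start <- floor(runif(n) * (len - 200))
  end <- start + sample.int(200, n, replace = TRUE)
  val <- round(runif(n, 0, 10), 3)
  lines <- sprintf("%s\t%d\t%d\t%g", chrom, start, end, val)
  bs <- 64
  tr <- read_bedgraph(write_lines_tmp(lines, ".bedGraph"), layout, bs)
  for (cn in c("c1", "c2")) {
    base <- numeric(layout$chrom_lengths[[cn]])
    sel <- chrom == cn
    for (i in which(sel)) base[(start[i] + 1):end[i]] <- base[(start[i] + 1):end[i]] + val[i]
    nb <- ceiling(length(base) / bs)
    brute <- vapply(seq_len(nb), function(b) {
      sum(base[((b - 1) * bs + 1):min(b * bs, length(base))]) / bs
    }, numeric(1))
    expect_equal(tr$values[[cn]], brute, tolerance = 1e-12)
  }
  # mass conservation
  expect_equal(sum(vapply(tr$values, sum, numeric(1))) * bs,
               sum(val * (end - start)), tolerance = 1e-9)
})

test_that("GMT reader deduplicates members and rejects malformed input", {
  sets <- read_gmt(write_lines_tmp("S1\tdesc\tA\tB\tA", ".gmt"))
  expect_equal(sets$S1, c("A", "B"))
  expect_error(read_gmt(write_lines_tmp("S1\tdesc", ".gmt")), "no members")
  expect_error(read_gmt(write_lines_tmp(c("S1\td\tA", "S1\td\tB"), ".gmt")),
               "duplicate")

  # 5-set round trip
  set.seed(3)
  sets <- setNames(lapply(1:5, function(i) sprintf("G%02d", sample.int(60, 10 + i))),
                   paste0("SET", 1:5))
  attr(sets, "description") <- setNames(paste0("d", 1:5), names(sets))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back[], sets[], ignore_attr = TRUE)
  expect_equal(attr(back, "description"), attr(sets, "description"))
})
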