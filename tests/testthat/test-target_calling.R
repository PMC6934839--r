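test_that("high-confidence filter uses strict thresholds and is idempotent", {
  pk <- make_peaks("chr1", c(100L, 300L, 500L, 700L), c(250L, 450L, 650L, 850L),
                   10L, fold = c(5, 4, 12, 3.5), nlp = c(8.0, 9, 30, 40))
  hc <- filter_high_confidence(pk)
  # boundary values (nlp == 8, fold == 4) are excluded
  expect_equal(hc$peak_id, "pk3")
  expect_equal(filter_high_confidence(hc), hc)
  expect_equal(nrow(filter_high_confidence(pk[0, ])), 0)
  expect_true(all(hc$peak_id %in% pk$peak_id))

  # brute-force predicate scan on random scores
  set.seed(21)
  n <- 200
  st <- sort(sample.int(1e6, n))
  pk <- make_peaks("chr1", st, st + 200L, 100L,
                   fold = round(runif(n, 0, 10), 2),
                   nlp = round(runif(n, 0, 16), 2))
  hc <- filter_high_confidence(pk)
  expect_equal(hc$peak_id, pk$peak_id[pk$neg_log10_p > 8 & pk$fold_enrichment > 4])
})

test_that("peak-gene assignment matches the all-pairs oracle and conventions", {
  # boundary: summit exactly `window` away is included
  g <- make_genes("chr1", 200000L, 210000L, "+")
  pk <- make_peaks("chr1", 99900L, 100101L, 100L, 10, 20)  # summit 100000
  asn <- assign_peaks_to_genes(pk, g, window = 100000)
  expect_equal(nrow(asn), 1)
  expect_equal(asn$signed_distance, -100000)

  # '-'-strand gene, summit 500 bp left of the TSS -> downstream (+500)
  g <- make_genes("chr1", 1000L, 5001L, "-")  # tss 5000
  pk <- make_peaks("chr1", 4400L, 4601L, 100L, 10, 20)  # summit 4500
  asn <- assign_peaks_to_genes(pk, g)
  expect_equal(asn$signed_distance, 500)

  expect_error(assign_peaks_to_genes(pk, g, window = 0), "window")

  # random instance vs the O(n*m) oracle
  set.seed(31)
  n <- 100
  st <- sort(sample.int(3e6, n))
  pk <- make_peaks(sample(c("chr1", "chr2"), n, replace = TRUE),
                   st, st + 300L, 150L, 10, 20)
  gs <- sort(sample.int(3e6, 50))
  g <- make_genes(sample(c("chr1", "chr2"), 50, replace = TRUE),
                  gs, gs + 5000L, sample(c("+", "-"), 50, replace = TRUE))
  expect_equal(assign_peaks_to_genes(pk, g), assign_oracle(pk, g))
})

test_that("target classification requires a peak, significance and strict log2FC", {
  g <- make_genes("chr1", c(10000L, 300000L, 600000L), c(15000L, 305000L, 605000L),
                  c("+", "+", "+"))
  pk <- make_peaks("chr1", c(9000L, 299000L), c(9501L, 299501L), 250L, 10, 20)
  asn <- assign_peaks_to_genes(pk, g)
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     log2fc = c(2.0, 3.5, 4.0),
                     is_significant = c(TRUE, TRUE, TRUE))
  tg <- classify_targets(asn, expr)
  # g1: log2fc exactly 2.0 -> none (strict); g2: activated; g3: no peak in window
  expect_equal(tg$class[tg$gene_id == "g1"], "none")
  expect_equal(tg$class[tg$gene_id == "g2"], "activated")
  expect_false("g3" %in% tg$gene_id)
  expect_error(classify_targets(asn, expr, up_lfc = -1, down_lfc = 1), "exceed")

  # missing expression -> none with a warning
  expect_warning(tg2 <- classify_targets(asn, expr[-1, ]), "missing")
  expect_equal(tg2$class[tg2$gene_id == "g1"], "none")
})

test_that("peak labels follow their genes' classes", {
  # one peak equidistant between an activated and a repressed gene
  g <- make_genes("chr1", c(100000L, 200000L), c(105000L, 205000L), c("+", "+"))
  pk <- make_peaks("chr1", 149000L, 151001L, 1000L, 10, 20)  # summit 150000
  asn <- assign_peaks_to_genes(pk, g)
  expr <- data.frame(gene_id = c("g1", "g2"), log2fc = c(4, -4),
                     is_significant = TRUE)
  tg <- classify_targets(asn, expr)
  lab <- label_peaks(pk, asn, tg)
  expect_equal(lab$label, "ambiguous")

  expr$log2fc <- c(4, 4)
  lab <- label_peaks(pk, asn, classify_targets(asn, expr))
  expect_equal(lab$label, "activating")

  expr$is_significant <- FALSE
  lab <- label_peaks(pk, asn, classify_targets(asn, expr))
  expect_equal(lab$label, "unassigned")
})

test_that("distance histogram tallies |distance| into half-open bins", {
  asn <- data.frame(peak_id = "p", gene_id = "g", signed_distance = 0)
  h <- distance_distribution(asn)
  expect_equal(h$count, c(1, 0, 0))

  set.seed(41)
  d <- sample(c(-1, 1), 500, replace = TRUE) * sample.int(100000, 500)
  asn <- data.frame(peak_id = "p", gene_id = sprintf("g%d", 1:500),
                    signed_distance = d)
  h <- distance_distribution(asn)
  expect_equal(sum(h$fraction), 1)
  tally <- c(sum(abs(d) < 5000), sum(abs(d) >= 5000 & abs(d) < 50000),
             sum(abs(d) >= 50000 & abs(d) <= 100000))
  expect_equal(h$count, tally)
  expect_error(distance_distribution(
    data.frame(peak_id = "p", gene_id = "g", signed_distance = 2e5)), "beyond")
})

test_that("target calling recovers the planted truth exactly", {
  s <- small_study()
  genes <- read_gene_annotation(file.path(s$dir, "genes.gtf"), "gtf")
  peaks <- read_narrowpeak(file.path(s$dir, "peaks.narrowPeak"))
  expr <- read_expression(file.path(s$dir, "expression.tsv"))
  tc <- call_targets(peaks, genes, expr)
  truth <- s$manifest$genes
  expect_setequal(tc$targets$gene_id[tc$targets$class == "activated"],
                  truth$gene_id[truth$class == "activated"])
  expect_setequal(tc$targets$gene_id[tc$targets$class == "repressed"],
                  truth$gene_id[truth$class == "repressed"])
  # peak labels match the manifest for all non-decoy peaks
  lab <- merge(tc$peak_labels, s$manifest$peaks, by = "peak_id")
  non_decoy <- lab[lab$label.y != "decoy", ]
  expect_equal(non_decoy$label.x, non_decoy$label.y)
  # decoys never reach the high-confidence set
  expect_false(any(s$manifest$peaks$peak_id[s$manifest$peaks$label == "decoy"]
                   %in% tc$hc_peaks$peak_id))
})

test_that("mirroring coordinates and strands leaves calls invariant", {
  set.seed(51)
  L <- 2e6
  n <- 40
  st <- sort(sample.int(L - 1000L, n))
  pk <- make_peaks("chr1", st, st + 400L, 200L, runif(n, 0, 12), runif(n, 0, 16))
  gs <- sort(sample.int(L - 20000L, 15))
  strand <- sample(c("+", "-"), 15, replace = TRUE)
  g <- make_genes("chr1", gs, gs + 8000L, strand)
  expr <- data.frame(gene_id = g$gene_id, log2fc = rnorm(15, 0, 3),
                     is_significant = runif(15) < 0.8)

  mirror_pk <- make_peaks("chr1", L - pk$end, L - pk$start,
                          as.integer(L - 1 - pk$summit - (L - pk$end)),
                          pk$fold_enrichment, pk$neg_log10_p, id = pk$peak_id)
  g_m <- make_genes("chr1", L - g$end, L - g$start,
                    ifelse(strand == "+", "-", "+"), id = g$gene_id)

  t1 <- call_targets(pk, g, expr)
  t2 <- call_targets(mirror_pk, g_m, expr)
  expect_equal(t1$targets$class[order(t1$targets$gene_id)],
               t2$targets$class[order(t2$targets$gene_id)])
  a1 <- t1$assignment
  a2 <- t2$assignment
  key <- function(a) paste(a$peak_id, a$gene_id)
  expect_setequal(key(a1), key(a2))
  expect_equal(abs(a1$signed_distance[order(key(a1))]),
               abs(a2$signed_distance[order(key(a2))]))
})
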