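# Set-overlap and preranked gene-set enrichment statistics, implemented
# from first principles: an exact upper-tail hypergeometric overlap test
# (log-space), and the weighted Kolmogorov-Smirnov running-score GSEA
# with a same-size random-set permutation null (ES, NES, nominal p,
# leading edge).

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at
#' least the seen overlap when `|query|` genes are drawn without
#' replacement from a universe containing `|reference|` successes,
#' computed exactly in log space from binomial coefficients. Fold
#' enrichment is `(k / |query|) / (|reference| / |universe|)`.
#'
#' @param query character vector of gene ids (e.g. upregulated genes)
#' @param reference character vector of gene ids (e.g. an MSigDB set)
#' @param universe character vector containing both
#' @return list with `overlap` (k), `fold_enrichment`, `p_value`,
#'   `n_query`, `n_reference`, `n_universe`
#' @export
hypergeometric_overlap <- function(query, reference, universe) {
  universe <- unique(universe)
  query <- unique(query)
  reference <- unique(reference)
  if (!length(universe)) stop_fmt("empty universe")
  if (!length(query)) stop_fmt("empty query")
  if (length(setdiff(query, universe)))
    stop_fmt("query contains genes outside the universe")
  if (length(setdiff(reference, universe)))
    stop_fmt("reference contains genes outside the universe")
  N <- length(universe)
  K <- length(reference)
  n <- length(query)
  k <- length(intersect(query, reference))
  # P(X = i) = C(K, i) C(N-K, n-i) / C(N, n), summed for i = k..min(K, n)
  i <- k:min(K, n)
  if (k == 0) {
    p <- 1.0
  } else {
    logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(logp)
    p <- min(1, exp(m) * sum(exp(logp - m)))
  }
  list(overlap = k,
       fold_enrichment = (k / n) / (K / N),
       p_value = p,
       n_query = n, n_reference = K, n_universe = N)
}

#' Overlap table for a gene-set collection
#'
#' Runs [hypergeometric_overlap()] of one query set against every set in
#' a collection and ranks by p ascending with overlap count (descending)
#' as tiebreak -- the shape of a "top K overlapping gene sets" table.
#'
#' @param query character vector of gene ids
#' @param collection named list of gene sets (see [read_gmt()])
#' @param universe character vector of all eligible gene ids
#' @param top keep the first `top` rows after ranking (default all)
#' @return data.frame with `set`, `n_set`, `overlap`, `fold_enrichment`,
#'   `p_value`
#' @export
overlap_table <- function(query, collection, universe, top = Inf) {
  rows <- lapply(names(collection), function(nm) {
    ref <- intersect(collection[[nm]], universe)
    if (!length(ref)) {
      return(data.frame(set = nm, n_set = 0L, overlap = 0L,
                        fold_enrichment = NA_real_, p_value = 1.0,
                        stringsAsFactors = FALSE))
    }
    h <- hypergeometric_overlap(query, ref, universe)
    data.frame(set = nm, n_set = h$n_reference, overlap = h$overlap,
               fold_enrichment = h$fold_enrichment, p_value = h$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -out$overlap, out$set), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(top)) as.integer(top) else nrow(out))
}

#' Rank genes by log2 fold change
#'
#' Descending by `log2fc`; ties broken by `gene_id` lexicographically so
#' the ranking is a deterministic function of the table contents.
#'
#' @param expression data.frame with `gene_id`, `log2fc`
#' @return data.frame with `gene_id`, `score`, in rank order
#' @export
rank_by_log2fc <- function(expression) {
  if (anyDuplicated(expression$gene_id)) stop_fmt("duplicate gene_id in ranking input")
  bad <- !is.finite(expression$log2fc)
  if (any(bad))
    stop_fmt("non-finite score for gene %s", expression$gene_id[bad][1])
  ord <- order(-expression$log2fc, expression$gene_id)
  data.frame(gene_id = expression$gene_id[ord], score = expression$log2fc[ord],
             stringsAsFactors = FALSE)
}

#' GSEA enrichment score of a gene set on a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov running statistic: walking down
#' the ranked list, set members ("hits") increment the running sum by
#' `|score|^weight_exponent` normalised by the sum of those weights over
#' all hits, and non-members decrement it by `1 / (N - Nh)`. The
#' enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed).
#'
#' @param ranked output of [rank_by_log2fc()] (columns `gene_id`, `score`)
#' @param gene_set character vector of member gene ids
#' @param weight_exponent hit-weight exponent (default 1; 0 gives the
#'   unweighted KS statistic)
#' @return list with `es`, `running_sum` (length N), `hit_index`,
#'   `leading_edge` (member gene ids at or before/after the extremum)
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1.0) {
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  Nh <- sum(hit)
  if (Nh == 0) stop_fmt("no gene-set member present in the ranked list")
  if (Nh == N) stop_fmt("gene set covers the whole ranked list")
  w <- abs(ranked$score)^weight_exponent
  wr <- sum(w[hit])
  inc <- numeric(N)
  if (wr > 0) {
    inc[hit] <- w[hit] / wr
  } else {
    inc[hit] <- 1 / Nh  # all hit scores zero: fall back to equal weights
  }
  inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) {
    ranked$gene_id[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    ranked$gene_id[i_max:N][hit[i_max:N]]
  }
  list(es = es, running_sum = running, hit_index = which(hit),
       leading_edge = leading)
}

#' Preranked GSEA with a permutation null
#'
#' The null distribution of the enrichment score is generated from
#' random gene sets of the same size drawn uniformly from the ranked
#' list (standard preranked behaviour: with a single ranking there is no
#' phenotype to permute). The nominal p uses a +1 pseudo-count,
#' `p = (1 + #{same-sign |null| >= |ES|}) / (1 + #{same-sign nulls})`,
#' and NES divides ES by the mean same-sign null magnitude.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100; default 1000)
#' @param seed integer seed making the null reproducible
#' @return list with `set_size`, `es`, `nes`, `nominal_p`,
#'   `n_permutations`, `seed`, `leading_edge`, `running_sum`,
#'   `no_same_sign_null` flag
#' @export
gsea_permutation <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                             weight_exponent = 1.0) {
  if (n_perm < 100) stop_fmt("n_perm must be at least 100")
  obs <- gsea_es(ranked, gene_set, weight_exponent)
  Nh <- length(obs$hit_index)
  N <- nrow(ranked)
  # Precompute weights once; a permutation only changes the hit mask.
  w <- abs(ranked$score)^weight_exponent
  null_es <- numeric(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(N, Nh)
    hit <- logical(N)
    hit[idx] <- TRUE
    wr <- sum(w[hit])
    inc <- numeric(N)
    if (wr > 0) inc[hit] <- w[hit] / wr else inc[hit] <- 1 / Nh
    inc[!hit] <- -1 / (N - Nh)
    running <- cumsum(inc)
    null_es[b] <- running[which.max(abs(running))]
  }
  same <- if (obs$es >= 0) null_es >= 0 else null_es < 0
  n_same <- sum(same)
  no_same_sign <- n_same == 0
  if (no_same_sign) {
    p <- 1 / (n_perm + 1)
    nes <- NA_real_
    n_exceed <- 0L
  } else {
    n_exceed <- sum(abs(null_es[same]) >= abs(obs$es))
    p <- (1 + n_exceed) / (1 + n_same)
    nes <- obs$es / mean(abs(null_es[same]))
  }
  list(set_size = Nh, es = obs$es, nes = nes, nominal_p = p,
       n_permutations = n_perm, n_same_sign = n_same, n_exceed = n_exceed,
       seed = seed,
       leading_edge = obs$leading_edge, running_sum = obs$running_sum,
       no_same_sign_null = no_same_sign)
}
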