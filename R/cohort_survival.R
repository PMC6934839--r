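# Oncogenic-context cohort analysis: RAS-pathway patient classification,
# upper-quartile expression stratification, and self-implemented
# Kaplan-Meier / log-rank survival comparison.

#' RAS classification gene lists
#'
#' *RAS-driven*: oncogenic alteration in KRAS, NRAS, HRAS, RIT1 or NF1.
#' *RAS-activated*: oncogenic alteration in EGFR, ERBB2, MET, KRAS, NRAS,
#' HRAS, RIT1, NF1, BRAF or MAP2K1 (a superset, so RAS-driven implies
#' RAS-activated).
#' @return named list with `ras_driven` and `ras_activated` gene vectors
#' @export
ras_gene_lists <- function() {
  driven <- c("KRAS", "NRAS", "HRAS", "RIT1", "NF1")
  list(ras_driven = driven,
       ras_activated = c("EGFR", "ERBB2", "MET", driven, "BRAF", "MAP2K1"))
}

cohort_flag_cols <- function() paste0("alt_", ras_gene_lists()$ras_activated)

#' Classify patients by RAS-pathway alteration context
#'
#' @param cohort data.frame with one logical/0-1 column `alt_<GENE>` per
#'   gene in [ras_gene_lists()]`$ras_activated`
#' @return the cohort with logical columns `ras_driven` and
#'   `ras_activated` appended
#' @export
classify_ras <- function(cohort) {
  gl <- ras_gene_lists()
  need <- paste0("alt_", gl$ras_activated)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_fmt("missing alteration flag column(s): %s", paste(miss, collapse = ", "))
  flags <- lapply(need, function(cn) {
    v <- cohort[[cn]]
    if (anyNA(v)) stop_fmt("NA alteration flag in column %s", cn)
    as.logical(v)
  })
  names(flags) <- gl$ras_activated
  any_of <- function(genes) Reduce(`|`, flags[genes])
  cohort$ras_driven <- any_of(gl$ras_driven)
  cohort$ras_activated <- any_of(gl$ras_activated)
  cohort
}

#' Upper-quartile stratification of expression values
#'
#' `high` iff `value >= Q3`, where Q3 is the 75th percentile computed
#' with the linear-interpolation definition (`stats::quantile` type 7).
#' Ties straddling Q3 all go to `high`.
#'
#' @param values numeric expression values, one per sample
#' @return character vector of `"high"` / `"low"` labels
#' @export
stratify_upper_quartile <- function(values) {
  if (length(values) < 8) stop_fmt("need at least 8 samples to stratify")
  if (anyNA(values)) stop_fmt("NA expression values")
  if (diff(range(values)) == 0) stop_fmt("all expression values identical")
  q3 <- as.numeric(quantile(values, 0.75, type = 7))
  ifelse(values >= q3, "high", "low")
}

#' Kaplan-Meier product-limit curve
#'
#' At each distinct event time `t` with `d` deaths among `n` at risk, the
#' survival estimate multiplies by `(1 - d/n)`. Censored-only times
#' reduce the risk set without a step. With no censoring the curve equals
#' the empirical survivor function.
#'
#' @param time follow-up times (>= 0)
#' @param event 1 = death, 0 = censored
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival`; `survival` is non-increasing and
#'   starts from S(0) = 1 before the first row
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop_fmt("empty survival input")
  if (any(time < 0)) stop_fmt("negative survival time")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  et <- sort(unique(time[event == 1]))
  if (!length(et)) {
    return(data.frame(time = numeric(), n_risk = integer(), n_event = integer(),
                      survival = numeric()))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  data.frame(time = et, n_risk = as.integer(n_risk), n_event = as.integer(n_event),
             survival = cumprod(1 - n_event / n_risk))
}

#' Median survival time from a KM curve
#'
#' First event time at which the survival estimate drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#' @param curve output of [km_curve()]
#' @return scalar time or `NA`
#' @export
km_median <- function(curve) {
  i <- which(curve$survival <= 0.5)
  if (!length(i)) NA_real_ else curve$time[i[1]]
}

#' Two-group log-rank test
#'
#' Standard O-E statistic: at each distinct event time (pooled over both
#' groups), the observed group-A deaths are compared with the
#' expectation under the null (hypergeometric mean `d * nA / n`), with
#' the hypergeometric variance `d (n-d) nA nB / (n^2 (n-1))`, which
#' handles tied event times natively. The statistic
#' `(sum(O-E))^2 / sum(V)` is referred to a chi-square with 1 df.
#'
#' @param time_a,event_a group A follow-up times and event indicators
#' @param time_b,event_b group B follow-up times and event indicators
#' @return list with `chi_square`, `p_value`, `observed_a`, `expected_a`,
#'   `n_a`, `n_b`
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop_fmt("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) == 0) stop_fmt("no events in either group")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1]))
  o_a <- e_a <- v <- numeric(length(et))
  for (i in seq_along(et)) {
    t <- et[i]
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp_a)
    o_a[i] <- d_a
    e_a[i] <- d * n_a / n
    v[i] <- if (n > 1) d * (n - d) * n_a * (n - n_a) / (n^2 * (n - 1)) else 0
  }
  V <- sum(v)
  if (V <= 0) stop_fmt("zero log-rank variance (no comparable events)")
  chi <- (sum(o_a) - sum(e_a))^2 / V
  list(chi_square = chi,
       p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       observed_a = sum(o_a), expected_a = sum(e_a),
       n_a = length(time_a), n_b = length(time_b))
}

#' Stratified survival analysis within an alteration context
#'
#' Filters the cohort to a RAS context (optionally requiring TP53 loss of
#' function), stratifies the remaining patients by the upper quartile of
#' target-gene expression, and compares the high vs low strata with
#' Kaplan-Meier curves and the log-rank test.
#'
#' @param cohort data.frame with columns `sample_id`, `expression`,
#'   `tp53_lof`, `time`, `event` and the `alt_<GENE>` flags
#' @param context `"all"`, `"ras_driven"` or `"ras_activated"`
#' @param require_tp53_lof restrict to TP53 loss-of-function patients
#' @return list with `context`, `require_tp53_lof`, `n`, `strata`
#'   (per-sample labels), `curve_high`, `curve_low`, `logrank`
#' @export
run_stratified_survival <- function(cohort,
                                    context = c("all", "ras_driven", "ras_activated"),
                                    require_tp53_lof = FALSE) {
  context <- match.arg(context)
  cohort <- classify_ras(cohort)
  keep <- rep(TRUE, nrow(cohort))
  if (context != "all") keep <- keep & cohort[[context]]
  if (require_tp53_lof) {
    if (anyNA(cohort$tp53_lof)) stop_fmt("NA tp53_lof flag")
    keep <- keep & as.logical(cohort$tp53_lof)
  }
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) < 8)
    stop_fmt("context filter leaves %d patient(s); need at least 8", nrow(sub))
  strata <- stratify_upper_quartile(sub$expression)
  hi <- strata == "high"
  if (!any(hi) || all(hi)) stop_fmt("degenerate expression stratification")
  lr <- logrank_test(sub$time[hi], sub$event[hi], sub$time[!hi], sub$event[!hi])
  list(context = context, require_tp53_lof = require_tp53_lof,
       n = nrow(sub),
       strata = data.frame(sample_id = sub$sample_id, stratum = strata,
                           stringsAsFactors = FALSE),
       curve_high = km_curve(sub$time[hi], sub$event[hi]),
       curve_low = km_curve(sub$time[!hi], sub$event[!hi]),
       logrank = lr)
}

#' Read a cohort table
#'
#' TSV with columns `sample_id`, `expression`, `tp53_lof`, `time`,
#' `event` and one `alt_<GENE>` column per classification gene.
#' @param path file path
#' @return data.frame
#' @export
read_cohort <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "expression", "tp53_lof", "time", "event", cohort_flag_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("cohort table missing column(s): %s",
                             paste(miss, collapse = ", "))
  df
}

#' Write a cohort table
#' @param cohort data.frame as read by [read_cohort()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  keep <- c("sample_id", "expression", "tp53_lof", "time", "event", cohort_flag_cols())
  out <- cohort[keep]
  for (cn in c("tp53_lof", cohort_flag_cols())) out[[cn]] <- as.integer(out[[cn]])
  write_tsv(out, path)
}
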