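#' Precision, recall and F1 from a match result
#'
#' Computes `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)`. `TP + FP` equals the
#' number of called SVs and `TP + FN` the number of reference SVs. A metric
#' with an empty denominator is `NA` (never silently 0), and an `NA`
#' precision or recall propagates into F1.
#'
#' @param match An `"sv_match"` from [match_callsets()], or a list/tibble
#'   with `tp`, `fp`, `fn` counts.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @examples
#' compute_prf(list(tp = 8, fp = 2, fn = 8))  # P = 0.8, R = 0.5
#' @export
compute_prf <- function(match) {
  if (inherits(match, "sv_match")) {
    tp <- nrow(match$tp_calls); fp <- nrow(match$fp_calls)
    fn <- nrow(match$fn_refs)
  } else {
    tp <- match$tp; fp <- match$fp; fn <- match$fn
  }
  prf_row(tp, fp, fn)
}

prf_row <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 precision = precision, recall = recall, f1 = f1)
}

#' SV size bins
#'
#' The default bins tile `[50, Inf)` without gaps: 50-100, 100-300,
#' 300-1,000 and > 1,000 bp, each half-open on the right (`[50,100)`,
#' `[100,300)`, `[300,1000)`, `[1000, Inf)`; a 1,000 bp SV falls in the
#' `>1000` bin).
#'
#' @param boundaries Strictly increasing cut points in bp; the first must
#'   equal the read policy's minimum size.
#' @return An object of class `"size_bins"` with `boundaries` and `labels`.
#' @export
size_bins <- function(boundaries = c(50L, 100L, 300L, 1000L)) {
  boundaries <- as.integer(boundaries)
  stopifnot(length(boundaries) >= 2, all(diff(boundaries) > 0))
  k <- length(boundaries)
  labels <- c(paste0(boundaries[-k], "-", boundaries[-1]),
              paste0(">", boundaries[k]))
  structure(list(boundaries = boundaries, labels = labels),
            class = "size_bins")
}

#' Assign SV records to size bins
#'
#' @param records A tibble of SV records, or a numeric vector of sizes.
#' @param bins A [size_bins()].
#' @return A character vector of bin labels, one per record. A size below
#'   the first boundary is an error — such records should have been
#'   filtered at read time.
#' @examples
#' size_bin(c(50, 100, 999, 1000), size_bins())
#' @export
size_bin <- function(records, bins = size_bins()) {
  sz <- if (is.data.frame(records)) records$svlen else records
  if (length(sz) == 0) return(character(0))
  if (any(is.na(sz)) || any(sz < bins$boundaries[1])) {
    stop("SV size below ", bins$boundaries[1],
         " bp; records must be size-filtered before binning", call. = FALSE)
  }
  idx <- findInterval(sz, bins$boundaries)
  bins$labels[idx]
}

#' Stratified precision/recall/F1 against a truth set
#'
#' Matches the calls against the truth once, globally, inside the benchmark
#' regions, and then distributes the TP pairs, FP calls and FN truth records
#' into the strata of `{INS, DEL} x {in TRR, outside TRR} x ({all} + size
#' bins)`. A TP pair is assigned the stratum of its *reference* record (the
#' benchmark composition defines the strata); an FP call uses its own TRR
#' status and size. Matching before stratifying prevents a call inside a TRR
#' from going unmatched merely because its partner's breakpoint falls 1 bp
#' outside; `stratify_first = TRUE` switches to the alternative
#' (per-stratum matching of the partitioned inputs) for sensitivity
#' analysis.
#'
#' @param calls,truth Tibbles of SV records.
#' @param trr TRR region set.
#' @param bench Benchmark region set (`NULL` for no restriction).
#' @param criteria A [match_criteria()].
#' @param bins A [size_bins()].
#' @param stratify_first Match within each stratum instead of globally.
#' @return A tibble with one row per stratum: `source`, `svtype`,
#'   `trr_status` (`"in_TRR"`/`"outside_TRR"`), `size_bin` (`"all"` or a bin
#'   label), `tp`, `fp`, `fn`, `precision`, `recall`, `f1`. Within each
#'   `size_bin = "all"` slice the counts sum to the global TP/FP/FN.
#' @export
stratified_metrics <- function(calls, truth, trr, bench = NULL,
                               criteria = match_criteria(),
                               bins = size_bins(),
                               stratify_first = FALSE) {
  src <- if (nrow(calls) > 0) calls$source[1] else "callset"
  strata <- tidyr::expand_grid(
    svtype = c("INS", "DEL"),
    trr_status = c("in_TRR", "outside_TRR"),
    size_bin = c("all", bins$labels)
  )
  if (stratify_first) {
    counts <- purrr::pmap_dfr(
      list(strata$svtype, strata$trr_status, strata$size_bin),
      function(ty, trr_st, bin) {
        pick <- function(x) {
          keep <- x$svtype == ty &
            (breakpoints_in_regions(x, trr) == (trr_st == "in_TRR"))
          if (bin != "all") keep <- keep & size_bin(x, bins) == bin
          x[keep, ]
        }
        m <- compare_to_benchmark(pick(calls), pick(truth), bench, criteria)
        tibble::tibble(tp = nrow(m$tp_calls), fp = nrow(m$fp_calls),
                       fn = nrow(m$fn_refs))
      })
    out <- dplyr::bind_cols(source = src, strata)
    return(dplyr::bind_cols(out, prf_row(counts$tp, counts$fp, counts$fn)))
  }

  m <- compare_to_benchmark(calls, truth, bench, criteria)
  label <- function(x) {
    tibble::tibble(
      svtype = as.character(x$svtype),
      trr_status = as.character(ifelse(breakpoints_in_regions(x, trr),
                                       "in_TRR", "outside_TRR")),
      size_bin = as.character(size_bin(x, bins))
    )
  }
  # TP stratum follows the reference record
  ref_restricted <- if (is.null(bench)) truth else
    restrict_to_regions(truth, bench)
  tp_lab <- label(ref_restricted[m$pairs$ref_idx, ])
  fp_lab <- label(m$fp_calls)
  fn_lab <- label(m$fn_refs)

  count_strata <- function(lab) {
    full <- dplyr::bind_rows(lab, dplyr::mutate(lab, size_bin = "all"))
    dplyr::count(full, .data$svtype, .data$trr_status, .data$size_bin)
  }
  tab <- strata
  for (cls in c("tp", "fp", "fn")) {
    lab <- switch(cls, tp = tp_lab, fp = fp_lab, fn = fn_lab)
    cnt <- count_strata(lab)
    tab <- dplyr::left_join(tab, stats::setNames(cnt, c(names(strata), cls)),
                            by = names(strata))
  }
  tab <- tidyr::replace_na(tab, list(tp = 0L, fp = 0L, fn = 0L))
  out <- dplyr::bind_cols(source = src, tab[1:3],
                          prf_row(tab$tp, tab$fp, tab$fn))
  # conservation: per "all" slice the strata tile the global result
  all_slice <- out[out$size_bin == "all", ]
  stopifnot(sum(all_slice$tp) == nrow(m$tp_calls),
            sum(all_slice$fp) == nrow(m$fp_calls),
            sum(all_slice$fn) == nrow(m$fn_refs))
  out
}

#' Micro- and macro-aggregated metrics per TRR stratum
#'
#' Pools insertions and deletions per TRR stratum. The micro aggregate pools
#' the TP/FP/FN counts before computing precision/recall/F1; the macro
#' aggregate averages the per-type metrics. Both are emitted, labeled, since
#' pooled headline F1 values can be read either way.
#'
#' @param strat_tbl Output of [stratified_metrics()].
#' @return A tibble with `trr_status`, `aggregation`, and metric columns.
#' @export
aggregate_trr_metrics <- function(strat_tbl) {
  base <- dplyr::filter(strat_tbl, .data$size_bin == "all")
  micro <- base |>
    dplyr::group_by(.data$trr_status) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp),
                     fn = sum(.data$fn), .groups = "drop")
  micro <- dplyr::bind_cols(
    micro[, "trr_status"], aggregation = "micro",
    prf_row(micro$tp, micro$fp, micro$fn)
  )
  macro <- base |>
    dplyr::group_by(.data$trr_status) |>
    dplyr::summarise(
      aggregation = "macro", tp = sum(.data$tp), fp = sum(.data$fp),
      fn = sum(.data$fn),
      precision = mean(.data$precision), recall = mean(.data$recall),
      f1 = mean(.data$f1), .groups = "drop"
    )
  dplyr::bind_rows(micro, macro)
}

#' Precision of the calls carrying an INFO flag
#'
#' Matches globally inside the benchmark regions, then computes precision
#' over the call subset carrying a flag (by default the `IMPRECISE` flag,
#' i.e. records with `precise == FALSE`). Useful to decide whether flagged
#' calls are worth filtering.
#'
#' @param calls,truth Tibbles of SV records.
#' @param bench Benchmark region set or `NULL`.
#' @param criteria A [match_criteria()].
#' @param flagged Logical vector marking the call subset, or `NULL` for the
#'   IMPRECISE subset.
#' @return A one-row tibble as from [compute_prf()] (fn is the global FN
#'   count; precision/recall refer to the flagged subset). All-`NA` metrics
#'   with a warning when no call carries the flag.
#' @export
flag_subset_precision <- function(calls, truth, bench = NULL,
                                  criteria = match_criteria(),
                                  flagged = NULL) {
  if (is.null(flagged)) flagged <- !calls$precise
  stopifnot(length(flagged) == nrow(calls))
  m <- compare_to_benchmark(calls, truth, bench, criteria)
  flagged_ids <- calls$id[flagged]
  if (length(flagged_ids) == 0) {
    warning("no call carries the flag; precision undefined", call. = FALSE)
    return(prf_row(0L, 0L, nrow(m$fn_refs)))
  }
  tp <- sum(m$tp_calls$id %in% flagged_ids)
  fp <- sum(m$fp_calls$id %in% flagged_ids)
  prf_row(tp, fp, nrow(m$fn_refs))
}
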