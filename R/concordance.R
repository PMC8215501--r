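#' Overlap between two callsets
#'
#' Matches two callsets against each other under the usual criteria; the
#' callset with more SVs plays the reference role (on a tie, the first
#' argument — deterministic). The shared count is the number of matched
#' pairs; the per-set overlap rate is the fraction of that set's records
#' matched in the other set.
#'
#' @param a,b Tibbles of SV records; names are taken from their `source`
#'   column.
#' @param criteria A [match_criteria()].
#' @return An `"overlap_summary"`: list with `set_names`, `venn_counts`
#'   (tibble of `set`, `pattern`, `count` where `pattern` names the sets a
#'   record was found in), `overlap_rate` (named numeric), `n` (named set
#'   sizes).
#' @export
pairwise_overlap <- function(a, b, criteria = match_criteria()) {
  na <- set_name(a, "A"); nb <- set_name(b, "B")
  if (nrow(b) > nrow(a)) {
    m <- match_callsets(a, b, criteria)  # b is the larger set: reference
    matched_a <- nrow(m$pairs); matched_b <- nrow(m$pairs)
  } else {
    m <- match_callsets(b, a, criteria)
    matched_a <- nrow(m$pairs); matched_b <- nrow(m$pairs)
  }
  venn <- tibble::tibble(
    set = c(na, na, nb, nb),
    pattern = c(na, paste(na, nb, sep = "&"), nb, paste(na, nb, sep = "&")),
    count = c(nrow(a) - matched_a, matched_a, nrow(b) - matched_b, matched_b)
  )
  new_overlap_summary(c(na, nb), venn,
                      n = stats::setNames(c(nrow(a), nrow(b)), c(na, nb)))
}

#' Overlap among three callsets
#'
#' Runs the three pairwise comparisons (each with the larger set as
#' reference, per [pairwise_overlap()]) and labels every record of every set
#' with the other sets in which it found a match. The seven-region overlap
#' decomposition is reported per set: for set A, the counts of records found
#' in A only, in A&B, in A&C and in A&B&C — which by construction sum to
#' |A|. Where the three pairwise one-to-one assignments disagree, the shared
#' regions seen from different sets may differ slightly; this decomposition
#' is the natural one for "fraction of X's calls also detected by Y".
#'
#' @param a,b,c Tibbles of SV records.
#' @param criteria A [match_criteria()].
#' @return An `"overlap_summary"` as in [pairwise_overlap()], with
#'   `overlap_rate` the fraction of each set matched in at least one other.
#' @export
three_way_overlap <- function(a, b, c, criteria = match_criteria()) {
  sets <- list(a, b, c)
  names(sets) <- vapply(seq_along(sets), function(i)
    set_name(sets[[i]], LETTERS[i]), character(1))
  nm <- names(sets)
  # matched-in-other-set label matrix per set
  lab <- lapply(sets, function(x) {
    matrix(FALSE, nrow = nrow(x), ncol = 3, dimnames = list(NULL, nm))
  })
  for (i in 1:2) for (j in (i + 1):3) {
    x <- sets[[i]]; y <- sets[[j]]
    if (nrow(y) > nrow(x)) {
      m <- match_callsets(x, y, criteria)
      xi <- m$pairs$call_idx; yi <- m$pairs$ref_idx
    } else {
      m <- match_callsets(y, x, criteria)
      xi <- m$pairs$ref_idx; yi <- m$pairs$call_idx
    }
    lab[[i]][xi, nm[j]] <- TRUE
    lab[[j]][yi, nm[i]] <- TRUE
  }
  venn <- purrr::map_dfr(nm, function(s) {
    l <- lab[[s]]
    others <- l[, setdiff(nm, s), drop = FALSE]
    pattern <- vapply(seq_len(nrow(l)), function(r) {
      inn <- c(s, colnames(others)[others[r, ]])
      paste(sort(inn), collapse = "&")
    }, character(1))
    if (nrow(l) == 0) {
      return(tibble::tibble(set = character(), pattern = character(),
                            count = integer()))
    }
    dplyr::count(tibble::tibble(set = s, pattern = pattern),
                 .data$set, .data$pattern, name = "count")
  })
  new_overlap_summary(nm, venn,
                      n = stats::setNames(vapply(sets, nrow, integer(1)), nm))
}

new_overlap_summary <- function(set_names, venn, n) {
  # per-set reconstruction invariant
  tot <- tapply(venn$count, venn$set, sum)
  stopifnot(all(tot[set_names] == n[set_names] | n[set_names] == 0))
  rate <- vapply(set_names, function(s) {
    v <- venn[venn$set == s, ]
    shared <- sum(v$count[v$pattern != s])
    if (n[[s]] == 0) NA_real_ else shared / n[[s]]
  }, numeric(1))
  structure(list(set_names = set_names, venn_counts = venn,
                 overlap_rate = rate, n = n),
            class = "overlap_summary")
}

#' Overlap rate from printed overlap counts
#'
#' The rate a stacked-overlap figure reports for one callset: the number of
#' its records also detected elsewhere over its total record count —
#' `sum(shared_counts) / n_total`.
#'
#' @param shared_counts Counts of the set's records found in each other-set
#'   pattern (e.g. shared-with-X-only and shared-with-all).
#' @param n_total The set's total record count.
#' @return The overlap rate as a fraction.
#' @examples
#' overlap_rate(c(3846, 628), 6182)  # about 0.72
#' @export
overlap_rate <- function(shared_counts, n_total) {
  stopifnot(n_total > 0, all(shared_counts >= 0),
            sum(shared_counts) <= n_total)
  sum(shared_counts) / n_total
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary> sets:", paste(x$set_names, collapse = ", "), "\n")
  print(x$venn_counts)
  cat("overlap rates:",
      paste(sprintf("%s=%.3f", names(x$overlap_rate), x$overlap_rate),
            collapse = ", "), "\n")
  invisible(x)
}

#' Concurrent detection of truth SVs across callsets
#'
#' Labels each truth record (restricted to the benchmark regions) with the
#' number of callsets in which it found a match, using independent pairwise
#' benchmark comparisons, and returns the histogram of proportions over
#' `0..K` for `K` callsets.
#'
#' @param truth Tibble of truth SV records.
#' @param callsets Named list of call tibbles.
#' @param bench Benchmark region set or `NULL`.
#' @param criteria A [match_criteria()].
#' @return A tibble with `n_pipelines` (0..K), `count` and `proportion`
#'   (summing to 1 over the restricted truth set).
#' @export
concurrent_detection <- function(truth, callsets, bench = NULL,
                                 criteria = match_criteria()) {
  stopifnot(length(callsets) >= 1)
  truth_r <- if (is.null(bench)) truth else restrict_to_regions(truth, bench)
  hits <- rep(0L, nrow(truth_r))
  for (cs in callsets) {
    m <- compare_to_benchmark(cs, truth_r, bench, criteria)
    hits[m$pairs$ref_idx] <- hits[m$pairs$ref_idx] + 1L
  }
  k <- length(callsets)
  cnt <- vapply(0:k, function(i) sum(hits == i), integer(1))
  tibble::tibble(
    n_pipelines = 0:k, count = cnt,
    proportion = if (nrow(truth_r) > 0) cnt / nrow(truth_r) else NA_real_
  )
}

#' Trio "de novo" SV rate
#'
#' A son record is counted "de novo" when it matches no record of the father
#' and no record of the mother under the same criteria used for
#' benchmarking (son as calls, each parent in turn as the reference). The
#' rate is the number of son-only records over the number of all son
#' records, overall and stratified by the son record's TRR status. Note
#' these are raw callset-level rates: with imperfect callsets they absorb
#' false positives in the son and false negatives in the parents, which is
#' exactly why observed rates can far exceed the true biological de novo
#' rate.
#'
#' @param son,father,mother Tibbles of SV records.
#' @param trr TRR region set, or `NULL` for no stratification.
#' @param criteria A [match_criteria()].
#' @return A tibble with `stratum` (`all`, `in_TRR`, `outside_TRR`),
#'   `n_son`, `n_denovo`, `denovo_rate` (`NA` when the son callset slice is
#'   empty).
#' @export
denovo_rate <- function(son, father, mother, trr = NULL,
                        criteria = match_criteria()) {
  in_parent <- function(parent) {
    if (nrow(parent) == 0) return(rep(FALSE, nrow(son)))
    m <- match_callsets(son, parent, criteria)
    seq_len(nrow(son)) %in% m$pairs$call_idx
  }
  denovo <- !(in_parent(father) | in_parent(mother))
  strata <- list(all = rep(TRUE, nrow(son)))
  if (!is.null(trr)) {
    inside <- breakpoints_in_regions(son, trr)
    strata$in_TRR <- inside
    strata$outside_TRR <- !inside
  }
  purrr::imap_dfr(strata, function(keep, name) {
    n <- sum(keep); nd <- sum(denovo & keep)
    tibble::tibble(stratum = name, n_son = n, n_denovo = nd,
                   denovo_rate = if (n > 0) nd / n else NA_real_)
  })
}

set_name <- function(x, default) {
  if (nrow(x) > 0 && !is.null(x$source) && !is.na(x$source[1])) x$source[1]
  else default
}
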