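#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a match result
#'
#' One row per record involved in the comparison, labeled `TP` (matched
#' call), `FP` (unmatched call) or `FN` (unmatched reference), with the
#' partner id and match score for pairs.
#'
#' @param x An `"sv_match"`.
#' @param ... Unused.
#' @return A tibble with the record columns plus `class`, `partner_id`,
#'   `score`.
#' @exportS3Method generics::tidy
tidy.sv_match <- function(x, ...) {
  tp <- x$tp_calls
  if (nrow(tp) > 0) {
    i <- match(tp$id, x$pairs$call_id)
    tp$class <- "TP"
    tp$partner_id <- x$pairs$ref_id[i]
    tp$score <- x$pairs$score[i]
  }
  fp <- x$fp_calls
  fn <- x$fn_refs
  if (nrow(fp) > 0) {
    fp$class <- "FP"; fp$partner_id <- NA_character_; fp$score <- NA_real_
  }
  if (nrow(fn) > 0) {
    fn$class <- "FN"; fn$partner_id <- NA_character_; fn$score <- NA_real_
  }
  dplyr::bind_rows(tp, fp, fn)
}

#' One-row summary of a match result
#'
#' @param x An `"sv_match"`.
#' @param ... Unused.
#' @return A one-row tibble: `n_calls`, `n_refs`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @exportS3Method generics::glance
glance.sv_match <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_calls = x$n_calls, n_refs = x$n_refs),
    compute_prf(x)
  )
}

#' Tidy an overlap summary
#'
#' @param x An `"overlap_summary"`.
#' @param ... Unused.
#' @return The per-set overlap decomposition with the set totals and rates.
#' @exportS3Method generics::tidy
tidy.overlap_summary <- function(x, ...) {
  dplyr::mutate(x$venn_counts,
                n_set = x$n[.data$set],
                overlap_rate = x$overlap_rate[.data$set])
}

#' @exportS3Method generics::glance
glance.overlap_summary <- function(x, ...) {
  tibble::tibble(set = x$set_names,
                 n = unname(x$n[x$set_names]),
                 overlap_rate = unname(x$overlap_rate[x$set_names]))
}
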