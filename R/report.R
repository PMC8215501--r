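#' Run the full evaluation over a set of callsets
#'
#' Ties the stages together: per-callset summaries (counts by type, TRR
#' status and size bin), pairwise/three-way overlap summaries, the
#' concurrent-detection histogram against the truth, stratified
#' precision/recall/F1 tables with their TRR-level micro/macro aggregates,
#' IMPRECISE-subset precision, and — when trio callsets are supplied — de
#' novo rates. Every number in the report is produced by the corresponding
#' module function; the reporting layer only assembles. When `out_dir` is
#' given, each table is written both as TSV (human surface, percentages
#' rounded in separate `*_pct` columns) and as JSON (full precision), and
#' the configuration is serialized alongside for provenance.
#'
#' @param callsets Named list of call tibbles (names = pipeline names).
#' @param truth Truth SV tibble, or `NULL` to skip benchmark-based stages.
#' @param trr TRR region set.
#' @param bench Benchmark region set or `NULL`.
#' @param trio Optional named list with `son`, `father`, `mother` tibbles.
#' @param criteria A [match_criteria()].
#' @param bins A [size_bins()].
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return A list of tibbles: `callset_summary`, `overlap`, `concurrent`,
#'   `metrics`, `trr_aggregate`, `imprecise_precision`, `denovo`
#'   (`NULL` where the inputs for a stage were not given), plus
#'   `region_summary` for the benchmark regions.
#' @export
run_full_evaluation <- function(callsets, truth = NULL, trr, bench = NULL,
                                trio = NULL, criteria = match_criteria(),
                                bins = size_bins(), out_dir = NULL) {
  stopifnot(is.list(callsets), !is.null(names(callsets)))
  report <- list()

  report$callset_summary <- purrr::imap_dfr(callsets, function(cs, name) {
    tibble::tibble(
      source = name, svtype = cs$svtype,
      trr_status = ifelse(breakpoints_in_regions(cs, trr),
                          "in_TRR", "outside_TRR"),
      size_bin = size_bin(cs, bins)
    ) |>
      dplyr::count(.data$source, .data$svtype, .data$trr_status,
                   .data$size_bin, name = "n")
  })

  report$overlap <- if (length(callsets) == 3) {
    ov <- three_way_overlap(callsets[[1]], callsets[[2]], callsets[[3]],
                            criteria)
    dplyr::mutate(
      ov$venn_counts,
      overlap_rate = ov$overlap_rate[.data$set],
      n_set = ov$n[.data$set]
    )
  } else if (length(callsets) == 2) {
    ov <- pairwise_overlap(callsets[[1]], callsets[[2]], criteria)
    dplyr::mutate(
      ov$venn_counts,
      overlap_rate = ov$overlap_rate[.data$set],
      n_set = ov$n[.data$set]
    )
  } else NULL

  if (!is.null(truth)) {
    report$concurrent <- concurrent_detection(truth, callsets, bench,
                                              criteria)
    report$metrics <- purrr::imap_dfr(callsets, function(cs, name) {
      dplyr::mutate(
        stratified_metrics(cs, truth, trr, bench, criteria, bins),
        source = name
      )
    })
    report$trr_aggregate <- report$metrics |>
      dplyr::group_split(.data$source) |>
      purrr::map_dfr(function(x) {
        dplyr::bind_cols(source = x$source[1], aggregate_trr_metrics(x))
      })
    report$imprecise_precision <- purrr::imap_dfr(callsets,
      function(cs, name) {
        res <- if (any(!cs$precise)) {
          flag_subset_precision(cs, truth, bench, criteria)
        } else prf_row(NA_integer_, NA_integer_, NA_integer_)
        dplyr::bind_cols(source = name, res)
      })
  }

  if (!is.null(trio)) {
    report$denovo <- denovo_rate(trio$son, trio$father, trio$mother, trr,
                                 criteria)
  }
  if (!is.null(bench)) report$region_summary <- summarize_regions(bench)

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Size composition of a region set
#'
#' Counts regions in the classes below 1 kb, 1-10 kb and above 10 kb —
#' the way benchmark-region composition is usually quoted.
#'
#' @param regions A region set.
#' @return A tibble with `size_class`, `n` and `fraction` (summing to 1).
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) == 0) stop("empty region set", call. = FALSE)
  width <- regions$end - regions$start
  cls <- cut(width, c(0, 1000, 10000, Inf),
             labels = c("<1kb", "1-10kb", ">10kb"), right = FALSE)
  out <- tibble::tibble(size_class = factor(cls, levels = levels(cls))) |>
    dplyr::count(.data$size_class, name = "n", .drop = FALSE) |>
    dplyr::mutate(size_class = as.character(.data$size_class),
                  fraction = .data$n / sum(.data$n))
  out
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (name in names(report)) {
    x <- report[[name]]
    if (is.null(x)) next
    readr::write_tsv(round_pct_cols(x), file.path(out_dir,
                                                  paste0(name, ".tsv")),
                     progress = FALSE)
    jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                         dataframe = "columns", digits = NA, na = "null")
  }
  invisible(out_dir)
}

# human surface: add integer-percent companions for fraction columns
round_pct_cols <- function(x) {
  frac_cols <- intersect(names(x), c("precision", "recall", "f1",
                                     "proportion", "fraction",
                                     "overlap_rate", "denovo_rate"))
  for (cc in frac_cols) {
    x[[paste0(cc, "_pct")]] <- round(100 * x[[cc]])
  }
  x
}
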