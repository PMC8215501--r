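#' Construct a region set
#'
#' A region set is a tibble of genomic intervals in 0-based half-open
#' coordinates (`[start, end)`, BED convention) with a `name` attribute.
#' Chromosome names are normalized exactly as for SV records.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends (`end > start`).
#' @param label Free-text label per interval (e.g. repeat class).
#' @param name Identifier for the whole set.
#' @return A tibble with columns `chrom`, `start`, `end`, `label` and
#'   attribute `"name"`.
#' @export
region_tbl <- function(chrom, start, end, label = NA_character_,
                       name = "regions") {
  n <- length(start)
  out <- tibble::tibble(
    chrom = normalize_chrom(rep_len(as.character(chrom), n)),
    start = as.integer(start), end = as.integer(end),
    label = rep_len(as.character(label), n)
  )
  if (any(out$end <= out$start)) {
    stop("regions must satisfy end > start (0-based half-open)",
         call. = FALSE)
  }
  attr(out, "name") <- name
  out
}

#' Load tandem repeat regions from a UCSC RepeatMasker table
#'
#' Reads an `rmsk.txt`-format table (the UCSC schema: `genoName`,
#' `genoStart`, `genoEnd` at columns 6-8, `repClass` at column 12) and keeps
#' the rows whose repeat class is `Simple_repeat` (short-pattern tandem
#' repeats) or `Satellite` (medium-to-long-pattern tandem repeats). The union
#' of the two classes is the working definition of tandem repeat regions
#' (TRRs). Coordinates stay 0-based half-open as in the source.
#'
#' @param path Path to the table (gzip-transparent).
#' @param classes Repeat classes to keep.
#' @return A region set ([region_tbl()]) named `"TRR"`, with `label` holding
#'   the repeat class. Malformed rows are skipped with a warning; zero
#'   qualifying rows is an error, since an empty TRR set almost certainly
#'   means a schema mismatch.
#' @export
load_rmsk_trr <- function(path, classes = c("Simple_repeat", "Satellite")) {
  raw <- readr::read_tsv(
    path, col_names = FALSE, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(raw) < 12) {
    stop("'", path, "' has fewer than 12 columns; not an rmsk.txt table",
         call. = FALSE)
  }
  tab <- tibble::tibble(
    chrom = raw[[6]],
    start = suppressWarnings(as.integer(raw[[7]])),
    end = suppressWarnings(as.integer(raw[[8]])),
    class = raw[[12]]
  )
  bad <- is.na(tab$start) | is.na(tab$end) | is.na(tab$chrom) |
    tab$end <= tab$start
  if (any(bad)) {
    warning(sum(bad), " malformed rmsk row(s) skipped", call. = FALSE)
    tab <- tab[!bad, ]
  }
  tab <- dplyr::filter(tab, .data$class %in% classes)
  if (nrow(tab) == 0) {
    stop("no rows with repClass in {", paste(classes, collapse = ", "),
         "} found in '", path, "'; wrong file or schema?", call. = FALSE)
  }
  region_tbl(tab$chrom, tab$start, tab$end, label = tab$class, name = "TRR")
}

#' Load a region set from a BED file
#'
#' Reads a BED3+ file (track lines tolerated) preserving the 0-based
#' half-open coordinates.
#'
#' @param path Path to the BED file.
#' @param name Name for the resulting region set.
#' @return A region set ([region_tbl()]).
#' @export
load_bed <- function(path, name = "regions") {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("cannot parse BED '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) stop("empty BED file: ", path, call. = FALSE)
  region_tbl(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    label = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    name = name
  )
}

#' Write a region set to BED3
#' @param regions A region set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(
    dplyr::select(regions, "chrom", "start", "end"),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Do a record's breakpoints fall inside a region set?
#'
#' Region comparison in this package only asks whether breakpoints overlap
#' the regions. An insertion has a single breakpoint at `pos`; a deletion has
#' two, at `pos` and `end`. The 1-based VCF breakpoint `p` is tested as the
#' 0-based point `p - 1` against the half-open intervals, and the record is
#' inside when any of its breakpoints is (the `"any"` combinator; `"all"` and
#' `"start"` are available for sensitivity analysis).
#'
#' @param records A tibble of SV records.
#' @param regions A region set.
#' @param combinator How to combine a deletion's two breakpoints: any (the
#'   default), all, or start-only.
#' @return A logical vector, one element per record.
#' @export
breakpoints_in_regions <- function(records, regions,
                                   combinator = c("any", "all", "start")) {
  combinator <- match.arg(combinator)
  if (nrow(records) == 0) return(logical(0))
  start_in <- points_in_regions(records$chrom, records$pos, regions)
  if (combinator == "start") return(start_in)
  is_del <- records$svtype == "DEL"
  end_in <- start_in
  if (any(is_del)) {
    end_in[is_del] <- points_in_regions(records$chrom[is_del],
                                        records$end[is_del], regions)
  }
  if (combinator == "any") start_in | end_in else start_in & end_in
}

# Membership of 1-based points (tested as 0-based p-1) in half-open regions,
# via IRanges per chromosome.
points_in_regions <- function(chrom, pos, regions) {
  out <- logical(length(pos))
  if (nrow(regions) == 0) return(out)
  by_chrom <- split(seq_along(pos), chrom)
  reg_split <- split(regions, regions$chrom)
  for (ch in names(by_chrom)) {
    reg <- reg_split[[ch]]
    if (is.null(reg) || nrow(reg) == 0) next
    idx <- by_chrom[[ch]]
    # point p-1 in [start, end)  <=>  start + 1 <= p <= end  (1-based closed)
    q <- IRanges::IRanges(start = pos[idx], width = 1L)
    s <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    out[idx] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Partition records by TRR membership
#'
#' Splits a callset into the records whose breakpoints fall inside tandem
#' repeat regions and those outside, preserving input order. Every record
#' lands in exactly one part.
#'
#' @inheritParams breakpoints_in_regions
#' @param trr The TRR region set.
#' @return A named list with tibbles `in_trr` and `outside_trr`.
#' @export
partition_by_trr <- function(records, trr,
                             combinator = c("any", "all", "start")) {
  inside <- breakpoints_in_regions(records, trr, match.arg(combinator))
  list(in_trr = records[inside, ], outside_trr = records[!inside, ])
}

#' Restrict a callset to records inside a region set
#'
#' Keeps the records whose breakpoints overlap the regions — the operation
#' applied to both the calls and the truth set before benchmark comparison,
#' so records outside the benchmark regions contribute to neither TP, FP nor
#' FN.
#'
#' @inheritParams breakpoints_in_regions
#' @param bench The region set to restrict to (e.g. benchmark regions).
#' @return The subset of `records` inside `bench`, in input order.
#' @export
restrict_to_regions <- function(records, bench,
                                combinator = c("any", "all", "start")) {
  records[breakpoints_in_regions(records, bench, match.arg(combinator)), ]
}
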