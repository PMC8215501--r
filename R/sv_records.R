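#' Construct a tibble of normalized SV records
#'
#' The canonical in-memory representation of a structural-variant callset is a
#' tibble with one row per SV allele. `sv_tbl()` builds one from vectors,
#' filling defaults, normalizing chromosome names (the leading `"chr"` prefix
#' is stripped so GRCh37 callsets and hg19 annotation interoperate) and
#' checking the record invariants:
#'
#' * `end >= pos`; insertions have `end == pos` (a single breakpoint);
#' * deletions span `(pos, end]` and their size is `end - pos`;
#' * `svlen` is strictly positive.
#'
#' @param chrom Chromosome names (any atomic vector; coerced to character).
#' @param pos 1-based start breakpoint (bp).
#' @param end 1-based end breakpoint; defaults to `pos` for insertions and
#'   `pos + svlen` for deletions.
#' @param svtype SV type, `"INS"` or `"DEL"` (other types are representable
#'   but excluded by the default read policy).
#' @param svlen Positive SV size in bp; for deletions defaults to `end - pos`.
#' @param filter Raw VCF FILTER string (default `"PASS"`).
#' @param precise Logical; `FALSE` when the record carries the `IMPRECISE`
#'   INFO flag.
#' @param source Callset identifier attached to every record.
#' @param id Record identifiers; autogenerated when missing.
#' @param szcount,coverage Optional PBHoney Spots support tags.
#' @return A tibble with columns `id`, `chrom`, `pos`, `end`, `svtype`,
#'   `svlen`, `filter`, `precise`, `source`, `szcount`, `coverage`.
#' @examples
#' sv_tbl(chrom = "1", pos = c(100L, 500L), svtype = c("DEL", "INS"),
#'        svlen = c(300L, 120L))
#' @export
sv_tbl <- function(chrom, pos, end = NULL, svtype, svlen = NULL,
                   filter = "PASS", precise = TRUE, source = "callset",
                   id = NULL, szcount = NA_integer_, coverage = NA_integer_) {
  n <- max(length(chrom), length(pos), length(svtype))
  chrom <- normalize_chrom(rep_len(as.character(chrom), n))
  pos <- rep_len(as.integer(pos), n)
  svtype <- rep_len(as.character(svtype), n)
  if (is.null(svlen) && is.null(end)) {
    stop("need at least one of `svlen`, `end`", call. = FALSE)
  }
  if (is.null(end)) {
    svlen <- rep_len(as.integer(svlen), n)
    end <- ifelse(svtype == "INS", pos, pos + svlen)
  } else {
    end <- rep_len(as.integer(end), n)
  }
  if (is.null(svlen)) svlen <- ifelse(svtype == "INS", NA_integer_, end - pos)
  svlen <- rep_len(as.integer(svlen), n)
  if (is.null(id)) id <- sprintf("sv%06d", seq_len(n))
  out <- tibble::tibble(
    id = rep_len(as.character(id), n),
    chrom = chrom, pos = pos, end = as.integer(end),
    svtype = svtype, svlen = svlen,
    filter = rep_len(as.character(filter), n),
    precise = rep_len(as.logical(precise), n),
    source = rep_len(as.character(source), n),
    szcount = rep_len(as.integer(szcount), n),
    coverage = rep_len(as.integer(coverage), n)
  )
  validate_sv_tbl(out)
}

#' Check SV record invariants
#'
#' @param x A tibble as built by [sv_tbl()].
#' @return `x`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_sv_tbl <- function(x) {
  req <- c("id", "chrom", "pos", "end", "svtype", "svlen")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("SV table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) return(x)
  if (any(x$end < x$pos)) stop("SV records with end < pos", call. = FALSE)
  ins <- x$svtype == "INS"
  if (any(ins & x$end != x$pos)) {
    stop("insertion records must have end == pos", call. = FALSE)
  }
  if (any(!is.na(x$svlen) & x$svlen <= 0)) {
    stop("svlen must be positive", call. = FALSE)
  }
  del <- x$svtype == "DEL"
  if (any(del & (x$end - x$pos) != x$svlen)) {
    stop("deletion svlen inconsistent with end - pos", call. = FALSE)
  }
  x
}

#' An empty SV record tibble
#' @return A zero-row tibble with the canonical SV columns.
#' @export
empty_sv_tbl <- function() {
  sv_tbl(chrom = character(), pos = integer(), svtype = character(),
         svlen = integer())[0, ]
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x))
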