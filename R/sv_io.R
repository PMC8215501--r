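#' Filtering policy for reading SV callsets
#'
#' Encodes the inclusion rules applied when ingesting a callset: minimum SV
#' size (50 bp, the conventional lower bound for a structural variant),
#' exclusion of breakend (`BND`) records, restriction to the autosomes plus
#' the sex chromosomes, optional PASS-only selection (used for truth sets),
#' and the PBHoney Spots support-ratio rule, which drops records whose
#' `szCount / coverage` ratio is below 0.2.
#'
#' @param min_size Minimum SV size in bp (default 50).
#' @param excluded_types Character vector of SVTYPE values to drop
#'   (default `"BND"`; `DUP`/`INV` and other non-INS/DEL types are also
#'   dropped unless listed in `keep_types`).
#' @param keep_types SVTYPE values retained (default `c("INS", "DEL")`).
#' @param allowed_chroms Chromosome whitelist after `"chr"`-prefix stripping
#'   (default `1:22`, `X`, `Y`; `NULL` disables the check).
#' @param require_pass Keep only records with FILTER `PASS` (truth sets).
#' @param spots_ratio_min PBHoney Spots threshold: records with
#'   `szCount / coverage < spots_ratio_min` are filtered out (default 0.2).
#'   Applied only when `dialect = "pbhoney"` at read time.
#' @return A list with class `"filter_policy"`.
#' @seealso [read_sv_vcf()]
#' @export
filter_policy <- function(min_size = 50L,
                          excluded_types = "BND",
                          keep_types = c("INS", "DEL"),
                          allowed_chroms = c(as.character(1:22), "X", "Y"),
                          require_pass = FALSE,
                          spots_ratio_min = 0.2) {
  stopifnot(min_size > 0, spots_ratio_min >= 0, spots_ratio_min <= 1)
  structure(
    list(min_size = as.integer(min_size),
         excluded_types = excluded_types,
         keep_types = keep_types,
         allowed_chroms = if (is.null(allowed_chroms)) NULL
                          else normalize_chrom(allowed_chroms),
         require_pass = isTRUE(require_pass),
         spots_ratio_min = spots_ratio_min),
    class = "filter_policy"
  )
}

#' A policy that keeps every parseable INS/DEL record
#'
#' Convenience permissive policy (1 bp minimum, all chromosomes, no PASS
#' requirement) used mainly for round-trip tests.
#' @return A `"filter_policy"`.
#' @export
permissive_policy <- function() {
  filter_policy(min_size = 1L, allowed_chroms = NULL, require_pass = FALSE,
                spots_ratio_min = 0)
}

#' Read and filter an SV callset from VCF
#'
#' Parses a VCF 4.x file, normalizes each record into the canonical SV
#' representation (see [sv_tbl()]) and applies the inclusion rules of a
#' [filter_policy()]. SVTYPE/SVLEN/END are taken from INFO when present;
#' records without them but with sequence-resolved REF/ALT alleles are
#' classified by allele-length difference. Multi-allelic records are split
#' into one row per ALT allele. Negative SVLEN values are mapped to their
#' absolute value; a deletion's size is `END - POS` when both are present
#' (SVLEN is the fallback), and a discrepancy above 10% between the two is
#' resolved in favour of `END - POS` with a warning.
#'
#' The per-reason attrition of the filter is attached as the `"attrition"`
#' attribute, a tibble of `(reason, n)` satisfying
#' `records_in = records_kept + sum(n)`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param policy A [filter_policy()].
#' @param source Callset identifier stamped on every record.
#' @param dialect `"generic"` or `"pbhoney"`. The PBHoney Spots dialect
#'   additionally applies the `szCount / coverage >= spots_ratio_min` rule;
#'   the two tags are read from INFO or from the first sample's FORMAT
#'   fields, whichever is present.
#' @return A tibble of SV records in input order, with attribute
#'   `"attrition"`.
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' write_sv_vcf(sv_tbl(chrom = "1", pos = 1000L, svtype = "DEL",
#'                     svlen = 300L), vcf)
#' read_sv_vcf(vcf, filter_policy(), source = "demo")
#' @export
read_sv_vcf <- function(path, policy = filter_policy(), source = "callset",
                        dialect = c("generic", "pbhoney")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("unparseable VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    out <- empty_sv_tbl()
    attr(out, "attrition") <- tibble::tibble(reason = character(), n = integer())
    return(out)
  }
  raw <- tibble::as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  names(raw) <- tolower(names(raw))
  raw$row <- seq_len(nrow(raw))
  raw <- tidyr::separate_rows(raw, "alt", sep = ",")
  info <- raw$info
  fmt_tags <- pbhoney_format_tags(v, raw$row)

  parsed <- normalize_vcf_rows(
    chrom = raw$chrom, pos = raw$pos, id = raw$id, ref = raw$ref,
    alt = raw$alt, filter = raw$filter, info = info,
    fmt_szcount = fmt_tags$szcount, fmt_coverage = fmt_tags$coverage,
    source = source
  )
  apply_filter_policy(parsed, policy, dialect)
}

# Vectorized normalization of raw VCF rows into the canonical SV columns.
# Returns the full table plus a `skip` marker for unclassifiable records.
normalize_vcf_rows <- function(chrom, pos, id, ref, alt, filter, info,
                               fmt_szcount, fmt_coverage, source) {
  n <- length(chrom)
  pos <- as.integer(pos)
  svtype <- info_field(info, "SVTYPE")
  svlen <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  end <- suppressWarnings(as.integer(info_field(info, "END")))
  precise <- !stringr::str_detect(info, "(^|;)IMPRECISE(;|$)") %in% TRUE
  szcount <- suppressWarnings(as.integer(info_field(info, "szCount")))
  coverage <- suppressWarnings(as.integer(info_field(info, "coverage")))
  szcount <- dplyr::coalesce(szcount, fmt_szcount)
  coverage <- dplyr::coalesce(coverage, fmt_coverage)

  # sequence-resolved fallback: classify by allele-length difference
  seqish <- is.na(svtype) & !is.na(ref) & !is.na(alt) &
    stringr::str_detect(ref, "^[ACGTNacgtn]+$") &
    stringr::str_detect(alt, "^[ACGTNacgtn]+$")
  dlen <- ifelse(seqish, nchar(alt) - nchar(ref), NA_integer_)
  svtype[seqish & dlen > 0] <- "INS"
  svtype[seqish & dlen < 0] <- "DEL"
  svlen[seqish & is.na(svlen)] <- abs(dlen[seqish & is.na(svlen)])
  # symbolic ALT fallback, e.g. <DEL>, <INS>
  symb <- is.na(svtype) & !is.na(alt) &
    stringr::str_detect(alt, "^<[A-Za-z:]+>$")
  svtype[symb] <- stringr::str_remove_all(alt[symb], "[<>]")
  svtype[!is.na(svtype)] <- sub(":.*$", "", svtype[!is.na(svtype)])

  svlen <- abs(svlen)
  is_ins <- !is.na(svtype) & svtype == "INS"
  is_del <- !is.na(svtype) & svtype == "DEL"
  # DEL size: END - POS is authoritative when both present
  del_both <- is_del & !is.na(end) & !is.na(svlen)
  span <- end - pos
  clash <- del_both & span > 0 &
    abs(span - svlen) / pmax(span, svlen) > 0.10
  if (any(clash)) {
    warning(sum(clash), " deletion record(s) with SVLEN inconsistent with ",
            "END - POS (relative discrepancy > 10%); END - POS used",
            call. = FALSE)
  }
  svlen[is_del & !is.na(end)] <- span[is_del & !is.na(end)]
  end[is_del & is.na(end)] <- pos[is_del & is.na(end)] +
    svlen[is_del & is.na(end)]
  end[is_ins] <- pos[is_ins]

  id <- ifelse(is.na(id) | id == ".", sprintf("rec%06d", seq_len(n)), id)
  tibble::tibble(
    id = make.unique(as.character(id)),
    chrom = normalize_chrom(chrom), pos = pos,
    end = as.integer(end), svtype = svtype, svlen = as.integer(svlen),
    filter = ifelse(is.na(filter), ".", filter),
    precise = precise, source = source,
    szcount = szcount, coverage = coverage,
    skip = is.na(svtype) | (svtype %in% c("INS", "DEL") & is.na(svlen))
  )
}

apply_filter_policy <- function(parsed, policy, dialect) {
  stopifnot(inherits(policy, "filter_policy"))
  n_in <- nrow(parsed)
  reasons <- integer()
  drop_count <- function(name, mask) {
    reasons[[name]] <<- sum(mask)
    mask
  }
  if (any(parsed$skip)) {
    warning(sum(parsed$skip),
            " record(s) with unresolvable SVTYPE/size skipped", call. = FALSE)
  }
  dropped <- drop_count("unresolvable", parsed$skip)
  live <- !dropped

  m <- live & parsed$svtype %in% policy$excluded_types
  dropped <- dropped | drop_count("excluded_type", m)
  live <- !dropped
  m <- live & !(parsed$svtype %in%
                  c(policy$keep_types, policy$excluded_types))
  dropped <- dropped | drop_count("other_type", m)
  live <- !dropped
  if (!is.null(policy$allowed_chroms)) {
    m <- live & !(parsed$chrom %in% policy$allowed_chroms)
    dropped <- dropped | drop_count("chromosome", m)
    live <- !dropped
  }
  m <- live & (is.na(parsed$svlen) | parsed$svlen < policy$min_size)
  dropped <- dropped | drop_count("below_min_size", m)
  live <- !dropped
  if (policy$require_pass) {
    m <- live & parsed$filter != "PASS"
    dropped <- dropped | drop_count("not_pass", m)
    live <- !dropped
  }
  if (dialect == "pbhoney" && policy$spots_ratio_min > 0) {
    ratio <- parsed$szcount / parsed$coverage
    m <- live & !is.na(ratio) & ratio < policy$spots_ratio_min
    dropped <- dropped | drop_count("spots_ratio", m)
    live <- !dropped
  }
  out <- validate_sv_tbl(dplyr::select(parsed[live, ], -"skip"))
  attr(out, "attrition") <- tibble::tibble(
    reason = names(reasons), n = unname(unlist(reasons))
  )
  attr(out, "n_input") <- n_in
  out
}

# szCount / coverage from the first sample's FORMAT fields, aligned to the
# (possibly allele-expanded) row index.
pbhoney_format_tags <- function(v, row_index) {
  gt <- v@gt
  n <- length(row_index)
  out <- list(szcount = rep(NA_integer_, n), coverage = rep(NA_integer_, n))
  if (is.null(gt) || ncol(gt) < 2 || nrow(gt) == 0) return(out)
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  val <- strsplit(gt[, 2], ":", fixed = TRUE)
  pick <- function(tag) {
    vapply(seq_along(fmt), function(i) {
      j <- match(tag, fmt[[i]])
      if (is.na(j) || j > length(val[[i]])) NA_integer_
      else suppressWarnings(as.integer(val[[i]][j]))
    }, integer(1))
  }
  sz <- pick("szCount"); cov <- pick("coverage")
  out$szcount <- sz[row_index]
  out$coverage <- cov[row_index]
  out
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- stringr::str_match(info, pat)
  m[, 2]
}

#' Write SV records to a minimal VCF
#'
#' Emits a minimal, spec-compliant VCF 4.2 with symbolic ALT alleles and
#' `SVTYPE`/`SVLEN`/`END` INFO keys (plus `IMPRECISE`, `szCount` and
#' `coverage` where set), such that reading the file back with
#' [read_sv_vcf()] under [permissive_policy()] reproduces the records.
#' Deletions are written with a negative `SVLEN` and an explicit `END`
#' (the usual VCF convention); insertions with a positive `SVLEN`.
#'
#' @param records A tibble of SV records ([sv_tbl()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path) {
  records <- validate_sv_tbl(records)
  chroms <- unique(records$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svtrr",
    sprintf("##contig=<ID=%s>", chroms),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise structural variation\">",
    "##INFO=<ID=szCount,Number=1,Type=Integer,Description=\"Number of reads supporting the variant size\">",
    "##INFO=<ID=coverage,Number=1,Type=Integer,Description=\"Read depth at the variant site\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- character(0)
  if (nrow(records) > 0) {
    info <- sprintf(
      "SVTYPE=%s;SVLEN=%d;END=%d", records$svtype,
      ifelse(records$svtype == "DEL", -records$svlen, records$svlen),
      records$end
    )
    info <- paste0(info, ifelse(records$precise, "", ";IMPRECISE"))
    has_tags <- !is.na(records$szcount) & !is.na(records$coverage)
    info <- paste0(info, ifelse(
      has_tags,
      sprintf(";szCount=%d;coverage=%d", records$szcount, records$coverage),
      ""
    ))
    body <- paste(records$chrom, records$pos, records$id, "N",
                  sprintf("<%s>", records$svtype), ".", records$filter, info,
                  sep = "\t")
  }
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
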