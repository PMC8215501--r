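#' Matching criteria for SV comparison
#'
#' Two SVs of the same type are considered the same variant when they satisfy
#' the type-specific criterion: insertions when their breakpoints are within
#' `ins_max_breakpoint_dist` bp of each other (inclusive), deletions when
#' they exhibit at least `del_min_reciprocal_overlap` reciprocal overlap
#' (inclusive). Type consistency is always required.
#'
#' @param ins_max_breakpoint_dist Maximum insertion breakpoint distance in bp
#'   (default 200).
#' @param del_min_reciprocal_overlap Minimum deletion reciprocal overlap
#'   fraction (default 0.5).
#' @param require_type_match Must be `TRUE`; matching across types is
#'   reserved and unsupported.
#' @return A list with class `"match_criteria"`.
#' @export
match_criteria <- function(ins_max_breakpoint_dist = 200L,
                           del_min_reciprocal_overlap = 0.5,
                           require_type_match = TRUE) {
  stopifnot(ins_max_breakpoint_dist >= 0,
            del_min_reciprocal_overlap > 0,
            del_min_reciprocal_overlap <= 1)
  if (!isTRUE(require_type_match)) {
    stop("require_type_match = FALSE is reserved and unsupported",
         call. = FALSE)
  }
  structure(
    list(ins_max_breakpoint_dist = as.integer(ins_max_breakpoint_dist),
         del_min_reciprocal_overlap = del_min_reciprocal_overlap,
         require_type_match = TRUE),
    class = "match_criteria"
  )
}

#' Reciprocal overlap between two deletions
#'
#' The reciprocal overlap of deletion spans `[pos_a, end_a]` and
#' `[pos_b, end_b]` is `min(o / len_a, o / len_b)` where `o` is the overlap
#' length `max(0, min(end_a, end_b) - max(pos_a, pos_b))` and `len = end -
#' pos` — i.e. both deletions must be covered by the shared stretch for the
#' fraction to be high. Disjoint spans or spans on different chromosomes give
#' 0. Vectorized over rows; the shorter input is recycled.
#'
#' @param a,b Tibbles of DEL records (compared row by row).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- sv_tbl(chrom = "1", pos = 100L, end = 200L, svtype = "DEL")
#' b <- sv_tbl(chrom = "1", pos = 150L, end = 350L, svtype = "DEL")
#' reciprocal_overlap(a, b)  # min(50/100, 50/200) = 0.25
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  len_a <- a$end[ia] - a$pos[ia]; len_b <- b$end[ib] - b$pos[ib]
  if (any(len_a <= 0) || any(len_b <= 0)) {
    stop("zero-length deletion span", call. = FALSE)
  }
  o <- pmax(0L, pmin(a$end[ia], b$end[ib]) - pmax(a$pos[ia], b$pos[ib]))
  ro <- pmin(o / len_a, o / len_b)
  ro[a$chrom[ia] != b$chrom[ib]] <- 0
  ro
}

#' Breakpoint distance between two insertions
#'
#' @param a,b Tibbles of INS records (compared row by row, shorter recycled).
#' @return `|pos_a - pos_b|` in bp on the same chromosome, `Inf` otherwise.
#' @export
breakpoint_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  d <- abs(a$pos[ia] - b$pos[ib])
  d[a$chrom[ia] != b$chrom[ib]] <- Inf
  d
}

#' Match a callset against a reference set
#'
#' Produces a one-to-one assignment between calls and reference records.
#' Candidate pairs are same-type pairs satisfying the type's criterion
#' (insertions: breakpoint distance within the window, inclusive; deletions:
#' reciprocal overlap at or above the threshold). Among all one-to-one
#' assignments the matcher selects one that first maximizes the number of
#' pairs and then optimizes the total score (minimum summed breakpoint
#' distance for insertions, maximum summed reciprocal overlap for
#' deletions), with deterministic tie-breaking by (reference chromosome,
#' reference position, call position). Unassigned calls are false positives,
#' unassigned references false negatives.
#'
#' The candidate graph is decomposed into connected components; each small
#' component is solved exactly by dynamic programming, so the assignment is
#' provably optimal at the scales this package targets (components larger
#' than 12 records per side — never reached in practice — fall back to a
#' deterministic greedy sweep).
#'
#' @param calls,refs Tibbles of SV records.
#' @param criteria A [match_criteria()].
#' @return An object of class `"sv_match"`: a list with `pairs` (tibble of
#'   `call_id`, `ref_id`, `svtype`, `score`), `tp_calls`, `fp_calls`,
#'   `fn_refs` (record tibbles), `criteria`, `n_calls`, `n_refs`. Use
#'   [generics::tidy()] / [generics::glance()] to flatten.
#' @export
match_callsets <- function(calls, refs, criteria = match_criteria()) {
  stopifnot(inherits(criteria, "match_criteria"))
  calls <- validate_sv_tbl(calls); refs <- validate_sv_tbl(refs)
  cand <- candidate_pairs(calls, refs, criteria)
  sel <- assign_one_to_one(cand, calls, refs)
  pairs <- cand[sel, c("call_idx", "ref_idx", "svtype", "score")]
  pairs <- pairs[order(match(pairs$ref_idx, order(refs$chrom, refs$pos))), ]
  pairs <- tibble::tibble(
    call_id = calls$id[pairs$call_idx], ref_id = refs$id[pairs$ref_idx],
    svtype = pairs$svtype, score = pairs$score,
    call_idx = pairs$call_idx, ref_idx = pairs$ref_idx
  )
  tp <- sort(unique(pairs$call_idx))
  matched_refs <- sort(unique(pairs$ref_idx))
  res <- structure(
    list(pairs = pairs,
         tp_calls = calls[tp, ],
         fp_calls = calls[setdiff(seq_len(nrow(calls)), tp), ],
         fn_refs = refs[setdiff(seq_len(nrow(refs)), matched_refs), ],
         criteria = criteria,
         n_calls = nrow(calls), n_refs = nrow(refs)),
    class = "sv_match"
  )
  # conservation identities, asserted on every run
  stopifnot(
    nrow(res$tp_calls) == nrow(res$pairs),
    nrow(res$tp_calls) + nrow(res$fp_calls) == res$n_calls,
    nrow(res$pairs) + nrow(res$fn_refs) == res$n_refs,
    !anyDuplicated(res$pairs$call_idx), !anyDuplicated(res$pairs$ref_idx)
  )
  res
}

# Candidate (call, ref) pairs passing the type-specific criterion.
# score: INS = breakpoint distance (smaller is better);
#        DEL = reciprocal overlap (larger is better).
candidate_pairs <- function(calls, refs, criteria) {
  out <- list()
  for (ty in c("INS", "DEL")) {
    ci <- which(calls$svtype == ty); ri <- which(refs$svtype == ty)
    if (length(ci) == 0 || length(ri) == 0) next
    cc <- calls[ci, ]; rr <- refs[ri, ]
    hits <- NULL
    for (ch in intersect(unique(cc$chrom), unique(rr$chrom))) {
      i <- which(cc$chrom == ch); j <- which(rr$chrom == ch)
      if (ty == "INS") {
        w <- criteria$ins_max_breakpoint_dist
        q <- IRanges::IRanges(start = cc$pos[i] - w, end = cc$pos[i] + w)
        s <- IRanges::IRanges(start = rr$pos[j], width = 1L)
      } else {
        q <- IRanges::IRanges(start = cc$pos[i], end = cc$end[i])
        s <- IRanges::IRanges(start = rr$pos[j], end = rr$end[j])
      }
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      hits <- rbind(hits, cbind(i[S4Vectors::queryHits(ov)],
                                j[S4Vectors::subjectHits(ov)]))
    }
    if (is.null(hits)) next
    a <- cc[hits[, 1], ]; b <- rr[hits[, 2], ]
    if (ty == "INS") {
      score <- breakpoint_distance(a, b)
      keep <- score <= criteria$ins_max_breakpoint_dist
    } else {
      score <- reciprocal_overlap(a, b)
      keep <- score >= criteria$del_min_reciprocal_overlap
    }
    out[[ty]] <- tibble::tibble(
      call_idx = ci[hits[keep, 1]], ref_idx = ri[hits[keep, 2]],
      svtype = ty, score = score[keep]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(call_idx = integer(), ref_idx = integer(),
                          svtype = character(), score = numeric()))
  }
  dplyr::bind_rows(out)
}

# One-to-one assignment over candidate pairs: maximize pair count, then
# total score (INS: minimize summed distance; DEL: maximize summed overlap).
# Returns the selected row indices of `cand`.
assign_one_to_one <- function(cand, calls, refs, exact_limit = 12L) {
  if (nrow(cand) == 0) return(integer(0))
  # value to MAXIMIZE per pair; integer-friendly
  cand$value <- ifelse(cand$svtype == "INS", -cand$score, cand$score)
  comp <- edge_components(cand$call_idx, cand$ref_idx)
  selected <- integer(0)
  for (edges in comp) {
    sub <- cand[edges, ]
    nc <- length(unique(sub$call_idx)); nr <- length(unique(sub$ref_idx))
    sel <- if (nc <= exact_limit && nr <= exact_limit) {
      solve_component_exact(sub, calls, refs)
    } else {
      solve_component_greedy(sub, calls, refs)
    }
    selected <- c(selected, edges[sel])
  }
  selected
}

# Connected components of the bipartite candidate graph; returns a list of
# edge-index vectors.
edge_components <- function(call_idx, ref_idx) {
  cnode <- match(call_idx, sort(unique(call_idx)))
  rnode <- match(ref_idx, sort(unique(ref_idx))) + max(cnode)
  parent <- seq_len(max(rnode))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(cnode)) {
    a <- find(cnode[k]); b <- find(rnode[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(cnode, find, integer(1))
  unname(split(seq_along(cnode), roots))
}

# Exact solver: bitmask DP over calls, refs processed in (chrom, pos) order.
# dp[i][mask] = best total value for the first i refs using call-set `mask`;
# number of pairs is popcount(mask). Backtrace prefers pairing over skipping
# and candidates in (value desc, call pos asc) order, giving the documented
# (ref chrom, ref pos, call pos) tie-break.
solve_component_exact <- function(sub, calls, refs) {
  cids <- sort(unique(sub$call_idx))
  rids <- unique(sub$ref_idx)
  rids <- rids[order(refs$chrom[rids], refs$pos[rids], rids)]
  nc <- length(cids); nr <- length(rids)
  sub$orig <- seq_len(nrow(sub))
  sub$c <- match(sub$call_idx, cids)
  sub$r <- match(sub$ref_idx, rids)
  sub <- sub[order(sub$r, -sub$value, calls$pos[sub$call_idx],
                   sub$call_idx), ]
  edges_by_ref <- split(seq_len(nrow(sub)), sub$r)

  nmask <- bitwShiftL(1L, nc)
  neg <- -Inf
  dp <- matrix(neg, nrow = nr + 1L, ncol = nmask)
  dp[1L, 1L] <- 0
  popcnt <- vapply(0:(nmask - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(nc - 1L))) > 0), numeric(1))
  for (i in seq_len(nr)) {
    dp[i + 1L, ] <- dp[i, ]  # skip ref i
    er <- edges_by_ref[[as.character(i)]]
    if (is.null(er)) next
    for (k in er) {
      bit <- bitwShiftL(1L, sub$c[k] - 1L)
      from <- which(dp[i, ] > neg)
      from <- from[bitwAnd(from - 1L, bit) == 0L]
      if (length(from) == 0) next
      to <- from + bit
      cand_val <- dp[i, from] + sub$value[k]
      upd <- cand_val > dp[i + 1L, to] + 1e-9
      dp[i + 1L, to[upd]] <- cand_val[upd]
    }
  }
  final <- dp[nr + 1L, ]
  reach <- which(final > neg)
  best_pairs <- max(popcnt[reach])
  pool <- reach[popcnt[reach] == best_pairs]
  best_mask <- pool[which.max(final[pool])]

  # backtrace
  chosen <- integer(0)
  mask <- best_mask
  val <- final[best_mask]
  for (i in rev(seq_len(nr))) {
    if (abs(dp[i, mask] - val) < 1e-9 && !is.infinite(dp[i, mask])) {
      next  # ref i skipped
    }
    er <- edges_by_ref[[as.character(i)]]
    done <- FALSE
    for (k in er) {
      bit <- bitwShiftL(1L, sub$c[k] - 1L)
      if (bitwAnd(mask - 1L, bit) == 0L) next
      prev <- mask - bit
      if (!is.infinite(dp[i, prev]) &&
          abs(dp[i, prev] + sub$value[k] - val) < 1e-9) {
        chosen <- c(chosen, k)
        mask <- prev; val <- dp[i, prev]; done <- TRUE
        break
      }
    }
    if (!done) stop("internal error: assignment backtrace failed")
  }
  sort(sub$orig[chosen])
}

# Greedy fallback for oversized components: sweep candidates best-score
# first with (ref chrom, ref pos, call pos) tie-break.
solve_component_greedy <- function(sub, calls, refs) {
  ord <- order(-sub$value, refs$chrom[sub$ref_idx], refs$pos[sub$ref_idx],
               calls$pos[sub$call_idx], sub$call_idx)
  used_c <- integer(0); used_r <- integer(0); sel <- integer(0)
  for (k in ord) {
    if (sub$call_idx[k] %in% used_c || sub$ref_idx[k] %in% used_r) next
    sel <- c(sel, k)
    used_c <- c(used_c, sub$call_idx[k]); used_r <- c(used_r, sub$ref_idx[k])
  }
  sort(sel)
}

#' Compare a callset with a truth set inside benchmark regions
#'
#' Restricts both the calls and the truth set to the benchmark regions
#' (records whose breakpoints fall outside contribute to neither TP, FP nor
#' FN), then matches them with [match_callsets()].
#'
#' @param calls,truth Tibbles of SV records.
#' @param bench_regions Benchmark region set; `NULL` to skip restriction.
#' @param criteria A [match_criteria()].
#' @return An `"sv_match"` object.
#' @export
compare_to_benchmark <- function(calls, truth, bench_regions = NULL,
                                 criteria = match_criteria()) {
  if (!is.null(bench_regions)) {
    calls <- restrict_to_regions(calls, bench_regions)
    truth <- restrict_to_regions(truth, bench_regions)
  }
  match_callsets(calls, truth, criteria)
}

#' @export
print.sv_match <- function(x, ...) {
  cat("<sv_match> ", nrow(x$pairs), " pairs: TP=", nrow(x$tp_calls),
      " FP=", nrow(x$fp_calls), " FN=", nrow(x$fn_refs), "\n", sep = "")
  invisible(x)
}
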