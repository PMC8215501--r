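# Independent brute-force matching oracle: enumerates one-to-one assignments
# (memoized over reference index x used-call bitmask) and returns the
# maximum-cardinality, then maximum-total-value solution. Value per pair:
# +reciprocal overlap for deletions, -breakpoint distance for insertions,
# both computed here from first principles.

oracle_candidates <- function(calls, refs, ins_win = 200, del_ro = 0.5) {
  cand <- vector("list", nrow(refs))
  for (j in seq_len(nrow(refs))) {
    lst <- list()
    for (i in seq_len(nrow(calls))) {
      if (calls$svtype[i] != refs$svtype[j]) next
      if (calls$chrom[i] != refs$chrom[j]) next
      if (calls$svtype[i] == "INS") {
        d <- abs(calls$pos[i] - refs$pos[j])
        if (d <= ins_win) lst[[length(lst) + 1]] <- c(i, -d)
      } else {
        la <- calls$end[i] - calls$pos[i]; lb <- refs$end[j] - refs$pos[j]
        o <- max(0, min(calls$end[i], refs$end[j]) -
                   max(calls$pos[i], refs$pos[j]))
        ro <- min(o / la, o / lb)
        if (ro >= del_ro) lst[[length(lst) + 1]] <- c(i, ro)
      }
    }
    cand[[j]] <- lst
  }
  cand
}

# returns c(n_pairs, total_value)
oracle_best_assignment <- function(calls, refs, ins_win = 200,
                                   del_ro = 0.5) {
  cand <- oracle_candidates(calls, refs, ins_win, del_ro)
  nr <- nrow(refs)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(j, mask) {
    if (j > nr) return(c(0, 0))
    key <- paste(j, mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(j + 1, mask)  # leave ref j unmatched
    for (e in cand[[j]]) {
      bit <- bitwShiftL(1L, e[1] - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      sub <- rec(j + 1, bitwOr(mask, bit))
      trial <- c(sub[1] + 1, sub[2] + e[2])
      if (trial[1] > best[1] ||
          (trial[1] == best[1] && trial[2] > best[2] + 1e-12)) {
        best <- trial
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L)
}

# total value of an sv_match under the oracle's value convention
match_total_value <- function(m) {
  if (nrow(m$pairs) == 0) return(0)
  sum(ifelse(m$pairs$svtype == "INS", -m$pairs$score, m$pairs$score))
}

# random mixed callset over a compact span so that candidate conflicts occur
random_callset <- function(n, source = "x", span = 30000L,
                           chroms = c("1", "2")) {
  if (n == 0) return(empty_sv_tbl())
  svtype <- sample(c("INS", "DEL"), n, replace = TRUE)
  svlen <- sample(50:2000, n, replace = TRUE)
  pos <- sample(seq_len(span), n, replace = TRUE) + 1000L
  sv_tbl(chrom = sample(chroms, n, replace = TRUE, prob = c(0.8, 0.2)),
         pos = pos, end = pos + ifelse(svtype == "INS", 0L, svlen),
         svtype = svtype, svlen = svlen, source = source,
         id = sprintf("%s%04d", source, seq_len(n)))
}

# brute-force membership: is 1-based breakpoint p inside any region row?
linear_scan_in_regions <- function(record, regions) {
  pts <- if (record$svtype == "DEL") c(record$pos, record$end) else record$pos
  for (p in pts) {
    hit <- any(regions$chrom == record$chrom &
                 regions$start <= (p - 1) & (p - 1) < regions$end)
    if (hit) return(TRUE)
  }
  FALSE
}
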