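#' Configuration for the synthetic SV benchmark generator
#'
#' Describes the simulated study: a small multi-chromosome genome, a truth
#' callset of insertions and deletions spanning the four standard size bins,
#' tandem-repeat regions covering a configurable genome fraction (with SVs
#' enriched inside them), benchmark regions covering every truth record plus
#' margins, and per-pipeline callsets derived from the truth with planted
#' false negatives, false positives, breakpoint jitter and IMPRECISE flags.
#'
#' Defaults emulate the structure of a real trio benchmark: insertions make
#' up 7281/12745 of the truth (the composition of a high-confidence
#' insertion/deletion truth set), sizes fall off quickly across the
#' 50-100 / 100-300 / 300-1000 / >1000 bp bins, TRRs cover about 10% of the
#' genome, and the enrichment multiplier places roughly a third of SVs
#' inside them.
#'
#' @param seed RNG seed for truth and region generation.
#' @param n_chroms,chrom_length Genome model (equal-length chromosomes
#'   named `"1"`, `"2"`, ...).
#' @param n_truth Number of truth SVs.
#' @param ins_fraction Fraction of insertions (the rest are deletions).
#' @param size_mix Probability per size bin, summing to 1.
#' @param max_size Upper bound for the open top bin, bp.
#' @param trr_genome_fraction Target fraction of the genome covered by TRRs.
#' @param trr_sv_enrichment Multiplier on `trr_genome_fraction` giving the
#'   probability that a truth SV is placed inside a TRR.
#' @param min_gap Minimum distance between the extents of two planted
#'   records, bp. Must exceed twice the largest recoverable jitter plus the
#'   insertion match window so that planted records can never cross-match.
#' @param fp_guard Minimum distance between a planted false positive and any
#'   truth extent, bp.
#' @param bench_margin Margin around truth extents included in the benchmark
#'   regions, bp; must exceed `fp_guard` so false positives have room
#'   inside the regions.
#' @param denovo_rate Fraction of son records planted as de novo in
#'   [generate_trio()].
#' @param parent_extra_fraction Untransmitted records per parent, as a
#'   fraction of the inherited son records.
#' @return A list with class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L, chrom_length = 2e7,
                             n_truth = 1000L,
                             ins_fraction = 7281 / 12745,
                             size_mix = c(0.50, 0.30, 0.15, 0.05),
                             max_size = 5000L,
                             trr_genome_fraction = 0.10,
                             trr_sv_enrichment = 3.5,
                             min_gap = 6000L,
                             fp_guard = 1500L,
                             bench_margin = 3000L,
                             denovo_rate = 0.20,
                             parent_extra_fraction = 0.5) {
  stopifnot(
    abs(sum(size_mix) - 1) < 1e-9, length(size_mix) == 4,
    ins_fraction >= 0, ins_fraction <= 1,
    trr_genome_fraction >= 0, trr_genome_fraction < 1,
    denovo_rate >= 0, denovo_rate <= 1,
    bench_margin > fp_guard
  )
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_length = as.integer(chrom_length),
         n_truth = as.integer(n_truth), ins_fraction = ins_fraction,
         size_mix = size_mix, max_size = as.integer(max_size),
         trr_genome_fraction = trr_genome_fraction,
         trr_sv_enrichment = trr_sv_enrichment,
         min_gap = as.integer(min_gap), fp_guard = as.integer(fp_guard),
         bench_margin = as.integer(bench_margin),
         denovo_rate = denovo_rate,
         parent_extra_fraction = parent_extra_fraction),
    class = "synthetic_config"
  )
}

#' Generate a synthetic truth set with TRR and benchmark regions
#'
#' Truth records are at least 50 bp, deletions never overlap (planted
#' extents keep a `min_gap` separation, which also guarantees that distinct
#' planted records can never satisfy the matching criteria against each
#' other), and each record is placed inside a TRR with probability
#' `trr_genome_fraction * trr_sv_enrichment`. Benchmark regions are the
#' merged truth extents padded by `bench_margin`, so every truth breakpoint
#' lies well inside them. Deterministic under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `"sv_bundle"`: a list with `truth` (SV
#'   tibble, `source = "truth"`, plus a `planted_in_trr` column), `trr` and
#'   `bench` region sets, `callsets` (empty named list, see
#'   [derive_callset()]), `labels` and `config`.
#' @export
generate_truth <- function(config = synthetic_config()) {
  set.seed(config$seed)
  chrom_lengths <- stats::setNames(
    rep(config$chrom_length, config$n_chroms),
    as.character(seq_len(config$n_chroms))
  )
  trr <- generate_trr_regions(chrom_lengths, config$trr_genome_fraction)
  p_trr <- min(1, config$trr_genome_fraction * config$trr_sv_enrichment)

  n <- config$n_truth
  svtype <- ifelse(stats::runif(n) < config$ins_fraction, "INS", "DEL")
  svlen <- sample_sizes(n, config$size_mix, config$max_size)
  want_trr <- stats::runif(n) < p_trr
  placed <- place_spans(
    sizes = ifelse(svtype == "INS", 0L, svlen), want_trr = want_trr,
    trr = trr, chrom_lengths = chrom_lengths, min_gap = config$min_gap,
    occupied = NULL
  )
  truth <- sv_tbl(
    chrom = placed$chrom, pos = placed$pos,
    end = placed$pos + ifelse(svtype == "INS", 0L, svlen),
    svtype = svtype, svlen = svlen, source = "truth",
    id = sprintf("truth%05d", seq_len(n))
  )
  truth$planted_in_trr <- want_trr

  bench <- bench_from_truth(truth, chrom_lengths, config$bench_margin)
  structure(
    list(truth = truth, trr = trr, bench = bench,
         callsets = list(), labels = list(),
         chrom_lengths = chrom_lengths, config = config),
    class = "sv_bundle"
  )
}

#' Derive a labeled pipeline callset from a truth bundle
#'
#' Each truth record is dropped with probability `fn_rate` (a planted false
#' negative); survivors are emitted with breakpoint jitter drawn from a
#' rounded normal and truncated to recoverable bounds — insertion
#' breakpoints move at most half the 200 bp match window, deletion endpoints
#' at most a sixth of the span, which keeps the reciprocal overlap with the
#' source record (and with any independently jittered copy of it) at or
#' above 50%. A fraction `unrecoverable_rate` of the survivors is instead
#' displaced just beyond the matching criteria, turning the call into a
#' planted false positive and its truth record into a planted false
#' negative. `fp_rate * n_truth` unmatched false positives are placed inside
#' the benchmark regions at least `fp_guard` away from every truth extent,
#' so they can never be matched. Provenance labels are recorded in
#' `bundle$labels[[name]]`, and the expected evaluation outcome is an exact
#' integer consequence of the labels (see [bundle_expected()]).
#'
#' @param bundle An `"sv_bundle"` from [generate_truth()].
#' @param name Callset name.
#' @param fn_rate,fp_rate Planted false-negative and false-positive rates.
#' @param breakpoint_jitter_sd Jitter standard deviation, bp (0 = exact
#'   copies).
#' @param imprecise_rate Fraction of calls flagged IMPRECISE.
#' @param unrecoverable_rate Fraction of surviving calls displaced beyond
#'   the matching criteria.
#' @param seed RNG seed for this callset.
#' @return The bundle with the new callset appended to `bundle$callsets`
#'   and its labels to `bundle$labels`.
#' @export
derive_callset <- function(bundle, name, fn_rate = 0, fp_rate = 0,
                           breakpoint_jitter_sd = 0, imprecise_rate = 0,
                           unrecoverable_rate = 0, seed = 1L) {
  stopifnot(inherits(bundle, "sv_bundle"))
  set.seed(seed)
  truth <- bundle$truth
  n <- nrow(truth)
  dropped <- stats::runif(n) < fn_rate
  kept <- which(!dropped)
  unrec <- kept[stats::runif(length(kept)) < unrecoverable_rate]
  recov <- setdiff(kept, unrec)

  calls <- dplyr::select(truth[kept, ], -dplyr::any_of("planted_in_trr"))
  calls$source <- name
  if (breakpoint_jitter_sd > 0 && length(recov) > 0) {
    calls[match(recov, kept), ] <- jitter_recoverable(
      truth[recov, ], breakpoint_jitter_sd, name
    )
  }
  if (length(unrec) > 0) {
    calls[match(unrec, kept), ] <- displace_unrecoverable(truth[unrec, ], name)
  }
  n_fp <- round(fp_rate * n)
  fps <- place_false_positives(bundle, n_fp, name)
  calls <- dplyr::bind_rows(calls, fps)
  calls$id <- sprintf("%s_%05d", name, seq_len(nrow(calls)))
  calls$precise <- stats::runif(nrow(calls)) >= imprecise_rate
  calls <- validate_sv_tbl(calls)

  labels <- tibble::tibble(
    call_id = calls$id,
    label = c(ifelse(kept %in% unrec, "FP_displaced", "TP"),
              rep("FP_planted", n_fp)),
    truth_id = c(truth$id[kept], rep(NA_character_, n_fp))
  )
  labels$truth_id[labels$label != "TP"] <- NA_character_
  bundle$callsets[[name]] <- calls
  bundle$labels[[name]] <- labels
  bundle
}

#' Expected evaluation outcome implied by a bundle's labels
#'
#' Recomputes, from the provenance labels alone (no matching), the TP/FP/FN
#' counts and expected precision and recall each callset must achieve
#' against the truth. By construction these are exact integer identities:
#' every call labeled `TP` is recoverable under the matching criteria, every
#' other call can match nothing.
#'
#' @param bundle An `"sv_bundle"` with callsets.
#' @return A tibble with one row per callset: `source`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
bundle_expected <- function(bundle) {
  purrr::imap_dfr(bundle$labels, function(lab, name) {
    tp <- sum(lab$label == "TP")
    fp <- sum(lab$label != "TP")
    fn <- nrow(bundle$truth) - tp
    dplyr::bind_cols(source = name, prf_row(tp, fp, fn))
  })
}

#' Generate a trio of callsets with a planted de novo rate
#'
#' Builds a pooled set of planted variant sites and assigns them to family
#' members: the son carries `n_truth` records of which a fraction
#' `denovo_rate` occur in neither parent; every inherited record is carried
#' by the father only, the mother only, or both (probabilities 0.45 / 0.45 /
#' 0.10); each parent additionally carries untransmitted records. Breakpoint
#' jitter (recoverable by construction) can be applied to the son's copies
#' so inherited records still match their parental counterparts under the
#' standard criteria, making the planted rate exactly recoverable by
#' [denovo_rate()].
#'
#' @param config A [synthetic_config()].
#' @param breakpoint_jitter_sd Jitter on the son's inherited copies, bp.
#' @return A list with `son`, `father`, `mother` (SV tibbles), `trr`, the
#'   planted `expected_denovo` count and `config`.
#' @export
generate_trio <- function(config = synthetic_config(),
                          breakpoint_jitter_sd = 0) {
  set.seed(config$seed + 1L)
  chrom_lengths <- stats::setNames(
    rep(config$chrom_length, config$n_chroms),
    as.character(seq_len(config$n_chroms))
  )
  trr <- generate_trr_regions(chrom_lengths, config$trr_genome_fraction)
  p_trr <- min(1, config$trr_genome_fraction * config$trr_sv_enrichment)

  n_son <- config$n_truth
  n_denovo <- as.integer(round(config$denovo_rate * n_son))
  n_inherit <- n_son - n_denovo
  n_extra <- as.integer(round(config$parent_extra_fraction * n_inherit))
  n_pool <- n_son + 2L * n_extra

  svtype <- ifelse(stats::runif(n_pool) < config$ins_fraction, "INS", "DEL")
  svlen <- sample_sizes(n_pool, config$size_mix, config$max_size)
  want_trr <- stats::runif(n_pool) < p_trr
  placed <- place_spans(
    sizes = ifelse(svtype == "INS", 0L, svlen), want_trr = want_trr,
    trr = trr, chrom_lengths = chrom_lengths, min_gap = config$min_gap,
    occupied = NULL
  )
  pool <- sv_tbl(
    chrom = placed$chrom, pos = placed$pos,
    end = placed$pos + ifelse(svtype == "INS", 0L, svlen),
    svtype = svtype, svlen = svlen, source = "pool",
    id = sprintf("site%05d", seq_len(n_pool))
  )

  son_sites <- seq_len(n_son)
  denovo_sites <- son_sites[seq_len(n_denovo)]
  inherit_sites <- setdiff(son_sites, denovo_sites)
  origin <- sample(c("father", "mother", "both"), length(inherit_sites),
                   replace = TRUE, prob = c(0.45, 0.45, 0.10))
  father_sites <- c(inherit_sites[origin %in% c("father", "both")],
                    n_son + seq_len(n_extra))
  mother_sites <- c(inherit_sites[origin %in% c("mother", "both")],
                    n_son + n_extra + seq_len(n_extra))

  make_member <- function(sites, who) {
    x <- pool[sort(sites), ]
    x$source <- who
    x$id <- sprintf("%s_%05d", who, seq_len(nrow(x)))
    x
  }
  son <- make_member(son_sites, "son")
  if (breakpoint_jitter_sd > 0) {
    son <- jitter_recoverable(son, breakpoint_jitter_sd, "son")
  }
  list(son = son,
       father = make_member(father_sites, "father"),
       mother = make_member(mother_sites, "mother"),
       trr = trr, expected_denovo = n_denovo, config = config)
}

#' Write a synthetic bundle to a directory
#'
#' Emits `truth.vcf`, one `<name>.vcf` per callset, `trr.bed`, `bench.bed`
#' and `expected.json` (the [bundle_expected()] table plus per-callset
#' labels), such that re-ingesting the files through [read_sv_vcf()] /
#' [load_bed()] reproduces the in-memory records.
#'
#' @param bundle An `"sv_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", dir, "'", call. = FALSE)
  }
  write_sv_vcf(bundle$truth, file.path(dir, "truth.vcf"))
  for (name in names(bundle$callsets)) {
    write_sv_vcf(bundle$callsets[[name]], file.path(dir, paste0(name, ".vcf")))
  }
  if (nrow(bundle$trr) > 0) write_bed(bundle$trr, file.path(dir, "trr.bed"))
  write_bed(bundle$bench, file.path(dir, "bench.bed"))
  jsonlite::write_json(
    list(expected = bundle_expected(bundle), labels = bundle$labels),
    file.path(dir, "expected.json"), dataframe = "columns"
  )
  invisible(dir)
}

# ---- internal generation machinery ----------------------------------------

# Non-overlapping TRR intervals laid out by an exponential-gap walk tuned to
# the target coverage fraction; interval lengths uniform in [500, 3000] bp.
generate_trr_regions <- function(chrom_lengths, fraction) {
  if (fraction <= 0) {
    return(region_tbl(character(), integer(), integer(), name = "TRR"))
  }
  mean_len <- 1750
  mean_gap <- mean_len * (1 - fraction) / fraction
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n_est <- ceiling(len / (mean_len + mean_gap)) * 2L
    gaps <- stats::rexp(n_est, rate = 1 / mean_gap)
    widths <- as.integer(stats::runif(n_est, 500, 3000))
    starts <- as.integer(cumsum(gaps + widths) - widths)
    keep <- starts + widths < len
    out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep],
                                end = starts[keep] + widths[keep])
  }
  tab <- dplyr::bind_rows(out)
  region_tbl(tab$chrom, tab$start, tab$end, label = "Simple_repeat",
             name = "TRR")
}

sample_sizes <- function(n, size_mix, max_size) {
  lo <- c(50L, 100L, 300L, 1000L)
  hi <- c(99L, 299L, 999L, max_size)
  bin <- sample.int(4L, n, replace = TRUE, prob = size_mix)
  as.integer(floor(stats::runif(n, lo[bin], hi[bin] + 1)))
}

# Rejection-place spans (size 0 = insertion breakpoint) so that extents keep
# `min_gap` from each other and from `occupied`; records with want_trr have
# their start breakpoint inside a TRR interval, others keep both breakpoints
# outside every TRR.
place_spans <- function(sizes, want_trr, trr, chrom_lengths, min_gap,
                        occupied = NULL, max_tries = 200L) {
  n <- length(sizes)
  trr_by_chrom <- split(trr, trr$chrom)
  occ <- lapply(chrom_lengths, function(...) {
    list(start = integer(), end = integer())
  })
  if (!is.null(occupied)) {
    for (ch in names(occupied)) occ[[ch]] <- occupied[[ch]]
  }
  chroms <- names(chrom_lengths)
  pr <- chrom_lengths / sum(chrom_lengths)
  out_chrom <- character(n); out_pos <- integer(n)
  n_trr_rows <- nrow(trr)
  for (i in seq_len(n)) {
    size <- sizes[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (want_trr[i] && n_trr_rows > 0) {
        r <- trr[sample.int(n_trr_rows, 1L), ]
        ch <- r$chrom
        pos <- as.integer(floor(stats::runif(1, r$start + 1L, r$end + 1)))
      } else {
        ch <- sample(chroms, 1L, prob = pr)
        pos <- as.integer(floor(stats::runif(1, min_gap + 1,
                                             chrom_lengths[[ch]] - size -
                                               min_gap)))
        tr <- trr_by_chrom[[ch]]
        if (!is.null(tr) &&
            (point_in_sorted(pos, tr) || point_in_sorted(pos + size, tr))) {
          next
        }
      }
      if (pos <= min_gap || pos + size + min_gap >= chrom_lengths[[ch]]) next
      s <- pos; e <- pos + size
      o <- occ[[ch]]
      if (length(o$start) > 0 &&
          any(o$start - min_gap < e & o$end + min_gap > s)) next
      occ[[ch]]$start <- c(o$start, s); occ[[ch]]$end <- c(o$end, e)
      out_chrom[i] <- ch; out_pos[i] <- pos
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("cannot place ", n, " records on a ",
           sum(chrom_lengths), " bp genome with min_gap = ", min_gap,
           "; enlarge the genome or reduce n_truth", call. = FALSE)
    }
  }
  list(chrom = out_chrom, pos = out_pos, occupied = occ)
}

# Fast membership of 1-based point p in non-overlapping sorted regions.
point_in_sorted <- function(p, reg) {
  i <- findInterval(p - 1L, reg$start)
  i > 0 && (p - 1L) < reg$end[i]
}

# Recoverable jitter: INS breakpoints move at most floor(window / 2) = 100
# bp; DEL endpoints at most floor(len / 6), which keeps reciprocal overlap
# >= 0.5 against the source record and any independently jittered copy.
jitter_recoverable <- function(records, sd, source) {
  n <- nrow(records)
  is_ins <- records$svtype == "INS"
  d1 <- as.integer(round(stats::rnorm(n, 0, sd)))
  d2 <- as.integer(round(stats::rnorm(n, 0, sd)))
  ins_cap <- 100L
  # stay recoverable (<= len/6 per endpoint) AND >= 50 bp after shrinking
  del_cap <- pmax(0L, pmin(as.integer(floor(records$svlen / 6)) - 1L,
                           as.integer(floor((records$svlen - 50L) / 2))))
  d1 <- pmin(pmax(d1, -ifelse(is_ins, ins_cap, del_cap)),
             ifelse(is_ins, ins_cap, del_cap))
  d2 <- pmin(pmax(d2, -del_cap), del_cap)
  pos <- records$pos + d1
  end <- ifelse(is_ins, pos, records$end + d2)
  sv_tbl(chrom = records$chrom, pos = pos, end = end,
         svtype = records$svtype,
         svlen = ifelse(is_ins, records$svlen, end - pos),
         filter = records$filter, precise = records$precise,
         source = source, id = records$id)
}

# Displace a record just beyond the matching criteria: an INS breakpoint
# moves 201-400 bp (outside the window, still far from every other planted
# record); a DEL span shifts right by ceil(0.6 * len), size preserved, so
# the reciprocal overlap with the source drops to <= 0.4.
displace_unrecoverable <- function(records, source) {
  n <- nrow(records)
  is_ins <- records$svtype == "INS"
  ins_shift <- as.integer(stats::runif(n, 201, 401)) *
    sample(c(-1L, 1L), n, replace = TRUE)
  del_shift <- as.integer(ceiling(records$svlen * 0.6))
  pos <- ifelse(is_ins, records$pos + ins_shift, records$pos + del_shift)
  end <- ifelse(is_ins, pos, records$end + del_shift)
  sv_tbl(chrom = records$chrom, pos = pos, end = end,
         svtype = records$svtype, svlen = records$svlen,
         filter = records$filter, precise = records$precise,
         source = source, id = records$id)
}

# False positives inside benchmark regions, >= fp_guard from every truth
# extent.
place_false_positives <- function(bundle, n_fp, name) {
  if (n_fp == 0) return(empty_sv_tbl())
  cfg <- bundle$config
  truth <- bundle$truth
  svtype <- ifelse(stats::runif(n_fp) < cfg$ins_fraction, "INS", "DEL")
  svlen <- sample_sizes(n_fp, cfg$size_mix, cfg$max_size)
  occupied <- lapply(split(truth, truth$chrom), function(x) {
    list(start = x$pos, end = x$end)
  })
  # guard against truth via min_gap = fp_guard; want_trr irrelevant here
  placed <- place_spans(
    sizes = ifelse(svtype == "INS", 0L, svlen),
    want_trr = rep(FALSE, n_fp),
    trr = region_tbl(character(), integer(), integer(), name = "none"),
    chrom_lengths = bundle$chrom_lengths,
    min_gap = cfg$fp_guard, occupied = occupied
  )
  # keep only FPs whose breakpoints fall inside the benchmark regions
  fp <- sv_tbl(
    chrom = placed$chrom, pos = placed$pos,
    end = placed$pos + ifelse(svtype == "INS", 0L, svlen),
    svtype = svtype, svlen = svlen, source = name
  )
  inside <- breakpoints_in_regions(fp, bundle$bench)
  if (!all(inside)) {
    # re-place the strays by sampling positions directly inside bench gaps
    fp <- fp[inside, ]
    need <- n_fp - nrow(fp)
    extra <- place_fp_in_bench(bundle, need, name)
    fp <- dplyr::bind_rows(fp, extra)
  }
  fp
}

# Direct placement of insertion FPs in benchmark margins: positions at
# fp_guard..bench_margin beyond a random truth extent (still inside bench,
# guarded from every truth record because truth extents are min_gap apart).
place_fp_in_bench <- function(bundle, n, name) {
  if (n <= 0) return(empty_sv_tbl())
  cfg <- bundle$config
  truth <- bundle$truth
  idx <- sample.int(nrow(truth), n, replace = TRUE)
  hi <- min(cfg$bench_margin, cfg$min_gap - cfg$bench_margin) - 1L
  stopifnot(hi > cfg$fp_guard + 1L)
  off <- as.integer(stats::runif(n, cfg$fp_guard + 1, hi))
  side <- sample(c(-1L, 1L), n, replace = TRUE)
  pos <- ifelse(side > 0, truth$end[idx] + off, truth$pos[idx] - off)
  sv_tbl(chrom = truth$chrom[idx], pos = pos, end = pos,
         svtype = "INS", svlen = sample_sizes(n, cfg$size_mix, cfg$max_size),
         source = name)
}

bench_from_truth <- function(truth, chrom_lengths, margin) {
  out <- purrr::map_dfr(split(truth, truth$chrom), function(x) {
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, x$pos - margin), end = x$end + margin
    ))
    tibble::tibble(chrom = x$chrom[1],
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir))
  })
  region_tbl(out$chrom, out$start, out$end, name = "benchmark")
}
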