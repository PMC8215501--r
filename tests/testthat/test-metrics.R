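test_that("precision/recall/F1 formulas and undefined propagation", {
  got <- compute_prf(list(tp = 8, fp = 2, fn = 8))
  expect_equal(got$precision, 0.8)
  expect_equal(got$recall, 0.5)
  expect_equal(got$f1, 2 * 0.8 * 0.5 / 1.3)

  degenerate <- compute_prf(list(tp = 0, fp = 0, fn = 5))
  expect_true(is.na(degenerate$precision))
  expect_equal(degenerate$recall, 0)
  expect_true(is.na(degenerate$f1))  # NA, never a silent 0

  set.seed(9)
  x <- random_callset(12, "p")
  perfect <- compute_prf(match_callsets(x, x))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
})

test_that("F1 lies between precision and recall whenever defined", {
  set.seed(13)
  for (k in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    r <- compute_prf(list(tp = tp, fp = fp, fn = fn))
    if (!is.na(r$f1)) {
      expect_gte(r$f1 + 1e-12, min(r$precision, r$recall))
      expect_lte(r$f1 - 1e-12, max(r$precision, r$recall))
    }
  }
})

test_that("size bins are half-open with the top bin at >1000", {
  bins <- size_bins()
  expect_equal(size_bin(c(50, 99, 100, 299, 300, 999, 1000, 4000), bins),
               c("50-100", "50-100", "100-300", "100-300", "300-1000",
                 "300-1000", ">1000", ">1000"))
  expect_error(size_bin(49, bins), "size-filtered")
  expect_error(size_bins(c(100, 100)))
})

test_that("stratified metrics recover planted per-stratum counts exactly", {
  cfg <- synthetic_config(seed = 21, n_truth = 400)
  b <- generate_truth(cfg)
  b <- derive_callset(b, "pipe", fn_rate = 0.25, fp_rate = 0.1,
                      breakpoint_jitter_sd = 25, seed = 5)
  calls <- b$callsets$pipe
  lab <- b$labels$pipe
  got <- stratified_metrics(calls, b$truth, b$trr, b$bench)

  # expected per-stratum counts straight from the generator labels
  truth_st <- tibble::tibble(
    id = b$truth$id, svtype = b$truth$svtype,
    trr_status = ifelse(breakpoints_in_regions(b$truth, b$trr),
                        "in_TRR", "outside_TRR"),
    size_bin = size_bin(b$truth)
  )
  call_st <- tibble::tibble(
    id = calls$id, svtype = calls$svtype,
    trr_status = ifelse(breakpoints_in_regions(calls, b$trr),
                        "in_TRR", "outside_TRR"),
    size_bin = size_bin(calls)
  )
  tp_ids <- lab$truth_id[lab$label == "TP"]
  for (i in seq_len(nrow(got))) {
    st <- got[i, ]
    pick <- function(x) {
      x$svtype == st$svtype & x$trr_status == st$trr_status &
        (st$size_bin == "all" | x$size_bin == st$size_bin)
    }
    exp_tp <- sum(pick(truth_st) & truth_st$id %in% tp_ids)
    exp_fn <- sum(pick(truth_st) & !(truth_st$id %in% tp_ids))
    fp_ids <- lab$call_id[lab$label != "TP"]
    exp_fp <- sum(pick(call_st) & call_st$id %in% fp_ids)
    expect_equal(c(st$tp, st$fp, st$fn), c(exp_tp, exp_fp, exp_fn))
  }

  # conservation across the "all" slice
  all_slice <- got[got$size_bin == "all", ]
  expect_equal(sum(all_slice$tp), sum(lab$label == "TP"))
  expect_equal(sum(all_slice$fp), sum(lab$label != "TP"))
  expect_equal(sum(all_slice$fn), nrow(b$truth) - sum(lab$label == "TP"))
  # size bins within type tile the type totals
  per_type <- dplyr::count(got[got$size_bin != "all", ],
                           .data$svtype, wt = .data$tp)
  per_type_all <- dplyr::count(all_slice, .data$svtype, wt = .data$tp)
  expect_equal(per_type, per_type_all)
})

test_that("all-INS input leaves every DEL stratum empty", {
  cfg <- synthetic_config(seed = 31, n_truth = 120, ins_fraction = 1)
  b <- generate_truth(cfg)
  b <- derive_callset(b, "pipe", seed = 2)
  got <- stratified_metrics(b$callsets$pipe, b$truth, b$trr, b$bench)
  delrows <- got[got$svtype == "DEL", ]
  expect_true(all(delrows$tp == 0 & delrows$fp == 0 & delrows$fn == 0))
  expect_true(all(is.na(delrows$f1)))
})

test_that("match-then-stratify and stratify-then-match agree on well-separated data", {
  cfg <- synthetic_config(seed = 41, n_truth = 150)
  b <- generate_truth(cfg)
  b <- derive_callset(b, "pipe", fn_rate = 0.2, fp_rate = 0.1, seed = 3)
  a <- stratified_metrics(b$callsets$pipe, b$truth, b$trr, b$bench)
  s <- stratified_metrics(b$callsets$pipe, b$truth, b$trr, b$bench,
                          stratify_first = TRUE)
  expect_equal(a[c("svtype", "trr_status", "size_bin", "tp", "fn")],
               s[c("svtype", "trr_status", "size_bin", "tp", "fn")])
})

test_that("micro and macro TRR aggregates are labeled and consistent", {
  cfg <- synthetic_config(seed = 51, n_truth = 200)
  b <- generate_truth(cfg)
  b <- derive_callset(b, "pipe", fn_rate = 0.3, fp_rate = 0.1, seed = 4)
  strat <- stratified_metrics(b$callsets$pipe, b$truth, b$trr, b$bench)
  agg <- aggregate_trr_metrics(strat)
  expect_setequal(agg$aggregation, c("micro", "macro"))
  micro_in <- agg[agg$aggregation == "micro" & agg$trr_status == "in_TRR", ]
  base_in <- strat[strat$size_bin == "all" & strat$trr_status == "in_TRR", ]
  expect_equal(micro_in$tp, sum(base_in$tp))
  expect_equal(micro_in$precision,
               sum(base_in$tp) / (sum(base_in$tp) + sum(base_in$fp)))
  macro_in <- agg[agg$aggregation == "macro" & agg$trr_status == "in_TRR", ]
  expect_equal(macro_in$precision, mean(base_in$precision))
})

test_that("IMPRECISE-subset precision is computed over the flagged calls only", {
  # plant 1 recoverable + 4 unmatched flagged calls: precision 0.2
  truth <- sv_tbl(chrom = "1", pos = c(10000L, 20000L),
                  svtype = "INS", svlen = 100L, id = c("t1", "t2"),
                  source = "truth")
  calls <- sv_tbl(
    chrom = "1",
    pos = c(10050L, 30000L, 40000L, 50000L, 60000L, 20010L),
    svtype = "INS", svlen = 100L,
    precise = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    id = sprintf("c%d", 1:6), source = "pipe"
  )
  got <- flag_subset_precision(calls, truth)
  expect_equal(got$tp, 1L)
  expect_equal(got$fp, 4L)
  expect_equal(got$precision, 0.2)

  # no flagged calls -> undefined with a warning
  calls$precise <- TRUE
  expect_warning(none <- flag_subset_precision(calls, truth), "undefined")
  expect_true(is.na(none$precision))

  # all calls flagged -> equals global precision
  calls$precise <- FALSE
  all_fl <- flag_subset_precision(calls, truth)
  glob <- compute_prf(match_callsets(calls, truth))
  expect_equal(all_fl$precision, glob$precision)
})

test_that("precision converges to the planted rate on stochastic bundles", {
  # fp_rate 0.15 with fn_rate 0.2: planted precision = kept/(kept + n_fp)
  cfg <- synthetic_config(seed = 61)
  b <- generate_truth(cfg)
  b <- derive_callset(b, "pipe", fn_rate = 0.2, fp_rate = 0.15,
                      breakpoint_jitter_sd = 40, seed = 6)
  m <- compare_to_benchmark(b$callsets$pipe, b$truth, b$bench)
  got <- compute_prf(m)
  exp <- bundle_expected(b)
  # exact by construction, hence trivially within 3 binomial SE of the
  # planted expectation
  expect_equal(got$precision, exp$precision)
  n_calls <- exp$tp + exp$fp
  se <- sqrt(exp$precision * (1 - exp$precision) / n_calls)
  planted <- (1 - 0.2) / ((1 - 0.2) + 0.15)
  expect_lt(abs(got$precision - planted), 3 * se + 0.02)
})
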