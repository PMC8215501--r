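write_rmsk <- function(rows) {
  path <- tempfile(fileext = ".txt")
  writeLines(rows, path)
  path
}

# a full 17-column rmsk row with the coordinate/class fields filled in
rmsk_row <- function(chrom, start, end, class) {
  paste(c("585", "1000", "10", "5", "2", chrom, start, end, "-1000", "+",
          "rep", class, "family", "1", "100", "1", "1"), collapse = "\t")
}

test_that("rmsk parsing keeps only Simple_repeat and Satellite rows", {
  path <- write_rmsk(c(
    rmsk_row("chr1", 100, 200, "Simple_repeat"),
    rmsk_row("chr1", 5000, 5100, "Satellite"),
    rmsk_row("chr1", 9000, 9100, "LINE"),
    rmsk_row("chr2", 100, 300, "SINE"),
    rmsk_row("chr2", 700, 800, "LTR")
  ))
  trr <- load_rmsk_trr(path)
  expect_equal(nrow(trr), 2L)
  expect_equal(trr$label, c("Simple_repeat", "Satellite"))
  expect_equal(trr$start, c(100L, 5000L))  # 0-based half-open preserved

  # chr prefix is stripped
  path7 <- write_rmsk(rmsk_row("chr7", 10, 50, "Simple_repeat"))
  expect_equal(load_rmsk_trr(path7)$chrom, "7")

  # zero qualifying rows is a schema-mismatch hard error
  none <- write_rmsk(rmsk_row("chr1", 1, 2, "LINE"))
  expect_error(load_rmsk_trr(none), "repClass")

  # malformed rows are skipped with a warning
  mixed <- write_rmsk(c(rmsk_row("chr1", 100, 200, "Simple_repeat"),
                        rmsk_row("chr1", 300, 250, "Satellite")))
  expect_warning(got <- load_rmsk_trr(mixed), "malformed")
  expect_equal(nrow(got), 1L)
})

test_that("overlapping repeat rows are retained and queries stay correct", {
  path <- write_rmsk(c(
    rmsk_row("chr1", 100, 300, "Simple_repeat"),
    rmsk_row("chr1", 200, 400, "Simple_repeat")
  ))
  trr <- load_rmsk_trr(path)
  expect_equal(nrow(trr), 2L)
  recs <- sv_tbl(chrom = "1", pos = c(150L, 250L, 350L, 450L),
                 svtype = "INS", svlen = 60L)
  got <- breakpoints_in_regions(recs, trr)
  oracle <- vapply(seq_len(nrow(recs)), function(i)
    linear_scan_in_regions(recs[i, ], trr), logical(1))
  expect_equal(got, oracle)
  expect_equal(got, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("BED3+ loads with track lines skipped and empty files rejected", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t100\t200", "chr1\t500\t800",
               "2\t0\t50"), path)
  bed <- load_bed(path)
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$chrom, c("1", "1", "2"))
  expect_equal(bed$start, c(100L, 500L, 0L))
  expect_equal(bed$end, c(200L, 800L, 50L))

  empty <- tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_error(load_bed(empty), "empty")

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\tfoo\tbar", bad)
  expect_error(load_bed(bad))

  # write_bed / load_bed round trip
  out <- tempfile(fileext = ".bed")
  write_bed(bed, out)
  again <- load_bed(out)
  expect_equal(again[c("chrom", "start", "end")],
               bed[c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("breakpoint membership uses the 1-based to 0-based convention", {
  reg <- region_tbl("1", 100L, 200L)  # covers 0-based points 100..199
  ins_at <- function(p) sv_tbl(chrom = "1", pos = p, svtype = "INS",
                               svlen = 60L)
  # 1-based breakpoint p maps to point p-1: both sides of both edges
  expect_false(breakpoints_in_regions(ins_at(100L), reg))
  expect_true(breakpoints_in_regions(ins_at(101L), reg))
  expect_true(breakpoints_in_regions(ins_at(200L), reg))
  expect_false(breakpoints_in_regions(ins_at(201L), reg))
  expect_true(breakpoints_in_regions(ins_at(150L), reg))

  # deletion: any breakpoint inside counts
  del_in_end <- sv_tbl(chrom = "1", pos = 90L, end = 150L, svtype = "DEL")
  expect_true(breakpoints_in_regions(del_in_end, reg))
  del_outside <- sv_tbl(chrom = "1", pos = 10L, end = 95L, svtype = "DEL")
  expect_false(breakpoints_in_regions(del_outside, reg))
  # spanning deletion: both breakpoints outside, "any" rule says outside
  del_span <- sv_tbl(chrom = "1", pos = 50L, end = 250L, svtype = "DEL")
  expect_false(breakpoints_in_regions(del_span, reg))
  expect_false(breakpoints_in_regions(del_span, reg, combinator = "all"))
  # chromosome absent from the region set
  other <- sv_tbl(chrom = "9", pos = 150L, svtype = "INS", svlen = 60L)
  expect_false(breakpoints_in_regions(other, reg))
})

test_that("membership agrees with a brute-force linear scan on random fixtures", {
  set.seed(101)
  for (rep in 1:20) {
    n_reg <- sample(1:15, 1)
    start <- sample(0:5000, n_reg)
    reg <- region_tbl(sample(c("1", "2"), n_reg, replace = TRUE),
                      start, start + sample(10:500, n_reg, replace = TRUE))
    recs <- random_callset(sample(1:12, 1), span = 5000L)
    got <- breakpoints_in_regions(recs, reg)
    oracle <- vapply(seq_len(nrow(recs)), function(i)
      linear_scan_in_regions(recs[i, ], reg), logical(1))
    expect_equal(got, oracle)
  }
})

test_that("partition is exhaustive/exclusive and restriction is idempotent", {
  set.seed(7)
  reg <- region_tbl("1", c(1000L, 8000L), c(3000L, 9000L))
  recs <- random_callset(40, span = 10000L, chroms = c("1", "1"))
  parts <- partition_by_trr(recs, reg)
  expect_equal(nrow(parts$in_trr) + nrow(parts$outside_trr), nrow(recs))
  expect_equal(dplyr::bind_rows(parts$in_trr, parts$outside_trr)$id |> sort(),
               sort(recs$id))
  # order preserved within each part
  expect_equal(parts$in_trr$id,
               recs$id[breakpoints_in_regions(recs, reg)])

  r1 <- restrict_to_regions(recs, reg)
  r2 <- restrict_to_regions(r1, reg)
  expect_equal(r1, r2)
  expect_equal(r1, parts$in_trr)

  # degenerate region sets
  empty_reg <- region_tbl(character(), integer(), integer())
  p0 <- partition_by_trr(recs, empty_reg)
  expect_equal(nrow(p0$in_trr), 0L)
  all_reg <- region_tbl(c("1", "2"), c(0L, 0L), c(10^6L, 10^6L))
  pall <- partition_by_trr(recs, all_reg)
  expect_equal(nrow(pall$outside_trr), 0L)
})
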