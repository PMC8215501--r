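# helper: write a raw VCF from header + body lines
write_raw_vcf <- function(body, info_extra = character()) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>", "##contig=<ID=2>", "##contig=<ID=3>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"i\">",
    "##INFO=<ID=szCount,Number=1,Type=Integer,Description=\"s\">",
    "##INFO=<ID=coverage,Number=1,Type=Integer,Description=\"c\">",
    info_extra,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    body
  ), path)
  path
}

test_that("size, BND and chromosome rules are applied on read", {
  path <- write_raw_vcf(c(
    "1\t100\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-49;END=149",
    "1\t500\tb\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-50;END=550",
    "1\t900\tc\tN\tN[2:222[\t.\tPASS\tSVTYPE=BND"
  ))
  got <- read_sv_vcf(path, filter_policy(), source = "t")
  expect_equal(nrow(got), 1L)
  expect_equal(got$id, "b")
  expect_equal(got$svlen, 50L)
  att <- attr(got, "attrition")
  # count conservation: in = kept + sum(per-reason exclusions)
  expect_equal(attr(got, "n_input"), nrow(got) + sum(att$n))
  expect_equal(att$n[att$reason == "excluded_type"], 1L)
  expect_equal(att$n[att$reason == "below_min_size"], 1L)
})

test_that("a PASS-only truth set with the benchmark composition reads to the printed total", {
  n_ins <- 7281L; n_del <- 5464L; n_other <- 30L
  pos <- seq(1000L, by = 2000L, length.out = n_ins + n_del + n_other)
  filt <- c(rep("PASS", n_ins + n_del), rep("LongReadHomRef", n_other))
  ty <- c(rep("INS", n_ins), rep("DEL", n_del), rep("INS", n_other))
  truth <- sv_tbl(chrom = "1", pos = pos,
                  end = pos + ifelse(ty == "INS", 0L, 120L),
                  svtype = ty, svlen = 120L, filter = filt,
                  source = "benchmark")
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(truth, path)
  got <- read_sv_vcf(path, filter_policy(require_pass = TRUE), "benchmark")
  expect_equal(nrow(got), 12745L)
  expect_equal(sum(got$svtype == "INS"), 7281L)
  expect_equal(sum(got$svtype == "DEL"), 5464L)
})

test_that("the PBHoney support-ratio rule keeps ratio >= 0.2, INFO or FORMAT", {
  path <- write_raw_vcf(c(
    "1\t1000\tlow\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300;END=1300;szCount=3;coverage=20",
    "1\t9000\thigh\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300;END=9300;szCount=5;coverage=20",
    "1\t20000\tedge\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300;END=20300;szCount=4;coverage=20"
  ))
  got <- read_sv_vcf(path, filter_policy(), "pbh", dialect = "pbhoney")
  # 3/20 = 0.15 < 0.2 dropped; 5/20 = 0.25 kept; 4/20 = 0.2 kept (boundary)
  expect_equal(got$id, c("high", "edge"))
  # generic dialect ignores the tags
  all3 <- read_sv_vcf(path, filter_policy(), "gen", dialect = "generic")
  expect_equal(nrow(all3), 3L)

  # same tags through FORMAT fields
  fmt_path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=1>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=szCount,Number=1,Type=Integer,Description=\"s\">",
    "##FORMAT=<ID=coverage,Number=1,Type=Integer,Description=\"c\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "1\t1000\tf_low\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300\tszCount:coverage\t2:20",
    "1\t9000\tf_high\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300\tszCount:coverage\t10:20"
  ), fmt_path)
  got2 <- read_sv_vcf(fmt_path, filter_policy(), "pbh", dialect = "pbhoney")
  expect_equal(got2$id, "f_high")
})

test_that("records are normalized: signs, derived ends, chr prefix, alleles", {
  path <- write_raw_vcf(c(
    "1\t100\tneg\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-300",
    "1\t5000\tinspt\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=120;END=5000",
    "chr3\t900\tpfx\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=60",
    paste0("2\t700\tseq\t", strrep("A", 81), "\tA\t.\tPASS\t."),
    "2\t4000\timp\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=99;IMPRECISE"
  ))
  got <- read_sv_vcf(path, permissive_policy(), "t")
  neg <- got[got$id == "neg", ]
  expect_equal(c(neg$end, neg$svlen), c(400L, 300L))
  ins <- got[got$id == "inspt", ]
  expect_equal(c(ins$end, ins$svlen), c(5000L, 120L))
  expect_equal(got$chrom[got$id == "pfx"], "3")
  seqrec <- got[got$id == "seq", ]   # sequence-resolved 80 bp deletion
  expect_equal(c(seqrec$svtype, seqrec$svlen), c("DEL", 80L))
  expect_false(got$precise[got$id == "imp"])
  expect_true(all(got$precise[got$id != "imp"]))
})

test_that("irreconcilable DEL SVLEN vs END-POS warns and END-POS wins", {
  path <- write_raw_vcf(
    "1\t100\tx\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-500;END=400"
  )
  expect_warning(got <- read_sv_vcf(path, permissive_policy(), "t"),
                 "END - POS")
  expect_equal(got$svlen, 300L)
})

test_that("multi-allelic records are split per ALT allele", {
  path <- write_raw_vcf(
    paste0("1\t100\tma\t", "A", "\t", strrep("T", 101), ",",
           strrep("G", 201), "\t.\tPASS\t.")
  )
  got <- read_sv_vcf(path, permissive_policy(), "t")
  expect_equal(nrow(got), 2L)
  expect_equal(sort(got$svlen), c(100L, 200L))
  expect_true(all(got$svtype == "INS"))
})

test_that("write/read round-trips records and is idempotent under a policy", {
  set.seed(42)
  x <- random_callset(10, "rt")
  x$precise[c(2, 5)] <- FALSE
  x$szcount[1] <- 8L; x$coverage[1] <- 20L
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(x, path)
  y <- read_sv_vcf(path, permissive_policy(), "rt")
  expect_equal(as.data.frame(y), as.data.frame(x), ignore_attr = TRUE)

  # filtering is idempotent: re-filtering the kept records changes nothing
  pol <- filter_policy()
  f1 <- read_sv_vcf(path, pol, "rt")
  path2 <- tempfile(fileext = ".vcf")
  write_sv_vcf(f1, path2)
  f2 <- read_sv_vcf(path2, pol, "rt")
  expect_equal(as.data.frame(f2), as.data.frame(f1), ignore_attr = TRUE)

  # empty callset -> valid header-only VCF
  path3 <- tempfile(fileext = ".vcf")
  write_sv_vcf(empty_sv_tbl(), path3)
  expect_equal(nrow(read_sv_vcf(path3, permissive_policy(), "e")), 0L)
})

test_that("unparseable files and unwritable paths are hard errors", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all"), bad)
  expect_error(read_sv_vcf(bad, permissive_policy(), "t"))
  expect_error(read_sv_vcf(tempfile(), permissive_policy(), "t"),
               "no such file")
  expect_error(
    write_sv_vcf(sv_tbl(chrom = "1", pos = 1L, svtype = "INS", svlen = 60L),
                 file.path(tempdir(), "no/such/dir/out.vcf")),
    "cannot write"
  )
})
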