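test_that("native probability format parses as documented", {
  f <- withr::local_tempfile(fileext = ".prob")
  writeLines(c("r1 2 tA 0.5 tB 0.5", "r2 1 tA 1.0"), f)
  a <- read_prob(f)
  expect_s3_class(a, "jointde_align")
  expect_equal(nrow(a), 3)
  r1 <- a[a$read == "r1", ]
  expect_setequal(r1$transcript, c("tA", "tB"))
  expect_equal(r1$dens, c(0.5, 0.5))
  expect_equal(a[a$read == "r2", ]$dens, 1.0)
})

test_that("malformed and invalid probability lines raise with line numbers", {
  f <- withr::local_tempfile(fileext = ".prob")
  writeLines(c("r1 1 tA 0.4", "r3 1 tA -0.1"), f)
  expect_error(read_prob(f), "line 2.*positive")
  writeLines(c("r1 2 tA 0.4"), f)
  expect_error(read_prob(f), "line 1")
  writeLines(c("r1 1 tA x"), f)
  expect_error(read_prob(f), "non-numeric")
  writeLines(c("r1 1 tZ 0.4"), f)
  expect_error(read_prob(f, transcript_ids = c("tA")), "unknown transcript")
})

test_that("write_prob / read_prob round-trip random instances exactly", {
  for (seed in 1:5) {
    inst <- random_tiny_instance(K = 4, r = 6, s = 1, seed = seed)$x
    f <- withr::local_tempfile(fileext = ".prob")
    write_prob(inst, f)
    back <- read_prob(f, transcript_ids = transcript_ids(inst))
    key <- function(a) as.data.frame(a[order(a$read, a$transcript), ])
    expect_equal(key(back), key(inst))
  }
})

test_that("duplicate alignment records keep the maximum density", {
  a <- alignments(data.frame(read = c("r1", "r1"), transcript = c("tA", "tA"),
                             dens = c(0.2, 0.7)))
  expect_equal(nrow(a), 1)
  expect_equal(a$dens, 0.7)
  expect_error(alignments(data.frame(read = "r", transcript = "t", dens = 0)),
               "positive")
})

test_that("SAM alignments get uniform-position densities", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:tA\tLN:1000",
    "@SQ\tSN:tB\tLN:100",
    "r1\t0\ttA\t10\t60\t100M\t*\t0\t0\t*\t*",
    "r1\t256\ttB\t1\t0\t100M\t*\t0\t0\t*\t*",
    "r2\t0\ttA\t50\t60\t100M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  catalog <- transcript_catalog(c("tA", "tB"), c(1000, 100))
  expect_message(a <- read_sam(sam, catalog, read_length = 100),
                 "1 unmapped")
  # length 1000, L 100 -> 1/901; length == L -> denominator floored at 1
  expect_equal(a$dens[a$transcript == "tA"], rep(1 / 901, 2))
  expect_equal(a$dens[a$transcript == "tB"], 1)
  expect_equal(sum(a$read == "r1"), 2)  # multi-mapping kept as two entries
  expect_identical(transcript_ids(a), c("tA", "tB"))
  short <- transcript_catalog("tA", 1000)
  expect_error(suppressMessages(read_sam(sam, short, 100)),
               "absent from catalog")
})

test_that("sam densities depend only on transcript and read length", {
  set.seed(8)
  for (i in 1:5) {
    len <- sample(80:2000, 1)
    L <- sample(30:150, 1)
    sam <- withr::local_tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:t1\tLN:%d", len),
                 sprintf("r1\t0\tt1\t1\t60\t%dM\t*\t0\t0\t*\t*", min(L, len))),
               sam)
    a <- read_sam(sam, transcript_catalog("t1", len), read_length = L)
    expect_equal(a$dens, 1 / max(len - L + 1, 1))
  }
})

test_that("results tables round-trip through TSV", {
  tab <- tibble::tibble(transcript = c("a", "b", "c"),
                        q = c(0.9, 0.2, 0), log2fc = c(1.5, -0.2, 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_results(tab, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$q, tab$q)
  write_results(tab[0, ], f)
  expect_equal(nrow(utils::read.delim(f)), 0)
  expect_equal(names(utils::read.delim(f)), names(tab))
})
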