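# SAM realignment pipeline.

make_perfect_sam <- function(ref, n = 6L, len = 40L) {
  starts <- seq(1L, nchar(ref) - len + 1L, length.out = n)
  rows <- data.frame(
    name = sprintf("p%02d", seq_len(n)),
    pos = as.integer(round(starts)),
    cigar = sprintf("%dM", len),
    seq = vapply(as.integer(round(starts)), function(s) {
      substr(ref, s, s + len - 1L)
    }, character(1)))
  toy_sam(rows, contig_len = nchar(ref))
}

test_that("reads matching the reference keep their CIGARs", {
  cfg <- sim_config(seed = 5L)
  sr <- make_reference(cfg)
  sam <- make_perfect_sam(sr$seq)
  dir <- withr::local_tempdir()
  in_sam <- file.path(dir, "in.sam"); out_sam <- file.path(dir, "out.sam")
  write_sam(sam, in_sam)
  res <- realign_bam(in_sam, c(ctg1 = sr$seq), default_model(), out_sam)
  expect_equal(unname(res$counters["realigned"]), 6L)
  out <- read_sam(out_sam)
  for (k in seq_along(out$records)) {
    expect_equal(out$records[[k]][[6]], sam$records[[k]][[6]])
  }
})

test_that("realignment rewrites only CIGAR/NM/MD and fixes INDEL placement", {
  cfg <- e2e_config(seed = 21L)
  sr <- make_reference(cfg)
  reads <- simulate_reads(sr, cigar_mode = "naive")
  dir <- withr::local_tempdir()
  in_sam <- file.path(dir, "in.sam"); out_sam <- file.path(dir, "out.sam")
  write_sam(reads$sam, in_sam)
  m <- default_model()
  res <- realign_bam(in_sam, c(ctg1 = sr$seq), m, out_sam)
  expect_equal(unname(res$counters["band_failures"]), 0L)
  inp <- read_sam(in_sam); out <- read_sam(out_sam)
  expect_equal(length(inp$records), length(out$records))
  ann <- annotate_reference(sr$seq, cfg$params)
  iv <- npoly_intervals(ann)
  n_indels <- 0L; n_inside <- 0L
  for (k in seq_along(out$records)) {
    a <- inp$records[[k]]; b <- out$records[[k]]
    # untouched fields are byte-identical
    for (f in c(1, 2, 3, 4, 5, 7, 8, 9, 10, 11)) {
      expect_identical(a[[f]], b[[f]])
    }
    # the HP tag survives
    expect_identical(grep("^HP:", a, value = TRUE),
                     grep("^HP:", b, value = TRUE))
    # emitted CIGAR is well formed and conserves lengths
    cons <- cigar_consumed(b[[6]])
    expect_equal(cons[["read"]], nchar(b[[10]]))
    # INDEL runs land at annotated unit starts
    p <- parse_cigar(b[[6]])
    pos <- as.integer(b[[4]])
    j <- pos - 1L
    for (q in seq_along(p$ops)) {
      if (p$ops[q] %in% c("M", "D")) {
        if (p$ops[q] == "D") {
          n_indels <- n_indels + 1L
          if (any(iv$start <= j + 1L & iv$end >= j + 1L)) {
            n_inside <- n_inside + 1L
          }
        }
        j <- j + p$lengths[q]
      } else if (p$ops[q] == "I") {
        n_indels <- n_indels + 1L
        if (any(iv$start - 1L <= j + 1L & iv$end >= j + 1L)) {
          n_inside <- n_inside + 1L
        }
      }
    }
  }
  expect_gt(n_indels, 20L)
  expect_gt(n_inside / n_indels, 0.9)
})

test_that("worker count does not change the output", {
  cfg <- sim_config(seed = 31L, depth = 6L)
  sr1 <- make_reference(cfg)
  cfg2 <- sim_config(seed = 32L, depth = 6L)
  sr2 <- make_reference(cfg2)
  reads1 <- simulate_reads(sr1, cigar_mode = "naive", contig = "ctgA")
  reads2 <- simulate_reads(sr2, cigar_mode = "naive", contig = "ctgB")
  sam <- list(header = c("@HD\tVN:1.6\tSO:coordinate",
                         sprintf("@SQ\tSN:ctgA\tLN:%d", nchar(sr1$seq)),
                         sprintf("@SQ\tSN:ctgB\tLN:%d", nchar(sr2$seq))),
              records = c(reads1$sam$records, reads2$sam$records))
  ref <- c(ctgA = sr1$seq, ctgB = sr2$seq)
  dir <- withr::local_tempdir()
  in_sam <- file.path(dir, "in.sam")
  write_sam(sam, in_sam)
  m <- default_model()
  out1 <- file.path(dir, "t1.sam"); out2 <- file.path(dir, "t2.sam")
  realign_bam(in_sam, ref, m, out1, threads = 1L)
  realign_bam(in_sam, ref, m, out2, threads = 2L)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("realignment is score-idempotent", {
  cfg <- e2e_config(seed = 41L)
  cfg$depth <- 10L
  sr <- make_reference(cfg)
  reads <- simulate_reads(sr, cigar_mode = "naive")
  dir <- withr::local_tempdir()
  s0 <- file.path(dir, "r0.sam"); s1 <- file.path(dir, "r1.sam")
  s2 <- file.path(dir, "r2.sam")
  write_sam(reads$sam, s0)
  m <- default_model()
  realign_bam(s0, c(ctg1 = sr$seq), m, s1)
  realign_bam(s1, c(ctg1 = sr$seq), m, s2)
  r1 <- read_sam(s1); r2 <- read_sam(s2)
  ann <- annotate_reference(sr$seq, cfg$params)
  for (k in seq_along(r1$records)) {
    a <- r1$records[[k]]; b <- r2$records[[k]]
    pos <- as.integer(a[[4]])
    win_len <- cigar_consumed(a[[6]])[["ref"]]
    window <- substr(sr$seq, pos, pos + win_len - 1L)
    ann_w <- annotation_window(ann, pos, win_len)
    sc1 <- score_cigar(a[[10]], window, a[[6]], ann_w, m)
    win_len2 <- cigar_consumed(b[[6]])[["ref"]]
    window2 <- substr(sr$seq, pos, pos + win_len2 - 1L)
    ann_w2 <- annotation_window(ann, pos, win_len2)
    sc2 <- score_cigar(b[[10]], window2, b[[6]], ann_w2, m)
    expect_lte(sc2, sc1 + 1e-9)
  }
})

test_that("clips, unmapped and secondary records pass through", {
  ref <- c(ctg1 = "GATTACAGGCTAAAAAATTCGGATCATGCATCAGT")
  core <- substr(ref, 5, 30)
  rows <- data.frame(
    name = c("clip1", "unmapped", "secondary"),
    pos = c(5L, 0L, 5L),
    cigar = c(paste0("3S", nchar(core), "M2S"), "*", "10M"),
    seq = c(paste0("TTT", core, "GG"), "ACGTACGT",
            substr(ref, 5, 14)))
  sam <- toy_sam(rows, contig_len = nchar(ref))
  sam$records[[2]][[2]] <- "4"    # unmapped flag
  sam$records[[3]][[2]] <- "256"  # secondary flag
  dir <- withr::local_tempdir()
  in_sam <- file.path(dir, "in.sam"); out_sam <- file.path(dir, "out.sam")
  write_sam(sam, in_sam)
  res <- realign_bam(in_sam, ref, default_model(), out_sam)
  out <- read_sam(out_sam)
  # soft clips preserved verbatim around the realigned core
  p <- parse_cigar(out$records[[1]][[6]])
  expect_equal(p$ops[1], "S"); expect_equal(p$lengths[1], 3L)
  expect_equal(p$ops[length(p$ops)], "S")
  expect_equal(p$lengths[length(p$ops)], 2L)
  # unmapped and secondary untouched
  expect_identical(out$records[[2]], sam$records[[2]])
  expect_identical(out$records[[3]], sam$records[[3]])
  expect_equal(unname(res$counters["passed_through"]), 2L)
})

test_that("BAM paths convert through Rsamtools on both ends", {
  cfg <- sim_config(seed = 51L, depth = 4L)
  sr <- make_reference(cfg)
  reads <- simulate_reads(sr, cigar_mode = "truth")
  dir <- withr::local_tempdir()
  in_bam <- file.path(dir, "in.bam"); out_bam <- file.path(dir, "out.bam")
  write_sam(reads$sam, in_bam)
  expect_true(file.exists(in_bam))
  res <- realign_bam(in_bam, c(ctg1 = sr$seq), default_model(), out_bam)
  expect_gt(unname(res$counters["realigned"]), 0L)
  back <- read_sam(out_bam)
  expect_equal(length(back$records), length(reads$sam$records))
  expect_equal(vapply(back$records, `[[`, character(1), 1L),
               vapply(reads$sam$records, `[[`, character(1), 1L))
})

test_that("reads on missing contigs pass through with a warning", {
  rows <- data.frame(name = "x", pos = 1L, cigar = "4M", seq = "ACGT")
  sam <- toy_sam(rows, contig = "ctgZ", contig_len = 100L)
  dir <- withr::local_tempdir()
  in_sam <- file.path(dir, "in.sam"); out_sam <- file.path(dir, "out.sam")
  write_sam(sam, in_sam)
  expect_warning(
    res <- realign_bam(in_sam, c(ctg1 = "ACGTACGT"), default_model(),
                       out_sam),
    "absent")
  expect_equal(unname(res$counters["skipped_contig"]), 1L)
})
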