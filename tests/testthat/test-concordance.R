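# Gini-purity concordance evaluation.

test_that("Gini purity closed forms match the definition", {
  expect_equal(gini_purity(c(A = 10)), 1)
  expect_equal(gini_purity(c(A = 5, C = 5)), 0.5)
  expect_equal(gini_purity(rep(1, 5)), 0.2)
  expect_true(is.na(gini_purity(c(0, 0))))
})

test_that("Gini purity is label- and scale-invariant and bounded", {
  set.seed(501)
  for (k in 1:50) {
    n_cls <- sample(2:6, 1)
    counts <- rpois(n_cls, 10) + 1
    gp <- gini_purity(counts)
    expect_equal(gini_purity(sample(counts)), gp)
    expect_equal(gini_purity(counts * 7), gp)
    expect_gte(gp, 1 / n_cls)
    expect_lte(gp, 1)
  }
  expect_equal(gini_purity(c(3, 0, 0)), 1) # one observed class
})

test_that("identical reads put all histogram mass at GP = 1", {
  ref <- "GATTACAGGCTATTCGGATCATGCATCAGTACGT"
  rows <- data.frame(name = sprintf("r%d", 1:8), pos = 1L,
                     cigar = sprintf("%dM", nchar(ref)), seq = ref)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "u.sam")
  write_sam(toy_sam(rows, contig_len = nchar(ref)), path)
  h <- gini_histograms(path)
  expect_true(all(h$column_scores$gp == 1))
  expect_true(all(h$insertion_scores$gp == 1))
  expect_equal(sum(h$columns), nchar(ref))
  expect_equal(sum(h$columns[-length(h$columns)]), 0)
})

test_that("a hand-built pileup reproduces hand-computed scores", {
  ref <- "ACGTACGTAC"
  # 6 reads over 10 bp; read 5 has a SNP at pos 3, reads 4-6 delete pos 6
  rows <- data.frame(
    name = sprintf("r%d", 1:6),
    pos = 1L,
    cigar = c("10M", "10M", "10M", "5M1D4M", "10M", "5M1D4M"),
    seq = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC",
            "ACGTAGTAC", "ACTTACGTAC", "ACGTAGTAC"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "h.sam")
  write_sam(toy_sam(rows, contig_len = 10L), path)
  h <- gini_histograms(path, min_depth = 5)
  sc <- h$column_scores[order(h$column_scores$pos)]
  expect_equal(nrow(sc), 10L)
  # pos 3: 5 G + 1 T
  expect_equal(sc$gp[sc$pos == 3], (5 / 6)^2 + (1 / 6)^2)
  # pos 6: 4 C + 2 deletions
  expect_equal(sc$gp[sc$pos == 6], (4 / 6)^2 + (2 / 6)^2)
  # all other columns unanimous
  expect_equal(sum(sc$gp == 1), 8L)
})

test_that("insertions are scored separately with an explicit empty class", {
  ref <- "ACGTACGTAC"
  rows <- data.frame(
    name = sprintf("r%d", 1:6),
    pos = 1L,
    cigar = c("10M", "10M", "5M2I5M", "5M2I5M", "5M1I5M", "10M"),
    seq = c("ACGTACGTAC", "ACGTACGTAC", "ACGTATTCGTAC", "ACGTATTCGTAC",
            "ACGTATCGTAC", "ACGTACGTAC"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "i.sam")
  write_sam(toy_sam(rows, contig_len = 10L), path)
  h <- gini_histograms(path, min_depth = 5)
  ins <- h$insertion_scores[order(h$insertion_scores$gap)]
  # gap after pos 5: 3 empty, 2 "TT", 1 "T"
  g5 <- ins$gp[ins$gap == 5]
  expect_equal(g5, (3 / 6)^2 + (2 / 6)^2 + (1 / 6)^2)
  # every base column is still unanimous
  expect_true(all(h$column_scores$gp == 1))
  # all other gaps are pure
  expect_true(all(ins$gp[ins$gap != 5] == 1))
})

test_that("columns below the depth threshold are skipped, not scored", {
  ref <- "ACGTACGTAC"
  rows <- data.frame(name = c("a", "b"), pos = c(1L, 1L),
                     cigar = c("10M", "10M"), seq = c(ref, ref))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "d.sam")
  write_sam(toy_sam(rows, contig_len = 10L), path)
  expect_equal(nrow(gini_histograms(path, min_depth = 5)$column_scores), 0L)
  expect_equal(nrow(gini_histograms(path, min_depth = 2)$column_scores), 10L)
})

test_that("haplotype grouping scores each haplotype's pileup separately", {
  ref <- "ACGTACGTAC"
  alt <- "ACGTAGGTAC" # SNP at pos 6 on haplotype 2
  rows <- data.frame(name = sprintf("r%d", 1:10), pos = 1L,
                     cigar = "10M",
                     seq = rep(c(ref, alt), 5))
  sam <- toy_sam(rows, contig_len = 10L)
  for (k in seq_along(sam$records)) {
    sam$records[[k]] <- c(sam$records[[k]],
                          paste0("HP:i:", if (k %% 2) 1L else 2L))
  }
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hp.sam")
  write_sam(sam, path)
  pooled <- gini_histograms(path, min_depth = 5)
  expect_equal(pooled$column_scores$gp[pooled$column_scores$pos == 6], 0.5)
  split <- gini_histograms(path, min_depth = 5, by_haplotype = TRUE)
  expect_true(all(split$column_scores$gp == 1))
})

test_that("realigning the same reads preserves the scored column set", {
  cfg <- e2e_config(seed = 61L)
  cfg$depth <- 12L
  sr <- make_reference(cfg)
  reads <- simulate_reads(sr, cigar_mode = "naive")
  dir <- withr::local_tempdir()
  s0 <- file.path(dir, "a.sam"); s1 <- file.path(dir, "b.sam")
  write_sam(reads$sam, s0)
  realign_bam(s0, c(ctg1 = sr$seq), default_model(), s1)
  h0 <- gini_histograms(s0)
  h1 <- gini_histograms(s1)
  expect_equal(nrow(h0$column_scores), nrow(h1$column_scores))
  expect_equal(sum(h0$columns), sum(h1$columns))
})

test_that("histogram TSV has the documented layout", {
  ref <- "ACGTACGTAC"
  rows <- data.frame(name = sprintf("r%d", 1:5), pos = 1L, cigar = "10M",
                     seq = ref)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.sam")
  write_sam(toy_sam(rows, contig_len = 10L), path)
  h <- gini_histograms(path)
  tsv <- file.path(dir, "h.tsv")
  write_gini_tsv(h, tsv)
  df <- read.delim(tsv)
  expect_named(df, c("bin_low", "bin_high", "column_count",
                     "insertion_count"))
  expect_equal(nrow(df), 100L)
  expect_equal(sum(df$column_count), 10L)
})
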