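# The five-matrix repeat-aware aligner.

test_that("identity alignments emit all-match CIGARs scored by P", {
  m <- small_model()
  ref <- "GATCGTACGGAT"
  ann <- annotate_reference(ref, small_params())
  al <- align(ref, ref, ann, m)
  expect_equal(al$cigar, "12M")
  rf <- strsplit(ref, "")[[1]]
  expected <- sum(vapply(rf, function(b) {
    i <- match(b, c("A", "C", "G", "T")); m$P[i, i]
  }, numeric(1)))
  expect_equal(al$score, expected, tolerance = 1e-9)
})

test_that("a one-copy homopolymer deletion is charged the tensor, not the gap", {
  m <- small_model()
  ref <- "GGCTAAAAATCG"
  ann <- annotate_reference(ref, small_params())
  al <- align("GGCTAAAATCG", ref, ann, m)
  p <- parse_cigar(al$cigar)
  expect_equal(sum(p$lengths[p$ops == "D"]), 1L)
  expect_equal(sum(p$ops == "D"), 1L)
  # score decomposes into 11 matches plus N[1, 5, 4] (0-based copies)
  rf <- strsplit("GGCTAAAATCG", "")[[1]]
  match_cost <- sum(vapply(rf, function(b) {
    i <- match(b, c("A", "C", "G", "T")); m$P[i, i]
  }, numeric(1)))
  expect_equal(al$score, match_cost + m$N[1, 6, 5], tolerance = 1e-9)
  expect_lt(m$N[1, 6, 5], m$G_open) # cheaper than opening an affine gap
  # the deletion sits at the polymer start (canonical placement)
  expect_equal(al$cigar, "4M1D7M")
})

test_that("with the tensor disabled the program is exactly affine Gotoh", {
  set.seed(301)
  m <- small_model()
  for (k in seq_len(300)) {
    ref <- random_dna(sample(1:12, 1), c("A", "A", "C", "G", "T", "T"))
    read <- random_dna(sample(1:12, 1), c("A", "A", "C", "G", "T", "T"))
    a <- align(read, ref, NULL, m, use_npoly = FALSE)
    g <- gotoh_score(read, ref, m$P, m$G_open, m$G_extend)
    expect_equal(a$score, g, tolerance = 1e-9,
                 label = paste(read, ref))
  }
})

test_that("the full program matches exhaustive path enumeration", {
  set.seed(302)
  m <- small_model()
  par <- small_params()
  for (k in seq_len(60)) {
    u <- sample(c("A", "T", "AT", "CAG"), 1)
    l <- sample(3:5, 1)
    core <- paste(rep(u, l), collapse = "")
    ref <- substr(paste0(random_dna(sample(0:2, 1)), core,
                         random_dna(sample(0:2, 1))), 1, 10)
    delta <- sample(c(-1, 0, 1), 1)
    read <- substr(paste0(random_dna(sample(0:2, 1)),
                          paste(rep(u, max(1, l + delta)), collapse = ""),
                          random_dna(sample(0:2, 1))), 1, 10)
    ann <- annotate_reference(ref, par)
    a <- align(read, ref, ann, m)
    e <- enum_align_score(read, ref, ann, m)
    expect_equal(a$score, e, tolerance = 1e-9, label = paste(read, ref))
  }
})

test_that("emitted CIGARs conserve read and window lengths", {
  set.seed(303)
  m <- small_model()
  par <- small_params()
  for (k in seq_len(100)) {
    ref <- random_dna(sample(5:40, 1), c("A", "A", "A", "C", "G", "T", "T"))
    read <- random_dna(sample(5:40, 1), c("A", "A", "A", "C", "G", "T", "T"))
    ann <- annotate_reference(ref, par)
    al <- align(read, ref, ann, m)
    cons <- cigar_consumed(al$cigar)
    expect_equal(cons[["read"]], nchar(read))
    expect_equal(cons[["ref"]], nchar(ref))
  }
})

test_that("re-scoring the emitted CIGAR reproduces the alignment score", {
  set.seed(304)
  m <- small_model()
  par <- small_params()
  for (k in seq_len(60)) {
    core <- paste(rep(sample(c("A", "AT", "GGC"), 1), sample(3:6, 1)),
                  collapse = "")
    ref <- paste0(random_dna(5), core, random_dna(5))
    read_core <- paste(rep(substr(core, 1, sample(1:3, 1)), sample(2:7, 1)),
                       collapse = "")
    read <- paste0(random_dna(5), read_core, random_dna(5))
    ann <- annotate_reference(ref, par)
    al <- align(read, ref, ann, m)
    expect_equal(score_cigar(read, ref, al$cigar, ann, m), al$score,
                 tolerance = 1e-9, label = paste(read, ref, al$cigar))
  }
})

test_that("copy-number moves fire only inside annotated polymers", {
  m <- small_model()
  # a repeat-free window: the full program must equal plain affine
  set.seed(305)
  for (k in seq_len(50)) {
    repeat {
      ref <- random_dna(sample(6:20, 1))
      if (sum(annotate_reference(ref, small_params())$l) == 0) break
    }
    read <- random_dna(nchar(ref) + sample(-2:2, 1))
    ann <- annotate_reference(ref, small_params())
    full <- align(read, ref, ann, m)$score
    affine <- align(read, ref, NULL, m, use_npoly = FALSE)$score
    expect_equal(full, affine, tolerance = 1e-9)
  }
})

test_that("alignment is deterministic", {
  m <- small_model()
  ref <- "GGCAAAAAATTTTTGGATCGAT"
  read <- "GGCAAAAATTTTTTGGATCGAT"
  ann <- annotate_reference(ref, small_params())
  c1 <- replicate(5, align(read, ref, ann, m)$cigar)
  expect_length(unique(c1), 1L)
})

test_that("degenerate windows and unknown bases are handled", {
  m <- small_model()
  al <- align("ACGT", "", NULL, m, use_npoly = FALSE)
  expect_equal(al$cigar, "4I")
  expect_equal(al$score, m$G_open + 3 * m$G_extend)
  al2 <- align("", "ACG", NULL, m, use_npoly = FALSE)
  expect_equal(al2$cigar, "3D")
  # N in the read is charged the maximum substitution penalty
  al3 <- align("ANG", "ACG", NULL, m, use_npoly = FALSE)
  p_max <- max(m$P)
  rf <- c("A", "G")
  base_cost <- sum(vapply(rf, function(b) {
    i <- match(b, c("A", "C", "G", "T")); m$P[i, i]
  }, numeric(1)))
  expect_equal(al3$score, base_cost + p_max, tolerance = 1e-9)
  # N in the reference is never annotated, so no copy-number moves fire
  ann <- annotate_reference("AANAA", small_params())
  expect_true(all(ann$l == 0))
})
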