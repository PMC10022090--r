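# Penalty estimation: substitution matrix, affine fit, copy-number tensor.

test_that("substitution penalties follow the smoothed negative-log law", {
  # uniform row: every outcome penalised log(4)
  C <- matrix(1e6, 4, 4)
  P <- substitution_penalties(C, eps = 0.01)
  expect_equal(unname(P[1, ]), rep(log(4), 4), tolerance = 1e-6)
  # dominant diagonal row evaluated directly
  C2 <- matrix(0, 4, 4); C2[1, ] <- c(97, 1, 1, 1)
  P2 <- substitution_penalties(C2, eps = 0.01)
  expect_equal(P2[1, 1], -log(97.01 / 100.01))
  expect_equal(P2[1, 2], -log(1.01 / 100.01))
  # all-zero row: the eps-only limit gives zero penalty
  expect_true(all(substitution_penalties(matrix(0, 4, 4))[2, ] == 0))
})

test_that("implied probabilities are row-normalized up to smoothing", {
  set.seed(9)
  for (k in 1:20) {
    C <- matrix(rpois(16, lambda = sample(c(5, 50, 5000), 1)) + 1, 4, 4)
    P <- substitution_penalties(C, eps = 0.01)
    rs <- rowSums(exp(-P))
    tol <- 5 * 0.01 / rowSums(C) + 1e-9
    expect_true(all(abs(rs - 1) <= tol))
  }
})

test_that("doubling an event's probability lowers its penalty by log 2", {
  C <- matrix(0, 4, 4)
  C[1, ] <- c(1e6, 1000, 2000, 1e6 - 3000) # row total fixed
  P <- substitution_penalties(C, eps = 0.01)
  expect_equal(P[1, 2] - P[1, 3], log(2), tolerance = 1e-4)
  # same law for the copy-number tensor
  C_N <- array(0, dim = c(1, 6, 6))
  C_N[1, 5, ] <- c(0, 0, 500, 8500, 1000, 0)
  N <- npolymer_penalties(C_N, regularize = FALSE)
  expect_equal(N[1, 5, 3] - N[1, 5, 5], log(2), tolerance = 1e-4)
})

test_that("affine parameters are recovered from penalty curves", {
  lens <- 1:10
  pen <- setNames(5 + (lens - 1) * 1, lens)
  fit <- fit_affine(pen)
  expect_equal(unname(fit), c(5, 1), tolerance = 1e-9)
  # affine cost of a 3-base gap under the defaults
  expect_equal(fit[["G_open"]] + 2 * fit[["G_extend"]], 7)
  # noisy curves recover the generating parameters within 3 standard errors
  set.seed(77)
  noisy <- setNames(5 + (lens - 1) * 1 + rnorm(10, sd = 0.2), lens)
  f <- lm(noisy ~ I(lens - 1))
  se <- sqrt(diag(vcov(f)))
  fit2 <- fit_affine(noisy)
  expect_lt(abs(fit2[["G_open"]] - 5), 3 * se[1])
  expect_lt(abs(fit2[["G_extend"]] - 1), 3 * se[2])
})

test_that("degenerate INDEL curves fall back to the defaults", {
  expect_warning(fit <- fit_affine(setNames(3, 1), observed = c(TRUE)),
                 "default")
  expect_equal(unname(fit), c(5, 1))
})

test_that("indel penalty curve applies the negative-log formula", {
  C <- setNames(c(100, 10, 1), 1:3)
  pen <- indel_penalty_curve(C, eps = 0.01)
  expect_equal(unname(pen[1]), -log(100.01 / 111.01))
})

test_that("eps-dominated off-diagonals are flat before regularization", {
  C_N <- array(0, dim = c(2, 8, 8))
  for (i in 1:8) C_N[1, i, i] <- 50
  N <- npolymer_penalties(C_N, regularize = FALSE)
  off <- N[1, 4, -4]
  expect_true(all(abs(off - off[1]) < 1e-12))
})

test_that("the tensor matches a spreadsheet-style oracle", {
  set.seed(13)
  C_N <- array(0, dim = c(1, 6, 6))
  C_N[1, , ] <- matrix(rpois(36, 40), 6, 6) + diag(500, 6)
  N <- npolymer_penalties(C_N, eps = 0.01)
  O <- oracle_npoly_penalties(C_N, eps = 0.01)
  expect_equal(N, O, tolerance = 1e-9)
})

test_that("both regularity families hold after regularization", {
  set.seed(14)
  for (k in 1:5) {
    C_N <- array(rpois(2 * 10 * 10, 3), dim = c(2, 10, 10))
    N <- npolymer_penalties(C_N)
    expect_true(npoly_regular_ok(N))
  }
  # the printed-direction flag flips both families
  C_N <- array(rpois(100, 3), dim = c(1, 10, 10))
  Nf <- npolymer_penalties(C_N, printed_direction = TRUE)
  expect_true(npoly_regular_ok(-Nf))
})

test_that("confusion counting handles matches, runs, and polymer spans", {
  ref <- "GGCTAAAAATTCGGATCGAT"
  ann <- annotate_reference(ref)
  # identical read: diagonal substitution counts only
  al <- list(list(read = ref, cigar = "20M", ref_start = 1L))
  cc <- count_confusions(al, ref, ann)
  expect_equal(sum(diag(cc$C_P)), 20)
  expect_equal(sum(cc$C_P) - sum(diag(cc$C_P)), 0)
  expect_true(all(cc$C_I == 0) && all(cc$C_D == 0))
  # the spanned A-homopolymer counts one diagonal C_N event
  expect_equal(cc$C_N[1, 6, 6], 1)
  # a 3-base insertion run increments one length-3 bucket
  al2 <- list(list(read = paste0(substr(ref, 1, 12), "TTT",
                                 substr(ref, 13, 20)),
                   cigar = "12M3I8M", ref_start = 1L))
  cc2 <- count_confusions(al2, ref, ann)
  expect_equal(unname(cc2$C_I[3]), 1)
  expect_equal(sum(cc2$C_I), 1)
  # one deleted A in the homopolymer: C_N[1, 5, 4] in 0-based copies
  al3 <- list(list(read = paste0(substr(ref, 1, 4), "AAAA",
                                 substr(ref, 10, 20)),
                   cigar = "4M1D15M", ref_start = 1L))
  cc3 <- count_confusions(al3, ref, ann)
  expect_equal(cc3$C_N[1, 6, 5], 1)
  expect_equal(unname(cc3$C_D[1]), 1)
  # length mismatch errors name the read
  expect_error(count_confusions(list(list(read = "ACG", cigar = "5M",
                                          ref_start = 1L, name = "bad1")),
                                ref, ann), "bad1")
})

test_that("counting is additive over alignment sets", {
  ref <- "GGCTAAAAATTCGGATCGAT"
  ann <- annotate_reference(ref)
  a1 <- list(list(read = ref, cigar = "20M", ref_start = 1L))
  a2 <- list(list(read = paste0(substr(ref, 1, 4), "AAAA",
                                substr(ref, 10, 20)),
                  cigar = "4M1D15M", ref_start = 1L))
  cc_union <- count_confusions(c(a1, a2), ref, ann)
  cc_sum <- combine_counts(count_confusions(a1, ref, ann),
                           count_confusions(a2, ref, ann))
  expect_equal(cc_union$C_P, cc_sum$C_P)
  expect_equal(cc_union$C_N, cc_sum$C_N)
  expect_equal(cc_union$C_I, cc_sum$C_I)
  expect_equal(cc_union$C_D, cc_sum$C_D)
})

test_that("models serialize to JSON and back", {
  m <- small_model(l_max = 12L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$P, m$P, tolerance = 1e-12)
  expect_equal(m2$N, m$N, tolerance = 1e-12)
  expect_equal(m2$G_open, m$G_open)
  expect_equal(m2$eps, m$eps)
})

test_that("train_model assembles all components", {
  ref <- "GGCTAAAAATTCGGATCGAT"
  ann <- annotate_reference(ref)
  als <- rep(list(list(read = ref, cigar = "20M", ref_start = 1L)), 3)
  # both the insertion and the deletion curve fall back to defaults
  warns <- capture_warnings(m <- train_model(als, ref, ann))
  expect_length(warns, 2L)
  expect_match(warns, "default", all = TRUE)
  expect_s3_class(m, "penalty_model")
  expect_equal(m$G_open, 5)
  expect_equal(dim(m$N), c(6L, 100L, 100L))
})
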