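# Independent oracles used by the test suite. These deliberately re-derive
# results from first principles (per-position scanning, textbook three-matrix
# affine DP, depth-first enumeration of move sequences) rather than sharing
# code with the package implementation.

ORACLE_BASES <- c("A", "C", "G", "T")

random_dna <- function(len, alphabet = ORACLE_BASES) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# ---- brute-force repeat scanner --------------------------------------------
# For every position p and unit length n, count exact unit copies backward
# and forward; annotate when total >= min_repeats.
brute_annotation <- function(seq, n_max = 6L, min_repeats = 3L) {
  L <- nchar(seq)
  s <- strsplit(toupper(seq), "")[[1]]
  lmat <- matrix(0L, n_max, L)
  imat <- matrix(0L, n_max, L)
  unit_at <- function(p, n) {
    if (p < 1L || p + n - 1L > L) return(NULL)
    u <- s[p:(p + n - 1L)]
    if (any(u == "N")) return(NULL)
    u
  }
  for (n in seq_len(n_max)) {
    for (p in seq_len(L)) {
      u <- unit_at(p, n)
      if (is.null(u)) next
      fwd <- 0L
      q <- p + n
      while (!is.null(v <- unit_at(q, n)) && all(v == u)) {
        fwd <- fwd + 1L; q <- q + n
      }
      bwd <- 0L
      q <- p - n
      while (!is.null(v <- unit_at(q, n)) && all(v == u)) {
        bwd <- bwd + 1L; q <- q - n
      }
      total <- bwd + fwd + 1L
      if (total >= min_repeats) {
        lmat[n, p] <- total
        imat[n, p] <- bwd
      }
    }
  }
  list(l = lmat, idx = imat)
}

# ---- textbook affine-gap (Gotoh) aligner -----------------------------------
gotoh_score <- function(read, ref, P, g_open, g_extend) {
  rd <- match(strsplit(toupper(read), "")[[1]], ORACLE_BASES)
  rf <- match(strsplit(toupper(ref), "")[[1]], ORACLE_BASES)
  p_max <- max(P)
  subst <- function(r, q) {
    if (is.na(r) || is.na(q)) p_max else P[r, q]
  }
  nr <- length(rd); mc <- length(rf)
  best <- matrix(Inf, nr + 1L, mc + 1L)
  D <- matrix(Inf, nr + 1L, mc + 1L)
  I <- matrix(Inf, nr + 1L, mc + 1L)
  best[1, 1] <- 0
  for (i in 0:nr) {
    for (j in 0:mc) {
      if (i == 0L && j == 0L) next
      if (j > 0L) {
        D[i + 1, j + 1] <- min(best[i + 1, j] + g_open, D[i + 1, j] + g_extend)
      }
      if (i > 0L) {
        I[i + 1, j + 1] <- min(best[i, j + 1] + g_open, I[i, j + 1] + g_extend)
      }
      cand <- c(if (i > 0L && j > 0L) best[i, j] + subst(rf[j], rd[i]) else Inf,
                D[i + 1, j + 1], I[i + 1, j + 1])
      best[i + 1, j + 1] <- min(cand)
    }
  }
  best[nr + 1, mc + 1]
}

# ---- exhaustive move-sequence enumerator -----------------------------------
# Depth-first search over all monotone paths built from single-base M/D/I
# moves and whole-unit shorten/lengthen moves, with branch-and-bound
# pruning. An upper bound from the affine-only oracle initialises the bound
# (any affine path is a legal path of the full system).
enum_align_score <- function(read, ref, ann, model) {
  rd <- match(strsplit(toupper(read), "")[[1]], ORACLE_BASES)
  rf <- match(strsplit(toupper(ref), "")[[1]], ORACLE_BASES)
  nr <- length(rd); mc <- length(rf)
  P <- model$P; go <- model$G_open; ge <- model$G_extend
  p_max <- max(P)
  N <- model$N
  n_max <- dim(N)[1]; l_max <- dim(N)[2]
  npen <- function(n, l, obs) {
    N[n, min(l, l_max - 1L) + 1L, min(max(obs, 0L), l_max - 1L) + 1L]
  }
  best <- gotoh_score(read, ref, P, go, ge)
  # state: i, j consumed; last in {"", "D", "I", "S", "L"}; for affine runs
  # nothing extra; for S/L runs: run bases + cost at run entry
  rec <- function(i, j, cost, last, run, base, run_n) {
    if (cost >= best) return(invisible())
    if (i == nr && j == mc) {
      best <<- cost
      return(invisible())
    }
    # M move
    if (i < nr && j < mc) {
      s <- if (is.na(rd[i + 1]) || is.na(rf[j + 1])) p_max else
        P[rf[j + 1], rd[i + 1]]
      rec(i + 1L, j + 1L, cost + s, "M", 0L, 0, 0L)
    }
    # affine D / I moves
    if (j < mc) {
      rec(i, j + 1L, cost + if (last == "D") ge else go, "D", 0L, 0, 0L)
    }
    if (i < nr) {
      rec(i + 1L, j, cost + if (last == "I") ge else go, "I", 0L, 0, 0L)
    }
    # shorten: delete one unit of length n starting at column j; a run
    # keeps its unit length (entering requires the polymer start)
    for (n in seq_len(n_max)) {
      if (j + n > mc) next
      l <- ann$l[n, j + 1L]
      if (l <= 0L) next
      in_run <- last == "S" && run_n == n
      r0 <- if (in_run) run else 0L
      b0 <- if (in_run) base else cost
      k <- r0 %/% n
      if (ann$idx[n, j + 1L] != k) next
      if (l - k - 1L < 0L) next
      rec(i, j + n, b0 + npen(n, l, l - k - 1L), "S", r0 + n, b0, n)
    }
    # lengthen: insert one unit matching the reference unit at column j
    for (n in seq_len(n_max)) {
      if (i + n > nr || j + n > mc) next
      l <- ann$l[n, j + 1L]
      if (l <= 0L || ann$idx[n, j + 1L] != 0L) next
      seg_r <- rd[(i + 1):(i + n)]; seg_f <- rf[(j + 1):(j + n)]
      if (anyNA(seg_r) || anyNA(seg_f) || any(seg_r != seg_f)) next
      in_run <- last == "L" && run_n == n
      r0 <- if (in_run) run else 0L
      b0 <- if (in_run) base else cost
      k <- r0 %/% n
      rec(i + n, j, b0 + npen(n, l, l + k + 1L), "L", r0 + n, b0, n)
    }
    invisible()
  }
  rec(0L, 0L, 0, "", 0L, 0, 0L)
  best
}

# ---- spreadsheet-style n-polymer penalty oracle ----------------------------
# Direct per-cell -log evaluation, then naive loop-based enforcement of the
# two monotonicity families in the package's documented order: within-row
# fix (penalty rises with INDEL size), then ascending copy-number chain
# from the first observed row (observed rows clamped below their
# predecessor, unobserved rows inheriting the bound), then a backward raise
# of the structurally impossible leading rows.
oracle_npoly_penalties <- function(C_N, eps) {
  n_max <- dim(C_N)[1]; l_max <- dim(C_N)[2]
  N <- array(0, dim(C_N))
  for (n in seq_len(n_max)) {
    for (i in seq_len(l_max)) {
      tot <- sum(C_N[n, i, ])
      for (j in seq_len(l_max)) {
        N[n, i, j] <- max(0, -log((C_N[n, i, j] + eps) / (tot + eps)))
      }
    }
  }
  delta <- 1e-6
  fix_row_naive <- function(v) {
    for (t in seq_along(v)[-1]) {
      if (v[t] < v[t - 1] + delta) v[t] <- v[t - 1] + delta
    }
    v
  }
  for (n in seq_len(n_max)) {
    obs <- vapply(seq_len(l_max), function(i) sum(C_N[n, i, ]) > 0,
                  logical(1))
    f1 <- function(i) {
      for (side in c(-1L, 1L)) {
        js <- i + side * seq_len(l_max)
        js <- js[js >= 1L & js <= l_max]
        if (length(js) >= 2L) N[n, i, js] <<- fix_row_naive(N[n, i, js])
      }
    }
    first_obs <- which(obs)[1]
    if (is.na(first_obs)) first_obs <- 1L
    f1(first_obs)
    if (first_obs < l_max) {
      for (i in first_obs:(l_max - 1L)) {
        for (side in c(-1L, 1L)) {
          for (k in seq_len(l_max)) {
            jh <- i + 1L + side * k; jl <- i + side * k
            if (jh < 1L || jh > l_max || jl < 1L || jl > l_max) next
            bound <- N[n, i, jl] - delta
            if (obs[i + 1L]) {
              if (N[n, i + 1L, jh] > bound) N[n, i + 1L, jh] <- bound
            } else {
              N[n, i + 1L, jh] <- bound
            }
          }
        }
        f1(i + 1L)
      }
    }
    if (first_obs > 1L) {
      for (i in seq(first_obs - 1L, 1L)) {
        for (side in c(-1L, 1L)) {
          for (k in seq_len(l_max)) {
            jh <- i + 1L + side * k; jl <- i + side * k
            if (jh < 1L || jh > l_max || jl < 1L || jl > l_max) next
            if (N[n, i, jl] < N[n, i + 1L, jh] + delta) {
              N[n, i, jl] <- N[n, i + 1L, jh] + delta
            }
          }
        }
        f1(i)
      }
    }
  }
  N
}

# check both monotonicity families; returns TRUE when they hold everywhere
npoly_regular_ok <- function(N, strict_margin = 0) {
  n_max <- dim(N)[1]; l_max <- dim(N)[2]
  for (n in seq_len(n_max)) {
    for (i in seq_len(l_max)) {
      for (side in c(-1L, 1L)) {
        for (k in seq_len(l_max - 1L)) {
          j1 <- i + side * k; j2 <- i + side * (k + 1L)
          if (j1 >= 1L && j1 <= l_max && j2 >= 1L && j2 <= l_max) {
            if (!(N[n, i, j1] < N[n, i, j2] - strict_margin)) return(FALSE)
          }
        }
        if (i < l_max) {
          for (k in seq_len(l_max)) {
            jl <- i + side * k; jh <- i + 1L + side * k
            if (jl >= 1L && jl <= l_max && jh >= 1L && jh <= l_max) {
              if (!(N[n, i + 1L, jh] < N[n, i, jl] - strict_margin)) {
                return(FALSE)
              }
            }
          }
        }
      }
    }
  }
  TRUE
}
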