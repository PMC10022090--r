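# Penalty model: every alignment penalty is the negative natural log of a
# measured event frequency. Three components are estimated from alignment
# confusion statistics:
#   * P      4x4 substitution penalties, -log((C_P[i,j]+eps)/(sum row+eps))
#   * G_open, G_extend   affine gap parameters, least-squares fit to the
#                        per-length -log INDEL frequencies (defaults 5, 1)
#   * N      n_max x l_max x l_max copy-number penalties for shortening /
#            lengthening an n-polymer from expected length i to observed j,
#            row-normalized and regularized so that penalties rise with
#            INDEL size and fall with polymer length.

BASES <- c("A", "C", "G", "T")

#' Empty confusion counts
#'
#' @param n_max,l_max,max_indel dimensions: repeat-unit lengths tracked,
#'   copy-number extent of the `C_N` tensor, and longest INDEL run length
#'   bucketed in `C_I`/`C_D`.
#' @return An object of class `confusion_counts` with components `C_P`
#'   (4x4 aligned base counts, reference in rows), `C_I`/`C_D` (counts of
#'   insertion/deletion runs by length), and `C_N` (`n_max x l_max x l_max`
#'   counts of expected-vs-observed polymer copy numbers).
#' @export
confusion_counts <- function(n_max = 6L, l_max = 100L, max_indel = 50L) {
  structure(list(
    C_P = matrix(0, 4, 4, dimnames = list(ref = BASES, read = BASES)),
    C_I = setNames(numeric(max_indel), seq_len(max_indel)),
    C_D = setNames(numeric(max_indel), seq_len(max_indel)),
    C_N = array(0, dim = c(n_max, l_max, l_max)),
    n_max = as.integer(n_max), l_max = as.integer(l_max),
    max_indel = as.integer(max_indel)
  ), class = "confusion_counts")
}

#' Sum two sets of confusion counts
#'
#' Counting two alignment sets separately and adding the results equals
#' counting their union.
#'
#' @param a,b `confusion_counts` objects with matching dimensions.
#' @return Combined `confusion_counts`.
#' @export
combine_counts <- function(a, b) {
  stopifnot(inherits(a, "confusion_counts"), inherits(b, "confusion_counts"),
            a$n_max == b$n_max, a$l_max == b$l_max, a$max_indel == b$max_indel)
  a$C_P <- a$C_P + b$C_P
  a$C_I <- a$C_I + b$C_I
  a$C_D <- a$C_D + b$C_D
  a$C_N <- a$C_N + b$C_N
  a
}

#' Accumulate confusion counts from alignments
#'
#' Walks each alignment's CIGAR against its reference window. Aligned base
#' pairs increment `C_P`; each contiguous insertion (deletion) run increments
#' one `C_I` (`C_D`) bucket at its run length. For `C_N`, every annotated
#' n-polymer span that the read alignment covers end-to-end (with one base of
#' flank on each side) contributes one count at (n, expected copies, observed
#' copies), where the observed copy number is the expected one plus the net
#' inserted-minus-deleted bases inside the span divided by n; events whose
#' net is not a whole number of units are skipped for `C_N` (they still feed
#' `C_I`/`C_D`).
#'
#' @param alignments a list of alignments, each a list with elements `read`
#'   (read sequence), `cigar`, and `ref_start` (1-based start of the aligned
#'   window on the reference). Soft/hard clips must be removed beforehand.
#' @param ref reference sequence string the windows refer to.
#' @param annotation [annotate_reference()] result for `ref`.
#' @param counts optional existing `confusion_counts` to add into.
#' @return Updated `confusion_counts`.
#' @export
count_confusions <- function(alignments, ref, annotation,
                             counts = confusion_counts(
                               n_max = annotation$params$n_max,
                               l_max = annotation$params$l_max)) {
  iv <- npoly_intervals(annotation)
  rf <- strsplit(toupper(ref), "")[[1]]
  for (al in alignments) {
    p <- parse_cigar(al$cigar)
    cons <- cigar_consumed(al$cigar)
    if (cons[["read"]] != nchar(al$read)) {
      stop("CIGAR/sequence length mismatch for read ",
           if (!is.null(al$name)) al$name else "<unnamed>",
           ": CIGAR consumes ", cons[["read"]], " read bases, sequence has ",
           nchar(al$read))
    }
    rd <- strsplit(toupper(al$read), "")[[1]]
    i <- 0L                       # read bases consumed
    j <- al$ref_start - 1L        # ref bases consumed (0-based offset)
    # per-position indel accounting for C_N:
    # ins_at[q] = bases inserted between ref positions q and q+1 (q 1-based);
    # del_at[q] = 1 if ref position q deleted
    ins_pos <- integer(0); ins_len <- integer(0)
    del_pos <- integer(0)
    for (k in seq_along(p$ops)) {
      op <- p$ops[k]; len <- p$lengths[k]
      if (op %in% c("M", "=", "X")) {
        a <- rd[(i + 1):(i + len)]
        r <- rf[(j + 1):(j + len)]
        ok <- a %in% BASES & r %in% BASES
        if (any(ok)) {
          tab <- table(factor(r[ok], BASES), factor(a[ok], BASES))
          counts$C_P <- counts$C_P + unclass(tab)
        }
        i <- i + len; j <- j + len
      } else if (op == "I") {
        b <- min(len, counts$max_indel)
        counts$C_I[b] <- counts$C_I[b] + 1
        ins_pos <- c(ins_pos, j); ins_len <- c(ins_len, len)
        i <- i + len
      } else if (op == "D") {
        b <- min(len, counts$max_indel)
        counts$C_D[b] <- counts$C_D[b] + 1
        del_pos <- c(del_pos, (j + 1):(j + len))
        j <- j + len
      } else {
        stop("count_confusions: unsupported CIGAR op ", op)
      }
    }
    ref_end <- j # last ref position consumed (1-based inclusive)
    # C_N: polymers fully spanned with 1 bp flanks
    if (nrow(iv) > 0L) {
      spanned <- iv[iv$start - 1L >= al$ref_start & iv$end + 1L <= ref_end, ,
                    drop = FALSE]
      for (q in seq_len(nrow(spanned))) {
        n <- spanned$n[q]; l <- spanned$l[q]
        s0 <- spanned$start[q]; e0 <- spanned$end[q]
        # insertions anchored in [s0-1, e0]; deletions of positions in [s0, e0]
        net <- 0L
        if (length(ins_pos)) {
          sel <- ins_pos >= s0 - 1L & ins_pos <= e0
          net <- net + sum(ins_len[sel])
        }
        if (length(del_pos)) net <- net - sum(del_pos >= s0 & del_pos <= e0)
        if (net %% n != 0L) next
        obs <- l + net %/% n
        li <- min(l, counts$l_max - 1L)
        oi <- min(max(obs, 0L), counts$l_max - 1L)
        # 0-based copy-number indices stored at R index + 1
        counts$C_N[n, li + 1L, oi + 1L] <- counts$C_N[n, li + 1L, oi + 1L] + 1
      }
    }
  }
  counts
}

#' Substitution penalty matrix from confusion counts
#'
#' `P[i,j] = -log((C_P[i,j] + eps) / (sum(C_P[i,]) + eps))`, natural log.
#' The smoothing constant guards rows with no observations (an all-zero row
#' yields all-zero penalties, the eps-only limit).
#'
#' @param C_P 4x4 matrix of aligned base counts (reference in rows).
#' @param eps smoothing constant, > 0 (default 0.01).
#' @return 4x4 non-negative penalty matrix.
#' @export
substitution_penalties <- function(C_P, eps = 0.01) {
  stopifnot(eps > 0, all(dim(C_P) == c(4, 4)), all(C_P >= 0))
  P <- -log((C_P + eps) / (rowSums(C_P) + eps))
  dimnames(P) <- list(ref = BASES, read = BASES)
  pmax(P, 0)
}

#' Per-length INDEL penalty curve
#'
#' `-log((C[len] + eps) / (sum(C) + eps))` for each run length.
#'
#' @param C named numeric vector of INDEL run-length counts (`C_I` or `C_D`).
#' @param eps smoothing constant.
#' @return Numeric vector of penalties, named by length.
#' @export
indel_penalty_curve <- function(C, eps = 0.01) {
  stopifnot(eps > 0, all(C >= 0))
  -log((C + eps) / (sum(C) + eps))
}

#' Fit affine gap parameters to an INDEL penalty curve
#'
#' Least-squares fit of `penalty(len) ~ G_open + (len - 1) * G_extend` over
#' lengths with observed counts; both parameters are clipped at zero. With
#' fewer than two observed lengths the defaults (5, 1) are returned with a
#' warning.
#'
#' @param penalties per-length penalties from [indel_penalty_curve()].
#' @param observed logical (or count) vector marking lengths that were
#'   actually observed; defaults to all lengths.
#' @return Named numeric vector `c(G_open=, G_extend=)`.
#' @export
fit_affine <- function(penalties, observed = rep(TRUE, length(penalties))) {
  lens <- as.numeric(names(penalties))
  if (is.null(names(penalties))) lens <- seq_along(penalties)
  keep <- as.logical(observed > 0)
  if (sum(keep) < 2L) {
    warning("fewer than 2 observed INDEL lengths; returning default affine ",
            "parameters (G_open=5, G_extend=1)")
    return(c(G_open = 5, G_extend = 1))
  }
  fit <- lm(penalties[keep] ~ I(lens[keep] - 1))
  c(G_open = max(0, unname(coef(fit)[1])),
    G_extend = max(0, unname(coef(fit)[2])))
}

#' n-polymer copy-number penalty tensor from confusion counts
#'
#' Each row of `C_N` (fixed unit length n and expected copy number i) is
#' converted to penalties `-log((C_N[n,i,j] + eps) / (sum_j C_N[n,i,] + eps))`
#' and then regularized so that, for every in-bounds k > 0:
#' \itemize{
#'   \item shorter INDELs are more likely:
#'     `N[n,i,i+-k] < N[n,i,i+-(k+1)]`;
#'   \item longer n-polymers are more likely to contain an INDEL of a given
#'     size: `N[n,i+1,(i+1)+-k] < N[n,i,i+-k]`.
#' }
#' Enforcement is one ordered pass ascending in copy number, with a
#' strictness margin of 1e-6: each row is made k-monotone by raising the
#' farther cell minimally, then the next row is clamped strictly below it.
#' Rows without observations inherit the running bound (their smoothed
#' penalties collapse to zero and carry no information), and rows below
#' the first observed copy number -- expected lengths that cannot occur --
#' are raised above it afterwards. `printed_direction = TRUE` flips both
#' inequalities (penalty of the nearer/longer case forced higher), for
#' comparison only.
#'
#' @param C_N `n_max x l_max x l_max` count array.
#' @param eps smoothing constant.
#' @param regularize apply the monotonicity sweeps (default TRUE).
#' @param printed_direction flip the enforced inequality directions.
#' @return Penalty array of the same shape.
#' @export
npolymer_penalties <- function(C_N, eps = 0.01, regularize = TRUE,
                               printed_direction = FALSE) {
  stopifnot(eps > 0, length(dim(C_N)) == 3L)
  n_max <- dim(C_N)[1]; l_max <- dim(C_N)[2]
  N <- array(0, dim = dim(C_N))
  nonempty <- matrix(FALSE, n_max, l_max)
  for (n in seq_len(n_max)) {
    row_tot <- rowSums(C_N[n, , , drop = TRUE])
    nonempty[n, ] <- row_tot > 0
    N[n, , ] <- -log((C_N[n, , ] + eps) / (row_tot + eps))
  }
  N <- pmax(N, 0)
  if (regularize) {
    N <- if (printed_direction) -regularize_npoly(-N, nonempty) else
      regularize_npoly(N, nonempty)
  }
  N
}

# Ordered enforcement of the two monotonicity families:
#   family 1: within a row, penalty strictly rises with INDEL size k
#             (the farther cell is raised minimally);
#   family 2: at matching k, a longer polymer's penalty is strictly lower
#             (the longer row is clamped from above by the shorter one).
# The cross-row chain runs in ascending copy number starting at the first
# row with observations: rows without observations carry no information
# (their smoothed penalties collapse to zero) and inherit the running
# bound instead of acting as sources, and rows before the first observed
# copy number -- expected lengths that can never occur, since a polymer
# needs at least three copies -- are afterwards raised above it, keeping
# the global property without distorting any row the aligner can index.
# One ordered pass reaches a fixed point: clamping preserves within-row
# monotonicity (the pointwise minimum of two strictly k-increasing rows is
# strictly increasing), and re-fixing a clamped row cannot push it back
# above its predecessor. Indices are 1-based R indices over copy numbers
# 0..l_max-1.
regularize_npoly <- function(N, nonempty = NULL, delta = 1e-6) {
  n_max <- dim(N)[1]; l_max <- dim(N)[2]
  if (is.null(nonempty)) nonempty <- matrix(TRUE, n_max, l_max)
  fix_row <- function(v) {
    t <- seq_along(v)
    cummax(v - delta * t) + delta * t
  }
  shift_pairs <- function(i, side) {
    ks <- seq_len(l_max)
    j_hi <- (i + 1L) + side * ks
    j_lo <- i + side * ks
    ok <- j_hi >= 1L & j_hi <= l_max & j_lo >= 1L & j_lo <= l_max
    list(hi = j_hi[ok], lo = j_lo[ok])
  }
  for (n in seq_len(n_max)) {
    M <- N[n, , ]
    f1 <- function(i) {
      for (side in c(-1L, 1L)) {
        js <- i + side * seq_len(l_max)
        js <- js[js >= 1L & js <= l_max]
        if (length(js) >= 2L) M[i, js] <<- fix_row(M[i, js])
      }
    }
    first_obs <- which(nonempty[n, ])[1]
    if (is.na(first_obs)) first_obs <- 1L
    f1(first_obs)
    if (first_obs < l_max) {
      for (i in first_obs:(l_max - 1L)) {
        for (side in c(-1L, 1L)) {
          p <- shift_pairs(i, side)
          if (!length(p$lo)) next
          if (nonempty[n, i + 1L]) {
            M[i + 1L, p$hi] <- pmin(M[i + 1L, p$hi], M[i, p$lo] - delta)
          } else {
            M[i + 1L, p$hi] <- M[i, p$lo] - delta
          }
        }
        f1(i + 1L)
      }
    }
    if (first_obs > 1L) {
      for (i in seq(first_obs - 1L, 1L)) {
        for (side in c(-1L, 1L)) {
          p <- shift_pairs(i, side)
          if (!length(p$lo)) next
          M[i, p$lo] <- pmax(M[i, p$lo], M[i + 1L, p$hi] + delta)
        }
        f1(i)
      }
    }
    N[n, , ] <- M
  }
  N
}

#' Construct a penalty model
#'
#' @param P 4x4 substitution penalty matrix.
#' @param G_open,G_extend affine gap open/extension penalties.
#' @param N copy-number penalty tensor (`n_max x l_max x l_max`), or NULL to
#'   disable n-polymer transitions.
#' @param eps smoothing constant recorded with the model.
#' @param meta optional provenance metadata list.
#' @return Object of class `penalty_model`.
#' @export
penalty_model <- function(P, G_open = 5, G_extend = 1, N = NULL, eps = 0.01,
                          meta = list()) {
  stopifnot(all(dim(P) == c(4, 4)), all(is.finite(P)), all(P >= 0),
            G_open >= 0, G_extend >= 0)
  if (!is.null(N)) {
    # regularization's strictness margin can leave a handful of cells a few
    # millionths below zero in rows with no observations; tolerate that
    stopifnot(length(dim(N)) == 3L, all(is.finite(N)), all(N >= -1e-3))
  }
  structure(list(P = P, G_open = G_open, G_extend = G_extend, N = N,
                 eps = eps, meta = meta),
            class = "penalty_model")
}

#' @export
print.penalty_model <- function(x, ...) {
  cat("penalty model: G_open =", format(x$G_open, digits = 4),
      ", G_extend =", format(x$G_extend, digits = 4),
      if (is.null(x$N)) "(affine only)" else
        sprintf("(N tensor %dx%dx%d)", dim(x$N)[1], dim(x$N)[2], dim(x$N)[3]),
      "\n")
  invisible(x)
}

#' Parametric copy-number error profile
#'
#' Probability distribution over observed copy numbers j (0-based, up to
#' `l_max - 1`) for an n-polymer of expected copy number l. The error rate
#' rises quadratically with polymer length and halves with each unit-length
#' increase; conditional on an error, the copy-number change follows a
#' geometric distribution over sizes with a slight excess of insertions over
#' deletions. This is the generator behind [default_model()] and the
#' simulated reads in [simulate_reads()].
#'
#' @param n repeat-unit length.
#' @param l expected copy number (>= 1).
#' @param l_max extent of the returned vector.
#' @param base_rate error-rate coefficient for n = 1 (default 0.0045, which
#'   puts a length-10 homopolymer at a 45 percent INDEL rate).
#' @param decay geometric decay of the INDEL size distribution.
#' @param ins_frac fraction of copy-number errors that are insertions.
#' @return Numeric probability vector of length `l_max` (index j+1 holds
#'   P(observed = j)), summing to 1.
#' @export
copy_error_profile <- function(n, l, l_max = 100L, base_rate = 0.0045,
                               decay = 0.25, ins_frac = 0.55) {
  stopifnot(n >= 1, l >= 1, l < l_max)
  pe <- min(0.45, base_rate * 2^(1 - n) * l^2)
  w <- numeric(l_max)
  w[l + 1L] <- 1 - pe
  for (k in seq_len(l_max)) {
    up <- l + k; dn <- l - k
    if (up <= l_max - 1L) w[up + 1L] <- pe * ins_frac * (1 - decay) * decay^(k - 1)
    if (dn >= 0L) w[dn + 1L] <- pe * (1 - ins_frac) * (1 - decay) * decay^(k - 1)
  }
  w / sum(w)
}

#' Default penalty model
#'
#' Substitution penalties from a 99 percent-identity confusion prior, affine
#' defaults G_open = 5 and G_extend = 1, and a copy-number tensor filled from
#' [copy_error_profile()] for every (n, l) row, then regularized. Suitable
#' for realignment when no training alignments are available.
#'
#' @param n_max,l_max tensor dimensions.
#' @param eps smoothing constant.
#' @return A `penalty_model`.
#' @export
default_model <- function(n_max = 6L, l_max = 100L, eps = 0.01) {
  C_P <- matrix(1e4 / 3, 4, 4); diag(C_P) <- 99e4
  P <- substitution_penalties(C_P, eps)
  C_N <- array(0, dim = c(n_max, l_max, l_max))
  for (n in seq_len(n_max)) {
    for (l in seq_len(l_max - 1L)) {
      C_N[n, l + 1L, ] <- 1e6 * copy_error_profile(n, l, l_max)
    }
  }
  N <- npolymer_penalties(C_N, eps)
  penalty_model(P, 5, 1, N, eps, meta = list(source = "default parametric"))
}

#' Train a penalty model from alignments
#'
#' Runs [count_confusions()] over the alignments and derives all penalty
#' components. Affine parameters are fit separately to the insertion and
#' deletion curves and averaged.
#'
#' @inheritParams count_confusions
#' @param eps smoothing constant.
#' @return A `penalty_model`.
#' @export
train_model <- function(alignments, ref, annotation, eps = 0.01) {
  cc <- count_confusions(alignments, ref, annotation)
  P <- substitution_penalties(cc$C_P, eps)
  fi <- fit_affine(indel_penalty_curve(cc$C_I, eps), cc$C_I)
  fd <- fit_affine(indel_penalty_curve(cc$C_D, eps), cc$C_D)
  N <- npolymer_penalties(cc$C_N, eps)
  penalty_model(P, unname((fi[1] + fd[1]) / 2), unname((fi[2] + fd[2]) / 2),
                N, eps,
                meta = list(source = "trained",
                            n_alignments = length(alignments)))
}

#' Write / read a penalty model as JSON
#'
#' @param model a `penalty_model`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "penalty_model"))
  obj <- list(P = model$P, G_open = model$G_open, G_extend = model$G_extend,
              eps = model$eps, meta = model$meta)
  if (!is.null(model$N)) {
    obj$N_dim <- dim(model$N)
    obj$N <- as.vector(model$N)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- matrix(as.numeric(obj$P), 4, 4, byrow = TRUE,
              dimnames = list(ref = BASES, read = BASES))
  N <- NULL
  if (!is.null(obj$N)) N <- array(as.numeric(obj$N), dim = obj$N_dim)
  penalty_model(P, obj$G_open, obj$G_extend, N, obj$eps,
                meta = as.list(obj$meta))
}
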