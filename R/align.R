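# R-level alignment interface over the C++ kernel, plus independent
# re-scoring of an existing CIGAR under the model.

encode_bases <- function(seq) {
  # 0..3 = ACGT, 4 = anything else (N); empty string -> integer(0)
  if (nchar(seq) == 0L) return(integer(0))
  x <- strsplit(toupper(seq), "")[[1]]
  code <- match(x, BASES)
  code[is.na(code)] <- 5L
  as.integer(code - 1L)
}

ann_matrices <- function(annotation, width) {
  if (is.null(annotation)) {
    return(list(l = matrix(0L, 1, max(width, 1L)),
                idx = matrix(0L, 1, max(width, 1L))))
  }
  stopifnot(inherits(annotation, "npoly_annotation"),
            annotation$seq_len == width)
  list(l = annotation$l, idx = annotation$idx)
}

new_alignment_result <- function(ops, score, ref_start, ref_end, read_id) {
  structure(list(cigar = collapse_cigar(ops), score = score,
                 ref_start = ref_start, ref_end = ref_end,
                 read_id = read_id),
            class = "npoly_alignment")
}

#' @export
print.npoly_alignment <- function(x, ...) {
  cat(sprintf("alignment%s: score %.4f, CIGAR %s (window %d..%d)\n",
              if (is.null(x$read_id)) "" else paste0(" ", x$read_id),
              x$score, x$cigar, x$ref_start, x$ref_end))
  invisible(x)
}

#' Repeat-aware global alignment
#'
#' Aligns a read end-to-end against a reference window with the five-matrix
#' dynamic program. The affine delete/insert matrices use `G_open`/`G_extend`
#' from the model; annotated n-polymers additionally admit shortening and
#' lengthening moves that add or remove whole repeat units at the copy-number
#' penalty `N[n, expected, observed]`. With `use_npoly = FALSE` (or a model
#' without `N`) the program reduces exactly to Needleman-Wunsch with affine
#' gaps.
#'
#' @param read read sequence (string).
#' @param ref_window reference window sequence (string).
#' @param annotation [annotate_reference()] result for `ref_window` (or a
#'   matching [annotation_window()] slice); may be NULL when
#'   `use_npoly = FALSE`.
#' @param model a [penalty_model()].
#' @param use_npoly enable the shortening/lengthening matrices.
#' @param read_id optional identifier carried into the result.
#' @param ref_start 1-based coordinate of the window start on its contig,
#'   recorded in the result.
#' @return An object of class `npoly_alignment` with elements `cigar`,
#'   `score`, `ref_start`, `ref_end`, `read_id`.
#' @examples
#' m <- default_model(l_max = 20)
#' a <- annotate_reference("GGCTAAAAAATTCG", annotation_params(l_max = 20))
#' align("GGCTAAAAATTCG", "GGCTAAAAAATTCG", a, m)
#' @export
align <- function(read, ref_window, annotation = NULL, model,
                  use_npoly = TRUE, read_id = NULL, ref_start = 1L) {
  stopifnot(inherits(model, "penalty_model"))
  m <- nchar(ref_window)
  ann <- ann_matrices(annotation, m)
  use_npoly <- use_npoly && !is.null(model$N) && !is.null(annotation)
  res <- .align_kernel(encode_bases(read), encode_bases(ref_window),
                       ann$l, ann$idx, model$P, model$G_open, model$G_extend,
                       if (use_npoly) model$N else NULL,
                       if (use_npoly) dim(model$N) else c(0L, 0L, 0L),
                       use_npoly)
  new_alignment_result(res$ops, res$score, ref_start, ref_start + m - 1L,
                       read_id)
}

#' Follow-banded repeat-aware alignment
#'
#' Identical contract to [align()], but the dynamic program is evaluated
#' only inside a band of half-width `b` that follows the read's original
#' alignment path: the original CIGAR is expanded to an insertion/deletion
#' path ([expand_to_id()]), and computation proceeds one anti-diagonal of
#' width `2b + 1` at a time, centered on that path. Cells outside the band
#' are treated as unreachable; shortening/lengthening writes that would land
#' outside the band are dropped. The workspace holds exactly
#' `(2b + 1) * (read length + window length)` cells regardless of window
#' size.
#'
#' @inheritParams align
#' @param original_cigar the read's existing CIGAR over M/I/D (clips
#'   removed), consistent with `read` and `ref_window` lengths.
#' @param b band half-width (default 30).
#' @param return_workspace also return the workspace cell count.
#' @return An `npoly_alignment`; with `return_workspace = TRUE` it carries an
#'   extra element `workspace_cells`.
#' @export
banded_align <- function(read, ref_window, original_cigar, annotation = NULL,
                         model, b = 30L, use_npoly = TRUE, read_id = NULL,
                         ref_start = 1L, return_workspace = FALSE) {
  stopifnot(inherits(model, "penalty_model"), b >= 0L)
  m <- nchar(ref_window)
  cons <- cigar_consumed(original_cigar)
  if (cons[["read"]] != nchar(read) || cons[["ref"]] != m) {
    stop("original CIGAR consumes (", cons[["read"]], " read, ",
         cons[["ref"]], " ref) bases but sequences have (",
         nchar(read), ", ", m, ")")
  }
  id_path <- expand_to_id(original_cigar)
  ann <- ann_matrices(annotation, m)
  use_npoly <- use_npoly && !is.null(model$N) && !is.null(annotation)
  res <- .banded_kernel(encode_bases(read), encode_bases(ref_window),
                        ann$l, ann$idx, model$P, model$G_open,
                        model$G_extend,
                        if (use_npoly) model$N else NULL,
                        if (use_npoly) dim(model$N) else c(0L, 0L, 0L),
                        use_npoly,
                        as.integer(id_path == "D"), as.integer(b))
  out <- new_alignment_result(res$ops, res$score, ref_start,
                              ref_start + m - 1L, read_id)
  if (return_workspace) out$workspace_cells <- res$cells
  out
}

#' Re-score a CIGAR under a penalty model
#'
#' Computes the minimum model cost of an alignment path consistent with the
#' given CIGAR: matches/mismatches are charged via `P`; each maximal
#' insertion or deletion run is charged the cheapest decomposition into
#' affine gap segments and (where the annotation permits) whole-unit
#' n-polymer shortening/lengthening runs. Replaying an alignment emitted by
#' [align()] or [banded_align()] reproduces its score.
#'
#' @param read,ref_window,annotation,model as in [align()].
#' @param cigar CIGAR over M/I/D consistent with the sequences.
#' @param use_npoly allow copy-number segments in gap decompositions.
#' @return Numeric score.
#' @export
score_cigar <- function(read, ref_window, cigar, annotation = NULL, model,
                        use_npoly = TRUE) {
  stopifnot(inherits(model, "penalty_model"))
  m <- nchar(ref_window)
  cons <- cigar_consumed(cigar)
  stopifnot(cons[["read"]] == nchar(read), cons[["ref"]] == m)
  use_npoly <- use_npoly && !is.null(model$N) && !is.null(annotation)
  rd <- encode_bases(read); rf <- encode_bases(ref_window)
  p_max <- max(model$P)
  l_max <- if (use_npoly) dim(model$N)[2] else 0L
  n_pen <- function(n, l, obs) {
    li <- min(l, l_max - 1L)
    oi <- min(max(obs, 0L), l_max - 1L)
    model$N[n, li + 1L, oi + 1L]
  }
  affine <- function(len) model$G_open + (len - 1) * model$G_extend
  # cheapest cover of a deletion run of g ref bases starting at 0-based j0
  del_run_cost <- function(g, j0) {
    cost <- c(0, rep(Inf, g))
    for (t in seq_len(g)) {
      for (s in 0:(t - 1)) {
        cand <- cost[s + 1] + affine(t - s)
        if (cand < cost[t + 1]) cost[t + 1] <- cand
        if (use_npoly) {
          pos <- j0 + s # 0-based column of segment start
          for (n in seq_len(nrow(annotation$l))) {
            l <- annotation$l[n, pos + 1L]
            if (l > 0 && annotation$idx[n, pos + 1L] == 0 &&
                (t - s) %% n == 0) {
              k <- (t - s) %/% n
              if (k >= 1 && k <= l) {
                cand <- cost[s + 1] + n_pen(n, l, l - k)
                if (cand < cost[t + 1]) cost[t + 1] <- cand
              }
            }
          }
        }
      }
    }
    cost[g + 1]
  }
  # cheapest cover of an insertion run of g read bases at 0-based column j0
  ins_run_cost <- function(g, i0, j0) {
    cost <- c(0, rep(Inf, g))
    for (t in seq_len(g)) {
      for (s in 0:(t - 1)) {
        cand <- cost[s + 1] + affine(t - s)
        if (cand < cost[t + 1]) cost[t + 1] <- cand
        if (use_npoly && j0 < m) {
          for (n in seq_len(nrow(annotation$l))) {
            l <- annotation$l[n, j0 + 1L]
            if (l > 0 && annotation$idx[n, j0 + 1L] == 0 &&
                (t - s) %% n == 0 && j0 + n <= m) {
              k <- (t - s) %/% n
              if (k >= 1) {
                unit <- rf[(j0 + 1):(j0 + n)]
                ins <- rd[(i0 + s + 1):(i0 + t)]
                if (all(unit <= 3) &&
                    identical(rep(unit, k), ins)) {
                  cand <- cost[s + 1] + n_pen(n, l, l + k)
                  if (cand < cost[t + 1]) cost[t + 1] <- cand
                }
              }
            }
          }
        }
      }
    }
    cost[g + 1]
  }
  p <- parse_cigar(cigar)
  i <- 0L; j <- 0L; total <- 0
  for (k in seq_along(p$ops)) {
    op <- p$ops[k]; len <- p$lengths[k]
    if (op %in% c("M", "=", "X")) {
      for (t in seq_len(len)) {
        a <- rd[i + t]; r <- rf[j + t]
        total <- total + if (a > 3L || r > 3L) p_max else
          model$P[r + 1L, a + 1L]
      }
      i <- i + len; j <- j + len
    } else if (op == "D") {
      total <- total + del_run_cost(len, j)
      j <- j + len
    } else if (op == "I") {
      total <- total + ins_run_cost(len, i, j)
      i <- i + len
    } else {
      stop("score_cigar: unsupported op ", op)
    }
  }
  total
}
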