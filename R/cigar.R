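# CIGAR manipulation: parsing, expansion, collapsing, consumption accounting,
# and the ID-expansion used by follow-banding.

#' Parse a CIGAR string into operation/length vectors
#'
#' @param cigar CIGAR string, e.g. `"3M1D1M1I2M"`. `"*"` or `""` give an
#'   empty parse.
#' @return A list with integer `lengths` and character `ops`.
#' @examples
#' parse_cigar("3M1D1M1I2M")
#' @export
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    return(list(lengths = integer(0), ops = character(0)))
  }
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops  <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) ||
      nchar(cigar) != sum(nchar(lens)) + length(ops)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(lengths = as.integer(lens), ops = ops)
}

#' Build a CIGAR string from operation/length vectors
#'
#' Adjacent runs of the same operation are merged; zero-length runs dropped.
#'
#' @param lengths integer run lengths.
#' @param ops character operation codes, same length as `lengths`.
#' @return CIGAR string (`""` for empty input).
#' @export
build_cigar <- function(lengths, ops) {
  stopifnot(length(lengths) == length(ops))
  keep <- lengths > 0L
  lengths <- lengths[keep]; ops <- ops[keep]
  if (length(ops) == 0L) return("")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  lens <- vapply(split(lengths, grp), sum, numeric(1))
  ops  <- vapply(split(ops, grp), `[`, character(1), 1L)
  paste0(as.integer(lens), ops, collapse = "")
}

#' Expand a CIGAR into one character per operation
#'
#' @param cigar CIGAR string.
#' @return Character vector with one element per consumed base/op.
#' @export
expand_cigar <- function(cigar) {
  p <- parse_cigar(cigar)
  if (length(p$ops) == 0L) return(character(0))
  rep(p$ops, p$lengths)
}

#' Collapse per-operation codes into a run-length encoded CIGAR
#'
#' The inverse of [expand_cigar()]: `"MMMDMIMM"` (as a vector or a single
#' string) collapses to `"3M1D1M1I2M"`.
#'
#' @param ops character vector of single-op codes, or one string of codes.
#' @return CIGAR string; `""` for empty input.
#' @examples
#' collapse_cigar(c("M", "M", "M", "D", "M", "I", "M", "M"))
#' collapse_cigar("MMMDMIMM")
#' @export
collapse_cigar <- function(ops) {
  if (length(ops) == 1L && nchar(ops) > 1L) {
    ops <- strsplit(ops, "")[[1]]
  }
  if (length(ops) == 0L) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Reference/read bases consumed by a CIGAR
#'
#' M, =, X and D, N consume reference; M, =, X and I, S consume read
#' (query), following the SAM specification.
#'
#' @param cigar CIGAR string.
#' @return Named integer vector with elements `ref` and `read`.
#' @export
cigar_consumed <- function(cigar) {
  p <- parse_cigar(cigar)
  ref_ops  <- p$ops %in% c("M", "D", "N", "=", "X")
  read_ops <- p$ops %in% c("M", "I", "S", "=", "X")
  c(ref = sum(p$lengths[ref_ops]), read = sum(p$lengths[read_ops]))
}

#' Expand a CIGAR to the insertion/deletion path used by follow-banding
#'
#' Every M (or =/X) operation becomes an insertion followed by a deletion
#' ("ID"); I and D pass through. The resulting path over \{I, D\} has length
#' (read consumed) + (reference consumed) and traces the original alignment
#' through the full dynamic-programming matrix one step at a time.
#'
#' @param cigar CIGAR over M/I/D (and =/X, treated as M). Clips must be
#'   removed by the caller first.
#' @return Character vector over `"I"`, `"D"`.
#' @examples
#' expand_to_id("2M") # I D I D
#' @export
expand_to_id <- function(cigar) {
  p <- parse_cigar(cigar)
  if (any(!(p$ops %in% c("M", "I", "D", "=", "X")))) {
    stop("expand_to_id: resolve ops other than M/I/D (=,X allowed) first; got: ",
         paste(unique(p$ops), collapse = ","))
  }
  out <- character(0)
  pieces <- vector("list", length(p$ops))
  for (k in seq_along(p$ops)) {
    op <- p$ops[k]; len <- p$lengths[k]
    pieces[[k]] <- if (op %in% c("M", "=", "X")) {
      rep(c("I", "D"), len)
    } else {
      rep(op, len)
    }
  }
  unlist(pieces, use.names = FALSE)
}

#' Map banded-matrix coordinates back to the full alignment matrix
#'
#' The banded workspace stores anti-diagonals of the full matrix A, centered
#' on the ID-expanded original alignment path. A cell at anti-diagonal `i`
#' and in-band offset `j` sits at `row = INSs[i] + b - j`,
#' `col = DELs[i] - b + j` of A (0-based).
#'
#' @param i anti-diagonal index (0-based, `0..length(id_path)`).
#' @param j in-band offset in `0..2b`.
#' @param INSs,DELs cumulative insertion/deletion counts along the ID path;
#'   element `k + 1` holds the count after `k` ops (so `INSs[1] = 0`).
#' @param b band half-width.
#' @return List with `row`, `col` (0-based) and logical `in_bounds` relative
#'   to a matrix with `n_rows` rows / `n_cols` cols if supplied.
#' @param n_rows,n_cols optional full-matrix dimensions (read length + 1,
#'   window length + 1) used to flag out-of-bounds cells.
#' @export
band_coords <- function(i, j, INSs, DELs, b, n_rows = NULL, n_cols = NULL) {
  stopifnot(j >= 0, j <= 2 * b)
  row <- INSs[i + 1L] + b - j
  col <- DELs[i + 1L] - b + j
  ok <- TRUE
  if (!is.null(n_rows)) ok <- ok && row >= 0 && row < n_rows
  if (!is.null(n_cols)) ok <- ok && col >= 0 && col < n_cols
  list(row = row, col = col, in_bounds = ok)
}

#' Cumulative insertion/deletion offsets along an ID path
#'
#' @param id_path character vector over I/D, from [expand_to_id()].
#' @return List with integer vectors `INSs` and `DELs`, each of length
#'   `length(id_path) + 1` (prefix counts, starting at 0).
#' @export
id_offsets <- function(id_path) {
  list(INSs = c(0L, cumsum(id_path == "I")),
       DELs = c(0L, cumsum(id_path == "D")))
}

# NM tag: edits = mismatches + inserted + deleted bases (clips excluded).
# MD tag: matched-run lengths, mismatched reference bases, ^-prefixed
# deleted reference stretches. `read`/`ref` are the aligned (clip-free)
# sequences.
cigar_nm_md <- function(read, ref, cigar) {
  p <- parse_cigar(cigar)
  i <- 0L; j <- 0L # consumed read / ref
  nm <- 0L
  md <- character(0)
  match_run <- 0L
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  for (k in seq_along(p$ops)) {
    op <- p$ops[k]; len <- p$lengths[k]
    if (op %in% c("M", "=", "X")) {
      for (t in seq_len(len)) {
        a <- rd[i + t]; r <- rf[j + t]
        if (identical(a, r)) {
          match_run <- match_run + 1L
        } else {
          nm <- nm + 1L
          md <- c(md, as.character(match_run), r)
          match_run <- 0L
        }
      }
      i <- i + len; j <- j + len
    } else if (op == "I") {
      nm <- nm + len
      i <- i + len
    } else if (op == "D") {
      nm <- nm + len
      md <- c(md, as.character(match_run),
              paste0("^", paste(rf[(j + 1):(j + len)], collapse = "")))
      match_run <- 0L
      j <- j + len
    } else {
      stop("cigar_nm_md: unsupported op ", op)
    }
  }
  md <- c(md, as.character(match_run))
  list(nm = nm, md = paste(md, collapse = ""))
}
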