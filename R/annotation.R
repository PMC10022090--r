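# Reference n-polymer annotation.
#
# An n-polymer is at least `min_repeats` exact copies of the same 1..n_max bp
# repeat unit (homopolymer for n = 1, short tandem repeat for 2 <= n <= 6).
# For every n and every reference position that starts a repeat unit we store
# l, the total number of consecutive unit copies in the polymer, and idx, the
# 0-based index of that unit within the polymer. Positions that do not start
# a unit carry l = 0, idx = 0. Phase-shifted overlapping polymers of the same
# n (AT x4 and TA x3 inside ATATATAT) are each annotated, and annotations for
# different n may overlap freely.

#' Annotation parameters
#'
#' @param n_max maximum repeat-unit length considered (default 6).
#' @param min_repeats minimum number of exact unit copies for a run to count
#'   as an n-polymer (default 3; values below 3 are rejected because two
#'   copies never place a unit with identical repeated context on both
#'   sides).
#' @param l_max cap on the copy-number index used for penalty lookups
#'   (default 100, the extent of the penalty tensor). Longer runs keep their
#'   true `l` in the annotation; only tensor lookups clamp to `l_max - 1`.
#' @return An object of class `annotation_params`.
#' @export
annotation_params <- function(n_max = 6L, min_repeats = 3L, l_max = 100L) {
  n_max <- as.integer(n_max); min_repeats <- as.integer(min_repeats)
  l_max <- as.integer(l_max)
  stopifnot(n_max >= 1L, l_max >= min_repeats)
  if (min_repeats < 3L) {
    stop("min_repeats must be >= 3: fewer exact copies never form an n-polymer")
  }
  structure(list(n_max = n_max, min_repeats = min_repeats, l_max = l_max),
            class = "annotation_params")
}

seq_to_ints <- function(seq) {
  # A,C,G,T -> 1..4; N -> 5; anything else is an error naming the position
  x <- strsplit(toupper(seq), "")[[1]]
  code <- match(x, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop("invalid character '", x[bad], "' at position ", bad,
         " (1-based); expected A/C/G/T/N")
  }
  code
}

ints_to_seq <- function(code) {
  paste(c("A", "C", "G", "T", "N")[code], collapse = "")
}

#' Annotate a reference sequence with n-polymer repeat information
#'
#' For each repeat-unit length `n` in `1..n_max`, finds every maximal run of
#' at least `min_repeats` exact copies of an n-base unit and annotates each
#' unit-start position with the total copy number `l` and the 0-based unit
#' index `idx`. N bases break repeats (they compare unequal to everything,
#' including themselves) and are never annotated.
#'
#' @param seq reference sequence (string over A/C/G/T/N, case-insensitive).
#' @param params an [annotation_params()] object.
#' @return An object of class `npoly_annotation`: a list with integer
#'   matrices `l` and `idx` of dimension `n_max x nchar(seq)` (row n holds
#'   the annotation for unit length n), plus `params` and `seq_len`.
#' @examples
#' a <- annotate_reference("ATATATATTTTTAAAGCGCGC")
#' a$l[1, ]  # homopolymer copy counts
#' a$l[2, ]  # 2-polymer copy counts
#' @export
annotate_reference <- function(seq, params = annotation_params()) {
  stopifnot(inherits(params, "annotation_params"))
  L <- nchar(seq)
  lmat <- matrix(0L, nrow = params$n_max, ncol = L)
  imat <- matrix(0L, nrow = params$n_max, ncol = L)
  if (L > 0L) {
    s <- seq_to_ints(seq)
    for (n in seq_len(params$n_max)) {
      if (L < n * params$min_repeats) next
      # d[p] : base p equals base p+n and neither is N (p = 1..L-n)
      p_idx <- seq_len(L - n)
      d <- (s[p_idx] == s[p_idx + n]) & s[p_idx] != 5L & s[p_idx + n] != 5L
      # unit_eq[p] : unit starting at p equals unit starting at p+n
      if (L - n >= n) {
        ue_len <- L - 2L * n + 1L
        if (ue_len < 1L) next
        cs <- cumsum(as.integer(d))
        runsum <- cs[seq(n, length.out = ue_len)] -
          c(0L, cs)[seq_len(ue_len)]
        unit_eq <- runsum == n
      } else next
      # walk each phase chain p, p+n, p+2n, ... and run-length encode
      for (phase in seq_len(n)) {
        chain <- seq(phase, ue_len, by = n)
        if (length(chain) == 0L) next
        r <- rle(unit_eq[chain])
        pos <- 1L
        for (k in seq_along(r$lengths)) {
          if (r$values[k]) {
            copies <- r$lengths[k] + 1L
            if (copies >= params$min_repeats) {
              start <- chain[pos] # 1-based position of first unit
              units <- seq(0L, copies - 1L)
              lmat[n, start + units * n] <- copies
              imat[n, start + units * n] <- units
            }
          }
          pos <- pos + r$lengths[k]
        }
      }
    }
  }
  structure(list(l = lmat, idx = imat, params = params, seq_len = L),
            class = "npoly_annotation")
}

#' @export
print.npoly_annotation <- function(x, ...) {
  npoly <- sum(x$l > 0 & x$idx == 0)
  cat("n-polymer annotation over", x$seq_len, "bp:",
      npoly, "polymers (n <=", x$params$n_max, ")\n")
  invisible(x)
}

#' Extract a window of an annotation
#'
#' Returns the `l`/`idx` columns for reference positions
#' `start .. start + width - 1` (1-based). Copy counts of polymers that
#' extend past the window keep their full-contig values; this is
#' intentional, as `l` means the expected copy number of the whole polymer.
#'
#' @param annotation an [annotate_reference()] result.
#' @param start 1-based first position of the window.
#' @param width window width.
#' @return An `npoly_annotation` restricted to the window.
#' @export
annotation_window <- function(annotation, start, width) {
  stopifnot(inherits(annotation, "npoly_annotation"),
            start >= 1L, start + width - 1L <= annotation$seq_len)
  cols <- seq(start, length.out = width)
  structure(list(l = annotation$l[, cols, drop = FALSE],
                 idx = annotation$idx[, cols, drop = FALSE],
                 params = annotation$params, seq_len = as.integer(width)),
            class = "npoly_annotation")
}

#' n-polymer intervals from an annotation
#'
#' @param annotation an [annotate_reference()] result.
#' @return A data.frame with columns `n`, `start` (1-based), `end`
#'   (inclusive), `l`: one row per polymer (per phase and per n).
#' @export
npoly_intervals <- function(annotation) {
  out <- list()
  for (n in seq_len(annotation$params$n_max)) {
    starts <- which(annotation$l[n, ] > 0 & annotation$idx[n, ] == 0)
    if (length(starts) == 0L) next
    l <- annotation$l[n, starts]
    out[[n]] <- data.frame(n = n, start = starts, end = starts + l * n - 1L,
                           l = l)
  }
  if (length(out) == 0L) {
    return(data.frame(n = integer(0), start = integer(0), end = integer(0),
                      l = integer(0)))
  }
  do.call(rbind, out)
}

#' Write n-polymer stratification BED files
#'
#' Emits one BED per repeat-unit length n with each polymer interval widened
#' by one base on each side (slop = 1), a merged BED covering all n, and a
#' complement BED of everything else. Coordinates are 0-based half-open as
#' BED requires.
#'
#' @param annotation an [annotate_reference()] result.
#' @param contig contig name used in the BED records.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_npoly_beds <- function(annotation, contig, dir, prefix = "npoly") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iv <- npoly_intervals(annotation)
  L <- annotation$seq_len
  slop <- function(df) {
    if (nrow(df) == 0L) return(df[, c("start", "end")])
    data.frame(start = pmax(df$start - 1L, 1L), end = pmin(df$end + 1L, L))
  }
  merge_iv <- function(df) {
    # merge overlapping/adjacent 1-based inclusive intervals
    if (nrow(df) == 0L) return(df)
    df <- df[order(df$start, df$end), , drop = FALSE]
    s <- df$start; e <- df$end
    keep_s <- s[1]; keep_e <- e[1]; out_s <- c(); out_e <- c()
    for (k in seq_along(s)[-1]) {
      if (s[k] <= keep_e + 1L) keep_e <- max(keep_e, e[k])
      else { out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
             keep_s <- s[k]; keep_e <- e[k] }
    }
    data.frame(start = c(out_s, keep_s), end = c(out_e, keep_e))
  }
  write_bed <- function(df, path) {
    if (nrow(df) == 0L) { writeLines(character(0), path); return(path) }
    writeLines(sprintf("%s\t%d\t%d", contig, df$start - 1L, df$end), path)
    path
  }
  paths <- c()
  all_iv <- list()
  for (n in seq_len(annotation$params$n_max)) {
    sub <- merge_iv(slop(iv[iv$n == n, , drop = FALSE]))
    all_iv[[n]] <- sub
    p <- file.path(dir, sprintf("%s_n%d.bed", prefix, n))
    paths <- c(paths, setNames(write_bed(sub, p), sprintf("n%d", n)))
  }
  merged <- merge_iv(do.call(rbind, all_iv))
  p_all <- file.path(dir, sprintf("%s_all.bed", prefix))
  paths <- c(paths, all = write_bed(merged, p_all))
  # complement over [1, L]
  comp <- data.frame(start = integer(0), end = integer(0))
  if (nrow(merged) == 0L) {
    if (L > 0) comp <- data.frame(start = 1L, end = L)
  } else {
    gaps_s <- c(1L, merged$end + 1L)
    gaps_e <- c(merged$start - 1L, L)
    keep <- gaps_s <= gaps_e
    comp <- data.frame(start = gaps_s[keep], end = gaps_e[keep])
  }
  p_comp <- file.path(dir, sprintf("%s_complement.bed", prefix))
  paths <- c(paths, complement = write_bed(comp, p_comp))
  invisible(paths)
}
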