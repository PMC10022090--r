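# Record-level SAM I/O. SAM records are kept as character vectors of their
# tab-separated fields so that every tag and field passes through
# realignment byte-identically except the ones deliberately rewritten
# (CIGAR, NM, MD). BAM paths are accepted and produced through
# Rsamtools/samtools conversion when available.

#' Read a SAM (or BAM) file into header lines and records
#'
#' @param path path to a `.sam` file, or a `.bam` file if Rsamtools is
#'   installed.
#' @return A list with `header` (character vector of `@` lines) and
#'   `records` (list of character vectors, one per alignment line, each
#'   holding the tab-separated fields).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package; supply SAM instead")
    }
    tmp <- tempfile(fileext = ".sam")
    Rsamtools::asSam(path, sub("\\.sam$", "", tmp), overwrite = TRUE)
    path <- tmp
    on.exit(unlink(tmp))
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  list(header = lines[is_hdr],
       records = strsplit(lines[!is_hdr], "\t", fixed = TRUE))
}

#' Write header lines and records to a SAM (or BAM) file
#'
#' @param sam a list as returned by [read_sam()].
#' @param path output path; `.bam` triggers conversion via Rsamtools.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  lines <- c(sam$header,
             vapply(sam$records, paste, character(1), collapse = "\t"))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("writing BAM requires the Rsamtools package; use a .sam path")
    }
    tmp <- tempfile(fileext = ".sam")
    writeLines(lines, tmp)
    on.exit(unlink(tmp))
    Rsamtools::asBam(tmp, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

sam_field <- function(rec, k) rec[[k]]

sam_flag <- function(rec) as.integer(rec[[2]])

sam_is_mapped <- function(rec) bitwAnd(sam_flag(rec), 4L) == 0L

sam_is_primary <- function(rec) {
  bitwAnd(sam_flag(rec), 256L) == 0L && bitwAnd(sam_flag(rec), 2048L) == 0L
}

# split a CIGAR into leading/trailing clip ops and the aligned core
split_clips <- function(cigar) {
  p <- parse_cigar(cigar)
  n <- length(p$ops)
  lead <- 0L
  while (lead < n && p$ops[lead + 1L] %in% c("H", "S")) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && p$ops[n - trail] %in% c("H", "S")) {
    trail <- trail + 1L
  }
  core_idx <- if (lead + trail >= n) integer(0) else (lead + 1L):(n - trail)
  list(
    lead = list(lengths = p$lengths[seq_len(lead)], ops = p$ops[seq_len(lead)]),
    core = list(lengths = p$lengths[core_idx], ops = p$ops[core_idx]),
    trail = list(lengths = p$lengths[seq(n - trail + 1L, length.out = trail)],
                 ops = p$ops[seq(n - trail + 1L, length.out = trail)])
  )
}

set_tag <- function(rec, tag, type, value) {
  if (length(rec) >= 12L) {
    hit <- grep(paste0("^", tag, ":"), rec[12:length(rec)])
    if (length(hit)) {
      rec[[11L + hit[1]]] <- paste0(tag, ":", type, ":", value)
      return(rec)
    }
  }
  c(rec, paste0(tag, ":", type, ":", value))
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  stopifnot(length(hdr) > 0)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    paste(lines[seq(hdr[k] + 1L, ends[k])], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>([^ \t]+).*", "\\1", lines[hdr])
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[k]), con)
    s <- seqs[[k]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
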