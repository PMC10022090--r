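# Read-concordance evaluation by Gini purity.
#
# For each reference position, reads spanning it are classified into
# A, C, G, T or deletion and the column is scored GP = sum_i P(i)^2: 1 when
# all reads agree, 1/N for an even split over N classes. Insertions are
# scored separately per inter-base gap, with one class per insertion string
# (including the empty insertion), because the variable class count shifts
# the GP distribution.

#' Gini purity of a column of class counts
#'
#' @param counts non-negative class counts (any labels; zeros allowed).
#' @return `sum((counts / sum(counts))^2)`, or `NA_real_` when the total is
#'   zero (such columns are skipped, not scored).
#' @examples
#' gini_purity(c(A = 10))            # 1
#' gini_purity(c(A = 5, C = 5))      # 0.5
#' gini_purity(rep(1, 5))            # 0.2
#' @export
gini_purity <- function(counts) {
  stopifnot(all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  sum((counts / tot)^2)
}

# per-read pileup events: returns list(bases = data.table(pos, class),
# ins = data.table(gap, seq), span = c(start, end)) for one record
pileup_events <- function(rec) {
  clips <- split_clips(rec[[6]])
  core <- build_cigar(clips$core$lengths, clips$core$ops)
  if (core == "") return(NULL)
  pos <- as.integer(rec[[4]])
  lead_soft <- sum(clips$lead$lengths[clips$lead$ops == "S"])
  p <- parse_cigar(core)
  read <- rec[[10]]
  i <- lead_soft; j <- pos - 1L
  base_pos <- integer(0); base_cls <- character(0)
  gap_pos <- integer(0); gap_seq <- character(0)
  for (k in seq_along(p$ops)) {
    op <- p$ops[k]; len <- p$lengths[k]
    if (op %in% c("M", "=", "X")) {
      base_pos <- c(base_pos, (j + 1L):(j + len))
      base_cls <- c(base_cls,
                    strsplit(toupper(substr(read, i + 1L, i + len)), "")[[1]])
      i <- i + len; j <- j + len
    } else if (op == "D") {
      base_pos <- c(base_pos, (j + 1L):(j + len))
      base_cls <- c(base_cls, rep("-", len))
      j <- j + len
    } else if (op == "I") {
      gap_pos <- c(gap_pos, j)
      gap_seq <- c(gap_seq, toupper(substr(read, i + 1L, i + len)))
      i <- i + len
    }
  }
  list(pos = base_pos, cls = base_cls, gap = gap_pos, ins = gap_seq,
       span = c(pos, j))
}

#' Gini purity histograms for a SAM/BAM pileup
#'
#' Builds the pileup column class counts (A/C/G/T/deletion) and the
#' insertion class counts (insertion strings, including the empty
#' insertion, between each pair of adjacent reference bases) for all mapped
#' primary reads, scores each sufficiently deep column with
#' [gini_purity()], and bins the scores. With `by_haplotype = TRUE`, reads
#' are grouped by their `HP` tag before scoring (untagged reads are grouped
#' as unphased, with a warning).
#'
#' @param in_path SAM/BAM path.
#' @param min_depth minimum reads spanning a column for it to be scored
#'   (default 5).
#' @param bin_width histogram bin width on `[0, 1]` (default 0.01).
#' @param by_haplotype score per haplotype group.
#' @return Object of class `gini_histogram`: a list with `breaks`, integer
#'   vectors `columns` and `insertions` (bin counts), and the raw
#'   per-column score tables `column_scores`, `insertion_scores`
#'   (data.tables with `contig`, `pos`, `gp`, and `hap` if grouped).
#' @export
gini_histograms <- function(in_path, min_depth = 5L, bin_width = 0.01,
                            by_haplotype = FALSE) {
  sam <- read_sam(in_path)
  recs <- Filter(function(r) sam_is_mapped(r) && sam_is_primary(r) &&
                   r[[6]] != "*", sam$records)
  hap_of <- function(rec) {
    if (!by_haplotype) return("all")
    hit <- grep("^HP:i:", rec)
    if (length(hit)) sub("^HP:i:", "", rec[[hit[1]]]) else "unphased"
  }
  haps <- vapply(recs, hap_of, character(1))
  if (by_haplotype && any(haps == "unphased")) {
    warning("reads without HP tags grouped as unphased")
  }
  col_tabs <- list(); ins_tabs <- list()
  for (h in unique(haps)) {
    hrecs <- recs[haps == h]
    evs <- lapply(hrecs, pileup_events)
    evs <- Filter(Negate(is.null), evs)
    if (!length(evs)) next
    contigs <- vapply(hrecs[seq_along(evs)], function(r) r[[3]], character(1))
    bases <- data.table::rbindlist(lapply(seq_along(evs), function(k) {
      data.table::data.table(contig = contigs[k], pos = evs[[k]]$pos,
                             cls = evs[[k]]$cls)
    }))
    cols <- bases[, .N, by = c("contig", "pos", "cls")]
    col_gp <- cols[, list(gp = sum((N / sum(N))^2), depth = sum(N)),
                   by = c("contig", "pos")]
    col_gp <- col_gp[col_gp$depth >= min_depth, ]
    col_gp$hap <- h
    col_tabs[[h]] <- col_gp
    # insertions: coverage of each inter-base gap = reads whose aligned span
    # strictly contains the gap (gap g sits between positions g and g+1)
    spans <- data.table::rbindlist(lapply(seq_along(evs), function(k) {
      data.table::data.table(contig = contigs[k],
                             start = evs[[k]]$span[1],
                             end = evs[[k]]$span[2])
    }))
    ins <- data.table::rbindlist(lapply(seq_along(evs), function(k) {
      if (!length(evs[[k]]$gap)) return(NULL)
      data.table::data.table(contig = contigs[k], gap = evs[[k]]$gap,
                             seq = evs[[k]]$ins)
    }))
    gap_cov <- data.table::rbindlist(lapply(seq_len(nrow(spans)), function(k) {
      s <- spans$start[k]; e <- spans$end[k]
      if (e - 1L < s) return(NULL)
      data.table::data.table(contig = spans$contig[k], gap = s:(e - 1L))
    }))
    cov <- gap_cov[, .N, by = c("contig", "gap")]
    data.table::setnames(cov, "N", "depth")
    ins_gp <- cov[cov$depth >= min_depth, ]
    if (nrow(ins_gp)) {
      ins_counts <- if (nrow(ins)) ins[, .N, by = c("contig", "gap", "seq")]
        else data.table::data.table(contig = character(0), gap = integer(0),
                                    seq = character(0), N = integer(0))
      ins_gp <- merge(ins_gp,
                      ins_counts[, list(sq = sum(N^2), n_ins = sum(N)),
                                 by = c("contig", "gap")],
                      by = c("contig", "gap"), all.x = TRUE)
      ins_gp$sq[is.na(ins_gp$sq)] <- 0
      ins_gp$n_ins[is.na(ins_gp$n_ins)] <- 0
      ins_gp$gp <- (ins_gp$sq + (ins_gp$depth - ins_gp$n_ins)^2) /
        ins_gp$depth^2
      ins_gp$hap <- h
      ins_tabs[[h]] <- ins_gp[, c("contig", "gap", "gp", "depth", "hap")]
    }
  }
  col_scores <- data.table::rbindlist(col_tabs)
  ins_scores <- data.table::rbindlist(ins_tabs)
  breaks <- seq(0, 1, by = bin_width)
  bin <- function(x) {
    if (!length(x)) return(integer(length(breaks) - 1L))
    tabulate(pmin(pmax(ceiling(x / bin_width), 1L), length(breaks) - 1L),
             nbins = length(breaks) - 1L)
  }
  structure(list(breaks = breaks,
                 columns = bin(col_scores$gp),
                 insertions = bin(ins_scores$gp),
                 column_scores = col_scores,
                 insertion_scores = ins_scores),
            class = "gini_histogram")
}

#' @export
print.gini_histogram <- function(x, ...) {
  cat("Gini purity:", nrow(x$column_scores), "scored columns (mean GP",
      sprintf("%.4f", mean(x$column_scores$gp)), "),",
      nrow(x$insertion_scores), "scored insertion gaps\n")
  invisible(x)
}

#' Write a Gini histogram as TSV
#'
#' Columns: `bin_low`, `bin_high`, `column_count`, `insertion_count`.
#'
#' @param hist a [gini_histograms()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gini_tsv <- function(hist, path) {
  df <- data.frame(bin_low = head(hist$breaks, -1),
                   bin_high = tail(hist$breaks, -1),
                   column_count = hist$columns,
                   insertion_count = hist$insertions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
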