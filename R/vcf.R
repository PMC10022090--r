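# Phased truth-VCF standardization.
#
# A phased VCF and a reference FASTA imply two haplotype sequences per
# contig. The realigner prefers to express differences inside n-polymers as
# whole-unit copy-number INDELs anchored at the polymer start, while truth
# sets often encode the same haplotypes with SNPs or differently-placed
# gaps. Standardization applies the phased variants to obtain the haplotype
# sequences, realigns each haplotype to the reference with the banded
# repeat-aware aligner (its construction CIGAR seeds the band), and parses
# the resulting alignments back into a VCF. The haplotype sequences implied
# by the output are byte-identical to the input's.

#' Read a phased VCF (light-weight)
#'
#' Parses CHROM, POS, REF, ALT and the first sample's GT from a plain-text
#' VCF. Multi-allelic records are supported; other INFO/FORMAT content is
#' ignored.
#'
#' @param path VCF file path (uncompressed text).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt` (comma
#'   separated alternates), `gt` (e.g. `"0|1"`).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  gt <- vapply(f, function(x) {
    if (length(x) < 10L) return(NA_character_)
    fmt <- strsplit(x[[9]], ":", fixed = TRUE)[[1]]
    val <- strsplit(x[[10]], ":", fixed = TRUE)[[1]]
    g <- val[match("GT", fmt)]
    if (is.na(g)) NA_character_ else g
  }, character(1))
  data.frame(chrom = vapply(f, `[[`, character(1), 1L),
             pos = as.integer(vapply(f, `[[`, character(1), 2L)),
             ref = toupper(vapply(f, `[[`, character(1), 4L)),
             alt = toupper(vapply(f, `[[`, character(1), 5L)),
             gt = gt)
}

#' Write a phased VCF (light-weight)
#'
#' @param vcf data.frame as from [read_vcf()].
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          contigs))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "SAMPLE", sep = "\t"))
  body <- if (nrow(vcf)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            vcf$chrom, vcf$pos, vcf$ref, vcf$alt, vcf$gt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

hap_allele <- function(gt, hap) {
  parts <- strsplit(gt, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    return(NA_integer_)
  }
  as.integer(parts[hap])
}

#' Apply a phased VCF to a reference
#'
#' Builds the two haplotype sequences per contig, plus the CIGAR of each
#' haplotype's construction relative to the reference (M runs interrupted by
#' I/D at each applied INDEL). Unphased or conflicting (overlapping applied)
#' records raise an error naming the coordinates, as do REF alleles that do
#' not match the FASTA.
#'
#' @param ref named character vector of reference sequences, or FASTA path.
#' @param vcf data.frame from [read_vcf()], or a VCF path.
#' @return Named list (per contig) of lists `hap1`, `hap2`, each with
#'   elements `seq` and `cigar`.
#' @export
apply_phased_vcf <- function(ref, vcf) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    ref <- read_fasta(ref)
  }
  if (is.character(vcf)) vcf <- read_vcf(vcf)
  out <- list()
  for (contig in names(ref)) {
    rseq <- toupper(ref[[contig]])
    sub <- vcf[vcf$chrom == contig, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    haps <- list()
    for (h in 1:2) {
      pieces <- character(0)
      lens <- integer(0); ops <- character(0)
      cur <- 1L # next unconsumed reference position
      last_end <- 0L
      for (k in seq_len(nrow(sub))) {
        gt <- sub$gt[k]
        a <- hap_allele(gt, h)
        if (is.na(a)) {
          stop("unphased or malformed genotype '", gt, "' at ", contig, ":",
               sub$pos[k])
        }
        if (a == 0L) next
        alts <- strsplit(sub$alt[k], ",", fixed = TRUE)[[1]]
        if (a > length(alts)) {
          stop("allele index ", a, " out of range at ", contig, ":",
               sub$pos[k])
        }
        alt <- alts[a]
        refa <- sub$ref[k]
        pos <- sub$pos[k]
        if (substr(rseq, pos, pos + nchar(refa) - 1L) != refa) {
          stop("REF allele mismatch at ", contig, ":", pos, " (VCF says ",
               refa, ", FASTA has ",
               substr(rseq, pos, pos + nchar(refa) - 1L), ")")
        }
        if (pos <= last_end) {
          stop("overlapping applied records on haplotype ", h, " at ",
               contig, ":", pos)
        }
        if (pos > cur) {
          pieces <- c(pieces, substr(rseq, cur, pos - 1L))
          lens <- c(lens, pos - cur); ops <- c(ops, "M")
        }
        # decompose ref/alt into leading shared M, then I or D or MNP
        nr <- nchar(refa); na <- nchar(alt)
        common <- min(nr, na)
        pieces <- c(pieces, alt)
        if (common > 0L) { lens <- c(lens, common); ops <- c(ops, "M") }
        if (na > nr) { lens <- c(lens, na - nr); ops <- c(ops, "I") }
        if (nr > na) { lens <- c(lens, nr - na); ops <- c(ops, "D") }
        cur <- pos + nr
        last_end <- pos + nr - 1L
      }
      if (cur <= nchar(rseq)) {
        pieces <- c(pieces, substr(rseq, cur, nchar(rseq)))
        lens <- c(lens, nchar(rseq) - cur + 1L); ops <- c(ops, "M")
      }
      haps[[paste0("hap", h)]] <- list(seq = paste(pieces, collapse = ""),
                                       cigar = build_cigar(lens, ops))
    }
    out[[contig]] <- haps
  }
  out
}

# parse one haplotype's realignment into atomic records:
# contiguous mismatch runs -> SNP/MNP; I/D runs -> anchored INDELs
hap_records <- function(hapseq, rseq, cigar, contig) {
  p <- parse_cigar(cigar)
  i <- 0L; j <- 0L
  rd <- strsplit(hapseq, "")[[1]]
  rf <- strsplit(rseq, "")[[1]]
  rec <- list()
  push <- function(pos, ref, alt) {
    rec[[length(rec) + 1L]] <<- list(pos = pos, ref = ref, alt = alt)
  }
  for (k in seq_along(p$ops)) {
    op <- p$ops[k]; len <- p$lengths[k]
    if (op %in% c("M", "=", "X")) {
      mism <- rd[(i + 1):(i + len)] != rf[(j + 1):(j + len)]
      if (any(mism)) {
        r <- rle(mism)
        at <- cumsum(c(0L, r$lengths))
        for (q in seq_along(r$lengths)) {
          if (r$values[q]) {
            s <- at[q] + 1L; e <- at[q + 1L]
            push(j + s,
                 paste(rf[(j + s):(j + e)], collapse = ""),
                 paste(rd[(i + s):(i + e)], collapse = ""))
          }
        }
      }
      i <- i + len; j <- j + len
    } else if (op == "I") {
      if (j == 0L) {
        # insertion before the first base: anchor on the following base
        push(1L, rf[1L],
             paste(c(rd[(i + 1):(i + len)], rf[1L]), collapse = ""))
      } else {
        push(j, rf[j],
             paste(c(rf[j], rd[(i + 1):(i + len)]), collapse = ""))
      }
      i <- i + len
    } else if (op == "D") {
      if (j == 0L) {
        push(1L, paste(rf[1:(len + 1L)], collapse = ""), rf[len + 1L])
      } else {
        push(j, paste(rf[j:(j + len)], collapse = ""), rf[j])
      }
      j <- j + len
    } else {
      stop("hap_records: unsupported op ", op)
    }
  }
  if (length(rec)) {
    data.frame(chrom = contig,
               pos = vapply(rec, `[[`, numeric(1), "pos"),
               ref = vapply(rec, `[[`, character(1), "ref"),
               alt = vapply(rec, `[[`, character(1), "alt"))
  } else {
    data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
               alt = character(0))
  }
}

# merge per-haplotype record tables into genotyped records
merge_hap_records <- function(r1, r2) {
  key1 <- paste(r1$pos, r1$ref, sep = ":")
  key2 <- paste(r2$pos, r2$ref, sep = ":")
  out <- list()
  used2 <- logical(nrow(r2))
  for (k in seq_len(nrow(r1))) {
    hit <- which(!used2 & key2 == key1[k])
    if (length(hit)) {
      hit <- hit[1]; used2[hit] <- TRUE
      if (r2$alt[hit] == r1$alt[k]) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = r1$chrom[k], pos = r1$pos[k], ref = r1$ref[k],
          alt = r1$alt[k], gt = "1|1")
      } else {
        out[[length(out) + 1L]] <- data.frame(
          chrom = r1$chrom[k], pos = r1$pos[k], ref = r1$ref[k],
          alt = paste(r1$alt[k], r2$alt[hit], sep = ","), gt = "1|2")
      }
    } else {
      out[[length(out) + 1L]] <- data.frame(
        chrom = r1$chrom[k], pos = r1$pos[k], ref = r1$ref[k],
        alt = r1$alt[k], gt = "1|0")
    }
  }
  for (k in which(!used2)) {
    out[[length(out) + 1L]] <- data.frame(
      chrom = r2$chrom[k], pos = r2$pos[k], ref = r2$ref[k],
      alt = r2$alt[k], gt = "0|1")
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
               alt = character(0), gt = character(0))
  res[order(res$pos), , drop = FALSE]
}

# split a construction CIGAR into independent chunks at the midpoints of
# long M runs, so whole-contig alignment is never needed
chunk_alignment <- function(cigar, anchor = 200L) {
  p <- parse_cigar(cigar)
  chunks <- list()
  cur_l <- integer(0); cur_o <- character(0)
  for (k in seq_along(p$ops)) {
    op <- p$ops[k]; len <- p$lengths[k]
    if (op == "M" && len >= 2L * anchor && k > 1L && k < length(p$ops)) {
      half <- len %/% 2L
      chunks[[length(chunks) + 1L]] <- list(lengths = c(cur_l, half),
                                            ops = c(cur_o, "M"))
      cur_l <- len - half; cur_o <- "M"
    } else {
      cur_l <- c(cur_l, len); cur_o <- c(cur_o, op)
    }
  }
  chunks[[length(chunks) + 1L]] <- list(lengths = cur_l, ops = cur_o)
  chunks
}

#' Standardize a phased truth VCF
#'
#' Applies the phased variants to build both haplotype sequences, realigns
#' each haplotype to the reference with [banded_align()] (seeded by its
#' construction CIGAR, processed in chunks split at long variant-free
#' anchors), parses every substitution/insertion/deletion run of the
#' realignment into records, and merges the two haplotypes' records into
#' genotyped phased records (a multi-allelic record when positions and REF
#' coincide exactly). Applying the returned VCF reproduces the input's
#' haplotype sequences exactly.
#'
#' @param ref named character vector of references, or FASTA path.
#' @param vcf data.frame from [read_vcf()], or VCF path.
#' @param model a [penalty_model()].
#' @param b band half-width for the realignment.
#' @param anchor minimum variant-free M-run length (bases) at which the
#'   haplotype alignment is split into independent chunks.
#' @param params annotation parameters.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gt`,
#'   sorted by position within contig.
#' @export
standardize_vcf <- function(ref, vcf, model, b = 30L, anchor = 200L,
                            params = annotation_params()) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    ref <- read_fasta(ref)
  }
  if (is.character(vcf)) vcf <- read_vcf(vcf)
  out <- list()
  for (contig in names(ref)) {
    rseq <- toupper(ref[[contig]])
    haps <- apply_phased_vcf(setNames(list(rseq), contig), vcf)[[contig]]
    ann <- annotate_reference(rseq, params)
    recs <- list()
    for (h in 1:2) {
      hap <- haps[[paste0("hap", h)]]
      chunks <- chunk_alignment(hap$cigar, anchor)
      i <- 0L; j <- 0L
      new_l <- integer(0); new_o <- character(0)
      for (ch in chunks) {
        ccig <- build_cigar(ch$lengths, ch$ops)
        cons <- cigar_consumed(ccig)
        hseq <- substr(hap$seq, i + 1L, i + cons[["read"]])
        wseq <- substr(rseq, j + 1L, j + cons[["ref"]])
        ann_w <- annotation_window(ann, j + 1L, cons[["ref"]])
        al <- tryCatch(
          banded_align(hseq, wseq, ccig, ann_w, model, b = b),
          error = function(e) align(hseq, wseq, ann_w, model))
        pa <- parse_cigar(al$cigar)
        new_l <- c(new_l, pa$lengths); new_o <- c(new_o, pa$ops)
        i <- i + cons[["read"]]; j <- j + cons[["ref"]]
      }
      new_cigar <- build_cigar(new_l, new_o)
      recs[[h]] <- hap_records(hap$seq, rseq, new_cigar, contig)
    }
    out[[contig]] <- merge_hap_records(recs[[1]], recs[[2]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
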