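# Synthetic references, reads, and phased truth VCFs with controlled
# n-polymer content and error processes. The generator emulates the error
# structure of nanopore reads at the level the realigner addresses:
# substitutions and short affine INDELs in unique sequence, and
# copy-number INDELs inside repeats whose rate grows with polymer length
# (the copy_error_profile shared with default_model). Signal-level
# artefacts are out of scope.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' @param seed RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @param polymers data.frame with columns `n`, `l`, `count`: how many
#'   polymers of each unit length / copy number to embed.
#' @param adjacent_pairs number of polymer pairs placed back-to-back with no
#'   spacer, which is where naive alignment tends to merge INDELs into
#'   substitutions.
#' @param ref_length minimum reference length; the tail is padded with
#'   repeat-free spacer.
#' @param spacer_range min/max spacer length between embedded polymers.
#' @param sub_rate per-base substitution rate outside polymers.
#' @param ins_rate,del_rate per-base rates of affine (non-copy-number)
#'   insertions/deletions outside polymers.
#' @param indel_decay geometric decay of affine INDEL lengths.
#' @param base_rate,decay,ins_frac copy-number error profile parameters,
#'   see [copy_error_profile()].
#' @param read_length,depth read length and mean coverage for
#'   [simulate_reads()].
#' @param het_cn_frac fraction of designed polymers that carry a true
#'   heterozygous one-unit copy-number variant in [simulate_reads()]; reads
#'   are assigned alternately to the two haplotypes (HP tags) and variant
#'   polymers shift their expected copy number on haplotype 2 before
#'   error sampling. This is what makes pileup columns genuinely mixed, as
#'   they are around real het INDELs.
#' @param n_variants number of variants drawn by [make_phased_truth()].
#' @param params annotation parameters (also fixes `l_max` for profiles).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       polymers = data.frame(n = c(1L, 1L, 2L, 3L),
                                             l = c(6L, 10L, 4L, 4L),
                                             count = c(4L, 4L, 4L, 4L)),
                       adjacent_pairs = 0L,
                       ref_length = 0L,
                       spacer_range = c(12L, 25L),
                       sub_rate = 0.005,
                       ins_rate = 0.001, del_rate = 0.001,
                       indel_decay = 0.3,
                       base_rate = 0.0045, decay = 0.25, ins_frac = 0.55,
                       read_length = 250L, depth = 20L,
                       het_cn_frac = 0,
                       n_variants = 6L,
                       params = annotation_params()) {
  stopifnot(all(polymers$n >= 1), all(polymers$n <= params$n_max),
            all(polymers$l >= params$min_repeats),
            sub_rate >= 0, sub_rate <= 1, ins_rate >= 0, del_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

random_spacer <- function(len, params) {
  # repeat-free spacer: rejection-sample until annotation is empty
  repeat {
    s <- paste(sample(BASES, len, replace = TRUE), collapse = "")
    if (sum(annotate_reference(s, params)$l) == 0) return(s)
  }
}

random_unit <- function(n) {
  # primitive unit: not a whole-number power of a shorter unit
  repeat {
    u <- paste(sample(BASES, n, replace = TRUE), collapse = "")
    if (n == 1L) return(u)
    prim <- TRUE
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          paste(rep(substr(u, 1, d), n %/% d), collapse = "") == u) {
        prim <- FALSE; break
      }
    }
    if (prim) return(u)
  }
}

#' Build a synthetic reference with embedded n-polymers
#'
#' Polymers from `config$polymers` (plus `adjacent_pairs` back-to-back
#' pairs) are embedded between repeat-free spacers; the assembled sequence
#' is re-annotated and rebuilt until every designed polymer is recovered at
#' exactly its designed copy number (junction effects can otherwise extend
#' or merge them).
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_reference`: list with `seq`, `polymers`
#'   (data.frame `n`, `l`, `unit`, `start`, 1-based), and `config`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    specs <- config$polymers[rep(seq_len(nrow(config$polymers)),
                                 config$polymers$count), c("n", "l")]
    for (attempt in seq_len(50L)) {
      order_ix <- if (nrow(specs) > 0L) sample.int(nrow(specs)) else
        integer(0)
      pieces <- character(0)
      tail_txt <- ""   # last few bases of the assembly so far
      tbl <- list()
      cur <- 1L
      add_spacer <- function(forbid_first) {
        # spacer must be repeat-free and must not start with the preceding
        # polymer unit's first base: any continuation of the period -- a
        # unit prefix -- would extend a phase-shifted copy of the polymer,
        # and every such prefix starts with that base
        repeat {
          len <- sample(seq(config$spacer_range[1], config$spacer_range[2]),
                        1)
          sp <- random_spacer(len, config$params)
          if (is.null(forbid_first) ||
              substr(sp, 1, 1) != substr(forbid_first, 1, 1)) {
            return(sp)
          }
        }
      }
      add_polymer <- function(row, tail_txt) {
        # the preceding context must not end with the unit's last base:
        # any unit suffix would add a backward phase-shifted copy, and
        # every suffix ends with that base
        last_ctx <- substr(tail_txt, nchar(tail_txt), nchar(tail_txt))
        for (tries in seq_len(100L)) {
          unit <- random_unit(row$n)
          if (substr(unit, row$n, row$n) != last_ctx) {
            return(list(unit = unit,
                        poly = paste(rep(unit, row$l), collapse = "")))
          }
        }
        stop("unit sampling failed")
      }
      sp <- add_spacer(NULL)
      pieces <- c(pieces, sp); cur <- cur + nchar(sp); tail_txt <- sp
      adj_remaining <- config$adjacent_pairs
      k <- 1L
      while (k <= length(order_ix)) {
        group <- if (adj_remaining > 0L && k < length(order_ix)) 2L else 1L
        if (group == 2L) adj_remaining <- adj_remaining - 1L
        last_unit <- NULL
        for (g in seq_len(group)) {
          row <- specs[order_ix[k], ]
          pl <- add_polymer(row, tail_txt)
          # adjacency: the new polymer must not continue the previous
          # polymer's period either
          if (!is.null(last_unit) &&
              substr(pl$poly, 1, 1) == substr(last_unit, 1, 1)) {
            for (tries in seq_len(100L)) {
              pl <- add_polymer(row, tail_txt)
              if (substr(pl$poly, 1, 1) != substr(last_unit, 1, 1)) break
            }
          }
          tbl[[length(tbl) + 1L]] <- data.frame(
            n = row$n, l = row$l, unit = pl$unit, start = cur)
          pieces <- c(pieces, pl$poly)
          cur <- cur + nchar(pl$poly)
          tail_txt <- substr(paste0(tail_txt, pl$poly),
                             max(1L, nchar(tail_txt) + nchar(pl$poly) - 12L),
                             nchar(tail_txt) + nchar(pl$poly))
          last_unit <- pl$unit
          k <- k + 1L
          if (k > length(order_ix)) break
        }
        sp <- add_spacer(last_unit)
        pieces <- c(pieces, sp); cur <- cur + nchar(sp)
        tail_txt <- sp
      }
      seq <- paste(pieces, collapse = "")
      while (nchar(seq) < config$ref_length) {
        # pad with repeat-free spacer; re-check the junction window so the
        # concatenation cannot create a polymer either
        repeat {
          sp <- random_spacer(
            min(25L, config$ref_length - nchar(seq) + 10L), config$params)
          junction <- paste0(substr(seq, max(1L, nchar(seq) - 11L),
                                    nchar(seq)), sp)
          if (sum(annotate_reference(junction, config$params)$l) == 0) break
        }
        seq <- paste0(seq, sp)
      }
      tbl <- if (length(tbl)) do.call(rbind, tbl) else
        data.frame(n = integer(0), l = integer(0), unit = character(0),
                   start = integer(0))
      ann <- annotate_reference(seq, config$params)
      ok <- all(vapply(seq_len(nrow(tbl)), function(q) {
        n <- tbl$n[q]; s <- tbl$start[q]
        ann$l[n, s] == tbl$l[q] && ann$idx[n, s] == 0L
      }, logical(1)))
      if (ok) {
        return(structure(list(seq = seq, polymers = tbl, config = config),
                         class = "sim_reference"))
      }
    }
    stop("could not assemble a reference with the designed polymers intact")
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("synthetic reference:", nchar(x$seq), "bp,", nrow(x$polymers),
      "designed polymers\n")
  invisible(x)
}

# sample events for one read window; returns read seq + truth cigar parts
mutate_window <- function(window, rel_polymers, config, l_max) {
  W <- nchar(window)
  # blocked positions: designed polymers plus 2 bp margin
  blocked <- rep(FALSE, W)
  for (q in seq_len(nrow(rel_polymers))) {
    s <- max(1L, rel_polymers$start[q] - 2L)
    e <- min(W, rel_polymers$end[q] + 2L)
    blocked[s:e] <- TRUE
  }
  w <- strsplit(window, "")[[1]]
  # substitutions outside polymers
  subs <- which(!blocked & stats::runif(W) < config$sub_rate)
  for (p in subs) w[p] <- sample(setdiff(BASES, w[p]), 1)
  # events that change length: copy-number INDELs at eligible polymers,
  # affine INDELs in unblocked spacer
  events <- list()
  for (q in seq_len(nrow(rel_polymers))) {
    n <- rel_polymers$n[q]; l <- rel_polymers$l[q]
    l_exp <- if (!is.null(rel_polymers$l_expected)) {
      rel_polymers$l_expected[q]
    } else l
    prof <- copy_error_profile(n, l_exp, l_max, config$base_rate,
                               config$decay, config$ins_frac)
    obs <- sample.int(l_max, 1, prob = prof) - 1L
    delta <- obs - l # net change relative to the reference
    if (delta == 0L) next
    events[[length(events) + 1L]] <- list(
      pos = rel_polymers$start[q], type = if (delta < 0) "del" else "ins",
      len = abs(delta) * n,
      seq = if (delta > 0) paste(rep(rel_polymers$unit[q], delta),
                                 collapse = "") else NULL,
      polymer = q, delta = delta)
  }
  free <- which(!blocked)
  free <- free[free > 2L & free < W - 2L]
  for (p in free) {
    u <- stats::runif(1)
    if (u < config$del_rate) {
      len <- min(1L + stats::rgeom(1, 1 - config$indel_decay), 3L)
      if (all(!blocked[p:min(W, p + len - 1L)]) && p + len - 1L <= W) {
        events[[length(events) + 1L]] <- list(pos = p, type = "del",
                                              len = len, seq = NULL,
                                              polymer = NA, delta = NA)
      }
    } else if (u < config$del_rate + config$ins_rate) {
      len <- min(1L + stats::rgeom(1, 1 - config$indel_decay), 3L)
      events[[length(events) + 1L]] <- list(
        pos = p, type = "ins", len = len,
        seq = paste(sample(BASES, len, replace = TRUE), collapse = ""),
        polymer = NA, delta = NA)
    }
  }
  if (length(events)) {
    ord <- order(vapply(events, `[[`, numeric(1), "pos"))
    events <- events[ord]
    # drop events whose deletion spans overlap a previous event
    keep <- list(); last_end <- 0L
    for (ev in events) {
      ev_end <- if (ev$type == "del") ev$pos + ev$len - 1L else ev$pos
      if (ev$pos > last_end) { keep[[length(keep) + 1L]] <- ev
                               last_end <- ev_end }
    }
    events <- keep
  }
  # walk the window building read + cigar
  read_parts <- character(0)
  lens <- integer(0); ops <- character(0)
  cur <- 1L
  for (ev in events) {
    if (ev$pos > cur) {
      read_parts <- c(read_parts, paste(w[cur:(ev$pos - 1L)], collapse = ""))
      lens <- c(lens, ev$pos - cur); ops <- c(ops, "M")
      cur <- ev$pos
    }
    if (ev$type == "del") {
      lens <- c(lens, ev$len); ops <- c(ops, "D")
      cur <- cur + ev$len
    } else {
      read_parts <- c(read_parts, ev$seq)
      lens <- c(lens, ev$len); ops <- c(ops, "I")
    }
  }
  if (cur <= W) {
    read_parts <- c(read_parts, paste(w[cur:W], collapse = ""))
    lens <- c(lens, W - cur + 1L); ops <- c(ops, "M")
  }
  list(read = paste(read_parts, collapse = ""),
       cigar = build_cigar(lens, ops),
       events = events, n_subs = length(subs))
}

#' Simulate reads over a synthetic reference
#'
#' Reads are windows of the reference carrying substitutions at the
#' configured rate, copy-number INDELs inside designed polymers drawn from
#' [copy_error_profile()], and affine INDELs elsewhere. With
#' `cigar_mode = "truth"` each SAM record carries the generating CIGAR
#' (INDELs unit-aligned at polymer starts); with `"naive"` the CIGAR is a
#' plain affine-gap global alignment with a mildly substitution-favouring
#' score scheme, which merges opposing INDELs of nearby polymers into
#' substitution runs the way minimizing aligners do, giving realignment
#' something measurable to fix.
#'
#' @param sim_ref a [make_reference()] result.
#' @param cigar_mode `"truth"` or `"naive"`.
#' @param contig contig name for the SAM.
#' @return List with `sam` (header + records, see [read_sam()]), and
#'   `truth` (data.frame of per-read events: read, type, pos, len, delta).
#' @export
simulate_reads <- function(sim_ref, cigar_mode = c("truth", "naive"),
                           contig = "ctg1") {
  stopifnot(inherits(sim_ref, "sim_reference"))
  cigar_mode <- match.arg(cigar_mode)
  config <- sim_ref$config
  L <- nchar(sim_ref$seq)
  rl <- min(config$read_length, L)
  n_reads <- ceiling(config$depth * L / rl)
  naive_model <- penalty_model(
    P = matrix(3.9, 4, 4) - diag(3.9, 4), G_open = 5, G_extend = 1)
  poly <- sim_ref$polymers
  poly$end <- poly$start + poly$l * poly$n - 1L
  with_seed(config$seed + 1L, {
    # phased one-unit copy-number variants on a subset of polymers
    poly$var_delta <- 0L
    if (config$het_cn_frac > 0 && nrow(poly) > 0L) {
      nv <- round(config$het_cn_frac * nrow(poly))
      if (nv > 0L) {
        vix <- sample.int(nrow(poly), nv)
        poly$var_delta[vix] <- ifelse(
          poly$l[vix] > config$params$min_repeats,
          sample(c(-1L, 1L), nv, replace = TRUE), 1L)
      }
    }
    records <- vector("list", n_reads)
    truth <- list()
    starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
    haps <- rep_len(1:2, n_reads)
    for (r in seq_len(n_reads)) {
      wstart <- starts[r]
      window <- substr(sim_ref$seq, wstart, wstart + rl - 1L)
      inside <- poly$start - 1L >= wstart & poly$end + 1L <= wstart + rl - 1L
      rel <- poly[inside, , drop = FALSE]
      rel$start <- rel$start - wstart + 1L
      rel$end <- rel$end - wstart + 1L
      # haplotype 2 carries the variant copy numbers
      rel$l_expected <- rel$l + if (haps[r] == 2L) rel$var_delta else 0L
      mut <- mutate_window(window, rel, config, config$params$l_max)
      cigar <- mut$cigar
      if (cigar_mode == "naive") {
        al <- align(mut$read, window, annotation = NULL, model = naive_model,
                    use_npoly = FALSE)
        cigar <- al$cigar
      }
      name <- sprintf("r%05d", r)
      nmmd <- cigar_nm_md(mut$read, window, cigar)
      records[[r]] <- c(name, "0", contig, as.character(wstart), "60",
                        cigar, "*", "0", "0", mut$read,
                        strrep("I", nchar(mut$read)),
                        paste0("NM:i:", nmmd$nm), paste0("MD:Z:", nmmd$md),
                        paste0("HP:i:", haps[r]))
      for (ev in mut$events) {
        truth[[length(truth) + 1L]] <- data.frame(
          read = name, type = ev$type, pos = wstart + ev$pos - 1L,
          len = ev$len, delta = if (is.na(ev$delta)) NA_integer_ else
            as.integer(ev$delta))
      }
    }
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", contig, L))
    list(sam = list(header = header, records = records),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(read = character(0), type = character(0),
                      pos = integer(0), len = integer(0),
                      delta = integer(0)))
  })
}

#' Draw a phased truth VCF over a synthetic reference
#'
#' Samples `config$n_variants` phased germline variants: SNPs in unique
#' sequence, SNPs inside polymers, and one-unit copy-number INDELs at
#' designed polymers, with genotypes drawn from 1|0, 0|1, 1|1. Records
#' never overlap.
#'
#' @param sim_ref a [make_reference()] result.
#' @param contig contig name.
#' @return data.frame in [read_vcf()] layout.
#' @export
make_phased_truth <- function(sim_ref, contig = "ctg1") {
  stopifnot(inherits(sim_ref, "sim_reference"))
  config <- sim_ref$config
  s <- strsplit(sim_ref$seq, "")[[1]]
  L <- length(s)
  poly <- sim_ref$polymers
  poly$end <- poly$start + poly$l * poly$n - 1L
  with_seed(config$seed + 2L, {
    recs <- list()
    occupied <- rep(FALSE, L)
    gts <- c("1|0", "0|1", "1|1")
    n_target <- config$n_variants
    tries <- 0L
    while (length(recs) < n_target && tries < n_target * 50L) {
      tries <- tries + 1L
      kind <- sample(c("snp", "polysnp", "cnv"), 1,
                     prob = c(0.4, 0.2, 0.4))
      if (kind == "cnv" && nrow(poly) > 0L) {
        q <- sample.int(nrow(poly), 1)
        anchor <- poly$start[q] - 1L
        if (anchor < 1L) next
        n <- poly$n[q]
        span <- anchor:min(L, poly$end[q])
        if (any(occupied[span])) next
        unit <- poly$unit[q]
        if (stats::runif(1) < 0.5) { # delete one unit
          ref <- paste(s[anchor:(anchor + n)], collapse = "")
          alt <- s[anchor]
        } else {                     # insert one unit
          ref <- s[anchor]
          alt <- paste0(s[anchor], unit)
        }
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = contig, pos = anchor, ref = ref, alt = alt,
          gt = sample(gts, 1))
        occupied[span] <- TRUE
      } else {
        pos <- sample.int(L - 2L, 1) + 1L
        inside_poly <- any(pos >= poly$start & pos <= poly$end)
        if (kind == "snp" && inside_poly) next
        if (kind == "polysnp" && !inside_poly) next
        if (occupied[pos]) next
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = contig, pos = pos, ref = s[pos],
          alt = sample(setdiff(BASES, s[pos]), 1), gt = sample(gts, 1))
        occupied[pos] <- TRUE
      }
    }
    out <- if (length(recs)) do.call(rbind, recs) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), gt = character(0))
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a full synthetic dataset to a directory
#'
#' Emits `ref.fa`, `reads.sam` (coordinate sorted), `truth.vcf`, and
#' `truth_edits.tsv`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param cigar_mode CIGAR mode for [simulate_reads()].
#' @return Invisibly, the paths written.
#' @export
simulate_dataset <- function(config, out_dir, cigar_mode = "naive") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_ref <- make_reference(config)
  reads <- simulate_reads(sim_ref, cigar_mode = cigar_mode)
  vcf <- make_phased_truth(sim_ref)
  paths <- c(
    ref = write_fasta(c(ctg1 = sim_ref$seq), file.path(out_dir, "ref.fa")),
    sam = write_sam(reads$sam, file.path(out_dir, "reads.sam")),
    vcf = write_vcf(vcf, file.path(out_dir, "truth.vcf"),
                    contigs = c(ctg1 = nchar(sim_ref$seq))))
  utils::write.table(reads$truth, file.path(out_dir, "truth_edits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, truth = file.path(out_dir, "truth_edits.tsv"))
  invisible(paths)
}
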