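# Shared fixture builders for the test suite.

# small model with a reduced tensor extent: faster to build than the full
# 6x100x100 default and sufficient for toy polymers
small_model <- function(l_max = 30L) {
  default_model(l_max = l_max)
}

small_params <- function(l_max = 30L) {
  annotation_params(l_max = l_max)
}

# a zero-substitution-cost affine-only model
affine_model <- function(g_open = 5, g_extend = 1) {
  penalty_model(P = matrix(0, 4, 4), G_open = g_open, G_extend = g_extend)
}

# build a SAM object in memory from (name, pos, cigar, seq) rows
toy_sam <- function(rows, contig = "ctg1", contig_len = 1000L) {
  records <- lapply(seq_len(nrow(rows)), function(k) {
    c(rows$name[k], "0", contig, as.character(rows$pos[k]), "60",
      rows$cigar[k], "*", "0", "0", rows$seq[k],
      strrep("I", nchar(rows$seq[k])))
  })
  list(header = c("@HD\tVN:1.6\tSO:coordinate",
                  sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len)),
       records = records)
}

# the copy-number-error study fixture: long adjacent homopolymers with a
# Fig-2-like wide error spread plus phased het copy-number variants
e2e_config <- function(seed = 42L) {
  sim_config(
    seed = seed,
    polymers = data.frame(n = c(1, 1, 1, 2, 3), l = c(10, 12, 14, 5, 4),
                          count = c(10, 10, 8, 4, 4)),
    adjacent_pairs = 14L, read_length = 350L, depth = 40L,
    decay = 0.35, het_cn_frac = 0.5,
    sub_rate = 0.002, ins_rate = 0.0005, del_rate = 0.0005)
}

# the penalty-recovery fixture: pure copy-number errors (no substitutions,
# no affine INDELs), one-unit shifts only, rows sized so the assessed cells
# are well populated. Homopolymer lengths 7 and 11 are chosen because
# their dinucleotide/trinucleotide phase shadows fall into copy-number
# rows (2,3), (2,5) and (3,3), none of which is a designed row: shadow
# intervals otherwise inflate a designed row's span count and bias the
# measured frequencies.
recovery_config <- function(seed = 7L, depth = 520L) {
  sim_config(
    seed = seed,
    polymers = data.frame(n = c(1, 1, 2, 3), l = c(7, 11, 4, 4),
                          count = c(20, 20, 30, 40)),
    read_length = 400L, depth = depth,
    base_rate = 0.03, decay = 0, ins_frac = 0.55,
    sub_rate = 0, ins_rate = 0, del_rate = 0)
}

sam_to_alignments <- function(sam) {
  lapply(sam$records, function(r) {
    list(name = r[[1]], read = r[[10]], cigar = r[[6]],
         ref_start = as.integer(r[[4]]))
  })
}
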