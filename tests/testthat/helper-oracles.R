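# Independent oracles used by the test suite.  These re-derive expected
# values from first principles (exhaustive enumeration, direct counting)
# and must stay independent of the implementation paths they check.

# --- brute-force spliced alignment ------------------------------------------
# Enumerates every alignment the state grammar admits:
#   ALIGN  := CODON (LINK CODON)*
#   CODON  := consume one residue and k nt (k in 1,2,3,4,5; k != 3 pays the
#             frameshift penalty), scored residue vs the 3-mer ending at the
#             chunk's last nt (needs >= 3 nt of context)
#   LINK   := nothing | a run of protein gaps (3 nt each, affine)
#           | a run of dna gaps (1 residue each, affine)
#           | one intron (>= min_intron nt, flat penalty)
# and returns the maximum local score (0 if nothing scores positive).
bf_spliced_score <- function(protein, dna, params) {
  pv <- strsplit(protein, "")[[1]]
  n <- nchar(dna)
  m <- length(pv)
  mat <- params$matrix
  aa_of <- function(j) {            # 3-mer ending at offset j (1-based count)
    if (j < 3L) return(NULL)
    vestigr::translate_cds(substring(dna, j - 2L, j))
  }
  sc <- function(a, b) {
    if (!a %in% rownames(mat)) a <- "X"
    if (!b %in% colnames(mat)) b <- "X"
    mat[a, b]
  }
  best <- 0
  # after(i, j, acc): residue i..m still to consume, j nt consumed, acc score
  # so far ending in a codon op; try every continuation.
  consume_codon <- function(i, j, acc) {
    for (k in c(1L, 2L, 3L, 4L, 5L)) {
      j2 <- j + k
      if (j2 > n || j2 < 3L) next
      aa <- aa_of(j2)
      if (is.null(aa)) next
      acc2 <- acc + sc(pv[i], aa) + if (k == 3L) 0 else params$frameshift
      best <<- max(best, acc2)
      if (i < m) links(i, j2, acc2)
    }
  }
  links <- function(i, j2, acc2) {
    consume_codon(i + 1L, j2, acc2)                  # adjacent codon
    t <- 1L                                          # protein-gap run
    repeat {
      jg <- j2 + 3L * t
      if (jg + 1L > n) break
      accg <- acc2 + params$gap_open + (t - 1L) * params$gap_extend
      consume_codon(i + 1L, jg, accg)
      t <- t + 1L
    }
    t <- 1L                                          # dna-gap run
    repeat {
      ig <- i + t
      if (ig + 1L > m) break
      accg <- acc2 + params$gap_open + (t - 1L) * params$gap_extend
      consume_codon(ig + 1L, j2, accg)
      t <- t + 1L
    }
    for (L in seq(params$min_intron, n - j2)) {      # intron
      if (j2 + L >= n) break
      consume_codon(i + 1L, j2 + L, acc2 + params$intron_open)
    }
  }
  for (i0 in seq_len(m)) for (j0 in 0:(n - 1L))
    consume_codon(i0, j0, 0)
  best
}

# --- brute-force longest common (order-preserving) marker chain -------------
# Maximum-length subset of shared markers appearing in the same order in
# both genomes, by enumeration over all subsets of the shared set.
bf_max_chain <- function(ref_ids, qry_ids) {
  shared <- intersect(ref_ids, qry_ids)
  k <- length(shared)
  if (k == 0L) return(0L)
  best <- 0L
  for (mask in 0:(2^k - 1L)) {
    sel <- shared[bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) == 1L]
    if (length(sel) <= best) next
    ro <- order(match(sel, ref_ids))
    qo <- order(match(sel, qry_ids))
    if (identical(ro, qo)) best <- length(sel)
  }
  best
}

# --- direct per-read overlap count ------------------------------------------
bf_count_reads <- function(rs, exons) {
  if (nrow(rs$reads) == 0L) return(0L)
  hit <- logical(nrow(rs$reads))
  for (e in seq_len(nrow(exons))) {
    hit <- hit | (rs$reads$chrom == exons$chrom[e] &
                    rs$reads$start < exons$end[e] &
                    rs$reads$end > exons$start[e])
  }
  sum(hit)
}

# --- random sequences --------------------------------------------------------
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
rand_protein <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                         n, replace = TRUE), collapse = "")
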