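# Six-frame translation, motif scanning, the frameshift-aware spliced
# aligner, and exon-model inference.

# one fixed codon per residue, for exact back-translation fixtures
backtranslate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  pick <- vapply(strsplit(protein, "")[[1]], function(a)
    names(code)[code == a][1], character(1))
  paste(pick, collapse = "")
}

test_that("six-frame translation and its coordinate map", {
  sf <- six_frame_translate("ATGAAATAA")
  expect_equal(sf$tracks[[1]]$peptide, "MK*")
  # reverse frames equal forward frames of the reverse complement
  d <- "ATGCCGTTAGGAC"
  sf2 <- six_frame_translate(d)
  rc <- revcomp(d)
  for (f in 3:5)
    expect_equal(sf2$tracks[[f + 1]]$peptide,
                 six_frame_translate(rc)$tracks[[f - 2]]$peptide)
  # coordinate map round trip: peptide pos -> codon interval -> source codon
  set.seed(7)
  d <- rand_dna(200)
  sf3 <- six_frame_translate(d)
  for (f in 0:5) {
    pep <- sf3$tracks[[f + 1]]$peptide
    for (pos in sample(nchar(pep), min(10L, nchar(pep)))) {
      iv <- frame_codon_interval(sf3, f, pos)
      codon <- substring(d, iv$start + 1L, iv$end)
      if (iv$strand == "-") codon <- revcomp(codon)
      expect_equal(translate_cds(codon), substring(pep, pos, pos))
    }
  }
})

test_that("motif_scan finds verbatim motifs at the right place and frame", {
  set.seed(11)
  motif <- rand_protein(12)
  self <- sum(diag(scoring_params()$matrix[strsplit(motif, "")[[1]],
                                           strsplit(motif, "")[[1]]]))
  left <- rand_dna(90); right <- rand_dna(60)
  dna <- paste0(left, backtranslate(motif), right)
  hits <- motif_scan(dna, c(m = motif), min_score = self)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$start[1], 90L)
  expect_equal(hits$end[1], 90L + 36L)
  expect_equal(hits$frame[1], 0L)
  expect_equal(hits$score[1], self)

  # and on the reverse strand
  hits_rc <- motif_scan(revcomp(dna), c(m = motif), min_score = self)
  expect_equal(hits_rc$strand[1], "-")
  expect_equal(nchar(dna) - hits_rc$end[1], 90L)

  # scrambled genome at the self-score threshold: nothing
  expect_equal(nrow(motif_scan(rand_dna(500), c(m = motif),
                               min_score = self)), 0L)
})

test_that("motif_scan equals a brute-force sliding-window scorer", {
  set.seed(12)
  dna <- rand_dna(999)
  motifs <- c(a = rand_protein(6), b = rand_protein(9))
  hits <- motif_scan(dna, motifs, min_score = -1e9)
  mat <- scoring_params()$matrix
  sf <- six_frame_translate(dna)
  for (mi in names(motifs)) {
    mv <- strsplit(motifs[[mi]], "")[[1]]
    for (f in 0:5) {
      pep <- strsplit(sf$tracks[[f + 1]]$peptide, "")[[1]]
      W <- length(pep) - length(mv) + 1L
      for (w in seq_len(W)) {
        sc <- sum(mat[cbind(mv, pep[w:(w + length(mv) - 1L)])])
        iv <- frame_codon_interval(sf, f, w, length(mv))
        row <- hits[hits$motif_id == mi & hits$frame == f &
                      hits$start == iv$start, ]
        expect_equal(nrow(row), 1L)
        expect_equal(row$score, sc)
      }
    }
  }
})

test_that("spliced_align on an exact back-translation is a perfect block", {
  set.seed(13)
  prot <- rand_protein(40)
  dna <- backtranslate(prot)
  aln <- spliced_align(prot, dna)
  mat <- scoring_params()$matrix
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(aln$blocks$dna_start, 0L)
  expect_equal(aln$blocks$dna_end, 120L)
  expect_equal(nrow(aln$frameshifts), 0L)
  expect_equal(aln$identity_pct, 100)
  pv <- strsplit(prot, "")[[1]]
  expect_equal(aln$score, sum(mat[cbind(pv, pv)]))
})

test_that("a single deleted base is reported as one -1 frameshift", {
  set.seed(14)
  prot <- rand_protein(40)
  dna <- backtranslate(prot)
  del_at <- 60L   # delete base 61 (codon 21)
  dna2 <- paste0(substring(dna, 1, del_at), substring(dna, del_at + 2L, 120L))
  aln <- spliced_align(prot, dna2)
  expect_equal(nrow(aln$frameshifts), 1L)
  expect_equal(aln$frameshifts$shift, -1L)
  expect_lte(abs(aln$frameshifts$pos - del_at), 3L)
})

test_that("local alignment score is invariant to unrelated flanks", {
  set.seed(15)
  prot <- rand_protein(30)
  core <- backtranslate(prot)
  s0 <- spliced_align(prot, core)$score
  for (r in 1:5) {
    flanked <- paste0(rand_dna(150), core, rand_dna(150))
    expect_equal(spliced_align(prot, flanked)$score, s0)
  }
})

test_that("alignment score is self-consistent with its operations", {
  set.seed(16)
  for (r in 1:10) {
    g <- make_gene(random_gene_blueprint(r + 300L), gene_id = "g")
    ev <- evolve(g$seq, g$model,
                 evolution_params(sub_rate = 0.05, indel_rate = 0.002,
                                  seed = r))
    aln <- spliced_align(g$protein, ev$seq)
    if (aln$score == 0) next
    expect_equal(alignment_score_from_ops(aln, g$protein, ev$seq), aln$score)
  }
})

test_that("infer_exon_model recovers an intact gene exactly", {
  g <- make_gene(gene_blueprint(2L, c(222L, 141L), 300L, seed = 21L),
                 gene_id = "t")
  flank <- 500L
  withr::with_seed(3, {
    chrom <- paste0(rand_dna(flank), g$seq, rand_dna(flank))
  })
  cand <- genome_interval("c", 0L, nchar(chrom))
  aln <- spliced_align(g$protein, chrom)
  model <- infer_exon_model(aln, chrom, cand,
                            ref_protein_length = nchar(g$protein),
                            expected_exons = 2L)
  expect_equal(model$exons$start, g$model$exons$start + flank)
  expect_equal(model$exons$end, g$model$exons$end + flank)
  orf <- reconstruct_orf(stats::setNames(chrom, "c"), model)
  expect_true(orf$intact)
  expect_equal(orf$protein, g$protein)
})

test_that("snap window 0 keeps raw block boundaries", {
  g <- make_gene(gene_blueprint(2L, c(120L, 60L), 100L, seed = 22L))
  cand <- genome_interval("locus", 0L, nchar(g$seq))
  aln <- spliced_align(g$protein, g$seq)
  m0 <- infer_exon_model(aln, g$seq, cand, expected_exons = 2L,
                         snap_window = 0L)
  expect_equal(m0$exons$start[2], aln$blocks$dna_start[2])
  expect_equal(m0$exons$end[1], aln$blocks$dna_end[1])
})

test_that("a degraded terminal exon is recovered partially and flagged", {
  g <- make_gene(gene_blueprint(3L, c(120L, 90L, 90L), c(80L, 80L),
                                seed = 23L), gene_id = "t")
  # scramble exon 3 beyond recognition
  ex3 <- g$model$exons[3, ]
  withr::with_seed(9, {
    scrambled <- paste0(substring(g$seq, 1, ex3$start),
                        rand_dna(ex3$end - ex3$start),
                        substring(g$seq, ex3$end + 1L, nchar(g$seq)))
  })
  cand <- genome_interval("locus", 0L, nchar(scrambled))
  aln <- spliced_align(g$protein, scrambled)
  model <- infer_exon_model(aln, scrambled, cand,
                            ref_protein_length = nchar(g$protein),
                            expected_exons = 3L)
  expect_equal(model$exons$start[1], g$model$exons$start[1])
  expect_equal(model$exons$start[2], g$model$exons$start[2])
  expect_equal(model$exons$end[1], g$model$exons$end[1])
  support <- attr(model, "support")
  # exon 3 either was not seeded at all or carries weak alignment support
  expect_true(nrow(model$exons) < 3L || support[3] < 0.5)
})

test_that("reconstruction failure on an empty alignment is an error", {
  aln <- spliced_align("MW", "AAAAAAAAAAAA")   # nothing scores positive
  expect_equal(aln$score, 0)
  expect_error(infer_exon_model(aln, "AAAAAAAAAAAA",
                                genome_interval("c", 0L, 12L)),
               "reconstruction failure")
})
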