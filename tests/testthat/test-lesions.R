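# ORF reconstruction, lesion classification, percent identity.

test_that("reconstruct_orf on an intact gene reproduces the design", {
  g <- make_gene(gene_blueprint(2L, c(120L, 90L), 70L, seed = 31L))
  orf <- reconstruct_orf(g$seq, g$model)
  expect_true(orf$intact)
  expect_equal(orf$protein, g$protein)
  expect_null(orf$premature_stop)
  expect_equal(orf$internal_stops, integer())
})

test_that("reconstruct_orf works strand-aware on the minus strand", {
  g <- make_gene(gene_blueprint(2L, c(120L, 90L), 70L, seed = 32L))
  n <- nchar(g$seq)
  flipped <- revcomp(g$seq)
  ex <- g$model$exons
  ex_flip <- genome_interval("locus", n - ex$end, n - ex$start, "-")
  m_flip <- gene_model("g", exons = ex_flip)
  orf <- reconstruct_orf(flipped, m_flip)
  expect_true(orf$intact)
  expect_equal(orf$protein, g$protein)
})

test_that("an implanted mid-CDS TGA is a premature stop at that codon", {
  g <- make_gene(gene_blueprint(1L, 300L, seed = 33L))
  imp <- implant_lesions(g$seq, g$model,
                         list(list(kind = "nonsense", codon = 40L,
                                   stop_codon = "TGA")), seed = 1L)
  orf <- reconstruct_orf(imp$seq, imp$model,
                         ref_protein_length = nchar(g$protein))
  expect_false(orf$intact)
  expect_equal(orf$premature_stop$codon_index, 40L)
  expect_lt(orf$premature_stop$fraction, 0.95)
})

test_that("a late stop (past 95% of reference) is not premature", {
  g <- make_gene(gene_blueprint(1L, 300L, seed = 34L))   # 99-aa protein
  imp <- implant_lesions(g$seq, g$model,
                         list(list(kind = "nonsense", codon = 97L,
                                   stop_codon = "TAA")), seed = 1L)
  orf <- reconstruct_orf(imp$seq, imp$model,
                         ref_protein_length = nchar(g$protein))
  expect_null(orf$premature_stop)
})

test_that("degenerate exon models are rejected", {
  m <- gene_model("g", exons = genome_interval("c", 0L, 4L))
  expect_error(reconstruct_orf(stats::setNames("ACGTA", "c"), m),
               "degenerate")
})

test_that("classify_lesions is empty on noise-free intact orthologs", {
  for (r in 1:10) {
    g <- make_gene(random_gene_blueprint(r + 600L), gene_id = "g")
    aln <- spliced_align(g$protein, g$seq)
    les <- classify_lesions(g$seq, g$model, alignment = aln,
                            alignment_offset = 0L, ref_protein = g$protein,
                            ref_protein_length = nchar(g$protein))
    expect_equal(nrow(les), 0L, info = paste("rep", r))
  }
})

test_that("intact=true is equivalent to an empty lesion table", {
  kinds <- c("frameshift", "nonsense", "splice_donor", "splice_acceptor",
             "start_loss")
  for (r in 1:60) {
    g <- make_gene(random_gene_blueprint(r + 700L), gene_id = "g")
    lesioned <- r %% 2L == 0L
    if (lesioned) {
      imp <- implant_random_lesions(g, sample(kinds, 1L), seed = r)
      seqq <- imp$seq; mod <- imp$model
    } else {
      seqq <- g$seq; mod <- g$model
    }
    aln <- spliced_align(g$protein, seqq)
    orf <- reconstruct_orf(seqq, mod, ref_protein_length = nchar(g$protein))
    les <- classify_lesions(seqq, mod, orf, aln, alignment_offset = 0L,
                            ref_protein = g$protein,
                            ref_protein_length = nchar(g$protein))
    expect_equal(orf$intact, nrow(les) == 0L, info = paste("rep", r))
  }
})

test_that("percent identity: hand-countable cases and the recount oracle", {
  expect_equal(percent_identity("MKVLW", "MKVLW"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_true(is.na(percent_identity("", "", alignment = list(a = "", b = ""))))
  # X and U match only themselves
  expect_equal(percent_identity("AXA", "AXA"), 100)

  set.seed(41)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (r in 1:100) {
    n <- sample(10:40, 1)
    a <- sample(c(alpha, "-"), n, replace = TRUE, prob = c(rep(1, 20), 3))
    b <- sample(c(alpha, "-"), n, replace = TRUE, prob = c(rep(1, 20), 3))
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    got <- percent_identity(NA, NA, alignment = list(
      a = paste(a, collapse = ""), b = paste(b, collapse = "")))
    want <- 100 * sum(a == b & a != "-") / length(a)   # independent recount
    expect_equal(got, want)
  }
})

test_that("percent identity is symmetric and bounded", {
  set.seed(42)
  for (r in 1:10) {
    a <- rand_protein(sample(30:80, 1))
    b <- rand_protein(sample(30:80, 1))
    ab <- percent_identity(a, b)
    expect_equal(ab, percent_identity(b, a))
    expect_gte(ab, 0); expect_lte(ab, 100)
  }
  expect_lt(percent_identity(rand_protein(50), rand_protein(50)), 100)
})

test_that("identity_matrix is symmetric with a 100 diagonal", {
  set.seed(43)
  seqs <- stats::setNames(vapply(1:6, function(i) rand_protein(60),
                                 character(1)), paste0("s", 1:6))
  m <- identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 6))
  m2 <- identity_matrix(c(a = "MKVLW", b = "MKVLW"))
  expect_equal(unname(m2), matrix(100, 2, 2))
})

test_that("neutral clades lose more identity than purifying clades", {
  # paired simulation at equal divergence rates; the neutral replicate is
  # conditioned on carrying at least one exonic frameshift (the
  # lesion-accumulating regime by definition)
  has_exonic_fs <- function(ev, model0) {
    lg <- ev$log
    ind <- lg[lg$type %in% c("ins", "del") & lg$len %% 3L != 0L, ,
              drop = FALSE]
    if (!nrow(ind)) return(FALSE)
    any(vapply(ind$pos, function(p)
      any(p >= model0$exons$start & p < model0$exons$end), logical(1)))
  }
  wins <- 0L; n <- 100L
  for (r in seq_len(n)) {
    g <- make_gene(gene_blueprint(1L, 600L, seed = r + 400L), gene_id = "g")
    pur <- evolve(g$seq, g$model,
                  evolution_params(sub_rate = 0.05, indel_rate = 0.003,
                                   constrained = TRUE, seed = r))
    neu <- NULL
    for (try in 0:50) {
      cand <- evolve(g$seq, g$model,
                     evolution_params(sub_rate = 0.05, indel_rate = 0.003,
                                      seed = r + 1000L + try * 7919L))
      if (has_exonic_fs(cand, g$model) &&
          !is_gene_intact(cand$seq, cand$model)) { neu <- cand; break }
    }
    expect_false(is.null(neu))
    pp <- translate_cds(spliced_cds(stats::setNames(pur$seq, "locus"),
                                    pur$model))
    pn <- translate_cds(spliced_cds(stats::setNames(neu$seq, "locus"),
                                    neu$model))
    if (percent_identity(g$protein, pp) > percent_identity(g$protein, pn))
      wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
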