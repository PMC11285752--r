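# Simulator: gene construction, divergence regimes, lesion implantation,
# genome assembly, read simulation.

test_that("make_gene satisfies the gene-architecture invariants", {
  # smallest gene: ATG + one sense codon + stop
  g <- make_gene(gene_blueprint(1L, 9L, seed = 3L))
  expect_equal(nchar(g$cds), 9L)
  expect_match(g$cds, "^ATG")
  expect_true(substring(g$cds, 7, 9) %in% c("TAA", "TAG", "TGA"))
  expect_equal(nchar(g$protein), 2L)

  g2 <- make_gene(gene_blueprint(2L, c(30L, 30L), 40L, seed = 4L))
  intron <- substring(g2$seq, 31, 70)
  expect_equal(substring(intron, 1, 2), "GT")
  expect_equal(substring(intron, 39, 40), "AG")

  expect_error(gene_blueprint(2L, c(30L, 31L), 40L), "multiple of 3")
  expect_error(gene_blueprint(2L, c(30L, 30L), 3L), ">= 4")
})

test_that("random blueprints always realize intact genes (property sweep)", {
  for (i in 1:300) {
    bp <- random_gene_blueprint(i, n_exons = 1L + (i %% 3L))
    g <- make_gene(bp, gene_id = "g")
    expect_true(is_gene_intact(g$seq, g$model), info = paste("seed", i))
    expect_false(grepl("*", substring(translate_cds(g$cds), 1,
                                      nchar(g$protein)), fixed = TRUE))
  }
})

test_that("evolve with zero rates is the identity with an empty log", {
  g <- make_gene(gene_blueprint(1L, 60L, seed = 1L))
  ev <- evolve(g$seq, g$model, evolution_params(0, 0, seed = 9L))
  expect_identical(ev$seq, g$seq)
  expect_equal(nrow(ev$log), 0L)
})

test_that("unconstrained substitution divergence matches the site-wise oracle", {
  # oracle: each site substituted independently with probability p to a
  # different base, so E(identity) = 1 - p
  set.seed(5)
  s <- rand_dna(10000)
  model <- gene_model("x", exons = genome_interval("locus", 0L, 10000L))
  p <- 0.1
  ids <- vapply(1:50, function(r) {
    ev <- evolve(s, model, evolution_params(sub_rate = p, seed = r))
    v1 <- strsplit(s, "")[[1]]; v2 <- strsplit(ev$seq, "")[[1]]
    mean(v1 == v2)
  }, numeric(1))
  se <- stats::sd(ids) / sqrt(length(ids))
  expect_lt(abs(mean(ids) - (1 - p)), 3 * se + 1e-12)
})

test_that("constrained evolution always leaves the gene intact", {
  for (r in 1:25) {
    g <- make_gene(random_gene_blueprint(r + 50L), gene_id = "g")
    ev <- evolve(g$seq, g$model,
                 evolution_params(sub_rate = 0.05, indel_rate = 0.001,
                                  constrained = TRUE, seed = r))
    expect_true(is_gene_intact(ev$seq, ev$model), info = paste("rep", r))
    orf <- reconstruct_orf(ev$seq, ev$model)
    expect_match(orf$cds, "^ATG")
    expect_null(orf$premature_stop)
  }
})

test_that("evolve event log records every substitution", {
  g <- make_gene(gene_blueprint(1L, 300L, seed = 2L))
  ev <- evolve(g$seq, g$model, evolution_params(sub_rate = 0.05, seed = 4L))
  lg <- ev$log[ev$log$type == "sub", ]
  v1 <- strsplit(g$seq, "")[[1]]; v2 <- strsplit(ev$seq, "")[[1]]
  expect_equal(sort(which(v1 != v2) - 1L), sort(lg$pos))
  expect_true(all(lg$ref != lg$alt))
})

test_that("implant_lesions records exact post-edit truth", {
  g <- make_gene(gene_blueprint(2L, c(120L, 60L), 80L, seed = 6L))
  # 1-bp deletion inside exon 1 -> frameshift at the disrupted codon
  imp <- implant_lesions(g$seq, g$model,
                         list(list(kind = "frameshift", exon = 1L,
                                   offset = 40L, op = "del", len = 1L)),
                         seed = 1L)
  expect_equal(imp$truth$kind, "frameshift")
  expect_equal(nchar(imp$seq), nchar(g$seq) - 1L)
  expect_equal(imp$model$exons$end[1], g$model$exons$end[1] - 1L)

  # substitution to an in-frame TGA -> nonsense at that codon
  imp2 <- implant_lesions(g$seq, g$model,
                          list(list(kind = "nonsense", codon = 20L,
                                    stop_codon = "TGA")), seed = 1L)
  expect_equal(imp2$truth$kind, "nonsense")
  expect_equal(imp2$truth$cds_offset, 60L)
  expect_equal(substring(spliced_cds(stats::setNames(imp2$seq, "locus"),
                                     imp2$model), 61, 63), "TGA")

  # overlapping specs rejected
  expect_error(
    implant_lesions(g$seq, g$model,
                    list(list(kind = "nonsense", codon = 20L),
                         list(kind = "nonsense", codon = 20L)), seed = 1L),
    "overlapping")
  # nonsense 3' of a frameshift rejected (not an independent event)
  expect_error(
    implant_lesions(g$seq, g$model,
                    list(list(kind = "frameshift", exon = 1L, offset = 30L,
                              op = "del", len = 1L),
                         list(kind = "nonsense", codon = 30L)), seed = 1L),
    "incompatible")
})

test_that("an exon-1 frameshift can induce a discoverable stop in exon 1", {
  # the echidna-like scenario: shifted frame hits a stop before the intron
  g <- make_gene(gene_blueprint(2L, c(222L, 141L), 300L, seed = 101L + 1L),
                 gene_id = "t")
  found <- FALSE
  for (o in seq(15L, 180L)) {
    imp <- implant_lesions(g$seq, g$model,
                           list(list(kind = "frameshift", exon = 1L,
                                     offset = o, op = "del", len = 1L)),
                           seed = 1L)
    orf <- reconstruct_orf(imp$seq, imp$model,
                           ref_protein_length = nchar(g$protein))
    st <- orf$internal_stops
    if (length(st) && 3L * st[1] + 3L <= 221L) {
      found <- TRUE
      aln <- spliced_align(g$protein, imp$seq)
      les <- classify_lesions(imp$seq, imp$model, alignment = aln,
                              alignment_offset = 0L, ref_protein = g$protein,
                              ref_protein_length = nchar(g$protein))
      expect_equal(les$kind, "frameshift")
      expect_equal(les$exon_index, 1L)
      expect_match(les$detail, "induces stop")
      break
    }
  }
  expect_true(found)
})

test_that("assemble_genome preserves marker order and is seed-deterministic", {
  tgt <- make_gene(gene_blueprint(1L, 90L, seed = 8L), gene_id = "T")
  asm <- assemble_genome(c("A", "B", "T", "C", "D"), tgt,
                         intergenic = c(200L, 400L), seed = 12L)
  ord <- names(asm$models)[order(vapply(asm$models, function(m)
    min(m$exons$start), integer(1)))]
  expect_equal(ord, c("A", "B", "T", "C", "D"))
  expect_equal(unname(substring(asm$genome, asm$target_span$start + 1L,
                                asm$target_span$end)), tgt$seq)
  asm2 <- assemble_genome(c("A", "B", "T", "C", "D"), tgt,
                          intergenic = c(200L, 400L), seed = 12L)
  expect_identical(asm$genome, asm2$genome)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gtf(asm$models, f1); write_gtf(asm2$models, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pure-noise read simulation matches the binomial window oracle", {
  set.seed(2)
  genome <- stats::setNames(rand_dna(50000), "c")
  model <- gene_model("g", exons = genome_interval("c", 100L, 200L))
  n_reads <- 20000L; rl <- 50L
  # window [10000, 11000): a read overlaps iff start in (10000-rl, 11000)
  L <- 1000L
  slots <- nchar(genome) - rl + 1L
  p <- (L + rl - 1L) / slots
  counts <- vapply(1:20, function(r) {
    rs <- simulate_reads(genome, list(g = model),
                         read_sim_params(c(g = 0), noise_rate = 1,
                                         read_length = rl,
                                         n_reads = n_reads, seed = r))
    count_reads(rs, genome_interval("c", 10000L, 11000L))
  }, integer(1))
  expected <- n_reads * p
  sd_tot <- sqrt(n_reads * p * (1 - p) / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * sd_tot)
})

test_that("transcript-only reads all land on the source gene's exons", {
  asm <- get_expression_world()$asm
  rs <- simulate_reads(asm$genome, asm$models,
                       read_sim_params(c(m1 = 1), noise_rate = 0,
                                       read_length = 100L, n_reads = 2000L,
                                       seed = 3L))
  expect_equal(count_reads(rs, asm$models[["m1"]]), 2000L)
  expect_error(read_sim_params(c(m1 = 0), noise_rate = 0, n_reads = 10L),
               "nothing to sample")
})

test_that("simulate_reads is seed-deterministic", {
  w <- get_expression_world()
  p <- read_sim_params(c(m1 = 1, m2 = 2), noise_rate = 0.05,
                       read_length = 100L, n_reads = 5000L, seed = 11L)
  r1 <- simulate_reads(w$asm$genome, w$asm$models, p)
  r2 <- simulate_reads(w$asm$genome, w$asm$models, p)
  expect_identical(r1$reads, r2$reads)
})
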