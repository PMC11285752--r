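# Read counting, RPKM/TPM, the intergenic null, expression calls.

test_that("count_reads follows the half-open >=1 bp overlap rule", {
  feat <- gene_model("g", exons = genome_interval("c", c(100L, 300L),
                                                  c(200L, 350L)))
  rs0 <- read_set(NULL, 10)
  expect_equal(count_reads(rs0, feat), 0L)

  reads <- genome_interval("c",
                           c(50L, 150L, 200L, 199L, 340L, 90L, 10L),
                           c(100L, 250L, 250L, 200L, 400L, 101L, 20L))
  rs <- read_set(reads, 100)
  # abutting read [50,100) does not overlap exon [100,200); [199,200) does;
  # [90,101) overlaps by 1 bp; read spanning both exons counted once
  expect_equal(count_reads(rs, feat), 4L)
  expect_equal(bf_count_reads(rs, feat$exons), 4L)
})

test_that("count_reads equals brute-force overlap on random fixtures", {
  set.seed(51)
  for (r in 1:5) {
    reads <- genome_interval(
      sample(c("c1", "c2"), 2000L, replace = TRUE),
      st <- sample(0:9900, 2000L, replace = TRUE), st + 100L)
    rs <- read_set(reads, 5000)
    s <- sort(sample(0:9000, 3L))
    feat <- genome_interval(c("c1", "c1", "c2"), s, s + c(400L, 250L, 700L))
    expect_equal(count_reads(rs, feat), bf_count_reads(rs, feat))
  }
})

test_that("rpkm is the canonical formula with exact zeros", {
  expect_identical(rpkm(0, 54548375, 6000), 0)
  expect_equal(rpkm(1000, 1e6, 1000), 1000)
  expect_equal(rpkm(2, 47923676, 5965, digits = 3), 0.007)
  expect_error(rpkm(1, 0, 100), "positive")
  expect_error(rpkm(1, 100, 0), "positive")
})

test_that("rpkm is strictly monotone in N and L", {
  Ns <- c(1e6, 2e6, 5e6, 1e7); Ls <- c(500, 1000, 2000, 4000)
  expect_true(all(diff(rpkm(10, Ns, 1000)) < 0))
  expect_true(all(diff(rpkm(10, 1e6, Ls)) < 0))
})

test_that("tpm normalises to one million and matches a two-pass oracle", {
  expect_equal(unname(tpm(c(a = 10, b = 10), c(100, 100))), c(5e5, 5e5))
  expect_equal(unname(tpm(c(a = 0, b = 0), c(100, 100))), c(0, 0))
  set.seed(52)
  for (r in 1:100) {
    k <- sample(3:30, 1)
    counts <- rpois(k, 50)
    lens <- sample(200:5000, k)
    v <- tpm(counts, lens)
    if (all(counts == 0)) { expect_true(all(v == 0)); next }
    expect_lt(abs(sum(v) - 1e6) / 1e6, 1e-6)
    rate <- counts / lens                       # independent two-pass
    expect_equal(unname(v), 1e6 * rate / sum(rate))
  }
})

test_that("sample_intergenic avoids exons and fails on full genomes", {
  model <- gene_model("g", exons = genome_interval("c", 0L, 1000L))
  expect_error(sample_intergenic(list(model), c(c = 1000L), 5L, 100L),
               "insufficient intergenic space")

  w <- get_expression_world()
  regions <- sample_intergenic(w$asm$models, w$glens, 1000L, 500L, seed = 4L)
  exons <- do.call(rbind, lapply(w$asm$models, function(m) m$exons))
  for (e in seq_len(nrow(exons)))
    expect_true(all(regions$end <= exons$start[e] |
                      regions$start >= exons$end[e]))
  # determinism
  r2 <- sample_intergenic(w$asm$models, w$glens, 1000L, 500L, seed = 4L)
  expect_identical(regions, r2)
})

test_that("intergenic starts are uniform over placeable positions", {
  # one small gene in the middle of a small chromosome; chi-square over
  # equal-width bins of the placeable coordinate space at alpha = 0.01
  model <- gene_model("g", exons = genome_interval("c", 5000L, 5200L))
  L <- 50L
  regions <- sample_intergenic(list(model), c(c = 10000L), 10000L, L,
                               seed = 6L)
  # placeable starts: [0, 4950] and [5200, 9950]
  expect_true(all(regions$end <= 5000L | regions$start >= 5200L))
  x <- ifelse(regions$start < 5000L, regions$start,
              regions$start - (5200L - 4951L))
  breaks <- seq(0, 4951L + 4751L, length.out = 21L)
  ct <- table(cut(x + 0.5, breaks))
  p <- stats::chisq.test(ct)$p.value
  expect_gt(p, 0.01)
})

test_that("expression_call implements the decision rule", {
  w <- get_expression_world()
  nullreg <- w$nullreg
  rs <- simulate_reads(w$asm$genome, w$asm$models,
                       read_sim_params(c(m1 = 1), noise_rate = 0.01,
                                       read_length = 100L, n_reads = 50000L,
                                       seed = 8L))
  nd <- null_distribution(rs, nullreg)
  Lt <- w$lens[["tgt"]]
  # C = 0 can never exceed a nonnegative null quantile
  rec0 <- expression_record("t", "tgt", 0L, 50000, Lt, 100)
  expect_equal(expression_call(rec0, nd)$call, "noise")
  # high count + high tpm -> expressed
  rec1 <- expression_record("t", "tgt", 5000L, 50000, Lt, 50)
  expect_equal(expression_call(rec1, nd)$call, "expressed")
  # high count but sub-threshold tpm -> ambiguous
  rec2 <- expression_record("t", "tgt", 5000L, 50000, Lt, 0.2)
  expect_equal(expression_call(rec2, nd)$call, "ambiguous")
  # undersized null -> configuration error
  small <- null_distribution(rs, lapply(1:5, function(i) nullreg[[i]]))
  expect_error(expression_call(rec1, small), "too small")
})

test_that("expression_table has the report column layout", {
  w <- get_expression_world()
  rs <- simulate_reads(w$asm$genome, w$asm$models,
                       read_sim_params(c(tgt = 1), noise_rate = 0,
                                       read_length = 100L, n_reads = 1000L,
                                       seed = 9L))
  tab <- expression_table(w$asm$models[["tgt"]], list(ovary = rs))
  expect_equal(names(tab), c("tissue", "mapped read total for gene",
                             "mapped read total for tissue", "RPKM"))
  expect_equal(tab$tissue, "ovary")
  expect_equal(tab[["mapped read total for gene"]], 1000L)
  expect_equal(tab$RPKM, round(rpkm(1000, 1000, w$lens[["tgt"]]), 3))
})
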