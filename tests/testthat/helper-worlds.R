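# Shared simulated worlds, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, builder(), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# Expression world: one chromosome with 8 intact marker genes around a
# two-exon target, spacers sized so that 1% genome-wide noise leaves ~0-2
# reads on the silenced 363-bp target at 1e5-read depth.
get_expression_world <- function() {
  cache_get("expression_world", function() {
    gene <- make_gene(gene_blueprint(2L, c(222L, 141L), 300L, seed = 102L),
                      gene_id = "tgt")
    markers <- paste0("m", 1:8)
    asm <- assemble_genome(c(markers[1:4], "tgt", markers[5:8]), gene,
                           intergenic = c(80000L, 110000L), seed = 55L)
    glens <- stats::setNames(nchar(asm$genome), names(asm$genome))
    nullreg <- sample_intergenic(asm$models, glens, 100L,
                                 feature_length(asm$models[["tgt"]]),
                                 seed = 77L, piece_lengths = c(222L, 141L))
    list(gene = gene, markers = markers, asm = asm, glens = glens,
         nullreg = nullreg,
         lens = vapply(asm$models, feature_length, numeric(1)))
  })
}

# Demo bundle plus both pipeline verdicts (shared across test files).
get_demo_bundle <- function() {
  cache_get("demo_bundle", function() {
    dir <- file.path(tempdir(), "vestigr_demo_cache")
    demo <- demo_dataset(dir, seed = 1L)
    list(demo = demo,
         control_verdict = run_pipeline(demo$control),
         target_verdict = run_pipeline(demo$target))
  })
}

# Draw a compatible lesion-spec set: `kinds` in implantation-compatible
# order (nonsense specs are placed 5' of frameshifts by the module itself
# rejecting incompatible draws, so we retry with fresh seeds).
implant_random_lesions <- function(gene, kinds, seed) {
  for (try in 0:25) {
    res <- tryCatch(
      implant_lesions(gene$seq, gene$model,
                      lapply(kinds, function(k) list(kind = k)),
                      seed = seed + 997L * try),
      error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  NULL
}

lesion_kind_cycle <- function(i, n_exons = 2L) {
  kinds <- c("frameshift", "nonsense", "splice_donor", "splice_acceptor",
             "start_loss")
  n <- 1L + (i %% 3L)
  idx <- ((i + seq_len(n) - 1L) %% length(kinds)) + 1L
  out <- unique(kinds[idx])
  if (n_exons < 2L)
    out <- setdiff(out, c("splice_donor", "splice_acceptor"))
  if (!length(out)) out <- "nonsense"
  out
}
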