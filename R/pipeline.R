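# Pipeline orchestration: synteny -> reconstruction -> lesion classification
# -> expression evidence -> verdict.
#
# Decision table (total over all evidence combinations):
#   lesions > 0 and no tissue expressed  -> pseudogene
#   lesions > 0 and some tissue expressed -> candidate_pseudogene
#   lesions = 0 and some tissue expressed -> functional
#   otherwise                             -> inconclusive
# Stage failures degrade to "inconclusive" with the failure named in notes.

#' Assemble a pipeline run configuration
#'
#' All paths are validated lazily by [run_pipeline()].  In-memory equivalents
#' (already-parsed genomes/models) are also accepted by the stage functions;
#' the config carries file paths for the CLI.
#'
#' @param reference_genome,reference_gtf,reference_protein reference files
#'   (FASTA / GTF / protein FASTA; protein optional, derived from the
#'   reference annotation when NULL)
#' @param query_genome,query_gtf query genome FASTA and marker annotation GTF
#' @param reads named character vector, tissue -> BED path of mapped reads
#' @param library_totals TSV path (tissue, library_total)
#' @param target_gene gene id of the locus under test
#' @param left_anchor,right_anchor marker gene ids bracketing the locus
#' @param motifs optional peptide-motif FASTA (default: packaged NK-class
#'   homeodomain consensus stand-in)
#' @param expected_exons expected exon count
#' @param snap_window splice-site snapping window (nt)
#' @param scoring [scoring_params()]
#' @param thresholds [expression_thresholds()]
#' @param n_null_regions intergenic null size
#' @param seed integer seed (null sampling)
#' @param out_dir report directory or NULL
#' @return object of class `run_config`
#' @export
run_config <- function(reference_genome, reference_gtf,
                       reference_protein = NULL, query_genome, query_gtf,
                       reads, library_totals, target_gene,
                       left_anchor, right_anchor, motifs = NULL,
                       expected_exons = 2L, snap_window = 12L,
                       scoring = scoring_params(),
                       thresholds = expression_thresholds(),
                       n_null_regions = 100L, seed = 1L, out_dir = NULL) {
  structure(list(reference_genome = reference_genome,
                 reference_gtf = reference_gtf,
                 reference_protein = reference_protein,
                 query_genome = query_genome, query_gtf = query_gtf,
                 reads = reads, library_totals = library_totals,
                 target_gene = target_gene, left_anchor = left_anchor,
                 right_anchor = right_anchor, motifs = motifs,
                 expected_exons = as.integer(expected_exons),
                 snap_window = as.integer(snap_window),
                 scoring = scoring, thresholds = thresholds,
                 n_null_regions = as.integer(n_null_regions),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

decide_classification <- function(n_lesions, calls) {
  expressed <- any(calls == "expressed")
  if (n_lesions > 0L && !expressed) "pseudogene"
  else if (n_lesions > 0L && expressed) "candidate_pseudogene"
  else if (n_lesions == 0L && expressed) "functional"
  else "inconclusive"
}

#' Run the full pseudogene-detection pipeline
#'
#' @param config [run_config()]
#' @param verbose print stage status lines
#' @return object of class `pseudogene_verdict`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  notes <- character()
  logline <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  fail_verdict <- function(stage, e) {
    structure(list(gene_id = config$target_gene,
                   classification = "inconclusive",
                   sequence_evidence = empty_lesion_table(),
                   expression_evidence = NULL, expression_table = NULL,
                   notes = paste0("stage '", stage, "' failed: ",
                                  conditionMessage(e)),
                   chain = NULL, candidate = NULL, model = NULL, orf = NULL,
                   alignment = NULL),
              class = "pseudogene_verdict")
  }

  # --- inputs ---------------------------------------------------------------
  stage <- "inputs"
  res <- tryCatch({
    ref_genome <- read_fasta(config$reference_genome)
    ref_models <- read_gtf(config$reference_gtf)
    qry_genome <- read_fasta(config$query_genome)
    qry_models <- read_gtf(config$query_gtf)
    ref_protein <- if (!is.null(config$reference_protein))
      unname(read_fasta(config$reference_protein)[1])
    else {
      rid <- vapply(ref_models, `[[`, character(1), "gene_id")
      tm <- ref_models[[match(config$target_gene, rid)]]
      sub("\\*$", "", translate_cds(spliced_cds(ref_genome, tm)))
    }
    totals <- read_library_totals(config$library_totals)
    read_sets <- lapply(names(config$reads), function(tt)
      read_bed_reads(config$reads[[tt]], totals[[tt]]))
    names(read_sets) <- names(config$reads)
    list(ref_genome = ref_genome, ref_models = ref_models,
         qry_genome = qry_genome, qry_models = qry_models,
         ref_protein = ref_protein, read_sets = read_sets)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail_verdict(stage, res))
  inp <- res
  logline(stage, "ok")

  # --- synteny --------------------------------------------------------------
  stage <- "synteny"
  res <- tryCatch({
    ref_ids <- vapply(inp$ref_models, `[[`, character(1), "gene_id")
    qry_ids <- vapply(inp$qry_models, `[[`, character(1), "gene_id")
    ref_mo <- marker_order("reference",
                           inp$ref_models[ref_ids != config$target_gene])
    qry_mo <- marker_order("query",
                           inp$qry_models[qry_ids != config$target_gene])
    chain <- find_anchor_chain(ref_mo, qry_mo)
    cand <- candidate_interval(chain, qry_mo, config$left_anchor,
                               config$right_anchor)
    list(chain = chain, cand = cand, qry_mo = qry_mo)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail_verdict(stage, res))
  syn <- res
  logline(stage, sprintf("candidate %s:%d-%d", syn$cand$chrom,
                         syn$cand$start, syn$cand$end))

  # --- reconstruction -------------------------------------------------------
  stage <- "reconstruction"
  res <- tryCatch({
    chrom_seq <- inp$qry_genome[[syn$cand$chrom]]
    dna <- substring(chrom_seq, syn$cand$start + 1L, syn$cand$end)
    motif_path <- if (!is.null(config$motifs)) config$motifs else
      system.file("extdata", "nk_homeodomain_consensus_synthetic.fasta",
                  package = "vestigr")
    hits <- if (nzchar(motif_path))
      motif_scan(dna, read_fasta(motif_path), config$scoring) else NULL
    # a wide candidate interval is narrowed to a window around the motif
    # hits before the (quadratic-cost) spliced alignment
    region <- syn$cand
    max_direct <- 20000L
    if (interval_width(syn$cand) > max_direct) {
      if (is.null(hits) || nrow(hits) == 0L)
        stop("candidate interval ", interval_width(syn$cand),
             " bp wide and no motif hits to focus the alignment")
      pad <- 3000L + 3L * nchar(inp$ref_protein)
      region <- genome_interval(
        syn$cand$chrom,
        max(syn$cand$start, syn$cand$start + min(hits$start) - pad),
        min(syn$cand$end, syn$cand$start + max(hits$end) + pad), "+")
      dna <- substring(chrom_seq, region$start + 1L, region$end)
    }
    aln <- spliced_align(inp$ref_protein, dna, config$scoring)
    model <- infer_exon_model(aln, chrom_seq, region,
                              ref_protein_length = nchar(inp$ref_protein),
                              expected_exons = config$expected_exons,
                              snap_window = config$snap_window, hits = hits,
                              gene_id = config$target_gene)
    list(aln = aln, model = model, hits = hits, region = region)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail_verdict(stage, res))
  rec <- res
  logline(stage, sprintf("%d exon(s), alignment score %.0f, identity %.1f%%",
                         nrow(rec$model$exons), rec$aln$score,
                         rec$aln$identity_pct))

  # --- lesion classification ------------------------------------------------
  stage <- "lesions"
  res <- tryCatch({
    orf <- reconstruct_orf(inp$qry_genome, rec$model,
                           ref_protein_length = nchar(inp$ref_protein))
    lesions <- classify_lesions(inp$qry_genome, rec$model, orf, rec$aln,
                                alignment_offset = rec$region$start,
                                ref_protein = inp$ref_protein,
                                ref_protein_length = nchar(inp$ref_protein))
    list(orf = orf, lesions = lesions)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail_verdict(stage, res))
  les <- res
  logline(stage, sprintf("%d lesion(s)", nrow(les$lesions)))

  # --- expression evidence --------------------------------------------------
  stage <- "expression"
  res <- tryCatch({
    all_models <- inp$qry_models
    all_models[[config$target_gene]] <- rec$model
    lens <- vapply(all_models, feature_length, numeric(1))
    ids <- vapply(all_models, `[[`, character(1), "gene_id")
    glens <- stats::setNames(nchar(inp$qry_genome), names(inp$qry_genome))
    Lt <- feature_length(rec$model)
    nullreg <- sample_intergenic(all_models, glens, config$n_null_regions,
                                 Lt, seed = config$seed,
                                 piece_lengths = interval_width(rec$model$exons))
    records <- list()
    for (tt in names(inp$read_sets)) {
      rs <- inp$read_sets[[tt]]
      counts <- vapply(all_models, function(m) count_reads(rs, m), integer(1))
      tpms <- tpm(counts, lens)
      ti <- match(config$target_gene, ids)
      rec_t <- expression_record(tt, config$target_gene, counts[ti],
                                 rs$library_total, Lt, tpms[ti])
      nd <- null_distribution(rs, nullreg)
      records[[tt]] <- expression_call(rec_t, nd, config$thresholds)
    }
    tab <- expression_table(rec$model, inp$read_sets, config$thresholds)
    null_tab <- expression_table(do.call(rbind, nullreg), inp$read_sets,
                                 config$thresholds)
    list(records = records, table = tab, null_table = null_tab,
         null_regions = nullreg)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail_verdict(stage, res))
  expr <- res
  calls <- vapply(expr$records, `[[`, character(1), "call")
  logline(stage, paste(names(calls), calls, sep = "=", collapse = " "))

  classification <- decide_classification(nrow(les$lesions), calls)
  verdict <- structure(list(
    gene_id = config$target_gene, classification = classification,
    sequence_evidence = les$lesions, expression_evidence = expr$records,
    expression_table = expr$table, null_table = expr$null_table,
    notes = if (length(notes)) paste(notes, collapse = "; ") else "",
    chain = syn$chain, candidate = syn$cand, model = rec$model,
    orf = les$orf, alignment = rec$aln), class = "pseudogene_verdict")
  if (!is.null(config$out_dir)) write_report(verdict, config$out_dir)
  verdict
}

#' @export
print.pseudogene_verdict <- function(x, ...) {
  cat(sprintf("<pseudogene_verdict> %s: %s (%d lesion(s))\n", x$gene_id,
              x$classification, nrow(x$sequence_evidence)))
  if (nzchar(x$notes)) cat("  notes: ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Write pipeline reports
#'
#' Emits a machine-readable JSON verdict, the per-tissue expression table
#' (columns `tissue`, `mapped read total for gene`, `mapped read total for
#' tissue`, `RPKM`), the intergenic null table, the lesion table, the
#' reconstructed exon model as GTF, and a plain-text summary.  Deterministic
#' given the same verdict.
#'
#' @param verdict [run_pipeline()] result
#' @param out_dir output directory (created if needed)
#' @return named character vector of files written, invisibly
#' @export
write_report <- function(verdict, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  p <- function(f) file.path(out_dir, f)

  jv <- list(gene_id = verdict$gene_id,
             classification = verdict$classification,
             notes = verdict$notes,
             lesions = verdict$sequence_evidence,
             expression = lapply(verdict$expression_evidence, function(r)
               list(tissue = r$tissue, count = r$count,
                    library_total = r$library_total, length_bp = r$length_bp,
                    rpkm = r$rpkm, tpm = r$tpm, call = r$call)),
             candidate = verdict$candidate,
             anchor_chain = if (!is.null(verdict$chain))
               verdict$chain$pairs else NULL)
  jsonlite::write_json(jv, p("verdict.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["verdict"] <- p("verdict.json")

  if (!is.null(verdict$expression_table)) {
    utils::write.table(verdict$expression_table, p("expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files["expression"] <- p("expression.tsv")
  }
  if (!is.null(verdict$null_table)) {
    utils::write.table(verdict$null_table, p("null_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["null"] <- p("null_regions.tsv")
  }
  utils::write.table(verdict$sequence_evidence, p("lesions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["lesions"] <- p("lesions.tsv")
  if (!is.null(verdict$model)) {
    write_gtf(verdict$model, p("reconstructed.gtf"))
    files["gtf"] <- p("reconstructed.gtf")
  }
  summary_lines <- c(
    sprintf("gene: %s", verdict$gene_id),
    sprintf("classification: %s", verdict$classification),
    sprintf("lesions: %d", nrow(verdict$sequence_evidence)),
    if (!is.null(verdict$expression_evidence))
      vapply(verdict$expression_evidence, function(r)
        sprintf("expression[%s]: %s (rpkm %.3f, tpm %s)", r$tissue, r$call,
                r$rpkm, format(r$tpm, digits = 3)), character(1)),
    if (nzchar(verdict$notes)) sprintf("notes: %s", verdict$notes))
  writeLines(summary_lines, p("summary.txt"))
  files["summary"] <- p("summary.txt")
  invisible(files)
}

# Find an exon-1 offset whose 1-bp deletion shifts the frame onto a stop
# codon still inside exon 1 (the echidna-like scenario).
find_fs_stop_offset <- function(gene) {
  w1 <- interval_width(gene$model$exons)[1]
  for (o in seq(15L, w1 - 20L)) {
    trial <- tryCatch(
      implant_lesions(gene$seq, gene$model,
                      list(list(kind = "frameshift", exon = 1L, offset = o,
                                op = "del", len = 1L)), seed = 1L),
      error = function(e) NULL)
    if (is.null(trial)) next
    orf <- reconstruct_orf(stats::setNames(trial$seq, trial$model$chrom),
                           trial$model,
                           ref_protein_length = nchar(gene$protein))
    st <- orf$internal_stops
    if (length(st) && 3L * st[1] + 3L <= w1 - 1L) return(o)
  }
  stop("no exon-1 frameshift-stop offset found for this gene")
}

#' Generate the packaged demonstration dataset
#'
#' Two query scenarios around one reference: a control query carrying an
#' intact, expressed ortholog of the target gene, and a pseudogenized query
#' carrying an exon-1 frameshift whose shifted frame hits a stop codon still
#' in exon 1, with no transcript reads.  Marker genes (including the
#' anchors) are intact and expressed in both.  Everything is written as
#' plain text (FASTA/GTF/BED/TSV/JSON).
#'
#' @param out_dir output directory
#' @param seed integer seed
#' @param tissues tissue labels
#' @param n_reads reads per tissue library
#' @return list with `control` and `target` [run_config()] objects, plus
#'   `truth` (lesion truth table) and `files`
#' @export
demo_dataset <- function(out_dir, seed = 1L,
                         tissues = c("stomach", "liver", "spleen"),
                         n_reads = 50000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  # markers emulate the conserved block around the locus; spacers are sized
  # so that 1% genome-wide noise leaves 0-2 reads on a silenced 363-bp
  # feature at this library depth, the magnitude seen in real tissue panels
  markers <- c("Cpeb2", "C1qtnf7", "Rab28", "Nkx3-2", "Bod1l1", "Lap3",
               "Med28", "Klf3")
  spacer_range <- c(80000L, 110000L)
  target_id <- "Nkx3-2"

  gene <- make_gene(gene_blueprint(2L, c(222L, 141L), 300L,
                                   seed = seed + 101L),
                    gene_id = target_id)

  # reference genome: intact target, annotated
  ref <- assemble_genome(markers, gene, intergenic = spacer_range,
                         seed = seed + 1L, chrom = "ref_chr1")
  write_fasta(ref$genome, p("reference_genome.fa"))
  write_gtf(ref$models, p("reference_annotation.gtf"))
  write_fasta(stats::setNames(gene$protein, target_id),
              p("reference_protein.fa"))
  # conserved-domain stand-ins: peptide blocks cut from the reference protein
  np <- nchar(gene$protein)
  motifs <- c(nbox = substring(gene$protein, 2L, 13L),
              homeodomain = substring(gene$protein, np %/% 2L - 14L,
                                      np %/% 2L + 15L),
              cbox = substring(gene$protein, np - 11L, np))
  write_fasta(motifs, p("motifs.fa"))

  scenarios <- list()
  truth <- NULL
  for (scen in c("control", "target")) {
    if (scen == "control") {
      g <- gene
    } else {
      off <- find_fs_stop_offset(gene)
      imp <- implant_lesions(gene$seq, gene$model,
                             list(list(kind = "frameshift", exon = 1L,
                                       offset = off, op = "del", len = 1L)),
                             seed = seed + 7L)
      g <- list(seq = imp$seq, model = imp$model)
      truth_local <- imp$truth
    }
    asm <- assemble_genome(markers, g, intergenic = spacer_range,
                           seed = seed + (if (scen == "control") 2L else 3L),
                           chrom = "qry_chr1")
    write_fasta(asm$genome, p(paste0(scen, "_genome.fa")))
    # query annotation: markers only (the target locus is unannotated)
    qmodels <- asm$models[names(asm$models) != target_id]
    write_gtf(qmodels, p(paste0(scen, "_annotation.gtf")))
    if (scen == "target") {
      # truth coordinates shifted to assembled-genome space
      shift <- asm$target_span$start
      truth_local$chrom <- asm$target_span$chrom
      truth_local$start <- truth_local$start + shift
      truth_local$end <- truth_local$end + shift
      truth <- truth_local
      write_lesion_truth(truth, p("target_lesion_truth.json"))
    }
    # reads: markers expressed everywhere; the target transcribed only in
    # the control's stomach library
    beds <- character()
    for (ti in seq_along(tissues)) {
      w <- stats::setNames(rep(1, length(markers)), markers)
      w[target_id] <- if (scen == "control" && tissues[ti] == "stomach")
        1 else 0
      if (scen == "target") w[target_id] <- 0
      prm <- read_sim_params(w, noise_rate = 0.01, read_length = 100L,
                             n_reads = n_reads,
                             seed = seed + 10L * ti +
                               (if (scen == "control") 0L else 500L))
      rs <- simulate_reads(asm$genome, asm$models, prm)
      bed <- p(paste0(scen, "_", tissues[ti], ".bed"))
      write_bed_reads(rs, bed)
      beds[tissues[ti]] <- bed
    }
    tot_path <- p(paste0(scen, "_library_totals.tsv"))
    utils::write.table(data.frame(tissue = tissues, library_total = n_reads),
                       tot_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    scenarios[[scen]] <- run_config(
      reference_genome = p("reference_genome.fa"),
      reference_gtf = p("reference_annotation.gtf"),
      reference_protein = p("reference_protein.fa"),
      query_genome = p(paste0(scen, "_genome.fa")),
      query_gtf = p(paste0(scen, "_annotation.gtf")),
      reads = beds, library_totals = tot_path, target_gene = target_id,
      left_anchor = "Rab28", right_anchor = "Bod1l1",
      motifs = p("motifs.fa"), seed = seed,
      out_dir = p(paste0(scen, "_report")))
  }
  list(control = scenarios$control, target = scenarios$target, truth = truth,
       files = list.files(out_dir, full.names = TRUE))
}
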