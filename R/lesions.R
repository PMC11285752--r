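# ORF reconstruction and inactivating-lesion classification.
#
# A gene is intact when its spliced CDS starts ATG, contains no internal
# stop, ends on a stop, and all introns carry GT/AG dinucleotides.  The
# classifier reports one lesion per inactivating event: frameshifts come
# from the spliced alignment, premature stops from the reconstructed ORF
# (folded into an upstream frameshift when the shift explains them),
# splice-site losses from direct dinucleotide inspection, and start loss
# from the first codon.

#' Reconstruct and translate the ORF of an exon model
#'
#' @param genome named character vector of chromosome sequences
#' @param model [gene_model()]
#' @param ref_protein_length optional reference protein length; a stop is
#'   called premature only before `premature_frac` of this length
#' @param premature_frac fraction of the reference length below which a stop
#'   is premature (default 0.95, avoids calling natural stop drift)
#' @return object of class `orf_report`: `cds`, `protein`, `premature_stop`
#'   (`codon_index` 0-based and `fraction`, or NULL), `internal_stops`
#'   (0-based codon indices), `splice_ok`, `intact`
#' @export
reconstruct_orf <- function(genome, model, ref_protein_length = NULL,
                            premature_frac = 0.95) {
  if (is.character(genome) && is.null(names(genome)))
    genome <- stats::setNames(genome, model$chrom)
  cds <- spliced_cds(genome, model)
  if (nchar(cds) < 6L)
    stop("degenerate exon model: CDS shorter than 2 codons")
  protein_full <- translate_cds(cds)
  n_aa <- nchar(protein_full)
  ref_len <- if (is.null(ref_protein_length)) n_aa - 1L else ref_protein_length
  stops <- as.integer(gregexpr("*", protein_full, fixed = TRUE)[[1]])
  stops <- stops[stops > 0L]
  internal <- stops[stops < n_aa] - 1L     # 0-based codon indices
  cutoff <- ceiling(premature_frac * ref_len)
  premature <- internal[internal < cutoff]
  premature_stop <- if (length(premature))
    list(codon_index = premature[1L], fraction = premature[1L] / ref_len)
  else NULL
  chrom_seq <- genome[[model$chrom]]
  introns <- model_introns(model)
  splice_ok <- vapply(introns, function(intr) {
    oriented_dinuc(chrom_seq, intr$donor, model$strand) == "GT" &&
      oriented_dinuc(chrom_seq, intr$acceptor, model$strand) == "AG"
  }, logical(1))
  intact <- substring(cds, 1L, 3L) == "ATG" &&
    nchar(cds) %% 3L == 0L &&
    length(internal) == 0L &&
    length(stops) > 0L && stops[length(stops)] == n_aa &&
    all(splice_ok)
  structure(list(cds = cds, protein = sub("\\*$", "", protein_full),
                 protein_full = protein_full,
                 premature_stop = premature_stop,
                 internal_stops = internal, splice_ok = splice_ok,
                 intact = intact, model = model),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("<orf_report> %d aa, %s%s\n", nchar(x$protein),
              if (x$intact) "intact" else "not intact",
              if (!is.null(x$premature_stop))
                sprintf(", premature stop at codon %d (%.0f%% of reference)",
                        x$premature_stop$codon_index,
                        100 * x$premature_stop$fraction) else ""))
  invisible(x)
}

#' Classify gene-inactivating lesions
#'
#' @param genome named character vector holding the query chromosome
#' @param model query [gene_model()] (reconstructed or known)
#' @param orf [reconstruct_orf()] report for that model; computed when NULL
#' @param alignment [spliced_align()] of the reference protein against the
#'   gene-span dna (plus optional flank); `alignment_offset` gives the
#'   genome position of the dna's first base
#' @param alignment_offset genome offset of the aligned dna (default: gene
#'   span start)
#' @param ref_protein reference protein, used to canonicalize frameshift
#'   positions (5'-most equivalent codon)
#' @param ref_protein_length reference length for the premature-stop rule
#' @param premature_frac see [reconstruct_orf()]
#' @return data frame of lesions sorted by genome position: `kind`, `chrom`,
#'   `start`, `end`, `strand`, `exon_index`, `cds_offset`, `detail`
#' @export
classify_lesions <- function(genome, model, orf = NULL, alignment = NULL,
                             alignment_offset = NULL, ref_protein = NULL,
                             ref_protein_length = NULL,
                             premature_frac = 0.95) {
  if (is.character(genome) && is.null(names(genome)))
    genome <- stats::setNames(genome, model$chrom)
  if (is.null(orf))
    orf <- reconstruct_orf(genome, model, ref_protein_length, premature_frac)
  chrom_seq <- genome[[model$chrom]]
  out <- list()

  # start loss
  if (substring(orf$cds, 1L, 3L) != "ATG") {
    g <- cds_to_genome(model, 0:2)
    out[[length(out) + 1L]] <- data.frame(
      kind = "start_loss", chrom = model$chrom, start = min(g),
      end = max(g) + 1L, strand = model$strand, exon_index = 1L,
      cds_offset = 0L,
      detail = paste0("first codon ", substring(orf$cds, 1L, 3L),
                      ", not ATG"),
      stringsAsFactors = FALSE)
  }

  # splice-site losses
  introns <- model_introns(model)
  for (ii in seq_along(introns)) {
    intr <- introns[[ii]]
    don <- oriented_dinuc(chrom_seq, intr$donor, model$strand)
    acc <- oriented_dinuc(chrom_seq, intr$acceptor, model$strand)
    if (don != "GT")
      out[[length(out) + 1L]] <- data.frame(
        kind = "splice_donor", chrom = model$chrom, start = intr$donor[1],
        end = intr$donor[2], strand = model$strand,
        exon_index = NA_integer_, cds_offset = NA_integer_,
        detail = paste0("intron ", ii, " donor ", don, ", not GT"),
        stringsAsFactors = FALSE)
    if (acc != "AG")
      out[[length(out) + 1L]] <- data.frame(
        kind = "splice_acceptor", chrom = model$chrom,
        start = intr$acceptor[1], end = intr$acceptor[2],
        strand = model$strand, exon_index = NA_integer_,
        cds_offset = NA_integer_,
        detail = paste0("intron ", ii, " acceptor ", acc, ", not AG"),
        stringsAsFactors = FALSE)
  }

  # frameshifts from the alignment
  fs_cds <- integer()
  if (!is.null(alignment) && nrow(alignment$frameshifts)) {
    if (is.null(alignment_offset))
      alignment_offset <- min(model$exons$start)
    for (r in seq_len(nrow(alignment$frameshifts))) {
      gpos <- alignment$frameshifts$pos[r] + alignment_offset
      shift <- alignment$frameshifts$shift[r]
      cds_off <- genome_to_cds(model, gpos)
      if (!is.na(cds_off) && !is.null(ref_protein)) {
        k <- canonical_fs_codon(ref_protein, orf$cds, shift,
                                mat = alignment$params$matrix)
        cds_off <- 3L * k
        gpos <- cds_to_genome(model, cds_off)
      }
      fs_cds <- c(fs_cds, cds_off)
      # does the shifted frame run into a stop?
      induced <- if (is.na(cds_off)) integer() else
        orf$internal_stops[orf$internal_stops * 3L >= cds_off]
      detail <- paste0("frameshift (shift ", ifelse(shift > 0, "+", ""),
                       shift, ")")
      if (length(induced))
        detail <- paste0(detail, "; induces stop at codon ", induced[1])
      out[[length(out) + 1L]] <- data.frame(
        kind = "frameshift", chrom = model$chrom, start = gpos,
        end = gpos + 1L, strand = model$strand,
        exon_index = if (is.na(gpos)) NA_integer_ else exon_index_of(model, gpos),
        cds_offset = cds_off, detail = detail, stringsAsFactors = FALSE)
    }
  }

  # premature stops not explained by an upstream frameshift
  cutoff <- ceiling(premature_frac *
                      (if (is.null(ref_protein_length))
                        nchar(orf$protein_full) - 1L else ref_protein_length))
  for (ci in orf$internal_stops) {
    if (ci >= cutoff) next
    if (length(fs_cds) && any(!is.na(fs_cds) & fs_cds <= 3L * ci)) next
    g <- cds_to_genome(model, 3L * ci + 0:2)
    codon <- substring(orf$cds, 3L * ci + 1L, 3L * ci + 3L)
    out[[length(out) + 1L]] <- data.frame(
      kind = "nonsense", chrom = model$chrom, start = min(g),
      end = max(g) + 1L, strand = model$strand,
      exon_index = exon_index_of(model, cds_to_genome(model, 3L * ci)),
      cds_offset = 3L * ci,
      detail = paste0("premature stop ", codon, " at codon ", ci),
      stringsAsFactors = FALSE)
  }

  lesions <- do.call(rbind, c(list(empty_lesion_table()), out))
  lesions <- lesions[order(lesions$start), , drop = FALSE]
  rownames(lesions) <- NULL
  lesions
}

aa_matrix <- function() scoring_params()$matrix

#' Percent identity of two aligned sequences
#'
#' When no alignment is supplied, sequences are aligned with an ends-free
#' (overlap) global aligner: BLOSUM62 for proteins, +1/-1 for nucleotides.
#' Identity is `100 * identical columns / aligned columns`; gap columns
#' count in the denominator, terminal overhangs do not.  Symmetric by
#' construction.
#'
#' @param seq_a,seq_b sequences (strings)
#' @param alignment optional list with `a`, `b`: equal-length gapped strings
#' @return percent identity in `[0, 100]`, or `NA` for an empty alignment
#' @export
percent_identity <- function(seq_a, seq_b, alignment = NULL) {
  if (is.null(alignment)) {
    swap <- seq_b < seq_a   # symmetry: canonical argument order
    a <- if (swap) seq_b else seq_a
    b <- if (swap) seq_a else seq_b
    is_nuc <- !is.na(guess_alphabet(a)) && guess_alphabet(a) == "nucleotide" &&
      !is.na(guess_alphabet(b)) && guess_alphabet(b) == "nucleotide"
    mat <- if (is_nuc)
      Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                               baseOnly = FALSE)
    else aa_matrix()
    pa <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                        substitutionMatrix = mat,
                                        gapOpening = 10, gapExtension = 1)
    ga <- as.character(Biostrings::alignedPattern(pa))
    gb <- as.character(Biostrings::alignedSubject(pa))
    if (!nzchar(ga)) {
      # sequences so diverged that no overlap scores positive: fall back to
      # a forced global comparison rather than reporting no value
      pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                          substitutionMatrix = mat,
                                          gapOpening = 10, gapExtension = 1)
      ga <- as.character(Biostrings::alignedPattern(pa))
      gb <- as.character(Biostrings::alignedSubject(pa))
    }
  } else {
    ga <- alignment$a; gb <- alignment$b
    if (nchar(ga) != nchar(gb)) stop("aligned strings differ in length")
  }
  if (!nzchar(ga)) return(NA_real_)
  va <- strsplit(ga, "")[[1]]
  vb <- strsplit(gb, "")[[1]]
  matches <- sum(va == vb & va != "-")
  100 * matches / length(va)
}

#' Pairwise percent-identity matrix
#'
#' @param seqs named character vector of >= 2 sequences
#' @return symmetric numeric matrix with 100 on the diagonal
#' @export
identity_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    v <- percent_identity(seqs[[i]], seqs[[j]])
    m[i, j] <- v; m[j, i] <- v
  }
  m
}
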