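# Small sequence helpers shared across modules.

#' Evaluate an expression with a private RNG stream
#'
#' All simulator entry points route their randomness through this helper so
#' that a call is fully determined by its `seed` argument and never disturbs
#' the caller's RNG state.
#' @param seed integer seed
#' @param code expression
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a nucleotide string
#' @param s nucleotide string (A,C,G,T,N)
#' @return reverse complement string
#' @export
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> amino acid lookup, N-containing codons give X
codon_table <- local({
  tab <- Biostrings::GENETIC_CODE
  tab
})

#' Translate an in-frame nucleotide string
#'
#' Trailing partial codons are dropped; codons containing `N` give `X`;
#' stop codons give `*`.
#' @param dna nucleotide string
#' @return amino-acid string
#' @export
translate_cds <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Extract the spliced CDS of a gene model from a genome
#'
#' Exons are concatenated in transcription order; minus-strand exons are
#' reverse-complemented.
#' @param genome named character vector of chromosome sequences
#' @param model [gene_model()]
#' @return nucleotide string (the mRNA/CDS)
#' @export
spliced_cds <- function(genome, model) {
  chrom_seq <- genome[[model$chrom]]
  if (is.null(chrom_seq)) stop("chromosome not in genome: ", model$chrom)
  pieces <- substring(chrom_seq, model$exons$start + 1L, model$exons$end)
  if (model$strand == "-") pieces <- vapply(pieces, revcomp, character(1))
  paste(pieces, collapse = "")
}

# Introns of a model in transcription order: list of genome intervals between
# consecutive exons, with donor/acceptor dinucleotide genome positions.
model_introns <- function(model) {
  k <- nrow(model$exons)
  if (k < 2L) return(NULL)
  ex <- model$exons
  out <- vector("list", k - 1L)
  for (i in seq_len(k - 1L)) {
    if (model$strand == "+") {
      s <- ex$end[i]; e <- ex$start[i + 1L]
      donor <- c(s, s + 2L); acceptor <- c(e - 2L, e)
    } else {
      s <- ex$end[i + 1L]; e <- ex$start[i]
      # transcription runs right to left: donor is at the right edge
      donor <- c(e - 2L, e); acceptor <- c(s, s + 2L)
    }
    out[[i]] <- list(start = s, end = e, donor = donor, acceptor = acceptor)
  }
  out
}

# Dinucleotide read in transcription orientation at genome positions [a,b).
oriented_dinuc <- function(chrom_seq, pos2, strand) {
  d <- substring(chrom_seq, pos2[1] + 1L, pos2[2])
  if (strand == "-") revcomp(d) else d
}

# Map 0-based CDS offsets to 0-based genome positions for a model
# (position of the base at that CDS offset).
cds_to_genome <- function(model, offsets) {
  widths <- interval_width(model$exons)
  cum <- cumsum(c(0L, widths))
  vapply(as.integer(offsets), function(o) {
    ei <- findInterval(o, cum, left.open = FALSE)  # exon index (1-based)
    if (o < 0L || ei > nrow(model$exons)) return(NA_integer_)
    within <- o - cum[ei]
    if (model$strand == "+") model$exons$start[ei] + within
    else model$exons$end[ei] - 1L - within
  }, integer(1))
}

# Inverse of cds_to_genome for positions inside exons; NA for intronic.
genome_to_cds <- function(model, pos) {
  widths <- interval_width(model$exons)
  cum <- cumsum(c(0L, widths))
  vapply(as.integer(pos), function(p) {
    for (ei in seq_len(nrow(model$exons))) {
      e <- model$exons[ei, ]
      if (p >= e$start && p < e$end) {
        within <- if (model$strand == "+") p - e$start else e$end - 1L - p
        return(cum[ei] + within)
      }
    }
    NA_integer_
  }, integer(1))
}

# Exon index (1-based, transcription order) containing a genome position.
exon_index_of <- function(model, pos) {
  for (ei in seq_len(nrow(model$exons))) {
    e <- model$exons[ei, ]
    if (pos >= e$start && pos < e$end) return(ei)
  }
  NA_integer_
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n random sense (non-stop) codons
random_sense_codons <- function(n) {
  if (n == 0L) return("")
  sense <- setdiff(names(codon_table), STOP_CODONS)
  paste(sample(sense, n, replace = TRUE), collapse = "")
}
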