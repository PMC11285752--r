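# File formats and core containers.
#
# Every coordinate inside the package is 0-based half-open on the forward
# strand of a named chromosome.  Conversion to/from 1-based inclusive happens
# in exactly two places: write_gtf() and read_gtf().

NUC_CHARS  <- c("A", "C", "G", "T", "N")
PROT_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "U")

#' Construct a genomic interval
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand`; `start` is 0-based inclusive, `end` is 0-based exclusive.
#' Vectorised over all arguments.
#'
#' @param chrom sequence name(s)
#' @param start 0-based inclusive start(s)
#' @param end 0-based exclusive end(s)
#' @param strand `"+"` or `"-"`
#' @return data frame of intervals
#' @export
genome_interval <- function(chrom, start, end, strand = "+") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  bad <- df$start < 0L | df$start >= df$end
  if (any(bad))
    stop("invalid interval: require 0 <= start < end (rows ",
         paste(which(bad), collapse = ","), ")")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df
}

interval_width <- function(iv) iv$end - iv$start

#' Construct a gene model
#'
#' A gene model is one transcript's exon chain on a single chromosome and
#' strand.  Exons are stored in *transcription* order (5' to 3' of the
#' mRNA): ascending genomic start for `+` genes, descending for `-` genes.
#'
#' @param gene_id,transcript_id identifiers
#' @param exons interval data frame (see [genome_interval()]); all rows must
#'   share `chrom` and `strand`
#' @param phase optional integer vector in `{0,1,2}`, CDS phase per exon
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_id, transcript_id = paste0(gene_id, ".t1"),
                       exons, phase = NULL) {
  stopifnot(is.data.frame(exons), nrow(exons) >= 1L)
  if (length(unique(exons$chrom)) != 1L || length(unique(exons$strand)) != 1L)
    stop("gene model '", gene_id, "': exons must share one chrom and strand")
  strand <- exons$strand[1]
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  so <- exons[order(exons$start), , drop = FALSE]
  if (nrow(so) > 1L && any(so$start[-1L] < so$end[-nrow(so)]))
    stop("gene model '", gene_id, "': exons overlap")
  if (!is.null(phase)) {
    phase <- as.integer(phase)[ord]
    stopifnot(length(phase) == nrow(exons), all(phase %in% 0:2))
  }
  structure(list(gene_id = as.character(gene_id),
                 transcript_id = as.character(transcript_id),
                 chrom = exons$chrom[1], strand = strand,
                 exons = exons, phase = phase),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d (%s), %d exon(s), %d bp\n",
              x$gene_id, x$transcript_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), sum(interval_width(x$exons))))
  invisible(x)
}

gene_span <- function(model) {
  genome_interval(model$chrom, min(model$exons$start), max(model$exons$end),
                  model$strand)
}

#' Construct a set of mapped reads
#'
#' @param reads interval data frame, one row per mapped read
#' @param library_total total mapped reads in the library; must be at least
#'   `nrow(reads)` (the listed reads are the subset falling in the region of
#'   interest, or all of them for simulated libraries)
#' @return object of class `read_set`
#' @export
read_set <- function(reads, library_total) {
  if (is.null(reads))
    reads <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character())
  library_total <- as.double(library_total)
  if (length(library_total) != 1L || is.na(library_total) ||
      library_total < nrow(reads))
    stop("library_total (", library_total,
         ") must be a single number >= number of reads (", nrow(reads), ")")
  structure(list(reads = reads, library_total = library_total),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads listed, library total %.0f\n",
              nrow(x$reads), x$library_total))
  invisible(x)
}

guess_alphabet <- function(s) {
  ch <- unique(strsplit(s, "")[[1]])
  if (all(ch %in% NUC_CHARS)) "nucleotide"
  else if (all(ch %in% PROT_CHARS)) "protein"
  else NA_character_
}

#' Read a FASTA file
#'
#' Sequences are uppercased on read (soft-masking is discarded).  Each record
#' must be purely nucleotide (`A,C,G,T,N`) or purely amino acid; anything
#' else is a format error reported with its line number.
#'
#' @param path file path
#' @return named character vector of uppercase sequences, in file order
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[match(TRUE, nzchar(lines))])
    stop("malformed FASTA in ", path, ": first non-empty line is not a header")
  names_raw <- sub("^>\\s*", "", lines[hdr])
  names_out <- sub("\\s.*$", "", names_raw)
  if (any(!nzchar(names_out)))
    stop("malformed FASTA in ", path, ": empty record name at line ",
         which(hdr)[!nzchar(names_out)][1])
  if (anyDuplicated(names_out))
    stop("duplicate record name in ", path, ": ",
         names_out[duplicated(names_out)][1])
  grp <- cumsum(hdr)
  body <- !hdr & nzchar(lines)
  ok <- grepl(sprintf("^[%s%s]*$", paste(NUC_CHARS, collapse = ""),
                      "ACDEFGHIKLMNPQRSTVWYXU*"),
              toupper(lines[body]))
  if (!all(ok))
    stop("illegal sequence character in ", path, " at line ",
         which(body)[!ok][1])
  seqs <- vapply(seq_along(names_out), function(i)
    paste(toupper(lines[body & grp == i]), collapse = ""), character(1))
  names(seqs) <- names_out
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

parse_gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, "\\s+\"([^\"]*)\""), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read gene models from a GTF file
#'
#' Only `exon` features are used.  GTF coordinates (1-based inclusive) are
#' converted to the internal 0-based half-open convention.  Exons are grouped
#' by `transcript_id` and sorted into transcription order.
#'
#' @param path GTF file path
#' @return list of [gene_model()] objects, ordered by first appearance
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  if (!any(keep)) return(list())
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9L))
    stop("malformed GTF in ", path, ": expected 9 tab-separated fields at line ",
         which(keep)[nf < 9L][1])
  tab <- as.data.frame(do.call(rbind, lapply(f, `[`, 1:9)),
                       stringsAsFactors = FALSE)
  names(tab) <- c("chrom", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attr")
  tab$line <- which(keep)
  tab <- tab[tab$feature == "exon", , drop = FALSE]
  if (nrow(tab) == 0L) return(list())
  tab$start <- suppressWarnings(as.integer(tab$start))
  tab$end <- suppressWarnings(as.integer(tab$end))
  bad <- is.na(tab$start) | is.na(tab$end) | tab$start > tab$end |
    tab$start < 1L
  if (any(bad))
    stop("malformed GTF in ", path, ": bad coordinates at line ",
         tab$line[bad][1])
  if (!all(tab$strand %in% c("+", "-")))
    stop("malformed GTF in ", path, ": unknown strand at line ",
         tab$line[!tab$strand %in% c("+", "-")][1])
  tab$gene_id <- parse_gtf_attr(tab$attr, "gene_id")
  tab$transcript_id <- parse_gtf_attr(tab$attr, "transcript_id")
  if (anyNA(tab$gene_id))
    stop("malformed GTF in ", path, ": missing gene_id at line ",
         tab$line[is.na(tab$gene_id)][1])
  tab$transcript_id[is.na(tab$transcript_id)] <-
    paste0(tab$gene_id[is.na(tab$transcript_id)], ".t1")
  tab$frame_i <- suppressWarnings(as.integer(tab$frame))
  models <- lapply(unique(tab$transcript_id), function(tx) {
    sub <- tab[tab$transcript_id == tx, , drop = FALSE]
    ph <- if (all(!is.na(sub$frame_i))) sub$frame_i else NULL
    ex <- genome_interval(sub$chrom, sub$start - 1L, sub$end, sub$strand)
    if (!is.null(ph)) {
      ord <- order(ex$start, decreasing = (ex$strand[1] == "-"))
      gene_model(sub$gene_id[1], tx, ex[ord, ], ph[ord])
    } else gene_model(sub$gene_id[1], tx, ex)
  })
  models
}

#' Write gene models as GTF
#'
#' Emits one `exon` feature per exon with 1-based inclusive coordinates and a
#' deterministic field layout, so `read_gtf(write_gtf(x))` round-trips
#' coordinates exactly.
#'
#' @param models list of [gene_model()] objects
#' @param path output path
#' @param source value for the GTF source column
#' @return `path`, invisibly
#' @export
write_gtf <- function(models, path, source = "vestigr") {
  if (inherits(models, "gene_model")) models <- list(models)
  lines <- unlist(lapply(models, function(m) {
    ph <- if (is.null(m$phase)) rep(".", nrow(m$exons)) else
      as.character(m$phase)
    sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t%s\tgene_id "%s"; transcript_id "%s";',
            m$chrom, source, m$exons$start + 1L, m$exons$end, m$strand, ph,
            m$gene_id, m$transcript_id)
  }))
  writeLines(if (is.null(lines)) character() else lines, path)
  invisible(path)
}

#' Read mapped reads from a BED file
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate shift is applied.  The strand column (field 6) is honoured when
#' present; otherwise reads are stored as `+`.
#'
#' @param path BED3+ file
#' @param library_total total mapped reads in the originating library
#' @return [read_set()]
#' @export
read_bed_reads <- function(path, library_total) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(read_set(NULL, library_total))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L))
    stop("malformed BED in ", path, ": fewer than 3 fields at line ",
         which(lengths(f) < 3L)[1])
  chrom <- vapply(f, `[`, character(1), 1L)
  start <- as.integer(vapply(f, `[`, character(1), 2L))
  end <- as.integer(vapply(f, `[`, character(1), 3L))
  strand <- vapply(f, function(x)
    if (length(x) >= 6L && x[6] %in% c("+", "-")) x[6] else "+", character(1))
  if (length(lines) > library_total)
    stop("library_total (", library_total, ") smaller than number of reads (",
         length(lines), ") in ", path)
  read_set(genome_interval(chrom, start, end, strand), library_total)
}

#' Write a read set as BED6
#'
#' @param rs [read_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed_reads <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  r <- rs$reads
  lines <- if (nrow(r)) sprintf("%s\t%d\t%d\tread%d\t0\t%s", r$chrom, r$start,
                                r$end, seq_len(nrow(r)), r$strand)
  else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read per-tissue library totals from a two-column TSV
#'
#' @param path TSV with columns `tissue`, `library_total` (header optional)
#' @return named numeric vector, tissue -> total mapped reads
#' @export
read_library_totals <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("library-total TSV needs 2 columns: ", path)
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, ]
  totals <- as.numeric(tab[[2]])
  if (anyNA(totals)) stop("non-numeric library total in ", path)
  stats::setNames(totals, as.character(tab[[1]]))
}
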