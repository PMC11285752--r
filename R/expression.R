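# Expression evidence: read counting over exon unions, RPKM/TPM, an
# intergenic transcriptional-noise null, and the per-tissue expression call.

#' Thresholds for expression calling
#'
#' @param tpm_min minimum TPM for an "expressed" call (default 0.5)
#' @param null_quantile quantile of the intergenic null an expressed
#'   feature must exceed (default 0.95)
#' @param digits decimal places for reported RPKM (default 3)
#' @param min_null_regions minimum usable null size (default 20)
#' @return object of class `expression_thresholds`
#' @export
expression_thresholds <- function(tpm_min = 0.5, null_quantile = 0.95,
                                  digits = 3L, min_null_regions = 20L) {
  stopifnot(tpm_min > 0, null_quantile > 0, null_quantile < 1)
  structure(list(tpm_min = tpm_min, null_quantile = null_quantile,
                 digits = as.integer(digits),
                 min_null_regions = as.integer(min_null_regions)),
            class = "expression_thresholds")
}

feature_granges <- function(feature) {
  if (inherits(feature, "gene_model")) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      feature$exons$chrom,
      IRanges::IRanges(feature$exons$start + 1L, feature$exons$end)))
  } else {
    GenomicRanges::GRanges(feature$chrom,
                           IRanges::IRanges(feature$start + 1L, feature$end))
  }
}

#' Exon-union length of a feature in bp
#' @param feature [gene_model()] or interval data frame
#' @return integer length
#' @export
feature_length <- function(feature) {
  sum(GenomicRanges::width(feature_granges(feature)))
}

#' Count reads overlapping a feature
#'
#' A read is counted once if it overlaps the feature's exon union by at
#' least one bp (half-open intervals: a read abutting an exon end does not
#' overlap).
#'
#' @param rs [read_set()]
#' @param feature [gene_model()] or interval data frame
#' @return nonnegative integer
#' @export
count_reads <- function(rs, feature) {
  stopifnot(inherits(rs, "read_set"))
  if (nrow(rs$reads) == 0L) return(0L)
  reads <- GenomicRanges::GRanges(
    rs$reads$chrom, IRanges::IRanges(rs$reads$start + 1L, rs$reads$end))
  sum(IRanges::overlapsAny(reads, feature_granges(feature),
                           minoverlap = 1L))
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = C * 1e9 / (N * L)` for read count `C`, library total `N`, and
#' feature length `L` in bp.  Exactly zero when `C = 0`.
#'
#' @param count mapped reads on the feature (C)
#' @param library_total mapped reads in the library (N, > 0)
#' @param length_bp feature exon-union length (L, > 0)
#' @param digits optional rounding for reporting
#' @return numeric, vectorised
#' @export
rpkm <- function(count, library_total, length_bp, digits = NULL) {
  if (any(library_total <= 0)) stop("library_total must be positive")
  if (any(length_bp <= 0)) stop("feature length must be positive")
  v <- count * 1e9 / (library_total * length_bp)
  if (!is.null(digits)) round(v, digits) else v
}

#' Transcripts per million
#'
#' Length-normalised read rates rescaled to sum to one million.  All-zero
#' counts give an all-zero mapping (no normalisation attempted).
#'
#' @param counts named nonnegative counts per feature
#' @param lengths_bp matching feature lengths (bp)
#' @return named numeric vector summing to 1e6 (or all zeros)
#' @export
tpm <- function(counts, lengths_bp) {
  stopifnot(length(counts) == length(lengths_bp), all(lengths_bp > 0))
  rate <- counts / lengths_bp
  if (all(rate == 0)) return(rate * 0)
  1e6 * rate / sum(rate)
}

#' Sample random intergenic regions
#'
#' Regions of `region_length` bp are placed uniformly over all positions at
#' which they fit without overlapping any annotated exon.  When
#' `piece_lengths` is given, each sampled "region" is instead a set of
#' independently placed intergenic pieces with those lengths: for a
#' multi-exon feature this matches not just the exon-union length but the
#' fragment structure, so that overlap counting (which gains one read-length
#' window per fragment) is calibrated against the feature.
#'
#' @param models list of [gene_model()] (the annotation to avoid)
#' @param genome_lengths named integer vector of chromosome lengths
#' @param n_regions number of regions
#' @param region_length region length in bp (typically matched to the
#'   feature of interest); ignored when `piece_lengths` is given
#' @param seed integer seed
#' @param piece_lengths optional vector of piece lengths (typically the
#'   feature's exon widths)
#' @return interval data frame of `n_regions` rows, or (with
#'   `piece_lengths`) a list of `n_regions` interval data frames
#' @export
sample_intergenic <- function(models, genome_lengths, n_regions,
                              region_length, seed = 1L,
                              piece_lengths = NULL) {
  if (!is.null(piece_lengths)) {
    pieces <- with_seed(seed, lapply(seq_along(piece_lengths), function(pi)
      sample_intergenic(models, genome_lengths, n_regions,
                        piece_lengths[pi], seed = sample.int(2^30, 1L))))
    return(lapply(seq_len(n_regions), function(r)
      do.call(rbind, lapply(pieces, function(p) p[r, , drop = FALSE]))))
  }
  exons <- do.call(rbind, lapply(models, function(m) m$exons))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end)))
  gaps <- list()
  for (ch in names(genome_lengths)) {
    occ <- gr[GenomicRanges::seqnames(gr) == ch]
    occ_df <- if (length(occ))
      data.frame(start = GenomicRanges::start(occ) - 1L,
                 end = GenomicRanges::end(occ))
    else data.frame(start = integer(), end = integer())
    occ_df <- occ_df[order(occ_df$start), , drop = FALSE]
    cur <- 0L
    for (r in seq_len(nrow(occ_df))) {
      if (occ_df$start[r] > cur)
        gaps[[length(gaps) + 1L]] <- data.frame(chrom = ch, start = cur,
                                                end = occ_df$start[r])
      cur <- max(cur, occ_df$end[r])
    }
    if (cur < genome_lengths[[ch]])
      gaps[[length(gaps) + 1L]] <- data.frame(chrom = ch, start = cur,
                                              end = genome_lengths[[ch]])
  }
  gaps <- do.call(rbind, gaps)
  gaps$slots <- pmax(gaps$end - gaps$start - region_length + 1L, 0L)
  total <- sum(gaps$slots)
  if (total < 1L)
    stop("insufficient intergenic space: no gap holds a ", region_length,
         " bp region")
  with_seed(seed, {
    gi <- sample(nrow(gaps), n_regions, replace = TRUE, prob = gaps$slots)
    st <- gaps$start[gi] + floor(stats::runif(n_regions) * gaps$slots[gi])
    genome_interval(gaps$chrom[gi], as.integer(st),
                    as.integer(st + region_length), "+")
  })
}

#' Intergenic null distribution of per-region RPKM
#'
#' @param rs [read_set()]
#' @param regions intergenic regions from [sample_intergenic()]: an interval
#'   data frame (one region per row) or a list of interval data frames
#'   (structure-matched multi-piece regions)
#' @return object of class `null_distribution` with per-region `counts` and
#'   `rpkm`
#' @export
null_distribution <- function(rs, regions) {
  if (is.data.frame(regions))
    regions <- lapply(seq_len(nrow(regions)), function(r)
      regions[r, , drop = FALSE])
  flat <- do.call(rbind, regions)
  idx <- rep(seq_along(regions), vapply(regions, nrow, integer(1)))
  counts <- integer(length(regions))
  if (nrow(rs$reads) > 0L) {
    reads_gr <- GenomicRanges::GRanges(
      rs$reads$chrom, IRanges::IRanges(rs$reads$start + 1L, rs$reads$end))
    reg_gr <- GenomicRanges::GRanges(
      flat$chrom, IRanges::IRanges(flat$start + 1L, flat$end))
    ov <- GenomicRanges::findOverlaps(reads_gr, reg_gr, minoverlap = 1L)
    if (length(ov)) {
      pair <- unique(data.frame(read = S4Vectors::queryHits(ov),
                                region = idx[S4Vectors::subjectHits(ov)]))
      tab <- table(pair$region)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  lens <- vapply(regions, function(r) sum(r$end - r$start), integer(1))
  structure(list(regions = regions, counts = counts,
                 rpkm = rpkm(counts, rs$library_total, lens),
                 n_regions = length(regions)),
            class = "null_distribution")
}

#' One feature's expression record for one tissue
#'
#' @param tissue tissue label
#' @param feature_id feature label
#' @param count mapped reads on the feature
#' @param library_total library mapped-read total
#' @param length_bp feature exon-union length
#' @param tpm_value optional TPM (needs all features; may be NA)
#' @return object of class `expression_record`
#' @export
expression_record <- function(tissue, feature_id, count, library_total,
                              length_bp, tpm_value = NA_real_) {
  structure(list(tissue = tissue, feature_id = feature_id,
                 count = as.integer(count), library_total = library_total,
                 length_bp = as.integer(length_bp),
                 rpkm = rpkm(count, library_total, length_bp),
                 tpm = tpm_value, call = NA_character_),
            class = "expression_record")
}

#' Call expression against the intergenic null
#'
#' `expressed` requires TPM above `tpm_min` *and* RPKM above the
#' `null_quantile` empirical quantile of the intergenic null; `noise` means
#' RPKM at or below that quantile; anything else is `ambiguous`.
#'
#' @param record [expression_record()]
#' @param null [null_distribution()]
#' @param thresholds [expression_thresholds()]
#' @return the record with `call` filled in
#' @export
expression_call <- function(record, null, thresholds = expression_thresholds()) {
  stopifnot(inherits(record, "expression_record"),
            inherits(null, "null_distribution"))
  if (null$n_regions < thresholds$min_null_regions)
    stop("null distribution too small: ", null$n_regions, " < ",
         thresholds$min_null_regions, " regions")
  q <- stats::quantile(null$rpkm, thresholds$null_quantile, type = 1,
                       names = FALSE)
  record$null_quantile_rpkm <- q
  record$call <-
    if (record$rpkm <= q) "noise"
    else if (!is.na(record$tpm) && record$tpm > thresholds$tpm_min) "expressed"
    else "ambiguous"
  record
}

#' Per-tissue expression table for one feature
#'
#' Produces the standard report shape: one row per tissue with columns
#' `tissue`, `mapped read total for gene`, `mapped read total for tissue`,
#' `RPKM` (rounded to `thresholds$digits`).
#'
#' @param feature [gene_model()] or interval data frame
#' @param read_sets named list of [read_set()], one per tissue
#' @param thresholds [expression_thresholds()]
#' @return data frame
#' @export
expression_table <- function(feature, read_sets,
                             thresholds = expression_thresholds()) {
  L <- feature_length(feature)
  rows <- lapply(names(read_sets), function(tt) {
    rs <- read_sets[[tt]]
    C <- count_reads(rs, feature)
    data.frame(tissue = tt, gene_reads = C, tissue_reads = rs$library_total,
               RPKM = rpkm(C, rs$library_total, L, digits = thresholds$digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("tissue", "mapped read total for gene",
                  "mapped read total for tissue", "RPKM")
  out
}
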