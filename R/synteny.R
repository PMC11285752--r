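# Synteny anchoring: locate a candidate locus in a query genome by chaining
# marker genes shared with a reference.  Markers are matched by identical
# gene_id; the chain is the longest run of shared markers appearing in the
# same relative order in both genomes (longest increasing subsequence over
# the query's reference ranks).  Inversions are not chained.

#' Build a marker order from gene models
#'
#' @param genome_id label for the genome
#' @param models list of [gene_model()] objects (the marker annotation)
#' @return object of class `marker_order`: a data frame of gene spans sorted
#'   by chromosome then start
#' @export
marker_order <- function(genome_id, models) {
  stopifnot(length(models) >= 1L)
  rows <- do.call(rbind, lapply(models, function(m) {
    sp <- gene_span(m)
    data.frame(gene_id = m$gene_id, chrom = sp$chrom, start = sp$start,
               end = sp$end, strand = sp$strand, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(rows$gene_id))
    stop("marker_order: duplicated gene_id (markers must be single-copy): ",
         rows$gene_id[duplicated(rows$gene_id)][1])
  rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(genome_id = genome_id, markers = rows),
            class = "marker_order")
}

# Longest strictly increasing subsequence of `ranks`, returning indices.
# Among maximum-length solutions, returns the one whose value sequence is
# lexicographically smallest (earliest reference positions first).
lis_indices <- function(ranks) {
  n <- length(ranks)
  if (n == 0L) return(integer())
  f <- integer(n)  # f[i]: longest increasing run starting at i
  for (i in n:1) {
    later <- if (i < n) which(ranks[(i + 1):n] > ranks[i]) + i else integer()
    f[i] <- 1L + if (length(later)) max(f[later]) else 0L
  }
  L <- max(f)
  out <- integer(L)
  last_rank <- -Inf; from <- 1L
  for (step in seq_len(L)) {
    need <- L - step + 1L
    cand <- which(f[from:n] == need & ranks[from:n] > last_rank) + from - 1L
    pick <- cand[which.min(ranks[cand])]
    out[step] <- pick
    last_rank <- ranks[pick]; from <- pick + 1L
  }
  out
}

#' Chain shared markers between two genomes
#'
#' Returns the maximum-length set of shared markers that appears in the same
#' relative order in both genomes.  Ties are broken toward the chain with the
#' earliest reference positions.
#'
#' @param reference,query [marker_order()] objects
#' @return object of class `anchor_chain` with `pairs` (gene ids in chain
#'   order) and `collinear` (`TRUE` when every shared marker made the chain)
#' @export
find_anchor_chain <- function(reference, query) {
  stopifnot(inherits(reference, "marker_order"), inherits(query, "marker_order"))
  ref_ids <- reference$markers$gene_id
  qry_ids <- query$markers$gene_id
  shared <- qry_ids[qry_ids %in% ref_ids]
  if (length(shared) == 0L)
    return(structure(list(pairs = character(), collinear = FALSE),
                     class = "anchor_chain"))
  ranks <- match(shared, ref_ids)
  idx <- lis_indices(ranks)
  structure(list(pairs = shared[idx],
                 collinear = length(idx) == length(shared)),
            class = "anchor_chain")
}

#' @export
print.anchor_chain <- function(x, ...) {
  cat(sprintf("<anchor_chain> %d markers%s: %s\n", length(x$pairs),
              if (x$collinear) " (collinear)" else "",
              paste(x$pairs, collapse = " - ")))
  invisible(x)
}

#' Candidate interval between two anchors on the query genome
#'
#' The interval runs from the end of the left anchor's gene body to the start
#' of the right anchor's gene body, strand-agnostic.
#'
#' @param chain [find_anchor_chain()] result
#' @param query the query [marker_order()]
#' @param left_anchor,right_anchor gene ids bracketing the expected locus
#' @return interval data frame
#' @export
candidate_interval <- function(chain, query, left_anchor, right_anchor) {
  if (!all(c(left_anchor, right_anchor) %in% chain$pairs))
    stop("anchoring error: anchors not in conserved chain (",
         left_anchor, ", ", right_anchor, ")")
  mk <- query$markers
  la <- mk[mk$gene_id == left_anchor, ]
  ra <- mk[mk$gene_id == right_anchor, ]
  if (la$chrom != ra$chrom)
    stop("anchoring error: anchors on different query chromosomes")
  lo <- min(la$end, ra$end); hi <- max(la$start, ra$start)
  if (lo >= hi)
    stop("anchoring error: no interval between anchor gene bodies")
  genome_interval(la$chrom, lo, hi, "+")
}
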