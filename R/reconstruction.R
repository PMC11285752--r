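# Exon-model reconstruction inside a candidate interval: six-frame motif
# scanning and a frameshift-aware protein-to-genome spliced aligner.
#
# The aligner is a local (Smith-Waterman style) dynamic programme over
# states:
#   M    - reference residue i aligned to a dna chunk of 1,2,3,4 or 5 nt
#          ending at position j; chunks of length k != 3 are frameshifts
#          (shift k-3 in {-2,-1,+1,+2}) and pay a single frameshift penalty.
#          The residue is always scored against the 3-mer ending at j.
#   Dg   - gap in the protein: a dna codon consumed with no residue (affine).
#   Pg   - gap in the dna: a residue consumed with no dna (affine).
#   Intr - intron skip: >= min_intron nt of dna consumed between codons for
#          a flat intron-open penalty.
# Introns are modelled between codons (phase 0); a phase-1/2 intron is
# absorbed as a frameshift next to the junction instead.

NEG <- -1e9

#' Scoring parameters for motif scanning and spliced alignment
#'
#' Defaults are the conventional protein-alignment values: BLOSUM62 with
#' affine gaps `-11/-1`, a frameshift penalty of `-15` (one event, strictly
#' worse than a gap extension), a flat intron-open penalty of `-20`, and a
#' minimum intron length of 30 nt.
#'
#' @param matrix substitution matrix name (`"BLOSUM62"`) or a numeric matrix
#' @param gap_open,gap_extend affine gap penalties (<= 0)
#' @param frameshift frameshift penalty (< `gap_extend`)
#' @param intron_open flat intron penalty (<= 0)
#' @param min_intron minimum intron length in nt
#' @return object of class `scoring_params`
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = -11,
                           gap_extend = -1, frameshift = -15,
                           intron_open = -20, min_intron = 30L) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), gap_open <= 0, gap_extend <= 0,
            intron_open <= 0, frameshift < gap_extend, min_intron >= 1)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, frameshift = frameshift,
                 intron_open = intron_open, min_intron = as.integer(min_intron)),
            class = "scoring_params")
}

score_lookup <- function(mat, a, b) {
  a[!a %in% rownames(mat)] <- "X"
  b[!b %in% colnames(mat)] <- "X"
  mat[cbind(a, b)]
}

#' Six-frame translation with coordinate maps
#'
#' Frames 0-2 translate the forward strand with offsets 0-2; frames 3-5
#' translate the reverse complement.  Stop codons are emitted as `*`, codons
#' containing `N` as `X`.
#'
#' @param dna nucleotide string (length >= 3)
#' @return object of class `six_frame`: list of 6 tracks with `frame` and
#'   `peptide`, plus the source length; use [frame_codon_interval()] to map
#'   a peptide position back to forward-strand coordinates
#' @export
six_frame_translate <- function(dna) {
  n <- nchar(dna)
  stopifnot(n >= 3L)
  rc <- revcomp(dna)
  tracks <- lapply(0:5, function(f) {
    src <- if (f < 3L) dna else rc
    off <- f %% 3L
    list(frame = f, peptide = translate_cds(substring(src, off + 1L, n)))
  })
  structure(list(tracks = tracks, n = n), class = "six_frame")
}

#' Map a peptide window in a six-frame track to forward-strand coordinates
#'
#' @param sf [six_frame_translate()] result
#' @param frame frame in 0..5
#' @param pos 1-based peptide position
#' @param len window length in residues
#' @return interval columns `start`, `end` (0-based half-open, forward
#'   strand) and `strand`
#' @export
frame_codon_interval <- function(sf, frame, pos, len = 1L) {
  n <- sf$n; off <- frame %% 3L
  if (frame < 3L) {
    start <- off + 3L * (pos - 1L)
    list(start = start, end = start + 3L * len, strand = "+")
  } else {
    # position on the reverse complement, reflected to forward coordinates
    rc_start <- off + 3L * (pos - 1L)
    rc_end <- rc_start + 3L * len
    list(start = n - rc_end, end = n - rc_start, strand = "-")
  }
}

#' Scan six translation frames for conserved peptide motifs
#'
#' Every ungapped window scoring at least `min_score` under the substitution
#' matrix is reported, sorted by score (descending) then position.
#'
#' @param dna nucleotide string, or a [six_frame_translate()] result
#' @param motifs named character vector of peptide motifs (length >= 4)
#' @param params [scoring_params()]
#' @param min_score score threshold; default 60% of each motif's self-score
#' @return data frame of hits: `motif_id`, `frame`, `start`, `end`,
#'   `strand`, `score`
#' @export
motif_scan <- function(dna, motifs, params = scoring_params(),
                       min_score = NULL) {
  sf <- if (inherits(dna, "six_frame")) dna else six_frame_translate(dna)
  stopifnot(!is.null(names(motifs)), all(nchar(motifs) >= 4L))
  mat <- params$matrix
  hits <- list()
  for (mi in seq_along(motifs)) {
    mv <- strsplit(motifs[[mi]], "")[[1]]
    L <- length(mv)
    self <- sum(score_lookup(mat, mv, mv))
    thr <- if (is.null(min_score)) 0.6 * self else min_score
    for (tr in sf$tracks) {
      pv <- strsplit(tr$peptide, "")[[1]]
      W <- length(pv) - L + 1L
      if (W < 1L) next
      sc <- numeric(W)
      for (o in seq_len(L))
        sc <- sc + score_lookup(mat, rep(mv[o], W), pv[o:(o + W - 1L)])
      keep <- which(sc >= thr)
      for (w in keep) {
        iv <- frame_codon_interval(sf, tr$frame, w, L)
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = names(motifs)[mi], frame = tr$frame, start = iv$start,
          end = iv$end, strand = iv$strand, score = sc[w],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(motif_id = character(), frame = integer(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(-out$score, out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frameshift-aware spliced alignment of a protein to genomic dna
#'
#' Local alignment under the state model described in the package vignette:
#' codon match/mismatch, +-1/+-2 frameshifts (single penalty), affine
#' residue gaps, and flat-penalty intron skips of at least `min_intron` nt
#' between codons.  Traceback is deterministic: ties prefer
#' match > frameshift > gap > intron, which places frameshifts at their
#' 5'-most equivalent position.
#'
#' @param protein amino-acid string
#' @param dna nucleotide string (forward strand of the candidate region)
#' @param params [scoring_params()]
#' @return object of class `spliced_alignment`: `score`, `blocks` (protein
#'   and dna intervals, 0-based half-open), `frameshifts` (`pos`, `shift`),
#'   `identity_pct`, `ops` (the traceback operations)
#' @export
spliced_align <- function(protein, dna, params = scoring_params()) {
  pv <- strsplit(toupper(protein), "")[[1]]
  pv[pv == "U"] <- "X"
  m <- length(pv)
  n <- nchar(dna)
  stopifnot(m >= 1L, n >= 3L)
  mat <- params$matrix
  go <- params$gap_open; ge <- params$gap_extend
  fs <- params$frameshift; io <- params$intron_open
  mi <- params$min_intron

  # aa3[j+1]: amino acid of the 3-mer ending at dna offset j (1-based j>=3)
  aa_full <- translate_cds(dna)
  aa1 <- translate_cds(substring(dna, 2L, n))
  aa2 <- translate_cds(substring(dna, 3L, n))
  aa3 <- rep("?", n + 1L)
  ends0 <- 3L * seq_len(nchar(aa_full))          # 3-mer ends (1-based)
  aa3[ends0 + 1L] <- strsplit(aa_full, "")[[1]]
  ends1 <- 1L + 3L * seq_len(nchar(aa1))
  aa3[ends1 + 1L] <- strsplit(aa1, "")[[1]]
  ends2 <- 2L + 3L * seq_len(nchar(aa2))
  aa3[ends2 + 1L] <- strsplit(aa2, "")[[1]]

  ncol1 <- n + 1L
  M <- matrix(NEG, m + 1L, ncol1)
  Dg <- matrix(NEG, m + 1L, ncol1)
  Pg <- matrix(NEG, m + 1L, ncol1)
  In <- matrix(NEG, m + 1L, ncol1)
  shiftv <- function(v, k) {
    if (k == 0L) return(v)
    if (k >= ncol1) return(rep(NEG, ncol1))
    c(rep(NEG, k), v[seq_len(ncol1 - k)])
  }
  valid <- c(rep(FALSE, 3L), rep(TRUE, n - 2L))  # j >= 3 has a 3-mer

  for (i in seq_len(m)) {
    srow <- ifelse(valid, score_lookup(mat, rep(pv[i], ncol1), aa3), NEG)
    prev <- pmax(M[i, ], Dg[i, ], Pg[i, ], In[i, ], 0)
    best <- pmax(shiftv(prev, 3L),
                 shiftv(prev, 2L) + fs, shiftv(prev, 4L) + fs,
                 shiftv(prev, 1L) + fs, shiftv(prev, 5L) + fs)
    M[i + 1L, ] <- best + srow
    Pg[i + 1L, ] <- pmax(M[i, ] + go, Pg[i, ] + ge)
    # Dg: same-row chain with stride 3 (affine over codome gaps)
    dgrow <- rep(NEG, ncol1)
    for (r in 0:2) {
      js <- seq(r, n, by = 3L) + 1L
      if (length(js) < 2L) next
      Mc <- M[i + 1L, js]
      t <- seq_along(js) - 1L
      A <- Mc + go - ge * (t + 1L)
      B <- c(NEG, cummax(A)[-length(A)])
      dgrow[js] <- ge * t + B
    }
    Dg[i + 1L, ] <- pmax(dgrow, NEG)
    cm <- cummax(M[i + 1L, ])
    In[i + 1L, ] <- shiftv(cm, mi) + io
  }

  best_score <- max(M)
  if (best_score <= 0) {
    return(structure(list(score = 0, blocks = data.frame(
      prot_start = integer(), prot_end = integer(), dna_start = integer(),
      dna_end = integer()), frameshifts = data.frame(pos = integer(),
      shift = integer()), identity_pct = NA_real_,
      ops = data.frame(type = character(), i = integer(), j_start = integer(),
                       j_end = integer(), k = integer()),
      params = params), class = "spliced_alignment"))
  }
  hit <- which(M == best_score, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[1] - 1L; j <- hit[2] - 1L
  state <- "M"
  ops <- list()
  near <- function(a, b) abs(a - b) < 1e-6
  repeat {
    if (state == "M") {
      cur <- M[i + 1L, j + 1L]
      s <- score_lookup(mat, pv[i], aa3[j + 1L])
      done <- FALSE
      for (k in c(3L, 2L, 4L, 1L, 5L)) {
        pen <- if (k == 3L) 0 else fs
        need <- cur - s - pen
        if (j - k < 0L) next
        pi <- i - 1L; pj <- j - k
        for (st in c("M", "Pg", "Dg", "In", "0")) {
          val <- switch(st, M = M[pi + 1L, pj + 1L], Pg = Pg[pi + 1L, pj + 1L],
                        Dg = Dg[pi + 1L, pj + 1L], In = In[pi + 1L, pj + 1L],
                        `0` = 0)
          if (st == "0" && val > need + 1e-6) next  # local start only if best
          if (near(val, need) || (st == "0" && near(need, 0))) {
            ops[[length(ops) + 1L]] <- data.frame(
              type = "codon", i = i, j_start = j - k, j_end = j, k = k,
              stringsAsFactors = FALSE)
            i <- pi; j <- pj; state <- st; done <- TRUE; break
          }
        }
        if (done) break
      }
      if (!done) stop("traceback failure in M at (", i, ",", j, ")")
      if (state == "0") break
    } else if (state == "Pg") {
      cur <- Pg[i + 1L, j + 1L]
      if (near(M[i, j + 1L] + go, cur)) state <- "M" else state <- "Pg"
      ops[[length(ops) + 1L]] <- data.frame(type = "gap_dna", i = i,
                                            j_start = j, j_end = j, k = 0L,
                                            stringsAsFactors = FALSE)
      i <- i - 1L
    } else if (state == "Dg") {
      cur <- Dg[i + 1L, j + 1L]
      if (near(M[i + 1L, j - 3L + 1L] + go, cur)) state <- "M" else state <- "Dg"
      ops[[length(ops) + 1L]] <- data.frame(type = "gap_protein", i = i,
                                            j_start = j - 3L, j_end = j,
                                            k = 0L, stringsAsFactors = FALSE)
      j <- j - 3L
    } else if (state == "In") {
      cur <- In[i + 1L, j + 1L]
      cand <- which(near(M[i + 1L, seq_len(j - mi + 1L)], cur - io))
      if (!length(cand)) stop("traceback failure in intron state")
      jp <- max(cand) - 1L  # shortest intron on ties
      ops[[length(ops) + 1L]] <- data.frame(type = "intron", i = i,
                                            j_start = jp, j_end = j, k = 0L,
                                            stringsAsFactors = FALSE)
      j <- jp
      state <- "M"
    }
  }
  ops <- do.call(rbind, rev(ops))
  rownames(ops) <- NULL

  codon_ops <- ops[ops$type == "codon", , drop = FALSE]
  ncols <- sum(ops$type %in% c("codon", "gap_dna", "gap_protein"))
  matches <- sum(pv[codon_ops$i] == aa3[codon_ops$j_end + 1L])
  identity_pct <- if (ncols > 0L) 100 * matches / ncols else NA_real_

  # blocks: contiguous dna-consuming stretches between introns
  brk <- c(0L, which(ops$type == "intron"), nrow(ops) + 1L)
  blocks <- list()
  for (b in seq_len(length(brk) - 1L)) {
    seg <- ops[seq(brk[b] + 1L, brk[b + 1L] - 1L), , drop = FALSE]
    seg <- seg[seg$type != "intron", , drop = FALSE]
    if (!nrow(seg)) next
    cseg <- seg[seg$type == "codon", , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- data.frame(
      prot_start = min(seg$i) - 1L, prot_end = max(seg$i),
      dna_start = min(seg$j_start), dna_end = max(seg$j_end))
  }
  blocks <- do.call(rbind, blocks)
  fs_ops <- codon_ops[codon_ops$k != 3L, , drop = FALSE]
  frameshifts <- data.frame(pos = fs_ops$j_start,
                            shift = fs_ops$k - 3L)

  structure(list(score = best_score, blocks = blocks,
                 frameshifts = frameshifts, identity_pct = identity_pct,
                 ops = ops, params = params),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> score %.0f, %d block(s), %d frameshift(s), identity %.1f%%\n",
              x$score, if (is.null(x$blocks)) 0L else nrow(x$blocks),
              nrow(x$frameshifts), x$identity_pct))
  invisible(x)
}

#' Recompute a spliced alignment's score from its operations
#'
#' Self-consistency check: sums the substitution scores and penalties of the
#' traceback operations.
#' @param aln [spliced_align()] result
#' @param protein,dna the aligned sequences
#' @return numeric score
#' @export
alignment_score_from_ops <- function(aln, protein, dna) {
  pv <- strsplit(toupper(protein), "")[[1]]
  pv[pv == "U"] <- "X"
  mat <- aln$params$matrix
  total <- 0
  prev_type <- ""
  for (r in seq_len(nrow(aln$ops))) {
    op <- aln$ops[r, ]
    if (op$type == "codon") {
      codon <- substring(dna, op$j_end - 2L, op$j_end)
      total <- total + score_lookup(mat, pv[op$i], translate_cds(codon)) +
        if (op$k != 3L) aln$params$frameshift else 0
    } else if (op$type == "intron") {
      total <- total + aln$params$intron_open
    } else {
      total <- total + if (prev_type == op$type) aln$params$gap_extend else
        aln$params$gap_open
    }
    prev_type <- op$type
  }
  total
}

merge_to_count <- function(blocks, target_n) {
  while (nrow(blocks) > target_n) {
    gaps <- blocks$dna_start[-1L] - blocks$dna_end[-nrow(blocks)]
    g <- which.min(gaps)
    blocks$dna_end[g] <- blocks$dna_end[g + 1L]
    blocks$prot_end[g] <- blocks$prot_end[g + 1L]
    blocks <- blocks[-(g + 1L), , drop = FALSE]
  }
  blocks
}

find_dinuc_near <- function(chrom_seq, pos, dinuc, window, at_end = FALSE) {
  # candidate positions p where substring(p..p+1) == dinuc (0-based p);
  # for acceptors, pos is the exon start and the dinucleotide sits at p-2
  offs <- order(abs(seq(-window, window)))  # 0, -1, 1, -2, 2, ...
  for (d in seq(-window, window)[offs]) {
    p <- pos + d
    q <- if (at_end) p - 2L else p
    if (q < 0L || q + 2L > nchar(chrom_seq)) next
    if (substring(chrom_seq, q + 1L, q + 2L) == dinuc) return(p)
  }
  NA_integer_
}

#' Infer an exon model from motif hits and a spliced alignment
#'
#' Exons are seeded at alignment blocks, merged down to at most
#' `expected_exons`, boundaries snapped to the nearest `GT` donor / `AG`
#' acceptor within `snap_window` nt, and the terminal exons extended to an
#' in-frame start codon and stop codon where the alignment did not reach
#' them.  Boundaries with no canonical dinucleotide nearby are kept raw and
#' flagged, never forced.
#'
#' @param alignment [spliced_align()] of the reference protein against the
#'   candidate dna
#' @param chrom_seq the query chromosome sequence (string)
#' @param candidate candidate interval on that chromosome (the dna passed to
#'   the aligner must be `substring(chrom_seq, start+1, end)`)
#' @param ref_protein_length reference protein length (residues), used to
#'   extend terminal exons over unaligned residues
#' @param expected_exons expected exon count (default 2, the NK-class
#'   two-exon architecture)
#' @param avg_exon_lengths optional expected exon lengths (nt), currently
#'   informational
#' @param snap_window splice-site snapping window in nt (0 disables)
#' @param hits optional [motif_scan()] table, recorded in the result
#' @param gene_id id for the inferred model
#' @return [gene_model()] with attributes `support` (per-exon aligned
#'   fraction), `flags` (boundary diagnostics), and `hits`
#' @export
infer_exon_model <- function(alignment, chrom_seq, candidate,
                             ref_protein_length = NULL, expected_exons = 2L,
                             avg_exon_lengths = NULL, snap_window = 12L,
                             hits = NULL, gene_id = "reconstructed") {
  if (is.null(alignment$blocks) || nrow(alignment$blocks) == 0L)
    stop("reconstruction failure: no alignment blocks to seed exons")
  off <- candidate$start
  blocks <- alignment$blocks
  blocks$dna_start <- blocks$dna_start + off
  blocks$dna_end <- blocks$dna_end + off
  blocks <- merge_to_count(blocks, expected_exons)
  k <- nrow(blocks)
  flags <- list()

  # internal boundaries: snap to GT / AG
  if (k > 1L && snap_window > 0L) {
    for (b in seq_len(k - 1L)) {
      p <- find_dinuc_near(chrom_seq, blocks$dna_end[b], "GT", snap_window)
      flags[[paste0("donor_", b)]] <- !is.na(p)
      if (!is.na(p)) blocks$dna_end[b] <- p
      p <- find_dinuc_near(chrom_seq, blocks$dna_start[b + 1L], "AG",
                           snap_window, at_end = TRUE)
      flags[[paste0("acceptor_", b)]] <- !is.na(p)
      if (!is.na(p)) blocks$dna_start[b + 1L] <- p
    }
  } else if (k > 1L) {
    flags$snapping <- FALSE
  }

  # 5' terminus: pull back to the start codon
  lead <- blocks$prot_start[1L]
  want <- blocks$dna_start[1L] - 3L * lead
  start_found <- FALSE
  if (want >= candidate$start) {
    for (t in order(abs(seq(-snap_window, snap_window)))) {
      d <- seq(-snap_window, snap_window)[t]
      q <- want + 3L * d
      if (q < candidate$start || q + 3L > nchar(chrom_seq)) next
      if (substring(chrom_seq, q + 1L, q + 3L) == "ATG") {
        blocks$dna_start[1L] <- q; start_found <- TRUE; break
      }
    }
    if (!start_found) blocks$dna_start[1L] <- max(want, candidate$start)
  }
  flags$start_codon <- start_found

  # 3' terminus: run out the unaligned tail, then take in the stop codon
  trail <- if (is.null(ref_protein_length)) 0L else
    max(0L, ref_protein_length - blocks$prot_end[k])
  e <- blocks$dna_end[k] + 3L * trail
  stop_found <- FALSE
  for (d in 0:snap_window) {
    q <- e + 3L * d
    if (q + 3L > candidate$end) break
    if (substring(chrom_seq, q + 1L, q + 3L) %in% STOP_CODONS) {
      blocks$dna_end[k] <- q + 3L; stop_found <- TRUE; break
    }
  }
  if (!stop_found) blocks$dna_end[k] <- min(e, candidate$end)
  flags$stop_codon <- stop_found

  ex <- genome_interval(candidate$chrom, blocks$dna_start, blocks$dna_end, "+")
  model <- gene_model(gene_id, paste0(gene_id, ".t1"), ex)
  aligned <- alignment$blocks
  support <- vapply(seq_len(k), function(b) {
    ov <- pmin(aligned$dna_end + off, ex$end[b]) -
      pmax(aligned$dna_start + off, ex$start[b])
    sum(pmax(ov, 0L)) / (ex$end[b] - ex$start[b])
  }, numeric(1))
  attr(model, "support") <- support
  attr(model, "flags") <- flags
  attr(model, "hits") <- hits
  model
}
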