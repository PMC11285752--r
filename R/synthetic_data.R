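# Synthetic genomes, diverged orthologs, implanted lesions, mapped reads.
#
# The simulator states a small world with the statistical structure the
# analysis assumes: a chromosome carrying ordered single-copy marker genes
# around a target gene; orthologs diverged under a purifying (lesion-free)
# or neutral (lesion-accumulating) regime; and mapped-read sets made of
# transcript-derived reads plus uniform genome-wide background noise.
# Every entry point takes an explicit seed and leaves global RNG state alone.

#' Blueprint for a synthetic gene
#'
#' @param n_exons number of exons
#' @param exon_lengths exon lengths in nt; the concatenated CDS must be a
#'   multiple of 3 and at least 9 nt (start + one sense codon + stop)
#' @param intron_lengths `n_exons - 1` intron lengths, each >= 4 nt
#'   (room for the GT...AG dinucleotides)
#' @param seed integer seed
#' @return object of class `gene_blueprint`
#' @export
gene_blueprint <- function(n_exons, exon_lengths, intron_lengths = integer(),
                           seed = 1L) {
  n_exons <- as.integer(n_exons)
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (n_exons < 1L || length(exon_lengths) != n_exons)
    stop("need n_exons exon lengths")
  if (length(intron_lengths) != n_exons - 1L)
    stop("need n_exons - 1 intron lengths")
  if (any(exon_lengths < 3L)) stop("exon lengths must be >= 3")
  if (sum(exon_lengths) %% 3L != 0L)
    stop("total CDS length must be a multiple of 3")
  if (sum(exon_lengths) < 9L) stop("total CDS length must be >= 9")
  if (any(intron_lengths < 4L)) stop("intron lengths must be >= 4")
  structure(list(n_exons = n_exons, exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths, seed = as.integer(seed)),
            class = "gene_blueprint")
}

#' Random gene blueprint with mammal-like two-exon architecture
#'
#' Exon lengths are multiples of 3 so that introns fall between codons
#' (phase-0), matching what the spliced aligner models.
#' @param seed integer seed
#' @param n_exons number of exons (default 2, the NK-class architecture)
#' @param exon_range,intron_range length ranges to draw from
#' @return [gene_blueprint()]
#' @export
random_gene_blueprint <- function(seed, n_exons = 2L,
                                  exon_range = c(90L, 450L),
                                  intron_range = c(60L, 400L)) {
  with_seed(seed, {
    ex <- 3L * sample(seq(exon_range[1] %/% 3L, exon_range[2] %/% 3L),
                      n_exons, replace = TRUE)
    it <- if (n_exons > 1L)
      sample(seq(intron_range[1], intron_range[2]), n_exons - 1L,
             replace = TRUE) else integer()
    gene_blueprint(n_exons, ex, it, seed = seed)
  })
}

#' Realize a gene from a blueprint
#'
#' Builds a locus sequence (exons interleaved with GT...AG introns) whose
#' spliced CDS begins `ATG`, contains no internal stop codon, and ends with
#' exactly one stop codon.
#'
#' @param blueprint [gene_blueprint()]
#' @param gene_id identifier for the model
#' @param chrom chromosome name used in the model
#' @return list with `model` ([gene_model()] anchored at position 0),
#'   `seq` (locus nucleotide string), `cds`, and `protein` (stop trimmed)
#' @export
make_gene <- function(blueprint, gene_id = "target", chrom = "locus") {
  stopifnot(inherits(blueprint, "gene_blueprint"))
  with_seed(blueprint$seed, {
    n_codons <- sum(blueprint$exon_lengths) %/% 3L
    cds <- paste0("ATG", random_sense_codons(n_codons - 2L),
                  sample(STOP_CODONS, 1L))
    introns <- vapply(blueprint$intron_lengths, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), character(1))
    pieces <- character(0)
    starts <- integer(blueprint$n_exons)
    pos <- 0L; cds_off <- 0L
    for (i in seq_len(blueprint$n_exons)) {
      w <- blueprint$exon_lengths[i]
      pieces <- c(pieces, substring(cds, cds_off + 1L, cds_off + w))
      starts[i] <- pos
      pos <- pos + w; cds_off <- cds_off + w
      if (i < blueprint$n_exons) {
        pieces <- c(pieces, introns[i])
        pos <- pos + blueprint$intron_lengths[i]
      }
    }
    ex <- genome_interval(chrom, starts, starts + blueprint$exon_lengths, "+")
    phase <- (3L - c(0L, cumsum(blueprint$exon_lengths))[
      seq_len(blueprint$n_exons)] %% 3L) %% 3L
    model <- gene_model(gene_id, paste0(gene_id, ".t1"), ex, phase)
    protein <- translate_cds(cds)
    protein <- sub("\\*$", "", protein)
    list(model = model, seq = paste(pieces, collapse = ""), cds = cds,
         protein = protein)
  })
}

#' Parameters for ortholog divergence
#'
#' @param sub_rate per-site substitution probability in `[0,1)`
#' @param indel_rate per-site indel initiation probability in `[0,1)`
#' @param indel_mean mean of the geometric indel-length distribution (>= 1)
#' @param constrained if `TRUE`, the purifying regime: whole-gene mutation
#'   sets that would inactivate the gene are rejected and resampled
#' @param seed integer seed
#' @param max_tries rejection-sampling cap for the constrained regime
#' @return object of class `evolution_params`
#' @export
evolution_params <- function(sub_rate = 0, indel_rate = 0, indel_mean = 2,
                             constrained = FALSE, seed = 1L,
                             max_tries = 10000L) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            indel_mean >= 1)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean = indel_mean, constrained = isTRUE(constrained),
                 seed = as.integer(seed), max_tries = as.integer(max_tries)),
            class = "evolution_params")
}

# Shift one boundary set under a deletion [p, p+L) or insertion of L before p.
shift_starts <- function(b, p, L, op) {
  if (op == "ins") ifelse(b >= p, b + L, b)
  else ifelse(b <= p, b, pmax(p, b - L))
}
shift_ends <- function(b, p, L, op) {
  if (op == "ins") ifelse(b > p, b + L, b)
  else ifelse(b <= p, b, pmax(p, b - L))
}

# Apply one indel to a sequence string and a gene model; drops exons that the
# deletion removed entirely.
apply_indel <- function(seq, model, p, L, op, insert = NULL) {
  n <- nchar(seq)
  if (op == "del") {
    seq <- paste0(substring(seq, 1L, p), substring(seq, p + L + 1L, n))
  } else {
    seq <- paste0(substring(seq, 1L, p), insert, substring(seq, p + 1L, n))
  }
  ex <- model$exons
  ex$start <- shift_starts(ex$start, p, L, op)
  ex$end <- shift_ends(ex$end, p, L, op)
  keep <- ex$end > ex$start
  if (!any(keep)) return(NULL)
  model$exons <- ex[keep, , drop = FALSE]
  if (!is.null(model$phase)) model$phase <- model$phase[keep]
  rownames(model$exons) <- NULL
  list(seq = seq, model = model)
}

apply_substitutions <- function(seq, pos, alt) {
  if (length(pos) == 0L) return(seq)
  v <- strsplit(seq, "")[[1]]
  v[pos + 1L] <- alt
  paste(v, collapse = "")
}

# One unconstrained mutation draw; returns seq, model, log.
mutate_once <- function(seq, model, params) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  sub_pos <- which(stats::runif(n) < params$sub_rate) - 1L
  alt <- character(length(sub_pos))
  if (length(sub_pos)) {
    for (k in seq_along(sub_pos)) {
      cur <- v[sub_pos[k] + 1L]
      alt[k] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  log_sub <- data.frame(type = rep("sub", length(sub_pos)), pos = sub_pos,
                        len = 1L,
                        ref = if (length(sub_pos)) v[sub_pos + 1L] else character(),
                        alt = alt, stringsAsFactors = FALSE)
  indel_pos <- which(stats::runif(n) < params$indel_rate) - 1L
  log_ind <- data.frame(type = character(), pos = integer(), len = integer(),
                        ref = character(), alt = character(),
                        stringsAsFactors = FALSE)
  if (length(indel_pos)) {
    op <- sample(c("del", "ins"), length(indel_pos), replace = TRUE)
    len <- 1L + stats::rgeom(length(indel_pos), prob = 1 / params$indel_mean)
    ord <- order(indel_pos, decreasing = TRUE)
    log_ind <- data.frame(type = op[ord], pos = indel_pos[ord], len = len[ord],
                          ref = "", alt = "", stringsAsFactors = FALSE)
  }
  seq <- apply_substitutions(seq, sub_pos, alt)
  for (k in seq_len(nrow(log_ind))) {
    p <- log_ind$pos[k]; L <- log_ind$len[k]; op <- log_ind$type[k]
    if (op == "del") L <- min(L, nchar(seq) - p)
    if (L <= 0L) next
    ins <- if (op == "ins") random_dna(L) else NULL
    log_ind$len[k] <- L
    log_ind$alt[k] <- if (op == "ins") ins else ""
    res <- apply_indel(seq, model, p, L, op, ins)
    if (is.null(res)) return(NULL)
    seq <- res$seq; model <- res$model
  }
  list(seq = seq, model = model,
       log = rbind(log_sub, log_ind))
}

#' Is a gene free of inactivating lesions?
#'
#' Checks the definitional intactness conditions: spliced CDS length a
#' multiple of 3, starts `ATG`, no internal stop codon, ends with a stop,
#' and every intron carries canonical `GT`/`AG` dinucleotides.
#' @param genome named character vector (or a bare locus string named as the
#'   model's chrom)
#' @param model [gene_model()]
#' @return logical
#' @export
is_gene_intact <- function(genome, model) {
  if (is.character(genome) && is.null(names(genome)))
    genome <- stats::setNames(genome, model$chrom)
  cds <- spliced_cds(genome, model)
  if (nchar(cds) < 9L || nchar(cds) %% 3L != 0L) return(FALSE)
  if (substring(cds, 1L, 3L) != "ATG") return(FALSE)
  aa <- translate_cds(cds)
  stars <- gregexpr("*", aa, fixed = TRUE)[[1]]
  if (length(stars) != 1L || stars[1] != nchar(aa)) return(FALSE)
  introns <- model_introns(model)
  chrom_seq <- genome[[model$chrom]]
  for (intr in introns) {
    if (oriented_dinuc(chrom_seq, intr$donor, model$strand) != "GT")
      return(FALSE)
    if (oriented_dinuc(chrom_seq, intr$acceptor, model$strand) != "AG")
      return(FALSE)
  }
  TRUE
}

#' Diverge a locus under a substitution/indel process
#'
#' Each site is substituted independently with probability `sub_rate` to a
#' uniformly chosen different base; indels initiate per site with probability
#' `indel_rate` and take geometric lengths.  In the constrained (purifying)
#' regime the whole mutation set is rejection-sampled until the gene remains
#' intact per [is_gene_intact()].
#'
#' @param seq locus nucleotide string
#' @param model [gene_model()] on that locus
#' @param params [evolution_params()]
#' @return list with `seq`, `model` (coordinate-adjusted), and `log`
#'   (data frame of events in pre-mutation coordinates)
#' @export
evolve <- function(seq, model, params) {
  stopifnot(inherits(params, "evolution_params"))
  with_seed(params$seed, {
    if (params$sub_rate == 0 && params$indel_rate == 0)
      return(list(seq = seq, model = model,
                  log = data.frame(type = character(), pos = integer(),
                                   len = integer(), ref = character(),
                                   alt = character())))
    for (try in seq_len(if (params$constrained) params$max_tries else 1L)) {
      res <- mutate_once(seq, model, params)
      if (is.null(res)) next
      if (!params$constrained ||
          is_gene_intact(stats::setNames(res$seq, model$chrom), res$model))
        return(res)
    }
    if (params$constrained)
      stop("constrained evolve(): no intact mutation set found in ",
           params$max_tries, " tries; lower the rates")
    res
  })
}

lesion_kinds <- c("frameshift", "nonsense", "splice_donor", "splice_acceptor",
                  "start_loss")

empty_lesion_table <- function() {
  data.frame(kind = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), exon_index = integer(),
             cds_offset = integer(), detail = character(),
             stringsAsFactors = FALSE)
}

# Canonical codon for a single frame change: the placement of the shift
# that maximizes the summed substitution score of the reference protein
# read against the post-edit CDS (codons before the placement in frame 0,
# the placed codon and everything after in the shifted frame; every codon
# scored against the 3-mer ending at its last consumed nt, the aligner's
# convention).  Ties go to the 5'-most placement.  Shared by the implanting
# truth recorder and the lesion caller so both report one coordinate for
# placements that the scoring model cannot distinguish (e.g. third-position
# wobble around the indel).
canonical_fs_codon <- function(ref_protein, cds_post, shift, mat = NULL) {
  if (is.null(mat)) mat <- aa_matrix()
  pv <- strsplit(ref_protein, "")[[1]]
  pv[pv == "U"] <- "X"
  n_aa <- length(pv)
  score_at <- function(j) {
    total <- 0
    for (i in seq_len(n_aa)) {
      idx <- i - 1L
      e <- if (idx < j) 3L * idx + 3L else 3L * idx + 3L + shift
      s <- e - 2L
      total <- total + if (s >= 1L && e <= nchar(cds_post))
        score_lookup(mat, pv[i], translate_cds(substring(cds_post, s, e)))
      else -10
    }
    total
  }
  sc <- vapply(0:(n_aa - 1L), score_at, numeric(1))
  which.max(sc) - 1L          # which.max takes the first (5'-most) maximum
}

#' Implant inactivating lesions with a recorded truth set
#'
#' Lesion specs are lists with a `kind` field:
#' \describe{
#'   \item{frameshift}{`exon` (1-based), `offset` (0-based nt offset within
#'     that exon), `op` (`"del"`/`"ins"`), `len` (1 or 2)}
#'   \item{nonsense}{`codon` (0-based CDS codon index, internal),
#'     `stop_codon` (default `"TGA"`)}
#'   \item{splice_donor / splice_acceptor}{`intron` (1-based)}
#'   \item{start_loss}{no extra fields (`ATG -> GTG`)}
#' }
#' Unspecified positions are drawn from `seed`.  The truth set records the
#' exact post-edit coordinates of each lesion; frameshift coordinates are
#' the start of the disrupted codon, canonicalized to the 5'-most
#' alignment-equivalent codon (the aligner's own convention).
#'
#' A nonsense spec 3' of a frameshift spec is rejected: downstream of a
#' frameshift the original frame no longer exists, so such a stop is not an
#' independent event.
#'
#' @param seq locus/chromosome nucleotide string
#' @param model [gene_model()] on `seq`
#' @param lesions list of lesion specs
#' @param seed integer seed for unspecified positions
#' @return list with `seq`, `model` (post-edit), and `truth` (data frame)
#' @export
implant_lesions <- function(seq, model, lesions, seed = 1L) {
  stopifnot(is.list(lesions), length(lesions) >= 1L)
  cds0 <- spliced_cds(stats::setNames(seq, model$chrom), model)
  n_codons <- nchar(cds0) %/% 3L
  protein0 <- sub("\\*$", "", translate_cds(cds0))
  widths <- interval_width(model$exons)
  cumw <- cumsum(c(0L, widths))
  with_seed(seed, {
    # resolve unspecified positions
    specs <- lapply(lesions, function(sp) {
      if (!sp$kind %in% lesion_kinds) stop("unknown lesion kind: ", sp$kind)
      if (sp$kind == "frameshift") {
        if (is.null(sp$exon)) sp$exon <- sample(nrow(model$exons), 1L)
        if (is.null(sp$len)) sp$len <- sample(1:2, 1L)
        if (is.null(sp$op)) sp$op <- sample(c("del", "ins"), 1L)
        if (sp$len %% 3L == 0L) stop("frameshift len must not be a multiple of 3")
        if (is.null(sp$offset)) {
          # exon-interior placements only: a shift within a few codons of a
          # splice junction (or of the CDS ends) is not identifiable from a
          # spliced alignment -- the junction can absorb it
          margin <- 15L
          lo <- margin
          hi <- widths[sp$exon] - sp$len - margin
          if (hi <= lo) stop("exon too short for frameshift implant")
          sp$offset <- sample(lo:(hi - 1L), 1L)
        }
        sp$cds_off <- cumw[sp$exon] + sp$offset
      } else if (sp$kind == "nonsense") {
        if (is.null(sp$codon)) {
          # premature range only: a stop past 95% of the protein is natural
          # stop drift by the classifier's own definition
          hi <- ceiling(0.95 * (n_codons - 1L)) - 1L
          sp$codon <- sample(seq(2L, hi), 1L)
        }
        if (sp$codon < 1L || sp$codon >= n_codons - 1L)
          stop("nonsense codon index must be internal")
        if (is.null(sp$stop_codon)) sp$stop_codon <- sample(STOP_CODONS, 1L)
        sp$cds_off <- 3L * sp$codon
      } else if (sp$kind %in% c("splice_donor", "splice_acceptor")) {
        if (nrow(model$exons) < 2L) stop("no introns for splice lesion")
        if (is.null(sp$intron)) sp$intron <- sample(nrow(model$exons) - 1L, 1L)
        sp$cds_off <- cumw[sp$intron + (sp$kind == "splice_acceptor")]
      } else sp$cds_off <- 0L
      sp
    })
    kinds <- vapply(specs, `[[`, character(1), "kind")
    offs <- vapply(specs, function(s) as.integer(s$cds_off), integer(1))
    if (any(kinds == "frameshift")) {
      fs_min <- min(offs[kinds == "frameshift"])
      if (any(kinds == "nonsense" & offs > fs_min))
        stop("incompatible lesion specs: nonsense implant 3' of a frameshift")
    }
    # guard against overlapping edits (codon granularity)
    touched <- unlist(lapply(specs, function(sp) {
      if (sp$kind %in% c("splice_donor", "splice_acceptor"))
        paste0("intr", sp$intron, substr(sp$kind, 8, 8))
      else paste0("cds", (sp$cds_off %/% 3L) + 0:1)
    }))
    if (anyDuplicated(touched))
      stop("overlapping lesion specs")

    # build genome-coordinate edits (substitutions and indels)
    chrom_seq <- seq
    subs_pos <- integer(); subs_alt <- character()
    set_cds_base <- function(off, base) {
      g <- cds_to_genome(model, off)
      b <- if (model$strand == "-") COMP[[base]] else base
      subs_pos <<- c(subs_pos, g); subs_alt <<- c(subs_alt, b)
    }
    indels <- list()
    introns <- model_introns(model)
    truth_rows <- list()
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      if (sp$kind == "frameshift") {
        gpos <- cds_to_genome(model, sp$cds_off)
        if (model$strand == "-") gpos <- gpos - sp$len + 1L
        ins <- if (sp$op == "ins") random_dna(sp$len) else NULL
        indels[[length(indels) + 1L]] <-
          list(pos = gpos, len = sp$len, op = sp$op, insert = ins, spec = si)
      } else if (sp$kind == "nonsense") {
        stop_nt <- strsplit(sp$stop_codon, "")[[1]]
        for (b in 0:2) set_cds_base(sp$cds_off + b, stop_nt[b + 1L])
        truth_rows[[si]] <- data.frame(
          kind = "nonsense", chrom = model$chrom,
          start = min(cds_to_genome(model, sp$cds_off + 0:2)),
          end = max(cds_to_genome(model, sp$cds_off + 0:2)) + 1L,
          strand = model$strand, exon_index = exon_index_of(
            model, cds_to_genome(model, sp$cds_off)),
          cds_offset = sp$cds_off,
          detail = paste0("codon ", sp$cds_off %/% 3L, " -> ", sp$stop_codon),
          stringsAsFactors = FALSE)
      } else if (sp$kind %in% c("splice_donor", "splice_acceptor")) {
        intr <- introns[[sp$intron]]
        din <- if (sp$kind == "splice_donor") intr$donor else intr$acceptor
        # mutate the G of GT / the G of AG, read in transcript orientation
        tpos <- if (sp$kind == "splice_donor") {
          if (model$strand == "+") din[1] else din[2] - 1L
        } else {
          if (model$strand == "+") din[2] - 1L else din[1]
        }
        alt <- if (model$strand == "-") "G" else "C"
        subs_pos <- c(subs_pos, tpos); subs_alt <- c(subs_alt, alt)
        truth_rows[[si]] <- data.frame(
          kind = sp$kind, chrom = model$chrom, start = din[1], end = din[2],
          strand = model$strand, exon_index = NA_integer_,
          cds_offset = NA_integer_,
          detail = paste0("intron ", sp$intron, " ",
                          sub("splice_", "", sp$kind), " dinucleotide lost"),
          stringsAsFactors = FALSE)
      } else { # start_loss
        set_cds_base(0L, "G")
        g <- cds_to_genome(model, 0:2)
        truth_rows[[si]] <- data.frame(
          kind = "start_loss", chrom = model$chrom, start = min(g),
          end = max(g) + 1L, strand = model$strand, exon_index = 1L,
          cds_offset = 0L, detail = "ATG -> GTG", stringsAsFactors = FALSE)
      }
    }
    # apply substitutions, then indels 3' -> 5'
    new_seq <- apply_substitutions(chrom_seq, subs_pos, subs_alt)
    new_model <- model
    if (length(indels)) {
      ord <- order(vapply(indels, `[[`, integer(1), "pos"), decreasing = TRUE)
      for (ind in indels[ord]) {
        res <- apply_indel(new_seq, new_model, ind$pos, ind$len, ind$op,
                           ind$insert)
        if (is.null(res)) stop("lesion implant destroyed the gene model")
        new_seq <- res$seq; new_model <- res$model
      }
      # post-edit coordinates: shift substitution-lesion rows past indels
      deltas <- vapply(indels, function(x)
        if (x$op == "ins") x$len else -x$len, integer(1))
      poss <- vapply(indels, `[[`, integer(1), "pos")
      for (qi in seq_along(truth_rows)) {
        tr <- truth_rows[[qi]]
        if (is.null(tr)) next
        tr$start <- tr$start + sum(deltas[poss < tr$start])
        tr$end <- tr$end + sum(deltas[poss < tr$end])
        truth_rows[[qi]] <- tr
      }
      cds_post <- spliced_cds(stats::setNames(new_seq, model$chrom), new_model)
      for (qi in seq_along(indels)) {
        ind <- indels[[qi]]; sp <- specs[[ind$spec]]
        shift0 <- (if (sp$op == "ins") sp$len else -sp$len)
        kc <- canonical_fs_codon(protein0, cds_post, shift0)
        # the guard above used the raw implant codon; the canonical
        # placement can slide 5' onto an implanted stop, in which case the
        # two events are not separable and the spec set is incompatible
        nonsense_codons <- vapply(specs[kinds == "nonsense"], `[[`,
                                  numeric(1), "codon")
        if (length(nonsense_codons) && any(nonsense_codons >= kc))
          stop("incompatible lesion specs: nonsense implant 3' of a ",
               "frameshift (canonical placement)")
        gstart <- cds_to_genome(new_model, 3L * kc)
        truth_rows[[ind$spec]] <- data.frame(
          kind = "frameshift", chrom = model$chrom, start = gstart,
          end = gstart + 1L, strand = model$strand,
          exon_index = exon_index_of(new_model, gstart),
          cds_offset = 3L * kc,
          detail = paste0(sp$op, sp$len, " (shift ",
                          ifelse(shift0 > 0, "+", ""), shift0, ")"),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, c(list(empty_lesion_table()), truth_rows))
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(seq = new_seq, model = new_model, truth = truth)
  })
}

#' Assemble a chromosome from ordered marker genes and a target locus
#'
#' Marker loci are auto-generated intact single-copy genes; the supplied
#' target locus (typically lesioned or diverged) is inserted at the position
#' its id occupies in `marker_order`.  Genes are separated by random
#' intergenic spacers.
#'
#' @param marker_order character vector of gene ids in chromosomal order;
#'   must contain the target's gene id with at least two markers on each side
#'   if synteny anchoring is intended (not enforced here)
#' @param target list with `seq` and `model` (as from [make_gene()] or
#'   [implant_lesions()]); `NULL` to build a marker-only chromosome
#' @param intergenic length-2 vector, uniform range for spacer lengths
#' @param seed integer seed
#' @param chrom chromosome name
#' @return list with `genome` (named character vector of one chromosome),
#'   `models` (list of [gene_model()]), and `target_span` (interval or NULL)
#' @export
assemble_genome <- function(marker_order, target = NULL,
                            intergenic = c(500L, 2000L), seed = 1L,
                            chrom = "chr1") {
  target_id <- if (!is.null(target)) target$model$gene_id else NA_character_
  with_seed(seed, {
    pieces <- character(); pos <- 0L
    models <- list(); target_span <- NULL
    spacer <- function() random_dna(sample(intergenic[1]:intergenic[2], 1L))
    sp <- spacer(); pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    for (gid in marker_order) {
      if (!is.na(target_id) && gid == target_id) {
        g <- target
      } else {
        g <- make_gene(random_gene_blueprint(sample.int(2^30, 1L)),
                       gene_id = gid, chrom = chrom)
      }
      m <- g$model
      m$chrom <- chrom
      m$exons$chrom <- chrom
      m$exons$start <- m$exons$start + pos
      m$exons$end <- m$exons$end + pos
      models[[gid]] <- m
      if (!is.na(target_id) && gid == target_id)
        target_span <- genome_interval(chrom, pos, pos + nchar(g$seq),
                                       m$strand)
      pieces <- c(pieces, g$seq); pos <- pos + nchar(g$seq)
      sp <- spacer(); pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    }
    list(genome = stats::setNames(paste(pieces, collapse = ""), chrom),
         models = models, target_span = target_span)
  })
}

#' Parameters for read simulation
#'
#' @param weights named nonnegative vector, gene_id -> expression weight
#' @param noise_rate fraction of reads placed uniformly on the genome
#'   (the transcriptional-noise component)
#' @param read_length read length in nt
#' @param n_reads total reads in the library (`library_total` of the output)
#' @param seed integer seed
#' @return object of class `read_sim_params`
#' @export
read_sim_params <- function(weights, noise_rate = 0.01, read_length = 100L,
                            n_reads = 1e5L, seed = 1L) {
  stopifnot(all(weights >= 0), noise_rate >= 0, noise_rate <= 1,
            read_length >= 1, n_reads >= 0)
  if (all(weights == 0) && noise_rate == 0)
    stop("all weights zero and noise_rate 0: nothing to sample")
  structure(list(weights = weights, noise_rate = noise_rate,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate a mapped-read library for one tissue
#'
#' `round(noise_rate * n_reads)` reads are placed uniformly over the genome;
#' the rest are drawn from annotated transcripts with probability
#' proportional to `weight * transcript_length`, with start positions uniform
#' over within-exon placements.  Reads are single-end, fixed-length,
#' error-free intervals.
#'
#' @param genome named character vector of chromosome sequences
#' @param models list of [gene_model()]
#' @param params [read_sim_params()]
#' @return [read_set()] with `library_total = n_reads`
#' @export
simulate_reads <- function(genome, models, params) {
  stopifnot(inherits(params, "read_sim_params"))
  rl <- params$read_length
  glen <- nchar(genome)
  if (any(rl >= glen)) stop("read_length must be shorter than every chromosome")
  with_seed(params$seed, {
    n_noise <- round(params$noise_rate * params$n_reads)
    n_tx <- params$n_reads - n_noise
    w <- params$weights
    ids <- names(w)[w > 0]
    ids <- ids[ids %in% names(models)]
    out <- list()
    if (n_tx > 0L && length(ids)) {
      txlen <- vapply(ids, function(g) sum(interval_width(models[[g]]$exons)),
                      numeric(1))
      pr <- w[ids] * txlen
      gene_draw <- sample(ids, n_tx, replace = TRUE, prob = pr)
      tab <- table(gene_draw)
      for (g in names(tab)) {
        m <- models[[g]]
        ex <- m$exons
        slots <- pmax(interval_width(ex) - rl + 1L, 0L)
        if (sum(slots) == 0L) {
          # exons shorter than the read: place a clipped read on the exon
          ei <- sample(nrow(ex), tab[[g]], replace = TRUE)
          out[[length(out) + 1L]] <- data.frame(
            chrom = m$chrom, start = ex$start[ei], end = ex$end[ei],
            strand = "+", stringsAsFactors = FALSE)
        } else {
          ei <- sample(nrow(ex), tab[[g]], replace = TRUE, prob = slots)
          st <- ex$start[ei] +
            floor(stats::runif(tab[[g]]) * slots[ei])
          out[[length(out) + 1L]] <- data.frame(
            chrom = m$chrom, start = as.integer(st),
            end = as.integer(st + rl), strand = "+", stringsAsFactors = FALSE)
        }
      }
    } else if (n_tx > 0L && length(ids) == 0L) {
      # silenced library: transcript share contributes nothing mappable;
      # those fragments are unsequenced but still count in library_total
      n_tx <- 0L
    }
    if (n_noise > 0L) {
      slots <- glen - rl + 1L
      ch <- sample(names(genome), n_noise, replace = TRUE, prob = slots)
      st <- floor(stats::runif(n_noise) * slots[ch])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = as.integer(st), end = as.integer(st + rl),
        strand = "+", stringsAsFactors = FALSE)
    }
    reads <- if (length(out)) do.call(rbind, out) else NULL
    if (!is.null(reads)) {
      reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
      rownames(reads) <- NULL
    }
    read_set(reads, params$n_reads)
  })
}

#' Write a lesion truth set as JSON
#' @param truth lesion truth data frame (from [implant_lesions()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lesion_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
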