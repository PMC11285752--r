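---
title: "vestigr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vestigr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
made where the design was genuinely open.  It states no empirical result
that the test suite does not itself compute.

# The problem

A gene lost in one lineage leaves a relict: a locus still recognisable by
conserved gene order and sequence remnants, but carrying inactivating
lesions (frameshifts, premature stops, broken splice sites, a lost start)
and showing no expression above background transcription.  `vestigr`
operationalises this as four stages — synteny anchoring, exon-model
reconstruction, lesion classification, expression evidence — feeding one
decision table.

# Coordinates

All internal coordinates are 0-based half-open on the forward strand.
Conversion to the 1-based inclusive convention happens only in
`read_gtf()`/`write_gtf()`; BED shares the internal convention.  This keeps
every off-by-one in two functions, both covered by round-trip tests.

# Synteny anchoring

Markers are matched by identical `gene_id` (ortholog calling is out of
scope).  `find_anchor_chain()` computes the longest strictly increasing
subsequence of the query markers' reference ranks — the largest marker set
in the same relative order in both genomes.  Among equal-length chains the
one with lexicographically earliest reference positions is returned, for
determinism.  Inversions are deliberately not chained: the use case is a
compact conserved block, and a simple collinear model keeps the exhaustive
oracle (all permutations up to n = 7) feasible.  `candidate_interval()` is
plain arithmetic between the two anchor gene bodies, strand-agnostic.

# The spliced aligner

`spliced_align()` is a local (Smith–Waterman-style) dynamic programme of a
reference protein against genomic DNA with four state families:

* **M** — residue *i* aligned to a DNA chunk of 1, 2, 3, 4 or 5 nt ending
  at position *j*.  Chunks of length ≠ 3 are frameshifts (shift −2, −1,
  +1, +2) and pay one flat frameshift penalty.  Every chunk is scored as
  the substitution score of the residue against the 3-mer *ending at j*,
  which gives frameshifted codons a well-defined (if approximate) score.
* **Dg** — a gap in the protein: one codon of DNA consumed with no
  residue; affine.
* **Pg** — a gap in the DNA: one residue consumed with no DNA; affine.
* **Intr** — an intron skip of at least `min_intron` nt between two codon
  states, for a flat intron-open penalty.

Defaults: BLOSUM62, gap open −11, extend −1, frameshift −15, intron open
−20, `min_intron` 30 nt.  These are the conventional protein-alignment
values; the frameshift penalty is required (and asserted) to be strictly
worse than a gap extension.  The DP is vectorised over the DNA axis; the
affine protein-gap recurrence runs as three stride-3 cumulative-maximum
chains and the intron state as a lagged cumulative maximum, so the whole
table is O(m·n).

Traceback is deterministic: ties prefer match > frameshift > gap > intron,
which pushes frameshifts to their 5′-most equivalent position, and the
shortest intron is taken on intron ties.  `alignment_score_from_ops()`
recomputes the score from the traceback operations as a self-consistency
check, and the test suite proves score-optimality against exhaustive
enumeration on small instances.

**Introns are modelled between codons (phase 0).**  A phase-1/2 intron is
absorbed as a frameshift next to the junction instead.  The simulator's
default architectures use exon lengths that are multiples of 3, so this
assumption is exact within the package's stated world; on real loci with
phase-1/2 introns the reconstruction would flag a spurious junction
frameshift — a known limitation.

# Canonical frameshift coordinates

An indel inside a codon is often not identifiable at single-base
resolution: because of third-position wobble, absorbing the shift one
codon later can read to the same amino acids (or even score better).  Both
the simulator's truth recorder and the lesion caller therefore report the
*canonical* position: the placement of the frame change that maximises the
summed substitution score of the reference protein against the observed
CDS, 5′-most on ties.  Truth and call compute this independently from the
same definition, so the exact-coordinate recovery test is meaningful: it
verifies that the aligner localises the event to the same disrupted codon
the implant produced.

Two related identifiability limits shape the simulator defaults:

* a frameshift within ~5 codons of a splice junction or CDS terminus can
  be absorbed by shifting the junction at lower cost than the frameshift
  penalty, so auto-drawn implants stay ≥ 15 nt inside exons;
* a nonsense codon at or 3′ of a frameshift's canonical placement is not a
  separable event (the frame it was defined in no longer exists there);
  `implant_lesions()` rejects such spec sets as incompatible.

# Exon-model inference

Alignment blocks seed the exons; if more blocks than `expected_exons`
(default 2, the NK-class architecture) survive, the closest pair is merged.
Internal boundaries snap to the nearest `GT` donor / `AG` acceptor within
`snap_window` (default 12 nt; 0 disables); a boundary with no canonical
dinucleotide nearby is kept raw and flagged, never forced.  The 5′ end is
pulled back over any unaligned leading residues to an in-frame `ATG`; the
3′ end runs out the unaligned tail and takes in the stop codon if one sits
in frame.  Per-exon alignment support is attached so downstream code can
flag weakly supported (degraded) exons.

# Lesion classification

`reconstruct_orf()` splices the exon model (strand-aware), translates from
the first codon, and records internal stops.  A stop is *premature* only
before 95% of the reference protein length — natural stop-codon drift in
the last few percent is not an inactivating event.  `classify_lesions()`
then reports, sorted by genome position:

* every alignment frameshift (canonical coordinates, with any induced
  downstream stop cross-referenced in the detail — one event, not two);
* every premature stop not explained by an upstream frameshift;
* every intron whose donor is not `GT` or acceptor not `AG`;
* a non-`ATG` first codon.

`intact` is definitionally equivalent to an empty lesion table, and the
suite tests that equivalence on simulated genes.

# Percent identity

`percent_identity()` counts identical columns over aligned columns,
including gap columns, excluding terminal overhangs (the alignment is
ends-free).  When no positive-scoring overlap exists — conceptual
translations of heavily frameshifted relicts can be that diverged — it
falls back to a forced global alignment rather than reporting a missing
value; truly empty input still yields `NA`.  Symmetry is guaranteed by
canonicalising the argument order.  `U` and `X` match only themselves.

# Expression evidence

RPKM is C·10⁹/(N·L) with C the reads overlapping the exon union by ≥ 1 bp
(each read once), N the library's mapped-read total, L the exon-union
length in bp; zero counts give exactly zero.  TPM rescales length-
normalised rates to sum to 10⁶.  Reported RPKM is rounded to 3 decimals.

The null for transcriptional noise is built from random intergenic
regions.  They are **structure-matched**: one independently placed
intergenic piece per exon of the feature, with the exon's length.  With
the ≥ 1 bp overlap rule, each fragment contributes an extra read-length
window of eligible read starts, so a contiguous region of merely matched
union length systematically undercounts the null (about 20% for a
two-exon, 363 bp feature with 100 bp reads) and silenced features drift
above it.

`expression_call()`: *expressed* requires TPM > 0.5 **and** RPKM above the
0.95 empirical quantile (type 1, so attainable values with ties) of the
null; RPKM at or below the quantile is *noise*; the remainder (above the
null but sub-threshold TPM) is *ambiguous*.  The null must contain at
least 20 regions (default 100).

# The simulator's stated world

* **Genes**: `ATG` + random sense codons + one stop, split into exons
  joined by `GT…AG` introns; default two-exon, 222 + 141 nt CDS (~120 aa),
  mammal-scale introns.
* **Divergence**: independent per-site substitution to a uniformly chosen
  different base (so expected identity is 1 − p, the test oracle);
  geometric indels (mean 2 nt).  The purifying regime rejection-samples
  whole mutation sets until the gene stays intact; the neutral regime
  accumulates everything.
* **Reads**: single-end, fixed-length, error-free intervals; transcript
  reads placed uniformly within exons in proportion to weight × transcript
  length, plus a uniform genome-wide noise fraction (default 1%).
* **Scale**: the demo chromosome is ~0.9 Mb with 1e5-read (demo: 5e4)
  libraries, chosen so a silenced 363 bp feature collects 0–2 noise reads —
  the magnitude real tissue panels show at 5·10⁷-read scale.  Computed TPM
  over a 9-feature annotation is structurally inflated relative to a full
  transcriptome (TPM per read ≈ 10⁶/N_reads for same-length features), so
  the simulated "moderately expressed" gene is realized at source-scale
  *depth* (~45 expected transcript reads) rather than at a literal
  computed TPM of 5, which at this annotation size would mean half a read
  and would be undetectable at any library size.

What the generator does **not** emulate: sequencing error, mapping
ambiguity and multi-mapping, paired ends, coverage biases, codon-level
selection (dN/dS), real intron phase diversity, and transcriptome-scale
annotations.  A green test therefore establishes correctness of the
algorithms under the stated statistical structure, not performance on real
libraries.

# Determinism

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state (`with_seed()`), so identical configuration yields
byte-identical FASTA/GTF/BED/JSON outputs; the suite checks this for the
generator and the report writer.  All alignment and classification code is
deterministic including tie-breaks.

# Known limitations

* Phase-0 intron model in the aligner (above).
* Frameshift coordinates are codon-canonical, not base-exact, by
  identifiability; multiple frameshifts in one gene are classified but
  only single-frameshift placements are canonicalised against truth.
* The intergenic null assumes noise is uniform; structured noise (e.g.
  unannotated transcription) would require a larger annotation or an
  explicit mask.
* `candidate_interval` assumes both anchors land on one query chromosome;
  split assemblies surface as an anchoring error, by design.
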