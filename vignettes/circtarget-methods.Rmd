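---
title: "circtarget: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circtarget: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay being modelled

Targeted circularization turns selected restriction fragments of genomic
DNA into sequencing-ready circles in one reaction. After complete digestion
(MseI, `T^TAA`, by default), a splint capture oligonucleotide hybridizes
both ends of a chosen single-stranded fragment via two 20-nt targeting
arms; a universal vector oligo, complementary to the adapter-bearing common
region between the arms, is ligated between the fragment ends to close the
circle. The captured strand's 3' end must align perfectly on a restriction
cut; the 5' end may sit interior to the fragment, because the resulting 5'
flap is cleaved by the polymerase during circularization. Sequencing yields
fragment-end reads that begin exactly at the target sites, which makes
per-oligo yield directly countable from alignments.

`circtarget` implements the computational workflow around this chemistry:
digestion, oligo design and QC, full-length sequence assembly, capture/read
simulation, and performance analytics. It deliberately does not model the
wet-lab steps themselves (ligation kinetics, purification, gel extraction,
flow-cell chemistry) nor genome-scale probe precomputation.

## Coordinate and strand conventions

All internal coordinates are 0-based half-open (the BED convention); BED is
ingested verbatim, SAM positions are converted at the boundary, and nothing
else converts. An oligo's `strand` is the strand of its on-target
fragment-end read: `"+"` oligos are anchored at the *left* cut of their
fragment (reads run rightward from the cut), `"-"` oligos at the *right*
cut (reads run leftward). The biologically captured strand is the opposite
one; arm sequences are stored as reference-strand substrings and
complemented only at assembly. This convention makes the evaluator's
tagging rule a pure coordinate match: a read is an on-target fragment-end
read iff its alignment start equals a left-anchored region boundary or its
alignment end equals a right-anchored one (slack configurable, default 0 —
the tag-counting definition is an exact fragment-end match, and no
tolerance is stated for the assay, so exactness is the default rather than
a guess).

## Design rules and their defaults

`design_config()` centralizes every tunable; nothing is hard-coded
elsewhere.

* **Arms**: 20 nt (`arm_length`), the target-specific site length.
* **Anchoring**: the 3'-end arm sits exactly on a cut; flap-style 5' ends
  are enumerated at a 50-base stride (`flap_stride`) rather than
  exhaustively, bounding candidate counts while sampling the circle-size
  range. The exact flap policy used in practice is not specified by the
  assay description, so it is config, not dogma.
* **Circle size**: flagged outside 200–600 bases (`circle_min`/`max`),
  rejected outright above 800 (`circle_hard_max`). These encode the
  empirically observed optimum (robust capture at 200–600 bases; failure or
  low yield above, with 0.8 kb as the practical limit — an observed 1.1-kb
  target failed outright).
* **Arm G+C**: flagged outside 30–60% (`gc_min`/`gc_max`), the observed
  optimal annealing window at 55–60 °C hybridization.
* **SNP avoidance**: any supplied variant position inside either arm flags
  the candidate. Whether masking should be restricted to SNVs is
  unspecified upstream; the package masks every supplied position, which is
  conservative and puts the policy in the caller's hands.
* **Repeat screening**: the original assay screened arms against
  genome-wide repeats, paralogs and Alu consensus — resources with no
  operational definition here. The package substitutes three measurable
  proxies, each independently switchable: exact arm k-mer multiplicity in
  the supplied reference (both strands, palindromes counted once;
  `max_kmer_hits`), soft-masked fraction (> 0.5 flags; softmasking is
  retained from lowercase FASTA precisely for this), and homopolymer runs
  (≥ 8 flags). Same intent, testable without external databases.
* **Selection**: strict mode keeps flag-free candidates only; permissive
  mode rescues flagged (never hard-rejected) candidates for fragments that
  would otherwise be uncovered, mirroring design-with-redundancy practice.
  The preference order — fewer flags, mean arm G+C nearest 0.45, circle
  size nearest the window midpoint, leftmost, id — is total, so manifests
  are byte-reproducible.

`tile_region()` restricts itself to full-fragment circles so consecutive
tiles share cut boundaries; a fragment with no passing candidate is a
reported gap, not a silent hole.

## Assembly

Assembled capture oligos are `armA + forward(58) + reverse(61) + armB`,
with `armA` complementary to the captured strand's 3'-end site and `armB`
to its 5'-end site; the vector is the reverse complement of the common
region, 119 nt with defaults. Note the component arithmetic gives
20+58+61+20 = 159 even though the assay description quotes 158; the package
asserts the arithmetic identity (the 119-nt vector = 58+61 complement
supports it) and documents the discrepancy rather than reproducing it. The
real adapter component sequences are not public; the bundled defaults are
clearly-labelled synthetic placeholders of the correct lengths, because the
algorithmics depend on lengths and structure, not vendor sequences. Uracil
substitution (10 T→U, used in the assay for post-circularization
fragmentation of the splints) is deterministic: Ts of the common region at
evenly spaced T-ranks `ceiling(nT * i/10)`; only the count is specified
upstream, so the placement rule is the package's own, chosen for
reproducibility. Arms are never modified. End-blocking chemistry is
metadata, not sequence.

## The simulator: what it emulates, and what it does not

`make_synthetic_reference()` builds contigs in which restriction sites are
*planted* (exact fragment-length lists, or exponential spacing clamped to
50–1500 bases) and every accidental recognition site is scrubbed by
single-base edits, so digestion is fully controlled. Known-variant
positions, and duplicated soft-masked 20-mers for the repeat proxies, are
planted and recorded. Everything is byte-reproducible per seed.

`capture_yield()` is the package's own parameterization of effects that are
reported qualitatively upstream but never fitted: yield =
`S(size) · G(gc3) · G(gc5)` with `S` a decreasing logistic (half-max 600
bases, steepness 40 bases, hard zero beyond 1.2 kb) and `G` a plateau on
[0.30, 0.60] with logistic shoulders of width 0.05, the low-G+C shoulder
scaled by `55/temperature` so higher hybridization temperature penalizes
poorly annealing low-G+C arms more. The defaults were chosen once so the
qualitative patterns emerge (robust 200–600-base plateau, failure of
1.1-kb circles, temperature-dependent G+C window); nothing is fitted to any
measured count. The real assay's large-circle failure confounds
circularization, PCR bias and cluster formation; the simulator lumps them
into the single size term.

`simulate_reads()` draws capture events multinomially (∝ yield, times a
per-oligo log-normal factor of σ = 0.8 when PCR is on — the mechanism
behind amplification skew), plus uniform off-target genomic reads and
adapter-derived contaminant reads (defaults 10% and 2%). Reads are the
first 42 bases from the anchored fragment end (both ends, mate 2
reverse-complemented, in paired mode). One deliberate choice: off-target
reads are re-sampled if their endpoints would coincide exactly with an
on-target anchor, because such a read is *definitionally* a fragment-end
tag — leaving it labelled off-target would make the truth table wrong, not
the evaluator. Base-call errors are uniform substitutions at a configurable
rate (default 0); quality strings are constant, since quality modelling is
not the point. Because reads are error-free relative to their source
coordinates, the truth table doubles as an exact aligner's output and is
exported as SAM (`write_sam()`), standing in for the external aligner the
evaluator normally consumes.

A green simulation-based test therefore establishes that the analytics
recover what the generative model planted — it says nothing about library
chemistry, alignment ambiguity in real repetitive genomes, or sequencer
error profiles, none of which the generator emulates.

## Evaluation analytics

Target regions extend 42 bases (the read length) from each target site into
the fragment; single-read mode uses only the 3'-anchored end, paired mode
both. Region unions are deduplicated for base counting but not for
per-oligo attribution; reads matching a site shared by two oligos go to the
lexicographically first id, deterministically. Coverage is a per-base
pileup over the region union from on-target reads, reported at 1× and 30×
and as mean fold coverage; duplicates are not collapsed (raw tag counts).
The uniformity curve sorts per-oligo counts and divides by the median
count. Classification marks zero-count oligos `failed` and the top
`ceiling(0.25 · n)` non-failed by count `high` (the fraction generalizes
the observed 25-of-107 split; an absolute `high_n` is available for
fidelity). Yield correlates report Spearman rho of yield vs circle size
(undefined below n = 5, raw p-values, single planned test) and mean yield
by G+C bin with each oligo contributing its high- and low-G+C arm
separately.

Two published target-base totals for the paired-end accounting (8,778 vs
8,904) are mutually inconsistent and underdetermined without the original
oligo set; the package documents its counting rule (region-union bases)
and reproduces neither number. The single-end rule is, however, checked for
shape consistency: 105 non-overlapping anchored sites × 42 bases = 4,410
target bases.

## Numerical and degenerate-input choices

* Digestion is top-strand only; the enzyme constructor therefore *requires*
  palindromic recognition sequences (exact for MseI; non-palindromic
  enzymes would need both-strand scanning, which is out of scope and
  refused loudly rather than silently wrong). Ambiguity codes are likewise
  refused; `N` in the reference never matches a site (no cut inside
  ambiguous sequence).
* Fragments shorter than two arms yield no candidates (recorded, not an
  error); an all-flagged fragment in strict mode is a reported uncovered
  target.
* `uniformity_curve()` errors on all-zero or zero-median counts instead of
  emitting infinities.
* A region wider than its circle is clipped to the fragment with a warning.
* The uracil rule substitutes all Ts with a warning when fewer than 10 are
  available.
* One seed governs every stochastic stage of `run_end_to_end()`; no stage
  seeds itself, and outputs embed the config hash.

## Known limitations

No melting-temperature thermodynamics, cross-oligo hybridization, partial
digestion, methylation sensitivity, chimera formation, duplicate marking or
variant calling; alignment itself is upstream (the bundled SAM writer is a
truth-table stand-in, not an aligner). Genome-scale probe-database
regeneration is explicitly out of scope: the design algorithm is the
deliverable, not the precomputed resource.
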