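# circtarget

Design and in-silico evaluation of **targeted-circularization sequencing
assays**.

In this class of assay, genomic DNA is digested with a restriction
endonuclease (MseI, `T^TAA`, is the built-in), and single-stranded splint
**capture oligonucleotides** circularize chosen restriction fragments: each
oligo carries two 20-nt **targeting arms** complementary to the two ends of
its target fragment, flanking a common region made of inverted sequencing
adapter components (58 + 61 nt). A universal 119-nt **vector
oligonucleotide**, complementary to that common region, is ligated between
the fragment ends, completing a sequencing-ready circle in a single
reaction. Only the captured strand's 3' end must sit exactly on a
restriction site; a displaced 5' end forms a flap that is cleaved during
circularization. Sequencing the circles produces 42-base **fragment-end
reads** whose first bases coincide with the target sites, so each read can
be attributed to the oligo that captured it.

`circtarget` implements the computational side of this assay end to end:

| stage | functions |
|---|---|
| in-silico digestion | `enzyme()`, `mse_i()`, `find_sites()`, `digest_reference()` |
| oligo design + QC | `design_config()`, `enumerate_candidates()`, `apply_qc()`, `select_oligos()`, `tile_region()`, `roi_coverage()` |
| sequence assembly | `adapter_set()`, `assemble_oligos()`, `build_vector()`, `uracil_substitute()` |
| capture/read simulation | `sim_config()`, `make_synthetic_reference()`, `capture_yield()`, `simulate_reads()` |
| performance analytics | `ingest_alignments()`, `build_target_regions()`, `tag_reads()`, `coverage_metrics()`, `uniformity_curve()`, `classify_performance()`, `yield_correlates()`, `capture_report()` |
| pipeline / CLI | `run_end_to_end()`, `demo_config()`, `cli_main()` |

Design QC enforces the empirically optimal capture windows: circle size
200–600 bases (hard rejection above 0.8 kb), per-arm G+C 30–60%, SNP-free
arms, and three repeat proxies (exact arm k-mer multiplicity, softmask
fraction, homopolymer runs). The simulator's yield model is
`S(size) × G(gc_arm1) × G(gc_arm2)` — a decreasing logistic in circle size
(half-max 600 bases, zero beyond 1.2 kb) times a plateau window in arm G+C
whose low-G+C shoulder sharpens with hybridization temperature — with
optional per-oligo log-normal PCR amplification skew.

## Worked example

The demo pipeline builds a synthetic genome with 107 planted restriction
fragments spanning 210–590 bases, designs capture oligos over it, assembles
them, simulates a capture experiment (10% off-target reads, 2% adapter
contamination, PCR on, 25 planted zero-yield oligos), and evaluates the
resulting alignments:

```r
library(circtarget)
res <- run_end_to_end(demo_config(7, total_reads = 20000L),
                      out_dir = "demo_run")
print(res$report)
#> CaptureReport
#>   total reads          20000
#>   mapped reads         19604
#>   on-target reads      17682
#>   off-target reads     1922 (9.8% of mapped)
#>   target bases         4284
#>   bases at >=1x        3234
#>   bases at >=30x       3150
#>   mean fold coverage   173.4
#>   classification       failed 25, high 26, moderate 51
res$report$correlates$size_cor
#> $rho [1] -0.591   $p_value [1] 6.17e-11   $n [1] 102
```

Reading the numbers: 102 of the 107 fragments produced a passing oligo
(`target bases` = 102 × 42); the evaluator recovers the configured 10%
off-target rate from the alignments alone; exactly the 25 planted
zero-yield oligos are classified `failed` and their 25 × 42 target bases
stay uncovered; and per-oligo yield falls significantly with circle size
(negative Spearman rho), as the size term of the yield model dictates.

All artifacts (reference FASTA, oligo manifest TSV, oligo/vector FASTA,
FASTQ, SAM, truth table, JSON/TSV reports) are written under `out_dir`,
each stamped with the config hash; identical seeds reproduce identical
bytes.

The same pipeline is exposed on the command line:

```sh
inst/scripts/circtarget end-to-end --seed 7 --out demo_run
inst/scripts/circtarget design --reference ref.fa --roi panel.bed \
    --snps known.vcf --out mypanel
```

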