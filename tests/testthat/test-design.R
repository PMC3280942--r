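# A small designable world shared by several blocks: 5 fragments of known
# sizes with GC-conditioned end arms (see helper).
design_world <- local({
  ref <- make_tiling_contig(c(250, 400, 300, 550, 260), seed = 21)
  frags <- digest_reference(ref, list(mse_i()))
  roi <- list(contig = "tile1", start = 0, end = sum(contig_lengths(ref)))
  list(ref = ref, frags = frags, roi = roi)
})

test_that("enumeration matches brute force and the anchoring invariant", {
  w <- design_world
  cfg <- design_config()
  cand <- enumerate_candidates(w$ref, w$frags, w$roi, cfg)
  orc <- oracle_enumerate(w$frags, w$roi, cfg)
  got <- cand[order(cand$frag_id, cand$strand, cand$flap_offset),
              c("frag_id", "strand", "flap_offset", "circle_start",
                "circle_end")]
  rownames(got) <- rownames(orc) <- NULL
  expect_equal(got, orc)
  # anchoring: the 3'-arm's anchored edge coincides with a digest boundary
  plus <- cand$strand == "+"
  expect_true(all(cand$circle_start[plus] %in% w$frags$start))
  expect_true(all(cand$circle_end[!plus] %in% w$frags$end))
  # flap displacement shrinks the circle by exactly the offset
  expect_equal(cand$circle_size,
               (cand$frag_end - cand$frag_start) - cand$flap_offset)
  # arms never overlap
  expect_true(all(cand$circle_size >= 2 * cfg$arm_length))
})

test_that("fragments shorter than two arms yield no candidates", {
  ref <- reference(c(s = paste0(strrep("C", 29), "TTAA", strrep("G", 200))))
  frags <- digest_reference(ref, list(mse_i())) # first fragment length 30
  cand <- enumerate_candidates(ref, frags, list(contig = "s", start = 0,
                                                end = 30), design_config())
  expect_equal(nrow(cand), 0)
})

test_that("snp_filter respects half-open arm bounds", {
  w <- design_world
  cand <- enumerate_candidates(w$ref, w$frags, w$roi, design_config())
  c1 <- cand[1, ]
  inside <- data.frame(contig = "tile1", pos = c1$arm3_start)
  outside <- data.frame(contig = "tile1", pos = c1$arm3_end) # 1 past the arm
  expect_true(snp_filter(c1, inside))
  expect_false(snp_filter(c1, outside))
  expect_false(any(snp_filter(cand, NULL)))
})

test_that("uniqueness_filter flags planted duplicates, softmask, runs", {
  set.seed(5)
  base <- rand_dna(400)
  arm <- substr(base, 101, 120)
  dup <- paste0(base, strrep("C", 30), arm, strrep("G", 30))
  ref <- reference(c(d = dup))
  cand <- data.frame(oligo_id = "x", contig = "d",
                     arm3_start = 100, arm3_end = 120,
                     arm5_start = 200, arm5_end = 220,
                     arm3_seq = arm, arm5_seq = substr(base, 201, 220),
                     stringsAsFactors = FALSE)
  uf <- uniqueness_filter(cand, ref, design_config())
  expect_true(uf$nonunique)
  # brute-force hit-count oracle agrees on both arms
  expect_gt(oracle_kmer_hits(arm, ref$seqs), 1)
  expect_equal(oracle_kmer_hits(cand$arm5_seq, ref$seqs), 1)
  # softmask flag from lowercase source FASTA
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">m", paste0(tolower(substr(base, 1, 120)),
                            substr(base, 121, 400))), f)
  mref <- load_reference(f)
  cand2 <- cand
  cand2$contig <- "m"
  cand2$arm3_seq <- toupper(cand2$arm3_seq)
  uf2 <- uniqueness_filter(cand2, mref, design_config())
  expect_true(uf2$softmasked)
  # homopolymer boundary: an 8-run flags at max_homopolymer = 8
  cand3 <- cand
  cand3$arm5_seq <- paste0("AAAAAAAA", "CGTCGTCGTCGT")
  expect_true(uniqueness_filter(cand3, ref, design_config())$homopolymer)
  cand3$arm5_seq <- paste0("AAAAAAA", "CGTCGTCGTCGTC")
  uf3 <- uniqueness_filter(cand3, ref, design_config())
  expect_false(uf3$homopolymer)
})

test_that("size and GC windows flag and hard-reject as specified", {
  cand <- make_fake_manifest(4, c(400, 700, 1100, 400))
  cand$gc3 <- c(0.5, 0.5, 0.5, 0.05)
  sg <- size_gc_filter(cand, design_config())
  expect_equal(sg$size_out_of_range, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(sg$gc_out_of_range, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sg$rejected, c(FALSE, FALSE, TRUE, FALSE)) # only > 800
})

test_that("selection is deterministic, tie-broken by GC, with full audit", {
  w <- design_world
  cfg <- design_config()
  cand <- apply_qc(enumerate_candidates(w$ref, w$frags, w$roi, cfg),
                   w$ref, cfg)
  sel <- select_oligos(cand, cfg, "strict")
  expect_true(all(sel$selected$n_flags == 0))
  expect_equal(nrow(sel$selected) + nrow(sel$rejected), nrow(cand))
  expect_true(all(nzchar(sel$rejected$reasons)))
  # redundancy cap honoured per fragment
  expect_true(all(table(sel$selected$frag_id) <= cfg$redundancy))
  # GC tie-break: among flag-free candidates of one fragment, the kept one
  # has mean arm GC at least as close to 0.45 as any dropped flag-free one
  for (fid in unique(sel$selected$frag_id)) {
    kept <- sel$selected[sel$selected$frag_id == fid, ]
    pool <- cand[cand$frag_id == fid & cand$n_flags == 0 & !cand$rejected, ]
    if (nrow(pool) < 2 || min(pool$n_flags) > 0) next
    expect_lte(min(abs((kept$gc3 + kept$gc5) / 2 - 0.45)),
               min(abs((pool$gc3 + pool$gc5) / 2 - 0.45)) + 1e-12)
  }
  # byte-identical manifests on identical input
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_manifest(select_oligos(cand, cfg, "strict")$selected, f1)
  write_manifest(select_oligos(cand, cfg, "strict")$selected, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("strict mode reports uncovered targets; permissive rescues", {
  cand <- make_fake_manifest(2, 400)
  cand$frag_id <- c("f1", "f1")
  cand$n_flags <- c(1L, 2L)
  cand$flags <- c("gc_out_of_range", "gc_out_of_range,snp_overlap")
  cand$rejected <- FALSE
  strict <- select_oligos(cand, design_config(), "strict")
  expect_equal(nrow(strict$selected), 0)
  perm <- select_oligos(cand, design_config(), "permissive")
  expect_equal(perm$selected$oligo_id, "syn_001") # fewer flags preferred
})

test_that("tile_region tiles adjacent fragments and reports gaps", {
  w <- design_world
  tl <- tile_region(w$ref, w$frags, w$roi, design_config())
  expect_equal(nrow(tl$tiles), 5)
  expect_equal(nrow(tl$gaps), 0)
  # adjacency: shared cut boundaries between consecutive circles
  expect_equal(tl$tiles$circle_start[-1], tl$tiles$circle_end[-5])
  # ROI inside a single fragment -> a single tile
  one <- tile_region(w$ref, w$frags,
                     list(contig = "tile1", start = 260, end = 300),
                     design_config())
  expect_equal(nrow(one$tiles), 1)
})

test_that("roi_coverage fractions are exact interval arithmetic", {
  sel <- make_fake_manifest(2, c(400, 500))
  rois <- data.frame(contig = "simM",
                     start = c(sel$circle_start[1] + 10, 0),
                     end = c(sel$circle_start[1] + 110, 1000))
  cov <- roi_coverage(sel, rois)
  expect_equal(cov$per_roi$fraction[1], 1.0) # fully inside a circle
  # circles [100,500) and [600,1100) intersected with [0,1000): 400 + 400
  covered2 <- (sel$circle_end[1] - sel$circle_start[1]) +
    (1000 - sel$circle_start[2])
  expect_equal(cov$per_roi$covered_bases[2], covered2)
  none <- roi_coverage(sel[0, ], rois)
  expect_equal(none$per_roi$fraction, c(0, 0))
})
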