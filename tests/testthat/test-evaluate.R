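test_that("target regions extend from the anchored cut into the fragment", {
  m <- data.frame(oligo_id = "o1", contig = "c", strand = "+",
                  circle_start = 1000L, circle_end = 1400L,
                  circle_size = 400L, stringsAsFactors = FALSE)
  r <- build_target_regions(m, 42, "single")
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1000, 1042))
  expect_equal(r$anchor_pos, 1000)
  rp <- build_target_regions(m, 42, "paired")
  expect_equal(nrow(rp), 2) # both fragment ends in paired mode
  expect_setequal(rp$end_label, c("three_prime", "five_prime"))
  expect_equal(rp$start[rp$end_label == "five_prime"], 1400 - 42)
  # region clipped (with warning) when the circle is shorter than a read
  short <- m; short$circle_end <- 1030L; short$circle_size <- 30L
  expect_warning(rs <- build_target_regions(short, 42, "single"), "clipped")
  expect_equal(rs$end - rs$start, 30)
})

test_that("SAM ingestion counts mapped/unmapped and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".sam")
  seq42 <- strrep("A", 42); q42 <- strrep("I", 42)
  recs <- c(
    lapply(1:8, function(i)
      c(paste0("r", i), 0, "c1", 1001, 60, "42M", "*", 0, 0, seq42, q42)),
    lapply(9:10, function(i)
      c(paste0("r", i), 4, "*", 0, 0, "*", "*", 0, 0, seq42, q42))
  )
  write_mini_sam(f, c(c1 = 10000L), recs)
  rec <- ingest_alignments(f)
  expect_equal(sum(rec$mapped), 8)
  expect_equal(sum(!rec$mapped), 2)
  expect_equal(unique(rec$start[rec$mapped]), 1000) # POS 1001 -> 0-based
  expect_equal(unique(rec$end[rec$mapped]), 1042)
  # header-only SAM -> all-zero report
  write_mini_sam(f, c(c1 = 10000L), list())
  empty <- ingest_alignments(f)
  expect_equal(nrow(empty), 0)
  # missing @SQ lines are an error
  writeLines("@HD\tVN:1.6", f)
  expect_error(ingest_alignments(f), "header contigs")
})

test_that("tagging matches anchored fragment ends with slack semantics", {
  m <- make_fake_manifest(5, 300, strand = c("+", "-"))
  regions <- build_target_regions(m, 42, "single")
  mk <- function(start, contig = "simM")
    data.frame(read_id = sprintf("x%d", seq_along(start)), mapped = TRUE,
               contig = contig, start = start, end = start + 42L,
               strand = "+", mate = 1L, stringsAsFactors = FALSE)
  # 80 reads on anchors, 20 elsewhere
  anchors_left <- regions$anchor_pos[regions$anchor_side == "left"]
  rec <- mk(c(rep(anchors_left, length.out = 80), rep(7L, 20)))
  tags <- tag_reads(rec, regions)
  expect_equal(sum(tags$labels$on_target), 80)
  expect_equal(sum(tags$per_oligo$count), 80)
  # start 3 bases inside: off at slack 0, on at slack 5
  inside <- mk(anchors_left[1] + 3L)
  expect_false(tag_reads(inside, regions, slack = 0)$labels$on_target)
  expect_true(tag_reads(inside, regions, slack = 5)$labels$on_target)
  # right-anchored ("-") oligos match on the read end
  ar <- regions[regions$anchor_side == "right", ][1, ]
  rrec <- mk(ar$anchor_pos - 42L)
  rt <- tag_reads(rrec, regions)
  expect_true(rt$labels$on_target)
  expect_identical(rt$labels$oligo_id, ar$oligo_id)
})

test_that("shared-site attribution is deterministic (first oligo id)", {
  m <- make_fake_manifest(2, 300)
  m$circle_start <- c(100L, 100L); m$circle_end <- c(400L, 400L)
  regions <- build_target_regions(m, 42, "single")
  rec <- data.frame(read_id = "r", mapped = TRUE, contig = "simM",
                    start = 100L, end = 142L, strand = "+", mate = 1L)
  tags <- tag_reads(rec, regions)
  expect_identical(tags$labels$oligo_id, "syn_001")
})

test_that("coverage metrics equal a naive per-base pileup", {
  m <- make_fake_manifest(3, 300)
  regions <- build_target_regions(m, 42, "single")
  # one exact region read: 42 bases at 1x, none at 30x
  one <- data.frame(read_id = "a", mapped = TRUE, contig = "simM",
                    start = regions$start[1], end = regions$start[1] + 42L,
                    strand = "+", mate = 1L)
  lab1 <- tag_reads(one, regions)$labels
  cm <- coverage_metrics(one, regions, lab1)
  expect_equal(cm$target_bases, 3 * 42)
  expect_equal(unname(cm$bases_at["1"]), 42)
  expect_equal(unname(cm$bases_at["30"]), 0)
  # 30 identical reads: 42 bases at both thresholds, mean depth 10 over all
  thirty <- do.call(rbind, replicate(30, one, simplify = FALSE))
  thirty$read_id <- sprintf("a%d", 1:30)
  lab30 <- tag_reads(thirty, regions)$labels
  cm30 <- coverage_metrics(thirty, regions, lab30)
  expect_equal(unname(cm30$bases_at["30"]), 42)
  expect_equal(cm30$mean_coverage, 30 * 42 / (3 * 42))
  # random on-target reads vs the pileup oracle
  set.seed(14)
  starts <- sample(regions$anchor_pos, 200, replace = TRUE)
  rnd <- data.frame(read_id = sprintf("r%d", 1:200), mapped = TRUE,
                    contig = "simM", start = starts, end = starts + 42L,
                    strand = "+", mate = 1L)
  lab <- tag_reads(rnd, regions)$labels
  cmr <- coverage_metrics(rnd, regions, lab)
  depth <- oracle_pileup(starts, starts + 42L, max(regions$end) + 50L)
  tgt <- unlist(Map(function(s, e) (s + 1L):e, regions$start, regions$end))
  expect_equal(unname(cmr$bases_at["1"]), sum(depth[tgt] >= 1))
  expect_equal(unname(cmr$bases_at["30"]), sum(depth[tgt] >= 30))
  expect_equal(cmr$mean_coverage, mean(depth[tgt]))
})

test_that("uniformity curve is sorted, median-normalized, guarded", {
  expect_equal(uniformity_curve(c(0, 10, 20)), c(0, 1, 2))
  expect_equal(uniformity_curve(rep(7, 5)), rep(1, 5))
  expect_error(uniformity_curve(c(0, 0, 0)), "zero")
})

test_that("classification partitions failed/moderate/high by rank", {
  lab <- classify_performance(c(0, 0, 5, 9, 100, 120),
                              ids = sprintf("o%d", 1:6),
                              high_fraction = 1 / 3)
  expect_equal(unname(table(lab)[c("failed", "high", "moderate")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
  expect_identical(unname(lab[c("o5", "o6")]), c("high", "high"))
  expect_true(all(classify_performance(c(0, 0, 0)) == "failed"))
  # absolute-count option
  lab2 <- classify_performance(1:10, high_n = 3)
  expect_equal(sum(lab2 == "high"), 3)
})

test_that("yield correlates: monotone, null and GC-window behaviour", {
  sizes <- seq(100, 1090, by = 10)
  dec <- rev(seq_along(sizes)) # strictly size-decreasing yields
  gcs <- data.frame(gc3 = rep(0.45, 100), gc5 = rep(0.45, 100))
  yc <- yield_correlates(dec, sizes, gcs)
  expect_equal(yc$size_cor$rho, -1)
  # size-independent yields: small correlation, p > 0.05 at n = 100
  set.seed(2024)
  null_y <- rpois(100, 50)
  ycn <- yield_correlates(null_y, sample(sizes), gcs)
  expect_lt(abs(ycn$size_cor$rho), 0.2)
  expect_gt(ycn$size_cor$p_value, 0.05)
  # GC-window yields: the 30-60% bin out-yields the outside bins
  gc <- runif(100, 0.05, 0.95)
  gcs2 <- data.frame(gc3 = gc, gc5 = gc)
  y <- ifelse(gc >= 0.3 & gc <= 0.6, 100, 5) + rpois(100, 3)
  t2 <- yield_correlates(y, sizes, gcs2)$gc_table
  mid <- t2$mean_yield[t2$bin == "0.30-0.60"]
  out <- t2$mean_yield[t2$bin != "0.30-0.60"]
  expect_true(all(mid > out, na.rm = TRUE))
  # undefined below n = 5
  expect_true(is.na(yield_correlates(1:4, 1:4,
    data.frame(gc3 = rep(.4, 4), gc5 = rep(.4, 4)))$size_cor$rho))
})

test_that("capture_report conserves read accounting end to end", {
  manifest <- make_fake_manifest(30, 350, strand = c("+", "-"))
  ref <- fake_manifest_reference(manifest, seed = 20)
  cfg <- sim_config(seed = 3, total_reads = 3000L, off_target_rate = 0.12,
                    adapter_read_rate = 0.03)
  sim <- simulate_reads(manifest, ref, cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim, ref, sam)
  rec <- ingest_alignments(sam)
  rep <- capture_report(rec, manifest, read_length = 42, mode = "single")
  expect_equal(rep$total_reads, 3000)
  expect_equal(rep$on_target_reads + rep$off_target_reads, rep$mapped_reads)
  expect_equal(rep$mapped_reads + sum(!rec$mapped), rep$total_reads)
  expect_true(rep$bases_at["30"] <= rep$bases_at["1"])
  expect_true(rep$bases_at["1"] <= rep$target_bases)
  # attribution completeness on error-free reads
  truth_counts <- table(factor(
    sim$truth$oligo_id[sim$truth$class == "on_target"],
    levels = rep$per_oligo$oligo_id))
  expect_identical(rep$per_oligo$count, as.integer(truth_counts))
  expect_equal(sum(rep$per_oligo$count), rep$on_target_reads)
})
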