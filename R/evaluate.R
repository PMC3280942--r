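# Capture-performance analytics from alignments: target-region construction,
# on/off-target fragment-end tagging, coverage thresholds, median-normalized
# uniformity, failed/moderate/high classification and size/G+C yield
# correlates.

#' Build on-target fragment-end regions from a manifest
#'
#' Each region extends `read_length` bases from an oligo's target-specific
#' site boundary into the captured fragment. Single-read mode produces only
#' the 3'-anchored end's region; paired mode both ends. A region wider than
#' its circle is clipped with a warning. Regions of different oligos may
#' overlap; base counting deduplicates them, per-oligo attribution does not.
#'
#' @param manifest Oligo manifest with `oligo_id, contig, strand,
#'   circle_start, circle_end`.
#' @param read_length Read length defining the region width (default 42).
#' @param mode `"single"` or `"paired"`.
#' @return data.frame `oligo_id, end_label, contig, start, end, anchor_side,
#'   anchor_pos` where `anchor_side` says which region edge sits on the
#'   fragment end (`left` = reads start there, `right` = reads end there).
#' @export
build_target_regions <- function(manifest, read_length = 42L,
                                 mode = c("single", "paired")) {
  mode <- match.arg(mode)
  RL <- as.integer(read_length)
  if (any(manifest$circle_size < RL))
    warning("read_length exceeds some circle sizes; regions clipped")
  w <- pmin(RL, manifest$circle_end - manifest$circle_start)
  plus <- manifest$strand == "+"
  three <- data.frame(
    oligo_id = manifest$oligo_id, end_label = "three_prime",
    contig = manifest$contig,
    start = ifelse(plus, manifest$circle_start, manifest$circle_end - w),
    end = ifelse(plus, manifest$circle_start + w, manifest$circle_end),
    anchor_side = ifelse(plus, "left", "right"),
    stringsAsFactors = FALSE
  )
  out <- three
  if (mode == "paired") {
    five <- data.frame(
      oligo_id = manifest$oligo_id, end_label = "five_prime",
      contig = manifest$contig,
      start = ifelse(plus, manifest$circle_end - w, manifest$circle_start),
      end = ifelse(plus, manifest$circle_end, manifest$circle_start + w),
      anchor_side = ifelse(plus, "right", "left"),
      stringsAsFactors = FALSE
    )
    out <- rbind(three, five)
  }
  out$anchor_pos <- ifelse(out$anchor_side == "left", out$start, out$end)
  out[order(out$oligo_id, out$end_label), ]
}

#' @noRd
cigar_ref_width <- function(cigar) {
  # reference-consumed width of a CIGAR (M/D/N/=/X ops)
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0L, USE.NAMES = FALSE)
}

#' Ingest alignments from SAM or BAM
#'
#' SAM files are converted with [Rsamtools::asBam()]; coordinates are
#' converted from SAM's 1-based to the package's 0-based half-open
#' convention. Unmapped records are retained with `mapped = FALSE`.
#'
#' @param path SAM (`.sam`) or BAM path.
#' @return data.frame `read_id, mapped, contig, start, end, strand, mate`.
#' @export
ingest_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (length(hdr$targets) == 0)
    stop("missing header contigs (@SQ) in ", path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- bitwAnd(b$flag, 4L) == 0L
  mate <- ifelse(bitwAnd(b$flag, 128L) > 0L, 2L, 1L)
  rw <- cigar_ref_width(ifelse(is.na(b$cigar), "*", b$cigar))
  start <- ifelse(mapped, b$pos - 1L, NA_integer_)
  data.frame(
    read_id = b$qname, mapped = mapped,
    contig = ifelse(mapped, as.character(b$rname), NA_character_),
    start = start, end = start + rw,
    strand = ifelse(mapped, as.character(b$strand), NA_character_),
    mate = mate, stringsAsFactors = FALSE
  )
}

#' Tag reads as on/off-target and attribute per-oligo yields
#'
#' A mapped read is an on-target fragment-end read iff its alignment start
#' coincides with a left-anchored region boundary, or its alignment end with
#' a right-anchored one, within `slack` bases (default 0: exact fragment-end
#' match). Reads are attributed to the matching oligo; a read matching two
#' oligos' shared site goes to the lexicographically first oligo id.
#'
#' @param records Alignment records ([ingest_alignments()]).
#' @param regions Target regions ([build_target_regions()]).
#' @param slack Matching tolerance in bases (default 0).
#' @return List with `labels` (`read_id, on_target, oligo_id` for mapped
#'   reads) and `per_oligo` (`oligo_id, count`, zero rows included, ordered
#'   by oligo id).
#' @export
tag_reads <- function(records, regions, slack = 0L) {
  regions <- regions[order(regions$oligo_id), ]
  lmap <- regions[regions$anchor_side == "left", ]
  rmap <- regions[regions$anchor_side == "right", ]
  lookup <- function(map, keypos) {
    keys <- paste(map$contig, map$anchor_pos)
    first <- !duplicated(keys) # lexicographically first oligo id per key
    setNames(map$oligo_id[first], keys[first])[keypos]
  }
  m <- records[records$mapped, , drop = FALSE]
  hit <- rep(NA_character_, nrow(m))
  for (d in seq.int(-slack, slack)) {
    lk <- lookup(lmap, paste(m$contig, m$start + d))
    rk <- lookup(rmap, paste(m$contig, m$end + d))
    cand <- ifelse(!is.na(lk), lk, rk) # left anchor wins deterministic ties
    hit <- ifelse(is.na(hit), cand, hit)
  }
  labels <- data.frame(read_id = m$read_id, on_target = !is.na(hit),
                       oligo_id = hit, stringsAsFactors = FALSE)
  ids <- sort(unique(regions$oligo_id))
  tab <- table(factor(hit[!is.na(hit)], levels = ids))
  per_oligo <- data.frame(oligo_id = ids, count = as.integer(tab),
                          stringsAsFactors = FALSE)
  list(labels = labels, per_oligo = per_oligo)
}

#' Per-base coverage metrics over the target regions
#'
#' Depth is computed over the deduplicated union of target regions from
#' on-target reads only; reports bases reaching each threshold and the mean
#' depth over all target bases.
#'
#' @param records Alignment records.
#' @param regions Target regions.
#' @param labels Output of [tag_reads()] (`$labels`); identifies on-target
#'   reads.
#' @param thresholds Depth thresholds (default `c(1, 30)`).
#' @return List `target_bases`, `bases_at` (named by threshold), and
#'   `mean_coverage`.
#' @export
coverage_metrics <- function(records, regions, labels,
                             thresholds = c(1L, 30L)) {
  on_ids <- labels$read_id[labels$on_target]
  reads <- records[records$mapped & records$read_id %in% on_ids, ,
                   drop = FALSE]
  contigs <- unique(regions$contig)
  target_bases <- 0L
  bases_at <- setNames(numeric(length(thresholds)), thresholds)
  depth_sum <- 0
  for (cn in contigs) {
    rg <- regions[regions$contig == cn, ]
    tgt <- IRanges::reduce(IRanges::IRanges(rg$start + 1L, rg$end))
    target_bases <- target_bases + sum(IRanges::width(tgt))
    rd <- reads[reads$contig == cn, ]
    w <- max(c(IRanges::end(tgt), rd$end, 1L))
    cov <- IRanges::coverage(IRanges::IRanges(rd$start + 1L, rd$end),
                             width = w)
    v <- IRanges::Views(cov, tgt)
    depths <- unlist(lapply(v, function(x) as.integer(x)), use.names = FALSE)
    depth_sum <- depth_sum + sum(as.numeric(depths))
    for (j in seq_along(thresholds))
      bases_at[j] <- bases_at[j] + sum(depths >= thresholds[j])
  }
  list(target_bases = target_bases, bases_at = bases_at,
       mean_coverage = if (target_bases > 0) depth_sum / target_bases
                       else NA_real_)
}

#' Median-normalized uniformity curve
#'
#' Per-oligo counts sorted ascending and divided by the median count; flatter
#' curves mean more even capture.
#'
#' @param counts Per-oligo read counts (at least one nonzero).
#' @return Sorted numeric vector with median 1 (odd n).
#' @export
uniformity_curve <- function(counts) {
  if (length(counts) == 0 || all(counts == 0))
    stop("uniformity_curve: all per-oligo counts are zero")
  med <- median(counts)
  if (med == 0) stop("uniformity_curve: median count is zero")
  sort(counts) / med
}

#' Classify oligo performance from yields
#'
#' `failed` = zero count; `high` = the top `ceiling(high_fraction * n)` by
#' count among non-failed oligos (ties broken by oligo id; an absolute count
#' can be given via `high_n`); the rest are `moderate`.
#'
#' @param counts Per-oligo counts.
#' @param ids Oligo ids (tie-break and naming).
#' @param high_fraction Fraction of all oligos ranked high (default 0.25).
#' @param high_n Optional absolute number of high performers (overrides the
#'   fraction).
#' @return Character vector of labels, named by `ids`.
#' @export
classify_performance <- function(counts, ids = names(counts),
                                 high_fraction = 0.25, high_n = NULL) {
  n <- length(counts)
  if (is.null(ids)) ids <- sprintf("oligo_%05d", seq_len(n))
  lab <- rep("moderate", n)
  lab[counts == 0] <- "failed"
  nonfailed <- which(counts > 0)
  k <- if (!is.null(high_n)) high_n else ceiling(high_fraction * n)
  k <- min(k, length(nonfailed))
  if (k > 0) {
    ord <- nonfailed[order(-counts[nonfailed], ids[nonfailed])]
    lab[ord[seq_len(k)]] <- "high"
  }
  setNames(lab, ids)
}

#' Yield correlates: circle size and arm G+C
#'
#' Spearman rank correlation of per-oligo yield against circle size, and mean
#' yield by arm-G+C bin, with each oligo contributing its high-G+C and
#' low-G+C arm separately. Correlation is undefined (`NA`) below n = 5.
#'
#' @param counts Per-oligo yields, aligned with `circle_sizes` and `arm_gcs`.
#' @param circle_sizes Circle sizes (bases).
#' @param arm_gcs data.frame/list with `gc3`, `gc5` per oligo.
#' @return List with `size_cor` (`rho, p_value, n`) and `gc_table`
#'   (mean/median yield per G+C bin for high- and low-G+C arms).
#' @export
yield_correlates <- function(counts, circle_sizes, arm_gcs) {
  n <- length(counts)
  size_cor <- if (n < 5) {
    list(rho = NA_real_, p_value = NA_real_, n = n)
  } else {
    ct <- suppressWarnings(
      cor.test(counts, circle_sizes, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
  }
  hi <- pmax(arm_gcs$gc3, arm_gcs$gc5)
  lo <- pmin(arm_gcs$gc3, arm_gcs$gc5)
  breaks <- c(-Inf, 0.30, 0.60, Inf)
  bin_names <- c("gc<0.30", "0.30-0.60", "gc>0.60")
  gc_table <- do.call(rbind, lapply(
    list(high_gc_arm = hi, low_gc_arm = lo), function(g) {
      b <- cut(g, breaks, labels = bin_names, right = TRUE)
      data.frame(bin = bin_names,
                 n = as.integer(table(factor(b, bin_names))),
                 mean_yield = vapply(bin_names, function(x)
                   if (any(b == x)) mean(counts[b == x]) else NA_real_,
                   0),
                 stringsAsFactors = FALSE)
    }))
  gc_table$arm <- rep(c("high_gc_arm", "low_gc_arm"), each = 3)
  rownames(gc_table) <- NULL
  list(size_cor = size_cor, gc_table = gc_table)
}

#' Full capture report
#'
#' Assembles the summary analytics for one experiment: read accounting
#' (mapped, on-target fragment-end reads, off-target as a fraction of
#' mapped), target-base coverage at thresholds, mean on-target fold coverage,
#' per-oligo yields, uniformity, classification, and size/G+C correlates.
#'
#' @param records Alignment records ([ingest_alignments()]).
#' @param manifest Oligo manifest.
#' @param read_length Read length (default 42).
#' @param mode `"single"` or `"paired"`.
#' @param slack On-target matching tolerance (default 0).
#' @param thresholds Coverage thresholds (default `c(1, 30)`).
#' @param high_fraction Fraction for [classify_performance()].
#' @return An object of class `CaptureReport` (a list; see fields).
#' @export
capture_report <- function(records, manifest, read_length = 42L,
                           mode = c("single", "paired"), slack = 0L,
                           thresholds = c(1L, 30L), high_fraction = 0.25) {
  mode <- match.arg(mode)
  regions <- build_target_regions(manifest, read_length, mode)
  tags <- tag_reads(records, regions, slack)
  total <- nrow(records)
  mapped <- sum(records$mapped)
  on_target <- sum(tags$labels$on_target)
  off_target <- mapped - on_target
  cov <- coverage_metrics(records, regions, tags$labels, thresholds)
  counts <- setNames(tags$per_oligo$count, tags$per_oligo$oligo_id)
  m <- manifest[match(tags$per_oligo$oligo_id, manifest$oligo_id), ]
  structure(list(
    total_reads = total, mapped_reads = mapped,
    on_target_reads = on_target, off_target_reads = off_target,
    off_target_fraction_of_mapped = if (mapped > 0) off_target / mapped
                                    else NA_real_,
    target_bases = cov$target_bases, bases_at = cov$bases_at,
    mean_on_target_coverage = cov$mean_coverage,
    per_oligo = tags$per_oligo,
    uniformity = if (any(counts > 0) && median(counts) > 0)
      uniformity_curve(counts) else NULL,
    classification = classify_performance(counts, names(counts),
                                          high_fraction),
    correlates = yield_correlates(unname(counts), m$circle_size,
                                  m[, c("gc3", "gc5")]),
    regions = regions
  ), class = "CaptureReport")
}

#' @export
print.CaptureReport <- function(x, ...) {
  cat("CaptureReport\n")
  cat(sprintf("  total reads          %d\n", x$total_reads))
  cat(sprintf("  mapped reads         %d\n", x$mapped_reads))
  cat(sprintf("  on-target reads      %d\n", x$on_target_reads))
  cat(sprintf("  off-target reads     %d (%.1f%% of mapped)\n",
              x$off_target_reads,
              100 * x$off_target_fraction_of_mapped))
  cat(sprintf("  target bases         %d\n", x$target_bases))
  for (t in names(x$bases_at))
    cat(sprintf("  bases at >=%sx        %d\n", t, as.integer(x$bases_at[[t]])))
  cat(sprintf("  mean fold coverage   %.1f\n", x$mean_on_target_coverage))
  cls <- table(x$classification)
  cat("  classification      ",
      paste(names(cls), as.integer(cls), collapse = ", "), "\n")
  invisible(x)
}

#' Write a CaptureReport as JSON and TSV
#' @param report A [capture_report()].
#' @param prefix Output path prefix (writes `<prefix>.json`,
#'   `<prefix>_per_oligo.tsv`).
#' @param comment Optional comment line for the TSV (e.g. config hash).
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, prefix, comment = NULL) {
  js <- paste0(prefix, ".json")
  summary <- report[c("total_reads", "mapped_reads", "on_target_reads",
                      "off_target_reads", "off_target_fraction_of_mapped",
                      "target_bases", "mean_on_target_coverage")]
  summary$bases_at <- as.list(report$bases_at)
  summary$size_cor <- report$correlates$size_cor
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  tsv <- paste0(prefix, "_per_oligo.tsv")
  po <- report$per_oligo
  po$classification <- report$classification[po$oligo_id]
  write_manifest(po, tsv, comment = comment)
  invisible(c(js, tsv))
}
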