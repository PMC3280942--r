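# Capture-oligo design: candidate enumeration under the anchoring rule (the
# arm at the captured 3' end sits exactly on a restriction cut), QC filters
# (SNP overlap, arm uniqueness / softmask / homopolymer, circle size, arm GC),
# deterministic selection, tiling and ROI coverage accounting.
#
# Strand convention (used package-wide): an oligo's `strand` is the strand of
# its on-target fragment-end read. "+" oligos are anchored at the LEFT cut of
# the fragment (read extends rightwards from the cut); "-" oligos at the RIGHT
# cut (read extends leftwards). Arm sequences are stored as reference-strand
# substrings; complementation is deferred to assembly.

#' Design configuration
#'
#' Defaults encode the empirically optimal capture windows: circle size
#' 200-600 bases (hard failure limit 0.8 kb) and arm G+C between 30 and 60%.
#'
#' @param arm_length Targeting-arm length in nt (default 20).
#' @param circle_min,circle_max Soft circle-size window in bases (flag
#'   outside).
#' @param circle_hard_max Circles larger than this are rejected outright, not
#'   merely flagged (default 800).
#' @param gc_min,gc_max Per-arm G+C window (fractions).
#' @param max_kmer_hits Maximum number of genomic occurrences (both strands)
#'   an arm sequence may have before it is flagged non-unique (default 1, the
#'   arm's own locus).
#' @param max_homopolymer Flag arms containing a single-base run of at least
#'   this length (default 8).
#' @param softmask_max_fraction Flag arms with more than this fraction of
#'   soft-masked bases (repeat proxy; default 0.5).
#' @param flap_stride Spacing in bases between successive 5'-flap candidate
#'   offsets within a fragment (default 50).
#' @param redundancy Maximum selected oligos per fragment (default 1).
#' @return An object of class `DesignConfig`.
#' @export
design_config <- function(arm_length = 20L, circle_min = 200L,
                          circle_max = 600L, circle_hard_max = 800L,
                          gc_min = 0.30, gc_max = 0.60,
                          max_kmer_hits = 1L, max_homopolymer = 8L,
                          softmask_max_fraction = 0.5,
                          flap_stride = 50L, redundancy = 1L) {
  stopifnot(arm_length > 0,
            0 < circle_min, circle_min < circle_max,
            circle_max <= circle_hard_max,
            0 <= gc_min, gc_min < gc_max, gc_max <= 1,
            flap_stride > 0, redundancy >= 1)
  structure(list(arm_length = as.integer(arm_length),
                 circle_min = as.integer(circle_min),
                 circle_max = as.integer(circle_max),
                 circle_hard_max = as.integer(circle_hard_max),
                 gc_min = gc_min, gc_max = gc_max,
                 max_kmer_hits = as.integer(max_kmer_hits),
                 max_homopolymer = as.integer(max_homopolymer),
                 softmask_max_fraction = softmask_max_fraction,
                 flap_stride = as.integer(flap_stride),
                 redundancy = as.integer(redundancy)),
            class = "DesignConfig")
}

#' Enumerate capture-oligo candidates for a region of interest
#'
#' For every fragment overlapping `roi` and each strand, emits the candidate
#' whose 3'-end arm is anchored exactly at a restriction cut boundary of the
#' fragment, plus flap-style candidates whose 5'-end arm is displaced interior
#' to the fragment at multiples of `cfg$flap_stride` (the displaced 5'
#' overhang is cleaved during circularization, so only one end needs a
#' restriction site). `circle_size` is the distance from the 5'-arm start to
#' the anchored cut — the post-cleavage circle. Fragments shorter than
#' `2 * arm_length` yield no candidates.
#'
#' @param ref A [reference()].
#' @param frags A [digest_reference()] table.
#' @param roi One-row data.frame/list with `contig, start, end`.
#' @param cfg A [design_config()].
#' @return Candidate manifest: one row per candidate with fragment, arm and
#'   circle coordinates, arm sequences (reference strand) and per-arm G+C.
#' @export
enumerate_candidates <- function(ref, frags, roi, cfg = design_config()) {
  stopifnot(inherits(cfg, "DesignConfig"))
  al <- cfg$arm_length
  ov <- fragments_overlapping(frags, roi)
  rows <- list()
  for (i in seq_len(nrow(ov))) {
    fr <- ov[i, ]
    if (fr$length < 2L * al) next
    for (strand in c("+", "-")) {
      anchored <- if (strand == "+") fr$left_kind == "cut_site"
                  else fr$right_kind == "cut_site"
      if (!anchored) next
      offsets <- seq.int(0L, fr$length - 2L * al, by = cfg$flap_stride)
      for (k in offsets) {
        if (strand == "+") {
          circle_start <- fr$start
          circle_end <- fr$end - k
          arm3 <- c(circle_start, circle_start + al)
          arm5 <- c(circle_end - al, circle_end)
        } else {
          circle_start <- fr$start + k
          circle_end <- fr$end
          arm3 <- c(circle_end - al, circle_end)
          arm5 <- c(circle_start, circle_start + al)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = fr$contig, frag_id = fr$frag_id,
          frag_start = fr$start, frag_end = fr$end,
          strand = strand, flap_offset = k,
          circle_start = circle_start, circle_end = circle_end,
          circle_size = circle_end - circle_start,
          arm3_start = arm3[1], arm3_end = arm3[2],
          arm5_start = arm5[1], arm5_end = arm5[2],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(empty_manifest())
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$contig, cand$frag_start,
                     cand$strand, cand$flap_offset), ]
  cand$oligo_id <- sprintf("%s_f%s_%s%03d", cand$contig,
                           sub("^frag_", "", cand$frag_id),
                           ifelse(cand$strand == "+", "p", "m"),
                           cand$flap_offset)
  cand$arm3_seq <- mapply(function(c, s, e) ref_subseq(ref, c, s, e),
                          cand$contig, cand$arm3_start, cand$arm3_end,
                          USE.NAMES = FALSE)
  cand$arm5_seq <- mapply(function(c, s, e) ref_subseq(ref, c, s, e),
                          cand$contig, cand$arm5_start, cand$arm5_end,
                          USE.NAMES = FALSE)
  cand$gc3 <- gc_fraction(cand$arm3_seq)
  cand$gc5 <- gc_fraction(cand$arm5_seq)
  rownames(cand) <- NULL
  cand[, manifest_columns()]
}

#' @noRd
manifest_columns <- function() {
  c("oligo_id", "contig", "frag_id", "frag_start", "frag_end", "strand",
    "flap_offset", "circle_start", "circle_end", "circle_size",
    "arm3_start", "arm3_end", "arm5_start", "arm5_end",
    "arm3_seq", "arm5_seq", "gc3", "gc5")
}

#' @noRd
empty_manifest <- function() {
  m <- data.frame(oligo_id = character(), contig = character(),
                  frag_id = character(), frag_start = integer(),
                  frag_end = integer(), strand = character(),
                  flap_offset = integer(), circle_start = integer(),
                  circle_end = integer(), circle_size = integer(),
                  arm3_start = integer(), arm3_end = integer(),
                  arm5_start = integer(), arm5_end = integer(),
                  arm3_seq = character(), arm5_seq = character(),
                  gc3 = numeric(), gc5 = numeric(),
                  stringsAsFactors = FALSE)
  m
}

#' Flag candidates whose arms overlap known variants
#'
#' Arms must sit in SNP-free sequence: a single variant position inside either
#' arm interval (half-open) sets the `snp_overlap` flag.
#'
#' @param cand Candidate manifest ([enumerate_candidates()]).
#' @param variants VariantSet data.frame (`contig, pos`), e.g. from
#'   [load_variants()]; `NULL` means no known variants.
#' @return Logical vector, one element per candidate.
#' @export
snp_filter <- function(cand, variants) {
  if (is.null(variants) || nrow(variants) == 0)
    return(rep(FALSE, nrow(cand)))
  vapply(seq_len(nrow(cand)), function(i) {
    v <- variants[variants$contig == cand$contig[i], "pos"]
    any((v >= cand$arm3_start[i] & v < cand$arm3_end[i]) |
          (v >= cand$arm5_start[i] & v < cand$arm5_end[i]))
  }, NA)
}

#' @noRd
count_genomic_hits <- function(arms, ref) {
  # exact occurrence count of each arm sequence over both strands of the
  # reference; a palindromic arm is counted once per duplex position
  uniq <- unique(arms)
  subjects <- Biostrings::DNAStringSet(ref$seqs)
  counts <- setNames(integer(length(uniq)), uniq)
  clean <- !grepl("N", uniq)
  widths <- nchar(uniq)
  for (w in unique(widths[clean])) {
    set <- uniq[clean & widths == w]
    rc <- revcomp(set)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(c(set, rc)))
    hits <- rowSums(Biostrings::vcountPDict(pd, subjects))
    fwd <- hits[seq_along(set)]
    rev <- hits[seq_along(set) + length(set)]
    counts[set] <- as.integer(fwd + ifelse(set == rc, 0L, rev))
  }
  for (a in uniq[!clean]) { # N-containing arms: per-pattern fallback
    f <- sum(Biostrings::vcountPattern(a, subjects, fixed = TRUE))
    r <- if (revcomp(a) == a) 0L else
      sum(Biostrings::vcountPattern(revcomp(a), subjects, fixed = TRUE))
    counts[a] <- f + r
  }
  counts[arms]
}

#' @noRd
max_run <- function(seqs) {
  vapply(seqs, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
  }, 0L, USE.NAMES = FALSE)
}

#' Arm uniqueness / repeat-proxy filters
#'
#' Three measurable proxies for the repeat/paralog screen: exact arm k-mer
#' multiplicity in the supplied reference (both strands), soft-masked
#' fraction, and homopolymer runs. Each returns a flag column.
#'
#' @inheritParams snp_filter
#' @param ref The [reference()] the candidates were designed against.
#' @param cfg A [design_config()].
#' @return data.frame with logical columns `nonunique, softmasked,
#'   homopolymer`.
#' @export
uniqueness_filter <- function(cand, ref, cfg = design_config()) {
  if (nrow(cand) == 0)
    return(data.frame(nonunique = logical(), softmasked = logical(),
                      homopolymer = logical()))
  hits3 <- count_genomic_hits(cand$arm3_seq, ref)
  hits5 <- count_genomic_hits(cand$arm5_seq, ref)
  nonunique <- hits3 > cfg$max_kmer_hits | hits5 > cfg$max_kmer_hits
  sm3 <- mapply(function(c, s, e) softmask_fraction(ref, c, s, e),
                cand$contig, cand$arm3_start, cand$arm3_end)
  sm5 <- mapply(function(c, s, e) softmask_fraction(ref, c, s, e),
                cand$contig, cand$arm5_start, cand$arm5_end)
  softmasked <- sm3 > cfg$softmask_max_fraction |
    sm5 > cfg$softmask_max_fraction
  homopolymer <- pmax(max_run(cand$arm3_seq), max_run(cand$arm5_seq)) >=
    cfg$max_homopolymer
  data.frame(nonunique = unname(nonunique), softmasked = unname(softmasked),
             homopolymer = unname(homopolymer))
}

#' Circle-size and arm-G+C filters
#'
#' `size_out_of_range` flags circles outside `[circle_min, circle_max]`;
#' `gc_out_of_range` flags any arm G+C outside `[gc_min, gc_max]`. Circles
#' above `circle_hard_max` are additionally rejected outright.
#'
#' @inheritParams uniqueness_filter
#' @return data.frame with logical columns `size_out_of_range,
#'   gc_out_of_range, rejected`.
#' @export
size_gc_filter <- function(cand, cfg = design_config()) {
  size_bad <- cand$circle_size < cfg$circle_min |
    cand$circle_size > cfg$circle_max
  gc_bad <- cand$gc3 < cfg$gc_min | cand$gc3 > cfg$gc_max |
    cand$gc5 < cfg$gc_min | cand$gc5 > cfg$gc_max
  data.frame(size_out_of_range = size_bad, gc_out_of_range = gc_bad,
             rejected = cand$circle_size > cfg$circle_hard_max)
}

#' Apply every QC filter, annotating the candidate manifest
#'
#' @inheritParams uniqueness_filter
#' @param variants Optional VariantSet data.frame (`contig, pos`).
#' @return The manifest with logical flag columns, a comma-joined `flags`
#'   string, `n_flags` and `rejected`.
#' @export
apply_qc <- function(cand, ref, cfg = design_config(), variants = NULL) {
  if (nrow(cand) == 0) {
    cand$flags <- character(0); cand$n_flags <- integer(0)
    cand$rejected <- logical(0)
    return(cand)
  }
  cand$snp_overlap <- snp_filter(cand, variants)
  uf <- uniqueness_filter(cand, ref, cfg)
  cand$nonunique <- uf$nonunique
  cand$softmasked <- uf$softmasked
  cand$homopolymer <- uf$homopolymer
  sg <- size_gc_filter(cand, cfg)
  cand$size_out_of_range <- sg$size_out_of_range
  cand$gc_out_of_range <- sg$gc_out_of_range
  cand$rejected <- sg$rejected
  flag_names <- c("snp_overlap", "nonunique", "softmasked", "homopolymer",
                  "size_out_of_range", "gc_out_of_range")
  fm <- as.matrix(cand[, flag_names])
  cand$n_flags <- rowSums(fm)
  cand$flags <- apply(fm, 1, function(r)
    paste(flag_names[r], collapse = ","))
  cand
}

#' @noRd
preference_order <- function(cand, cfg) {
  mid <- (cfg$circle_min + cfg$circle_max) / 2
  order(cand$n_flags,
        abs((cand$gc3 + cand$gc5) / 2 - 0.45),
        abs(cand$circle_size - mid),
        cand$circle_start,
        cand$oligo_id)
}

#' Select oligos from a flagged candidate set
#'
#' Strict mode keeps only flag-free candidates; permissive mode additionally
#' keeps flagged-but-not-rejected candidates for fragments that would
#' otherwise have no oligo. Per-fragment redundancy is capped at
#' `cfg$redundancy` with a deterministic preference order: fewer flags, then
#' mean arm G+C closest to 0.45, then circle size closest to the midpoint of
#' the size window, then leftmost coordinate, then id. Every dropped candidate
#' is returned in the rejection table with its reasons.
#'
#' @param cand Flagged manifest from [apply_qc()].
#' @param cfg A [design_config()].
#' @param mode `"strict"` or `"permissive"`.
#' @return List with `selected` (manifest rows, genomic order) and `rejected`
#'   (dropped rows plus a `reasons` column).
#' @export
select_oligos <- function(cand, cfg = design_config(),
                          mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (nrow(cand) == 0)
    return(list(selected = cand, rejected = cbind(cand, reasons = character(0))))
  stopifnot(!is.null(cand$n_flags))
  reasons <- rep("", nrow(cand))
  keepable <- rep(TRUE, nrow(cand))
  hard <- cand$rejected
  reasons[hard] <- "above_circle_hard_max"
  keepable[hard] <- FALSE
  if (mode == "strict") {
    fl <- !hard & cand$n_flags > 0
    reasons[fl] <- paste0("flagged:", cand$flags[fl])
    keepable[fl] <- FALSE
  } else {
    # permissive: flagged candidates usable only where a fragment has no
    # flag-free candidate
    clean_frags <- unique(cand$frag_id[!hard & cand$n_flags == 0])
    fl <- !hard & cand$n_flags > 0 & cand$frag_id %in% clean_frags
    reasons[fl] <- paste0("flagged:", cand$flags[fl])
    keepable[fl] <- FALSE
  }
  sel_idx <- integer(0)
  for (fid in unique(cand$frag_id)) {
    idx <- which(cand$frag_id == fid & keepable)
    if (length(idx) == 0) next
    ord <- idx[preference_order(cand[idx, , drop = FALSE], cfg)]
    take <- head(ord, cfg$redundancy)
    sel_idx <- c(sel_idx, take)
    drop <- setdiff(ord, take)
    reasons[drop] <- "redundancy_cap"
    keepable[drop] <- FALSE
  }
  selected <- cand[sort(sel_idx), , drop = FALSE]
  selected <- selected[order(selected$contig, selected$circle_start,
                             selected$oligo_id), , drop = FALSE]
  rejected <- cand[setdiff(seq_len(nrow(cand)), sel_idx), , drop = FALSE]
  rejected$reasons <- reasons[setdiff(seq_len(nrow(cand)), sel_idx)]
  rownames(selected) <- rownames(rejected) <- NULL
  list(selected = selected, rejected = rejected)
}

#' Tile capture oligos across a region
#'
#' Chooses one oligo per fragment overlapping `roi`, in genomic order,
#' restricted to full-fragment circles (both circle edges on the fragment
#' boundaries) so that consecutive captured fragments share cut boundaries and
#' the tiling is gapless wherever design succeeds. Fragments with no passing
#' candidate are reported as gaps.
#'
#' @inheritParams enumerate_candidates
#' @param variants Optional VariantSet.
#' @return List with `tiles` (selected manifest rows, genomic order) and
#'   `gaps` (fragment rows with a `reason` column).
#' @export
tile_region <- function(ref, frags, roi, cfg = design_config(),
                        variants = NULL) {
  cand <- enumerate_candidates(ref, frags, roi, cfg)
  cand <- apply_qc(cand, ref, cfg, variants)
  full <- cand[cand$circle_start == cand$frag_start &
                 cand$circle_end == cand$frag_end, , drop = FALSE]
  ov <- fragments_overlapping(frags, roi)
  tiles <- list(); gaps <- list()
  for (i in seq_len(nrow(ov))) {
    fr <- ov[i, ]
    fc <- full[full$frag_id == fr$frag_id & !full$rejected &
                 full$n_flags == 0, , drop = FALSE]
    if (nrow(fc) > 0) {
      tiles[[length(tiles) + 1L]] <-
        fc[preference_order(fc, cfg)[1], , drop = FALSE]
    } else {
      all_fc <- full[full$frag_id == fr$frag_id, , drop = FALSE]
      reason <- if (nrow(all_fc) == 0) "no_anchored_candidate"
        else if (all(all_fc$rejected)) "above_circle_hard_max"
        else paste(unique(unlist(strsplit(all_fc$flags, ","))), collapse = ",")
      gp <- fr
      gp$reason <- reason
      gaps[[length(gaps) + 1L]] <- gp
    }
  }
  list(
    tiles = if (length(tiles)) do.call(rbind, tiles) else empty_manifest(),
    gaps = if (length(gaps)) do.call(rbind, gaps) else
      cbind(ov[0, , drop = FALSE], reason = character(0))
  )
}

#' ROI base-coverage of a selection
#'
#' Fraction of ROI bases lying inside the union of the selected oligos'
#' captured fragment (circle) intervals, per ROI and aggregate.
#'
#' @param selected Selected manifest rows.
#' @param rois data.frame of ROIs (`contig, start, end`).
#' @return List with `per_roi` (data.frame adding `covered_bases, fraction`)
#'   and `aggregate` (overall covered fraction).
#' @export
roi_coverage <- function(selected, rois) {
  cov_by_contig <- split(
    IRanges::IRanges(selected$circle_start + 1L, selected$circle_end),
    selected$contig
  )
  covered <- integer(nrow(rois))
  for (i in seq_len(nrow(rois))) {
    ir <- cov_by_contig[[rois$contig[i]]]
    if (is.null(ir)) next
    q <- IRanges::IRanges(rois$start[i] + 1L, rois$end[i])
    covered[i] <- sum(IRanges::width(
      IRanges::intersect(IRanges::reduce(ir), q)))
  }
  per_roi <- rois
  per_roi$covered_bases <- covered
  per_roi$fraction <- covered / (rois$end - rois$start)
  list(per_roi = per_roi,
       aggregate = if (nrow(rois)) sum(covered) / sum(rois$end - rois$start)
                   else NA_real_)
}

#' Write / read an oligo manifest TSV
#'
#' Tab-separated with a fixed header line; comment lines starting with `#`
#' (e.g. a config hash) are ignored on read.
#'
#' @param manifest Manifest data.frame.
#' @param path File path.
#' @param comment Optional character vector of comment lines (written
#'   `#`-prefixed).
#' @return `path` (write) or the manifest data.frame (read).
#' @export
write_manifest <- function(manifest, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(manifest, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
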