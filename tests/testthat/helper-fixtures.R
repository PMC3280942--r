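# Fixture builders and independent oracles. Oracles deliberately use
# different machinery from the implementation (regex lookahead scans,
# per-base loops, direct coordinate arithmetic).

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# regex-lookahead substring scan: cut positions of one enzyme
oracle_cuts <- function(seq, enz) {
  m <- gregexpr(paste0("(?=", enz$recognition, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  sort(as.integer(m) - 1L + enz$cut_offset)
}

# full digest boundary oracle (union across enzymes + contig ends)
oracle_boundaries <- function(seq, enzymes) {
  L <- nchar(seq)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e)
    oracle_cuts(seq, e)))))
  cuts <- cuts[cuts > 0 & cuts < L]
  c(0L, cuts, L)
}

# exact occurrence count of `pat` and its reverse complement in `seqs`
# (overlapping, regex lookahead; palindromes counted once)
oracle_kmer_hits <- function(pat, seqs) {
  cnt <- function(p) sum(vapply(seqs, function(s) {
    m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, 0L))
  rc <- revcomp(pat)
  cnt(pat) + if (rc == pat) 0L else cnt(rc)
}

# brute-force candidate enumeration by direct coordinate arithmetic
oracle_enumerate <- function(frags, roi, cfg) {
  al <- cfg$arm_length
  ov <- frags[frags$contig == roi$contig & frags$start < roi$end &
                frags$end > roi$start, ]
  ov <- ov[order(ov$start), ]
  rows <- list()
  for (i in seq_len(nrow(ov))) {
    fr <- ov[i, ]
    if (fr$end - fr$start < 2 * al) next
    for (strand in c("+", "-")) {
      if (strand == "+" && fr$left_kind != "cut_site") next
      if (strand == "-" && fr$right_kind != "cut_site") next
      for (k in seq(0, (fr$end - fr$start) - 2 * al, by = cfg$flap_stride)) {
        cs <- if (strand == "+") fr$start else fr$start + k
        ce <- if (strand == "+") fr$end - k else fr$end
        rows[[length(rows) + 1L]] <- data.frame(
          frag_id = fr$frag_id, strand = strand, flap_offset = k,
          circle_start = cs, circle_end = ce,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$frag_id, out$strand, out$flap_offset), ]
}

# naive per-base pileup over [0, width)
oracle_pileup <- function(starts, ends, width) {
  depth <- integer(width)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# a contig of planted fragments whose end arms are GC-conditioned so that
# full-fragment candidates pass the default design filters (the "all
# passing" tiling world; an oversized fragment still fails on size)
make_tiling_contig <- function(frag_lens, seed = 1, contig = "tile1") {
  set.seed(seed)
  L <- sum(frag_lens)
  cuts <- head(cumsum(frag_lens), -1L)
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  site_idx <- integer(0) # 1-based positions of planted TTAA bases
  for (cut in cuts) {
    chars[cut:(cut + 3L)] <- c("T", "T", "A", "A")
    site_idx <- c(site_idx, cut:(cut + 3L))
  }
  bounds <- c(0L, cuts, L)
  windows <- list()
  for (i in seq_along(frag_lens)) {
    windows <- c(windows, list(c(bounds[i], bounds[i] + 20L),
                               c(bounds[i + 1L] - 20L, bounds[i + 1L])))
  }
  for (w in windows) {
    idx <- (w[1] + 1L):w[2]
    free <- setdiff(idx, site_idx)
    fixed_gc <- sum(chars[setdiff(idx, free)] %in% c("G", "C"))
    need <- max(10L - fixed_gc, 0L)
    f <- length(free)
    for (try in 1:50) {
      pool <- c(rep(c("G", "C"), length.out = need),
                rep(c("A", "T"), length.out = f - need))
      chars[free] <- sample(pool)
      ctx <- paste(chars[max(w[1] - 2L, 1L):min(w[2] + 3L, L)],
                   collapse = "")
      extra <- gregexpr("TTAA", ctx, fixed = TRUE)[[1]]
      starts0 <- if (extra[1] == -1) integer(0) else
        as.integer(extra) - 1L + max(w[1] - 2L, 1L) - 1L # 0-based in contig
      if (all(starts0 %in% (cuts - 1L))) break
    }
  }
  # scrub remaining accidental sites (edits keep arm GC within the window)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  for (iter in 1:50) {
    s <- paste(chars, collapse = "")
    m <- gregexpr("TTAA", s, fixed = TRUE)[[1]]
    occ <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
    occ <- setdiff(occ, cuts - 1L)
    if (length(occ) == 0) break
    for (p in occ) {
      cand <- setdiff(p:(p + 3L), site_idx - 1L)
      j <- cand[1] + 1L
      chars[j] <- flip[[chars[j]]]
    }
  }
  reference(setNames(paste(chars, collapse = ""), contig))
}

# synthetic manifest rows for the simulator/evaluator, independent of the
# design stage: n oligos with given circle sizes laid head-to-tail with gaps
make_fake_manifest <- function(n, circle_sizes, gc = 0.45, gap = 100L,
                               contig = "simM", strand = "+") {
  circle_sizes <- rep_len(circle_sizes, n)
  strand <- rep_len(strand, n)
  starts <- cumsum(c(gap, head(circle_sizes + gap, -1L)))
  data.frame(
    oligo_id = sprintf("syn_%03d", seq_len(n)),
    contig = contig, strand = strand,
    frag_start = starts, frag_end = starts + circle_sizes,
    circle_start = starts, circle_end = starts + circle_sizes,
    circle_size = circle_sizes,
    gc3 = rep_len(gc, n), gc5 = rep_len(gc, n),
    stringsAsFactors = FALSE
  )
}

fake_manifest_reference <- function(manifest, seed = 7, pad = 200L) {
  set.seed(seed)
  L <- max(manifest$circle_end) + pad
  reference(setNames(rand_dna(L), manifest$contig[1]))
}

# minimal SAM writer for hand-built records (independent of write_sam)
write_mini_sam <- function(path, contigs, records) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs), con)
  for (r in records) writeLines(paste(r, collapse = "\t"), con)
  invisible(path)
}
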