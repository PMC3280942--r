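# Synthetic-data generator: references with controlled restriction-site
# spacing, planted SNP positions and duplicated (soft-masked) 20-mers; a
# capture-yield model in circle size, arm G+C and hybridization temperature;
# and fragment-end read simulation with truth tables, with or without PCR
# amplification skew.

#' Simulation configuration
#'
#' @param seed Mandatory RNG seed; all randomness in the simulator flows from
#'   it.
#' @param contig_lengths Named integer vector of contig lengths (density
#'   mode).
#' @param spacing Optional named list: per contig, the exact fragment-length
#'   vector to plant (overrides `contig_lengths` / `site_density_per_kb`).
#' @param site_density_per_kb Mean MseI cut density per kb in density mode;
#'   inter-site gaps are exponential, clamped to `[50, 1500]` bases.
#' @param snp_density Planted known-variant positions per base.
#' @param repeat_count Number of duplicated 20-mers to plant (both copies
#'   recorded and soft-masked).
#' @param hybridization_temp_C Circularization/hybridization temperature;
#'   higher temperatures sharpen the low-G+C yield penalty.
#' @param size_half_max Circle size at which yield is half-maximal (bases,
#'   default 600; yield is exactly 0 beyond twice this).
#' @param size_steepness Logistic steepness of the size term (bases).
#' @param gc_opt_low,gc_opt_high Plateau window of the arm-G+C term.
#' @param gc_shoulder Baseline logistic shoulder width of the G+C term.
#' @param off_target_rate,adapter_read_rate Fractions of reads drawn from
#'   random genomic positions and from adapter sequence, respectively.
#' @param pcr `"on"` or `"off"`; on multiplies each oligo's yield by a
#'   log-normal amplification factor.
#' @param pcr_lognormal_sigma Log-sd of the amplification factor.
#' @param read_length Read length (default 42).
#' @param mode `"single"` (3'-anchored end only) or `"paired"` (both ends).
#' @param total_reads Number of capture events to emit (read pairs in paired
#'   mode, reads in single mode).
#' @param error_rate Uniform per-base substitution error rate.
#' @param zero_yield_ids Oligo ids whose yield is forced to zero (planted
#'   failures).
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       contig_lengths = c(sim1 = 100000L),
                       spacing = NULL,
                       site_density_per_kb = 2.5,
                       snp_density = 0.001,
                       repeat_count = 0L,
                       hybridization_temp_C = 55,
                       size_half_max = 600,
                       size_steepness = 40,
                       gc_opt_low = 0.30, gc_opt_high = 0.60,
                       gc_shoulder = 0.05,
                       off_target_rate = 0.10,
                       adapter_read_rate = 0.02,
                       pcr = c("on", "off"),
                       pcr_lognormal_sigma = 0.8,
                       read_length = 42L,
                       mode = c("single", "paired"),
                       total_reads = 10000L,
                       error_rate = 0,
                       zero_yield_ids = character(0)) {
  if (missing(seed)) stop("seed is mandatory")
  pcr <- match.arg(pcr); mode <- match.arg(mode)
  stopifnot(off_target_rate >= 0, off_target_rate <= 1,
            adapter_read_rate >= 0, adapter_read_rate <= 1,
            off_target_rate + adapter_read_rate < 1,
            read_length >= 20, error_rate >= 0, error_rate <= 1,
            gc_opt_low < gc_opt_high, size_half_max > 0)
  structure(list(seed = as.integer(seed), contig_lengths = contig_lengths,
                 spacing = spacing,
                 site_density_per_kb = site_density_per_kb,
                 snp_density = snp_density,
                 repeat_count = as.integer(repeat_count),
                 hybridization_temp_C = hybridization_temp_C,
                 size_half_max = size_half_max,
                 size_steepness = size_steepness,
                 gc_opt_low = gc_opt_low, gc_opt_high = gc_opt_high,
                 gc_shoulder = gc_shoulder,
                 off_target_rate = off_target_rate,
                 adapter_read_rate = adapter_read_rate,
                 pcr = pcr, pcr_lognormal_sigma = pcr_lognormal_sigma,
                 read_length = as.integer(read_length), mode = mode,
                 total_reads = as.integer(total_reads),
                 error_rate = error_rate,
                 zero_yield_ids = zero_yield_ids),
            class = "SimConfig")
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove accidental TTAA occurrences outside the protected (planted-site /
# repeat) intervals by deterministic single-base edits.
#' @noRd
scrub_sites <- function(chars, site_starts, protected) {
  # chars: character vector of single bases; site_starts: 0-based planted
  # TTAA starts; protected: 0-based positions that must not be edited
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  for (iter in 1:50) {
    s <- paste(chars, collapse = "")
    m <- gregexpr("TTAA", s, fixed = TRUE)[[1]]
    if (m[1] == -1) break
    occ <- as.integer(m) - 1L
    occ <- setdiff(occ, site_starts)
    if (length(occ) == 0) break
    for (p in occ) {
      cand <- setdiff(p:(p + 3L), protected)
      if (length(cand) == 0) cand <- p:(p + 3L) # give up on protection
      j <- cand[1] + 1L
      chars[j] <- flip[[chars[j]]]
    }
  }
  chars
}

#' Build a synthetic reference with controlled structure
#'
#' Plants MseI (TTAA) sites so that the restriction-fragment lengths are
#' either exactly `cfg$spacing` (per contig) or exponentially spaced at
#' `cfg$site_density_per_kb` with gaps clamped to `[50, 1500]` bases. Any
#' accidental TTAA elsewhere is scrubbed by single-base edits, so the digest
#' is fully determined by the planted sites. Known-variant positions are
#' sampled at `cfg$snp_density`; `cfg$repeat_count` duplicated 20-mers are
#' planted, recorded, and soft-masked (so the design repeat proxies can see
#' them). Byte-reproducible per seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `reference` (a [reference()]), `variants`
#'   (`contig, pos`) and `features` (`contig, start, end, kind` with kinds
#'   `planted_site`, `repeat`).
#' @export
make_synthetic_reference <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  contigs <- if (!is.null(cfg$spacing)) names(cfg$spacing)
             else names(cfg$contig_lengths)
  if (is.null(contigs)) stop("contig names required")
  seqs <- list(); masks <- list(); feats <- list(); vars <- list()
  for (nm in contigs) {
    if (!is.null(cfg$spacing)) {
      sp <- cfg$spacing[[nm]]
      if (any(sp < 8)) stop("infeasible spacing: fragments must be >= 8 bases")
      L <- sum(sp)
      cuts <- head(cumsum(sp), -1L)
    } else {
      L <- cfg$contig_lengths[[nm]]
      mean_gap <- 1000 / cfg$site_density_per_kb
      gaps <- pmin(pmax(round(rexp(ceiling(2 * L / mean_gap) + 10,
                                   1 / mean_gap)), 50), 1500)
      cuts <- cumsum(gaps)
      cuts <- cuts[cuts < L - 4L]
    }
    site_starts <- cuts - 1L # TTAA planted so the cut (T^TAA) lands on `cuts`
    if (length(site_starts) && (min(site_starts) < 0 ||
                                max(site_starts) + 4L > L))
      stop("infeasible spacing: planted site outside contig")
    chars <- strsplit(random_dna(L), "")[[1]]
    for (p in site_starts) chars[(p + 1L):(p + 4L)] <- c("T", "T", "A", "A")
    protected <- if (length(site_starts))
      unlist(lapply(site_starts, function(p) p:(p + 3L))) else integer(0)
    feat <- data.frame(contig = character(), start = integer(),
                       end = integer(), kind = character())
    if (length(site_starts))
      feat <- data.frame(contig = nm, start = site_starts,
                         end = site_starts + 4L, kind = "planted_site")
    # planted repeats: copy a clean 20-mer to a second location
    mask <- IRanges::IRanges()
    reps <- 0L; tries <- 0L
    while (reps < cfg$repeat_count && tries < 200L) {
      tries <- tries + 1L
      src <- sample.int(L - 20L, 1L) - 1L
      dst <- sample.int(L - 20L, 1L) - 1L
      spans <- c(src:(src + 19L), dst:(dst + 19L))
      if (abs(src - dst) < 40L || any(spans %in% protected)) next
      kmer <- paste(chars[(src + 1L):(src + 20L)], collapse = "")
      if (grepl("TTAA", kmer, fixed = TRUE)) next
      chars[(dst + 1L):(dst + 20L)] <- strsplit(kmer, "")[[1]]
      protected <- c(protected, spans)
      mask <- c(mask, IRanges::IRanges(c(src, dst) + 1L, width = 20L))
      feat <- rbind(feat, data.frame(contig = nm, start = c(src, dst),
                                     end = c(src, dst) + 20L,
                                     kind = "repeat"))
      reps <- reps + 1L
    }
    chars <- scrub_sites(chars, site_starts, protected)
    n_snp <- round(cfg$snp_density * L)
    snp_pos <- if (n_snp > 0) sort(sample.int(L, n_snp) - 1L) else integer(0)
    seqs[[nm]] <- paste(chars, collapse = "")
    masks[[nm]] <- IRanges::reduce(mask)
    feats[[nm]] <- feat
    vars[[nm]] <- data.frame(contig = rep(nm, length(snp_pos)),
                             pos = snp_pos)
  }
  ref <- reference(unlist(seqs), softmask = masks)
  list(reference = ref,
       variants = do.call(rbind, unname(vars)),
       features = do.call(rbind, unname(feats)))
}

#' Capture-yield model
#'
#' `weight = S(circle_size) * G(gc3) * G(gc5)`. `S` is a decreasing logistic
#' with half-maximum at `size_half_max` (circles beyond twice that yield
#' exactly 0 — outsized templates fail to circularize, amplify and cluster).
#' `G` is a plateau window on `[gc_opt_low, gc_opt_high]` with logistic
#' shoulders; the low-G+C shoulder narrows as hybridization temperature
#' rises (poorly annealing low-G+C arms are penalized more at high
#' temperature).
#'
#' @param circle_size Numeric vector of circle sizes (bases).
#' @param gc3,gc5 Per-arm G+C fractions.
#' @param cfg A [sim_config()].
#' @return Non-negative numeric weights (same length as inputs).
#' @export
capture_yield <- function(circle_size, gc3, gc5, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  S <- stats::plogis((cfg$size_half_max - circle_size) / cfg$size_steepness)
  S[circle_size > 2 * cfg$size_half_max] <- 0
  w_low <- cfg$gc_shoulder * 55 / cfg$hybridization_temp_C
  w_high <- cfg$gc_shoulder
  G <- function(gc) {
    stats::plogis((gc - cfg$gc_opt_low) / w_low) *
      stats::plogis((cfg$gc_opt_high - gc) / w_high)
  }
  S * G(gc3) * G(gc5)
}

#' @noRd
oligo_yields <- function(manifest, cfg) {
  w <- capture_yield(manifest$circle_size, manifest$gc3, manifest$gc5, cfg)
  w[manifest$oligo_id %in% cfg$zero_yield_ids] <- 0
  w
}

#' @noRd
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate fragment-end reads from a capture experiment
#'
#' Capture events are drawn multinomially across oligos with probabilities
#' proportional to [capture_yield()] (times a per-oligo log-normal
#' amplification factor when `cfg$pcr == "on"`), off-target genomic reads and
#' adapter contaminant reads. On-target reads start exactly at the oligo's
#' anchored fragment end and extend `read_length` bases into the fragment
#' (the 3'-anchored end only in single mode; both ends in paired mode, read 2
#' reverse-complemented). Off-target reads are resampled if their endpoints
#' would coincide exactly with an on-target anchor, so truth provenance
#' labels stay correct by construction. Deterministic per `cfg$seed`.
#'
#' @param manifest Oligo manifest (selected oligos).
#' @param ref The [reference()].
#' @param cfg A [sim_config()].
#' @param adapters [adapter_set()] used for adapter contaminant reads.
#' @return An object of class `sim_reads`: list with `truth` (one row per
#'   emitted read: `read_id, class, oligo_id, contig, start, end, strand,
#'   mapped, seq`), `per_oligo` (`oligo_id, weight, count` of capture
#'   events), and `config`.
#' @export
simulate_reads <- function(manifest, ref, cfg,
                           adapters = default_adapters()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- nrow(manifest)
  RL <- cfg$read_length
  w <- oligo_yields(manifest, cfg)
  if (all(w == 0)) stop("zero passing oligos: all capture yields are zero")
  amp <- if (cfg$pcr == "on") rlnorm(n, 0, cfg$pcr_lognormal_sigma)
         else rep(1, n)
  eff <- w * amp
  p_on <- 1 - cfg$off_target_rate - cfg$adapter_read_rate
  probs <- c(eff / sum(eff) * p_on, cfg$off_target_rate,
             cfg$adapter_read_rate)
  counts <- as.integer(rmultinom(1, cfg$total_reads, probs))
  k_oligo <- counts[seq_len(n)]
  n_off <- counts[n + 1L]; n_ad <- counts[n + 2L]

  # on-target anchor keys (used to keep off-target reads genuinely off)
  paired <- cfg$mode == "paired"
  plus <- manifest$strand == "+"
  left_keys <- c(paste(manifest$contig[plus], manifest$circle_start[plus]),
                 if (paired) paste(manifest$contig[!plus],
                                   manifest$circle_start[!plus]))
  right_keys <- c(paste(manifest$contig[!plus], manifest$circle_end[!plus]),
                  if (paired) paste(manifest$contig[plus],
                                    manifest$circle_end[plus]))

  r1_len <- pmin(RL, manifest$circle_size)
  tmpl1 <- character(n); tmpl2 <- character(n)
  r1 <- data.frame(contig = manifest$contig, strand = manifest$strand,
                   start = ifelse(plus, manifest$circle_start,
                                  manifest$circle_end - r1_len))
  r1$end <- r1$start + r1_len
  for (i in seq_len(n)) {
    s <- ref_subseq(ref, r1$contig[i], r1$start[i], r1$end[i])
    tmpl1[i] <- if (plus[i]) s else revcomp(s)
  }
  if (paired) {
    r2 <- data.frame(contig = manifest$contig,
                     strand = ifelse(plus, "-", "+"),
                     start = ifelse(plus, manifest$circle_end - r1_len,
                                    manifest$circle_start))
    r2$end <- r2$start + r1_len
    for (i in seq_len(n)) {
      s <- ref_subseq(ref, r2$contig[i], r2$start[i], r2$end[i])
      tmpl2[i] <- if (plus[i]) revcomp(s) else s
    }
  }

  rows <- list()
  if (sum(k_oligo) > 0) {
    idx <- rep(seq_len(n), k_oligo)
    on1 <- data.frame(class = "on_target", oligo_id = manifest$oligo_id[idx],
                      contig = r1$contig[idx], start = r1$start[idx],
                      end = r1$end[idx], strand = r1$strand[idx],
                      mapped = TRUE, seq = tmpl1[idx], mate = 1L,
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- on1
    if (paired) {
      on2 <- data.frame(class = "on_target",
                        oligo_id = manifest$oligo_id[idx],
                        contig = r2$contig[idx], start = r2$start[idx],
                        end = r2$end[idx], strand = r2$strand[idx],
                        mapped = TRUE, seq = tmpl2[idx], mate = 2L,
                        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- on2
    }
  }
  clens <- contig_lengths(ref)
  if (n_off > 0) {
    oc <- sample(names(clens), n_off, replace = TRUE,
                 prob = clens / sum(clens))
    os <- vapply(oc, function(cn) sample.int(clens[[cn]] - RL + 1L, 1L) - 1L,
                 0L)
    ostr <- sample(c("+", "-"), n_off, replace = TRUE)
    for (iter in 1:100) { # resample anchor collisions
      bad <- paste(oc, os) %in% left_keys | paste(oc, os + RL) %in% right_keys
      if (!any(bad)) break
      os[bad] <- vapply(oc[bad],
                        function(cn) sample.int(clens[[cn]] - RL + 1L, 1L) - 1L,
                        0L)
    }
    oseq <- vapply(seq_len(n_off), function(i) {
      s <- ref_subseq(ref, oc[i], os[i], os[i] + RL)
      if (ostr[i] == "+") s else revcomp(s)
    }, "")
    off <- data.frame(class = "off_target", oligo_id = NA_character_,
                      contig = oc, start = os, end = os + RL,
                      strand = ostr, mapped = TRUE, seq = oseq, mate = 1L,
                      stringsAsFactors = FALSE)
    if (paired) {
      off2 <- off
      off2$strand <- ifelse(off$strand == "+", "-", "+")
      off2$mate <- 2L
      off2$seq <- revcomp(off$seq)
      rows[[length(rows) + 1L]] <- off
      rows[[length(rows) + 1L]] <- off2
    } else rows[[length(rows) + 1L]] <- off
  }
  if (n_ad > 0) {
    pool <- paste0(adapters$forward_component, adapters$reverse_component)
    starts <- sample.int(nchar(pool) - RL + 1L, n_ad, replace = TRUE)
    aseq <- substring(pool, starts, starts + RL - 1L)
    ad <- data.frame(class = "adapter", oligo_id = NA_character_,
                     contig = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = "+", mapped = FALSE,
                     seq = aseq, mate = 1L, stringsAsFactors = FALSE)
    if (paired) {
      ad2 <- ad; ad2$mate <- 2L
      starts2 <- sample.int(nchar(pool) - RL + 1L, n_ad, replace = TRUE)
      ad2$seq <- substring(pool, starts2, starts2 + RL - 1L)
      rows[[length(rows) + 1L]] <- ad
      rows[[length(rows) + 1L]] <- ad2
    } else rows[[length(rows) + 1L]] <- ad
  }
  truth <- do.call(rbind, rows)
  truth$seq <- mutate_seqs(truth$seq, cfg$error_rate)
  if (paired) {
    # interleave mates so each event's two reads share a template id
    n_ev <- nrow(truth) / 2L
    m1 <- truth[truth$mate == 1L, , drop = FALSE]
    m2 <- truth[truth$mate == 2L, , drop = FALSE]
    truth <- rbind(m1, m2)[order(rep(seq_len(n_ev), 2L)), , drop = FALSE]
    truth$read_id <- sprintf("read_%07d/%d", rep(seq_len(n_ev), each = 2L),
                             truth$mate)
  } else {
    truth$read_id <- sprintf("read_%07d", seq_len(nrow(truth)))
  }
  rownames(truth) <- NULL
  truth <- truth[, c("read_id", "class", "oligo_id", "contig", "start",
                     "end", "strand", "mapped", "mate", "seq")]
  per_oligo <- data.frame(oligo_id = manifest$oligo_id, weight = w,
                          amp_factor = amp, count = k_oligo,
                          stringsAsFactors = FALSE)
  structure(list(truth = truth, per_oligo = per_oligo, config = cfg),
            class = "sim_reads")
}

#' Write simulated reads as FASTQ
#'
#' Constant high base quality (`I`); single mode writes `<prefix>.fastq`,
#' paired mode `<prefix>_R1.fastq` and `<prefix>_R2.fastq`.
#'
#' @param sim A [simulate_reads()] result.
#' @param prefix Output path prefix.
#' @return Character vector of file(s) written, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_reads"))
  emit <- function(df, path) {
    x <- Biostrings::DNAStringSet(df$seq)
    names(x) <- sub("/[12]$", "", df$read_id)
    q <- Biostrings::PhredQuality(strrep("I", nchar(df$seq)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    path
  }
  if (sim$config$mode == "paired") {
    p1 <- emit(sim$truth[sim$truth$mate == 1L, ], paste0(prefix, "_R1.fastq"))
    p2 <- emit(sim$truth[sim$truth$mate == 2L, ], paste0(prefix, "_R2.fastq"))
    invisible(c(p1, p2))
  } else {
    invisible(emit(sim$truth, paste0(prefix, ".fastq")))
  }
}

#' Write simulated truth alignments as SAM
#'
#' The simulator's reads are error-free relative to their source coordinates,
#' so the truth table doubles as the output of an exact aligner; this writes
#' it as a minimal valid SAM (the bundled stand-in for an external aligner).
#' Adapter reads are emitted as unmapped records.
#'
#' @param sim A [simulate_reads()] result.
#' @param ref The [reference()] reads were simulated from.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, ref, path) {
  stopifnot(inherits(sim, "sim_reads"))
  tr <- sim$truth
  paired <- sim$config$mode == "paired"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  lens <- contig_lengths(ref)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  flag <- integer(nrow(tr))
  if (paired) flag <- flag + 1L + ifelse(tr$mate == 1L, 64L, 128L)
  flag <- flag + ifelse(tr$mapped, ifelse(tr$strand == "-", 16L, 0L), 4L)
  qname <- sub("/[12]$", "", tr$read_id)
  # SAM stores the forward-strand sequence for reverse alignments
  seq_fwd <- ifelse(tr$mapped & tr$strand == "-", revcomp(tr$seq), tr$seq)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 qname, flag,
                 ifelse(tr$mapped, tr$contig, "*"),
                 ifelse(tr$mapped, tr$start + 1L, 0L),
                 ifelse(tr$mapped, 60L, 0L),
                 ifelse(tr$mapped, sprintf("%dM", nchar(tr$seq)), "*"),
                 seq_fwd, strrep("I", nchar(tr$seq)))
  writeLines(rec, con)
  invisible(path)
}
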