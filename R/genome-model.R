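#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor.test median rexp rlnorm rmultinom runif setNames
#' @importFrom utils read.table write.table head tail
NULL

# All internal coordinates are 0-based half-open ([start, end)), the BED
# convention. SAM positions are converted on ingest; nothing else converts.

#' Reference genome container
#'
#' A `Reference` holds uppercase contig sequences over `{A,C,G,T,N}` plus, for
#' each contig, the intervals that were soft-masked (lowercase) in the source
#' FASTA. The softmask is retained because the arm quality filter uses it as a
#' repeat proxy (see [uniqueness_filter()]).
#'
#' @param seqs Named character vector of contig sequences (will be uppercased;
#'   alphabet `A,C,G,T,N`).
#' @param softmask Optional named list of [IRanges::IRanges] of 0-based
#'   half-open masked intervals per contig (stored internally as 1-based
#'   IRanges on the sequence).
#' @return An object of class `Reference`.
#' @export
reference <- function(seqs, softmask = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("contig names must be present and unique")
  if (any(!nzchar(seqs))) stop("contig sequences must be non-empty")
  up <- toupper(seqs)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad))
    stop("contig ", names(seqs)[bad][1], ": alphabet restricted to A,C,G,T,N")
  if (is.null(softmask)) {
    softmask <- lapply(seqs, function(x) IRanges::IRanges())
    names(softmask) <- names(seqs)
  }
  structure(list(seqs = up, softmask = softmask), class = "Reference")
}

#' @export
print.Reference <- function(x, ...) {
  cat("Reference with", length(x$seqs), "contig(s):\n")
  for (nm in names(x$seqs))
    cat(sprintf("  %s  %d bp\n", nm, nchar(x$seqs[[nm]])))
  invisible(x)
}

#' Contig lengths of a Reference
#' @param ref A [reference()] object.
#' @return Named integer vector.
#' @export
contig_lengths <- function(ref) {
  stopifnot(inherits(ref, "Reference"))
  setNames(nchar(ref$seqs), names(ref$seqs))
}

#' Extract a subsequence (0-based half-open)
#' @param ref A [reference()].
#' @param contig Contig name.
#' @param start,end 0-based half-open bounds.
#' @return Character scalar.
#' @export
ref_subseq <- function(ref, contig, start, end) {
  stopifnot(inherits(ref, "Reference"))
  s <- ref$seqs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  if (start < 0 || end > nchar(s) || start >= end)
    stop("invalid interval [", start, ",", end, ") on ", contig)
  substr(s, start + 1L, end)
}

#' Fraction of soft-masked bases in an interval
#' @inheritParams ref_subseq
#' @return Numeric in `[0,1]`.
#' @export
softmask_fraction <- function(ref, contig, start, end) {
  m <- ref$softmask[[contig]]
  if (is.null(m) || length(m) == 0) return(0)
  q <- IRanges::IRanges(start + 1L, end) # 1-based closed
  ov <- IRanges::intersect(IRanges::reduce(m), q)
  sum(IRanges::width(ov)) / (end - start)
}

#' Load a FASTA reference
#'
#' Sequences are uppercased; soft-masked (lowercase) stretches are recorded
#' per contig. Characters outside `A,C,G,T,N` (case-insensitive) are a parse
#' error.
#'
#' @param path Path to a FASTA file.
#' @return A [reference()].
#' @export
load_reference <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("no FASTA records in ", path)
  nms <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nms)) stop("duplicate contig names in ", path)
  seqs <- as.character(raw)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", nms[!nzchar(seqs)][1], "' in ", path)
  mask <- lapply(seqs, function(s) {
    m <- gregexpr("[a-z]+", s)[[1]]
    if (m[1] == -1) return(IRanges::IRanges())
    IRanges::IRanges(as.integer(m), width = attr(m, "match.length"))
  })
  names(seqs) <- names(mask) <- nms
  reference(seqs, softmask = mask)
}

#' Write a Reference as FASTA (60-column wrap)
#' @param ref A [reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Reverse complement
#'
#' Alphabet `{A,C,G,T,N,U}` (case-insensitive; returned uppercase). The
#' complement of U is A — U is legal only in assembled oligo sequences, never
#' in the reference.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  up <- toupper(seq)
  if (any(grepl("[^ACGTUN]", up)))
    stop("revcomp: alphabet restricted to A,C,G,T,N,U")
  comp <- chartr("ACGTUN", "TGCAAN", up)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), "", USE.NAMES = FALSE)
}

#' G+C fraction of a sequence
#'
#' `(#G + #C) / length`; `N` counts as neither G nor C but remains in the
#' denominator.
#'
#' @param seq Character vector of non-empty sequences.
#' @return Numeric vector in `[0,1]`.
#' @export
gc_fraction <- function(seq) {
  if (any(!nzchar(seq))) stop("gc_fraction: empty sequence")
  up <- toupper(seq)
  (nchar(up) - nchar(gsub("[GC]", "", up))) / nchar(up)
}

#' Load genomic intervals from a BED file
#'
#' BED3+ is accepted; coordinates are kept 0-based half-open verbatim. The
#' strand column (6th) is honoured when present, defaulting to `"+"`.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `contig, start, end, strand` (and `name`
#'   when a 4th column is present).
#' @export
load_intervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  # pre-validate so errors can carry a line number (rtracklayer's cannot)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3) stop(path, " line ", i, ": fewer than 3 BED columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop(path, " line ", i, ": non-numeric coordinates")
    if (s >= e) stop(path, " line ", i, ": start >= end (empty interval)")
  }
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(S4Vectors::decode(BiocGenerics::strand(gr)))
  strand[strand == "*"] <- "+"
  out <- data.frame(
    contig = as.character(S4Vectors::decode(GenomeInfoDb::seqnames(gr))),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write intervals as BED
#' @param intervals data.frame with `contig, start, end` (0-based half-open)
#'   and optional `name`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if (!is.null(intervals$name)) intervals$name else rep(".", n)
  strand <- if (!is.null(intervals$strand)) intervals$strand else rep("+", n)
  df <- data.frame(intervals$contig, intervals$start, intervals$end,
                   name, 0L, strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load known-variant positions
#'
#' Accepts BED (every base of each interval becomes a variant position) or a
#' minimal VCF from which only CHROM/POS are consulted (positions-only VCFs
#' routinely lack the header a full VCF parser requires, hence the light
#' reader).
#'
#' @param path BED or VCF path (format by extension, `.vcf` = VCF).
#' @return A data.frame with columns `contig`, `pos` (0-based), the
#'   `VariantSet`.
#' @export
load_variants <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0)
      return(data.frame(contig = character(), pos = integer()))
    f <- strsplit(lines, "\t")
    data.frame(contig = vapply(f, `[`, "", 1),
               pos = as.integer(vapply(f, `[`, "", 2)) - 1L,
               stringsAsFactors = FALSE)
  } else {
    iv <- load_intervals(path)
    data.frame(
      contig = rep(iv$contig, iv$end - iv$start),
      pos = unlist(Map(function(s, e) seq.int(s, e - 1L), iv$start, iv$end),
                   use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
}

#' @noRd
validate_variants <- function(variants, ref) {
  len <- contig_lengths(ref)
  bad <- !(variants$contig %in% names(len)) |
    variants$pos < 0 | variants$pos >= len[variants$contig]
  if (any(bad)) stop("variant position out of contig bounds")
  invisible(variants)
}
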