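# In-silico restriction digestion. Sites are matched on the top strand only;
# this is exact for palindromic recognition sequences (MseI, the built-in) and
# asserted at construction for anything else.

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence over `{A,C,G,T}` (no ambiguity
#'   codes). Must be palindromic (equal to its reverse complement) because
#'   digestion is modelled on the top strand only.
#' @param cut_offset Cut position in bases from the 5' start of the
#'   recognition site on the top strand, in `[0, nchar(recognition)]`.
#' @return An object of class `Enzyme`.
#' @examples
#' mse_i() # TTAA, cut T^TAA
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition))
    stop("recognition sequence restricted to A,C,G,T (no ambiguity codes)")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition sequence")
  if (revcomp(recognition) != recognition)
    stop("non-palindromic recognition sites are not supported ",
         "(top-strand-only digestion model)")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset), class = "Enzyme")
}

#' MseI (T^TAA), the built-in enzyme
#' @return An [enzyme()].
#' @export
mse_i <- function() enzyme("MseI", "TTAA", 1L)

#' Find cut positions of an enzyme in a sequence
#'
#' Returns the sorted 0-based offsets at which the top strand is cleaved
#' (`site_start + cut_offset`). Overlapping occurrences are all reported;
#' occurrences containing `N` never match.
#'
#' @param seq DNA string.
#' @param enz An [enzyme()].
#' @return Sorted integer vector of cut positions (possibly empty).
#' @export
find_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "Enzyme"))
  subject <- Biostrings::DNAString(toupper(seq))
  m <- Biostrings::matchPattern(enz$recognition, subject, fixed = TRUE)
  sort(BiocGenerics::start(m) - 1L + enz$cut_offset)
}

#' Digest a reference into restriction fragments
#'
#' The union of cut positions across all enzymes, deduplicated, plus the
#' contig ends, defines the fragment boundaries; the fragments of each contig
#' tile it exactly. Boundary provenance (cut site vs contig end, and which
#' enzymes cut there) is recorded. Complete digestion is assumed; capture
#' inefficiency is the simulator's job.
#'
#' @param ref A [reference()].
#' @param enzymes List of [enzyme()] objects (at least one).
#' @return data.frame with columns `frag_id, contig, start, end, length,
#'   left_kind, right_kind, left_enzymes, right_enzymes`, where `*_kind` is
#'   `"cut_site"`, `"contig_start"` or `"contig_end"`.
#' @export
digest_reference <- function(ref, enzymes) {
  stopifnot(inherits(ref, "Reference"))
  if (inherits(enzymes, "Enzyme")) enzymes <- list(enzymes)
  if (length(enzymes) < 1) stop("at least one enzyme required")
  out <- lapply(names(ref$seqs), function(contig) {
    s <- ref$seqs[[contig]]
    L <- nchar(s)
    cuts <- lapply(enzymes, function(e) find_sites(s, e))
    names(cuts) <- vapply(enzymes, `[[`, "", "name")
    pos <- sort(unique(unlist(cuts, use.names = FALSE)))
    pos <- pos[pos > 0 & pos < L] # a cut at a contig end adds no boundary
    who <- vapply(pos, function(p) {
      paste(names(cuts)[vapply(cuts, function(v) p %in% v, NA)],
            collapse = ",")
    }, "")
    bounds <- c(0L, pos, L)
    n <- length(bounds) - 1L
    data.frame(
      contig = contig,
      start = bounds[-length(bounds)],
      end = bounds[-1],
      left_kind = c("contig_start", rep("cut_site", n - 1L)),
      right_kind = c(rep("cut_site", n - 1L), "contig_end"),
      left_enzymes = c("", who),
      right_enzymes = c(who, ""),
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, out)
  frags$length <- frags$end - frags$start
  frags$frag_id <- sprintf("frag_%05d", seq_len(nrow(frags)))
  frags[, c("frag_id", "contig", "start", "end", "length",
            "left_kind", "right_kind", "left_enzymes", "right_enzymes")]
}

#' Fragment sequence(s) from coordinates
#' @param frags Rows of a [digest_reference()] table.
#' @param ref The [reference()] they came from.
#' @return Character vector of fragment sequences.
#' @export
fragment_seq <- function(frags, ref) {
  mapply(function(c, s, e) ref_subseq(ref, c, s, e),
         frags$contig, frags$start, frags$end, USE.NAMES = FALSE)
}

#' Fragments overlapping a region of interest
#'
#' @param frags A [digest_reference()] table.
#' @param roi A one-row data.frame (or list) with `contig, start, end`,
#'   0-based half-open.
#' @return The fragments with at least one base of overlap, in genomic order.
#' @export
fragments_overlapping <- function(frags, roi) {
  if (!roi$contig %in% frags$contig)
    stop("unknown contig in ROI: ", roi$contig)
  hit <- frags$contig == roi$contig & frags$start < roi$end &
    frags$end > roi$start
  out <- frags[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
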