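# Full-length oligo assembly: capture oligo = armA + forward adapter
# component + reverse adapter component + armB, the vector oligo is the
# reverse complement of the common (adapter) region, and ten thymines of the
# common region are substituted with uracils for post-circularization
# fragmentation. With the default 58/61-nt components and 20-nt arms the
# assembled length is 20+58+61+20 = 159 and the vector is 119 nt.

#' Adapter component set
#'
#' The two sequencing-adapter components embedded in every capture oligo
#' (defaults: forward 58 nt, reverse 61 nt). The bundled defaults are
#' synthetic placeholder sequences of the correct lengths, not vendor
#' adapter sequences; supply your own for real synthesis.
#'
#' @param forward_component,reverse_component DNA strings over `{A,C,G,T}`.
#' @param names Length-2 character vector naming the components.
#' @return An object of class `AdapterSet`.
#' @export
adapter_set <- function(forward_component, reverse_component,
                        names = c("forward", "reverse")) {
  f <- toupper(forward_component); r <- toupper(reverse_component)
  if (!nzchar(f) || !nzchar(r) || grepl("[^ACGT]", f) || grepl("[^ACGT]", r))
    stop("adapter components must be non-empty strings over A,C,G,T")
  structure(list(forward_component = f, reverse_component = r,
                 names = names), class = "AdapterSet")
}

#' Default (synthetic placeholder) adapter components, 58 + 61 nt
#' @return An [adapter_set()].
#' @export
default_adapters <- function() {
  adapter_set(
    "AACCCTATGACGTCTTGGTCCTCTAGCCTTACCCAGAACATAGTGACGAGAAGCTGAG",
    "CCAAGAACCACACTTCCTCCTAGGGTAACGTCGGGCAAAAAGCGCTTCCGGCTCGAGGCAA",
    names = c("synthetic_forward_58", "synthetic_reverse_61")
  )
}

#' Assemble full capture-oligo sequences for a manifest
#'
#' Each oligo is `armA + forward + reverse + armB` where `armA` is
#' complementary to the captured strand's 3'-end target site and `armB` to its
#' 5'-end site (splint orientation: each arm bridges the fragment end it
#' anneals to). Under the package strand convention, for a `"+"` oligo
#' `armA = arm3_seq` and `armB = arm5_seq` as stored (reference strand); for a
#' `"-"` oligo both are reverse-complemented.
#'
#' @param manifest Oligo manifest ([enumerate_candidates()] /
#'   [select_oligos()] output).
#' @param adapters An [adapter_set()].
#' @param arm_length Arm length (consistency check against the manifest).
#' @return data.frame `oligo_id, sequence, arm_a, arm_b, common_start,
#'   common_end, length` plus attribute `"layout"` describing segment
#'   boundaries.
#' @export
assemble_oligos <- function(manifest, adapters = default_adapters(),
                            arm_length = NULL) {
  stopifnot(inherits(adapters, "AdapterSet"))
  al <- unique(nchar(manifest$arm3_seq))
  if (length(al) != 1) stop("mixed arm lengths in manifest")
  if (!is.null(arm_length) && al != arm_length)
    stop("manifest arm length ", al, " != requested ", arm_length)
  plus <- manifest$strand == "+"
  arm_a <- ifelse(plus, manifest$arm3_seq, revcomp(manifest$arm3_seq))
  arm_b <- ifelse(plus, manifest$arm5_seq, revcomp(manifest$arm5_seq))
  common <- paste0(adapters$forward_component, adapters$reverse_component)
  seqs <- paste0(arm_a, common, arm_b)
  out <- data.frame(
    oligo_id = manifest$oligo_id,
    sequence = seqs,
    arm_a = arm_a, arm_b = arm_b,
    common_start = al, common_end = al + nchar(common),
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  attr(out, "layout") <- data.frame(
    segment = c("arm_a", "common_region", "arm_b"),
    start = c(0L, al, al + nchar(common)),
    end = c(al, al + nchar(common), al + nchar(common) + al)
  )
  out
}

#' Build the universal vector oligonucleotide
#'
#' The vector is complementary to the common (inverted-adapter) portion of
#' every capture oligo: the reverse complement of
#' `forward_component + reverse_component`. With default components it is
#' 119 nt.
#'
#' @param adapters An [adapter_set()].
#' @return DNA string.
#' @export
build_vector <- function(adapters = default_adapters()) {
  stopifnot(inherits(adapters, "AdapterSet"))
  revcomp(paste0(adapters$forward_component, adapters$reverse_component))
}

#' Substitute thymines with uracils in the common region
#'
#' Deterministically replaces `n` T with U at maximally even spacing over the
#' T ranks of the common region (ranks `ceiling(nT * i / n)`); arms are never
#' modified. If fewer than `n` thymines are available, all are substituted
#' with a warning.
#'
#' @param assembled Output of [assemble_oligos()].
#' @param n Number of substitutions per oligo (default 10).
#' @return `assembled` with `sequence` containing `U`, plus a `u_positions`
#'   list-column of 0-based offsets.
#' @export
uracil_substitute <- function(assembled, n = 10L) {
  n <- as.integer(n)
  upos <- vector("list", nrow(assembled))
  seqs <- assembled$sequence
  for (i in seq_len(nrow(assembled))) {
    if (n == 0L) { upos[[i]] <- integer(0); next }
    cs <- assembled$common_start[i]; ce <- assembled$common_end[i]
    common <- substr(seqs[i], cs + 1L, ce)
    tpos <- which(strsplit(common, "")[[1]] == "T") # 1-based within common
    if (length(tpos) < n) {
      warning("oligo ", assembled$oligo_id[i], ": only ", length(tpos),
              " thymines in common region; substituting all")
      take <- tpos
    } else {
      take <- tpos[ceiling(length(tpos) * seq_len(n) / n)]
    }
    glob <- cs + take # 1-based global position
    ch <- strsplit(seqs[i], "")[[1]]
    ch[glob] <- "U"
    seqs[i] <- paste(ch, collapse = "")
    upos[[i]] <- glob - 1L # 0-based offsets
  }
  assembled$sequence <- seqs
  assembled$u_positions <- upos
  assembled
}

#' Write assembled oligos (or the vector) as FASTA
#'
#' Written directly because assembled sequences may contain `U`, which the
#' standard DNA containers refuse.
#'
#' @param assembled Output of [assemble_oligos()] / [uracil_substitute()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(assembled, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(assembled))) {
    writeLines(paste0(">", assembled$oligo_id[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", assembled$sequence[i]), con)
  }
  invisible(path)
}
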