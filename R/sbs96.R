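#' @importFrom methods new validObject is setValidity setClass setMethod setGeneric representation show slot
#' @importFrom stats setNames var
#' @importFrom utils head combn packageVersion
NULL

.SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical SBS96 channel labels
#'
#' Returns the 96 single-base-substitution channel labels in the fixed COSMIC
#' ordering: substitution blocks C>A, C>G, C>T, T>A, T>C, T>G; within each
#' block the 16 flanking-base pairs in lexicographic order (5' flank outer,
#' 3' flank inner). All profile vectors and signature catalogs in this package
#' are indexed by this ordering, so catalog files are bit-compatible with
#' COSMIC SBS96 downloads.
#'
#' @return Character vector of 96 labels such as \code{"A[C>A]A"}.
#' @export
#' @examples
#' head(sbs96Channels())
sbs96Channels <- function() {
  unlist(lapply(.SBS_SUBS, function(s) {
    as.vector(t(outer(.BASES, .BASES, function(a, b) paste0(a, "[", s, "]", b))))
  }), use.names = FALSE)
}

.SBS96 <- sbs96Channels()

## source trinucleotide of each channel, e.g. "A[C>A]A" -> "ACA"
.channelTrinucleotide <- function(channels = .SBS96) {
  paste0(substr(channels, 1L, 1L), substr(channels, 3L, 3L), substr(channels, 7L, 7L))
}

.channelAlt <- function(channels = .SBS96) substr(channels, 5L, 5L)

## vectorized reverse complement of 3-mers (plain character, no XString
## overhead in the per-variant hot path)
.revcomp3 <- function(x) {
  y <- chartr("ACGT", "TGCA", x)
  paste0(substr(y, 3L, 3L), substr(y, 2L, 2L), substr(y, 1L, 1L))
}

## Pyrimidine-collapse a vector of reference-strand trinucleotides: 3-mers
## whose middle base is a purine are reverse complemented.
.collapseContext <- function(context) {
  mid <- substr(context, 2L, 2L)
  purine <- mid %in% c("A", "G")
  context[purine] <- .revcomp3(context[purine])
  context
}

#' Assign SBS96 channels to single-nucleotide variants
#'
#' Maps (ref, alt, reference-strand trinucleotide context) triples onto the
#' canonical pyrimidine-centered channel. Purine-reference variants are
#' reverse complemented. Non-SNV rows (indels, MNVs, missing context) get
#' \code{NA}.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @param context Character vector of reference-strand 3-mers centered on the
#'   variant position (middle base equal to \code{ref} for SNVs).
#' @return Character vector of channel labels (or \code{NA}).
#' @export
#' @examples
#' assignChannel("G", "A", "TGC")  # reverse complemented to "G[C>T]A"
#' assignChannel("C", "T", "ACA")
assignChannel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  context <- rep_len(as.character(context), n)
  out <- rep_len(NA_character_, n)
  snv <- ref %in% .BASES & alt %in% .BASES & ref != alt &
    !is.na(context) & nchar(context) == 3L
  if (!any(snv)) return(out)
  r <- ref[snv]; a <- alt[snv]; ctx <- context[snv]
  bad <- substr(ctx, 2L, 2L) != r
  if (any(bad)) {
    stop("context middle base does not match ref allele for ",
         sum(bad), " SNV(s)")
  }
  purine <- r %in% c("A", "G")
  ctx[purine] <- .revcomp3(ctx[purine])
  r[purine] <- .COMPLEMENT[r[purine]]
  a[purine] <- .COMPLEMENT[a[purine]]
  out[snv] <- paste0(substr(ctx, 1L, 1L), "[", r, ">", a, "]",
                     substr(ctx, 3L, 3L))
  out
}
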