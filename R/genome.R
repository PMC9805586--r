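#' Construct a genome description
#'
#' A genome is represented as a [GenomeInfoDb::Seqinfo] object: an ordered set
#' of uniquely named chromosomes with positive lengths. It is the coordinate
#' frame against which every interval operation validates, and its total size
#' is the denominator of the genome-fraction \eqn{p} of a term's regulatory
#' domain.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer-like vector of chromosome lengths in bases (> 0).
#' @return A `Seqinfo` object.
#' @examples
#' g <- make_genome(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_size(g)
#' @export
make_genome <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) {
    stop("a genome needs at least one chromosome")
  }
  if (length(chroms) != length(lengths)) {
    stop("'chroms' and 'lengths' must have the same length")
  }
  if (anyDuplicated(chroms)) {
    stop("duplicated chromosome names: ",
         paste(unique(chroms[duplicated(chroms)]), collapse = ", "))
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Total genome size in bases
#'
#' @param genome A `Seqinfo` genome, e.g. from [make_genome()].
#' @return Numeric scalar, the sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' One interval per chromosome spanning the whole genome
#'
#' @param genome A `Seqinfo` genome.
#' @return A `GRanges` covering every base of every chromosome.
#' @export
whole_genome_regions <- function(genome) {
  gr <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(genome),
    ranges   = IRanges::IRanges(1L, GenomeInfoDb::seqlengths(genome)),
    seqinfo  = genome
  )
  gr
}

# Stop with a chromosome-naming error if any seqname of `gr` (or any name in
# `chroms`) is absent from `genome`.
check_chroms <- function(chroms, genome, what = "interval") {
  chroms <- as.character(unique(chroms))
  known <- GenomeInfoDb::seqnames(genome)
  bad <- setdiff(chroms, known)
  if (length(bad)) {
    stop(sprintf(
      "%s on chromosome(s) not present in the genome: %s",
      what, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
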