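#' Build a validated interval set from 0-based half-open coordinates
#'
#' Intervals are carried internally as [GenomicRanges::GRanges] (1-based
#' closed, the Bioconductor convention); all user-facing coordinates in files
#' and in this constructor are 0-based half-open, BED-native. Strand is kept
#' as metadata but ignored by every interval operation; it only matters when
#' regulatory domains are derived from TSSs.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open (`start < end`).
#' @param genome A `Seqinfo` genome the intervals must lie on.
#' @param name Optional character vector of interval labels.
#' @param strand Optional strand vector (`"+"`, `"-"`, `"*"`).
#' @return A `GRanges` with `seqinfo` set to `genome`.
#' @export
as_regions <- function(chrom, start, end, genome, name = NULL, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  check_chroms(chrom, genome)
  if (any(start < 0) || any(end <= start)) {
    stop("intervals must satisfy 0 <= start < end (0-based half-open)")
  }
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  if (any(end > lens)) {
    i <- which(end > lens)[1L]
    stop(sprintf("interval %s:%.0f-%.0f exceeds chromosome length %.0f",
                 chrom[i], start[i], end[i], lens[i]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start + 1), end = as.integer(end)),
    strand = if (is.null(strand)) "*" else strand,
    seqinfo = genome
  )
  if (!is.null(name)) gr$name <- as.character(name)
  gr
}

# Validate a GRanges against a genome without rebuilding it.
validate_regions <- function(gr, genome, what = "interval") {
  check_chroms(as.character(GenomeInfoDb::seqnames(gr)), genome, what)
  lens <- GenomeInfoDb::seqlengths(genome)[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(GenomicRanges::end(gr) > lens) || any(GenomicRanges::start(gr) < 1L)) {
    stop(sprintf("%s out of chromosome bounds", what))
  }
  invisible(TRUE)
}

#' Merge an interval set
#'
#' Collapses an interval set to its canonical disjoint form: overlapping
#' intervals are unioned and book-ended (adjacent) intervals are coalesced,
#' so the result covers exactly the same bases with the fewest intervals.
#'
#' @param regions A `GRanges`.
#' @param genome Optional `Seqinfo`; when supplied, regions are validated
#'   against it first.
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_regions <- function(regions, genome = NULL) {
  if (!is.null(genome)) validate_regions(regions, genome)
  GenomicRanges::reduce(regions, ignore.strand = TRUE)
}

#' Intersect two interval sets
#'
#' Covered bases of the result are the intersection of the covered bases of
#' `a` and `b`. Fragments inherit the `name` metadata of the `a` interval
#' they derive from.
#'
#' @param a,b `GRanges` on the same genome.
#' @return A `GRanges` of intersection fragments.
#' @export
intersect_regions <- function(a, b) {
  bm <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(a, bm, ignore.strand = TRUE)
  frag <- GenomicRanges::pintersect(
    a[S4Vectors::queryHits(hits)], bm[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE
  )
  frag$hit <- NULL
  GenomicRanges::strand(frag) <- "*"
  sort(frag, ignore.strand = TRUE)
}

#' Subtract one interval set from another
#'
#' Covered bases of the result are the bases of `a` not covered by `b`.
#' The result is merged (disjoint, sorted); names are not carried.
#'
#' @param a,b `GRanges` on the same genome.
#' @return A merged `GRanges`.
#' @export
subtract_regions <- function(a, b) {
  am <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  if (length(b) == 0L) return(am)
  GenomicRanges::setdiff(am, b, ignore.strand = TRUE)
}

#' Total number of bases covered by an interval set
#'
#' Overlapping intervals are merged first, so each base counts once.
#'
#' @param regions A `GRanges`.
#' @return Numeric scalar base count.
#' @export
total_length <- function(regions) {
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(regions, ignore.strand = TRUE)
  )))
}

#' Region midpoints as width-1 intervals
#'
#' The midpoint of a region with 0-based half-open coordinates
#' `[start, end)` is `floor((start + end) / 2)`; an even-width region takes
#' the left of the two central bases. Each midpoint is returned as a
#' width-1 `GRanges` so overlap machinery applies directly.
#'
#' @param regions A `GRanges`.
#' @return A `GRanges` of width-1 midpoint positions, parallel to `regions`.
#' @export
region_midpoints <- function(regions) {
  s0 <- GenomicRanges::start(regions) - 1L   # 0-based start
  e0 <- GenomicRanges::end(regions)          # 0-based exclusive end
  mid1 <- (s0 + e0) %/% 2L + 1L              # back to 1-based position
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(regions),
    ranges = IRanges::IRanges(mid1, width = 1L),
    seqinfo = GenomeInfoDb::seqinfo(regions)
  )
}

#' Which input regions fall in a domain
#'
#' Under `hit_mode = "midpoint"` a region hits iff its midpoint base lies
#' inside the domain; under `"any_overlap"` iff it shares at least one base.
#' Input regions are never merged with one another: each region is one
#' Bernoulli trial of the binomial model.
#'
#' @param regions A `GRanges` of input regions.
#' @param domain A `GRanges` domain (merged or not; hits are by coverage).
#' @param hit_mode `"midpoint"` (default) or `"any_overlap"`.
#' @return Logical vector parallel to `regions`.
#' @export
region_hits <- function(regions, domain, hit_mode = c("midpoint", "any_overlap")) {
  hit_mode <- match.arg(hit_mode)
  probe <- if (hit_mode == "midpoint") region_midpoints(regions) else regions
  GenomicRanges::countOverlaps(probe, domain, ignore.strand = TRUE) > 0L
}

#' Count input regions falling in a domain
#'
#' @inheritParams region_hits
#' @return Integer count of hitting regions.
#' @export
count_hits <- function(regions, domain, hit_mode = c("midpoint", "any_overlap")) {
  sum(region_hits(regions, domain, hit_mode))
}
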