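#' Basal regulatory domains around TSSs
#'
#' Each gene receives a strand-aware basal window around its TSS: on the
#' plus strand `[tss - basal_upstream, tss + basal_downstream)` in 0-based
#' half-open coordinates, mirrored on the minus strand, clipped to the
#' chromosome. With the defaults (5 kb upstream, 1 kb downstream) a basal
#' domain away from chromosome ends is exactly 6000 bases wide.
#'
#' @param genes Gene annotation data.frame with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `tss` (0-based offset).
#' @param genome A `Seqinfo` genome.
#' @param basal_upstream,basal_downstream Basal window sizes in bases.
#' @return A `GRanges` (one range per gene, `gene_id` in `mcols`, stranded).
#' @export
basal_domains <- function(genes, genome, basal_upstream = 5000,
                          basal_downstream = 1000) {
  stopifnot(basal_upstream >= 0, basal_downstream >= 0)
  check_genes(genes, genome)
  check_chroms(genes$chrom, genome, what = "gene")
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, genes$tss - basal_upstream, genes$tss - basal_downstream)
  e0 <- ifelse(plus, genes$tss + basal_downstream, genes$tss + basal_upstream)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome)[genes$chrom])
  s0 <- pmax(s0, 0)
  e0 <- pmin(e0, lens)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = as.integer(s0 + 1), end = as.integer(e0)),
    strand = genes$strand,
    seqinfo = genome
  )
  gr$gene_id <- genes$gene_id
  gr
}

#' Regulatory domains: basal plus neighbour-bounded extension
#'
#' Builds the full per-gene regulatory domain. The basal window around each
#' TSS is grown in both directions up to `max_extension` bases, stopping
#' early at the nearest neighbouring gene's basal-domain boundary (any
#' strand) and at chromosome ends. A neighbour's basal domain reaching into
#' a gene's own basal window cannot shrink it: the basal domain is
#' unconditional, only the extension is bounded. Genes with identical TSS
#' are ordered by `gene_id` and bound each other at their shared basal
#' boundaries.
#'
#' @inheritParams basal_domains
#' @param max_extension Maximal extension in bases on each side (default
#'   1 Mb); `0` yields basal-only domains.
#' @return A `GRanges` of extended domains, one per gene, with `mcols`
#'   `gene_id` and `basal` (an `IRanges` of the basal window), plus `tss`.
#' @export
regulatory_domains <- function(genes, genome, basal_upstream = 5000,
                               basal_downstream = 1000, max_extension = 1e6) {
  stopifnot(max_extension >= 0)
  basal <- basal_domains(genes, genome, basal_upstream, basal_downstream)
  ord <- order(as.character(GenomeInfoDb::seqnames(basal)),
               genes$tss, genes$gene_id)
  basal <- basal[ord]
  genes <- genes[ord, , drop = FALSE]

  chrom <- as.character(GenomeInfoDb::seqnames(basal))
  bs <- GenomicRanges::start(basal)   # 1-based
  be <- GenomicRanges::end(basal)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome)[chrom])
  n <- length(basal)

  # Neighbour bounds within each chromosome (genes sorted by TSS): the
  # extension stops at the nearest basal boundary among ALL genes on that
  # side, so with mixed strands the running extremum is needed, not just the
  # immediate neighbour's boundary.
  prev_be <- rep(NA_real_, n)  # max basal end over genes sorting before i
  next_bs <- rep(NA_real_, n)  # min basal start over genes sorting after i
  for (idx in split(seq_len(n), chrom)) {
    k <- length(idx)
    if (k > 1L) {
      prev_be[idx[-1L]] <- cummax(be[idx])[-k]
      next_bs[idx[-k]] <- rev(cummin(rev(bs[idx])))[-1L]
    }
  }

  left <- pmax(bs - max_extension, 1)
  left <- ifelse(is.na(prev_be), left, pmax(left, prev_be + 1))
  left <- pmin(left, bs)              # never shrink the basal window
  right <- pmin(be + max_extension, lens)
  right <- ifelse(is.na(next_bs), right, pmin(right, next_bs - 1))
  right <- pmax(right, be)

  ext <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(as.integer(left), as.integer(right)),
    strand = GenomicRanges::strand(basal),
    seqinfo = genome
  )
  ext$gene_id <- basal$gene_id
  ext$basal <- IRanges::IRanges(bs, be)
  ext$tss <- genes$tss
  ext
}

#' Merged domain and genome fraction for one gene set
#'
#' Unions the extended regulatory domains of the gene-set members present in
#' the annotation into one merged region set, and computes the fraction `p`
#' of the genome it covers — the success probability of the binomial model.
#' Members missing from the annotation are tallied, not an error; a set with
#' no annotated member yields an empty domain with `p = 0`.
#'
#' @param gene_ids Character vector of member gene ids.
#' @param domains `GRanges` from [regulatory_domains()].
#' @param genome A `Seqinfo` genome.
#' @return A list with elements `domain` (merged `GRanges`), `p`,
#'   `n_genes_matched`, `n_genes_dropped`, `empty` (flag).
#' @export
term_domain <- function(gene_ids, domains, genome) {
  gene_ids <- unique(as.character(gene_ids))
  hit <- domains$gene_id %in% gene_ids
  dom <- GenomicRanges::reduce(domains[hit], ignore.strand = TRUE)
  n_matched <- sum(hit)
  list(
    domain = dom,
    p = total_length(dom) / genome_size(genome),
    n_genes_matched = n_matched,
    n_genes_dropped = length(gene_ids) - n_matched,
    empty = n_matched == 0L
  )
}

#' Build term domains for a whole gene-set collection
#'
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param domains `GRanges` from [regulatory_domains()].
#' @param genome A `Seqinfo` genome.
#' @return A named list of [term_domain()] results, one per set.
#' @export
build_term_domains <- function(gene_sets, domains, genome) {
  out <- lapply(gene_sets, term_domain, domains = domains, genome = genome)
  n_empty <- sum(vapply(out, `[[`, logical(1), "empty"))
  if (n_empty > 0L) {
    warning(sprintf("%d gene set(s) have no annotated member (p = 0)", n_empty),
            call. = FALSE)
  }
  out
}

#' Write per-gene extended domains as BED
#'
#' @param domains `GRanges` from [regulatory_domains()].
#' @param path Output path.
#' @export
write_domains_bed <- function(domains, path) {
  bed <- GenomicRanges::granges(domains)
  bed$name <- domains$gene_id
  write_bed(bed, path)
}
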