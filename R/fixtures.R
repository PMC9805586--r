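# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so the generator leaves no global side effects.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default synthetic-fixture configuration
#'
#' The study conditions the generator emulates: a small mammalian-like toy
#' genome (2 chromosomes of 10 Mb) with 200 genes placed uniformly, 20 gene
#' sets of 10 genes, and region sets of 500 width-100 regions — a scale at
#' which a 10-gene term's merged regulatory domain covers roughly 10% of
#' the genome under the default domain parameters, comparable to a real
#' GO-term domain fraction. `enrichment_fraction` is the share of regions
#' planted inside a chosen term's domain (0 = the uniform null of the
#' binomial model).
#'
#' @param seed Integer seed governing all draws.
#' @param n_chrom,chrom_length Genome shape.
#' @param n_genes,n_terms,genes_per_term Annotation and gene-set sizes.
#' @param n_regions,region_width Region-set shape.
#' @param enrichment_fraction Fraction of regions planted in the target
#'   domain, in [0, 1].
#' @return A named list of configuration values.
#' @export
fixture_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 1e7,
                           n_genes = 200L, n_terms = 20L, genes_per_term = 10L,
                           n_regions = 500L, region_width = 100L,
                           enrichment_fraction = 0) {
  stopifnot(n_chrom >= 1, chrom_length >= 1, n_genes >= 1, n_terms >= 1,
            genes_per_term >= 1, n_regions >= 1, region_width >= 1,
            enrichment_fraction >= 0, enrichment_fraction <= 1)
  list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
       chrom_length = as.numeric(chrom_length), n_genes = as.integer(n_genes),
       n_terms = as.integer(n_terms), genes_per_term = as.integer(genes_per_term),
       n_regions = as.integer(n_regions), region_width = as.integer(region_width),
       enrichment_fraction = as.numeric(enrichment_fraction))
}

#' Simulate a toy genome
#' @param config List from [fixture_config()].
#' @return A `Seqinfo` genome of `n_chrom` chromosomes named chr1, chr2, ...
#' @export
simulate_genome <- function(config = fixture_config()) {
  make_genome(paste0("chr", seq_len(config$n_chrom)),
              rep(config$chrom_length, config$n_chrom))
}

#' Simulate a gene annotation
#'
#' TSS positions are drawn uniformly without replacement on each
#' chromosome (genes split as evenly as possible across chromosomes);
#' strands are independent fair coin flips.
#'
#' @param genome A `Seqinfo` genome.
#' @param config List from [fixture_config()]; `config$seed` governs the
#'   draw.
#' @return A gene annotation data.frame (gene_id, chrom, strand, tss).
#' @export
simulate_genes <- function(genome, config = fixture_config()) {
  if (config$n_genes < 1L) stop("n_genes must be >= 1")
  chroms <- GenomeInfoDb::seqnames(genome)
  per <- rep(config$n_genes %/% length(chroms), length(chroms))
  extra <- config$n_genes %% length(chroms)
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  with_seed(config$seed, {
    tab <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      len <- as.numeric(GenomeInfoDb::seqlengths(genome)[i])
      data.frame(chrom = chroms[i],
                 tss = sort(sample.int(len, per[i], replace = FALSE)) - 1,
                 stringsAsFactors = FALSE)
    }))
    tab$strand <- ifelse(stats::runif(nrow(tab)) < 0.5, "+", "-")
    tab$gene_id <- sprintf("gene%04d", seq_len(nrow(tab)))
    tab[, c("gene_id", "chrom", "strand", "tss")]
  })
}

#' Simulate a gene-set collection
#'
#' `n_terms` sets of `genes_per_term` members, sampled without replacement
#' within each set from the annotated genes.
#'
#' @param genes Gene annotation data.frame.
#' @param config List from [fixture_config()].
#' @return A named list of gene-id vectors (GMT-writable), terms named
#'   term01, term02, ...
#' @export
simulate_gene_sets <- function(genes, config = fixture_config()) {
  if (config$genes_per_term > nrow(genes)) {
    stop("genes_per_term exceeds the number of annotated genes")
  }
  with_seed(config$seed + 1L, {
    sets <- lapply(seq_len(config$n_terms), function(i) {
      sample(genes$gene_id, config$genes_per_term, replace = FALSE)
    })
    names(sets) <- sprintf("term%02d", seq_len(config$n_terms))
    attr(sets, "descriptions") <- stats::setNames(
      sprintf("synthetic gene set %d", seq_len(config$n_terms)), names(sets))
    sets
  })
}

# Draw one uniform midpoint per requested region inside `domain` (a merged
# GRanges), base-weighted across its intervals. Returns 0-based positions
# and the chromosome of each.
sample_positions_in <- function(domain, n) {
  w <- as.numeric(GenomicRanges::width(domain))
  pick <- sample.int(length(domain), n, replace = TRUE, prob = w)
  offset <- floor(stats::runif(n) * w[pick])  # 0 .. width-1
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(domain))[pick],
             pos = (GenomicRanges::start(domain)[pick] - 1) + offset,
             stringsAsFactors = FALSE)
}

#' Simulate input regions (null or planted enrichment)
#'
#' With `target_domain = NULL` (or `enrichment_fraction = 0`), region
#' midpoints are uniform over the genome — the null of the binomial model.
#' Otherwise a fraction `enrichment_fraction` of midpoints is uniform
#' within `target_domain` and the remainder uniform genome-wide. Regions
#' are `region_width` bases centred on the midpoint, shifted inward at
#' chromosome ends to preserve the width.
#'
#' @param genome A `Seqinfo` genome.
#' @param config List from [fixture_config()].
#' @param target_domain Optional merged `GRanges` to plant regions into.
#' @param seed Seed for this draw; defaults to `config$seed + 2`.
#' @return A `GRanges` of `n_regions` regions named region00001, ...
#' @export
simulate_regions <- function(genome, config = fixture_config(),
                             target_domain = NULL, seed = config$seed + 2L) {
  n <- config$n_regions
  w <- config$region_width
  frac <- if (is.null(target_domain)) 0 else config$enrichment_fraction
  n_in <- round(n * frac)
  with_seed(seed, {
    genome_dom <- whole_genome_regions(genome)
    pts <- rbind(
      if (n_in > 0L) sample_positions_in(target_domain, n_in),
      if (n - n_in > 0L) sample_positions_in(genome_dom, n - n_in)
    )
    lens <- as.numeric(GenomeInfoDb::seqlengths(genome)[pts$chrom])
    s0 <- pts$pos - (w %/% 2)                 # midpoint at floor((s+e)/2)
    s0 <- pmax(0, pmin(s0, lens - w))         # shift inward at edges
    gr <- as_regions(pts$chrom, s0, s0 + w, genome,
                     name = sprintf("region%05d", seq_len(n)))
    gr
  })
}

#' Write a complete fixture to disk
#'
#' Emits the exact on-disk formats the command-line interface consumes:
#' `genome.chrom.sizes`, `genes.tsv`, `gene_sets.gmt`, `regions.bed` (and,
#' when `enrichment_fraction > 0`, regions planted into the first term's
#' domain). Byte-identical across runs for the same config.
#'
#' @param dir Output directory (created if needed).
#' @param config List from [fixture_config()].
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`genome`, `genes`, `gene_sets`, `regions`, `target_term`).
#' @export
simulate_fixture <- function(dir, config = fixture_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  genes <- simulate_genes(genome, config)
  gene_sets <- simulate_gene_sets(genes, config)
  target <- NULL
  target_term <- NA_character_
  if (config$enrichment_fraction > 0) {
    doms <- regulatory_domains(genes, genome)
    target_term <- names(gene_sets)[1L]
    target <- term_domain(gene_sets[[1L]], doms, genome)$domain
  }
  regions <- simulate_regions(genome, config, target_domain = target)
  paths <- list(
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    genes = file.path(dir, "genes.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    regions = file.path(dir, "regions.bed")
  )
  write_chrom_sizes(genome, paths$chrom_sizes)
  write_gene_table(genes, paths$genes)
  write_gmt(gene_sets, paths$gene_sets)
  write_bed(regions, paths$regions)
  invisible(c(paths, list(genome = genome, genes = genes,
                          gene_sets = gene_sets, regions = regions,
                          target_term = target_term)))
}
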