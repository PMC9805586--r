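#' Run a full GREAT analysis
#'
#' Convenience wrapper wiring the whole pipeline: regulatory-domain
#' construction from the gene annotation, per-term merged domains for the
#' gene-set collection, the binomial enrichment test (optionally
#' background-restricted), the optional hypergeometric background test,
#' and the region-gene association table with its distance histogram.
#'
#' @param regions `GRanges` of input regions.
#' @param genes Gene annotation data.frame (`gene_id`, `chrom`, `strand`,
#'   `tss`).
#' @param gene_sets Named list of gene-id vectors (e.g. [read_gmt()]).
#' @param genome A `Seqinfo` genome.
#' @param background,exclude Optional `GRanges`, mutually exclusive; see
#'   [great_enrichment()].
#' @param hypergeometric If `TRUE` (requires `background`), also run the
#'   classic hypergeometric background test.
#' @param basal_upstream,basal_downstream,max_extension Domain parameters;
#'   see [regulatory_domains()].
#' @param hit_mode `"midpoint"` (default) or `"any_overlap"`.
#' @return A list with elements `enrichment` (data.frame),
#'   `hypergeometric` (data.frame or `NULL`), `associations` (data.frame),
#'   `distance_summary` (data.frame), `domains` (`GRanges`), `terms`
#'   (list of term domains).
#' @examples
#' cfg <- fixture_config(seed = 42, enrichment_fraction = 0.4)
#' g <- simulate_genome(cfg)
#' genes <- simulate_genes(g, cfg)
#' sets <- simulate_gene_sets(genes, cfg)
#' doms <- regulatory_domains(genes, g)
#' target <- term_domain(sets[[1]], doms, g)$domain
#' regions <- simulate_regions(g, cfg, target_domain = target)
#' res <- great(regions, genes, sets, g)
#' head(res$enrichment, 3)
#' @export
great <- function(regions, genes, gene_sets, genome, background = NULL,
                  exclude = NULL, hypergeometric = FALSE,
                  basal_upstream = 5000, basal_downstream = 1000,
                  max_extension = 1e6,
                  hit_mode = c("midpoint", "any_overlap")) {
  hit_mode <- match.arg(hit_mode)
  if (hypergeometric && is.null(background)) {
    stop("the hypergeometric test requires 'background' regions")
  }
  domains <- regulatory_domains(genes, genome, basal_upstream,
                                basal_downstream, max_extension)
  terms <- build_term_domains(gene_sets, domains, genome)
  enr <- great_enrichment(regions, terms, genome, background = background,
                          exclude = exclude, hit_mode = hit_mode)
  hyp <- if (hypergeometric) {
    great_hypergeometric(regions, background, terms, genome, hit_mode)
  }
  assoc <- associate_regions(regions, domains, hit_mode)
  list(enrichment = enr,
       hypergeometric = hyp,
       associations = assoc,
       distance_summary = distance_summary(assoc),
       domains = domains,
       terms = terms)
}
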