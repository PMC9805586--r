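# Independent brute-force oracles and small construction helpers shared by
# the unit and acceptance tests. The oracles never touch the package's
# interval or tail routines.

# Build a GRanges from 0-based half-open coordinates (thin alias).
bed0 <- function(genome, chrom, start0, end0, name = NULL, strand = NULL) {
  as_regions(chrom, start0, end0, genome, name = name, strand = strand)
}

# Boolean coverage oracle: one logical vector per chromosome, TRUE where a
# base (0-based index i -> element i+1) is covered by `df`, a data.frame
# with columns chrom, start0, end0.
bool_cover <- function(df, genome) {
  lens <- GenomeInfoDb::seqlengths(genome)
  out <- lapply(stats::setNames(nm = GenomeInfoDb::seqnames(genome)),
                function(ch) logical(lens[[ch]]))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    out[[ch]][(df$start0[i] + 1):df$end0[i]] <- TRUE
  }
  out
}

# Boolean coverage of a GRanges result, for comparison with bool_cover().
bool_cover_gr <- function(gr, genome) {
  bool_cover(data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start0 = GenomicRanges::start(gr) - 1L,
                        end0 = GenomicRanges::end(gr)), genome)
}

# Random interval data.frame on `genome` (0-based half-open).
random_intervals <- function(n, genome, max_width = 500) {
  chroms <- GenomeInfoDb::seqnames(genome)
  ch <- sample(chroms, n, replace = TRUE)
  lens <- GenomeInfoDb::seqlengths(genome)[ch]
  w <- sample.int(max_width, n, replace = TRUE)
  w <- pmin(w, lens)
  s0 <- floor(runif(n) * (lens - w + 1))
  data.frame(chrom = ch, start0 = s0, end0 = s0 + w)
}

# Direct pmf-summation binomial upper tail via log binomial coefficients;
# independent of stats::pbinom.
binom_tail_oracle <- function(n_hits, n_trials, p) {
  if (n_hits == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- n_hits:n_trials
  sum(exp(lchoose(n_trials, k) + k * log(p) + (n_trials - k) * log1p(-p)))
}

# Enumeration oracle for the hypergeometric upper tail.
hyper_tail_oracle <- function(N_bg, N_fg, n_bg, n_fg) {
  if (n_fg == 0) return(1)
  k <- n_fg:min(N_fg, n_bg)
  sum(exp(lchoose(n_bg, k) + lchoose(N_bg - n_bg, N_fg - k) -
            lchoose(N_bg, N_fg)))
}

# Textbook BH step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Tiny deterministic fixture shared by several enrichment tests: one 1 Mb
# chromosome, a single term whose domain covers bases [0, 200000)
# (p = 0.2), and ten width-1 regions of which five lie in the domain.
toy_enrichment_fixture <- function() {
  genome <- make_genome("chr1", 1e6)
  domain <- bed0(genome, "chr1", 0, 200000)
  mids <- c(seq(10000, 170000, by = 40000),   # 5 inside [0, 200000)
            seq(210000, 970000, by = 190000)) # 5 outside
  regions <- bed0(genome, "chr1", mids, mids + 1)
  terms <- list(toy_term = list(domain = domain, p = 0.2,
                                n_genes_matched = 1L))
  list(genome = genome, domain = domain, regions = regions, terms = terms)
}

# Standard seeded fixture bundle used by statistical tests.
standard_fixture <- function(seed = 7, ...) {
  cfg <- fixture_config(seed = seed, ...)
  genome <- simulate_genome(cfg)
  genes <- simulate_genes(genome, cfg)
  sets <- simulate_gene_sets(genes, cfg)
  domains <- regulatory_domains(genes, genome)
  terms <- build_term_domains(sets, domains, genome)
  list(cfg = cfg, genome = genome, genes = genes, sets = sets,
       domains = domains, terms = terms)
}
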