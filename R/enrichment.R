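#' Exact binomial upper tail
#'
#' Enrichment P-value of the binomial model: with `n_trials` regions each
#' falling in a domain of genome fraction `p_domain` independently, returns
#' `Pr(X >= n_hits)` for `X ~ Binomial(n_trials, p_domain)`. Computed with
#' the exact tail routine for every `n_trials`; no normal approximation.
#'
#' @param n_hits Observed hit count (0..n_trials).
#' @param n_trials Number of input regions (Bernoulli trials).
#' @param p_domain Genome (or background) fraction covered by the domain.
#' @return Upper-tail probability in (0, 1]; exactly 1 when `n_hits == 0`.
#' @export
binomial_tail <- function(n_hits, n_trials, p_domain) {
  if (any(p_domain < 0 | p_domain > 1)) {
    stop("p_domain must lie in [0, 1]")
  }
  if (any(n_hits < 0) || any(n_hits > n_trials)) {
    stop("n_hits must lie in [0, n_trials]")
  }
  ifelse(n_hits == 0, 1,
         stats::pbinom(n_hits - 1, n_trials, p_domain, lower.tail = FALSE))
}

#' Exact hypergeometric upper tail
#'
#' Classic GREAT background test: of `N_bg` background regions, `n_bg` fall
#' in the term domain; `N_fg` foreground regions are drawn from the
#' background, of which `n_fg` fall in the domain. Returns
#' `Pr(X >= n_fg)` for `X ~ Hypergeometric(N_bg, N_fg, n_bg)`.
#'
#' @param N_bg Number of background regions (population size).
#' @param N_fg Number of foreground regions (draws), `<= N_bg`.
#' @param n_bg Background regions in the domain (successes), `<= N_bg`.
#' @param n_fg Foreground regions in the domain, `<= min(N_fg, n_bg)`.
#' @return Upper-tail probability in (0, 1]; exactly 1 when `n_fg == 0`.
#' @export
hypergeometric_tail <- function(N_bg, N_fg, n_bg, n_fg) {
  if (any(N_fg > N_bg) || any(n_bg > N_bg)) {
    stop("require N_fg <= N_bg and n_bg <= N_bg")
  }
  if (any(n_fg < 0) || any(n_fg > pmin(N_fg, n_bg))) {
    stop("require 0 <= n_fg <= min(N_fg, n_bg)")
  }
  ifelse(n_fg == 0, 1,
         stats::phyper(n_fg - 1, n_bg, N_bg - n_bg, N_fg, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across all terms of one run;
#' monotone, clipped at 1, input order preserved.
#'
#' @param p_values Numeric vector of raw P-values.
#' @return Adjusted P-values, same order as the input.
#' @export
adjust_bh <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

# Resolve the effective universe and label for a background specification.
resolve_universe <- function(genome, background = NULL, exclude = NULL) {
  if (!is.null(background) && !is.null(exclude)) {
    stop("'background' and 'exclude' are mutually exclusive")
  }
  if (!is.null(background)) {
    if (length(background) == 0L) {
      stop("background region set is empty")
    }
    list(kind = "background",
         universe = merge_regions(background, genome))
  } else if (!is.null(exclude) && length(exclude) > 0L) {
    validate_regions(exclude, genome, "exclude region")
    list(kind = "exclude",
         universe = subtract_regions(whole_genome_regions(genome), exclude))
  } else {
    list(kind = "none", universe = NULL)
  }
}

#' Binomial GREAT enrichment over a term collection
#'
#' The core region-based enrichment test. Without a background, each term's
#' hit count among the `N` input regions is tested against
#' `Binomial(N, p)` where `p` is the genome fraction of the term's merged
#' regulatory domain. When `background` regions (or `exclude` regions,
#' their complement) are given, the generalized background-restricted test
#' is used: domains are intersected with the universe `U`, giving
#' `p2 = |domain \eqn{\cap} U| / |U|`; trials are the `N2` whole input
#' regions falling in `U`; hits are the `n2` regions falling in the
#' restricted domain; and the P-value is the `Binomial(N2, p2)` upper tail.
#' Input regions are never fragmented: each remains one trial.
#'
#' @param regions `GRanges` of input regions.
#' @param terms Named list from [build_term_domains()].
#' @param genome A `Seqinfo` genome.
#' @param background Optional `GRanges` of pre-selected background regions.
#' @param exclude Optional `GRanges` of regions removed from the genome.
#'   Mutually exclusive with `background`.
#' @param hit_mode `"midpoint"` (default) or `"any_overlap"`.
#' @return A data.frame, one row per term, sorted by `p_binomial` then
#'   `term_id`, with columns `term_id`, `n_genes`, `p_domain`, `n_trials`,
#'   `n_hits`, `expected`, `fold_enrichment`, `p_binomial`, `p_adjusted`.
#' @export
great_enrichment <- function(regions, terms, genome, background = NULL,
                             exclude = NULL,
                             hit_mode = c("midpoint", "any_overlap")) {
  hit_mode <- match.arg(hit_mode)
  if (length(regions) == 0L) stop("no input regions")
  if (length(terms) == 0L) stop("no terms to test")
  validate_regions(regions, genome, "input region")

  bg <- resolve_universe(genome, background, exclude)
  if (bg$kind == "none") {
    n_trials <- length(regions)
    rows <- lapply(names(terms), function(id) {
      tm <- terms[[id]]
      n <- count_hits(regions, tm$domain, hit_mode)
      data.frame(term_id = id, n_genes = tm$n_genes_matched,
                 p_domain = tm$p, n_trials = n_trials, n_hits = n)
    })
  } else {
    U <- bg$universe
    u_len <- total_length(U)
    if (u_len == 0) stop("effective universe has zero length")
    in_universe <- region_hits(regions, U, hit_mode)
    n_trials <- sum(in_universe)
    if (n_trials == 0L) {
      stop("no input region overlaps the background universe; ",
           "the background does not cover the input regions")
    }
    kept <- regions[in_universe]
    rows <- lapply(names(terms), function(id) {
      tm <- terms[[id]]
      d2 <- intersect_regions(tm$domain, U)
      p2 <- total_length(d2) / u_len
      n2 <- count_hits(kept, d2, hit_mode)
      data.frame(term_id = id, n_genes = tm$n_genes_matched,
                 p_domain = p2, n_trials = n_trials, n_hits = n2)
    })
  }
  tab <- do.call(rbind, rows)
  if (any(tab$p_domain == 0 & tab$n_hits > 0)) {
    stop("internal inconsistency: hits counted in a zero-measure domain")
  }
  tab$expected <- tab$n_trials * tab$p_domain
  tab$fold_enrichment <- ifelse(tab$expected > 0, tab$n_hits / tab$expected,
                                NA_real_)
  tab$p_binomial <- binomial_tail(tab$n_hits, tab$n_trials, tab$p_domain)
  tab$p_adjusted <- adjust_bh(tab$p_binomial)
  tab <- tab[order(tab$p_binomial, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Hypergeometric GREAT background test
#'
#' The classic GREAT variant: foreground regions must be an exact
#' coordinate subset of the background regions. Per term, the number of
#' foreground regions in the domain is tested against
#' `Hypergeometric(N_bg, N_fg, n_bg)`.
#'
#' @param fg_regions `GRanges` of foreground (input) regions; every one
#'   must coincide exactly (chrom, start, end) with a background region.
#' @param bg_regions `GRanges` of background regions.
#' @inheritParams great_enrichment
#' @return A data.frame sorted by `p_hypergeometric` then `term_id`, with
#'   columns `term_id`, `n_genes`, `N_bg`, `N_fg`, `n_bg`, `n_fg`,
#'   `expected`, `fold_enrichment`, `p_hypergeometric`, `p_adjusted`.
#' @export
great_hypergeometric <- function(fg_regions, bg_regions, terms, genome,
                                 hit_mode = c("midpoint", "any_overlap")) {
  hit_mode <- match.arg(hit_mode)
  if (length(fg_regions) == 0L) stop("no foreground regions")
  if (length(bg_regions) == 0L) stop("no background regions")
  validate_regions(fg_regions, genome, "foreground region")
  validate_regions(bg_regions, genome, "background region")

  key <- function(gr) sprintf("%s:%d-%d",
                              as.character(GenomeInfoDb::seqnames(gr)),
                              GenomicRanges::start(gr),
                              GenomicRanges::end(gr))
  missing <- setdiff(key(fg_regions), key(bg_regions))
  if (length(missing)) {
    stop("foreground regions not present in the background (must be an ",
         "exact subset): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L)
         else "")
  }

  N_bg <- length(bg_regions)
  N_fg <- length(fg_regions)
  rows <- lapply(names(terms), function(id) {
    tm <- terms[[id]]
    n_bg <- count_hits(bg_regions, tm$domain, hit_mode)
    n_fg <- count_hits(fg_regions, tm$domain, hit_mode)
    expected <- N_fg * n_bg / N_bg
    data.frame(term_id = id, n_genes = tm$n_genes_matched,
               N_bg = N_bg, N_fg = N_fg, n_bg = n_bg, n_fg = n_fg,
               expected = expected,
               fold_enrichment = ifelse(expected > 0, n_fg / expected, NA_real_),
               p_hypergeometric = hypergeometric_tail(N_bg, N_fg, n_bg, n_fg))
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- adjust_bh(tab$p_hypergeometric)
  tab <- tab[order(tab$p_hypergeometric, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an enrichment table
#'
#' Tab-delimited, one row per term, deterministic column order and row
#' order as returned by the enrichment functions.
#'
#' @param tab Data.frame from [great_enrichment()] or
#'   [great_hypergeometric()].
#' @param path Output path.
#' @export
write_enrichment <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
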