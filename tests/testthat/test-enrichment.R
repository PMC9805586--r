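test_that("binomial_tail matches pmf summation and handles edge cases", {
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(10, 10, 1), 1)
  # frozen from the lchoose pmf-summation oracle
  expect_equal(binomial_tail(5, 10, 0.2), binom_tail_oracle(5, 10, 0.2),
               tolerance = 1e-14)
  expect_equal(binom_tail_oracle(5, 10, 0.2), 0.0327934976, tolerance = 1e-9)
  expect_error(binomial_tail(5, 4, 0.2), "n_trials")
  expect_error(binomial_tail(1, 10, 1.2), "0, 1")
})

test_that("binomial tail is non-increasing in the hit count and complements the lower pmf sum", {
  for (p in c(0.05, 0.3, 0.7)) {
    for (N in c(1, 7, 50)) {
      tails <- binomial_tail(0:N, N, p)
      expect_true(all(diff(tails) <= 1e-15))
      # Pr(X >= n) + Pr(X <= n-1) == 1 via independent pmf summation
      for (n in 1:N) {
        lower <- sum(vapply(0:(n - 1), function(k) {
          exp(lchoose(N, k) + k * log(p) + (N - k) * log1p(-p))
        }, numeric(1)))
        expect_equal(binomial_tail(n, N, p) + lower, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric_tail matches enumeration and guards its preconditions", {
  expect_equal(hypergeometric_tail(20, 5, 8, 0), 1)
  expect_equal(hypergeometric_tail(20, 5, 8, 4), hyper_tail_oracle(20, 5, 8, 4),
               tolerance = 1e-14)
  # draw-all degenerate case: foreground == background
  expect_equal(hypergeometric_tail(20, 20, 8, 8), 1)
  expect_error(hypergeometric_tail(20, 25, 8, 4), "N_fg <= N_bg")
  expect_error(hypergeometric_tail(20, 5, 8, 6), "min")
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(adjust_bh(0.01), 0.01)
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_bh(p), bh_oracle(p))
  withr::with_seed(2, {
    p <- runif(50)
    expect_equal(adjust_bh(p), bh_oracle(p))
  })
})

test_that("the toy one-term run reproduces hand-computed binomial statistics", {
  fx <- toy_enrichment_fixture()
  res <- great_enrichment(fx$regions, fx$terms, fx$genome)
  expect_equal(res$n_trials, 10)
  expect_equal(res$n_hits, 5)
  expect_equal(res$p_domain, 0.2)
  expect_equal(res$expected, 2)
  expect_equal(res$fold_enrichment, 2.5)
  expect_equal(res$p_binomial, binom_tail_oracle(5, 10, 0.2), tolerance = 1e-14)
  expect_equal(res$p_adjusted, res$p_binomial)
})

test_that("whole-genome background and empty exclude reproduce the plain run bit-for-bit", {
  fx <- standard_fixture(seed = 21)
  regions <- simulate_regions(fx$genome, fx$cfg)
  plain <- great_enrichment(regions, fx$terms, fx$genome)
  bg <- great_enrichment(regions, fx$terms, fx$genome,
                         background = whole_genome_regions(fx$genome))
  ex <- great_enrichment(regions, fx$terms, fx$genome,
                         exclude = GenomicRanges::GRanges(seqinfo = fx$genome))
  expect_identical(plain, bg)
  expect_identical(plain, ex)
})

test_that("background restriction recomputes p2, N2 and n2 within the universe", {
  fx <- toy_enrichment_fixture()
  # universe: bases [0, 400000) -> domain fraction doubles to 0.5,
  # and only the 6 regions with midpoints < 400000 remain trials
  U <- bed0(fx$genome, "chr1", 0, 400000)
  res <- great_enrichment(fx$regions, fx$terms, fx$genome, background = U)
  expect_equal(res$p_domain, 0.5)
  expect_equal(res$n_trials, 6)
  expect_equal(res$n_hits, 5)
  expect_equal(res$p_binomial, binom_tail_oracle(5, 6, 0.5), tolerance = 1e-14)
  # the same universe expressed as its complement via exclude
  res2 <- great_enrichment(fx$regions, fx$terms, fx$genome,
                           exclude = bed0(fx$genome, "chr1", 400000, 1e6))
  expect_equal(res2, res)
})

test_that("degenerate backgrounds are rejected with actionable errors", {
  fx <- toy_enrichment_fixture()
  far <- bed0(fx$genome, "chr1", 900000, 950000)
  r <- bed0(fx$genome, "chr1", 100, 200)
  expect_error(great_enrichment(r, fx$terms, fx$genome, background = far),
               "does not cover")
  expect_error(
    great_enrichment(fx$regions, fx$terms, fx$genome,
                     exclude = whole_genome_regions(fx$genome)),
    "zero length")
  expect_error(
    great_enrichment(fx$regions, fx$terms, fx$genome,
                     background = far, exclude = far),
    "mutually exclusive")
})

test_that("rows are ordered by binomial P-value with term_id tie-breaks", {
  fx <- standard_fixture(seed = 13)
  regions <- simulate_regions(fx$genome, fx$cfg)
  res <- great_enrichment(regions, fx$terms, fx$genome)
  expect_equal(nrow(res), length(fx$terms))
  expect_true(!is.unsorted(res$p_binomial))
  ties <- split(res$term_id, res$p_binomial)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
  expect_true(all(res$p_adjusted >= res$p_binomial))
})

test_that("hypergeometric run enforces the exact-subset requirement", {
  fx <- toy_enrichment_fixture()
  bg <- fx$regions
  fg <- bg[1:4]
  expect_silent(great_hypergeometric(fg, bg, fx$terms, fx$genome))
  rogue <- bed0(fx$genome, "chr1", 123, 456)
  expect_error(great_hypergeometric(c(fg, rogue), bg, fx$terms, fx$genome),
               "chr1:124-456")
})

test_that("foreground equal to background yields P = 1 everywhere", {
  fx <- standard_fixture(seed = 23)
  regions <- simulate_regions(fx$genome, fx$cfg)
  res <- great_hypergeometric(regions, regions, fx$terms, fx$genome)
  expect_true(all(res$p_hypergeometric == 1))
  expect_equal(res$N_bg, res$N_fg)
  expect_equal(res$n_bg, res$n_fg)
})

test_that("with disjoint background regions p2 equals the width-ratio identity", {
  # p2 = sum of widths of background regions inside the domain over the
  # total background width, when background regions are disjoint and each
  # lies fully inside or outside the domain
  fx <- toy_enrichment_fixture()
  s0 <- seq(0, 999000, by = 2000)          # 500 disjoint width-500 regions
  bg <- bed0(fx$genome, "chr1", s0, s0 + 500)
  inside <- s0 + 500 <= 200000
  res <- great_enrichment(bg[seq(1, 500, by = 5)], fx$terms, fx$genome,
                          background = bg)
  expect_equal(res$p_domain, sum(inside) * 500 / (500 * 500))
  expect_equal(res$p_domain, count_hits(bg, fx$terms[[1]]$domain) / length(bg))
})

test_that("an improper oversized background can only deflate P-values", {
  # regions truly sampled from chr1 only; testing genome-wide underestimates
  # p and yields a P-value no larger than the chr1-restricted test
  fx <- standard_fixture(seed = 31)
  chr1 <- whole_genome_regions(fx$genome)[1]
  chr1_genes <- fx$genes$gene_id[fx$genes$chrom == "chr1"][1:10]
  term1 <- list(chr1_term = term_domain(chr1_genes, fx$domains, fx$genome))
  for (rep in 1:5) {
    cfg <- fixture_config(seed = 100 + rep, n_regions = 300,
                          enrichment_fraction = 0.3)
    regions <- simulate_regions(fx$genome, cfg,
                                target_domain = term1[[1]]$domain,
                                seed = cfg$seed)
    # keep only the chr1 part of the draw: chr1 is the true universe
    regions <- regions[GenomeInfoDb::seqnames(regions) == "chr1"]
    p_wide <- great_enrichment(regions, term1, fx$genome)$p_binomial
    p_restricted <- great_enrichment(regions, term1, fx$genome,
                                     background = chr1)$p_binomial
    expect_lte(p_wide, p_restricted)
  }
})

test_that("empty-domain terms are reported with p = 0 and P = 1", {
  fx <- toy_enrichment_fixture()
  terms <- c(fx$terms, list(ghost = list(domain = GenomicRanges::GRanges(
    seqinfo = fx$genome), p = 0, n_genes_matched = 0L)))
  res <- great_enrichment(fx$regions, terms, fx$genome)
  ghost <- res[res$term_id == "ghost", ]
  expect_equal(ghost$p_binomial, 1)
  expect_equal(ghost$n_hits, 0)
  expect_true(is.na(ghost$fold_enrichment))
})
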