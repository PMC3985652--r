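test_that("gene-richness coefficient follows its definition", {
  g <- genome(c("c1", "c2"), c(1e6, 9e6))
  # c1: 20% of genes on 10% of bp -> GRC 2
  genes <- gene_set(sprintf("g%02d", 1:10),
                    c(rep("c1", 2), rep("c2", 8)),
                    seq(0, 9e5, length.out = 10),
                    seq(0, 9e5, length.out = 10) + 1000,
                    rep("+", 10))
  grc <- gene_richness(genes, g)
  expect_equal(unname(grc["c1"]), 2)
  expect_equal(unname(grc["c2"]), 8 / 10 / 0.9)

  # gene fraction equal to bp fraction everywhere -> all 1
  g2 <- genome(c("a", "b"), c(2e5, 6e5))
  genes2 <- gene_set(sprintf("g%02d", 1:4),
                     c("a", "b", "b", "b"),
                     c(0, 0, 1e5, 2e5), c(100, 100, 1e5 + 100, 2e5 + 100),
                     rep("+", 4))
  expect_equal(unname(gene_richness(genes2, g2)), c(1, 1))
})

test_that("bp-weighted mean GRC is exactly 1 for random placements", {
  set.seed(55)
  for (rep in 1:100) {
    nc <- sample(2:6, 1)
    lens <- sample(1e5:1e6, nc)
    g <- genome(paste0("c", 1:nc), lens)
    N <- sample(5:200, 1)
    ch <- sample(g$chrom_names, N, replace = TRUE, prob = lens)
    st <- floor(runif(N) * (lens[match(ch, g$chrom_names)] - 200))
    genes <- gene_set(sprintf("g%04d", 1:N), ch, st, st + 100,
                      sample(c("+", "-"), N, TRUE))
    grc <- gene_richness(genes, g)
    expect_equal(sum(grc * lens / sum(lens)), 1, tolerance = 1e-12)
  }
})

test_that("chromosome occupancy averages each chromosome's bins", {
  g <- tiny_genome(c(chrA = 1000, chrB = 500))
  const <- constant_track(g, 50, 2.5)
  pm <- signal_track(list(chrA = rep(1, 20), chrB = rep(-1, 10)), 50, g)
  occ <- chromosome_occupancy(list(v1 = const, v2 = pm))
  expect_equal(occ["v1", ], c(chrA = 2.5, chrB = 2.5))
  expect_equal(occ["v2", ], c(chrA = 1, chrB = -1))

  rt <- random_track(g, 50, seed = 81)
  occ2 <- chromosome_occupancy(list(r = rt))
  expect_equal(unname(occ2["r", "chrA"]), mean(rt$values$chrA))
  expect_equal(unname(occ2["r", "chrB"]), mean(rt$values$chrB))
})

test_that("occupancy clustering uses correlation distance with fallbacks", {
  occ <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
               c = c(4, 3, 2, 1))
  cl <- cluster_occupancy(occ, "variants")
  # identical profiles (up to scale) merge at distance 0
  m <- cl$hclust$merge; h <- cl$hclust$height
  expect_equal(min(h), 0)
  # anti-correlated rows sit at distance 2
  expect_equal(max(h), 2)

  flat <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(0, 0, 0))
  expect_warning(cl2 <- cluster_occupancy(flat, "variants"),
                 "zero-variance")
  expect_setequal(cl2$flagged, c("a", "c"))
})

test_that("region enrichment is n.s. on constant signal and deterministic", {
  g <- tiny_genome(c(chrA = 1e5, chrB = 1e5))
  tr <- constant_track(g, 50, 1)
  regs <- region_set(c("chrA", "chrA", "chrB"), c(1000, 20000, 5000),
                     c(3000, 24000, 9000))
  res <- region_enrichment_test(tr, regs, n_null = 50, seed = 4)
  expect_gte(res$p_value, 0.05)
  expect_equal(res$direction, "n.s.")

  noise <- random_track(g, 50, seed = 91)
  r1 <- region_enrichment_test(noise, regs, n_null = 100, seed = 17)
  r2 <- region_enrichment_test(noise, regs, n_null = 100, seed = 17)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- region_enrichment_test(noise, regs, n_null = 100, seed = 18)
  expect_false(identical(r1$null, r3$null))

  expect_error(region_enrichment_test(noise, regs, n_null = 2), "n_null")
})

test_that("enrichment direction tracks a planted mean shift", {
  g <- genome("chrA", 2e5)
  set.seed(95)
  v <- rnorm(4000)
  regs <- region_set("chrA", c(10000, 50000, 120000), c(20000, 60000, 130000))
  for (i in seq_len(nrow(regs)))
    v[(regs$start[i] / 50 + 1):(regs$end[i] / 50)] <-
      v[(regs$start[i] / 50 + 1):(regs$end[i] / 50)] + 2
  tr <- signal_track(list(chrA = v), 50, g)
  up <- region_enrichment_test(tr, regs, n_null = 200, seed = 5)
  expect_equal(up$direction, "enriched")
  expect_lt(up$p_value, 0.05)
  tr2 <- signal_track(list(chrA = -v), 50, g)
  dn <- region_enrichment_test(tr2, regs, n_null = 200, seed = 5)
  expect_equal(dn$direction, "depleted")
})

test_that("GC correlation recovers exact affine relations and rescales", {
  g <- tiny_genome(c(chrA = 50000, chrB = 30000))
  gc <- random_track(g, 50, seed = 101,
                     fun = function(n) runif(n, 0.3, 0.7))
  lin <- signal_track(lapply(gc$values, function(v) 3 * v + 1), 50, g)
  expect_equal(gc_correlation(lin, gc, 1000)$r, 1.0, tolerance = 1e-12)
  neg <- signal_track(lapply(gc$values, function(v) -v), 50, g)
  expect_equal(gc_correlation(neg, gc, 1000)$r, -1.0, tolerance = 1e-12)

  noisy <- random_track(g, 50, seed = 102)
  r0 <- gc_correlation(noisy, gc, 1000)$r
  scaled <- signal_track(lapply(noisy$values, function(v) -2 * v + 7),
                         50, g)
  r1 <- gc_correlation(scaled, gc, 1000)$r
  expect_equal(r1, -r0, tolerance = 1e-12)

  flat <- constant_track(g, 50, 2)
  expect_error(gc_correlation(flat, gc, 1000), "signal")
  expect_error(gc_correlation(noisy, constant_track(g, 50, 0.5), 1000),
               "GC")
})

test_that("GC correlation sign and magnitude recover the generative slope", {
  # high depth on a small genome keeps sampling attenuation low enough to
  # compare against the intensity field's own correlation
  truth <- generate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 0,
                           n_lads = 0, seed = 7)
  for (slope in c(-0.8, 0.8)) {
    m <- variant_model(gc_coupling = slope, depth = 4e6, seed = 11)
    sim <- simulate_reads(truth, m)
    sub <- normalize_subtract(bin_coverage(sim$chip, truth$genome),
                              bin_coverage(sim$input, truth$genome))
    r_hat <- gc_correlation(sub, truth$gc, 1000)$r
    field_1kb <- rebin_means(sim$field, 1000)$chr1
    gc_1kb <- rebin_means(truth$gc, 1000)$chr1
    r_field <- stats::cor(field_1kb, gc_1kb)
    expect_equal(sign(r_hat), sign(slope))
    expect_lt(abs(r_hat - r_field), 0.15)
  }
})

test_that("distal promoter scores are strand-aware and match the oracle", {
  g <- tiny_genome(c(chrA = 40000, chrB = 20000))
  tr <- constant_track(g, 50, 4)
  genes <- small_gene_fixture(g, n = 10, seed = 111, len = 2000)
  genes$start <- genes$start %/% 2 + 8000  # keep windows in bounds
  genes$end <- genes$start + 2000
  sc <- distal_promoter_score(tr, genes)
  expect_true(all(sc == 4))

  # a ramp distinguishes the two strands: the window sits on opposite sides
  ramp <- signal_track(lapply(g$chrom_lengths,
                              function(L) seq_len(ceiling(L / 50))), 50, g)
  pair <- gene_set(c("p", "m"), "chrA", c(20000, 20000), c(22000, 22000),
                   c("+", "-"))
  sp <- distal_promoter_score(ramp, pair)
  expect_lt(sp[["p"]], sp[["m"]])

  tr2 <- random_track(g, 50, seed = 112)
  genes30 <- small_gene_fixture(g, n = 30, seed = 113, len = 1200)
  got <- distal_promoter_score(tr2, genes30)
  for (i in seq_len(30)) {
    tss <- gene_tss(genes30)[i]
    if (genes30$strand[i] == "+") {
      s <- tss - 3200; e <- tss - 2000
    } else {
      s <- tss + 2001; e <- tss + 3201
    }
    expect_equal(unname(got[i]),
                 oracle_bp_mean(tr2, genes30$chrom[i], s, e),
                 tolerance = 1e-9)
  }
})

test_that("top/bottom overlap analysis honours rank symmetry and sizes", {
  g <- tiny_genome(c(chrA = 1e6))
  set.seed(121)
  N <- 200
  genes <- gene_set(sprintf("g%04d", 1:N), "chrA", (1:N) * 4000,
                    (1:N) * 4000 + 2000, rep("+", N),
                    expression = rlnorm(N))
  sa <- rnorm(N); names(sa) <- genes$id
  ov_same <- decile_overlap_analysis(sa, sa, genes, fraction = 0.1)
  k <- ov_same$k
  expect_equal(k, 20)
  expect_equal(unname(ov_same$counts), c(k, 0, 0, k))
  ov_anti <- decile_overlap_analysis(sa, -sa, genes, fraction = 0.1)
  expect_equal(unname(ov_anti$counts), c(0, k, k, 0))

  expect_error(decile_overlap_analysis(sa, sa, genes, fraction = 0.6),
               "fraction")

  # determinism under ties: duplicated scores resolve by gene id
  sb <- rep(c(1, 2), length.out = N); names(sb) <- genes$id
  o1 <- decile_overlap_analysis(sa, sb, genes)
  o2 <- decile_overlap_analysis(sa, sb, genes)
  expect_identical(o1$sets, o2$sets)

  # expression test flags a low-expression intersection
  lowexpr <- genes
  lowexpr$expression[1:20] <- lowexpr$expression[1:20] / 50
  sa2 <- c(rep(10, 20), rnorm(N - 20)); names(sa2) <- genes$id
  sb2 <- c(rep(-10, 20), rnorm(N - 20)); names(sb2) <- genes$id
  ov <- decile_overlap_analysis(sa2, sb2, lowexpr, fraction = 0.1)
  expect_equal(ov$expression_tests$hl$n, 20)
  expect_equal(ov$expression_tests$hl$direction, "lower")
  expect_lt(ov$expression_tests$hl$p_value, 0.05)
})
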