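test_that("the gap rule splits eligible windows further apart than gap", {
  # construct two read pile-ups whose windows are separated by 400 bp of
  # empty windows; with gap = 200 they must stay distinct islands
  g <- genome("chrA", 20000)
  mk_pile <- function(center, n) {
    read_set("chrA", rep(center, n), rep("+", n), g)
  }
  # use redundancy threshold high enough to keep the stacks
  par <- island_params(window = 200, gap = 200, fdr = 0.5,
                       min_fold_change = 0.1, redundancy_threshold = 1000)
  chip <- read_set("chrA", c(rep(100, 50), rep(700, 50)),
                   rep("+", 100), g)
  input <- uniform_reads(g, 100, seed = 1)
  isl <- call_islands(chip, input, g, par)
  expect_equal(nrow(isl), 2)
  expect_true(all(isl$end - isl$start <= 400))

  # same stacks 200 bp apart merge into one island
  chip2 <- read_set("chrA", c(rep(100, 50), rep(500, 50)),
                    rep("+", 100), g)
  isl2 <- call_islands(chip2, input, g, par)
  expect_equal(nrow(isl2), 1)
})

test_that("islands are disjoint, span >= 1 window, and empty input is safe", {
  g <- genome("chrA", 1e6)
  set.seed(5)
  hot <- sample(c(2e5, 5e5, 8e5), 3000, replace = TRUE) +
    sample.int(2000, 3000, replace = TRUE)
  chip <- read_set("chrA", c(uniform_reads(g, 20000, seed = 2)$pos, hot),
                   strand = sample(c("+", "-"), 23000, TRUE), g)
  input <- uniform_reads(g, 23000, seed = 3)
  isl <- call_islands(chip, input, g,
                      island_params(fdr = 0.05, min_fold_change = 1.5))
  expect_gt(nrow(isl), 0)
  expect_true(all(isl$end - isl$start >= 200))
  if (nrow(isl) > 1) {
    o <- order(isl$start)
    expect_true(all(isl$start[o][-1] >= isl$end[o][-nrow(isl)]))
  }
  expect_true(all(isl$q_value <= 0.05))
  expect_true(all(isl$fold_change >= 1.5))

  none <- read_set(character(0), numeric(0), character(0), g)
  expect_equal(nrow(call_islands(none, input, g)), 0)
  expect_error(call_islands(chip, input, genome("c", 100),
                            island_params(window = 200)), "window")
})

test_that("depleted calling equals enriched calling with channels swapped", {
  g <- genome("chrA", 5e5)
  set.seed(7)
  chip <- uniform_reads(g, 20000, seed = 11)
  cold <- uniform_reads(g, 30000, seed = 12)
  par <- island_params(fdr = 0.2, min_fold_change = 1.2)
  dep <- call_islands(chip, cold, g, par, direction = "depleted")
  enr_swapped <- call_islands(cold, chip, g, par, direction = "enriched")
  expect_equal(dep$start, enr_swapped$start)
  expect_equal(dep$chip_count, enr_swapped$chip_count)
  expect_equal(dep$p_value, enr_swapped$p_value)
  expect_equal(unique(dep$direction),
               if (nrow(dep)) "depleted" else character(0))
})

test_that("nearest-gene annotation matches the O(n*m) oracle and tie rule", {
  g <- tiny_genome(c(chrA = 100000, chrB = 50000))
  genes <- small_gene_fixture(g, n = 200, seed = 51, len = 400)
  set.seed(52)
  n <- 1000
  ch <- sample(g$chrom_names, n, replace = TRUE)
  st <- floor(runif(n) * (g$chrom_lengths[ch] - 500))
  islands <- region_set(ch, st, st + sample(100:500, n, TRUE))
  got <- annotate_nearest_gene(islands, genes)
  want <- oracle_nearest_gene(islands, genes)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$distance, want$distance)

  # island centred exactly on a TSS
  tss1 <- gene_tss(genes)[1]
  isl0 <- region_set(genes$chrom[1], tss1 - 10, tss1 + 11)
  ann <- annotate_nearest_gene(isl0, genes)
  expect_equal(ann$distance, 0)

  # equidistant between two TSSs: smaller coordinate wins
  g2 <- genome("chrA", 10000)
  two <- gene_set(c("left", "right"), "chrA", c(1000, 3000),
                  c(2000, 4000), c("+", "+"))
  mid_isl <- region_set("chrA", 1999, 2002)  # midpoint 2000, both 1000 away
  expect_equal(annotate_nearest_gene(mid_isl, two)$gene_id, "left")

  # chromosome without genes is flagged unassigned
  nogene <- region_set("chrB", 0, 100)
  expect_true(is.na(annotate_nearest_gene(
    nogene, two[two$chrom == "chrA", ])$gene_id))
})

test_that("feature classification follows the midpoint priority rules", {
  g <- genome("chrA", 100000)
  exons <- list(rbind(c(20000, 20500), c(24000, 24600), c(27000, 28000)),
                NULL)
  genes <- gene_set(c("gA", "gB"), "chrA", c(20000, 50000),
                    c(28000, 56000), c("+", "-"),
                    cds_start = c(20300, NA), cds_end = c(27500, NA),
                    exons = exons)
  cases <- list(
    list(19000, "promoter"),        # 1 kb upstream of gA TSS
    list(20100, "5'UTR"),           # first exon before CDS start
    list(24100, "exon"),            # internal exon inside CDS
    list(22000, "intron"),
    list(27800, "3'UTR"),           # last exon past CDS end
    list(29000, "downstream"),      # within 3 kb past gA TTS
    list(53000, "genic"),           # gB has no exon structure
    list(57000, "promoter"),        # gB is minus strand: promoter right of TSS
    list(48000, "downstream"),      # gB minus strand: downstream left of body
    list(95000, "distal intergenic"))
  for (cs in cases) {
    reg <- region_set("chrA", cs[[1]] - 5, cs[[1]] + 5)
    expect_equal(as.character(classify_feature(reg, genes)), cs[[2]],
                 label = paste("midpoint", cs[[1]]))
  }

  # nested annotation: promoter of one gene inside body of another wins
  host <- gene_set(c("host", "inner"), "chrA", c(10000, 16000),
                   c(30000, 18000), c("+", "+"))
  reg <- region_set("chrA", 14000 - 5, 14000 + 5)  # in host body, 2 kb
  expect_equal(as.character(classify_feature(reg, host)), "promoter")
})

test_that("target genes respect the strand-aware extended span to the base", {
  g <- genome("chrA", 100000)
  genes <- gene_set(c("p", "m"), "chrA", c(50000, 80000),
                    c(52000, 82000), c("+", "-"))
  # span of p: [45000, 55000); touching by exactly 1 bp
  expect_equal(target_genes(region_set("chrA", 44999, 45001), genes)$id,
               "p")
  expect_equal(nrow(target_genes(region_set("chrA", 44999, 45000), genes)),
               0)
  expect_equal(target_genes(region_set("chrA", 54999, 55100), genes)$id,
               "p")
  expect_equal(nrow(target_genes(region_set("chrA", 55000, 55100), genes)),
               0)
  # span of m: [77000, 87000)
  expect_equal(target_genes(region_set("chrA", 86999, 87100), genes)$id,
               "m")
  expect_equal(nrow(target_genes(region_set("chrA", 87000, 87100), genes)),
               0)

  # 50-gene fixture against a brute-force span check
  genes50 <- small_gene_fixture(tiny_genome(c(chrA = 2e5)), n = 50,
                                seed = 61, len = 1500)
  set.seed(62)
  isl <- region_set("chrA", st <- floor(runif(40) * 198000), st + 800)
  got <- target_genes(isl, genes50)
  span_s <- ifelse(genes50$strand == "+", genes50$start - 5000,
                   genes50$start - 3000)
  span_e <- ifelse(genes50$strand == "+", genes50$end + 3000,
                   genes50$end + 5000)
  hits <- vapply(seq_len(50), function(i) {
    sum(pmin(span_e[i], isl$end) - pmax(span_s[i], isl$start) >= 1)
  }, 0)
  expect_equal(got$id, genes50$id[hits > 0])
  expect_equal(got$n_islands, unname(hits[hits > 0]))
})

test_that("overlap detection is half-open exact and matches the O(n^2) oracle", {
  a <- region_set("chrA", 0, 10)
  expect_true(overlap_regions(a, region_set("chrA", 9, 20))$a_hit)
  expect_false(overlap_regions(a, region_set("chrA", 10, 20))$a_hit)
  expect_false(overlap_regions(a, region_set("chrB", 0, 10))$a_hit)

  g <- tiny_genome(c(chrA = 5e4, chrB = 5e4))
  set.seed(71)
  mk <- function(n) {
    ch <- sample(g$chrom_names, n, replace = TRUE)
    st <- floor(runif(n) * 49000)
    region_set(ch, st, st + sample(20:800, n, TRUE))
  }
  A <- mk(300); B <- mk(300)
  got <- overlap_regions(A, B)$pairs
  want <- oracle_overlap_pairs(A, B)
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
})

test_that("LAD-seeking variants yield more intergenic island bp than GC-seekers", {
  # strong generative contrast so both variants actually produce islands
  # at the FC >= 2 / FDR 0.01 operating point
  frac_distal <- function(isl, genes) {
    bp <- isl$end - isl$start
    f <- classify_feature(isl, genes)
    sum(bp[f == "distal intergenic"]) / sum(bp)
  }
  n_seeds <- 10
  wins <- 0L
  for (s in seq_len(n_seeds)) {
    truth <- generate_genome(seed = 700 + s)
    m_lad <- variant_model(gc_coupling = -1.5, lad_log_enrichment = 1.5,
                           depth = 1e6, seed = 710 + s)
    m_gc <- variant_model(gc_coupling = 6, lad_log_enrichment = -1.5,
                          depth = 1e6, seed = 720 + s)
    sim_lad <- simulate_reads(truth, m_lad)
    sim_gc <- simulate_reads(truth, m_gc)
    isl_lad <- call_islands(sim_lad$chip, sim_lad$input, truth$genome)
    isl_gc <- call_islands(sim_gc$chip, sim_gc$input, truth$genome)
    if (nrow(isl_lad) > 0 && nrow(isl_gc) > 0 &&
        frac_distal(isl_lad, truth$genes) > frac_distal(isl_gc, truth$genes))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
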