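#' Gene-richness coefficient per chromosome
#'
#' For each chromosome, the ratio of its share of genes to its share of
#' genomic base pairs: `(genes_c / genes_total) / (bp_c / bp_total)`.
#' Gene-poor chromosomes score below 1, gene-rich above; the
#' bp-weighted mean of the coefficients is exactly 1.
#'
#' @param genes an `h1_genes` data frame.
#' @param genome an `h1_genome`.
#' @return Named numeric vector of GRC values, one per chromosome
#'   (0 for chromosomes without genes).
#' @export
gene_richness <- function(genes, genome) {
  if (nrow(genes) == 0) stop("need at least one gene")
  if (any(genome$chrom_lengths <= 0)) stop("zero-length chromosome")
  n_c <- table(factor(genes$chrom, levels = genome$chrom_names))
  gene_frac <- as.numeric(n_c) / nrow(genes)
  bp_frac <- genome$chrom_lengths / genome$total_bp
  out <- gene_frac / bp_frac
  names(out) <- genome$chrom_names
  out
}

#' Mean occupancy per chromosome for a set of variants
#'
#' The per-chromosome average of each variant's input-subtracted binned
#' signal, returned as a variants x chromosomes matrix.
#'
#' @param tracks named list of `h1_track`s (one per variant) sharing a
#'   genome and bin size.
#' @return Numeric matrix (variants in rows, chromosomes in columns).
#' @export
chromosome_occupancy <- function(tracks) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  ref <- tracks[[1]]
  for (t in tracks) check_same_grid(ref, t)
  chroms <- ref$genome$chrom_names
  mat <- t(vapply(tracks, function(tr) {
    vapply(chroms, function(ch) mean(tr$values[[ch]]), 0)
  }, numeric(length(chroms))))
  dimnames(mat) <- list(names(tracks), chroms)
  mat
}

#' Hierarchical clustering of occupancy profiles
#'
#' Average-linkage agglomerative clustering with distance `1 - Pearson
#' correlation` computed across the other axis. Zero-variance items (for
#' which correlation is undefined) are flagged and fall back to scaled
#' Euclidean distance for the pairs involving them, with a warning.
#'
#' @param occ occupancy matrix from [chromosome_occupancy()].
#' @param axis cluster "variants" (rows) or "chromosomes" (columns).
#' @return A list with `hclust` (the tree), `order` (leaf order),
#'   `labels`, and `flagged` (zero-variance item names).
#' @export
cluster_occupancy <- function(occ, axis = c("variants", "chromosomes")) {
  axis <- match.arg(axis)
  m <- if (axis == "variants") occ else t(occ)
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  sds <- apply(m, 1, stats::sd)
  flagged <- rownames(m)[sds == 0]
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (length(flagged))
    warning("zero-variance item(s): ", paste(flagged, collapse = ", "),
            "; Euclidean fallback used for their distances")
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      if (sds[i] == 0 || sds[j] == 0) {
        dv <- sqrt(mean((m[i, ] - m[j, ])^2))
      } else {
        dv <- 1 - stats::cor(m[i, ], m[j, ])
      }
      d[i, j] <- d[j, i] <- dv
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, order = hc$order, labels = rownames(m),
       flagged = flagged)
}

#' Signal enrichment of a region class against a random-window null
#'
#' The observed distribution is the per-region mean signal; the null is
#' the per-window mean signal of `n_null` random windows whose widths are
#' resampled from the observed width multiset and which are placed
#' uniformly genome-wide (start uniform over valid positions, so windows
#' never run past a chromosome end). The two samples are compared with a
#' two-sided two-sample Kolmogorov-Smirnov test; the direction is the
#' sign of `median(observed) - median(null)` when significant at `alpha`.
#'
#' @param track an `h1_track` (typically input-subtracted signal).
#' @param regions an `h1_regions` data frame (nonempty).
#' @param n_null number of null windows (>= number of regions).
#' @param alpha significance level for the direction call.
#' @param seed RNG seed for the null sample.
#' @return A list of class `h1_enrichment` with fields `n_regions`,
#'   `observed`, `null`, `D`, `p_value`, `direction` ("enriched",
#'   "depleted" or "n.s.") and `seed`.
#' @export
region_enrichment_test <- function(track, regions, n_null = 1000,
                                   alpha = 0.05, seed = 1) {
  if (nrow(regions) == 0) stop("no regions: nothing to test")
  if (n_null < nrow(regions))
    stop("n_null must be at least the number of regions")
  widths <- regions$end - regions$start
  lens <- track$genome$chrom_lengths
  if (max(widths) > max(lens))
    stop("a region is wider than every chromosome")
  observed <- region_mean_signal(track, regions)
  null_regions <- with_seed(seed, {
    w <- sample(widths, n_null, replace = TRUE)
    chrom <- character(n_null); start <- numeric(n_null)
    for (i in seq_len(n_null)) {
      valid <- lens - w[i]
      valid[valid < 0] <- NA
      pr <- valid + 1
      pr[is.na(pr)] <- 0
      ch <- sample(names(lens), 1, prob = pr)
      chrom[i] <- ch
      start[i] <- floor(stats::runif(1) * (lens[[ch]] - w[i] + 1))
    }
    region_set(chrom, start, start + w)
  })
  null_means <- region_mean_signal(track, null_regions)
  ks <- suppressWarnings(stats::ks.test(observed, null_means))
  direction <- if (ks$p.value >= alpha) "n.s."
  else if (stats::median(observed) > stats::median(null_means)) "enriched"
  else "depleted"
  structure(list(n_regions = nrow(regions), observed = observed,
                 null = null_means, D = unname(ks$statistic),
                 p_value = ks$p.value, direction = direction,
                 seed = as.integer(seed)),
            class = "h1_enrichment")
}

#' @export
print.h1_enrichment <- function(x, ...) {
  cat(sprintf("<h1_enrichment> %d regions, D = %.3f, p = %.3g, %s\n",
              x$n_regions, x$D, x$p_value, x$direction))
  invisible(x)
}

#' Correlation between signal and GC content in coarse windows
#'
#' Both tracks are averaged into non-overlapping windows of `window` bp
#' (which must be a multiple of both bin sizes) and the Pearson
#' correlation is computed across windows.
#'
#' @param track signal `h1_track`.
#' @param gc GC-content `h1_track` on the same genome.
#' @param window window width in bp (default 1000).
#' @return A list with `r`, `n_windows` and `table` (per-window signal
#'   and GC values).
#' @export
gc_correlation <- function(track, gc, window = 1000) {
  if (window %% track$bin_size != 0 || window %% gc$bin_size != 0)
    stop("window must be a multiple of both bin sizes")
  s <- unlist(rebin_means(track, window), use.names = FALSE)
  g <- unlist(rebin_means(gc, window), use.names = FALSE)
  n <- min(length(s), length(g))
  s <- s[seq_len(n)]; g <- g[seq_len(n)]
  ok <- is.finite(s) & is.finite(g)
  s <- s[ok]; g <- g[ok]
  if (stats::sd(s) == 0) stop("signal track has zero variance across windows")
  if (stats::sd(g) == 0) stop("GC track has zero variance across windows")
  list(r = stats::cor(s, g), n_windows = length(s),
       table = data.frame(signal = s, gc = g))
}

#' Per-gene mean signal at the distal promoter
#'
#' The strand-aware window `[-3200, -2000)` bp relative to the TSS by
#' default. Windows truncated by a chromosome start are averaged over the
#' available bp; fully out-of-bounds windows give `NA`.
#'
#' @param track an `h1_track`.
#' @param genes an `h1_genes` data frame.
#' @param window two offsets (bp relative to TSS, upstream negative)
#'   defining the half-open scoring window.
#' @return Named numeric vector of per-gene scores.
#' @export
distal_promoter_score <- function(track, genes, window = c(-3200, -2000)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  tss <- gene_tss(genes)
  out <- rep(NA_real_, nrow(genes))
  for (chrom in unique(genes$chrom)) {
    rows <- which(genes$chrom == chrom)
    pre <- track_prefix(track, chrom)
    L <- chrom_length(track$genome, chrom)
    plus <- genes$strand[rows] == "+"
    # transcriptional offsets [w1, w2) map to genomic coordinates
    s <- ifelse(plus, tss[rows] + window[1], tss[rows] - window[2] + 1)
    e <- ifelse(plus, tss[rows] + window[2], tss[rows] - window[1] + 1)
    out[rows] <- interval_mean(pre, s, e, L)
  }
  names(out) <- genes$id
  out
}

#' Top/bottom overlap analysis of two per-gene scores
#'
#' Ranks the common gene universe by each score, takes the top and bottom
#' `ceiling(fraction * N)` genes of each (ties broken by gene id for
#' determinism), counts the four intersections (highA&highB, highA&lowB,
#' lowA&highB, lowA&lowB), and KS-tests each intersection's expression
#' distribution against the full universe.
#'
#' @param scores_a,scores_b named per-gene scores (names = gene ids).
#' @param genes an `h1_genes` data frame carrying expression.
#' @param fraction tail fraction in (0, 0.5].
#' @param alpha significance level for the direction call.
#' @return A list with `counts` (named vector hh/hl/lh/ll), `sets` (the
#'   four id vectors), `expression_tests` (per intersection: n, median,
#'   KS D, p, direction vs universe) and `n_universe`.
#' @export
decile_overlap_analysis <- function(scores_a, scores_b, genes,
                                    fraction = 0.10, alpha = 0.05) {
  if (!(fraction > 0 && fraction <= 0.5))
    stop("fraction must be in (0, 0.5]")
  ids <- intersect(names(scores_a)[!is.na(scores_a)],
                   names(scores_b)[!is.na(scores_b)])
  N <- length(ids)
  if (N < 1 / fraction)
    stop("common gene universe too small for fraction ", fraction)
  k <- ceiling(fraction * N)
  pick <- function(s, top) {
    v <- s[ids]
    o <- if (top) order(-v, ids) else order(v, ids)
    ids[o][seq_len(k)]
  }
  highA <- pick(scores_a, TRUE); lowA <- pick(scores_a, FALSE)
  highB <- pick(scores_b, TRUE); lowB <- pick(scores_b, FALSE)
  sets <- list(hh = intersect(highA, highB), hl = intersect(highA, lowB),
               lh = intersect(lowA, highB), ll = intersect(lowA, lowB))
  expr <- genes$expression[match(ids, genes$id)]
  names(expr) <- ids
  universe_expr <- expr[!is.na(expr)]
  tests <- lapply(sets, function(s) {
    e <- expr[s]; e <- e[!is.na(e)]
    if (length(e) < 3)
      return(list(n = length(e), median = stats::median(e),
                  D = NA_real_, p_value = NA_real_, direction = "n.s."))
    ks <- suppressWarnings(stats::ks.test(e, universe_expr))
    dir <- if (ks$p.value >= alpha) "n.s."
    else if (stats::median(e) > stats::median(universe_expr)) "higher"
    else "lower"
    list(n = length(e), median = stats::median(e),
         D = unname(ks$statistic), p_value = ks$p.value, direction = dir)
  })
  list(counts = vapply(sets, length, 0L), sets = sets,
       expression_tests = tests, n_universe = N, k = k)
}
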