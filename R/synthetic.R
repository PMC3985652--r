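#' Generative model of one H1 variant's ChIP intensity
#'
#' The per-bin ChIP intensity over the synthetic genome is
#' `exp(gc_coupling * GC + lad_log_enrichment * in_LAD)` multiplied, per
#' gene, by a TSS valley factor `1 - d_g * K(x - tss_g)` (Gaussian bump
#' `K` of scale `valley_halfwidth`; `d_g` is `tss_valley_depth` scaled by
#' the gene's expression rank, so the valley deepens with expression) and
#' an optional +1-nucleosome factor `1 + plus1_peak_amp * K1(x - tss_g -
#' 125)` (strand-aware, `K1` of 100 bp scale). Negative `gc_coupling` with
#' positive `lad_log_enrichment`, a deep wide valley and no +1 peak
#' mimics H1.2; the flipped signs with a shallower valley and a +1 peak
#' mimic H1.0/H1X-type variants.
#'
#' @param gc_coupling slope of log-intensity per unit GC fraction.
#' @param lad_log_enrichment log fold change of intensity inside LADs.
#' @param tss_valley_depth maximal fractional intensity dip at the TSS of
#'   the most-expressed genes, in `[0, 1]`.
#' @param valley_halfwidth Gaussian scale of the valley, bp (> 0).
#' @param plus1_peak_amp amplitude of the +125 bp downstream peak (>= 0).
#' @param depth target read count per library (>= 1).
#' @param seed integer RNG seed for read sampling.
#' @return A list of class `h1_variant_model`.
#' @export
variant_model <- function(gc_coupling = 0, lad_log_enrichment = 0,
                          tss_valley_depth = 0, valley_halfwidth = 500,
                          plus1_peak_amp = 0, depth = 2e6, seed = 1) {
  stopifnot(depth >= 1, valley_halfwidth > 0,
            tss_valley_depth >= 0, tss_valley_depth <= 1,
            plus1_peak_amp >= 0)
  structure(list(gc_coupling = gc_coupling,
                 lad_log_enrichment = lad_log_enrichment,
                 tss_valley_depth = tss_valley_depth,
                 valley_halfwidth = valley_halfwidth,
                 plus1_peak_amp = plus1_peak_amp,
                 depth = depth, seed = as.integer(seed)),
            class = "h1_variant_model")
}

#' H1.2-like and H1X-like model presets
#'
#' Effect sizes chosen once for the package's recovery experiments:
#' H1.2-like couples negatively to GC, is enriched in LADs, carries a deep
#' wide TSS valley and no +1 peak; the H1X-like preset flips every sign
#' and adds the +1-nucleosome peak with a shallower, narrower valley.
#'
#' @param depth reads per library.
#' @param seed RNG seed for read sampling.
#' @return An `h1_variant_model`.
#' @export
h12_like_model <- function(depth = 2e6, seed = 1) {
  variant_model(gc_coupling = -0.8, lad_log_enrichment = 0.7,
                tss_valley_depth = 0.9, valley_halfwidth = 900,
                plus1_peak_amp = 0, depth = depth, seed = seed)
}

#' @rdname h12_like_model
#' @export
h1x_like_model <- function(depth = 2e6, seed = 1) {
  variant_model(gc_coupling = 0.8, lad_log_enrichment = -0.7,
                tss_valley_depth = 0.45, valley_halfwidth = 400,
                plus1_peak_amp = 0.6, depth = depth, seed = seed)
}

# Run a block with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Moving-average smoother with edge shrinkage (window of 2k+1 bins).
running_mean <- function(x, k) {
  if (k < 1 || length(x) < 3) return(x)
  cs <- c(0, cumsum(x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - k, 1); hi <- pmin(i + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Generate a synthetic genome, GC landscape, LADs, genes and expression
#'
#' The GC track (50 bp bins) is a smoothed Gaussian random walk squashed
#' logistically into `[0.3, 0.7]`, giving an autocorrelated landscape with
#' long-range structure. LADs are centred on the lowest-GC stretches.
#' Genes (fixed 2 kb bodies, >= 1 kb spacing) are placed with probability
#' proportional to `exp(gamma * GC)` (`gamma = 5`), and land outside LADs
#' with probability 0.8. Expression is LogNormal(0, 1), scaled down 4-fold
#' inside LADs.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes to place.
#' @param n_lads number of LADs to place.
#' @param seed integer RNG seed.
#' @param gene_length gene body length in bp.
#' @param gene_spacing minimum gap between gene bodies in bp.
#' @param lad_width LAD width in bp.
#' @param gc_gamma gene-placement GC preference (log-weight per unit GC).
#' @param p_outside_lad probability a gene lands outside LADs.
#' @return A list of class `h1_truth` with elements `genome`, `gc`
#'   (`h1_track`), `lads` (`h1_regions`), `genes` (`h1_genes`) and the
#'   generation parameters. Read intensity is added by [simulate_reads()].
#' @export
generate_genome <- function(n_chrom = 2, chrom_length = 5e6, n_genes = 400,
                            n_lads = 20, seed = 1,
                            gene_length = 2000, gene_spacing = 1000,
                            lad_width = 100000, gc_gamma = 5,
                            p_outside_lad = 0.8) {
  stopifnot(n_chrom >= 1, chrom_length >= 1e4, n_genes >= 0, n_lads >= 0)
  gen <- genome(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom))
  B <- 50L
  with_seed(seed, {
    gc_vals <- lapply(gen$chrom_names, function(ch) {
      nb <- n_bins(chrom_length, B)
      w <- cumsum(stats::rnorm(nb))
      s <- running_mean(w, 100)       # ~10 kb smoothing window
      z <- (s - mean(s)) / max(stats::sd(s), 1e-12)
      0.3 + 0.4 * stats::plogis(z)
    })
    names(gc_vals) <- gen$chrom_names
    gc <- signal_track(gc_vals, B, gen)

    # LADs on the lowest-GC stretches: score candidate windows by mean GC
    lads <- local({
      if (n_lads == 0)
        return(region_set(character(0), numeric(0), numeric(0)))
      cand <- do.call(rbind, lapply(gen$chrom_names, function(ch) {
        starts <- seq(0, chrom_length - lad_width, by = lad_width / 2)
        v <- gc$values[[ch]]
        sc <- vapply(starts, function(s) {
          mean(v[(s %/% B + 1):min((s + lad_width) %/% B, length(v))])
        }, 0)
        data.frame(chrom = ch, start = starts, score = sc)
      }))
      cand <- cand[order(cand$score), ]
      picked <- list()
      for (i in seq_len(nrow(cand))) {
        if (length(picked) >= n_lads) break
        ok <- all(vapply(picked, function(p) {
          p$chrom != cand$chrom[i] ||
            cand$start[i] >= p$start + lad_width ||
            cand$start[i] + lad_width <= p$start
        }, TRUE))
        if (ok) picked <- c(picked, list(cand[i, ]))
      }
      if (length(picked) < n_lads)
        stop("could not place ", n_lads, " non-overlapping LADs")
      p <- do.call(rbind, picked)
      p <- p[order(match(p$chrom, gen$chrom_names), p$start), ]
      region_set(p$chrom, p$start, p$start + lad_width,
                 name = paste0("LAD", seq_len(nrow(p))))
    })

    in_lad_bin <- lad_indicator(lads, gc)

    genes <- local({
      if (n_genes == 0) {
        return(gene_set(character(0), character(0), numeric(0) + 1,
                        numeric(0) + 2, character(0)))
      }
      slot <- gene_length + gene_spacing
      placed <- vector("list", n_genes)
      occupied <- lapply(gen$chrom_names, function(ch) integer(0))
      names(occupied) <- gen$chrom_names
      # per-bin placement weight from GC, thinned inside LADs
      wts <- lapply(gen$chrom_names, function(ch) {
        w <- exp(gc_gamma * gc$values[[ch]])
        w * ifelse(in_lad_bin[[ch]] > 0, (1 - p_outside_lad), p_outside_lad)
      })
      names(wts) <- gen$chrom_names
      # candidate (chrom, bin) draws from the joint weight via inverse CDF
      allw <- unlist(wts, use.names = FALSE)
      cumw <- cumsum(allw)
      nb_per <- lengths(wts)
      chrom_of <- rep(gen$chrom_names, nb_per)
      bin_of <- unlist(lapply(nb_per, seq_len), use.names = FALSE)
      draw_batch <- function(m) {
        i <- findInterval(stats::runif(m) * cumw[length(cumw)], cumw) + 1
        list(chrom = chrom_of[i], start = (bin_of[i] - 1) * B)
      }
      k <- 0L; tries <- 0L; max_tries <- n_genes * 200L
      batch <- draw_batch(max(2L * n_genes, 64L)); bi <- 0L
      while (k < n_genes && tries < max_tries) {
        tries <- tries + 1L
        bi <- bi + 1L
        if (bi > length(batch$chrom)) {
          batch <- draw_batch(max(2L * n_genes, 64L)); bi <- 1L
        }
        ch <- batch$chrom[bi]; start <- batch$start[bi]
        if (start + gene_length > chrom_length) next
        slot_id <- start %/% slot
        near <- occupied[[ch]]
        if (any(abs(near - slot_id) <= 1)) next  # enforces >= spacing gap
        occupied[[ch]] <- c(near, slot_id)
        k <- k + 1L
        placed[[k]] <- data.frame(chrom = ch, start = start)
      }
      if (k < n_genes)
        stop("gene placement failed after ", tries, " tries: placed ", k,
             " of ", n_genes, " (occupancy too high)")
      p <- do.call(rbind, placed)
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      expr <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
      mid <- p$start + gene_length / 2
      inl <- in_region(lads, p$chrom, mid)
      expr[inl] <- expr[inl] / 4
      o <- order(match(p$chrom, gen$chrom_names), p$start)
      gene_set(sprintf("g%04d", seq_len(n_genes)), p$chrom[o], p$start[o],
               p$start[o] + gene_length, strand[o],
               expression = expr[o], genome = gen)
    })

    structure(list(genome = gen, gc = gc, lads = lads, genes = genes,
                   seed = as.integer(seed),
                   params = list(n_chrom = n_chrom,
                                 chrom_length = chrom_length,
                                 n_genes = n_genes, n_lads = n_lads,
                                 gene_length = gene_length,
                                 gene_spacing = gene_spacing,
                                 lad_width = lad_width,
                                 gc_gamma = gc_gamma,
                                 p_outside_lad = p_outside_lad)),
              class = "h1_truth")
  })
}

# Fraction of each GC-grid bin covered by a LAD (0/1 at LAD resolution).
lad_indicator <- function(lads, gc) {
  out <- lapply(names(gc$values), function(ch) {
    v <- numeric(length(gc$values[[ch]]))
    sub <- lads[lads$chrom == ch, , drop = FALSE]
    if (nrow(sub)) {
      B <- gc$bin_size
      for (j in seq_len(nrow(sub))) {
        k1 <- sub$start[j] %/% B + 1
        k2 <- min((sub$end[j] - 1) %/% B + 1, length(v))
        v[k1:k2] <- 1
      }
    }
    v
  })
  names(out) <- names(gc$values)
  out
}

in_region <- function(regions, chrom, pos) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    sub <- regions[regions$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(sub) == 0) next
    for (j in seq_len(nrow(sub)))
      out[idx] <- out[idx] | (pos[idx] >= sub$start[j] & pos[idx] < sub$end[j])
  }
  out
}

#' Per-bin ChIP intensity field of a variant model over a synthetic genome
#'
#' @param truth an `h1_truth` from [generate_genome()].
#' @param model an `h1_variant_model`.
#' @return An `h1_track` of non-negative intensities (arbitrary scale).
#' @export
intensity_field <- function(truth, model) {
  gc <- truth$gc
  B <- gc$bin_size
  inlad <- lad_indicator(truth$lads, gc)
  genes <- truth$genes
  # expression rank scaled to (0, 1]; highest expression -> 1
  d_g <- numeric(nrow(genes))
  if (nrow(genes) > 0) {
    r <- rank(genes$expression, ties.method = "first")
    d_g <- model$tss_valley_depth * r / nrow(genes)
  }
  tss <- gene_tss(genes)
  sgn <- ifelse(genes$strand == "+", 1, -1)
  plus1_scale <- 100
  vals <- lapply(names(gc$values), function(ch) {
    v <- exp(model$gc_coupling * gc$values[[ch]] +
               model$lad_log_enrichment * inlad[[ch]])
    rows <- which(genes$chrom == ch)
    if (length(rows)) {
      centers <- (seq_along(v) - 0.5) * B
      for (r_i in rows) {
        w <- 4 * model$valley_halfwidth
        k1 <- max(floor((tss[r_i] - w) / B) + 1, 1)
        k2 <- min(floor((tss[r_i] + w) / B) + 1, length(v))
        if (k2 >= k1) {
          x <- centers[k1:k2] - tss[r_i]
          bump <- exp(-x^2 / (2 * model$valley_halfwidth^2))
          v[k1:k2] <- v[k1:k2] * (1 - d_g[r_i] * bump)
        }
        if (model$plus1_peak_amp > 0) {
          c1 <- tss[r_i] + sgn[r_i] * 125
          w1 <- 4 * plus1_scale
          j1 <- max(floor((c1 - w1) / B) + 1, 1)
          j2 <- min(floor((c1 + w1) / B) + 1, length(v))
          if (j2 >= j1) {
            x <- centers[j1:j2] - c1
            peak <- exp(-x^2 / (2 * plus1_scale^2))
            v[j1:j2] <- v[j1:j2] * (1 + model$plus1_peak_amp * peak)
          }
        }
      }
    }
    if (any(v < 0)) stop("negative intensity; check tss_valley_depth")
    v
  })
  names(vals) <- names(gc$values)
  signal_track(vals, B, truth$genome)
}

sample_reads_from_field <- function(field, genome, depth) {
  B <- field$bin_size
  counts <- lapply(field$values, function(v) v)
  p <- unlist(field$values, use.names = FALSE)
  tot <- sum(p)
  if (tot <= 0) stop("intensity field sums to zero")
  draw <- stats::rmultinom(1, size = depth, prob = p / tot)[, 1]
  nb <- lengths(field$values)
  chrom_of_bin <- rep(names(field$values), nb)
  bin_within <- unlist(lapply(nb, seq_len), use.names = FALSE) - 1
  nz <- draw > 0
  chrom <- rep(chrom_of_bin[nz], draw[nz])
  bstart <- rep(bin_within[nz] * B, draw[nz])
  # uniform bp within the (possibly clipped) bin
  Ls <- genome$chrom_lengths[chrom]
  width <- pmin(bstart + B, Ls) - bstart
  pos <- bstart + floor(stats::runif(length(bstart)) * width)
  strand <- ifelse(stats::runif(length(pos)) < 0.5, "+", "-")
  read_set(chrom, pos, strand, genome = genome)
}

#' Simulate ChIP and input read sets
#'
#' ChIP reads are a multinomial sample of 5' positions from the model's
#' normalised intensity field (strand uniform, position uniform within the
#' sampled 50 bp bin); input reads are sampled from a uniform field. Both
#' libraries are `model$depth` reads.
#'
#' @param truth an `h1_truth`.
#' @param model an `h1_variant_model`.
#' @param simulate_input set FALSE to skip the input library (e.g. when
#'   several variants share one control).
#' @return A list with `chip` and `input` (`h1_reads`; `input` is NULL
#'   when skipped), and `field` (the `h1_track` intensity the chip reads
#'   were drawn from).
#' @export
simulate_reads <- function(truth, model, simulate_input = TRUE) {
  field <- intensity_field(truth, model)
  with_seed(model$seed, {
    chip <- sample_reads_from_field(field, truth$genome, model$depth)
    input <- if (simulate_input)
      sample_reads_from_field(constant_track(truth$genome, 50, 1),
                              truth$genome, model$depth)
    list(chip = chip, input = input, field = field)
  })
}

#' Write the full synthetic fixture bundle
#'
#' Emits chrom.sizes, genes.tsv, expression.tsv, lads.bed, gc.bedgraph,
#' chip.bed, input.bed and truth.yaml (model and genome parameters) into
#' a directory.
#'
#' @param truth an `h1_truth`.
#' @param reads the list returned by [simulate_reads()].
#' @param model the `h1_variant_model` used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(truth, reads, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(truth$genome, file.path(dir, "chrom.sizes"))
  write_genes(truth$genes, file.path(dir, "genes.tsv"),
              file.path(dir, "expression.tsv"))
  write_bed(truth$lads, file.path(dir, "lads.bed"))
  write_bedgraph(truth$gc, file.path(dir, "gc.bedgraph"))
  write_reads_bed(reads$chip, file.path(dir, "chip.bed"))
  write_reads_bed(reads$input, file.path(dir, "input.bed"))
  yaml::write_yaml(list(model = unclass(model),
                        genome = truth$params, seed = truth$seed),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
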