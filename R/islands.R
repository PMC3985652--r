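#' Island-calling parameters (SICER-style)
#'
#' Defaults are the standard histone-mark settings: 200 bp windows, 200 bp
#' gaps, 150 bp fragments, effective genome fraction 0.75, redundancy
#' threshold 1, FDR 0.01 and a minimum fold change of 2.
#'
#' @param window scoring window in bp.
#' @param gap maximal run of ineligible windows bridged inside an island,
#'   in bp (must be a multiple of `window`).
#' @param fdr island q-value cutoff in (0, 1).
#' @param min_fold_change minimum library-normalised chip/input fold
#'   change of a reported island.
#' @param fragment_size read extension in bp.
#' @param effective_genome_fraction fraction of the genome considered
#'   mappable when computing the background rate.
#' @param redundancy_threshold maximal reads kept per (position, strand).
#' @param window_p per-window Poisson eligibility p-value (SICER's
#'   first-stage filter).
#' @return A list of class `h1_island_params`.
#' @export
island_params <- function(window = 200, gap = 200, fdr = 0.01,
                          min_fold_change = 2.0, fragment_size = 150,
                          effective_genome_fraction = 0.75,
                          redundancy_threshold = 1, window_p = 0.2) {
  stopifnot(window >= 1, gap %% window == 0, fdr > 0, fdr < 1,
            min_fold_change > 0, fragment_size >= 1,
            effective_genome_fraction > 0, effective_genome_fraction <= 1,
            redundancy_threshold >= 1, window_p > 0, window_p < 1)
  structure(list(window = as.integer(window), gap = as.integer(gap),
                 fdr = fdr, min_fold_change = min_fold_change,
                 fragment_size = as.integer(fragment_size),
                 effective_genome_fraction = effective_genome_fraction,
                 redundancy_threshold = as.integer(redundancy_threshold),
                 window_p = window_p),
            class = "h1_island_params")
}

# Extended-fragment midpoints binned into non-overlapping windows.
window_counts <- function(reads, genome, params) {
  W <- params$window
  F <- params$fragment_size
  half <- F %/% 2
  out <- list()
  for (chrom in genome$chrom_names) {
    L <- chrom_length(genome, chrom)
    nw <- n_bins(L, W)
    idx <- reads$chrom == chrom
    if (!any(idx)) { out[[chrom]] <- integer(nw); next }
    sgn <- (reads$strand[idx] == "+") * 2L - 1L
    mid <- reads$pos[idx] + sgn * half
    mid <- pmin(pmax(mid, 0), L - 1)
    out[[chrom]] <- tabulate(mid %/% W + 1, nbins = nw)
  }
  out
}

#' SICER-style enriched or depleted island calling
#'
#' Reads are deduplicated (redundancy threshold), extended-fragment
#' midpoints are assigned to non-overlapping windows, and windows whose
#' count exceeds the Poisson background threshold (upper-tail p <
#' `window_p` at rate `libsize * window / (total_bp *
#' effective_genome_fraction)`) are merged into islands, bridging at most
#' `gap` bp of ineligible windows. Each island gets a Poisson score (sum
#' of `-ln P(count)` over its eligible windows), an upper-tail Poisson
#' p-value on its span's total chip count, Benjamini-Hochberg q-values
#' across islands, and a library-normalised fold change versus input
#' (input pseudocount of one read); reported islands satisfy `q <= fdr`
#' and `fold_change >= min_fold_change`. Depleted islands are called by
#' swapping the chip and input channels.
#'
#' @param chip,input `h1_reads` sets.
#' @param genome an `h1_genome`.
#' @param params an `h1_island_params`.
#' @param direction "enriched" or "depleted".
#' @return A data frame of class `h1_islands` (columns chrom, start, end,
#'   chip_count, input_count, fold_change, score, p_value, q_value,
#'   direction), sorted by genomic position.
#' @export
call_islands <- function(chip, input, genome, params = island_params(),
                         direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (direction == "depleted") {
    tmp <- chip; chip <- input; input <- tmp
  }
  if (any(genome$chrom_lengths < params$window))
    stop("genome chromosome smaller than one window")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), chip_count = integer(0),
                      input_count = integer(0), fold_change = numeric(0),
                      score = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), direction = character(0))
  class(empty) <- c("h1_islands", "data.frame")
  if (nrow(chip) == 0) return(empty)

  chip <- dedup_reads(chip, params$redundancy_threshold)
  input <- dedup_reads(input, params$redundancy_threshold)
  chip_lib <- nrow(chip); input_lib <- max(nrow(input), 1)
  W <- params$window
  lambda0 <- chip_lib * W /
    (genome$total_bp * params$effective_genome_fraction)
  # smallest count with upper-tail probability < window_p
  k0 <- stats::qpois(1 - params$window_p, lambda0) + 1

  cc <- window_counts(chip, genome, params)
  ic <- window_counts(input, genome, params)
  gap_w <- params$gap %/% W

  islands <- list()
  for (chrom in genome$chrom_names) {
    counts <- cc[[chrom]]
    elig <- which(counts >= k0)
    if (!length(elig)) next
    brk <- c(0, which(diff(elig) > gap_w + 1), length(elig))
    for (b in seq_len(length(brk) - 1)) {
      wset <- elig[(brk[b] + 1):brk[b + 1]]
      w1 <- wset[1]; w2 <- wset[length(wset)]
      span_w <- w1:w2
      chip_n <- sum(counts[span_w])
      input_n <- sum(ic[[chrom]][span_w])
      score <- -sum(stats::dpois(counts[wset], lambda0, log = TRUE))
      lam_isl <- lambda0 * length(span_w)
      p <- stats::ppois(chip_n - 1, lam_isl, lower.tail = FALSE)
      fc <- (chip_n / chip_lib) / (max(input_n, 1) / input_lib)
      islands[[length(islands) + 1]] <- data.frame(
        chrom = chrom,
        start = (w1 - 1) * W,
        end = min(w2 * W, chrom_length(genome, chrom)),
        chip_count = chip_n, input_count = input_n,
        fold_change = fc, score = score, p_value = p)
    }
  }
  if (!length(islands)) return(empty)
  out <- do.call(rbind, islands)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- direction
  out <- out[out$q_value <= params$fdr &
               out$fold_change >= params$min_fold_change, , drop = FALSE]
  out <- out[order(match(out$chrom, genome$chrom_names), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("h1_islands", "data.frame")
  out
}

#' Annotate regions to the nearest TSS
#'
#' Each region is assigned the gene whose TSS is closest to the region
#' midpoint (absolute distance; ties go to the gene at the smaller genomic
#' coordinate). The distance is signed by transcript orientation: negative
#' values lie transcriptionally upstream of the TSS.
#'
#' @param islands an `h1_regions`-like data frame.
#' @param genes an `h1_genes` data frame.
#' @return A data frame with columns chrom, start, end, gene_id, distance;
#'   regions on chromosomes without genes get `NA` (unassigned).
#' @export
annotate_nearest_gene <- function(islands, genes) {
  n <- nrow(islands)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  mid <- floor((islands$start + islands$end) / 2)
  for (chrom in unique(islands$chrom)) {
    ridx <- which(islands$chrom == chrom)
    gidx <- which(genes$chrom == chrom)
    if (!length(gidx)) next
    tss <- gene_tss(genes)[gidx]
    o <- order(tss, genes$start[gidx])  # ties: smaller coordinate first
    tss_s <- tss[o]; g_s <- gidx[o]
    k <- findInterval(mid[ridx], tss_s)
    left <- pmax(k, 1); right <- pmin(k + 1, length(tss_s))
    dl <- abs(mid[ridx] - tss_s[left])
    dr <- abs(mid[ridx] - tss_s[right])
    # tie at equal distance: the smaller genomic coordinate (left) wins
    use_left <- (k >= 1) & (k >= length(tss_s) | dl <= dr)
    pick <- ifelse(use_left, left, right)
    gi <- g_s[pick]
    gene_id[ridx] <- genes$id[gi]
    d_raw <- mid[ridx] - gene_tss(genes)[gi]
    distance[ridx] <- ifelse(genes$strand[gi] == "+", d_raw, -d_raw)
  }
  data.frame(chrom = islands$chrom, start = islands$start,
             end = islands$end, gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

feature_levels <- c("promoter", "5'UTR", "exon", "intron", "3'UTR",
                    "genic", "downstream", "distal intergenic")

#' Classify regions into genomic feature classes
#'
#' Assignment is by region midpoint with priority promoter > 5'UTR > exon
#' > intron > 3'UTR > downstream > distal intergenic when several
#' annotations overlap. Promoter and downstream regions extend
#' `promoter_bp` upstream of the TSS and `downstream_bp` past the TTS
#' (strand-aware). Exon/intron discrimination requires per-gene exon
#' structure; without it a gene body is the undivided class "genic".
#' UTRs additionally require a CDS interval (`cds_start`/`cds_end`).
#'
#' @param regions an `h1_regions`-like data frame.
#' @param genes an `h1_genes` data frame.
#' @param promoter_bp,downstream_bp promoter/downstream extent in bp.
#' @return A factor of feature classes, one per region.
#' @export
classify_feature <- function(regions, genes, promoter_bp = 3000,
                             downstream_bp = 3000) {
  exons <- attr(genes, "exons")
  mid <- floor((regions$start + regions$end) / 2)
  prio <- function(x) match(x, feature_levels)
  out <- rep("distal intergenic", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    gidx <- which(genes$chrom == regions$chrom[i])
    if (!length(gidx)) next
    m <- mid[i]
    best <- "distal intergenic"
    for (g in gidx) {
      tss <- gene_tss(genes)[g]; gs <- genes$start[g]; ge <- genes$end[g]
      plus <- genes$strand[g] == "+"
      prom <- if (plus) m >= tss - promoter_bp && m < tss
              else m > tss && m <= tss + promoter_bp
      down <- if (plus) m >= ge && m < ge + downstream_bp
              else m >= gs - downstream_bp && m < gs
      cls <- NULL
      if (prom) cls <- "promoter"
      else if (m >= gs && m < ge) {
        ex <- if (!is.null(exons)) exons[[g]] else NULL
        if (is.null(ex)) cls <- "genic"
        else {
          in_exon <- any(m >= ex[, 1] & m < ex[, 2])
          if (!in_exon) cls <- "intron"
          else {
            cs <- genes$cds_start[g]; ce <- genes$cds_end[g]
            if (is.na(cs) || is.na(ce)) cls <- "exon"
            else if (plus && m < cs) cls <- "5'UTR"
            else if (plus && m >= ce) cls <- "3'UTR"
            else if (!plus && m >= ce) cls <- "5'UTR"
            else if (!plus && m < cs) cls <- "3'UTR"
            else cls <- "exon"
          }
        }
      } else if (down) cls <- "downstream"
      if (!is.null(cls) && prio(cls) < prio(best)) best <- cls
    }
    out[i] <- best
  }
  factor(out, levels = feature_levels)
}

#' Genes targeted by at least one island
#'
#' A gene is a target when at least one island overlaps (>= 1 bp) its
#' extended span from `up` bp upstream of the TSS to `down` bp past the
#' TTS, strand-aware.
#'
#' @param islands an `h1_regions`-like data frame.
#' @param genes an `h1_genes` data frame.
#' @param up,down span extension in bp.
#' @return `genes` subset to targets, with a column `n_islands`.
#' @export
target_genes <- function(islands, genes, up = 5000, down = 3000) {
  if (nrow(genes) == 0 || nrow(islands) == 0) {
    out <- genes[integer(0), , drop = FALSE]
    out$n_islands <- integer(0)
    return(out)
  }
  span_s <- ifelse(genes$strand == "+", genes$start - up, genes$start - down)
  span_e <- ifelse(genes$strand == "+", genes$end + down, genes$end + up)
  span_s <- pmax(span_s, 0)
  lv <- union(unique(genes$chrom), unique(islands$chrom))
  spans <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lv),
    IRanges::IRanges(span_s + 1, span_e))
  isl <- as_granges(islands, seqlevels = lv)
  hits <- GenomicRanges::countOverlaps(spans, isl, minoverlap = 1)
  out <- genes[hits > 0, , drop = FALSE]
  out$n_islands <- hits[hits > 0]
  rownames(out) <- NULL
  out
}

#' All overlapping pairs between two region sets
#'
#' Overlap means the half-open intervals share at least one base.
#'
#' @param a,b `h1_regions`-like data frames.
#' @return A list with `pairs` (data frame of row indices `i` in `a`, `j`
#'   in `b`) and `a_hit` (logical per row of `a`).
#' @export
overlap_regions <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(pairs = data.frame(i = integer(0), j = integer(0)),
                a_hit = logical(nrow(a))))
  }
  lv <- union(unique(a$chrom), unique(b$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(a, lv), as_granges(b, lv),
                                      minoverlap = 1)
  pairs <- data.frame(i = S4Vectors::queryHits(hits),
                      j = S4Vectors::subjectHits(hits))
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, a_hit = seq_len(nrow(a)) %in% pairs$i)
}
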