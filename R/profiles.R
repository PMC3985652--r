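#' Anchored profile window specification
#'
#' Defaults reproduce the promoter window used throughout the package:
#' 3.2 kb upstream to 800 bp downstream of the TSS in 50 bp bins.
#'
#' @param upstream,downstream window extent in bp (>= 0).
#' @param bin profile bin width in bp; `(upstream + downstream) / bin`
#'   must be integral.
#' @param anchor one of "tss", "tts", "site-center".
#' @return A list of class `h1_profile_spec`.
#' @export
profile_spec <- function(upstream = 3200, downstream = 800, bin = 50,
                         anchor = c("tss", "tts", "site-center")) {
  anchor <- match.arg(anchor)
  stopifnot(upstream >= 0, downstream >= 0, bin >= 1)
  if ((upstream + downstream) %% bin != 0)
    stop("(upstream + downstream) must be a multiple of bin")
  structure(list(upstream = upstream, downstream = downstream,
                 bin = as.integer(bin), anchor = anchor),
            class = "h1_profile_spec")
}

#' Metagene specification
#'
#' Gene bodies are rescaled to `body_bins` positions (default 60, i.e. a
#' 3 kb metagene at 50 bp resolution) flanked by `flank` bp at native bin
#' size on both sides.
#'
#' @param body_bins number of bins the gene body is rescaled to.
#' @param flank flank extent in bp on each side.
#' @param min_gene_length genes shorter than this are excluded (default
#'   `body_bins * 10` bp, avoiding rescaling artifacts from genes much
#'   shorter than the target grid).
#' @return A list of class `h1_metagene_spec`.
#' @export
metagene_spec <- function(body_bins = 60, flank = 1000,
                          min_gene_length = body_bins * 10) {
  stopifnot(body_bins >= 1, flank >= 0, min_gene_length >= 1)
  structure(list(body_bins = as.integer(body_bins), flank = flank,
                 min_gene_length = min_gene_length),
            class = "h1_metagene_spec")
}

anchor_positions <- function(anchors, spec) {
  if (inherits(anchors, "h1_genes")) {
    if (spec$anchor == "site-center")
      stop("site-center anchoring expects a region set")
    if (any(is.na(anchors$strand)))
      stop("anchoring at ", spec$anchor, " requires a strand for every gene")
    a <- if (spec$anchor == "tss") gene_tss(anchors) else gene_tts(anchors)
    list(chrom = anchors$chrom, pos = a, strand = anchors$strand,
         id = anchors$id)
  } else {
    a <- floor((anchors$start + anchors$end) / 2)
    strand <- if (!is.null(anchors$strand)) anchors$strand else
      rep("+", nrow(anchors))
    strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "+"
    id <- if (!is.null(anchors$name)) anchors$name else
      as.character(seq_len(nrow(anchors)))
    list(chrom = anchors$chrom, pos = a, strand = strand, id = id)
  }
}

#' Signal matrix around anchored positions
#'
#' Extracts `[-upstream, +downstream)` of bp-level signal around each
#' anchor (TSS, TTS or region center), in transcriptional orientation:
#' rows of `-` strand anchors are mirrored so that upstream is always
#' transcriptionally upstream. Offset 0 is the anchor base itself; columns
#' are labelled by the left bp edge of their offset range. Cells extending
#' beyond chromosome bounds are masked (`NA`).
#'
#' Profile bins need not coincide with track bins: each cell is the
#' length-weighted bp average of the track over the cell's genomic range,
#' which handles both finer and coarser profile bins.
#'
#' @param track an `h1_track`.
#' @param anchors an `h1_genes` (anchor tss/tts) or `h1_regions`
#'   (anchor site-center) object.
#' @param spec an `h1_profile_spec`.
#' @return A numeric matrix of class `h1_profile` (rows = anchors, columns
#'   = offsets) with the spec stored as attribute `spec`.
#' @export
anchored_profile <- function(track, anchors, spec = profile_spec()) {
  an <- anchor_positions(anchors, spec)
  nc <- (spec$upstream + spec$downstream) %/% spec$bin
  lo <- -spec$upstream + (seq_len(nc) - 1) * spec$bin
  mat <- matrix(NA_real_, nrow = length(an$pos), ncol = nc,
                dimnames = list(an$id, lo))
  for (chrom in unique(an$chrom)) {
    rows <- which(an$chrom == chrom)
    if (is.null(track$values[[chrom]]))
      stop("anchor chromosome not in track: ", chrom)
    pre <- track_prefix(track, chrom)
    L <- chrom_length(track$genome, chrom)
    for (r in rows) {
      a <- an$pos[r]
      if (an$strand[r] == "+") {
        s <- a + lo
        e <- s + spec$bin
      } else {
        # transcriptional offset o of genomic base p is a - p
        e <- a - lo + 1
        s <- e - spec$bin
      }
      inb <- s >= 0 & e <= L
      if (any(inb))
        mat[r, inb] <- (pre(e[inb]) - pre(s[inb])) / spec$bin
    }
  }
  structure(mat, spec = spec, class = c("h1_profile", "matrix", "array"))
}

#' Per-position mean of a profile matrix
#'
#' @param matrix an `h1_profile` (or any matrix with NA masking).
#' @return A list with `mean` (per-column mean over unmasked cells; `NA`
#'   where a column is fully masked) and `n` (unmasked cells per column).
#' @export
column_mean_profile <- function(matrix) {
  if (nrow(matrix) == 0) stop("profile matrix has no rows")
  n <- colSums(!is.na(matrix))
  m <- suppressWarnings(colMeans(matrix, na.rm = TRUE))
  m[n == 0] <- NA_real_
  list(mean = m, n = n)
}

#' LOESS smoothing of a profile vector
#'
#' Local linear regression with tricube weights over the
#' `floor(span * n)` nearest neighbours of each position, evaluated at
#' every position (positions are taken as equally spaced). A degree-1
#' local fit reproduces exactly constant and exactly linear inputs.
#'
#' @param profile numeric vector (NA positions are dropped from the fit
#'   and returned as NA).
#' @param span neighbourhood fraction in (0, 1]; must cover at least 3
#'   points.
#' @return Smoothed numeric vector of the same length.
#' @export
loess_profile <- function(profile, span = 0.1) {
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  ok <- which(!is.na(profile))
  n <- length(ok)
  if (n < 3) stop("need at least 3 non-missing points")
  q <- floor(span * n)
  if (q < 3)
    stop(sprintf("span %.4g covers %d point(s); minimal span is %.4g",
                 span, q, 3 / n))
  x <- as.numeric(ok)
  y <- profile[ok]
  fit <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    if (h == 0) { fit[i] <- y[i]; next }
    w <- pmax(1 - (d / h)^3, 0)^3
    use <- w > 0
    ww <- w[use]; xx <- x[use]; yy <- y[use]
    sw <- sum(ww); sx <- sum(ww * xx); sy <- sum(ww * yy)
    sxx <- sum(ww * xx * xx); sxy <- sum(ww * xx * yy)
    den <- sw * sxx - sx * sx
    if (abs(den) < 1e-12 * max(1, sxx * sw)) {
      fit[i] <- sy / sw
    } else {
      b <- (sw * sxy - sx * sy) / den
      a <- (sy - b * sx) / sw
      fit[i] <- a + b * x[i]
    }
  }
  out <- rep(NA_real_, length(profile))
  out[ok] <- fit
  out
}

#' Expression groups of equal size (EG1 = highest)
#'
#' Genes with non-missing expression are sorted by expression descending
#' (ties broken by gene id, ascending, for determinism) and cut into
#' `n_groups` groups: `floor(N / n)` genes each, the first `N mod n`
#' groups taking one extra. EG1 holds the most expressed genes.
#'
#' @param genes an `h1_genes` data frame.
#' @param n_groups number of groups (default 10, i.e. deciles).
#' @return A factor of labels `EG1..EGn` aligned with `genes` rows (`NA`
#'   for genes without expression), with attribute `n_excluded`.
#' @export
expression_deciles <- function(genes, n_groups = 10) {
  has <- !is.na(genes$expression)
  N <- sum(has)
  if (N == 0) stop("all gene expression values are missing")
  if (N < n_groups)
    stop("need at least ", n_groups, " genes with expression; have ", N)
  idx <- which(has)
  ord <- idx[order(-genes$expression[idx], genes$id[idx])]
  base <- N %/% n_groups
  extra <- N %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1, extra), rep(0, n_groups - extra))
  lab <- rep(paste0("EG", seq_len(n_groups)), times = sizes)
  out <- rep(NA_character_, nrow(genes))
  out[ord] <- lab
  out <- factor(out, levels = paste0("EG", seq_len(n_groups)))
  attr(out, "n_excluded") <- sum(!has)
  out
}

#' Metagene average profile
#'
#' Each gene body `[TSS, TTS)` is rescaled to `body_bins` positions by
#' length-weighted averaging of the bp-level signal; flanks (upstream of
#' the TSS and downstream of the TTS) are taken at the native profile bin
#' size. `-` strand genes are flipped into transcriptional orientation.
#'
#' @param track an `h1_track`.
#' @param genes an `h1_genes` data frame.
#' @param spec an `h1_metagene_spec`.
#' @return A list with `mean` (per-bin mean vector over genes), `n`
#'   (contributing genes per bin), `section` (factor: upstream / body /
#'   downstream per bin) and `n_genes` used.
#' @export
metagene_profile <- function(track, genes, spec = metagene_spec()) {
  B <- track$bin_size
  keep <- (genes$end - genes$start) >= spec$min_gene_length
  if (!any(keep))
    stop("no gene passes the minimum length filter (",
         spec$min_gene_length, " bp)")
  genes <- genes[keep, , drop = FALSE]
  nf <- as.integer(spec$flank %/% B)
  nc <- nf + spec$body_bins + nf
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = nc)
  for (chrom in unique(genes$chrom)) {
    rows <- which(genes$chrom == chrom)
    pre <- track_prefix(track, chrom)
    L <- chrom_length(track$genome, chrom)
    for (r in rows) {
      gs <- genes$start[r]; ge <- genes$end[r]
      body_edges <- gs + (ge - gs) * (0:spec$body_bins) / spec$body_bins
      fl <- if (nf > 0) seq_len(nf) else integer(0)
      if (genes$strand[r] == "+") {
        up_s <- gs - rev(fl) * B
        dn_s <- ge + (fl - 1) * B
        s <- c(up_s, body_edges[-length(body_edges)], dn_s)
        e <- c(up_s + B, body_edges[-1], dn_s + B)
      } else {
        # transcriptional order runs along decreasing genomic coordinate:
        # upstream flank sits right of the gene, far bins first
        up_s <- ge + (rev(fl) - 1) * B
        body_s <- rev(body_edges[-length(body_edges)])
        body_e <- rev(body_edges[-1])
        dn_s <- gs - fl * B
        s <- c(up_s, body_s, dn_s)
        e <- c(up_s + B, body_e, dn_s + B)
      }
      inb <- s >= 0 & e <= L
      row <- rep(NA_real_, nc)
      if (any(inb)) row[inb] <- (pre(e[inb]) - pre(s[inb])) / (e[inb] - s[inb])
      mat[r, ] <- row
    }
  }
  n <- colSums(!is.na(mat))
  m <- suppressWarnings(colMeans(mat, na.rm = TRUE))
  m[n == 0] <- NA_real_
  section <- factor(rep(c("upstream", "body", "downstream"),
                        c(nf, spec$body_bins, nf)),
                    levels = c("upstream", "body", "downstream"))
  list(mean = m, n = n, section = section, n_genes = nrow(genes))
}
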