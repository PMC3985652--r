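#' Coverage parameters
#'
#' Defaults follow the histone ChIP-seq convention: reads extended to a
#' nominal 150 bp fragment from their 5' end, signal binned at 50 bp,
#' and at most one read kept per (position, strand) before counting
#' (redundancy threshold 1).
#'
#' @param bin_size bin width in bp.
#' @param fragment_size nominal fragment length in bp.
#' @param dedup keep at most one read per (position, strand)?
#' @return A list of class `h1_coverage_params`.
#' @export
coverage_params <- function(bin_size = 50, fragment_size = 150, dedup = TRUE) {
  stopifnot(bin_size >= 1, fragment_size >= 1, is.logical(dedup))
  structure(list(bin_size = as.integer(bin_size),
                 fragment_size = as.integer(fragment_size),
                 dedup = isTRUE(dedup)),
            class = "h1_coverage_params")
}

# Keep at most max_per reads per (chrom, pos, strand). Numeric keys keep
# this fast on multi-million-read sets.
dedup_reads <- function(reads, max_per = 1L) {
  if (nrow(reads) == 0) return(reads)
  chroms <- unique(reads$chrom)
  span <- 2 * (max(reads$pos) + 1)
  key <- (match(reads$chrom, chroms) - 1) * span +
    2 * reads$pos + (reads$strand == "+")
  if (max_per == 1L) {
    keep <- !duplicated(key)
  } else {
    o <- order(key)
    runs <- rle(key[o])$lengths
    within <- sequence(runs)
    keep <- logical(length(key))
    keep[o] <- within <= max_per
  }
  out <- reads[keep, , drop = FALSE]
  attr(out, "libsize") <- nrow(out)
  class(out) <- class(reads)
  out
}

# Half-open extended fragment for each read: a + read at p covers
# [p, p + F); a - read at p covers [p - F + 1, p + 1). Clipped to the
# chromosome later.
fragment_bounds <- function(pos, strand, fragment_size) {
  s <- pos
  neg <- strand == "-"
  s[neg] <- pos[neg] - fragment_size + 1
  cbind(start = s, end = s + fragment_size)
}

#' Fragment-overlap coverage in fixed bins
#'
#' Each read is extended to `fragment_size` bp from its 5' end in the read
#' direction; a bin counts every extended fragment overlapping it by at
#' least one bp. Fragments running past a chromosome end are clipped.
#'
#' @param reads an `h1_reads` data frame.
#' @param genome an `h1_genome`.
#' @param params an `h1_coverage_params`.
#' @return An `h1_track` of integer counts, with `libsize` set to the
#'   number of reads counted (after deduplication when enabled).
#' @export
bin_coverage <- function(reads, genome, params = coverage_params()) {
  stopifnot(inherits(genome, "h1_genome"),
            inherits(params, "h1_coverage_params"))
  if (params$dedup) reads <- dedup_reads(reads, 1L)
  B <- params$bin_size
  vals <- vector("list", length(genome$chrom_names))
  names(vals) <- genome$chrom_names
  for (chrom in genome$chrom_names) {
    L <- chrom_length(genome, chrom)
    nb <- n_bins(L, B)
    idx <- reads$chrom == chrom
    if (!any(idx)) { vals[[chrom]] <- numeric(nb); next }
    fb <- fragment_bounds(reads$pos[idx], reads$strand[idx],
                          params$fragment_size)
    s <- pmax(fb[, "start"], 0)
    e <- pmin(fb[, "end"], L)
    ok <- e > s
    b1 <- s[ok] %/% B          # first overlapped bin
    b2 <- (e[ok] - 1) %/% B    # last overlapped bin
    # difference-array accumulation, then cumulative sum
    d <- tabulate(b1 + 1, nbins = nb + 1) - tabulate(b2 + 2, nbins = nb + 1)
    vals[[chrom]] <- cumsum(d[seq_len(nb)])
  }
  signal_track(vals, B, genome, libsize = nrow(reads))
}

#' Input-subtracted, library-normalised signal
#'
#' Per bin: `(chip / chip_lib - input / input_lib) * 1e6`, i.e. the
#' difference of reads-per-million coverages. Values may be negative.
#'
#' @param chip,input `h1_track`s on the same genome and bin grid.
#' @param chip_lib,input_lib library sizes (total mapped reads); default to
#'   the tracks' own `libsize` metadata.
#' @return An `h1_track` in RPM units.
#' @export
normalize_subtract <- function(chip, input,
                               chip_lib = chip$libsize,
                               input_lib = input$libsize) {
  check_same_grid(chip, input)
  if (is.null(chip_lib) || is.null(input_lib) ||
      chip_lib < 1 || input_lib < 1)
    stop("library sizes must be provided and >= 1")
  vals <- mapply(function(c, i) (c / chip_lib - i / input_lib) * 1e6,
                 chip$values, input$values, SIMPLIFY = FALSE)
  signal_track(vals, chip$bin_size, chip$genome)
}

#' log2 fold-change track (ChIP vs input)
#'
#' Per bin: `log2((chip_rpm + pseudocount) / (input_rpm + pseudocount))`
#' with both coverages on the reads-per-million scale. The pseudocount
#' (default 0.5 RPM) regularises empty bins.
#'
#' @inheritParams normalize_subtract
#' @param pseudocount positive RPM pseudocount.
#' @return An `h1_track` of log2 ratios.
#' @export
fold_change_track <- function(chip, input,
                              chip_lib = chip$libsize,
                              input_lib = input$libsize,
                              pseudocount = 0.5) {
  check_same_grid(chip, input)
  if (is.null(chip_lib) || is.null(input_lib) ||
      chip_lib < 1 || input_lib < 1)
    stop("library sizes must be provided and >= 1")
  if (!(pseudocount > 0)) stop("pseudocount must be > 0")
  vals <- mapply(function(c, i) {
    log2((c / chip_lib * 1e6 + pseudocount) /
           (i / input_lib * 1e6 + pseudocount))
  }, chip$values, input$values, SIMPLIFY = FALSE)
  signal_track(vals, chip$bin_size, chip$genome)
}

check_same_grid <- function(a, b) {
  if (a$bin_size != b$bin_size)
    stop("bin sizes differ: ", a$bin_size, " vs ", b$bin_size)
  if (!identical(a$genome$chrom_lengths, b$genome$chrom_lengths))
    stop("tracks are binned against different genomes")
  invisible(TRUE)
}
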