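#' Binned signal track
#'
#' A per-chromosome fixed-width binned numeric signal: the carrier of
#' coverage and input-subtracted occupancy. Each chromosome holds
#' `ceiling(length / bin_size)` bins; the last bin may be partial.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_size bin width in bp.
#' @param genome the `h1_genome` the track is binned against.
#' @param libsize optional total mapped reads the track was normalised by.
#' @return An object of class `h1_track`.
#' @export
signal_track <- function(values, bin_size, genome, libsize = NULL) {
  stopifnot(inherits(genome, "h1_genome"), bin_size >= 1)
  if (!setequal(names(values), genome$chrom_names))
    stop("track chromosomes must match the genome")
  values <- values[genome$chrom_names]
  for (chrom in genome$chrom_names) {
    nb <- n_bins(chrom_length(genome, chrom), bin_size)
    v <- values[[chrom]]
    if (length(v) != nb)
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chrom, nb, length(v)))
    if (any(!is.finite(v)))
      stop(sprintf("chromosome %s: non-finite signal values", chrom))
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 genome = genome, libsize = libsize),
            class = "h1_track")
}

n_bins <- function(len, bin) as.integer(ceiling(len / bin))

#' @export
print.h1_track <- function(x, ...) {
  cat("<h1_track> bin ", x$bin_size, " bp, ",
      length(x$values), " chromosomes, ",
      format(sum(lengths(x$values)), big.mark = ","), " bins\n", sep = "")
  invisible(x)
}

#' A constant-valued track over a genome
#' @param genome an `h1_genome`.
#' @param bin_size bin width in bp.
#' @param value fill value.
#' @return An `h1_track`.
#' @export
constant_track <- function(genome, bin_size, value = 0) {
  vals <- lapply(genome$chrom_lengths,
                 function(L) rep(value, n_bins(L, bin_size)))
  names(vals) <- genome$chrom_names
  signal_track(vals, bin_size, genome)
}

# Per-chromosome prefix sums of the bp-level step function implied by a
# binned track: prefix(p) = integral of the signal over [0, p). Bin i
# contributes value_i * width_i, the last bin being clipped at the
# chromosome end. Returns closures evaluated at (possibly fractional)
# positions, vectorised.
track_prefix <- function(track, chrom) {
  v <- track$values[[chrom]]
  B <- track$bin_size
  L <- chrom_length(track$genome, chrom)
  widths <- rep(B, length(v))
  if (length(v)) widths[length(v)] <- L - (length(v) - 1) * B
  cum <- c(0, cumsum(v * widths))
  function(p) {
    # p in [0, L]
    k <- pmin(floor(p / B), length(v) - 1)
    cum[k + 1] + (p - k * B) * v[k + 1]
  }
}

# Mean bp-level signal over half-open [start, end) intervals on one
# chromosome, clipping to chromosome bounds; NA when the clipped interval
# is empty. start/end may be fractional (metagene rescaling).
interval_mean <- function(prefix_fun, start, end, chrom_len) {
  s <- pmax(start, 0)
  e <- pmin(end, chrom_len)
  out <- rep(NA_real_, length(s))
  ok <- e > s
  if (any(ok)) out[ok] <- (prefix_fun(e[ok]) - prefix_fun(s[ok])) / (e[ok] - s[ok])
  out
}

#' Mean signal per region (full bins, midpoint rule)
#'
#' The mean of all bins whose midpoints fall inside each region; regions
#' narrower than a bin fall back to the single bin containing the region
#' midpoint. Used for island fold changes and domain enrichment tests.
#'
#' @param track an `h1_track`.
#' @param regions an `h1_regions` data frame.
#' @return Numeric vector of per-region means.
#' @export
region_mean_signal <- function(track, regions) {
  B <- track$bin_size
  out <- numeric(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    idx <- which(regions$chrom == chrom)
    v <- track$values[[chrom]]
    if (is.null(v)) stop("region chromosome not in track: ", chrom)
    # bins with midpoint (k + 0.5) * B inside [start, end)
    k1 <- ceiling(regions$start[idx] / B - 0.5)
    k2 <- ceiling(regions$end[idx] / B - 0.5) - 1
    k1 <- pmax(k1, 0); k2 <- pmin(k2, length(v) - 1)
    for (j in seq_along(idx)) {
      if (k2[j] >= k1[j]) {
        out[idx[j]] <- mean(v[(k1[j] + 1):(k2[j] + 1)])
      } else {
        mid <- min(floor((regions$start[idx[j]] + regions$end[idx[j]]) / 2 / B),
                   length(v) - 1)
        out[idx[j]] <- v[mid + 1]
      }
    }
  }
  out
}

#' Rebin a track into coarser windows
#'
#' Averages consecutive bins into windows of `window` bp (which must be a
#' multiple of the bin size); a trailing partial window is dropped.
#'
#' @param track an `h1_track`.
#' @param window target window width in bp.
#' @return Named list of per-chromosome window-mean vectors.
#' @export
rebin_means <- function(track, window) {
  B <- track$bin_size
  if (window %% B != 0)
    stop("window must be a multiple of the track bin size")
  k <- window %/% B
  lapply(track$values, function(v) {
    nw <- length(v) %/% k
    if (nw == 0) return(numeric(0))
    colMeans(matrix(v[seq_len(nw * k)], nrow = k))
  })
}
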