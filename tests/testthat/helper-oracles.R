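# Independent brute-force oracles and tiny fixture builders shared by the
# test files. Oracles deliberately use naive per-bp / per-pair loops and
# never call the package code paths they check.

tiny_genome <- function(lens = c(chrA = 1000, chrB = 600)) {
  genome(names(lens), unname(lens))
}

random_track <- function(genome, bin_size = 50, seed = 1, fun = stats::rnorm) {
  set.seed(seed)
  vals <- lapply(genome$chrom_lengths,
                 function(L) fun(ceiling(L / bin_size)))
  names(vals) <- genome$chrom_names
  signal_track(vals, bin_size, genome)
}

# value of a binned track at a single bp
track_value_at <- function(track, chrom, p) {
  track$values[[chrom]][p %/% track$bin_size + 1]
}

# per-bp brute force: for every bin, count reads whose clipped extended
# fragment shares >= 1 bp with the bin
oracle_coverage <- function(reads, genome, bin_size, fragment_size) {
  vals <- list()
  for (chrom in genome$chrom_names) {
    L <- genome$chrom_lengths[[chrom]]
    nb <- ceiling(L / bin_size)
    v <- numeric(nb)
    idx <- which(reads$chrom == chrom)
    for (b in seq_len(nb)) {
      bs <- (b - 1) * bin_size
      be <- min(bs + bin_size, L)
      for (i in idx) {
        if (reads$strand[i] == "+") {
          fs <- reads$pos[i]; fe <- reads$pos[i] + fragment_size
        } else {
          fs <- reads$pos[i] - fragment_size + 1; fe <- reads$pos[i] + 1
        }
        fs <- max(fs, 0); fe <- min(fe, L)
        if (fs < be && fe > bs && fe > fs) v[b] <- v[b] + 1
      }
    }
    vals[[chrom]] <- v
  }
  vals
}

# per-bp mean of a track over [s, e) intersected with [0, L); NA if empty
oracle_bp_mean <- function(track, chrom, s, e) {
  L <- track$genome$chrom_lengths[[chrom]]
  bp <- seq(max(s, 0), min(e, L) - 1)
  if (length(bp) == 0 || max(s, 0) >= min(e, L)) return(NA_real_)
  mean(track_value_at(track, chrom, bp))
}

# column means of an anchored profile by explicit per-bp averaging
oracle_profile_colmeans <- function(track, genes, upstream, downstream, bin) {
  nc <- (upstream + downstream) / bin
  tot <- numeric(nc); n <- numeric(nc)
  for (i in seq_len(nrow(genes))) {
    tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1
    L <- track$genome$chrom_lengths[[genes$chrom[i]]]
    for (j in seq_len(nc)) {
      lo <- -upstream + (j - 1) * bin
      offs <- lo:(lo + bin - 1)
      bp <- if (genes$strand[i] == "+") tss + offs else tss - offs
      if (all(bp >= 0 & bp < L)) {
        tot[j] <- tot[j] + mean(track_value_at(track, genes$chrom[i], bp))
        n[j] <- n[j] + 1
      }
    }
  }
  out <- tot / n
  out[n == 0] <- NA_real_
  out
}

# exact integral of the track step function over real interval [a, b)
oracle_step_integral <- function(track, chrom, a, b) {
  v <- track$values[[chrom]]
  B <- track$bin_size
  L <- track$genome$chrom_lengths[[chrom]]
  total <- 0
  for (k in seq_along(v)) {
    ks <- (k - 1) * B
    ke <- min(ks + B, L)
    ov <- min(b, ke) - max(a, ks)
    if (ov > 0) total <- total + ov * v[k]
  }
  total
}

# metagene mean vector by explicit per-gene interval integration
oracle_metagene <- function(track, genes, body_bins, flank, min_len) {
  B <- track$bin_size
  nf <- flank %/% B
  keep <- (genes$end - genes$start) >= min_len
  genes <- genes[keep, , drop = FALSE]
  nc <- 2 * nf + body_bins
  tot <- numeric(nc); n <- numeric(nc)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    L <- track$genome$chrom_lengths[[ch]]
    gs <- genes$start[i]; ge <- genes$end[i]
    edges <- gs + (ge - gs) * (0:body_bins) / body_bins
    if (genes$strand[i] == "+") {
      s <- c(gs - (nf:1) * B, edges[-(body_bins + 1)], ge + (0:(nf - 1)) * B)
      e <- c(gs - (nf:1) * B + B, edges[-1], ge + (1:nf) * B)
    } else {
      s <- c(ge + ((nf:1) - 1) * B, rev(edges[-(body_bins + 1)]),
             gs - (1:nf) * B)
      e <- c(ge + (nf:1) * B, rev(edges[-1]), gs - (0:(nf - 1)) * B)
    }
    for (j in seq_len(nc)) {
      if (s[j] >= 0 && e[j] <= L) {
        tot[j] <- tot[j] + oracle_step_integral(track, ch, s[j], e[j]) /
          (e[j] - s[j])
        n[j] <- n[j] + 1
      }
    }
  }
  out <- tot / n
  out[n == 0] <- NA_real_
  out
}

# local linear tricube fit per point via lm(), independent of the
# closed-form implementation
oracle_loess <- function(y, span) {
  n <- length(y)
  x <- seq_len(n)
  q <- floor(span * n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(1 - (d / h)^3, 0)^3
    use <- w > 0
    fit <- stats::lm(y[use] ~ x[use], weights = w[use])
    out[i] <- unname(fit$coefficients[1] + fit$coefficients[2] * x[i])
  }
  out
}

# O(n*m) nearest-TSS assignment with the explicit tie rule
oracle_nearest_gene <- function(islands, genes) {
  n <- nrow(islands)
  gene_id <- rep(NA_character_, n); distance <- rep(NA_real_, n)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  for (i in seq_len(n)) {
    gidx <- which(genes$chrom == islands$chrom[i])
    if (!length(gidx)) next
    mid <- floor((islands$start[i] + islands$end[i]) / 2)
    d <- abs(mid - tss[gidx])
    best <- gidx[d == min(d)]
    if (length(best) > 1) best <- best[which.min(tss[best])]
    gene_id[i] <- genes$id[best]
    d_raw <- mid - tss[best]
    distance[i] <- if (genes$strand[best] == "+") d_raw else -d_raw
  }
  data.frame(gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

# O(n^2) overlap pair enumeration
oracle_overlap_pairs <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1)
        pairs[[length(pairs) + 1]] <- c(i = i, j = j)
    }
  }
  if (!length(pairs)) return(data.frame(i = integer(0), j = integer(0)))
  out <- as.data.frame(do.call(rbind, pairs))
  out[order(out$i, out$j), , drop = FALSE]
}

# uniform read sets for island-caller null experiments
uniform_reads <- function(genome, n, seed) {
  set.seed(seed)
  lens <- genome$chrom_lengths
  ch <- sample(names(lens), n, replace = TRUE, prob = lens)
  pos <- floor(stats::runif(n) * lens[ch])
  read_set(ch, pos, sample(c("+", "-"), n, replace = TRUE), genome)
}

small_gene_fixture <- function(genome, n = 20, seed = 42, len = 100) {
  set.seed(seed)
  ch <- sample(genome$chrom_names, n, replace = TRUE)
  start <- floor(stats::runif(n) * (genome$chrom_lengths[ch] - len))
  gene_set(sprintf("g%03d", seq_len(n)), ch, start, start + len,
           sample(c("+", "-"), n, replace = TRUE),
           expression = stats::rlnorm(n))
}
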