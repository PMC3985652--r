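#' Genome coordinate frame
#'
#' A genome is the ordered set of chromosome names and lengths that every
#' other object (tracks, reads, regions, genes) is validated against. All
#' coordinates in the package are 0-based, half-open.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of chromosome lengths in bp (>= 1).
#' @return An object of class `h1_genome`: a list with elements
#'   `chrom_names`, `chrom_lengths` (named by chromosome) and `total_bp`.
#' @examples
#' g <- genome(c("chr1", "chr2"), c(1e6, 5e5))
#' g$total_bp
#' @export
genome <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome names: ",
         paste(unique(chrom_names[duplicated(chrom_names)]), collapse = ", "))
  if (length(chrom_lengths) == 0 || any(!is.finite(chrom_lengths)) ||
      any(chrom_lengths < 1))
    stop("chromosome lengths must be finite and >= 1")
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = chrom_lengths,
                 total_bp = sum(chrom_lengths)),
            class = "h1_genome")
}

#' @export
print.h1_genome <- function(x, ...) {
  cat("<h1_genome> ", length(x$chrom_names), " chromosomes, ",
      format(x$total_bp, big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a TSV with columns chromosome name and length.
#' @return An `h1_genome`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome(tab$chrom, tab$length)
}

#' Write a chrom.sizes file
#' @param genome an `h1_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "h1_genome"))
  utils::write.table(
    data.frame(genome$chrom_names, format(genome$chrom_lengths, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  unname(genome$chrom_lengths[chrom])
}

#' Gene set container
#'
#' Genes are stored in genomic orientation as half-open intervals
#' `[start, end)` with a strand; the strand-aware anchors are exposed by
#' [gene_tss()] and [gene_tts()] (for `+` genes the TSS is `start`, for `-`
#' genes it is `end - 1`, and symmetrically for the TTS). Expression is an
#' optional per-gene value (`NA` where unmeasured).
#'
#' @param id character gene identifiers (unique).
#' @param chrom chromosome names.
#' @param start,end half-open 0-based interval bounds (start < end).
#' @param strand "+" or "-".
#' @param expression optional numeric expression values (NA allowed).
#' @param exons optional list of per-gene exon matrices (two columns,
#'   half-open genomic coordinates).
#' @param cds_start,cds_end optional half-open CDS interval per gene (NA
#'   where absent); used for UTR discrimination in [classify_feature()].
#' @param genome optional `h1_genome` to validate chromosomes and bounds.
#' @return A `data.frame` of class `h1_genes`.
#' @export
gene_set <- function(id, chrom, start, end, strand,
                     expression = NULL, exons = NULL,
                     cds_start = NULL, cds_end = NULL, genome = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id))
    stop("duplicate gene id(s): ",
         paste(utils::head(unique(id[duplicated(id)]), 5), collapse = ", "))
  start <- as.numeric(start); end <- as.numeric(end)
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(end <= start))
    stop("gene end must exceed start (half-open intervals)")
  df <- data.frame(id = id, chrom = as.character(chrom),
                   start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  df$expression <- if (is.null(expression)) rep(NA_real_, n)
                   else as.numeric(expression)
  df$cds_start <- if (is.null(cds_start)) rep(NA_real_, n)
                  else as.numeric(cds_start)
  df$cds_end <- if (is.null(cds_end)) rep(NA_real_, n)
                else as.numeric(cds_end)
  if (!is.null(exons)) {
    stopifnot(length(exons) == n)
    attr(df, "exons") <- exons
  }
  if (!is.null(genome)) {
    bad <- !(df$chrom %in% genome$chrom_names)
    if (any(bad))
      stop("gene chromosome(s) not in genome: ",
           paste(unique(df$chrom[bad]), collapse = ", "))
    if (any(df$end > chrom_length(genome, df$chrom)))
      stop("gene interval exceeds chromosome length")
  }
  class(df) <- c("h1_genes", "data.frame")
  df
}

#' Strand-aware gene anchors
#'
#' @param genes an `h1_genes` data frame.
#' @return Integer-valued vector of TSS (or TTS) base positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' @rdname gene_tss
#' @export
gene_tts <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1, genes$start)
}

#' Region set container
#'
#' @param chrom,start,end interval columns, 0-based half-open.
#' @param name,score optional per-interval annotation.
#' @param genome optional `h1_genome` for bounds validation.
#' @return A `data.frame` of class `h1_regions`.
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       genome = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (nrow(df) && any(df$end <= df$start))
    stop("regions must satisfy start < end")
  if (nrow(df) && any(df$start < 0))
    stop("regions must satisfy start >= 0")
  if (!is.null(genome) && nrow(df)) {
    bad <- !(df$chrom %in% genome$chrom_names)
    if (any(bad))
      stop("region chromosome(s) not in genome: ",
           paste(unique(df$chrom[bad]), collapse = ", "))
    if (any(df$end > chrom_length(genome, df$chrom)))
      stop("region exceeds chromosome length")
  }
  class(df) <- c("h1_regions", "data.frame")
  df
}

#' Aligned-read set container
#'
#' Post-alignment reads reduced to their 5' position and strand; read
#' length is irrelevant downstream because all methods extend reads to a
#' nominal fragment size.
#'
#' @param chrom,pos,strand per-read columns; `pos` is the 0-based 5' base.
#' @param genome optional `h1_genome` for bounds validation.
#' @return A `data.frame` of class `h1_reads` with attribute `libsize`.
#' @export
read_set <- function(chrom, pos, strand, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$strand %in% c("+", "-")))
    stop("read strand must be '+' or '-'")
  if (!is.null(genome) && nrow(df)) {
    bad <- !(df$chrom %in% genome$chrom_names)
    if (any(bad))
      stop("read chromosome(s) not in genome: ",
           paste(unique(df$chrom[bad]), collapse = ", "))
    if (any(df$pos < 0) || any(df$pos >= chrom_length(genome, df$chrom)))
      stop("read position out of chromosome bounds")
  }
  attr(df, "libsize") <- nrow(df)
  class(df) <- c("h1_reads", "data.frame")
  df
}

#' Library size of a read set
#' @param reads an `h1_reads` data frame.
#' @return Number of reads.
#' @export
libsize <- function(reads) {
  ls <- attr(reads, "libsize")
  if (is.null(ls)) nrow(reads) else ls
}

as_granges <- function(regions, seqlevels = unique(regions$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end))
}
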