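#' Read a BED3+ file into a region set
#'
#' Coordinates are taken as-is (BED is already 0-based half-open). Records
#' on chromosomes absent from `genome` are skipped and counted; records
#' with `end <= start` or out of chromosome bounds are rejected and
#' reported. Malformed lines are a hard error naming the line number.
#'
#' @param path BED file path.
#' @param genome an `h1_genome` used to resolve chromosomes and bounds.
#' @return An `h1_regions` data frame (columns chrom/start/end and, when
#'   present in the file, name/score/strand), with attributes
#'   `n_skipped_chrom` (records on unknown chromosomes) and `rejected`
#'   (data frame of rejected records with reasons).
#' @export
read_bed <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- region_set(character(0), numeric(0), numeric(0))
    attr(out, "n_skipped_chrom") <- 0L
    attr(out, "rejected") <- data.frame()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  name <- if (any(nf >= 4)) vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "") else NULL
  score <- if (any(nf >= 5)) suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""))) else NULL
  strand <- if (any(nf >= 6)) vapply(fields, function(f) if (length(f) >= 6) f[[6]] else NA_character_, "") else NULL

  known <- chrom %in% genome$chrom_names
  n_skipped <- sum(!known)
  if (n_skipped > 0)
    warning(n_skipped, " record(s) on chromosome(s) absent from genome skipped")

  bad <- known & (end <= start | start < 0 |
                    end > ifelse(known, genome$chrom_lengths[chrom], Inf))
  rejected <- data.frame(line = which(bad), chrom = chrom[bad],
                         start = start[bad], end = end[bad],
                         reason = ifelse(end[bad] <= start[bad],
                                         "end <= start", "out of bounds"))
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " record(s) rejected (bad coordinates)")

  keep <- known & !bad
  out <- data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- name[keep]
  if (!is.null(score)) out$score <- score[keep]
  if (!is.null(strand)) out$strand <- strand[keep]
  class(out) <- c("h1_regions", "data.frame")
  attr(out, "n_skipped_chrom") <- n_skipped
  attr(out, "rejected") <- rejected
  out
}

#' Write a region set as BED
#' @param regions an `h1_regions` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- list(regions$chrom,
               format(regions$start, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE))
  if (!is.null(regions$name)) {
    cols <- c(cols, list(regions$name))
    if (!is.null(regions$score)) {
      cols <- c(cols, list(format(regions$score, trim = TRUE)))
      if (!is.null(regions$strand)) cols <- c(cols, list(regions$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read reads from BED6 (5' position + strand)
#'
#' The 5' position of a `+` read is the BED start; of a `-` read the base
#' `end - 1`.
#'
#' @param path BED6 file path.
#' @param genome an `h1_genome`.
#' @return An `h1_reads` data frame.
#' @export
read_reads_bed <- function(path, genome) {
  bed <- read_bed(path, genome)
  if (nrow(bed) && is.null(bed$strand))
    stop("read BED must carry a strand column (BED6)")
  pos <- ifelse(bed$strand == "+", bed$start, bed$end - 1)
  read_set(bed$chrom, pos, bed$strand, genome = genome)
}

#' Write reads as BED6
#' @param reads an `h1_reads` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  writeLines(paste(reads$chrom,
                   format(reads$pos, scientific = FALSE, trim = TRUE),
                   format(reads$pos + 1, scientific = FALSE, trim = TRUE),
                   ".", 0, reads$strand, sep = "\t"),
             path)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' One record per bin at the track's fixed step, values printed at 6
#' decimal places (zeros retained explicitly); the final record of each
#' chromosome is clipped at the chromosome end.
#'
#' @param track an `h1_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in track$genome$chrom_names) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    start <- (seq_along(v) - 1) * track$bin_size
    end <- pmin(start + track$bin_size, chrom_length(track$genome, chrom))
    writeLines(paste(chrom,
                     format(start, scientific = FALSE, trim = TRUE),
                     format(end, scientific = FALSE, trim = TRUE),
                     sprintf("%.6f", v), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a fixed-step bedGraph into a signal track
#'
#' Expects the dense one-record-per-bin layout produced by
#' [write_bedgraph()]; the bin size is inferred from the records.
#'
#' @param path bedGraph path.
#' @param genome an `h1_genome`.
#' @param bin_size optional; inferred from the first record when NULL.
#' @return An `h1_track`.
#' @export
read_bedgraph <- function(path, genome, bin_size = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  if (nrow(tab) == 0) stop("empty bedGraph")
  if (is.null(bin_size)) bin_size <- tab$end[1] - tab$start[1]
  vals <- list()
  for (chrom in genome$chrom_names) {
    sub <- tab[tab$chrom == chrom, , drop = FALSE]
    nb <- n_bins(chrom_length(genome, chrom), bin_size)
    v <- numeric(nb)
    if (nrow(sub)) {
      k <- sub$start %/% bin_size
      if (any(sub$start %% bin_size != 0) || any(k >= nb))
        stop("bedGraph records on ", chrom, " are not on the bin grid")
      v[k + 1] <- sub$value
    }
    vals[[chrom]] <- v
  }
  signal_track(vals, bin_size, genome)
}

#' Load genes and attach expression
#'
#' The gene table is a header-bearing TSV with columns `id`, `chrom`,
#' `start`, `end`, `strand` (half-open 0-based coordinates); the
#' expression table has columns `id`, `expression`. Expression ids absent
#' from the annotation are ignored and counted.
#'
#' @param path gene annotation TSV.
#' @param expression_path optional expression TSV; NULL leaves expression
#'   missing.
#' @param genome optional `h1_genome` for validation.
#' @return An `h1_genes` data frame with attribute `n_unmatched_expression`.
#' @export
load_genes <- function(path, expression_path = NULL, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate gene id in annotation: ",
         tab$id[duplicated(tab$id)][1])
  expr <- rep(NA_real_, nrow(tab))
  n_unmatched <- 0L
  if (!is.null(expression_path)) {
    ex <- utils::read.table(expression_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character"))
    if (!all(c("id", "expression") %in% names(ex)))
      stop("expression table must have columns id, expression")
    val <- suppressWarnings(as.numeric(ex$expression))
    if (anyNA(val))
      stop("non-numeric expression at row ", which(is.na(val))[1])
    m <- match(ex$id, tab$id)
    n_unmatched <- sum(is.na(m))
    expr[m[!is.na(m)]] <- val[!is.na(m)]
  }
  out <- gene_set(tab$id, tab$chrom, tab$start, tab$end, tab$strand,
                  expression = expr,
                  cds_start = tab$cds_start, cds_end = tab$cds_end,
                  genome = genome)
  attr(out, "n_unmatched_expression") <- n_unmatched
  out
}

#' Write a gene table (and optionally its expression table)
#' @param genes an `h1_genes` data frame.
#' @param path gene TSV output path.
#' @param expression_path optional expression TSV output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, expression_path = NULL) {
  utils::write.table(
    data.frame(id = genes$id, chrom = genes$chrom,
               start = format(genes$start, scientific = FALSE, trim = TRUE),
               end = format(genes$end, scientific = FALSE, trim = TRUE),
               strand = genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(expression_path)) {
    has <- !is.na(genes$expression)
    utils::write.table(
      data.frame(id = genes$id[has],
                 expression = sprintf("%.6g", genes$expression[has])),
      expression_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
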