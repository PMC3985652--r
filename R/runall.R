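#' Build a validated pipeline run configuration
#'
#' A run configuration names every input path (chrom.sizes, gene and
#' expression tables, LAD bed, GC bedgraph, and per-variant chip/input
#' read beds), the parameter blocks of every stage, and the seeds; every
#' referenced path must exist at validation time and every random stage
#' is explicitly seeded, so a run is reproducible from its config alone.
#'
#' @param x a YAML file path or a list with fields `genome`, `genes`,
#'   `expression`, `lads`, `gc`, `variants` (named list with `chip` and
#'   `input` paths), `outdir`, and optional `params` overrides
#'   (`bin_size`, `fragment_size`, island/profile settings, `n_null`,
#'   `alpha`, `seed`, `n_groups`, `top_fraction`).
#' @return A validated list of class `h1_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  need <- c("genome", "genes", "expression", "lads", "variants", "outdir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing field(s): ", paste(miss, collapse = ", "))
  paths <- c(cfg$genome, cfg$genes, cfg$expression, cfg$lads, cfg$gc,
             unlist(lapply(cfg$variants, function(v) c(v$chip, v$input))))
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("config references missing path(s): ",
         paste(absent, collapse = ", "))
  if (is.null(names(cfg$variants)) || any(!nzchar(names(cfg$variants))))
    stop("variants must be a named list")
  p <- cfg$params
  defaults <- list(bin_size = 50, fragment_size = 150, dedup = TRUE,
                   n_null = 1000, alpha = 0.05, seed = 1, n_groups = 10,
                   top_fraction = 0.10, upstream = 3200, downstream = 800,
                   window = 200, gap = 200, fdr = 0.01,
                   min_fold_change = 2.0,
                   effective_genome_fraction = 0.75,
                   body_bins = 60, flank = 1000, gc_window = 1000)
  for (nm in names(defaults))
    if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  cfg$params <- p
  class(cfg) <- "h1_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full occupancy pipeline on a fixture bundle
#'
#' Executes, for every configured variant: coverage, input subtraction,
#' bedGraph export, TSS profiles stratified by expression group, metagene
#' profile, enriched and depleted island calling with nearest-gene and
#' feature annotation, and the domain statistics (GRC, chromosome
#' occupancy with clustering when the genome has enough chromosomes, LAD
#' enrichment test, GC correlation, distal-promoter scores). With two or
#' more variants the first two are compared by top/bottom-fraction
#' overlap analysis. All randomness derives from the configured seed, so
#' reruns are byte-identical.
#'
#' @param config an `h1_config`, a config list, or a YAML path.
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "h1_config")) config else run_config(config)
  p <- cfg$params
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("run_all started")
  logf("config: %s", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))

  stage <- "load inputs"
  summary <- list()
  res <- try({
    gen <- read_chrom_sizes(cfg$genome)
    genes <- load_genes(cfg$genes, cfg$expression, genome = gen)
    lads <- read_bed(cfg$lads, gen)
    gc <- if (!is.null(cfg$gc)) read_bedgraph(cfg$gc, gen) else NULL
    cov_par <- coverage_params(p$bin_size, p$fragment_size, p$dedup)
    isl_par <- island_params(window = p$window, gap = p$gap, fdr = p$fdr,
                             min_fold_change = p$min_fold_change,
                             fragment_size = p$fragment_size,
                             effective_genome_fraction =
                               p$effective_genome_fraction)
    pspec <- profile_spec(p$upstream, p$downstream, p$bin_size)
    mspec <- metagene_spec(p$body_bins, p$flank)

    groups <- expression_deciles(genes, p$n_groups)
    write_tsv(data.frame(chrom = names(gene_richness(genes, gen)),
                         grc = gene_richness(genes, gen)),
              file.path(cfg$outdir, "grc.tsv"))

    tracks <- list(); distal <- list()
    for (vn in names(cfg$variants)) {
      stage <- paste0("variant ", vn)
      chip <- read_reads_bed(cfg$variants[[vn]]$chip, gen)
      input <- read_reads_bed(cfg$variants[[vn]]$input, gen)
      chip_cov <- bin_coverage(chip, gen, cov_par)
      input_cov <- bin_coverage(input, gen, cov_par)
      sub <- normalize_subtract(chip_cov, input_cov)
      tracks[[vn]] <- sub
      write_bedgraph(sub, file.path(cfg$outdir,
                                    paste0(vn, "_subtracted.bedgraph")))

      prof <- anchored_profile(sub, genes, pspec)
      prof_tab <- data.frame(offset = as.numeric(colnames(prof)),
                             all = column_mean_profile(prof)$mean)
      for (g in levels(groups)) {
        sel <- which(!is.na(groups) & groups == g)
        prof_tab[[g]] <- if (length(sel))
          column_mean_profile(prof[sel, , drop = FALSE])$mean else NA_real_
      }
      write_tsv(prof_tab, file.path(cfg$outdir,
                                    paste0(vn, "_tss_profile.tsv")))
      mg <- metagene_profile(sub, genes, mspec)
      write_tsv(data.frame(bin = seq_along(mg$mean),
                           section = mg$section, mean = mg$mean,
                           n = mg$n),
                file.path(cfg$outdir, paste0(vn, "_metagene.tsv")))

      isl_counts <- list()
      for (dirn in c("enriched", "depleted")) {
        isl <- call_islands(chip, input, gen, isl_par, direction = dirn)
        ann <- if (nrow(isl))
          cbind(annotate_nearest_gene(isl, genes),
                feature = classify_feature(isl, genes),
                q_value = isl$q_value, fold_change = isl$fold_change)
        else data.frame()
        write_tsv(ann, file.path(cfg$outdir,
                                 paste0(vn, "_islands_", dirn, ".tsv")))
        isl_counts[[dirn]] <- list(
          n = nrow(isl),
          by_feature = if (nrow(isl)) as.list(table(ann$feature)) else list())
      }

      lad_test <- if (nrow(lads) > 0)
        region_enrichment_test(sub, lads, n_null = p$n_null,
                               alpha = p$alpha, seed = p$seed)
      else NULL
      gc_r <- if (!is.null(gc))
        gc_correlation(sub, gc, p$gc_window)$r else NA_real_
      distal[[vn]] <- distal_promoter_score(sub, genes)

      summary$variants[[vn]] <- list(
        libsize_chip = libsize(chip), libsize_input = libsize(input),
        gc_correlation = gc_r,
        lad = if (is.null(lad_test)) list(direction = "no regions")
        else list(D = lad_test$D, p_value = lad_test$p_value,
                  direction = lad_test$direction),
        islands = isl_counts)
      logf("variant %s done", vn)
    }

    stage <- "chromosome occupancy"
    occ <- chromosome_occupancy(tracks)
    write_tsv(data.frame(variant = rownames(occ), occ,
                         check.names = FALSE),
              file.path(cfg$outdir, "chrom_occupancy.tsv"))
    if (length(tracks) >= 2 && ncol(occ) >= 3) {
      cl <- cluster_occupancy(occ, "variants")
      writeLines(paste(cl$labels[cl$order], collapse = "\t"),
                 file.path(cfg$outdir, "variant_leaf_order.txt"))
      summary$variant_leaf_order <- cl$labels[cl$order]
    }

    if (length(distal) >= 2) {
      stage <- "decile overlap"
      ov <- decile_overlap_analysis(distal[[1]], distal[[2]], genes,
                                    fraction = p$top_fraction,
                                    alpha = p$alpha)
      write_tsv(data.frame(intersection = names(ov$counts),
                           n = as.integer(ov$counts)),
                file.path(cfg$outdir, "decile_overlap.tsv"))
      summary$decile_overlap <- list(
        a = names(distal)[1], b = names(distal)[2],
        counts = as.list(ov$counts),
        hl_expression = ov$expression_tests$hl[c("median", "p_value",
                                                 "direction")])
    }
    summary$grc <- as.list(gene_richness(genes, gen))
    summary
  }, silent = TRUE)

  if (inherits(res, "try-error")) {
    manifest <- list(complete = FALSE, failed_stage = stage,
                     error = attr(res, "condition")$message)
    yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
    stop("run_all failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  }
  yaml::write_yaml(list(complete = TRUE), file.path(cfg$outdir,
                                                    "manifest.yaml"))
  jsonlite::write_json(res, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("run_all finished")
  invisible(res)
}
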