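# Pipeline wiring: a validated configuration whose defaults are the
# standard published parameter sets for each stage, and a driver that
# runs the requested stages in dependency order, writing per-stage TSVs
# plus a machine-readable summary JSON.

#' Default analysis configuration
#'
#' Defaults are the conventional published settings of each stage:
#' IR detection minimum length 1,000 bp (exact copies); MISA minimum
#' repeat counts mono-12, di-6, tri-5, tetra-5, penta-4, hexa-4;
#' dispersed repeats minimum size 30 with at most 3 mismatches;
#' tandem-repeat weights +2/-7/-7 with minimum score 80 and maximum
#' period 500.
#'
#' @param ... overrides for any top-level entry.
#' @return named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    ir = list(min_ir_length = 1000L, max_mismatch_rate = 0),
    ssr = list(thresholds = c(`1` = 12L, `2` = 6L, `3` = 5L, `4` = 5L,
                              `5` = 4L, `6` = 4L)),
    dispersed = list(min_size = 30L, max_mismatch = 3L, exclude_ir = TRUE),
    tandem = list(weights = c(match = 2, mismatch = -7, indel = -7),
                  min_score = 80, max_period = 500L),
    dj = list(per_locus_N = TRUE, min_classes = 2L),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Load a configuration from YAML, merged over the defaults
#'
#' @param path YAML file with any subset of the [default_config()]
#'   entries.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  # vector-valued entries arrive from YAML as lists
  cfg$ssr$thresholds <- unlist(cfg$ssr$thresholds)
  cfg$tandem$weights <- unlist(cfg$tandem$weights)
  cfg
}

#' Run the plastome analysis pipeline
#'
#' Executes the requested stages in dependency order (io, structure,
#' ssr, dispersed, tandem, codon) on one input genome, writing one TSV
#' per stage plus `summary.json` into `out_dir`. Diversity and marker
#' stages operate on alignments and genotype tables and are driven
#' directly through [region_diversity()], [rank_regions()] and
#' [compare_marker_classes()].
#'
#' @param input path to a FASTA or GenBank genome, or a
#'   [plastome_record()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of c("structure", "ssr", "dispersed", "tandem",
#'   "codon").
#' @param config a `run_config` (default [default_config()]).
#' @return the summary list, invisibly; side effect: TSV/JSON files.
#' @export
run_pipeline <- function(input, out_dir,
                         stages = c("structure", "ssr", "dispersed",
                                    "tandem", "codon"),
                         config = default_config()) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  record <- if (inherits(input, "plastome_record")) input
  else if (grepl("\\.(gb|gbk|genbank)$", input, ignore.case = TRUE))
    read_genbank(input)
  else read_fasta(input)[[1L]]

  summary <- list(schema_version = "1.0",
                  record = record$id,
                  genome_length = genome_length(record),
                  config = unclass(config))
  partition <- NULL
  need_structure <- any(c("structure", "ssr", "dispersed", "codon") %in%
                        stages)
  if (need_structure) {
    partition <- detect_inverted_repeats(
      record, min_ir_length = config$ir$min_ir_length,
      max_mismatch_rate = config$ir$max_mismatch_rate)
    if (isTRUE(partition$no_structure)) {
      summary$structure <- list(no_quadripartite_structure = TRUE)
      partition <- NULL
    }
  }
  if ("structure" %in% stages && !is.null(partition)) {
    rl <- region_lengths(partition)
    pt <- data.frame(region = c("LSC", "IRb", "SSC", "IRa"),
                     start = c(partition$lsc[1], partition$irb[1],
                               partition$ssc[1], partition$ira[1]),
                     end = c(partition$lsc[2], partition$irb[2],
                             partition$ssc[2], partition$ira[2]))
    pt$length <- pt$end - pt$start
    write_tsv_report(pt, file.path(out_dir, "partition.tsv"),
                     "quadripartite region partition, canonical rotation")
    jr <- junction_report(partition)
    write_tsv_report(jr, file.path(out_dir, "junctions.tsv"),
                     "junction gene distances")
    pg <- call_boundary_pseudogenes(partition)
    write_tsv_report(pg, file.path(out_dir, "pseudogenes.tsv"),
                     "IR-duplicated fragments of junction-spanning genes")
    summary$structure <- list(region_lengths = as.list(rl),
                              n_boundary_pseudogenes = nrow(pg))
  }
  canon <- if (!is.null(partition)) partition$record else record
  if ("ssr" %in% stages) {
    ssrs <- find_ssrs(canon, thresholds = config$ssr$thresholds)
    if (!is.null(partition)) {
      dist <- summarize_by_region(ssrs, partition)
      write_tsv_report(dist, file.path(out_dir, "ssr_by_region.tsv"))
      summary$ssr <- list(n = nrow(ssrs),
                          by_region = stats::setNames(as.list(dist$count),
                                                      dist$region))
    } else summary$ssr <- list(n = nrow(ssrs))
    write_tsv_report(as.data.frame(ssrs), file.path(out_dir, "ssrs.tsv"))
  }
  if ("dispersed" %in% stages) {
    reps <- find_dispersed_repeats(
      canon, min_size = config$dispersed$min_size,
      max_mismatch = config$dispersed$max_mismatch,
      exclude_ir = if (isTRUE(config$dispersed$exclude_ir)) partition)
    write_tsv_report(as.data.frame(reps), file.path(out_dir, "repeats.tsv"))
    summary$dispersed <- list(n = nrow(reps),
                              by_class = as.list(table(reps$class)))
  }
  if ("tandem" %in% stages) {
    tr <- find_tandem_repeats(canon, weights = config$tandem$weights,
                              min_score = config$tandem$min_score,
                              max_period = config$tandem$max_period)
    write_tsv_report(as.data.frame(tr), file.path(out_dir, "tandem.tsv"))
    summary$tandem <- list(n = nrow(tr))
  }
  if ("codon" %in% stages) {
    gc <- gc_by_region(canon, partition)
    write_tsv_report(gc, file.path(out_dir, "gc_content.tsv"))
    summary$gc <- stats::setNames(as.list(gc$gc_percent), gc$scope)
    if (any(canon$features$kind == "CDS")) {
      cu <- codon_usage(canon)
      write_tsv_report(cu$codons, file.path(out_dir, "codon_usage.tsv"))
      summary$codon <- list(n_codons = cu$n_codons)
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Verify the package against a deposited reference plastome
#'
#' Recomputes, from a locally downloaded GenBank record of the deposited
#' miniature-rose plastome (accession MN435990), the published headline
#' quantities: genome length 157,395 bp; region lengths LSC 87,710 /
#' SSC 18,849 / IR 25,418 bp; GC content 37.19% (genome), 35.19% (LSC),
#' 31.20% (SSC), 43.34% (IR); 49 perfect SSRs (46 mononucleotide, 3
#' dinucleotide) with 85.71% in the LSC; and the 2,499 bp trnK-UUU
#' intron. The record itself is not redistributed with the package; a
#' one-time download (e.g. via NCBI EFetch) is required.
#'
#' @param genbank_path path to the downloaded GenBank flat file.
#' @return data frame with columns `quantity`, `expected`, `computed`,
#'   `ok`.
#' @export
check_reference_accession <- function(genbank_path) {
  record <- read_genbank(genbank_path)
  partition <- detect_inverted_repeats(record)
  rl <- region_lengths(partition)
  gc <- gc_by_region(partition$record, partition)
  gcv <- stats::setNames(gc$gc_percent, gc$scope)
  ssrs <- find_ssrs(partition$record)
  dist <- summarize_by_region(ssrs, partition)
  introns <- extract_introns(record)
  trnk <- introns[grepl("trnK", introns$name), , drop = FALSE]
  trnk_len <- if (nrow(trnk)) max(trnk$end - trnk$start) else NA_integer_
  exp <- c(genome_length = 157395, lsc = 87710, ssc = 18849, ir = 25418,
           gc_genome = 37.19, gc_lsc = 35.19, gc_ssc = 31.20,
           gc_ir = 43.34, n_ssr = 49, n_ssr_mono = 46, n_ssr_di = 3,
           pct_ssr_lsc = 85.71, trnK_intron = 2499)
  got <- c(genome_length = genome_length(record),
           lsc = unname(rl["lsc"]), ssc = unname(rl["ssc"]),
           ir = unname(rl["irb"]),
           gc_genome = unname(gcv["genome"]), gc_lsc = unname(gcv["LSC"]),
           gc_ssc = unname(gcv["SSC"]), gc_ir = unname(gcv["IR"]),
           n_ssr = nrow(ssrs),
           n_ssr_mono = sum(nchar(ssrs$motif) == 1L),
           n_ssr_di = sum(nchar(ssrs$motif) == 2L),
           pct_ssr_lsc = dist$percent[dist$region == "LSC"],
           trnK_intron = trnk_len)
  data.frame(quantity = names(exp), expected = unname(exp),
             computed = unname(got),
             ok = abs(unname(exp) - unname(got)) < 0.01 + 0.0001 * exp,
             stringsAsFactors = FALSE)
}
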