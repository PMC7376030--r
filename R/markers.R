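# Marker evaluation: genotype tables over a variety panel and the
# per-locus discriminating power
#   D_j = 1 - C_j = 1 - sum_i p_i (N p_i - 1) / (N - 1),
# the probability that two varieties drawn without replacement differ in
# genotype at locus j (C_j is the confusion probability). Algebraically
# D_j = 1 - (number of genotype-concordant unordered pairs) / C(N, 2).

#' Construct a genotype table
#'
#' Varieties in rows, loci in columns; entries are genotype labels as
#' text (cpSSR: the fragment size as integer text; SNV: the haplotype
#' string), with "." marking a missing genotype.
#'
#' @param genotypes character matrix or data frame (varieties x loci).
#' @param varieties optional variety ids (default from row names).
#' @param loci optional locus ids (default from column names).
#' @return object of class `genotype_table` (a character matrix with
#'   dimnames).
#' @export
genotype_table <- function(genotypes, varieties = NULL, loci = NULL) {
  m <- as.matrix(genotypes)
  mode(m) <- "character"
  if (!is.null(varieties)) rownames(m) <- varieties
  if (!is.null(loci)) colnames(m) <- loci
  if (is.null(rownames(m))) rownames(m) <- paste0("variety_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("locus_", seq_len(ncol(m)))
  if (any(colSums(m != ".") == 0L))
    stop("every locus needs at least one non-missing genotype")
  class(m) <- c("genotype_table", class(m))
  m
}

#' Read a genotype table from TSV
#'
#' Expects varieties in rows (first column = variety id), loci in
#' columns, "." for missing.
#'
#' @param path TSV file.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#")
  genotype_table(df[, -1L, drop = FALSE], varieties = df[[1L]])
}

#' Discriminating power D_j of one genotype column
#'
#' Genotype frequencies p_i are computed from the non-missing entries
#' (per-locus N, which keeps sum(p_i) = 1 exact); missing entries (".")
#' are excluded. D_j = 0 iff all non-missing genotypes fall in one
#' class; D_j = 1 iff all are distinct.
#'
#' @param genotypes character vector of genotype labels ("." = missing).
#' @param N optional panel size overriding the per-locus non-missing
#'   count in the formula's N.
#' @return D_j in [0, 1] with attributes `n_used` and `freqs`; NA (with
#'   a warning) when fewer than 2 non-missing genotypes remain.
#' @export
compute_dj <- function(genotypes, N = NULL) {
  g <- genotypes[genotypes != "." & !is.na(genotypes)]
  n_used <- length(g)
  if (n_used < 2L) {
    warning("fewer than 2 non-missing genotypes; D_j undefined")
    return(structure(NA_real_, n_used = n_used, freqs = numeric(0)))
  }
  if (is.null(N)) N <- n_used
  counts <- table(g)
  p <- as.numeric(counts) / n_used
  dj <- 1 - sum(p * (N * p - 1) / (N - 1))
  structure(dj, n_used = n_used,
            freqs = stats::setNames(p, names(counts)))
}

#' Call SNV haplotype genotypes from a flanking-sequence alignment
#'
#' Columns containing a gap in any row are removed (complete deletion);
#' among the remaining columns, the variable ones (more than one
#' distinct non-N base) are extracted, and each variety's genotype label
#' is the concatenation of its alleles across those columns in
#' coordinate order. A variety with N at any variable column is marked
#' missing. A monomorphic alignment yields one shared label (the locus
#' is flagged monomorphic; its D_j is 0).
#'
#' @param flank_alignment a [region_alignment()], one row per variety.
#' @return character vector of genotype labels named by taxon id, with
#'   attributes `n_variable_sites` and `monomorphic`.
#' @export
call_snv_haplotypes <- function(flank_alignment) {
  m <- do.call(rbind, strsplit(flank_alignment$rows, "", fixed = TRUE))
  keep <- colSums(m == "-") == 0L
  m <- m[, keep, drop = FALSE]
  variable <- apply(m, 2L, function(col) {
    length(unique(col[col != "N"])) > 1L
  })
  if (!any(variable)) {
    lab <- stats::setNames(rep("ref", nrow(m)), flank_alignment$taxon_ids)
    return(structure(lab, n_variable_sites = 0L, monomorphic = TRUE))
  }
  mv <- m[, variable, drop = FALSE]
  lab <- apply(mv, 1L, paste, collapse = "")
  lab[apply(mv == "N", 1L, any)] <- "."
  structure(stats::setNames(lab, flank_alignment$taxon_ids),
            n_variable_sites = sum(variable), monomorphic = FALSE)
}

#' Compare cpSSR and SNV marker classes locus by locus
#'
#' Computes D_j from the cpSSR fragment-size table (dj_a) and from the
#' SNV haplotype table (dj_b) for every shared locus, with class-level
#' summaries and the per-locus sign of the difference.
#'
#' @param table_ssr,table_snv [genotype_table()] objects sharing locus
#'   ids.
#' @param N optional fixed N for the D_j formula (default: per-locus
#'   non-missing count).
#' @return list with `per_locus` (locus, dj_a, dj_b, diff, sign) and
#'   `summary` (class, mean, min, max of D_j).
#' @export
compare_marker_classes <- function(table_ssr, table_snv, N = NULL) {
  loci <- intersect(colnames(table_ssr), colnames(table_snv))
  if (!length(loci)) stop("the two tables share no locus ids")
  dj_a <- vapply(loci, function(l) as.numeric(compute_dj(table_ssr[, l], N)),
                 numeric(1L))
  dj_b <- vapply(loci, function(l) as.numeric(compute_dj(table_snv[, l], N)),
                 numeric(1L))
  per_locus <- data.frame(locus = loci,
                          dj_a = round(dj_a, 4L), dj_b = round(dj_b, 4L),
                          diff = round(dj_b - dj_a, 4L),
                          sign = sign(round(dj_b - dj_a, 10L)),
                          stringsAsFactors = FALSE)
  rownames(per_locus) <- NULL
  summary <- data.frame(
    class = c("cpSSR", "SNV"),
    mean = round(c(mean(dj_a, na.rm = TRUE), mean(dj_b, na.rm = TRUE)), 4L),
    min = round(c(min(dj_a, na.rm = TRUE), min(dj_b, na.rm = TRUE)), 4L),
    max = round(c(max(dj_a, na.rm = TRUE), max(dj_b, na.rm = TRUE)), 4L),
    stringsAsFactors = FALSE)
  list(per_locus = per_locus, summary = summary)
}

#' Screen loci for polymorphism
#'
#' Retains loci with at least `min_classes` distinct genotype classes
#' among non-missing entries and reports the retained fraction as a
#' percentage (2 decimals).
#'
#' @param table a [genotype_table()].
#' @param min_classes minimum distinct genotype classes (default 2).
#' @return list: `loci` (retained ids), `n_total`, `n_retained`,
#'   `percent`.
#' @export
polymorphic_screen <- function(table, min_classes = 2L) {
  classes <- apply(table, 2L, function(col)
    length(unique(col[col != "."])))
  keep <- names(classes)[classes >= min_classes]
  list(loci = keep, n_total = ncol(table), n_retained = length(keep),
       percent = round(100 * length(keep) / ncol(table), 2L))
}
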