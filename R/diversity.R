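# Per-region nucleotide diversity (pi) and total number of mutations
# (eta) from multiple alignments, under complete deletion of columns
# containing a gap or N (the DnaSP convention, which keeps eta
# well-defined per column).

#' Construct a region alignment
#'
#' @param label region name (e.g. a gene or an intergenic spacer
#'   "geneA-geneB").
#' @param rows character vector of >= 2 aligned sequences of equal
#'   length over {A,C,G,T,N,-}.
#' @param class region class: coding, intron, IGS, rRNA or tRNA.
#' @param taxon_ids optional taxon labels (default seq_1..n).
#' @return object of class `region_alignment`.
#' @export
region_alignment <- function(label, rows, class = "IGS",
                             taxon_ids = NULL) {
  stopifnot(is.character(rows), length(rows) >= 2L)
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment for region '", label, "': rows differ in length")
  if (any(grepl("[^ACGTN-]", rows)))
    stop("alignment alphabet must be {A,C,G,T,N,-}")
  if (!class %in% c("coding", "intron", "IGS", "rRNA", "tRNA"))
    stop("unknown region class: ", class)
  if (is.null(taxon_ids)) taxon_ids <- paste0("seq_", seq_along(rows))
  stopifnot(length(taxon_ids) == length(rows))
  structure(list(label = label, class = class, rows = rows,
                 taxon_ids = taxon_ids), class = "region_alignment")
}

#' Read per-region alignments from aligned FASTA
#'
#' One alignment per file; the region label defaults to the file name
#' without extension.
#'
#' @param path aligned-FASTA file.
#' @param label region label.
#' @param class region class.
#' @return a [region_alignment()].
#' @export
read_region_alignment <- function(path,
                                  label = sub("\\.[^.]*$", "",
                                              basename(path)),
                                  class = "IGS") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment needs >= 2 sequences: ", path)
  region_alignment(label, as.character(set), class = class,
                   taxon_ids = sub("\\s.*$", "", names(set)))
}

# character matrix of an alignment plus the analyzed-site mask
# (complete deletion: a column is analyzed iff no row has a gap or N)
.alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  analyzed <- colSums(m == "-" | m == "N") == 0L
  list(m = m, analyzed = analyzed)
}

#' Nucleotide diversity of a region alignment
#'
#' pi is the average, over all unordered sequence pairs, of the
#' proportion of differing analyzed sites; analyzed sites are columns
#' with no gap and no N in any row (complete deletion). An alignment
#' with zero analyzed sites yields NA with a warning, never 0.
#'
#' @param aln a [region_alignment()].
#' @return numeric pi in [0, 1] with attribute `sites_used`.
#' @export
compute_pi <- function(aln) {
  am <- .alignment_matrix(aln)
  sites <- sum(am$analyzed)
  if (sites == 0L) {
    warning("region '", aln$label,
            "': no gap- and N-free sites; pi undefined")
    return(structure(NA_real_, sites_used = 0L))
  }
  m <- am$m[, am$analyzed, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  structure(tot / choose(n, 2L) / sites, sites_used = sites)
}

#' Total number of mutations of a region alignment
#'
#' eta is the sum over analyzed sites of (number of distinct nucleotides
#' at the site - 1), under the same complete-deletion rule as
#' [compute_pi()].
#'
#' @param aln a [region_alignment()].
#' @return integer eta with attribute `sites_used`; NA when no site is
#'   analyzable.
#' @export
compute_eta <- function(aln) {
  am <- .alignment_matrix(aln)
  sites <- sum(am$analyzed)
  if (sites == 0L) {
    warning("region '", aln$label,
            "': no gap- and N-free sites; eta undefined")
    return(structure(NA_integer_, sites_used = 0L))
  }
  m <- am$m[, am$analyzed, drop = FALSE]
  eta <- sum(apply(m, 2L, function(col) length(unique(col)) - 1L))
  structure(as.integer(eta), sites_used = sites)
}

#' Diversity summary of one region
#'
#' @param aln a [region_alignment()].
#' @return one-row data frame: `label`, `class`, `pi` (full precision),
#'   `pi_4dp` (rounded to 4 decimals as conventionally printed), `eta`,
#'   `length` (alignment length including gap columns), `sites_used`.
#' @export
region_diversity <- function(aln) {
  pi <- compute_pi(aln)
  eta <- compute_eta(aln)
  data.frame(label = aln$label, class = aln$class,
             pi = as.numeric(pi), pi_4dp = round(as.numeric(pi), 4L),
             eta = as.integer(eta), length = nchar(aln$rows[1L]),
             sites_used = attr(pi, "sites_used"),
             stringsAsFactors = FALSE)
}

#' Rank regions by nucleotide diversity
#'
#' Sorts regions ascending by pi (the hotspot-table convention), breaking
#' ties by eta descending, then label, and keeps the top_k most divergent
#' (i.e. the top_k largest pi values, presented in ascending order).
#' Class-level mean pi values are attached as attribute `class_means`.
#'
#' @param results data frame of [region_diversity()] rows.
#' @param top_k number of most-divergent regions to keep (the full list
#'   when larger than the number of regions).
#' @return ranked data frame with a leading `rank` column; attribute
#'   `class_means` is a named numeric vector of per-class mean pi.
#' @export
rank_regions <- function(results, top_k = 20L) {
  stopifnot(all(c("label", "class", "pi", "eta") %in% names(results)))
  res <- results[!is.na(results$pi), , drop = FALSE]
  o <- order(res$pi, -res$eta, res$label)
  res <- res[o, , drop = FALSE]
  if (top_k < nrow(res))
    res <- res[(nrow(res) - top_k + 1L):nrow(res), , drop = FALSE]
  res <- cbind(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  cm <- tapply(results$pi, results$class, mean, na.rm = TRUE)
  attr(res, "class_means") <- cm
  res
}
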