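# Base composition and codon usage. GC percentages exclude N from the
# denominator; scopes with > 10% N are flagged. Translation uses the
# standard genetic code (the plastid code differs only in start-codon
# policy, which is not exercised here).

.composition_row <- function(scope, s) {
  cnt <- table(factor(.chars(s), levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(cnt[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) 100 * sum(cnt[c("G", "C")]) / acgt else NA_real_
  data.frame(scope = scope, length = nchar(s),
             A = as.integer(cnt[["A"]]), C = as.integer(cnt[["C"]]),
             G = as.integer(cnt[["G"]]), T = as.integer(cnt[["T"]]),
             N = as.integer(cnt[["N"]]),
             gc_percent = round(gc, 2L),
             high_N = as.integer(cnt[["N"]]) > 0.1 * nchar(s),
             stringsAsFactors = FALSE)
}

#' GC content and base counts per plastome region
#'
#' One report per scope: the whole genome, LSC, SSC, the pooled IR
#' (IRa + IRb) and, when CDS features are annotated, the concatenated
#' CDS. GC is 100 (G+C)/(A+C+G+T), ignoring N.
#'
#' @param record a [plastome_record()] in the partition's canonical
#'   coordinates.
#' @param partition a `region_partition`; may be `NULL` to report only
#'   the genome scope.
#' @return data frame with columns `scope`, `length`, `A`, `C`, `G`,
#'   `T`, `N`, `gc_percent` (2 decimals), `high_N`.
#' @export
gc_by_region <- function(record, partition = NULL) {
  s <- record$sequence
  out <- .composition_row("genome", s)
  if (!is.null(partition) && !isTRUE(partition$no_structure)) {
    out <- rbind(
      out,
      .composition_row("LSC", .subseq0(s, partition$lsc[1], partition$lsc[2])),
      .composition_row("SSC", .subseq0(s, partition$ssc[1], partition$ssc[2])),
      .composition_row("IR", paste0(
        .subseq0(s, partition$irb[1], partition$irb[2]),
        .subseq0(s, partition$ira[1], partition$ira[2]))))
  }
  cds <- record$features[record$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    cds_seq <- paste(vapply(split(cds, cds$feature_id),
                            function(p) feature_sequence(record, p), ""),
                     collapse = "")
    out <- rbind(out, .composition_row("CDS", cds_seq))
  }
  rownames(out) <- NULL
  out
}

#' Codon usage and positional base composition of annotated CDS
#'
#' Counts codons over all CDS features on their coding strand (parts
#' joined, minus strand reverse-complemented). A CDS whose joined length
#' is not divisible by 3 has its trailing remainder dropped with a
#' warning. RSCU is computed per synonymous family of the standard
#' genetic code; stop codons are tallied but not given RSCU values.
#'
#' @param record an annotated [plastome_record()] with CDS features.
#' @return list with `codons` (codon, amino_acid, count, rscu),
#'   `by_position` (base composition percentages at codon positions
#'   1-3) and `n_codons`.
#' @export
codon_usage <- function(record) {
  cds <- record$features[record$features$kind == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("record '", record$id, "' has no CDS features")
  codons <- character(0)
  for (p in split(cds, cds$feature_id)) {
    s <- feature_sequence(record, p)
    if (nchar(s) %% 3L != 0L) {
      warning("CDS '", p$name[1L], "' length not divisible by 3; ",
              "trailing ", nchar(s) %% 3L, " base(s) dropped")
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
    if (nchar(s) >= 3L)
      codons <- c(codons, substring(s, seq(1L, nchar(s), 3L),
                                    seq(3L, nchar(s), 3L)))
  }
  codons <- codons[!grepl("N", codons)]
  code <- Biostrings::GENETIC_CODE
  cnt <- table(factor(codons, levels = names(code)))
  tab <- data.frame(codon = names(code), amino_acid = unname(code),
                    count = as.integer(cnt), stringsAsFactors = FALSE)
  # RSCU: count / (family mean), per amino acid, sense codons only
  tab$rscu <- NA_real_
  for (aa in setdiff(unique(tab$amino_acid), "*")) {
    fam <- tab$amino_acid == aa
    fam_mean <- mean(tab$count[fam])
    tab$rscu[fam] <- if (fam_mean > 0) tab$count[fam] / fam_mean else NA_real_
  }
  # positional base composition
  pos_comp <- sapply(1:3, function(q) {
    b <- substr(codons, q, q)
    100 * as.numeric(table(factor(b, levels = c("A", "C", "G", "T")))) /
      length(b)
  })
  by_position <- data.frame(base = c("A", "C", "G", "T"),
                            pos1 = round(pos_comp[, 1L], 2L),
                            pos2 = round(pos_comp[, 2L], 2L),
                            pos3 = round(pos_comp[, 3L], 2L),
                            stringsAsFactors = FALSE)
  list(codons = tab, by_position = by_position, n_codons = length(codons))
}
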