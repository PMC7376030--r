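# Perfect microsatellite (SSR) mining with MISA-style minimum repeat
# counts. The scan is periodicity-based: for each motif length m the
# boolean vector seq[i] == seq[i+m] is run-length encoded; a run of
# length t marks a periodic stretch of t+m bases starting at its first
# position, holding floor((t+m)/m) complete motif copies.

.default_ssr_thresholds <- c(`1` = 12L, `2` = 6L, `3` = 5L, `4` = 5L,
                             `5` = 4L, `6` = 4L)

# TRUE if the motif is not a repetition of a shorter unit
.is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        strrep(substr(motif, 1L, d), m %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Mine perfect SSRs from a plastome sequence
#'
#' Reports maximal perfect tracts of 1-6 bp motifs reaching the
#' per-motif-class minimum copy numbers (defaults are the MISA settings
#' mono-12, di-6, tri-5, tetra-5, penta-4, hexa-4). Tracts satisfying
#' multiple motif interpretations are reported once under the shortest
#' primitive motif; runs containing N are excluded; a shorter-motif run
#' wholly inside a reported longer-motif tract is suppressed. Motifs are
#' reported as observed on the given strand (A-runs and T-runs are
#' distinct classes).
#'
#' @param record a [plastome_record()] (or a plain sequence string).
#' @param thresholds named integer vector: minimum copies for motif
#'   lengths "1".."6".
#' @return data frame (class `ssr_table`): `motif`, `copies`, `start`,
#'   `end`, `length` (0-based half-open; length = motif length x
#'   copies), sorted by start.
#' @export
find_ssrs <- function(record, thresholds = .default_ssr_thresholds) {
  s <- if (inherits(record, "plastome_record")) record$sequence else record
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  ch <- .chars(s)
  n <- length(ch)
  isN <- ch == "N"
  rows <- list()
  for (m in 1:6) {
    thr <- as.integer(thresholds[[as.character(m)]])
    if (n < m * thr) next
    eq <- ch[seq_len(n - m)] == ch[(m + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      total <- r$lengths[j] + m          # periodic stretch length
      copies <- total %/% m
      if (copies < thr) next
      i <- starts[j]                     # 1-based leftmost position
      tract_len <- copies * m
      if (any(isN[i:(i + tract_len - 1L)])) next
      motif <- substr(s, i, i + m - 1L)
      if (!.is_primitive_motif(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, copies = copies, start = i - 1L,
        end = i - 1L + tract_len, length = tract_len,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(motif = character(), copies = integer(),
                      start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE)
    class(out) <- c("ssr_table", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  # suppress shorter-motif runs wholly inside a longer-motif tract and
  # exact duplicates
  keep <- rep(TRUE, nrow(out))
  ml <- nchar(out$motif)
  for (i in seq_len(nrow(out))) {
    inside <- which(out$start <= out$start[i] & out$end >= out$end[i] &
                    ml > ml[i])
    if (length(inside)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssr_table", class(out))
  out
}

#' Summarize loci counts by plastome region
#'
#' Assigns each locus to the quadripartite region containing its start
#' and tabulates counts and percentages (2 decimals). Rows are emitted
#' for LSC, IRb, IRa, the pooled IR, and SSC.
#'
#' @param loci data frame with a `start` column (e.g. [find_ssrs()]
#'   output) in the partition's canonical coordinates.
#' @param partition a `region_partition` from
#'   [detect_inverted_repeats()].
#' @return data frame with columns `region`, `count`, `percent`.
#' @export
summarize_by_region <- function(loci, partition) {
  regions <- c("LSC", "IRb", "IRa", "IR", "SSC")
  if (!nrow(loci)) {
    return(data.frame(region = regions, count = 0L, percent = 0,
                      stringsAsFactors = FALSE))
  }
  reg <- region_of(partition, loci$start)
  total <- nrow(loci)
  cnt <- c(LSC = sum(reg == "LSC"), IRb = sum(reg == "IRb"),
           IRa = sum(reg == "IRa"),
           IR = sum(reg %in% c("IRa", "IRb")), SSC = sum(reg == "SSC"))
  data.frame(region = regions, count = as.integer(cnt[regions]),
             percent = round(100 * cnt[regions] / total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
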