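# Tandem repeat detection under TRF-style alignment weights. Candidate
# periods are proposed from the distances between recurring k-mers; each
# candidate locus is verified by scoring the tract against its per-phase
# majority consensus under the weights (+2 match, -7 mismatch, -7 indel;
# no indels arise in the mismatch-only model scored here). This is a
# deliberate simplification of the full probabilistic Tandem Repeats
# Finder model: published weights and thresholds are preserved, but
# counts on real genomes are reported, not asserted equal to TRF output.

.default_tandem_weights <- c(match = 2, mismatch = -7, indel = -7)

#' Detect tandem repeats
#'
#' @param record a [plastome_record()] or sequence string.
#' @param weights named numeric vector `match`, `mismatch`, `indel`
#'   (defaults +2, -7, -7).
#' @param min_score minimum alignment score against the locus consensus
#'   (default 80).
#' @param max_period maximum period size in bp (default 500).
#' @return data frame (class `tandem_table`): `start`, `end` (0-based
#'   half-open), `period`, `copy_number` (real, >= 2), `consensus`,
#'   `alignment_score`. Overlapping reports are merged keeping the
#'   higher score (ties: smaller period).
#' @export
find_tandem_repeats <- function(record, weights = .default_tandem_weights,
                                min_score = 80, max_period = 500L) {
  s <- if (inherits(record, "plastome_record")) record$sequence else record
  ch <- .chars(s)
  n <- length(ch)
  k <- 7L
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      alignment_score = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("tandem_table", class(empty))
  if (n < 2L * 2L) return(empty)
  # candidate periods: distances between consecutive occurrences of the
  # same k-mer (a tandem tract of period p repeats its k-mers at lag p)
  periods <- integer(0)
  if (n >= k + 1L) {
    km <- substring(s, 1:(n - k + 1L), k:n)
    occ <- split(seq_along(km), km)
    lags <- unlist(lapply(occ[lengths(occ) > 1L], function(p) diff(p)),
                   use.names = FALSE)
    lags <- lags[lags <= max_period]
    # a scoreable tract (>= ~40 matching bases) supports its lag with
    # many recurring k-mers; isolated chance lags are not candidates
    support <- table(lags)
    periods <- sort(as.integer(names(support)[support >= 5L]))
  }
  # very short periods (< k) are still proposed through their k-mer lag,
  # but include small periods explicitly so short-motif tandems in short
  # sequences are not missed
  periods <- sort(unique(c(periods, seq_len(min(6L, max_period, n %/% 2L)))))
  rows <- list()
  for (p in periods) {
    if (n < 2L * p) next
    eq <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # merge TRUE runs separated by short mismatch gaps (point mutations
    # break the lag-p identity at two isolated positions). A gap of g
    # mismatches costs 9g score, so it is crossed only when the run on
    # the far side more than pays for it; this keeps tract boundaries
    # from drifting into unrelated flanking sequence.
    true_idx <- which(r$values)
    if (!length(true_idx)) next
    min_far_run <- c(5L, 10L, 14L)   # for gaps of 1, 2, 3
    merged <- list()
    cur <- c(starts[true_idx[1L]], ends[true_idx[1L]])
    for (j in true_idx[-1L]) {
      gap <- starts[j] - cur[2L] - 1L
      if (gap <= 3L && r$lengths[j] >= min_far_run[gap]) {
        cur[2L] <- ends[j]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(starts[j], ends[j])
      }
    }
    merged[[length(merged) + 1L]] <- cur
    # a segment shorter than the minimum achievable tract cannot score
    min_span <- max(2L * p - p, as.integer(ceiling(min_score / 2)) - p)
    merged <- Filter(function(iv) iv[2L] - iv[1L] + 1L >= min_span, merged)
    if (!length(merged)) next
    # trim each merged segment to its best-scoring sub-window (Kadane
    # over the run/gap decomposition, +2 per match, -9 per crossed
    # mismatch), so leading/trailing junk runs never stick
    merged <- lapply(merged, function(iv) {
      sub <- rle(eq[iv[1L]:iv[2L]])
      val <- ifelse(sub$values, 2L * sub$lengths, -9L * sub$lengths)
      best <- c(1L, 1L); best_s <- -Inf
      cur_s <- 0; cur_from <- 1L
      for (u in seq_along(val)) {
        if (cur_s <= 0) { cur_s <- 0; cur_from <- u }
        cur_s <- cur_s + val[u]
        if (sub$values[u] && cur_s > best_s) {
          best_s <- cur_s; best <- c(cur_from, u)
        }
      }
      offs <- cumsum(c(0L, sub$lengths))
      c(iv[1L] + offs[best[1L]], iv[1L] + offs[best[2L] + 1L] - 1L)
    })
    for (iv in merged) {
      tract <- c(iv[1L], iv[2L] + p)       # 1-based inclusive char range
      len <- tract[2L] - tract[1L] + 1L
      if (len < 2L * p) next
      sc <- .score_tandem(ch[tract[1L]:tract[2L]], p, weights)
      if (sc$score < min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = tract[1L] - 1L, end = tract[2L], period = p,
        copy_number = round(len / p, 1L), consensus = sc$consensus,
        alignment_score = sc$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # merge overlapping reports: keep the higher score, then smaller period
  out <- out[order(-out$alignment_score, out$period, out$start), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(out)) > i &
                   out$start < out$end[i] & out$end > out$start[i])
    keep[later] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tandem_table", class(out))
  out
}

# score a tract against its per-phase majority consensus (ties broken by
# alphabetical order, so results are deterministic)
.score_tandem <- function(tract_chars, p, weights) {
  len <- length(tract_chars)
  phase <- (seq_len(len) - 1L) %% p
  cons <- character(p)
  for (q in seq_len(p)) {
    b <- tract_chars[phase == (q - 1L)]
    tb <- sort(table(b), decreasing = TRUE)
    top <- names(tb)[tb == tb[1L]]
    cons[q] <- sort(top)[1L]
  }
  matches <- tract_chars == cons[phase + 1L]
  score <- sum(matches) * weights[["match"]] +
    sum(!matches) * weights[["mismatch"]]
  list(score = score, consensus = paste(cons, collapse = ""))
}
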