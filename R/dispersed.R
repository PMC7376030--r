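# Dispersed repeat mining in the four REPuter-style classes:
#   forward     - a segment repeated on the same strand, same orientation
#   palindromic - a segment and its reverse complement
#   reverse     - a segment and its reversal (no complementation)
#   complement  - a segment and its complement (no reversal)
#
# Matching semantics: a reported pair is a maximal chain of exact
# matching runs along one alignment diagonal, where every run is at
# least `chain_min` bases, consecutive runs are separated by exactly one
# mismatching position, at most `max_mismatch` mismatches are crossed,
# and the total span is at least `min_size`. This "isolated mismatches
# between solid exact runs" model is this package's concrete
# interpretation of mismatch repeats: it is deterministic, has an exact
# brute-force oracle, and recovers planted repeats with exact
# coordinates (reproducing REPuter's own maximal-repeat enumeration is
# explicitly out of scope). Chains are seeded by shared k-mers between
# the sequence and the class transform.

.transform_text <- function(s, class) {
  switch(class,
         forward = s,
         palindromic = revcomp(s),
         reverse = reverse_seq(s),
         complement = complement_seq(s),
         stop("unknown repeat class: ", class))
}

# map an interval [p, p+L) (1-based) of the transformed text back to the
# original sequence coordinates (1-based start)
.map_back <- function(p, L, n, class) {
  if (class %in% c("palindromic", "reverse")) n - (p - 1L) - L + 1L else p
}

# chains of exact runs on one diagonal. eq: logical match vector along
# the diagonal; returns matrix cols: off (1-based start), len, mm
.diagonal_chains <- function(eq, e, Lmin, chain_min) {
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  solid <- which(r$values & r$lengths >= chain_min)
  if (!length(solid)) return(NULL)
  # group consecutive solid runs joinable across single-mismatch gaps
  out <- NULL
  grp_start <- 1L
  emit <- function(members) {
    g <- length(members)
    if (g - 1L <= e) {
      wins <- list(members)
    } else {
      wins <- lapply(seq_len(g - e - 1L + 1L),
                     function(i) members[i:(i + e)])
    }
    res <- NULL
    for (w in wins) {
      off <- starts[w[1L]]
      len <- ends[w[length(w)]] - off + 1L
      if (len >= Lmin) res <- rbind(res, c(off, len, length(w) - 1L))
    }
    res
  }
  if (length(solid) == 1L) return(emit(solid))
  members <- solid[1L]
  for (i in 2L:length(solid)) {
    a <- solid[i - 1L]; b <- solid[i]
    joinable <- (b == a + 2L) && !r$values[a + 1L] && r$lengths[a + 1L] == 1L
    if (joinable) {
      members <- c(members, b)
    } else {
      out <- rbind(out, emit(members))
      members <- b
    }
  }
  rbind(out, emit(members))
}

#' Mine dispersed repeats (forward, palindromic, reverse, complement)
#'
#' Finds pairs of equal-length segments matching under each of the four
#' class transforms with at most `max_mismatch` isolated mismatches and
#' length at least `min_size` (REPuter-style parameterization; defaults
#' 30 and 3). A pair is a maximal chain of exact runs (each at least
#' `chain_min` bases) joined across single-base mismatches; pairs
#' contained in a longer reported pair of the same class are
#' suppressed, as are identical-interval self matches and, when a
#' partition is supplied, the genome-scale inverted-repeat pair itself.
#'
#' @param record a [plastome_record()] or sequence string.
#' @param min_size minimum repeat length (>= 8; k-mer seeding is
#'   unsound below that).
#' @param max_mismatch maximum mismatches crossed within a pair.
#' @param exclude_ir optional `region_partition`; palindromic pairs
#'   covering the quadripartite IR pair are dropped from the report.
#' @param chain_min minimum exact-run length on either side of a
#'   crossed mismatch.
#' @param classes repeat classes to search.
#' @return data frame (class `repeat_table`): `class`, `start1`, `end1`,
#'   `start2`, `end2` (0-based half-open), `length`, `mismatches`.
#' @export
find_dispersed_repeats <- function(record, min_size = 30L, max_mismatch = 3L,
                                   exclude_ir = NULL, chain_min = 10L,
                                   classes = c("forward", "palindromic",
                                               "reverse", "complement")) {
  if (min_size < 8L) stop("min_size < 8 rejected: k-mer seeding unsound")
  s <- if (inherits(record, "plastome_record")) record$sequence else record
  n <- nchar(s)
  chain_min <- min(as.integer(chain_min), as.integer(min_size))
  k <- chain_min
  sc <- .chars(s)
  ks <- substring(s, 1:(n - k + 1L), k:n)
  rows <- list()
  for (cl in classes) {
    t <- .transform_text(s, cl)
    tc <- .chars(t)
    kt <- if (cl == "forward") ks else substring(t, 1:(n - k + 1L), k:n)
    common <- intersect(ks, kt)
    if (!length(common)) next
    pos_s <- split(seq_along(ks), ks)[common]
    pos_t <- split(seq_along(kt), kt)[common]
    diags <- unique(unlist(lapply(seq_along(common), function(j)
      outer(pos_s[[j]], pos_t[[j]], `-`)), use.names = FALSE))
    if (cl == "forward") diags <- setdiff(diags, 0L)
    for (d in diags) {
      i1 <- max(1L, 1L + d); i2 <- min(n, n + d)
      if (i2 - i1 + 1L < min_size) next
      eq <- sc[i1:i2] == tc[(i1 - d):(i2 - d)]
      ch <- .diagonal_chains(eq, max_mismatch, min_size, chain_min)
      if (is.null(ch)) next
      for (w in seq_len(nrow(ch))) {
        a <- i1 + ch[w, 1L] - 1L            # 1-based in s
        L <- ch[w, 2L]
        p <- a - d                          # 1-based in t
        b <- .map_back(p, L, n, cl)         # 1-based in s
        if (a == b) next                    # trivial self match
        lo <- min(a, b); hi <- max(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, start1 = lo - 1L, end1 = lo - 1L + L,
          start2 = hi - 1L, end2 = hi - 1L + L,
          length = L, mismatches = ch[w, 3L], stringsAsFactors = FALSE)
      }
    }
  }
  out <- data.frame(class = character(), start1 = integer(),
                    end1 = integer(), start2 = integer(), end2 = integer(),
                    length = integer(), mismatches = integer(),
                    stringsAsFactors = FALSE)
  if (length(rows)) {
    out <- unique(do.call(rbind, rows))
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      cont <- which(out$class == out$class[i] & out$length > out$length[i] &
                    out$start1 <= out$start1[i] & out$end1 >= out$end1[i] &
                    out$start2 <= out$start2[i] & out$end2 >= out$end2[i])
      if (length(cont)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    if (!is.null(exclude_ir) && !isTRUE(exclude_ir$no_structure)) {
      irb <- exclude_ir$irb; ira <- exclude_ir$ira
      is_ir_pair <- out$class == "palindromic" &
        out$length >= 0.5 * exclude_ir$ir_length &
        out$start1 < irb[2L] & out$end1 > irb[1L] &
        out$start2 < ira[2L] & out$end2 > ira[1L]
      out <- out[!is_ir_pair, , drop = FALSE]
    }
    out <- out[order(out$class, out$start1, out$start2), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("repeat_table", class(out))
  out
}
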