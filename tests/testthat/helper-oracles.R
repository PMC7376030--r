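# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition by exhaustive enumeration, sharing no
# code path with the package implementations they check.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# longest disjoint inverted-repeat pair by exhaustive enumeration of
# (first-copy start, second-copy end) anchor pairs
oracle_lir <- function(s, min_len) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  best <- NULL
  for (a in seq_len(n)) {
    for (e in seq.int(a, n)) {
      cap <- (e - a + 1L) %/% 2L
      if (cap < min_len) next
      L <- 0L
      while (L < cap && ch[a + L] == .COMP[[ch[e - L]]]) L <- L + 1L
      if (L < min_len) next
      b <- e - L + 1L
      if (is.null(best) || L > best[1L] ||
          (L == best[1L] && (a < best[2L] ||
                             (a == best[2L] && b < best[3L]))))
        best <- c(L, a, b)
    }
  }
  if (is.null(best)) return(NULL)
  list(first = c(best[2L] - 1L, best[2L] - 1L + best[1L]),
       second = c(best[3L] - 1L, best[3L] - 1L + best[1L]),
       length = best[1L])
}

oracle_is_primitive <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L))
    if (m %% d == 0L && strrep(substr(motif, 1L, d), m %/% d) == motif)
      return(FALSE)
  TRUE
}

# exhaustive SSR scan: every (start, motif length) pair is tested by
# direct chunk comparison, then the reporting rules (leftmost anchor,
# primitivity, N exclusion, containment suppression) are applied
oracle_ssrs <- function(s, thresholds = c(`1` = 12L, `2` = 6L, `3` = 5L,
                                          `4` = 5L, `5` = 4L, `6` = 4L)) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    if (n < m * thr) next
    for (i in seq_len(n - m * thr + 1L)) {
      if (i > 1L && ch[i - 1L] == ch[i - 1L + m]) next  # not leftmost
      motif_ch <- ch[i:(i + m - 1L)]
      copies <- 1L
      while (i + (copies + 1L) * m - 1L <= n &&
             all(ch[(i + copies * m):(i + (copies + 1L) * m - 1L)] ==
                 motif_ch))
        copies <- copies + 1L
      if (copies < thr) next
      if (any(motif_ch == "N")) next
      motif <- paste(motif_ch, collapse = "")
      if (!oracle_is_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, copies = copies, start = i - 1L,
        end = i - 1L + copies * m, length = copies * m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), copies = integer(),
                      start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  ml <- nchar(out$motif)
  keep <- vapply(seq_len(nrow(out)), function(i)
    !any(out$start <= out$start[i] & out$end >= out$end[i] & ml > ml[i]),
    logical(1L))
  out <- out[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("start", "end")]), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-diagonal dispersed-repeat enumeration (no seeding): chains of
# exact runs >= chain_min joined across single mismatches
oracle_dispersed <- function(s, min_size = 30L, max_mismatch = 3L,
                             chain_min = 10L,
                             classes = c("forward", "palindromic",
                                         "reverse", "complement")) {
  n <- nchar(s)
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  chain_min <- min(chain_min, min_size)
  rows <- list()
  for (cl in classes) {
    t <- switch(cl, forward = s, palindromic = revcomp(s),
                reverse = reverse_seq(s), complement = complement_seq(s))
    tc <- strsplit(t, "", fixed = TRUE)[[1]]
    for (d in seq.int(-(n - 1L), n - 1L)) {
      if (cl == "forward" && d == 0L) next
      i1 <- max(1L, 1L + d); i2 <- min(n, n + d)
      if (i2 - i1 + 1L < min_size) next
      mvec <- sc[i1:i2] == tc[(i1:i2) - d]
      # exact runs as (start, end) in diagonal coordinates
      runs <- NULL
      u <- 1L
      len <- length(mvec)
      while (u <= len) {
        if (mvec[u]) {
          v <- u
          while (v < len && mvec[v + 1L]) v <- v + 1L
          runs <- rbind(runs, c(u, v))
          u <- v + 1L
        } else u <- u + 1L
      }
      if (is.null(runs)) next
      solid <- runs[runs[, 2L] - runs[, 1L] + 1L >= chain_min, ,
                    drop = FALSE]
      if (!nrow(solid)) next
      # groups of solid runs joined by single-mismatch gaps
      grp <- list()
      cur <- list(solid[1L, ])
      if (nrow(solid) > 1L) {
        for (r in 2L:nrow(solid)) {
          prev <- cur[[length(cur)]]
          if (solid[r, 1L] - prev[2L] - 1L == 1L &&
              # the single gap position must be the only thing between
              # them (no short non-solid run in between)
              !any(runs[, 1L] > prev[2L] & runs[, 2L] < solid[r, 1L])) {
            cur[[length(cur) + 1L]] <- solid[r, ]
          } else {
            grp[[length(grp) + 1L]] <- cur
            cur <- list(solid[r, ])
          }
        }
      }
      grp[[length(grp) + 1L]] <- cur
      for (g in grp) {
        gg <- length(g)
        wins <- if (gg - 1L <= max_mismatch) list(seq_len(gg))
        else lapply(seq_len(gg - max_mismatch),
                    function(i) i:(i + max_mismatch))
        for (w in wins) {
          off <- g[[w[1L]]][1L]
          endo <- g[[w[length(w)]]][2L]
          L <- endo - off + 1L
          if (L < min_size) next
          a <- i1 + off - 1L
          p <- a - d
          b <- if (cl %in% c("palindromic", "reverse"))
            n - (p - 1L) - L + 1L else p
          if (a == b) next
          lo <- min(a, b); hi <- max(a, b)
          rows[[length(rows) + 1L]] <- data.frame(
            class = cl, start1 = lo - 1L, end1 = lo - 1L + L,
            start2 = hi - 1L, end2 = hi - 1L + L, length = L,
            mismatches = length(w) - 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(class = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(),
                      end2 = integer(), length = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  keep <- vapply(seq_len(nrow(out)), function(i)
    !any(out$class == out$class[i] & out$length > out$length[i] &
         out$start1 <= out$start1[i] & out$end1 >= out$end1[i] &
         out$start2 <= out$start2[i] & out$end2 >= out$end2[i]),
    logical(1L))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$class, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pair-counting discriminating power: explicit enumeration of
# unordered variety pairs
oracle_dj <- function(genotypes) {
  g <- genotypes[genotypes != "." & !is.na(genotypes)]
  N <- length(g)
  conc <- 0L
  for (i in seq_len(N - 1L))
    for (j in seq.int(i + 1L, N))
      if (g[i] == g[j]) conc <- conc + 1L
  1 - conc / choose(N, 2L)
}

# nucleotide diversity by explicit pair enumeration over complete
# (gap- and N-free) columns
oracle_pi <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- apply(m, 2L, function(col) !any(col %in% c("-", "N")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  tot <- 0L
  np <- 0L
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + sum(m[i, ] != m[j, ])
      np <- np + 1L
    }
  tot / np / ncol(m)
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# normalize detector/oracle tables for comparison
norm_table <- function(df) {
  df <- as.data.frame(df)
  rownames(df) <- NULL
  class(df) <- "data.frame"
  df
}
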