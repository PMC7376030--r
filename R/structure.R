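# Quadripartite structure detection: the plastome's LSC/IRb/SSC/IRa
# architecture is located by finding the maximal pair of disjoint exact
# inverted repeats, using k-mer anchors against the reverse complement
# chained along diagonals and extended to maximal length.

#' Longest disjoint inverted-repeat pair of a linear sequence
#'
#' Finds the maximal-length pair of disjoint intervals `(first, second)`
#' such that the sequence of `first` equals the reverse complement of the
#' sequence of `second`. Candidates are seeded by shared k-mers between
#' the sequence and its reverse complement, merged along diagonals, and
#' extended to maximal exact matches; extensions whose copies would
#' overlap are trimmed to the longest disjoint sub-pair. Ties are broken
#' by smaller first-copy start, then smaller second-copy start.
#'
#' @param s nucleotide string (uppercase).
#' @param min_len minimum repeat length to report (>= 4).
#' @param seed_k anchor k-mer size; capped at `min_len`.
#' @return `NULL` if no pair of length >= `min_len` exists, else a list
#'   with 0-based half-open `first`, `second` (integer `c(start, end)`)
#'   and `length`.
#' @export
longest_inverted_repeat <- function(s, min_len, seed_k = 15L) {
  n <- nchar(s)
  if (min_len < 4L) stop("min_len must be >= 4")
  if (n < 2L * min_len) return(NULL)
  k <- min(as.integer(seed_k), as.integer(min_len))
  cand <- .inverted_candidates(s, k)
  if (!nrow(cand)) return(NULL)
  best <- .best_disjoint_pair(cand, min_len)
  if (is.null(best)) return(NULL)
  list(first = c(best$a, best$a + best$L),
       second = c(best$b, best$b + best$L),
       length = best$L)
}

# all maximal exact inverted matches (possibly overlapping copies),
# 0-based: data.frame(a, b, L) with s[a, a+L) == revcomp(s[b, b+L))
.inverted_candidates <- function(s, k) {
  n <- nchar(s)
  none <- data.frame(a = integer(), b = integer(), L = integer())
  if (n < k) return(none)
  rc <- revcomp(s)
  ks <- substring(s, 1:(n - k + 1L), k:n)
  kr <- substring(rc, 1:(n - k + 1L), k:n)
  common <- intersect(ks, kr)
  if (!length(common)) return(none)
  pos_s <- split(seq_along(ks), ks)[common]
  pos_r <- split(seq_along(kr), kr)[common]
  pairs <- do.call(rbind, lapply(seq_along(common), function(j)
    expand.grid(i = pos_s[[j]], p = pos_r[[j]])))
  # merge anchors on the same diagonal; keep run starts only
  d <- pairs$i - pairs$p
  key <- order(d, pairs$i)
  pairs <- pairs[key, , drop = FALSE]
  d <- d[key]
  first_of_run <- c(TRUE, !(d[-1L] == d[-length(d)] &
                            pairs$i[-1L] == pairs$i[-nrow(pairs)] + 1L))
  pairs <- pairs[first_of_run, , drop = FALSE]
  sc <- .chars(s); rcc <- .chars(rc)
  seen <- new.env(hash = TRUE)
  out <- vector("list", nrow(pairs))
  m <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; p <- pairs$p[r]
    # extend left
    while (i > 1L && p > 1L && sc[i - 1L] == rcc[p - 1L]) {
      i <- i - 1L; p <- p - 1L
    }
    L <- k + (pairs$i[r] - i)
    # extend right
    while (i + L <= n && p + L <= n && sc[i + L] == rcc[p + L]) L <- L + 1L
    a <- i - 1L                    # 0-based first copy
    b <- n - (p - 1L) - L          # 0-based second copy
    if (b < a) { tmp <- a; a <- b; b <- tmp }
    id <- paste(a, b, L)
    if (is.null(seen[[id]])) {
      seen[[id]] <- TRUE
      m <- m + 1L
      out[[m]] <- c(a, b, L)
    }
  }
  mat <- do.call(rbind, out[seq_len(m)])
  data.frame(a = mat[, 1L], b = mat[, 2L], L = mat[, 3L])
}

# pick the longest pair after trimming overlapping copies to the longest
# disjoint sub-pair (keep the left part of the first copy, right part of
# the second); ties: smaller a, then smaller b
.best_disjoint_pair <- function(cand, min_len) {
  a <- cand$a; b <- cand$b; L <- cand$L
  over <- a + L > b
  Lt <- ifelse(over, (b - a + L) %/% 2L, L)
  bt <- ifelse(over, b + (L - Lt), b)
  keep <- Lt >= min_len
  if (!any(keep)) return(NULL)
  a <- a[keep]; bt <- bt[keep]; Lt <- Lt[keep]
  o <- order(-Lt, a, bt)
  list(a = a[o[1L]], b = bt[o[1L]], L = Lt[o[1L]])
}

#' Detect the quadripartite LSC/IRb/SSC/IRa architecture
#'
#' Locates the maximal pair of disjoint inverted repeats on the (by
#' default circular) genome and derives the canonical region partition:
#' the longer inter-IR arc is the LSC, the shorter the SSC, and the
#' result is re-rotated so the LSC starts at coordinate 0 with region
#' order LSC, IRb, SSC, IRa. On unannotated records the strand is chosen
#' so the LSC string is lexicographically smallest; annotated records
#' keep their deposited orientation. When no qualifying repeat pair
#' exists an explicit no-structure result is returned, not an error.
#'
#' @param record a [plastome_record()].
#' @param min_ir_length minimum IR length in bp (default 1000; must be
#'   >= 25).
#' @param max_mismatch_rate allowed mismatch fraction when extending
#'   (default 0 = exact; positive rates extend through isolated
#'   mismatches but never through runs of 10 or more).
#' @return an object of class `region_partition`: either
#'   `no_structure = TRUE`, or canonical 0-based half-open intervals
#'   `lsc`, `irb`, `ssc`, `ira` tiling `[0, genome_length)`, the
#'   canonicalized `record` (rotated/flipped sequence and features), and
#'   the `rotation` offset and `flipped` flag mapping input coordinates
#'   to canonical ones.
#' @export
detect_inverted_repeats <- function(record, min_ir_length = 1000L,
                                    max_mismatch_rate = 0) {
  s <- record$sequence
  n <- nchar(s)
  if (min_ir_length < 25L) stop("min_ir_length must be >= 25")
  if (n < 2L * min_ir_length + 2L)
    stop("sequence shorter than 2*min_ir_length + 2")
  if (!grepl("[ACGT]", s)) stop("sequence contains only N")

  scan_seq <- if (record$circular) paste0(s, s) else s
  cand <- .inverted_candidates(scan_seq, k = min(25L, min_ir_length))
  if (max_mismatch_rate > 0 && nrow(cand))
    cand <- .extend_through_mismatches(scan_seq, cand, max_mismatch_rate)
  best <- NULL
  if (nrow(cand)) {
    if (record$circular) {
      cand$L <- pmin(cand$L, n %/% 2L)
      cand$a2 <- cand$a %% n
      cand$b2 <- cand$b %% n
      cand <- cand[!duplicated(cand[c("a2", "b2", "L")]), , drop = FALSE]
      ok <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        a <- cand$a2[r]; b <- cand$b2[r]; L <- cand$L[r]
        # shrink from the right of the first copy / left of the second
        # until both circular gaps admit the pair
        while (L >= min_ir_length) {
          bb <- cand$b2[r] + (cand$L[r] - L)
          g1 <- (bb - a) %% n
          g2 <- (a - bb) %% n
          if ((g1 >= L && g2 >= L) || (a == bb %% n && L <= n %/% 2L &&
                                       g1 == 0L)) break
          L <- L - max(1L, L - min(g1, g2))
        }
        cand$L[r] <- L
        cand$b2[r] <- (cand$b2[r] + (cand$L[r] - L)) %% n
        ok[r] <- L >= min_ir_length
      }
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand)) {
        o <- order(-cand$L, cand$a2, cand$b2)
        best <- list(a = cand$a2[o[1L]], b = cand$b2[o[1L]],
                     L = cand$L[o[1L]])
      }
    } else {
      best <- .best_disjoint_pair(cand, min_ir_length)
    }
  }
  if (is.null(best) || best$L < min_ir_length) {
    return(structure(list(no_structure = TRUE, genome_length = n,
                          record = record),
                     class = "region_partition"))
  }
  .partition_from_pair(record, best$a, best$b, best$L)
}

# optional fuzzy extension: extend maximal exact matches through isolated
# mismatches while the overall mismatch rate stays within bound and no
# run of >= 10 consecutive mismatches is crossed
.extend_through_mismatches <- function(s, cand, rate) {
  sc <- .chars(s); rcc <- .chars(revcomp(s)); n <- nchar(s)
  for (r in seq_len(nrow(cand))) {
    a <- cand$a[r]; b <- cand$b[r]; L <- cand$L[r]
    i <- a + 1L
    p <- n - (b + L) + 1L
    mm <- 0L
    repeat {
      j <- i + L
      run <- 0L
      while (j + run <= n && p + L + run <= n &&
             sc[j + run] != rcc[p + L + run]) run <- run + 1L
      if (j + run > n || p + L + run > n || run >= 10L) break
      newL <- L + run + 1L
      if ((mm + run) / newL > rate) break
      mm <- mm + run
      L <- newL
    }
    cand$L[r] <- L
    cand$b[r] <- n - (p - 1L) - L
    cand$a[r] <- a
  }
  cand
}

# build the canonical partition from an IR copy pair on the circle
.partition_from_pair <- function(record, a, b, L) {
  n <- genome_length(record)
  arcA <- (b - (a + L)) %% n          # arc following copy 1
  arcB <- (a - (b + L)) %% n          # arc following copy 2
  if (arcA >= arcB) {
    lsc_len <- arcA; ssc_len <- arcB
    offset <- (a + L) %% n
  } else {
    lsc_len <- arcB; ssc_len <- arcA
    offset <- (b + L) %% n
  }
  canon <- .canonicalize_record(record, offset, flip = FALSE)
  if (!nrow(record$features)) {
    # unannotated: pick the strand with the lexicographically smaller LSC
    lsc_fwd <- substr(canon$sequence, 1L, lsc_len)
    if (revcomp(lsc_fwd) < lsc_fwd) {
      # flip, then re-rotate so the LSC again starts at 0
      flip_rec <- .canonicalize_record(record, 0L, flip = TRUE)
      offset2 <- (n - (offset + lsc_len)) %% n
      canon <- .canonicalize_record(flip_rec, offset2, flip = FALSE)
      canon_rotation <- offset2
      flipped <- TRUE
    } else {
      canon_rotation <- offset; flipped <- FALSE
    }
  } else {
    canon_rotation <- offset; flipped <- FALSE
  }
  p <- structure(list(
    no_structure = FALSE,
    genome_length = n,
    lsc = c(0L, lsc_len),
    irb = c(lsc_len, lsc_len + L),
    ssc = c(lsc_len + L, lsc_len + L + ssc_len),
    ira = c(lsc_len + L + ssc_len, n),
    ir_length = L,
    rotation = canon_rotation,
    flipped = flipped,
    record = canon), class = "region_partition")
  stopifnot((p$lsc[2] - p$lsc[1]) + (p$irb[2] - p$irb[1]) +
            (p$ssc[2] - p$ssc[1]) + (p$ira[2] - p$ira[1]) == n)
  p
}

# rotate (and optionally flip to the reverse complement) a record,
# transforming feature coordinates accordingly
.canonicalize_record <- function(record, offset, flip = FALSE) {
  n <- genome_length(record)
  s <- record$sequence
  f <- record$features
  if (flip) {
    s <- revcomp(s)
    if (nrow(f)) {
      len <- f$end - f$start
      f$start <- ((n - f$end) %% n + n) %% n
      f$end <- f$start + len
      f$strand <- ifelse(f$strand == "+", "-", "+")
    }
  }
  s <- .rotate0(s, offset)
  if (nrow(f)) {
    len <- f$end - f$start
    f$start <- ((f$start - offset) %% n + n) %% n
    f$end <- f$start + len
    f <- f[order(f$feature_id, f$start), , drop = FALSE]
    rownames(f) <- NULL
  }
  plastome_record(record$id, s, circular = record$circular, features = f)
}

#' @export
print.region_partition <- function(x, ...) {
  if (isTRUE(x$no_structure)) {
    cat("<region_partition> no quadripartite structure (",
        x$genome_length, " bp)\n", sep = "")
  } else {
    cat(sprintf(paste0("<region_partition> %s bp: LSC %s | IRb %s | ",
                       "SSC %s | IRa %s\n"),
                format(x$genome_length, big.mark = ","),
                x$lsc[2] - x$lsc[1], x$irb[2] - x$irb[1],
                x$ssc[2] - x$ssc[1], x$ira[2] - x$ira[1]))
  }
  invisible(x)
}

#' Region lengths of a partition
#' @param partition a `region_partition`.
#' @return named integer vector (lsc, irb, ssc, ira), or `NULL` for a
#'   no-structure result.
#' @export
region_lengths <- function(partition) {
  if (isTRUE(partition$no_structure)) return(NULL)
  c(lsc = partition$lsc[2] - partition$lsc[1],
    irb = partition$irb[2] - partition$irb[1],
    ssc = partition$ssc[2] - partition$ssc[1],
    ira = partition$ira[2] - partition$ira[1])
}

#' Which region contains a canonical coordinate
#' @param partition a `region_partition`.
#' @param pos 0-based positions in canonical coordinates.
#' @return character vector over {LSC, IRb, SSC, IRa}.
#' @export
region_of <- function(partition, pos) {
  stopifnot(!isTRUE(partition$no_structure))
  pos <- pos %% partition$genome_length
  out <- character(length(pos))
  out[pos >= partition$lsc[1] & pos < partition$lsc[2]] <- "LSC"
  out[pos >= partition$irb[1] & pos < partition$irb[2]] <- "IRb"
  out[pos >= partition$ssc[1] & pos < partition$ssc[2]] <- "SSC"
  out[pos >= partition$ira[1] & pos < partition$ira[2]] <- "IRa"
  out
}

.junction_positions <- function(partition) {
  c(JLB = partition$irb[1L], JSB = partition$irb[2L],
    JSA = partition$ssc[2L], JLA = partition$genome_length)
}

#' Junction gene-distance report
#'
#' For each of the four single-copy/IR junctions (JLB: LSC/IRb, JSB:
#' IRb/SSC, JSA: SSC/IRa, JLA: IRa/LSC) reports the gene overlapping the
#' junction, if any, with the bp split on each side; otherwise the
#' nearest gene on each side with its distance to the junction (0 means
#' the gene ends exactly at the junction).
#'
#' @param partition a `region_partition` (with its canonicalized record).
#' @param features optional feature table in canonical coordinates;
#'   defaults to the partition record's features. Gene-level rows
#'   (kind gene/tRNA/rRNA) are used.
#' @return data frame with columns `junction`, `position`, `gene`,
#'   `relation` (spans/upstream/downstream), `distance`, `split_left`,
#'   `split_right`, `spans_boundary`.
#' @export
junction_report <- function(partition, features = NULL) {
  stopifnot(!isTRUE(partition$no_structure))
  if (is.null(features)) features <- partition$record$features
  n <- partition$genome_length
  jp <- .junction_positions(partition)
  if (!nrow(features)) {
    return(data.frame(junction = names(jp), position = unname(jp) %% n,
                      gene = NA_character_, relation = NA_character_,
                      distance = NA_integer_, split_left = NA_integer_,
                      split_right = NA_integer_, spans_boundary = FALSE,
                      stringsAsFactors = FALSE))
  }
  g <- features[features$kind %in% c("gene", "tRNA", "rRNA"), , drop = FALSE]
  if (!nrow(g)) g <- features
  # collapse multi-part features to their genomic footprint span
  span <- do.call(rbind, lapply(split(g, g$feature_id), function(p) {
    data.frame(name = p$name[1L], start = min(p$start),
               end = max(p$end), stringsAsFactors = FALSE)
  }))
  out <- list()
  for (jn in names(jp)) {
    j <- jp[[jn]]
    len <- span$end - span$start
    t_off <- (j - span$start) %% n
    spans <- t_off > 0L & t_off < len
    if (any(spans)) {
      idx <- which(spans)
      for (i in idx)
        out[[length(out) + 1L]] <- data.frame(
          junction = jn, position = j %% n, gene = span$name[i],
          relation = "spans", distance = NA_integer_,
          split_left = t_off[i], split_right = len[i] - t_off[i],
          spans_boundary = TRUE, stringsAsFactors = FALSE)
    } else {
      dl <- (j - span$end) %% n       # gene entirely left of junction
      dr <- (span$start - j) %% n     # gene entirely right of junction
      il <- which.min(dl); ir <- which.min(dr)
      out[[length(out) + 1L]] <- data.frame(
        junction = jn, position = j %% n, gene = span$name[il],
        relation = "upstream", distance = dl[il],
        split_left = NA_integer_, split_right = NA_integer_,
        spans_boundary = FALSE, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        junction = jn, position = j %% n, gene = span$name[ir],
        relation = "downstream", distance = dr[ir],
        split_left = NA_integer_, split_right = NA_integer_,
        spans_boundary = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call boundary pseudogenes created by IR duplication
#'
#' A gene spanning a single-copy/IR junction leaves its IR-internal
#' fragment duplicated at the mirrored position of the opposite IR; that
#' truncated duplicate is the boundary pseudogene (the rps19/ycf1
#' pattern of rosaceous plastomes). One call is emitted per spanning
#' gene, with the fragment interval in the opposite IR and its length
#' (equal to the in-IR overlap of the source gene).
#'
#' @param partition a `region_partition`.
#' @param features optional feature table in canonical coordinates.
#' @return data frame with columns `gene`, `source_junction`,
#'   `fragment_start`, `fragment_end`, `fragment_length`; zero rows when
#'   no gene spans a boundary.
#' @export
call_boundary_pseudogenes <- function(partition, features = NULL) {
  stopifnot(!isTRUE(partition$no_structure))
  jr <- junction_report(partition, features)
  jr <- jr[jr$spans_boundary, , drop = FALSE]
  out <- data.frame(gene = character(), source_junction = character(),
                    fragment_start = integer(), fragment_end = integer(),
                    fragment_length = integer(), stringsAsFactors = FALSE)
  if (!nrow(jr)) return(out)
  ib <- partition$irb; ia <- partition$ira
  n <- partition$genome_length
  rows <- list()
  for (i in seq_len(nrow(jr))) {
    jn <- jr$junction[i]
    # in-IR overlap length of the spanning gene at this junction
    if (jn %in% c("JLB", "JSB")) {
      src <- ib; dst <- ia
      frag_len <- if (jn == "JLB") jr$split_right[i] else jr$split_left[i]
      # fragment interval inside IRb
      f <- if (jn == "JLB") c(ib[1L], ib[1L] + frag_len)
           else c(ib[2L] - frag_len, ib[2L])
    } else {
      src <- ia; dst <- ib
      frag_len <- if (jn == "JSA") jr$split_right[i] else jr$split_left[i]
      f <- if (jn == "JSA") c(ia[1L], ia[1L] + frag_len)
           else c(ia[2L] - frag_len, ia[2L])
    }
    frag_len <- min(frag_len, src[2L] - src[1L])
    # mirror [f1, f2) of the source IR into the opposite IR
    m1 <- dst[1L] + (src[2L] - f[2L])
    m2 <- dst[1L] + (src[2L] - f[1L])
    rows[[i]] <- data.frame(gene = jr$gene[i], source_junction = jn,
                            fragment_start = as.integer(m1 %% n),
                            fragment_end = as.integer(m2),
                            fragment_length = as.integer(frag_len),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
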