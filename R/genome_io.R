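#' Plastome record constructor
#'
#' A `plastome_record` holds one (possibly annotated) plastid genome
#' sequence. All coordinates in this package are 0-based half-open
#' `[start, end)`; GenBank input is converted at the boundary. On circular
#' records a feature part may wrap the origin, encoded as `end > length`
#' (interpreted modulo the genome length).
#'
#' @param id text identifier.
#' @param sequence nucleotide string over {A,C,G,T,N}, uppercase.
#' @param circular logical topology flag.
#' @param features data frame of feature parts (see [empty_features()]):
#'   one row per part, columns `feature_id`, `name`, `kind`
#'   (gene/CDS/tRNA/rRNA/intron/IGS), `strand` ("+"/"-"), `part`
#'   (1-based part index in genomic order), `start`, `end`.
#' @return an object of class `plastome_record`.
#' @export
plastome_record <- function(id, sequence, circular = TRUE,
                            features = empty_features()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) > 0L)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 0L | features$end <= features$start |
      features$start >= n | (features$end - features$start) > n
    if (any(bad))
      stop("feature coordinates out of range for '",
           features$name[bad][1L], "'")
    if (!circular && any(features$end > n))
      stop("wrap-around feature part on a linear record")
    if (any(!nzchar(features$name))) stop("feature names must be non-empty")
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features),
            class = "plastome_record")
}

#' Empty feature table with the canonical columns
#' @return zero-row feature data frame.
#' @export
empty_features <- function() {
  data.frame(feature_id = integer(), name = character(), kind = character(),
             strand = character(), part = integer(), start = integer(),
             end = integer(), stringsAsFactors = FALSE)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d feature parts\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

#' Genome length of a plastome record
#' @param record a [plastome_record()].
#' @return integer length in bp.
#' @export
genome_length <- function(record) nchar(record$sequence)

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# normalize a raw sequence string per the input contract: uppercase,
# U -> T, IUPAC ambiguity codes (other than N) -> N with a warning,
# anything else is a parse error naming the record
.normalize_sequence <- function(s, id) {
  s <- toupper(s)
  s <- chartr("U", "T", s)
  bad <- setdiff(unique(.chars(s)), c("A", "C", "G", "T", "N"))
  ambig <- intersect(bad, .IUPAC_AMBIG)
  if (length(ambig)) {
    warning("record '", id, "': IUPAC ambiguity codes (",
            paste(ambig, collapse = ","), ") mapped to N", call. = FALSE)
    s <- chartr(paste(ambig, collapse = ""),
                strrep("N", length(ambig)), s)
    bad <- setdiff(bad, ambig)
  }
  if (length(bad))
    stop("record '", id, "': non-nucleotide characters: ",
         paste(bad, collapse = ","), call. = FALSE)
  s
}

#' Read plastome sequences from a FASTA file
#'
#' Sequences are read with Biostrings and normalized: lowercase to
#' uppercase, U to T, IUPAC ambiguity codes other than N to N (with a
#' warning). Characters outside the IUPAC nucleotide alphabet are a parse
#' error.
#'
#' @param path FASTA file (one or more entries).
#' @param circular topology flag applied to all records (FASTA carries no
#'   topology information).
#' @return list of [plastome_record()] objects, in file order.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    s <- .normalize_sequence(as.character(set[[i]]), ids[i])
    if (!nchar(s)) stop("record '", ids[i], "' has an empty sequence")
    plastome_record(ids[i], s, circular = circular)
  })
}

#' Write plastome records to a FASTA file
#'
#' @param records a [plastome_record()] or list of them.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "plastome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- GenBank flat file ------------------------------------------------
# No installed package parses local GenBank flat files with feature
# tables, so a minimal parser is provided: LOCUS topology, the feature
# keys gene/CDS/tRNA/rRNA with join()/complement() locations, and the
# ORIGIN sequence block.

.parse_location <- function(loc, feat_label) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("^order\\(", loc)) loc <- sub("^order\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^(\\d+)(\\.\\.(\\d+))?$", parts))
  if (any(vapply(m, length, 0L) == 0L))
    stop("unparseable location for feature '", feat_label, "': ", loc,
         call. = FALSE)
  starts <- as.integer(vapply(m, `[[`, "", 2L))
  ends <- vapply(m, function(g) if (nzchar(g[4L])) g[4L] else g[2L], "")
  # GenBank 1-based inclusive -> 0-based half-open
  data.frame(start = starts - 1L, end = as.integer(ends), strand = strand,
             stringsAsFactors = FALSE)
}

#' Read an annotated plastome from a GenBank flat file
#'
#' Populates features from gene, CDS, tRNA and rRNA entries; `join()`
#' locations become multi-part features, `complement()` sets the minus
#' strand, and the 1-based inclusive GenBank coordinates are converted to
#' the package's 0-based half-open convention. Circular topology is read
#' from the LOCUS line.
#'
#' @param path GenBank flat file with an ORIGIN sequence block.
#' @return a [plastome_record()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0L && grepl("circular", locus[1L],
                                          ignore.case = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1L])),
                                    "\\s+")[[1L]][1L] else "genbank_record"
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1L])), "\\s+")[[1L]][1L]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN block: ", path)
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- .normalize_sequence(
    gsub("[0-9[:space:]]", "", paste(seq_lines, collapse = "")), id)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    # feature lines start at column 6; qualifiers at column 22 with "/"
    is_key <- grepl("^ {5}\\S", block)
    key_idx <- which(is_key)
    rows <- list()
    fid <- 0L
    for (k in seq_along(key_idx)) {
      i <- key_idx[k]
      end_i <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
      toks <- strsplit(trimws(block[i]), "\\s+")[[1L]]
      kind <- toks[1L]
      if (!kind %in% c("gene", "CDS", "tRNA", "rRNA")) next
      loc <- paste(toks[-1L], collapse = "")
      # location may continue on following lines until a qualifier
      j <- i + 1L
      while (j <= end_i && !grepl("^ {21}/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      quals <- block[seq.int(i + 1L, length.out = max(0L, end_i - i))]
      gm <- regmatches(quals, regexec('/(gene|product|locus_tag)="?([^"]+)"?',
                                      quals))
      gm <- Filter(function(g) length(g) == 3L, gm)
      name <- if (length(gm)) gm[[1L]][3L] else kind
      parts <- .parse_location(loc, name)
      fid <- fid + 1L
      rows[[fid]] <- data.frame(feature_id = fid, name = name, kind = kind,
                                strand = parts$strand[1L],
                                part = seq_len(nrow(parts)),
                                start = parts$start, end = parts$end,
                                stringsAsFactors = FALSE)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  plastome_record(id, sequence, circular = circular, features = feats)
}

#' Extract intron features from multi-part genes
#'
#' For every multi-part gene/CDS/tRNA/rRNA feature, the gaps between
#' consecutive parts (in transcription order) are returned as intron
#' features named `"<gene>_intron<k>"`. Single-part features yield no
#' introns.
#'
#' @param record an annotated [plastome_record()].
#' @return feature data frame of introns (kind `"intron"`).
#' @export
extract_introns <- function(record) {
  f <- record$features
  out <- empty_features()
  if (!nrow(f)) return(out)
  rows <- list()
  nid <- 0L
  for (fid in unique(f$feature_id)) {
    p <- f[f$feature_id == fid, , drop = FALSE]
    if (nrow(p) < 2L) next
    p <- p[order(p$start), , drop = FALSE]
    gaps_start <- p$end[-nrow(p)]
    gaps_end <- p$start[-1L]
    keep <- gaps_end > gaps_start
    if (!any(keep)) next
    ord <- seq_len(sum(keep))
    if (p$strand[1L] == "-") ord <- rev(ord)   # transcription order
    nid <- nid + 1L
    rows[[nid]] <- data.frame(
      feature_id = -nid,
      name = paste0(p$name[1L], "_intron", ord),
      kind = "intron", strand = p$strand[1L], part = 1L,
      start = gaps_start[keep], end = gaps_end[keep],
      stringsAsFactors = FALSE)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the genome into coding, intron and intergenic-spacer regions
#'
#' Tiles the genome into coding parts (CDS), tRNA and rRNA parts, introns
#' of multi-part genes, and intergenic spacers (IGS) between consecutive
#' gene footprints. IGS labels concatenate the flanking gene names with
#' "-" in genome order; zero-length IGS between abutting or overlapping
#' genes are omitted. Where interval classes overlap (e.g. a CDS inside
#' its gene), per-base priority is coding > tRNA > rRNA > intron > IGS.
#'
#' @param record an annotated [plastome_record()].
#' @return data frame with columns `label`, `class`
#'   (coding/tRNA/rRNA/intron/IGS), `start`, `end`, `length`; class
#'   `region_class_partition`.
#' @export
classify_regions <- function(record) {
  f <- record$features
  if (!nrow(f))
    stop("record '", record$id, "' has no annotation; supply GenBank input")
  n <- genome_length(record)
  # per-base class bitmap: 0 none, 5 coding, 4 tRNA, 3 rRNA, 2 intron
  cls <- integer(n)
  lab <- integer(n)   # index into `labels`
  labels <- character(0)
  paint <- function(cls, lab, start, end, code, label, labels) {
    idx <- (seq.int(start, end - 1L) %% n) + 1L
    sel <- cls[idx] < code
    labels <- c(labels, label)
    cls[idx[sel]] <- code
    lab[idx[sel]] <- length(labels)
    list(cls = cls, lab = lab, labels = labels)
  }
  prio <- c(CDS = 5L, tRNA = 4L, rRNA = 3L)
  for (kind in c("intron", "rRNA", "tRNA", "CDS")) {  # ascending priority
    if (kind == "intron") {
      ff <- extract_introns(record)
      code <- 2L
    } else {
      ff <- f[f$kind == kind, , drop = FALSE]
      code <- prio[[kind]]
    }
    if (!nrow(ff)) next
    for (r in seq_len(nrow(ff))) {
      st <- paint(cls, lab, ff$start[r], ff$end[r], code, ff$name[r], labels)
      cls <- st$cls; lab <- st$lab; labels <- st$labels
    }
  }
  # gene footprints for IGS: union of parts of 'gene' features if present,
  # else of all annotated features
  gk <- if (any(f$kind == "gene")) f[f$kind == "gene", , drop = FALSE] else f
  foot <- logical(n)
  for (r in seq_len(nrow(gk)))
    foot[(seq.int(gk$start[r], gk$end[r] - 1L) %% n) + 1L] <- TRUE
  # also count any painted base as covered (CDS without a gene wrapper)
  foot <- foot | cls > 0L

  # name lookup for IGS flanks: the gene (or any feature) whose footprint
  # ends just before / starts just after a gap
  gene_at <- character(n)
  for (r in rev(seq_len(nrow(gk))))   # earlier features win on overlap
    gene_at[(seq.int(gk$start[r], gk$end[r] - 1L) %% n) + 1L] <- gk$name[r]

  out <- list()
  runs <- rle(cls)
  pos <- cumsum(c(0L, runs$lengths))
  for (i in seq_along(runs$values)) {
    v <- runs$values[i]
    s <- pos[i]; e <- pos[i + 1L]
    if (v == 0L) next
    cl <- c("intron", "rRNA", "tRNA", "coding")[match(v, c(2L, 3L, 4L, 5L))]
    # split the run by label so adjacent distinct genes stay distinct
    lr <- rle(lab[(s + 1L):e])
    lp <- cumsum(c(0L, lr$lengths))
    for (j in seq_along(lr$values))
      out[[length(out) + 1L]] <- data.frame(
        label = labels[lr$values[j]], class = cl,
        start = s + lp[j], end = s + lp[j + 1L], stringsAsFactors = FALSE)
  }
  # IGS runs over uncovered bases
  gaps <- rle(foot)
  gpos <- cumsum(c(0L, gaps$lengths))
  gap_iv <- NULL
  for (i in seq_along(gaps$values))
    if (!gaps$values[i])
      gap_iv <- rbind(gap_iv, c(gpos[i], gpos[i + 1L]))
  if (!is.null(gap_iv)) {
    # on circular records merge a terminal gap wrapping the origin
    if (record$circular && nrow(gap_iv) > 1L &&
        gap_iv[1L, 1L] == 0L && gap_iv[nrow(gap_iv), 2L] == n) {
      gap_iv[nrow(gap_iv), 2L] <- n + gap_iv[1L, 2L]
      gap_iv <- gap_iv[-1L, , drop = FALSE]
    }
    for (i in seq_len(nrow(gap_iv))) {
      s <- gap_iv[i, 1L]; e <- gap_iv[i, 2L]
      left <- gene_at[((s - 1L) %% n) + 1L]
      right <- gene_at[(e %% n) + 1L]
      label <- if (record$circular || (s > 0L && e < n)) {
        paste0(left, "-", right)
      } else if (s == 0L) paste0("5end-", right) else paste0(left, "-3end")
      out[[length(out) + 1L]] <- data.frame(
        label = label, class = "IGS", start = s, end = e,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  res$length <- res$end - res$start
  rownames(res) <- NULL
  class(res) <- c("region_class_partition", class(res))
  res
}

#' Extract the sequence of a feature (joining parts, minus-strand aware)
#'
#' @param record a [plastome_record()].
#' @param feature_rows rows of the feature table for one feature.
#' @return the feature sequence on its coding strand.
#' @export
feature_sequence <- function(record, feature_rows) {
  p <- feature_rows[order(feature_rows$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(p)), function(i)
    .subseq0(record$sequence, p$start[i], p$end[i]), ""), collapse = "")
  if (p$strand[1L] == "-") revcomp(s) else s
}
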