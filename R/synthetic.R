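# Synthetic plastome generator with full ground truth. Backgrounds are
# repeat-free by construction (periodic tracts broken, duplicate 15-mers
# removed against both strands), so that every planted SSR, dispersed
# repeat and tandem repeat is recovered at exactly its planted
# coordinates and nothing else is found. Genomes follow the canonical
# quadripartite layout LSC + IRb + SSC + revcomp(IRb).

#' Specification for a synthetic plastome study
#'
#' Default region sizes are a ~1:10 scale model of a rosaceous plastome
#' (LSC > IR > SSC in realistic proportion); default per-class mutation
#' probabilities are set so expected pairwise divergence matches the
#' order observed among congeneric plastomes (IGS a few-fold above
#' coding, rRNA invariant).
#'
#' @param seed integer random seed governing every draw.
#' @param lsc_len,ir_len,ssc_len region lengths in bp.
#' @param planted_ssrs data frame `motif`, `copies`, `region`
#'   (LSC/SSC/IRb/IRa) of perfect SSR tracts to plant.
#' @param planted_repeats data frame `class` (forward/palindromic/
#'   reverse/complement), `length`, `mismatches` of dispersed repeat
#'   pairs to plant (both copies in the LSC).
#' @param planted_tandems data frame `period`, `copies`, `mutations` of
#'   tandem repeats to plant (in the LSC; `copies` >= 3 when mutated).
#' @param junction_genes `NULL`, or list with bp overhangs `jlb` (gene
#'   reaching from LSC into IRb) and `jsb` (gene reaching from IRb into
#'   SSC) to exercise junction and pseudogene logic.
#' @param n_genes named integer vector: gene-like features to annotate
#'   per region (LSC/SSC/IR).
#' @param codon_bias_at3 probability mass shifted to A/T at codon third
#'   positions when writing CDS content (0 = uniform).
#' @param n_taxa clade size for [make_clade()].
#' @param mu_by_class per-class per-site substitution probability
#'   (coding, intron, IGS, rRNA, tRNA), each in [0, 0.2].
#' @param panel list for [make_panel()]: `n_varieties`, `loci` (list of
#'   genotype-class frequency vectors, each summing to 1; `"distinct"`
#'   for the all-distinct locus), `missing_rate`, `refine` (make SNV
#'   haplotypes a refinement of SSR classes).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       lsc_len = 9000L, ir_len = 2600L, ssc_len = 1900L,
                       planted_ssrs = NULL,
                       planted_repeats = NULL,
                       planted_tandems = NULL,
                       junction_genes = list(jlb = 120L, jsb = 150L),
                       n_genes = c(LSC = 6L, SSC = 3L, IR = 2L),
                       codon_bias_at3 = 0.5,
                       n_taxa = 5L,
                       mu_by_class = c(coding = 0.0027, intron = 0.004,
                                       IGS = 0.0055, rRNA = 0,
                                       tRNA = 0.001),
                       panel = list(n_varieties = 93L,
                                    loci = NULL,
                                    missing_rate = 0,
                                    refine = TRUE)) {
  stopifnot(lsc_len > 0L, ir_len > 0L, ssc_len > 0L, lsc_len >= ssc_len)
  stopifnot(all(mu_by_class >= 0), all(mu_by_class <= 0.2))
  spec <- list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
               ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
               planted_ssrs = planted_ssrs,
               planted_repeats = planted_repeats,
               planted_tandems = planted_tandems,
               junction_genes = junction_genes, n_genes = n_genes,
               codon_bias_at3 = codon_bias_at3, n_taxa = as.integer(n_taxa),
               mu_by_class = mu_by_class, panel = panel)
  class(spec) <- "synth_spec"
  spec
}

# ---- background hygiene ----------------------------------------------

# positions (1-based starts) of periodic tracts reaching the SSR
# thresholds, as (start, len) pairs; a plain re-use of the scan logic
# would do, but keep this private so generation does not depend on the
# reporting layer's filtering rules
.offending_tracts <- function(s, thresholds = .default_ssr_thresholds) {
  hits <- find_ssrs(s, thresholds)
  if (!nrow(hits)) return(NULL)
  cbind(hits$start + 1L, hits$length)
}

# starts (1-based) of k-mers occurring more than once within s or
# shared between s and its reverse complement (positions reported in s)
.duplicate_kmer_starts <- function(s, k = 15L, allow = NULL) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  km <- substring(s, 1:(n - k + 1L), k:n)
  dup_self <- km %in% km[duplicated(km)]
  rc <- revcomp(s)
  kr <- substring(rc, 1:(n - k + 1L), k:n)
  dup_rc <- km %in% kr
  which(dup_self | dup_rc)
}

# does [a, b] (1-based inclusive) intersect any protected window?
.in_protected <- function(a, b, protected) {
  if (is.null(protected) || !nrow(protected)) return(FALSE)
  any(a <= protected[, 2L] & b >= protected[, 1L])
}

# break repeats in s by point substitutions, never touching protected
# windows (1-based inclusive matrix cols start, end)
.clean_sequence <- function(s, protected = NULL, max_iter = 60L) {
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    tr <- .offending_tracts(s)
    if (!is.null(tr)) {
      for (i in seq_len(nrow(tr))) {
        a <- tr[i, 1L]; b <- a + tr[i, 2L] - 1L
        if (.in_protected(a, b, protected)) next
        mid <- a + (b - a) %/% 2L
        old <- substr(s, mid, mid)
        substr(s, mid, mid) <- sample(setdiff(bases, old), 1L)
        dirty <- TRUE
      }
    }
    dup <- .duplicate_kmer_starts(s)
    if (length(dup)) {
      for (a in dup) {
        b <- a + 14L
        if (.in_protected(a, b, protected)) next
        mid <- a + 7L
        old <- substr(s, mid, mid)
        substr(s, mid, mid) <- sample(setdiff(bases, old), 1L)
        dirty <- TRUE
        break   # k-mer sets are stale after one edit; rescan
      }
    }
    if (!dirty) return(s)
  }
  stop("background cleaning did not converge; try another seed")
}

# ---- planting ---------------------------------------------------------

# pick a placement window of `len` inside region [lo, hi] (1-based
# inclusive bounds), margin away from region ends, not colliding with
# occupied windows (matrix cols start, end; includes padding)
.place_window <- function(len, lo, hi, occupied, margin = 60L, pad = 12L) {
  lo2 <- lo + margin; hi2 <- hi - margin - len + 1L
  if (hi2 < lo2) stop("region too small to plant an element of ", len, " bp")
  for (try in 1:400) {
    a <- sample(lo2:hi2, 1L)
    b <- a + len - 1L
    if (!.in_protected(a - pad, b + pad, occupied)) return(c(a, b))
  }
  stop("could not place a planted element without overlap")
}

# overwrite s[a..b] (1-based inclusive) with tract
.overwrite <- function(s, a, tract) {
  substr(s, a, a + nchar(tract) - 1L) <- tract
  s
}

# force the base at 1-based position i to differ from every base in
# `forbid` (used to break periodic/diagonal extension at plant flanks)
.force_flank <- function(s, i, forbid) {
  if (i < 1L || i > nchar(s)) return(s)
  choices <- setdiff(c("A", "C", "G", "T"), forbid)
  if (!substr(s, i, i) %in% choices)
    substr(s, i, i) <- sample(choices, 1L)
  s
}

# evenly spaced interior substitution offsets (1-based, within len),
# keeping `gap` clear of both ends and of each other
.spaced_positions <- function(len, m, gap) {
  if (m == 0L) return(integer(0))
  pos <- round(len * seq_len(m) / (m + 1L))
  if (any(pos <= gap) || any(pos > len - gap) ||
      (m > 1L && any(diff(pos) <= gap)))
    stop("element too short for ", m, " well-separated mutations")
  as.integer(pos)
}

.mutate_at <- function(tract, pos) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    old <- substr(tract, p, p)
    substr(tract, p, p) <- sample(setdiff(bases, old), 1L)
  }
  tract
}

# ---- gene-like annotation --------------------------------------------

# lay out non-overlapping gene features inside [lo, hi) (0-based),
# avoiding 1-based protected windows; returns a feature data frame
.layout_genes <- function(lo, hi, n, prefix, strand_pool = c("+", "-"),
                          with_intron = FALSE) {
  rows <- list()
  fid <- 0L
  span <- hi - lo
  if (n == 0L || span < 400L) return(empty_features())
  slot <- span %/% n
  for (g in seq_len(n)) {
    s0 <- lo + (g - 1L) * slot + min(120L, slot %/% 6L)
    glen <- min(slot - 2L * min(120L, slot %/% 6L), 900L)
    glen <- glen - (glen %% 3L)   # CDS-friendly length
    if (glen < 150L) next
    strand <- sample(strand_pool, 1L)
    name <- paste0(prefix, g)
    fid <- fid + 1L
    if (with_intron && g == 1L && glen >= 450L) {
      ex1 <- 150L; intr <- 120L
      ex2 <- glen - ex1 - intr
      ex2 <- ex2 - (ex2 %% 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, name = name, kind = "gene", strand = strand,
        part = 1:2, start = c(s0, s0 + ex1 + intr),
        end = c(s0 + ex1, s0 + ex1 + intr + ex2), stringsAsFactors = FALSE)
      fid <- fid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, name = name, kind = "CDS", strand = strand,
        part = 1:2, start = c(s0, s0 + ex1 + intr),
        end = c(s0 + ex1, s0 + ex1 + intr + ex2), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, name = name, kind = "gene", strand = strand,
        part = 1L, start = s0, end = s0 + glen, stringsAsFactors = FALSE)
      fid <- fid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, name = name, kind = "CDS", strand = strand,
        part = 1L, start = s0, end = s0 + glen, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic plastome with ground truth
#'
#' Builds `LSC + IRb + SSC + revcomp(IRb)` over a repeat-free random
#' background, writes codon-structured CDS content, plants the requested
#' SSRs, dispersed repeats and tandem repeats with broken flanks (so
#' every planted element is maximal at exactly its planted coordinates),
#' annotates gene-like features including optional junction-spanning
#' genes, and re-validates the ground truth by re-scanning the final
#' sequence. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return list with `record` (annotated [plastome_record()]) and
#'   `truth` (boundaries, planted element tables including IR-mirrored
#'   copies, features, junction-gene arithmetic).
#' @export
make_plastome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  lsc <- spec$lsc_len; ir <- spec$ir_len; ssc <- spec$ssc_len
  core_len <- lsc + ir + ssc
  core <- .random_dna(core_len)

  # region bounds in core, 1-based inclusive
  bounds <- list(LSC = c(1L, lsc), IRb = c(lsc + 1L, lsc + ir),
                 SSC = c(lsc + ir + 1L, core_len))

  # gene-like features (0-based); junction-spanning genes first
  feats <- empty_features()
  truth_jg <- NULL
  if (!is.null(spec$junction_genes)) {
    jg <- spec$junction_genes
    fid0 <- 0L
    add <- function(name, start, end, feats) {
      fid <- max(0L, feats$feature_id, na.rm = TRUE) + 1L
      glen <- end - start
      glen3 <- glen - (glen %% 3L)
      rbind(feats,
            data.frame(feature_id = fid, name = name, kind = "gene",
                       strand = "+", part = 1L, start = start, end = end,
                       stringsAsFactors = FALSE),
            data.frame(feature_id = fid + 1L, name = name, kind = "CDS",
                       strand = "+", part = 1L, start = start,
                       end = start + glen3, stringsAsFactors = FALSE))
    }
    if (!is.null(jg$jlb)) {
      feats <- add("jgA", lsc - 400L, lsc + jg$jlb, feats)
      truth_jg <- rbind(truth_jg, data.frame(
        gene = "jgA", junction = "JLB", overhang = jg$jlb,
        split_left = 400L, split_right = jg$jlb, stringsAsFactors = FALSE))
    }
    if (!is.null(jg$jsb)) {
      feats <- add("jgB", lsc + ir - jg$jsb, lsc + ir + 350L, feats)
      truth_jg <- rbind(truth_jg, data.frame(
        gene = "jgB", junction = "JSB", overhang = jg$jsb,
        split_left = jg$jsb, split_right = 350L, stringsAsFactors = FALSE))
    }
  }
  jz_pad <- 500L   # keep ordinary genes away from junction zones
  lay <- rbind(
    .layout_genes(600L, lsc - 600L - jz_pad, spec$n_genes[["LSC"]], "gL",
                  with_intron = TRUE),
    .layout_genes(lsc + jz_pad, lsc + ir - jz_pad, spec$n_genes[["IR"]],
                  "gI"),
    .layout_genes(lsc + ir + jz_pad, core_len - 300L,
                  spec$n_genes[["SSC"]], "gS"))
  if (nrow(lay)) {
    # renumber: the three per-region layouts each start at id 1
    key <- paste(lay$name, lay$kind)
    lay$feature_id <- match(key, unique(key)) + max(0L, feats$feature_id)
    feats <- rbind(feats, lay)
  }

  # write codon-structured CDS content (third-position A/T excess)
  cds <- feats[feats$kind == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    len <- cds$end[i] - cds$start[i]
    ncod <- len %/% 3L
    if (ncod < 1L) next
    p3 <- spec$codon_bias_at3
    pos3 <- sample(c("A", "T", "C", "G"), ncod, replace = TRUE,
                   prob = c((1 + p3) / 4, (1 + p3) / 4,
                            (1 - p3) / 4, (1 - p3) / 4))
    cod <- paste(paste0(sample(c("A", "C", "G", "T"), ncod, TRUE),
                        sample(c("A", "C", "G", "T"), ncod, TRUE), pos3),
                 collapse = "")
    if (cds$strand[i] == "-") cod <- revcomp(cod)  # coding-strand bias
    core <- .overwrite(core, cds$start[i] + 1L, cod)
  }

  core <- .clean_sequence(core)

  occupied <- NULL
  truth_ssrs <- NULL
  ps <- spec$planted_ssrs
  if (!is.null(ps)) {
    for (i in seq_len(nrow(ps))) {
      motif <- toupper(ps$motif[i]); copies <- as.integer(ps$copies[i])
      region <- ps$region[i]
      m <- nchar(motif); len <- m * copies
      mirror <- FALSE
      if (region == "IRa") { region <- "IRb"; mirror <- TRUE }
      b <- bounds[[region]]
      w <- .place_window(len, b[1L], b[2L], occupied)
      tract <- if (mirror) revcomp(strrep(motif, copies))
               else strrep(motif, copies)
      core <- .overwrite(core, w[1L], tract)
      # break periodic extension at both flanks
      core <- .force_flank(core, w[1L] - 1L, substr(tract, m, m))
      core <- .force_flank(core, w[2L] + 1L, substr(tract, 1L, 1L))
      occupied <- rbind(occupied, c(w[1L] - 1L, w[2L] + 1L))
      truth_ssrs <- rbind(truth_ssrs, data.frame(
        motif = if (mirror) revcomp(motif) else motif, copies = copies,
        start = w[1L] - 1L, end = w[1L] - 1L + len, region = region,
        planted_as = ps$region[i], stringsAsFactors = FALSE))
    }
  }

  truth_reps <- NULL
  pr <- spec$planted_repeats
  if (!is.null(pr)) {
    for (i in seq_len(nrow(pr))) {
      cl <- pr$class[i]; L <- as.integer(pr$length[i])
      mm <- as.integer(pr$mismatches[i])
      seg <- .random_dna(L)
      w1 <- .place_window(L, bounds$LSC[1L], bounds$LSC[2L], occupied)
      occupied <- rbind(occupied, c(w1[1L] - 1L, w1[2L] + 1L))
      copy2 <- .transform_text(seg, cl)
      copy2 <- .mutate_at(copy2, .spaced_positions(L, mm, gap = 11L))
      w2 <- .place_window(L, bounds$LSC[1L], bounds$LSC[2L], occupied)
      occupied <- rbind(occupied, c(w2[1L] - 1L, w2[2L] + 1L))
      core <- .overwrite(core, w1[1L], seg)
      core <- .overwrite(core, w2[1L], copy2)
      # break diagonal extension just outside both copies
      c1l <- substr(core, w1[1L] - 1L, w1[1L] - 1L)
      c1r <- substr(core, w1[2L] + 1L, w1[2L] + 1L)
      if (cl == "forward") {
        core <- .force_flank(core, w2[1L] - 1L, c1l)
        core <- .force_flank(core, w2[2L] + 1L, c1r)
      } else if (cl == "complement") {
        core <- .force_flank(core, w2[1L] - 1L, complement_seq(c1l))
        core <- .force_flank(core, w2[2L] + 1L, complement_seq(c1r))
      } else if (cl == "palindromic") {
        core <- .force_flank(core, w2[2L] + 1L, complement_seq(c1l))
        core <- .force_flank(core, w2[1L] - 1L, complement_seq(c1r))
      } else { # reverse
        core <- .force_flank(core, w2[2L] + 1L, c1l)
        core <- .force_flank(core, w2[1L] - 1L, c1r)
      }
      lo <- min(w1[1L], w2[1L]); hi <- max(w1[1L], w2[1L])
      truth_reps <- rbind(truth_reps, data.frame(
        class = cl, start1 = lo - 1L, end1 = lo - 1L + L,
        start2 = hi - 1L, end2 = hi - 1L + L, length = L,
        mismatches = mm, stringsAsFactors = FALSE))
    }
  }

  truth_tand <- NULL
  pt <- spec$planted_tandems
  if (!is.null(pt)) {
    for (i in seq_len(nrow(pt))) {
      p <- as.integer(pt$period[i]); copies <- as.integer(pt$copies[i])
      nm <- as.integer(pt$mutations[i])
      if (nm > 0L && copies < 3L)
        stop("mutated planted tandems need copies >= 3")
      if (nm > 0L && p <= 6L)
        stop("mutated planted tandems need period >= 7 (shorter periods ",
             "interact with the SSR ground truth)")
      motif <- .random_dna(p)
      while (!.is_primitive_motif(motif)) motif <- .random_dna(p)
      len <- p * copies
      tract <- strrep(motif, copies)
      # interior mutations, clear of the first and last period
      gap <- max(p + 1L, 5L)
      mpos <- .spaced_positions(len, nm, gap = gap)
      # keep mutated phases distinct so the majority consensus stays the
      # original motif at every phase
      if (nm > 1L) {
        for (j in 2L:nm) {
          while (any((mpos[j] %% p) == (mpos[seq_len(j - 1L)] %% p)))
            mpos[j] <- mpos[j] + 1L
        }
        if (any(mpos > len - gap) || any(diff(mpos) <= gap))
          stop("element too short for ", nm, " phase-distinct mutations")
      }
      tract <- .mutate_at(tract, mpos)
      w <- .place_window(len, bounds$LSC[1L], bounds$LSC[2L], occupied)
      core <- .overwrite(core, w[1L], tract)
      # the flanks must differ from every tract char at their phase
      # (mutations included), or a harmonic-period window shifted by one
      # could outscore the planted tract
      tch <- strsplit(tract, "", fixed = TRUE)[[1L]]
      core <- .force_flank(core, w[1L] - 1L,
                           unique(tch[seq.int(p, len, by = p)]))
      core <- .force_flank(core, w[2L] + 1L,
                           unique(tch[seq.int(1L, len, by = p)]))
      occupied <- rbind(occupied, c(w[1L] - 1L, w[2L] + 1L))
      truth_tand <- rbind(truth_tand, data.frame(
        start = w[1L] - 1L, end = w[1L] - 1L + len, period = p,
        copies = copies, mutations = nm, motif = motif,
        score = 2 * len - 9 * nm, stringsAsFactors = FALSE))
      # a perfect short-period tandem is by definition also an SSR
      thr <- .default_ssr_thresholds
      if (p <= 6L && copies >= thr[[as.character(p)]]) {
        truth_ssrs <- rbind(truth_ssrs, data.frame(
          motif = motif, copies = copies, start = w[1L] - 1L,
          end = w[1L] - 1L + len, region = "LSC",
          planted_as = "tandem", stringsAsFactors = FALSE))
      }
    }
  }

  # final hygiene pass around everything planted
  core <- .clean_sequence(core, protected = occupied)

  # break inverted-repeat extension at the junctions so the detected IR
  # pair is exactly the planted one: the last LSC base must not pair
  # with the first genome base (JLA wrap), nor the first SSC base with
  # the last SSC base (JSB/JSA side)
  core <- .force_flank(core, lsc,
                       complement_seq(substr(core, 1L, 1L)))
  core <- .force_flank(core, lsc + ir + 1L,
                       complement_seq(substr(core, lsc + ir + ssc,
                                             lsc + ir + ssc)))

  genome <- paste0(core, revcomp(substr(core, lsc + 1L, lsc + ir)))
  n <- nchar(genome)

  # IR-mirrored ground truth for elements planted inside IRb
  mirror_pos <- function(a0, len) {
    off <- a0 - lsc                      # 0-based offset into IRb
    (lsc + ir + ssc) + (ir - off - len)  # 0-based start inside IRa
  }
  if (!is.null(truth_ssrs)) {
    in_ir <- truth_ssrs$region == "IRb"
    if (any(in_ir)) {
      mir <- truth_ssrs[in_ir, , drop = FALSE]
      mir$motif <- revcomp(mir$motif)
      newstart <- mirror_pos(mir$start, mir$end - mir$start)
      mir$end <- newstart + (mir$end - mir$start)
      mir$start <- newstart
      mir$region <- "IRa"
      mir$planted_as <- "ir_mirror"
      truth_ssrs <- rbind(truth_ssrs, mir)
    }
    truth_ssrs <- truth_ssrs[order(truth_ssrs$start), , drop = FALSE]
    rownames(truth_ssrs) <- NULL
  }

  # mirror fully-IR-internal ordinary genes into IRa (duplicated genes)
  if (nrow(feats)) {
    irb0 <- c(lsc, lsc + ir)
    dup <- feats[feats$start >= irb0[1L] & feats$end <= irb0[2L] &
                 grepl("^gI", feats$name), , drop = FALSE]
    if (nrow(dup)) {
      len <- dup$end - dup$start
      dup$start <- mirror_pos(dup$start + len, 0L)
      dup$end <- dup$start + len
      dup$strand <- ifelse(dup$strand == "+", "-", "+")
      dup$feature_id <- dup$feature_id + max(feats$feature_id)
      feats <- rbind(feats, dup)
    }
  }

  record <- plastome_record("synthetic_plastome", genome, circular = TRUE,
                            features = feats)
  truth <- list(
    boundaries = list(lsc = c(0L, lsc), irb = c(lsc, lsc + ir),
                      ssc = c(lsc + ir, lsc + ir + ssc),
                      ira = c(lsc + ir + ssc, n)),
    region_lengths = c(lsc = lsc, irb = ir, ssc = ssc, ira = ir),
    ssrs = truth_ssrs, repeats = truth_reps, tandems = truth_tand,
    junction_genes = truth_jg, features = feats, seed = spec$seed)

  # self-consistency: every planted SSR must be recovered verbatim
  found <- find_ssrs(record)
  found_key <- paste(found$motif, found$copies, found$start, found$end)
  want_key <- if (is.null(truth_ssrs)) character(0) else
    paste(truth_ssrs$motif, truth_ssrs$copies, truth_ssrs$start,
          truth_ssrs$end)
  if (!identical(sort(found_key), sort(want_key)))
    stop("ground-truth validation failed: SSR scan disagrees with plan\n",
         "  unexpected: ", paste(setdiff(found_key, want_key),
                                 collapse = " | "), "\n",
         "  missing: ", paste(setdiff(want_key, found_key),
                              collapse = " | "))
  list(record = record, truth = truth)
}

#' Simulate a clade of per-region alignments from one plastome
#'
#' Each region of [classify_regions()] is copied `n_taxa` times with
#' independent per-site substitutions at its class-specific rate
#' (uniform over the three alternative bases), emitting gap-free
#' alignments and a log of every mutation. With `planted_mutations`
#' set, exactly that many single-hit substitutions are placed at
#' distinct sites per region instead (so the total number of mutations
#' eta equals the planted count by construction).
#'
#' @param record an annotated [plastome_record()] (e.g. from
#'   [make_plastome()]).
#' @param spec a [synth_spec()] (uses `n_taxa`, `mu_by_class`, `seed`).
#' @param planted_mutations `NULL` for rate mode, else integer: exact
#'   mutation count per region.
#' @param seed optional seed override.
#' @return list of [region_alignment()]; attribute `mutations` is the
#'   per-region mutation log (region, site, taxon, from, to).
#' @export
make_clade <- function(record, spec, planted_mutations = NULL,
                       seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  regions <- classify_regions(record)
  n_taxa <- spec$n_taxa
  bases <- c("A", "C", "G", "T")
  alns <- list()
  log <- NULL
  for (i in seq_len(nrow(regions))) {
    anc <- .subseq0(record$sequence, regions$start[i], regions$end[i])
    len <- nchar(anc)
    rows <- rep(anc, n_taxa)
    if (is.null(planted_mutations)) {
      mu <- spec$mu_by_class[[regions$class[i]]]
      if (mu > 0) {
        for (t in seq_len(n_taxa)) {
          hit <- which(stats::runif(len) < mu)
          for (h in hit) {
            old <- substr(rows[t], h, h)
            new <- sample(setdiff(bases, old), 1L)
            substr(rows[t], h, h) <- new
            log <- rbind(log, data.frame(
              region = regions$label[i], site = h, taxon = t,
              from = old, to = new, stringsAsFactors = FALSE))
          }
        }
      }
    } else {
      m <- min(as.integer(planted_mutations), len)
      sites <- sample.int(len, m)
      taxa <- sample.int(n_taxa, m, replace = TRUE)
      for (j in seq_len(m)) {
        old <- substr(rows[taxa[j]], sites[j], sites[j])
        new <- sample(setdiff(bases, old), 1L)
        substr(rows[taxa[j]], sites[j], sites[j]) <- new
        log <- rbind(log, data.frame(
          region = regions$label[i], site = sites[j], taxon = taxa[j],
          from = old, to = new, stringsAsFactors = FALSE))
      }
    }
    alns[[length(alns) + 1L]] <- region_alignment(
      regions$label[i], rows, class = regions$class[i],
      taxon_ids = paste0("taxon_", seq_len(n_taxa)))
  }
  structure(alns, mutations = log)
}

.default_panel_loci <- function(N) {
  list(mono = c(1),
       biallelic = c(0.5, 0.5),
       skewed = c(0.7, 0.2, 0.1),
       four = c(0.4, 0.3, 0.2, 0.1),
       distinct = "distinct")
}

#' Simulate a variety genotyping panel (cpSSR and SNV tables)
#'
#' Per locus, genotype classes are drawn from the specified frequency
#' vector (the literal `"distinct"` gives every variety its own class).
#' cpSSR genotypes are fragment sizes (base size + 2 bp per class); SNV
#' genotypes are haplotype strings and, when `refine` is set, strict
#' refinements of the SSR classes (each SSR class split into up to 3
#' haplotype subclasses), so D_j(SNV) >= D_j(cpSSR) holds by
#' construction. Missing entries are injected at `missing_rate`.
#'
#' @param spec a [synth_spec()] (uses `panel`, `seed`).
#' @param seed optional seed override.
#' @return list with `ssr` and `snv` [genotype_table()]s and `truth`
#'   (class and subclass assignment matrices, frequency vectors).
#' @export
make_panel <- function(spec, seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  p <- spec$panel
  N <- as.integer(p$n_varieties)
  loci <- p$loci
  if (is.null(loci)) loci <- .default_panel_loci(N)
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    names(loci) <- paste0("locus_", seq_along(loci))
  miss <- if (is.null(p$missing_rate)) 0 else p$missing_rate
  refine <- isTRUE(p$refine)
  varieties <- paste0("variety_", seq_len(N))
  ssr <- matrix(".", N, length(loci),
                dimnames = list(varieties, names(loci)))
  snv <- ssr
  class_truth <- matrix(NA_integer_, N, length(loci),
                        dimnames = list(varieties, names(loci)))
  sub_truth <- class_truth
  hap_alphabet <- c("A", "C", "G", "T")
  for (l in seq_along(loci)) {
    fv <- loci[[l]]
    if (identical(fv, "distinct")) {
      cls <- seq_len(N)
    } else {
      stopifnot(abs(sum(fv) - 1) < 1e-8)
      cls <- sample.int(length(fv), N, replace = TRUE, prob = fv)
    }
    class_truth[, l] <- cls
    ssr[, l] <- as.character(180L + 2L * cls)
    nsub <- vapply(unique(cls), function(cc)
      if (refine) sample(1:3, 1L) else 1L, integer(1L))
    names(nsub) <- as.character(unique(cls))
    sub <- vapply(seq_len(N), function(v) {
      k <- nsub[[as.character(cls[v])]]
      sample.int(k, 1L)
    }, integer(1L))
    sub_truth[, l] <- sub
    # haplotype label encodes (class, subclass) uniquely per locus
    snv[, l] <- vapply(seq_len(N), function(v) {
      code <- (cls[v] - 1L) * 3L + (sub[v] - 1L)
      paste(hap_alphabet[1L + ((code %/% c(1L, 4L, 16L, 64L, 256L)) %% 4L)],
            collapse = "")
    }, character(1L))
    if (miss > 0) {
      drop <- which(stats::runif(N) < miss)
      drop <- drop[seq_len(min(length(drop), N - 2L))]
      ssr[drop, l] <- "."
      snv[drop, l] <- "."
    }
  }
  list(ssr = genotype_table(ssr), snv = genotype_table(snv),
       truth = list(classes = class_truth, subclasses = sub_truth,
                    loci = loci))
}
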