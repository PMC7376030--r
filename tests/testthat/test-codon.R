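# GC composition and codon usage.

test_that("GC percentages follow the definitional arithmetic", {
  rec <- plastome_record("x", "ATGC", circular = FALSE)
  gc <- gc_by_region(rec)
  expect_equal(gc$gc_percent[gc$scope == "genome"], 50)
  # N excluded from the denominator
  recN <- plastome_record("n", "ATGCNN", circular = FALSE)
  gcN <- gc_by_region(recN)
  expect_equal(gcN$gc_percent[1], 50)
  expect_equal(gcN$N[1], 2L)
})

test_that("per-region GC matches direct counts and the weighted mean", {
  mp <- make_plastome(synth_spec(seed = 91))
  part <- detect_inverted_repeats(mp$record)
  gc <- gc_by_region(part$record, part)
  s <- part$record$sequence
  count_gc <- function(x) {
    ch <- strsplit(x, "")[[1]]
    100 * sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
  }
  expect_equal(gc$gc_percent[gc$scope == "LSC"],
               round(count_gc(substr(s, part$lsc[1] + 1, part$lsc[2])), 2))
  expect_equal(gc$gc_percent[gc$scope == "SSC"],
               round(count_gc(substr(s, part$ssc[1] + 1, part$ssc[2])), 2))
  # whole-genome GC is the length-weighted mean of region GCs
  rl <- region_lengths(part)
  w <- c(rl[["lsc"]], rl[["ssc"]], rl[["irb"]] + rl[["ira"]])
  parts_gc <- c(count_gc(substr(s, part$lsc[1] + 1, part$lsc[2])),
                count_gc(substr(s, part$ssc[1] + 1, part$ssc[2])),
                count_gc(paste0(substr(s, part$irb[1] + 1, part$irb[2]),
                                substr(s, part$ira[1] + 1, part$ira[2]))))
  expect_equal(sum(w * parts_gc) / sum(w), count_gc(s), tolerance = 1e-10)
})

test_that("codons are counted on the coding strand with stops separate", {
  feats <- rbind(
    data.frame(feature_id = 1L, name = "one", kind = "CDS", strand = "+",
               part = 1L, start = 0L, end = 9L))
  rec <- plastome_record("c", paste0("ATGAAATAA", strrep("C", 11)),
                         circular = FALSE, features = feats)
  cu <- codon_usage(rec)
  expect_equal(cu$n_codons, 3L)
  expect_equal(cu$codons$count[cu$codons$codon == "ATG"], 1L)
  expect_equal(cu$codons$count[cu$codons$codon == "AAA"], 1L)
  expect_equal(cu$codons$count[cu$codons$codon == "TAA"], 1L)
  expect_true(is.na(cu$codons$rscu[cu$codons$codon == "TAA"]))
  # minus-strand CDS is reverse-complemented first
  featsm <- data.frame(feature_id = 1L, name = "m", kind = "CDS",
                       strand = "-", part = 1L, start = 0L, end = 9L)
  recm <- plastome_record("m", paste0(revcomp("ATGAAATAA"),
                                      strrep("C", 11)),
                          circular = FALSE, features = featsm)
  cum <- codon_usage(recm)
  expect_equal(cum$codons$count[cum$codons$codon == "ATG"], 1L)
  # non-multiple-of-3 CDS drops the remainder with a warning
  feats3 <- data.frame(feature_id = 1L, name = "r", kind = "CDS",
                       strand = "+", part = 1L, start = 0L, end = 10L)
  rec3 <- plastome_record("r", paste0("ATGAAATAAC", strrep("G", 10)),
                          circular = FALSE, features = feats3)
  expect_warning(cu3 <- codon_usage(rec3), "divisible")
  expect_equal(cu3$n_codons, 3L)
})

test_that("uniform usage within a family gives RSCU 1", {
  # 4 Gly codons (GGN) once each
  s <- paste0("ATG", "GGT", "GGC", "GGA", "GGG", "TAA")
  feats <- data.frame(feature_id = 1L, name = "g", kind = "CDS",
                      strand = "+", part = 1L, start = 0L,
                      end = nchar(s))
  rec <- plastome_record("g", paste0(s, strrep("C", 10)),
                         circular = FALSE, features = feats)
  cu <- codon_usage(rec)
  gly <- cu$codons[cu$codons$amino_acid == "G", ]
  expect_equal(gly$rscu, rep(1, 4))
})

test_that("planted third-position A/T excess is visible and counted", {
  mp <- make_plastome(synth_spec(seed = 92, codon_bias_at3 = 0.6))
  rec <- mp$record
  cu <- codon_usage(rec)
  at <- function(col) sum(cu$by_position[cu$by_position$base %in%
                                         c("A", "T"), col])
  expect_gt(at("pos3"), at("pos1"))
  expect_gt(at("pos3"), at("pos2"))
  # codon count identity over CDS features
  cds <- rec$features[rec$features$kind == "CDS", ]
  lens <- tapply(cds$end - cds$start, cds$feature_id, sum)
  expect_equal(cu$n_codons, sum(lens %/% 3L))
})
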