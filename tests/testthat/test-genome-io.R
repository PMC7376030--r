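# Sequence and annotation I/O, coordinate conventions, region classing.

make_gb_text <- function(circular = TRUE) {
  c(paste0("LOCUS       TEST0001               120 bp    DNA     ",
           if (circular) "circular" else "linear", " PLN 01-JAN-2020"),
    "DEFINITION  synthetic test record.",
    "ACCESSION   TEST0001",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     gene            10..20",
    '                     /gene="alpha"',
    "     CDS             10..20",
    '                     /gene="alpha"',
    "     gene            complement(30..50)",
    '                     /gene="beta"',
    "     tRNA            join(60..70,81..90)",
    '                     /gene="trnX"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("ttggccaatt", 6), collapse = " ")),
    "//")
}

test_that("FASTA reading normalizes case, RNA alphabet and entry order", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y desc here", "ACGU"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[2]]$id, "y")
  expect_equal(recs[[2]]$sequence, "ACGT")
})

test_that("FASTA round-trip reproduces the sequence bit-exactly", {
  set.seed(42)
  s <- random_dna_string(3000)
  f <- tempfile(fileext = ".fa")
  write_fasta(plastome_record("rt", s), f)
  expect_identical(read_fasta(f)[[1]]$sequence, s)
})

test_that("FASTA rejects junk and maps ambiguity codes to N with warning", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">amb", "ACGRYT"), f)
  expect_warning(recs <- read_fasta(f), "mapped to N")
  expect_equal(recs[[1]]$sequence, "ACGNNT")

  f2 <- tempfile(fileext = ".fa")
  writeLines(character(0), f2)
  expect_error(read_fasta(f2), "empty|parse")

  f3 <- tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACGT123"), f3)
  expect_error(suppressWarnings(read_fasta(f3)), "non-nucleotide|parse")
})

test_that("GenBank locations convert to 0-based half-open coordinates", {
  f <- tempfile(fileext = ".gb")
  writeLines(make_gb_text(), f)
  rec <- read_genbank(f)
  expect_true(rec$circular)
  expect_equal(genome_length(rec), 120L)
  expect_equal(toupper(substr(rec$sequence, 1, 8)), "ACGTACGT")

  alpha <- rec$features[rec$features$name == "alpha" &
                        rec$features$kind == "gene", ]
  expect_equal(c(alpha$start, alpha$end), c(9L, 20L))     # "10..20"
  beta <- rec$features[rec$features$name == "beta", ]
  expect_equal(beta$strand, "-")
  expect_equal(c(beta$start, beta$end), c(29L, 50L))
  trn <- rec$features[rec$features$name == "trnX", ]
  expect_equal(trn$start, c(59L, 80L))                    # join() parts
  expect_equal(trn$end, c(70L, 90L))

  # 1-based inclusive <-> 0-based half-open is a bijection
  for (iv in list(c(1L, 1L), c(10L, 20L), c(120L, 120L))) {
    zero <- c(iv[1L] - 1L, iv[2L])
    expect_equal(c(zero[1L] + 1L, zero[2L]), iv)
  }
})

test_that("GenBank parsing fails cleanly without ORIGIN", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA linear", "FEATURES", "//"), f)
  expect_error(read_genbank(f), "ORIGIN")
})

test_that("introns are the gaps between feature parts", {
  feats <- rbind(
    data.frame(feature_id = 1L, name = "g1", kind = "gene", strand = "+",
               part = 1:2, start = c(0L, 15L), end = c(10L, 25L)),
    data.frame(feature_id = 2L, name = "g2", kind = "CDS", strand = "-",
               part = 1:3, start = c(30L, 44L, 60L),
               end = c(40L, 50L, 70L)))
  rec <- plastome_record("t", strrep("ACGT", 20), circular = FALSE,
                         features = feats)
  intr <- extract_introns(rec)
  i1 <- intr[grepl("^g1", intr$name), ]
  expect_equal(c(i1$start, i1$end), c(10L, 15L))
  expect_equal(i1$end - i1$start, 5L)
  expect_equal(i1$name, "g1_intron1")
  i2 <- intr[grepl("^g2", intr$name), ]
  expect_equal(nrow(i2), 2L)        # three-part CDS -> two introns
  # minus strand: transcription order numbers introns right-to-left
  expect_equal(i2$name[order(i2$start)], c("g2_intron2", "g2_intron1"))
})

test_that("region classification labels IGS by flanking genes", {
  feats <- rbind(
    data.frame(feature_id = 1L, name = "A", kind = "gene", strand = "+",
               part = 1L, start = 0L, end = 10L),
    data.frame(feature_id = 2L, name = "B", kind = "gene", strand = "+",
               part = 1L, start = 20L, end = 30L))
  rec <- plastome_record("t", strrep("ACGT", 10), circular = FALSE,
                         features = feats)
  part <- classify_regions(rec)
  igs <- part[part$class == "IGS", ]
  expect_true(any(igs$label == "A-B" & igs$start == 10L & igs$end == 20L))
  expect_true(any(igs$start == 30L & igs$end == 40L))   # terminal IGS

  # overlapping genes leave no IGS between them
  feats2 <- feats
  feats2$start <- c(0L, 8L); feats2$end <- c(10L, 30L)
  rec2 <- plastome_record("t2", strrep("ACGT", 10), circular = FALSE,
                          features = feats2)
  part2 <- classify_regions(rec2)
  expect_false(any(part2$class == "IGS" & part2$start < 30L))
})

test_that("region classes tile every non-gene base exactly once", {
  mp <- make_plastome(synth_spec(seed = 21))
  rec <- mp$record
  part <- classify_regions(rec)
  n <- genome_length(rec)
  cover <- integer(n)
  for (i in seq_len(nrow(part))) {
    idx <- (seq.int(part$start[i], part$end[i] - 1L) %% n) + 1L
    cover[idx] <- cover[idx] + 1L
  }
  expect_true(all(cover <= 1L))     # partition intervals are disjoint
  genebase <- logical(n)
  f <- rec$features
  for (i in seq_len(nrow(f)))
    genebase[(seq.int(f$start[i], f$end[i] - 1L) %% n) + 1L] <- TRUE
  expect_true(all(cover + genebase >= 1L))  # union covers the genome
  expect_error(classify_regions(plastome_record("bare", "ACGTACGT")),
               "annotation|GenBank")
})
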