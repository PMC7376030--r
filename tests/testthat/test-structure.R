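# Quadripartite structure detection, junction distances, boundary
# pseudogenes.

fake_partition <- function(lsc, ir, ssc, features = empty_features()) {
  n <- lsc + 2L * ir + ssc
  structure(list(no_structure = FALSE, genome_length = n,
                 lsc = c(0L, lsc), irb = c(lsc, lsc + ir),
                 ssc = c(lsc + ir, lsc + ir + ssc),
                 ira = c(lsc + ir + ssc, n), ir_length = ir,
                 rotation = 0L, flipped = FALSE,
                 record = plastome_record("fake", strrep("A", n),
                                          features = features)),
            class = "region_partition")
}

test_that("planted quadripartite boundaries are recovered exactly", {
  sp <- synth_spec(seed = 31, lsc_len = 5000L, ir_len = 1200L,
                   ssc_len = 2000L)
  mp <- make_plastome(sp)
  part <- detect_inverted_repeats(mp$record)
  expect_false(part$no_structure)
  expect_equal(unname(region_lengths(part)), c(5000L, 1200L, 2000L, 1200L))
  expect_equal(part$lsc, c(0L, 5000L))
  expect_equal(part$irb, c(5000L, 6200L))
  # IRa is the exact reverse complement of IRb
  s <- part$record$sequence
  expect_identical(revcomp(substr(s, part$ira[1] + 1, part$ira[2])),
                   substr(s, part$irb[1] + 1, part$irb[2]))
  # region lengths always sum to the genome length
  expect_equal(sum(region_lengths(part)), genome_length(mp$record))
})

test_that("detection is invariant under rotation of the circle", {
  mp <- make_plastome(synth_spec(seed = 32, lsc_len = 4000L,
                                 ir_len = 1000L, ssc_len = 1500L))
  s <- mp$record$sequence
  n <- nchar(s)
  for (off in c(137L, 2950L, 6123L)) {
    rot <- paste0(substr(s, off + 1L, n), substr(s, 1L, off))
    part <- detect_inverted_repeats(plastome_record("rot", rot))
    expect_equal(unname(region_lengths(part)),
                 c(4000L, 1000L, 1500L, 1000L),
                 info = paste("rotation", off))
  }
})

test_that("absence of a qualifying IR pair yields an explicit result", {
  set.seed(33)
  s <- random_dna_string(3000)
  part <- detect_inverted_repeats(plastome_record("rand", s))
  expect_true(part$no_structure)
  expect_error(detect_inverted_repeats(plastome_record("x", s),
                                       min_ir_length = 10L), ">= 25")
})

test_that("inverted-repeat search equals the exhaustive oracle", {
  set.seed(34)
  n_agree <- 0L
  for (rep in 1:25) {
    n <- sample(60:140, 1L)
    s <- random_dna_string(n)
    got <- longest_inverted_repeat(s, min_len = 5L)
    want <- oracle_lir(s, min_len = 5L)
    expect_identical(got, want, info = paste("replicate", rep))
    n_agree <- n_agree + identical(got, want)
  }
  # and with planted inverted pairs, which random draws rarely contain
  for (rep in 1:10) {
    seg <- random_dna_string(12)
    s <- paste0(random_dna_string(40), seg, random_dna_string(35),
                revcomp(seg), random_dna_string(40))
    got <- longest_inverted_repeat(s, min_len = 6L)
    want <- oracle_lir(s, min_len = 6L)
    expect_identical(got, want)
    expect_gte(got$length, 12L)
  }
})

test_that("junction distances follow the stated arithmetic", {
  # JLB junction at position 210
  feats <- rbind(
    data.frame(feature_id = 1L, name = "left", kind = "gene",
               strand = "+", part = 1L, start = 100L, end = 200L),
    data.frame(feature_id = 2L, name = "right", kind = "gene",
               strand = "+", part = 1L, start = 400L, end = 450L))
  part <- fake_partition(210L, 100L, 80L, feats)
  jr <- junction_report(part)
  jlb <- jr[jr$junction == "JLB", ]
  expect_equal(jlb$distance[jlb$gene == "left"], 10L)   # ends 10 bp before
  expect_equal(jlb$relation[jlb$gene == "left"], "upstream")

  # a gene containing the junction strictly inside splits 110/90
  feats2 <- data.frame(feature_id = 1L, name = "span", kind = "gene",
                       strand = "+", part = 1L, start = 100L, end = 300L)
  part2 <- fake_partition(210L, 100L, 80L, feats2)
  jr2 <- junction_report(part2)
  sp_row <- jr2[jr2$junction == "JLB" & jr2$gene == "span", ]
  expect_true(sp_row$spans_boundary)
  expect_equal(c(sp_row$split_left, sp_row$split_right), c(110L, 90L))

  # empty feature list: positions only
  jr3 <- junction_report(fake_partition(210L, 100L, 80L))
  expect_equal(nrow(jr3), 4L)
  expect_true(all(is.na(jr3$gene)))
})

test_that("planted junction genes reproduce the planted arithmetic", {
  sp <- synth_spec(seed = 35, junction_genes = list(jlb = 220L, jsb = 60L))
  mp <- make_plastome(sp)
  part <- detect_inverted_repeats(mp$record)
  jr <- junction_report(part)
  a <- jr[jr$gene == "jgA" & jr$junction == "JLB", ]
  expect_equal(c(a$split_left, a$split_right), c(400L, 220L))
  b <- jr[jr$gene == "jgB" & jr$junction == "JSB", ]
  expect_equal(c(b$split_left, b$split_right), c(60L, 350L))
})

test_that("boundary pseudogene fragments mirror into the opposite IR", {
  # rps19-like gene ending 60 bp inside IRb
  sp <- synth_spec(seed = 36, junction_genes = list(jlb = 60L, jsb = NULL))
  mp <- make_plastome(sp)
  part <- detect_inverted_repeats(mp$record)
  pg <- call_boundary_pseudogenes(part)
  expect_equal(nrow(pg), 1L)
  expect_equal(pg$fragment_length, 60L)
  expect_equal(pg$source_junction, "JLB")
  # the fragment sits at the mirrored coordinates at the IRa/LSC end
  expect_equal(pg$fragment_end, part$genome_length)
  expect_equal(pg$fragment_start, part$genome_length - 60L)
  # fragment is shorter than the full gene
  g <- part$record$features
  glen <- max(g$end[g$name == "jgA"]) - min(g$start[g$name == "jgA"])
  expect_lt(pg$fragment_length, glen)

  # ycf1-like gene spanning JSB with 1,100 bp inside IRb
  sp2 <- synth_spec(seed = 37, junction_genes = list(jlb = NULL,
                                                     jsb = 1100L))
  mp2 <- make_plastome(sp2)
  pg2 <- call_boundary_pseudogenes(detect_inverted_repeats(mp2$record))
  expect_equal(pg2$fragment_length, 1100L)

  # no spanning genes -> empty call list
  sp3 <- synth_spec(seed = 38, junction_genes = NULL)
  mp3 <- make_plastome(sp3)
  pg3 <- call_boundary_pseudogenes(detect_inverted_repeats(mp3$record))
  expect_equal(nrow(pg3), 0L)
})
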