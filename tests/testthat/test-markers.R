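# Discriminating power D_j and marker-class comparison.

test_that("D_j hits its analytic endpoints and the enumerated case", {
  expect_equal(as.numeric(compute_dj(rep("180", 20))), 0)
  expect_equal(as.numeric(compute_dj(as.character(1:20))), 1)
  # {A, A, B, C}: one concordant pair of six
  expect_equal(as.numeric(compute_dj(c("A", "A", "B", "C"))), 1 - 1 / 6)
  expect_warning(d <- compute_dj(c("A", ".", ".")), "undefined")
  expect_true(is.na(as.numeric(d)))
})

test_that("D_j equals the pair-counting oracle on random columns", {
  set.seed(81)
  for (rep in 1:200) {
    N <- sample(3:40, 1L)
    k <- sample(1:6, 1L)
    g <- as.character(sample.int(k, N, replace = TRUE))
    if (runif(1) < 0.3) g[sample.int(N, 1L)] <- "."
    if (sum(g != ".") < 2) next
    expect_equal(as.numeric(compute_dj(g)), oracle_dj(g),
                 tolerance = 1e-12, info = paste("replicate", rep))
  }
})

test_that("D_j ignores labels and ordering, and refinement never hurts", {
  set.seed(82)
  for (rep in 1:50) {
    N <- sample(6:30, 1L)
    g <- as.character(sample.int(4L, N, replace = TRUE))
    d0 <- as.numeric(compute_dj(g))
    relab <- letters[as.integer(g)]
    expect_equal(as.numeric(compute_dj(relab)), d0)
    expect_equal(as.numeric(compute_dj(sample(g))), d0)
    # split one class in two: a refinement of the partition
    split_class <- sample(unique(g), 1L)
    idx <- which(g == split_class)
    g2 <- g
    g2[idx[seq_len(length(idx) %/% 2L)]] <- paste0(split_class, "b")
    expect_gte(as.numeric(compute_dj(g2)), d0)
  }
})

test_that("dropping a variety with a unique genotype keeps pairs apart", {
  set.seed(83)
  for (rep in 1:30) {
    N <- sample(5:25, 1L)
    g <- as.character(sample.int(3L, N, replace = TRUE))
    g <- c(g, "unique_one")
    conc <- function(x) {
      x <- x[x != "."]
      sum(choose(table(x), 2))
    }
    g_drop <- g[-length(g)]
    expect_lte(conc(g_drop), conc(g))
  }
})

test_that("SNV haplotypes concatenate alleles at variable columns", {
  aln <- region_alignment("loc", c("AACGA", "AGCTA", "AACTA"),
                          taxon_ids = c("v1", "v2", "v3"))
  # columns 2 (A/G/A) and 4 (G/T/T) vary
  h <- call_snv_haplotypes(aln)
  expect_equal(as.character(h), c("AG", "GT", "AT"))
  expect_equal(attr(h, "n_variable_sites"), 2L)

  mono <- call_snv_haplotypes(region_alignment("m", c("ACGT", "ACGT")))
  expect_true(attr(mono, "monomorphic"))
  expect_equal(length(unique(mono)), 1L)

  # N at a variable column marks the variety missing
  h2 <- call_snv_haplotypes(region_alignment(
    "n", c("AACGA", "AGCTA", "ANCTA")))
  expect_equal(as.character(h2)[3], ".")
})

test_that("haplotype class counts follow the planted panel", {
  sp <- synth_spec(seed = 84, panel = list(
    n_varieties = 60L,
    loci = list(l1 = c(1), l2 = c(0.5, 0.5), l3 = c(0.6, 0.3, 0.1),
                l4 = "distinct"),
    missing_rate = 0, refine = FALSE))
  pan <- make_panel(sp)
  for (l in colnames(pan$ssr)) {
    realized <- length(unique(pan$truth$classes[, l]))
    expect_equal(length(unique(pan$ssr[, l])), realized, info = l)
    expect_equal(length(unique(pan$snv[, l])), realized, info = l)
  }
  expect_equal(as.numeric(compute_dj(pan$ssr[, "l1"])), 0)
  expect_equal(as.numeric(compute_dj(pan$ssr[, "l4"])), 1)
})

test_that("SNV refinement dominates cpSSR discriminating power", {
  sp <- synth_spec(seed = 85, panel = list(
    n_varieties = 93L,
    loci = list(a = c(0.5, 0.5), b = c(0.7, 0.2, 0.1),
                c = c(0.4, 0.3, 0.2, 0.1), d = c(1),
                e = c(0.25, 0.25, 0.25, 0.25)),
    missing_rate = 0.05, refine = TRUE))
  pan <- make_panel(sp)
  cmp <- compare_marker_classes(pan$ssr, pan$snv)
  expect_true(all(cmp$per_locus$dj_b >= cmp$per_locus$dj_a))
  expect_gte(cmp$summary$mean[cmp$summary$class == "SNV"],
             cmp$summary$mean[cmp$summary$class == "cpSSR"])
  # oracle agreement on the realized tables
  for (l in colnames(pan$ssr)) {
    expect_equal(as.numeric(compute_dj(pan$ssr[, l])),
                 oracle_dj(pan$ssr[, l]), tolerance = 1e-12)
    expect_equal(as.numeric(compute_dj(pan$snv[, l])),
                 oracle_dj(pan$snv[, l]), tolerance = 1e-12)
  }
  # identical tables give identically zero differences
  same <- compare_marker_classes(pan$ssr, pan$ssr)
  expect_true(all(same$per_locus$diff == 0))
})

test_that("the polymorphism screen keeps multi-class loci", {
  tab <- genotype_table(cbind(
    mono = rep("200", 10),
    bi = rep(c("200", "202"), 5),
    with_missing = c(rep(".", 8), "200", "200")))
  scr <- polymorphic_screen(tab)
  expect_setequal(scr$loci, "bi")
  expect_equal(scr$n_total, 3L)
  expect_equal(scr$percent, 33.33)
  all_mono <- genotype_table(cbind(a = rep("1", 4), b = rep("2", 4)))
  expect_length(polymorphic_screen(all_mono)$loci, 0L)
})

test_that("genotype tables round-trip through TSV", {
  sp <- synth_spec(seed = 86, panel = list(
    n_varieties = 12L, loci = list(x = c(0.5, 0.5), y = "distinct"),
    missing_rate = 0.1, refine = TRUE))
  pan <- make_panel(sp)
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(variety = rownames(pan$ssr),
                   as.data.frame(unclass(pan$ssr)),
                   check.names = FALSE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_genotype_table(f)
  expect_equal(unclass(back), unclass(pan$ssr), ignore_attr = TRUE)
})
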