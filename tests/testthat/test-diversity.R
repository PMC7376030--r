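# Nucleotide diversity (pi) and total number of mutations (eta).

test_that("pi follows the pairwise-difference definition", {
  # identical rows
  aln0 <- region_alignment("r0", rep(strrep("ACGT", 25), 3))
  expect_equal(as.numeric(compute_pi(aln0)), 0)

  # two 100-site rows differing at 5 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 5), strrep("A", 95))
  expect_equal(as.numeric(compute_pi(region_alignment("r2", c(a, b)))),
               0.05)

  # three rows with pairwise differences 1, 2, 3 over 10 sites
  r1 <- "AAAAAAAAAA"
  r2 <- "CAAAAAAAAA"          # d(r1,r2) = 1
  r3 <- "GGAAAAAAAA"          # d(r1,r3) = 2, d(r2,r3) = 2 -> adjust
  r3 <- "CGGAAAAAAA"          # d(r1,r3) = 3, d(r2,r3) = 2
  aln3 <- region_alignment("r3", c(r1, r2, r3))
  expect_equal(as.numeric(compute_pi(aln3)), (1 + 3 + 2) / 3 / 10)
})

test_that("eta counts distinct alleles minus one per analyzed site", {
  rows <- c("AA", "AG", "CA", "TA")   # site1 {A,A,C,T}: 2; site2 {A,G,A,A}: 1
  expect_equal(as.numeric(compute_eta(region_alignment("e", rows))), 3L)
  expect_equal(as.numeric(compute_eta(region_alignment(
    "none", rep("ACGTACGT", 4)))), 0L)
  # eta is bounded below by segregating sites and above by 3x
  set.seed(71)
  for (rep in 1:20) {
    rows <- vapply(1:4, function(i) random_dna_string(30), "")
    aln <- region_alignment("p", rows)
    m <- do.call(rbind, strsplit(rows, ""))
    seg <- sum(apply(m, 2, function(cc) length(unique(cc)) > 1))
    eta <- as.numeric(compute_eta(aln))
    expect_gte(eta, seg)
    expect_lte(eta, 3L * seg)
  }
})

test_that("gap and N columns are removed before anything is counted", {
  rows <- c("A-GTN", "ACGTA", "ACTTC")
  aln <- region_alignment("g", rows)
  pi <- compute_pi(aln)
  expect_equal(attr(pi, "sites_used"), 3L)   # columns 2 and 5 dropped
  # only column 3 (G/G/T) varies among analyzed columns
  expect_equal(as.numeric(compute_eta(aln)), 1L)
  expect_equal(as.numeric(pi), (0 + 1 + 1) / 3 / 3)
  # all columns compromised: undefined, flagged, never 0
  expect_warning(pi0 <- compute_pi(region_alignment("z", c("-A", "A-"))),
                 "undefined")
  expect_true(is.na(as.numeric(pi0)))
})

test_that("pi is invariant under row order and reverse complement", {
  set.seed(72)
  rows <- vapply(1:5, function(i) random_dna_string(80), "")
  rows[2] <- paste0(substr(rows[1], 1, 70), substr(rows[2], 71, 80))
  base_pi <- as.numeric(compute_pi(region_alignment("x", rows)))
  expect_equal(as.numeric(compute_pi(region_alignment(
    "x", rev(rows)))), base_pi)
  expect_equal(as.numeric(compute_pi(region_alignment(
    "x", revcomp(rows)))), base_pi)
  # two-sequence pi times sites is an integer Hamming distance
  two <- region_alignment("h", rows[1:2])
  p2 <- compute_pi(two)
  expect_equal(as.numeric(p2) * attr(p2, "sites_used"),
               round(as.numeric(p2) * attr(p2, "sites_used")))
  # oracle agreement
  expect_equal(base_pi, oracle_pi(rows))
})

test_that("planted single-hit mutations are counted exactly by eta", {
  sp <- synth_spec(seed = 73, lsc_len = 2500L, ir_len = 800L,
                   ssc_len = 900L, junction_genes = NULL,
                   n_genes = c(LSC = 3L, SSC = 1L, IR = 0L))
  mp <- make_plastome(sp)
  alns <- make_clade(mp$record, sp, planted_mutations = 7L)
  for (aln in alns)
    expect_equal(as.numeric(compute_eta(aln)), 7L, info = aln$label)
  # mu = 0 leaves every region invariant
  sp0 <- synth_spec(seed = 74, lsc_len = 2500L, ir_len = 800L,
                    ssc_len = 900L, junction_genes = NULL,
                    n_genes = c(LSC = 3L, SSC = 1L, IR = 0L),
                    mu_by_class = c(coding = 0, intron = 0, IGS = 0,
                                    rRNA = 0, tRNA = 0))
  mp0 <- make_plastome(sp0)
  for (aln in make_clade(mp0$record, sp0)) {
    expect_equal(as.numeric(compute_pi(aln)), 0)
    expect_equal(as.numeric(compute_eta(aln)), 0L)
  }
})

test_that("regions rank ascending by pi with documented tie-breaks", {
  res <- data.frame(
    label = c("a", "b", "c", "d", "e"),
    class = c("IGS", "coding", "IGS", "IGS", "coding"),
    pi = c(0.03, 0.01, 0.05, 0.03, 0.002),
    eta = c(10L, 3L, 20L, 12L, 1L),
    stringsAsFactors = FALSE)
  rk <- rank_regions(res, top_k = 3L)
  expect_equal(rk$label, c("d", "a", "c"))   # ties: higher eta first
  expect_equal(rk$rank, 1:3)
  full <- rank_regions(res, top_k = 99L)
  expect_equal(nrow(full), 5L)
  expect_equal(full$label[1], "e")
  cm <- attr(full, "class_means")
  expect_equal(unname(cm["IGS"]), mean(c(0.03, 0.05, 0.03)))
  expect_equal(unname(cm["coding"]), mean(c(0.01, 0.002)))
})

test_that("faster-evolving spacers show higher diversity than coding", {
  sp <- synth_spec(seed = 75, lsc_len = 3000L, ir_len = 800L,
                   ssc_len = 900L, junction_genes = NULL,
                   n_genes = c(LSC = 3L, SSC = 1L, IR = 0L),
                   mu_by_class = c(coding = 0.004, intron = 0.006,
                                   IGS = 0.008, rRNA = 0, tRNA = 0.002))
  mp <- make_plastome(sp)
  igs_means <- coding_means <- numeric(0)
  for (rep in 1:25) {
    alns <- make_clade(mp$record, sp, seed = 7500L + rep)
    div <- do.call(rbind, lapply(alns, region_diversity))
    igs_means <- c(igs_means, mean(div$pi[div$class == "IGS"]))
    coding_means <- c(coding_means, mean(div$pi[div$class == "coding"]))
  }
  expect_gt(mean(igs_means), mean(coding_means))
})
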