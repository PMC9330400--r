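test_that("estimate_ks handles hand-enumerated NG86 cases", {
  # identical sequences
  e0 <- estimate_ks(strrep("ATGGAA", 50), strrep("ATGGAA", 50))
  expect_equal(e0$Ks, 0)
  expect_equal(e0$Ka, 0)

  # ATG GAA vs ATG GAG: the single difference is synonymous
  # (Glu GAA -> GAG). Hand NG86 enumeration: ATG contributes 0
  # synonymous sites; GAA and GAG each contribute 1/3 (only the third
  # position has a synonymous change among its non-stop neighbours,
  # 1 of 3), so S = 1/3 and Sd = 1 — a saturated proportion, flagged.
  e1 <- estimate_ks("ATGGAA", "ATGGAG")
  expect_equal(e1$Sd, 1)
  expect_equal(e1$Nd, 0)
  expect_equal(e1$S, 1 / 3)
  expect_equal(e1$N, 17 / 3)
  expect_true(e1$saturated_ks)
  expect_true(is.na(e1$Ks))
  expect_equal(e1$Ka, 0)

  # ten GAT codons, one third-position synonymous change: S = 10/3,
  # Sd = 1, pS = 0.3, Ks = -3/4 log(1 - 0.4)
  a <- strrep("GAT", 10)
  b <- paste0("GAC", strrep("GAT", 9))
  e2 <- estimate_ks(a, b)
  expect_equal(e2$S, 10 / 3)
  expect_equal(e2$Sd, 1)
  expect_equal(e2$Ks, -0.75 * log(1 - 0.4))

  # frame errors
  expect_error(estimate_ks("ATGA", "ATGA"), "divisible")
  expect_error(estimate_ks("ATGGAA", "ATG"), "equal length")
})

test_that("estimate_ks is exactly symmetric", {
  set.seed(5)
  for (i in 1:20) {
    a <- random_sense_codon_seq(30)
    b <- random_sense_codon_seq(30)
    ab <- estimate_ks(a, b)
    ba <- estimate_ks(b, a)
    expect_identical(ab$Ks, ba$Ks)
    expect_identical(ab$Ka, ba$Ka)
    expect_identical(ab$S, ba$S)
  }
})

test_that("NG86 counting equals the brute-force oracle on short pairs", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:5, 1)
    a <- random_sense_codon_seq(n)
    b <- random_sense_codon_seq(n)
    mine <- estimate_ks(a, b)
    orc <- oracle_ng86(a, b)
    expect_equal(mine$S, orc$S, tolerance = 1e-12)
    expect_equal(mine$N, orc$N, tolerance = 1e-12)
    expect_equal(mine$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(mine$Nd, orc$Nd, tolerance = 1e-12)
    expect_equal(mine$Ks, orc$Ks, tolerance = 1e-12)
    expect_equal(mine$Ka, orc$Ka, tolerance = 1e-12)
  }
})

make_cds_family <- function(id, genes, species, tree_nwk, params, seed) {
  fam <- structure(list(id = id,
                        genes = data.frame(gene_id = genes,
                                           species = species),
                        tree = ape::read.tree(text = tree_nwk),
                        extinct = FALSE), class = "gene_family")
  fam$cds <- evolve_codon_sequences(fam, params, seed = seed)
  fam
}

test_that("paralog distributions score within-species pairs with weights", {
  p <- seq_sim_params(0.002, 0.2, 400)
  fam2 <- make_cds_family("f2", c("a_g1", "a_g2"), c("a", "a"),
                          "(a_g1:50,a_g2:50)D;", p, seed = 21)
  d2 <- build_paralog_distribution(list(fam2), "a")
  expect_equal(nrow(d2$pairs), 1)
  expect_equal(d2$pairs$weight, 1)
  expect_false(d2$empty)

  # three genes: 3 pairs; node weighting reduces total weight to the
  # number of duplication nodes (2)
  fam3 <- make_cds_family("f3", c("a_g1", "a_g2", "a_g3"),
                          rep("a", 3),
                          "((a_g1:30,a_g2:30)D:70,a_g3:100)D;", p,
                          seed = 22)
  d3 <- build_paralog_distribution(list(fam3), "a", dedup = TRUE)
  expect_equal(nrow(d3$pairs), 3)
  expect_equal(sum(d3$pairs$weight), 2)
  d3f <- build_paralog_distribution(list(fam3), "a", dedup = FALSE)
  expect_equal(sum(d3f$pairs$weight), 3)

  # window: pairs outside [ks_min, ks_max] are dropped
  dd <- build_paralog_distribution(list(fam2), "a",
                                   window = c(2, 5))
  expect_true(dd$empty)
})

test_that("one-to-one ortholog Ks keeps only single-copy families", {
  p <- seq_sim_params(0.002, 0.2, 400)
  fam_ok <- make_cds_family("f1", c("a_g1", "b_g1"), c("a", "b"),
                            "(a_g1:60,b_g1:60)S;", p, seed = 31)
  fam_multi <- make_cds_family("f2", c("a_g1", "a_g2", "b_g1"),
                               c("a", "a", "b"),
                               "((a_g1:30,a_g2:30)D:30,b_g1:60)S;", p,
                               seed = 32)
  out <- ortholog_ks(list(fam_ok, fam_multi), "a", "b")
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$pairs$family, "f1")
  none <- ortholog_ks(list(fam_multi), "a", "b")
  expect_true(none$empty)
})

test_that("ortholog Ks mode recovers the speciation divergence", {
  # two species split at T = 100, r chosen so 2*T*r = 0.4
  p <- seq_sim_params(0.002, 0.2, 2000)
  fams <- lapply(1:200, function(i)
    make_cds_family(paste0("f", i), c("a_g1", "b_g1"), c("a", "b"),
                    "(a_g1:100,b_g1:100)S;", p, seed = 4000 + i))
  out <- ortholog_ks(fams, "a", "b")
  expect_equal(out$n, 200)
  expect_lt(abs(out$mode / 0.4 - 1), 0.10)
  expect_lt(abs(out$median / 0.4 - 1), 0.10)
})

test_that("trio rate correction follows the relative-rate arithmetic", {
  # equal rates: correction leaves the focal-sister divergence alone
  t1 <- correction_trio("F", "S", "O", d_fs = 0.8, d_fo = 1.1,
                        d_so = 1.1)
  expect_false(t1$inconsistent)
  out1 <- rate_correct_peak(t1, paralog_peak_ks = 1.0)
  expect_equal(out1$mean, 0.8)
  expect_equal(out1$verdict, "shared")

  # worked example: d_F = (1.0 + 1.2 - 0.8)/2 = 0.7, corrected = 1.4
  t2 <- correction_trio("F", "S", "O", 1.0, 1.2, 0.8)
  expect_equal(t2$d_f, 0.7)
  out2 <- rate_correct_peak(t2, paralog_peak_ks = 0.9)
  expect_equal(out2$mean, 1.4)
  expect_equal(out2$verdict, "lineage_specific")

  # inconsistent trio yields no verdict
  t3 <- correction_trio("F", "S", "O", 0.1, 0.2, 1.4)
  expect_true(t3$inconsistent)
  expect_equal(rate_correct_peak(t3, 1)$verdict, "inconsistent")

  # several outgroups: mean and SD across usable trios
  out4 <- rate_correct_peak(list(t2, correction_trio("F", "S", "O2",
                                                     1.0, 1.3, 0.9)),
                            paralog_peak_ks = 2)
  expect_equal(out4$mean, mean(c(1.4, 1.4)))
  expect_equal(out4$verdict, "shared")
})

test_that("rate correction is the identity under equal rates", {
  set.seed(3)
  for (i in 1:50) {
    d_fs <- runif(1, 0.1, 2)
    d_o <- runif(1, d_fs / 2 + 0.01, 3)   # d_fo = d_so >= d_fs/2
    tr <- correction_trio("F", "S", "O", d_fs, d_o, d_o)
    expect_equal(2 * tr$d_f, d_fs, tolerance = 1e-12)
  }
})

test_that("saturation flags apply strictly above Ks 2", {
  fake <- structure(list(k = 3L, means = c(0.104, 2.0, 2.191),
                         sds = c(0.05, 0.2, 0.3),
                         weights = c(0.5, 0.3, 0.2), x = numeric(0)),
                    class = "ks_mixture")
  fl <- flag_saturation(fake)
  expect_equal(fl$flagged, c(FALSE, FALSE, TRUE))
  expect_match(fl$note[3], "saturation")
})
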