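mk_dist <- function(ks) {
  structure(list(species = "a",
                 pairs = data.frame(
                   gene1 = paste0("a_g", seq_along(ks) * 2 - 1),
                   gene2 = paste0("a_g", seq_along(ks) * 2),
                   family = paste0("f", seq_along(ks)),
                   Ka = NA_real_, Ks = ks, weight = 1,
                   stringsAsFactors = FALSE),
                 window = c(0.01, 5), empty = FALSE),
            class = "ks_distribution")
}

test_that("paralog assignment applies both window and posterior criteria", {
  ks <- withr::with_seed(81, c(stats::rnorm(300, 0.4, 0.05),
                               stats::rnorm(300, 1.4, 0.1)))
  dist <- mk_dist(ks)
  fit <- fit_mixture(dist, k_max = 2, seed = 82)
  expect_equal(fit$k, 2)
  asn <- assign_paralogs(dist, fit, 2)
  # a pair at the component mean with clean separation is assigned
  at_mean <- which.min(abs(ks - fit$means[2]))
  expect_true(asn$assigned[at_mean])
  # outside +/- 1 SD the window criterion fails even with max posterior
  off <- which(ks > fit$means[2] + 1.5 * fit$sds[2])
  expect_true(all(!asn$assigned[off]))
  expect_true(all(asn$max_posterior[off]))
  # conjunction bookkeeping
  expect_equal(attr(asn, "n_assigned"), sum(asn$assigned))
  expect_true(all(asn$assigned == (asn$in_window & asn$max_posterior)))
  expect_error(assign_paralogs(dist, fit, 3), "component")
})

test_that("posterior ties are conservatively unassigned", {
  dist <- mk_dist(c(0.5, 0.5, 0.5, 0.5))
  fake <- structure(list(k = 2L, means = c(0.4, 0.6), sds = c(0.2, 0.2),
                         weights = c(0.5, 0.5),
                         posteriors = matrix(0.5, 4, 2),
                         x = dist$pairs$Ks),
                    class = "ks_mixture")
  asn <- assign_paralogs(dist, fake, 1)
  expect_true(all(asn$tie))
  expect_false(any(asn$assigned))
})

test_that("widening the window never removes an assignment", {
  ks <- withr::with_seed(83, c(stats::rnorm(300, 0.35, 0.06),
                               stats::rnorm(300, 1.2, 0.15)))
  dist <- mk_dist(ks)
  fit <- fit_mixture(dist, k_max = 2, seed = 84)
  a1 <- assign_paralogs(dist, fit, 2, sd_window = 1)
  a2 <- assign_paralogs(dist, fit, 2, sd_window = 2)
  expect_true(all(a2$assigned[a1$assigned]))
})

test_that("retention rate counts distinct genes against predicted genes", {
  # 12 assigned pairs over 24 distinct genes, 200 predicted genes
  asn <- data.frame(gene1 = paste0("g", 1:12 * 2 - 1),
                    gene2 = paste0("g", 1:12 * 2),
                    assigned = TRUE)
  rr <- retention_rate(asn, 200)
  expect_equal(rr$n_paralog_genes, 24)
  expect_equal(rr$percent_retained, 12.0)
  # no assignments: 0%
  asn0 <- asn
  asn0$assigned <- FALSE
  expect_equal(retention_rate(asn0, 200)$percent_retained, 0)
  expect_error(retention_rate(asn, 0), "positive")
})

test_that("chi-squared residuals match hand arithmetic and the oracle", {
  # identical composition: residuals all zero, p = 1
  bg <- c(A = 900, B = 100)
  same <- go_bias(c(A = 90, B = 10), bg)
  expect_equal(same$residual, c(0, 0), ignore_attr = TRUE)
  expect_true(all(same$call == "ns"))
  expect_equal(attr(same, "p_value"), 1)

  # hand-derived: E = {90, 10}; residual_B = (30 - 10)/sqrt(10)
  r <- go_bias(c(A = 70, B = 30), bg)
  expect_equal(r$expected, c(90, 10), ignore_attr = TRUE)
  expect_equal(r$residual[2], 20 / sqrt(10))
  expect_equal(r$call, c("under", "over"), ignore_attr = TRUE)
  expect_equal(r$call[1], "under")  # (70-90)/sqrt(90) = -2.11 < -2

  # residuals always balance: sum(O - E) = 0
  expect_equal(sum(r$observed - r$expected), 0)

  # random tables against the independent oracle and chisq.test
  set.seed(85)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    bg <- stats::setNames(sample(50:500, k), paste0("c", 1:k))
    obs <- stats::setNames(stats::rmultinom(1, 300, bg / sum(bg))[, 1],
                           names(bg))
    mine <- go_bias(obs, bg)
    orc <- oracle_residuals(as.numeric(obs), as.numeric(bg))
    expect_equal(mine$expected, orc$expected, ignore_attr = TRUE)
    expect_equal(mine$residual, orc$residual, ignore_attr = TRUE)
    expect_equal(attr(mine, "statistic"), orc$statistic)
    ct <- suppressWarnings(
      stats::chisq.test(as.numeric(obs), p = bg / sum(bg)))
    expect_equal(attr(mine, "statistic"), unname(ct$statistic),
                 tolerance = 1e-12)
    expect_equal(attr(mine, "p_value"), ct$p.value, tolerance = 1e-12)
    expect_equal(sum(mine$observed - mine$expected), 0, tolerance = 1e-9)
  }
})

test_that("planted GO bias is detected and the null fixture is calibrated", {
  tree3 <- make_ladder_tree(3, 100)
  out <- simulate_family_set(tree3, bd_rates(0, 0),
                             list(wgd_event("t3", retention_rate = 0.5)),
                             800, seed = 86)
  # biased fixture: factor 3 on one of 10 categories
  tab <- plant_go_bias(out$families, 10, "GO:0001", 3, seed = 87)
  par_genes <- attr(tab, "paralog_genes")
  expect_gt(length(par_genes), 100)
  enr <- go_bias(go_tally(tab, par_genes), go_tally(tab))
  expect_equal(enr$call[enr$category == "GO:0001"], "over")
  # biased-category frequency approx 3 / (3 + 9)
  freq <- go_tally(tab, par_genes)[["GO:0001"]] /
    sum(go_tally(tab, par_genes))
  expect_lt(abs(freq - 0.25), 0.05)

  # null fixture: factor 1 gives equal composition in expectation
  tab0 <- plant_go_bias(out$families, 10, "GO:0001", 1, seed = 88)
  enr0 <- go_bias(go_tally(tab0, attr(tab0, "paralog_genes")),
                  go_tally(tab0))
  expect_true(all(abs(enr0$residual) < 4))
  expect_error(plant_go_bias(out$families, 10, "GO:9999", 2, seed = 1),
               "universe")
})

test_that("cross-event matrices order events and measure convergence", {
  r1 <- go_bias(c(A = 70, B = 30), c(A = 900, B = 100))
  r2 <- go_bias(c(A = 60, B = 40), c(A = 900, B = 100))
  r3 <- go_bias(c(A = 97, B = 3), c(A = 900, B = 100))
  one <- cross_event_matrix(list(e1 = r1))
  expect_equal(unname(one$matrix[, 1]), r1$call)
  expect_true(all(is.na(one$convergence)))

  two <- cross_event_matrix(list(e1 = r1, e2 = r2))
  expect_equal(two$convergence[["B"]], 1.0)   # both call B over

  opp <- cross_event_matrix(list(e1 = r1, e3 = r3))
  expect_equal(opp$convergence[["B"]], 0.0)   # over vs under

  # events sorted by ascending component median Ks
  ord <- cross_event_matrix(list(old = r1, young = r2),
                            event_median_ks = c(1.5, 0.3))
  expect_equal(colnames(ord$matrix), c("young", "old"))
})
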