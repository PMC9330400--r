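mk_profile <- function(labels, n_mapped, n_dup) {
  out <- data.frame(node = seq_along(labels) + 100L, label = labels,
                    n_mapped = as.integer(n_mapped),
                    n_duplicated = as.integer(n_dup),
                    proportion = n_dup / n_mapped,
                    stringsAsFactors = FALSE)
  class(out) <- c("dup_profile", "data.frame")
  out
}

test_that("fisher_compare reproduces exact hypergeometric p-values", {
  # identical proportions: p = 1
  a <- mk_profile("N", 100, 5)
  b <- mk_profile("N", 100, 5)
  expect_equal(fisher_compare(a, b, "N")$p_value, 1)

  # worked 2x2 case [[8,2],[1,9]]
  e <- mk_profile("N", 10, 8)
  s <- mk_profile("N", 10, 1)
  fc <- fisher_compare(e, s, "N")
  expect_equal(fc$p_value, oracle_fisher(matrix(c(8, 2, 1, 9), 2,
                                                byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(round(fc$p_value, 6), 0.005477)
  expect_equal(fc$direction, 1L)

  # zero margin: undefined
  z <- fisher_compare(mk_profile("N", 50, 0), mk_profile("N", 70, 0),
                      "N")
  expect_true(z$undefined)
  expect_true(is.na(z$p_value))
})

test_that("fisher_compare equals the enumeration oracle on random tables", {
  set.seed(61)
  for (i in 1:400) {
    n <- sample(4:40, 1)
    r1 <- sample(1:(n - 1), 1)
    x <- stats::rbinom(1, r1, runif(1))
    y <- stats::rbinom(1, n - r1, runif(1))
    if ((x + y) == 0 || (x + y) == n) next
    e <- mk_profile("N", r1, x)
    s <- mk_profile("N", n - r1, y)
    tab <- matrix(c(x, r1 - x, y, n - r1 - y), 2, byrow = TRUE)
    expect_equal(fisher_compare(e, s, "N")$p_value, oracle_fisher(tab),
                 tolerance = 1e-10)
  }
})

test_that("the WGD decision rule distinguishes its three verdicts", {
  null_p <- mk_profile("N", 3000, 300)    # 10% background
  pos_p <- mk_profile("N", 3000, 900)     # 30% with the planted WGD
  # clearly at the positive level: supported
  sup <- call_wgd(mk_profile("N", 2000, 620), null_p, pos_p, "N")
  expect_equal(sup$verdict, "supported")
  # between null and positive, significantly below both ends: partial
  par <- call_wgd(mk_profile("N", 2000, 400), null_p, pos_p, "N")
  expect_equal(par$verdict, "partial")
  # at the null level: unsupported
  uns <- call_wgd(mk_profile("N", 2000, 200), null_p, pos_p, "N")
  expect_equal(uns$verdict, "unsupported")
  # below the null is also unsupported (direction matters)
  low <- call_wgd(mk_profile("N", 2000, 80), null_p, pos_p, "N")
  expect_equal(low$verdict, "unsupported")
})

test_that("simulation designs carry the printed protocol counts", {
  d <- simulation_design()
  expect_equal(d$regimes$multiplier, c(1, 0.5, 3))
  expect_equal(d$regimes$n_trees, rep(1000L, 3))
  expect_equal(d$positive_n_trees, 3000L)
  expect_equal(d$retention, 0.2)
  expect_error(simulation_design(retention = 1.2))
})

test_that("null and positive pools honour the design and retention limits", {
  tree6 <- make_ladder_tree(6, 300)
  design <- simulation_design(
    regimes = data.frame(multiplier = c(1, 0.5, 3),
                         n_trees = c(40L, 40L, 40L)),
    positive_n_trees = 120L, retention = 1)
  pools <- build_null_and_positive(
    tree6, bd_rates(1e-9, 1e-9), design,
    list(wgd_event("N4")), seed = 71)
  # retention 1 with negligible background: proportion 1 at the node
  expect_equal(pools$positive$proportion[pools$positive$label == "N4"],
               1.0)
  expect_equal(attr(pools$null, "n_trees"), 120)
  expect_equal(attr(pools$positive, "n_trees"), 120)
  expect_equal(length(pools$per_regime$null), 3)

  # retention 0 positives are indistinguishable from the null
  design0 <- simulation_design(
    regimes = data.frame(multiplier = c(1, 0.5, 3),
                         n_trees = c(150L, 150L, 150L)),
    positive_n_trees = 450L, retention = 0)
  pools0 <- build_null_and_positive(
    tree6, bd_rates(0.002, 0.002), design0,
    list(wgd_event("N4")), seed = 72)
  fc <- fisher_compare(pools0$positive, pools0$null, "N4")
  expect_gt(fc$p_value, 0.005)
})
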