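tree6 <- make_ladder_tree(6, 300)

test_that("without births, deaths or WGDs the gene tree mirrors the species tree", {
  for (seed in c(1, 2, 3, 17)) {
    fam <- simulate_gene_family(tree6, bd_rates(0, 0), seed = seed)
    expect_false(fam$extinct)
    expect_equal(sort(fam$genes$species), sort(tree6$tip.label))
    ref <- ape::read.tree(text = gsub("t(\\d+)", "t\\1_g1",
                                      ape::write.tree(tree6)))
    expect_true(ape::all.equal.phylo(ape::unroot(fam$tree),
                                     ape::unroot(ref),
                                     use.edge.length = FALSE))
    expect_true(all(fam$tree$node.label == "S"))
  }
})

test_that("a fully retained WGD duplicates every lineage below its branch", {
  fam <- simulate_gene_family(
    tree6, bd_rates(0, 0), list(wgd_event("root", retention_rate = 1)),
    seed = 5)
  cnt <- table(fam$genes$species)
  expect_true(all(cnt == 2))
  expect_equal(fam$tree$node.label[1], "D:wgd_root")

  fam2 <- simulate_gene_family(
    tree6, bd_rates(0, 0), list(wgd_event("N4", retention_rate = 1)),
    seed = 6)
  cnt2 <- table(fam2$genes$species)
  expect_equal(as.integer(cnt2[c("t4", "t5", "t6")]), rep(2L, 3))
  expect_equal(as.integer(cnt2[c("t1", "t2", "t3")]), rep(1L, 3))
  expect_true("D:wgd_N4" %in% fam2$tree$node.label)
})

test_that("WGD retention matches its binomial expectation", {
  tree3 <- make_ladder_tree(3, 100)
  n <- 10000
  prep <- wgdplacer:::.tree_prep(tree3)
  sim <- list(prep = prep, lambda = 0, mu = 0,
              wgds = wgdplacer:::.index_wgds(
                prep, list(wgd_event("t3", retention_rate = 0.2))))
  dup <- withr::with_seed(1234, {
    vapply(seq_len(n), function(i) {
      fam <- wgdplacer:::.simulate_family_core(sim, 1L, "f")
      sum(fam$genes$species == "t3") == 2L
    }, logical(1))
  })
  # binomial SE at p = 0.2, n = 10^4 is 0.004
  expect_lt(abs(mean(dup) - 0.2), 0.012)
})

test_that("duplication nodes carry exactly one origin label", {
  fam <- simulate_gene_family(
    tree6, bd_rates(0.004, 0.002),
    list(wgd_event("N3", retention_rate = 0.5)), seed = 11)
  if (!is.null(fam$tree)) {
    labs <- fam$tree$node.label
    expect_true(all(grepl("^(S|R|D:background|D:wgd_N3)$", labs)))
    dups <- labs[startsWith(labs, "D:")]
    expect_true(all(vapply(strsplit(dups, ":"), length, integer(1)) == 2))
  }
})

test_that("simulated families are reproducible under the same seed", {
  a <- simulate_gene_family(tree6, bd_rates(0.003, 0.003), seed = 42)
  b <- simulate_gene_family(tree6, bd_rates(0.003, 0.003), seed = 42)
  expect_identical(a$genes, b$genes)
  if (!is.null(a$tree)) {
    expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  }
  expect_error(simulate_gene_family(tree6, bd_rates(0, 0)),
               "seed")
})

test_that("critical birth-death keeps unit expected family size", {
  tree3 <- make_ladder_tree(3, 100)
  prep <- wgdplacer:::.tree_prep(tree3)
  sizes <- withr::with_seed(7, {
    vapply(seq_len(10000), function(i) {
      fam <- wgdplacer:::.simulate_family_core(
        list(prep = prep, lambda = 0.005, mu = 0.005,
             wgds = wgdplacer:::.index_wgds(prep, list())), 1L, "f")
      sum(fam$genes$species == "t1")   # copies reaching one tip
    }, numeric(1))
  })
  # E[size] = 1 for the critical process; allow 3 SE
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 1), 3 * se + 1e-9)
})

test_that("family-set conditioning filters are enforced", {
  out <- simulate_family_set(tree6, bd_rates(0, 0), list(), 500,
                             seed = 3)
  expect_equal(length(out$families), 500)
  expect_equal(sum(out$rejections), 0)
  expect_true(all(vapply(out$families, function(f)
    nrow(f$genes) == 6L, logical(1))))

  # heavy extinction: outgroup-extinct families must be rejected
  out2 <- simulate_family_set(tree6, bd_rates(0, 0.004), list(), 200,
                              seed = 4)
  og_ok <- vapply(out2$families, function(f)
    sum(f$genes$species == "t1") >= 1 &&
      sum(f$genes$species != "t1") >= 1, logical(1))
  expect_true(all(og_ok))
  expect_gt(out2$rejections[["no_outgroup"]] +
              out2$rejections[["extinct"]] +
              out2$rejections[["no_other"]], 0)

  # cap: families over the per-taxon cap are rejected
  out3 <- simulate_family_set(tree6, bd_rates(0.004, 0), list(), 100,
                              filters = list(max_per_taxon = 3L),
                              seed = 5)
  counts <- family_count_matrix(out3$families, tree6$tip.label)
  expect_lte(max(counts), 3L)
  expect_gt(out3$rejections[["over_cap"]], 0)
})

test_that("wgd_genes recovers exactly the WGD-descended tips", {
  fam <- simulate_gene_family(
    tree6, bd_rates(0, 0), list(wgd_event("N5", retention_rate = 1)),
    seed = 8)
  g <- wgd_genes(fam, "wgd_N5")
  expect_equal(sort(species_from_gene(g)),
               c("t5", "t5", "t6", "t6"))
  none <- simulate_gene_family(tree6, bd_rates(0, 0), seed = 9)
  expect_length(wgd_genes(none), 0)
})
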