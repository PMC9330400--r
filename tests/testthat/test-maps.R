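tree6 <- make_ladder_tree(6, 300)

test_that("hand-reconciled duplication mappings are reproduced", {
  sp2 <- ape::read.tree(text = "(A:10,B:10)R;")
  sp2$node.label <- "R"
  # ((A1,A2),B): the (A1,A2) node maps to tip A as a duplication
  g1 <- ape::read.tree(text = "((A_g1:1,A_g2:1):9,B_g1:10);")
  m1 <- lca_map(g1, sp2)
  inner <- m1[!m1$is_tip, ]
  expect_equal(inner$map_label, c("R", "A"))
  expect_equal(inner$duplication, c(FALSE, TRUE))

  # ((A1,B1),(A2,B2)): classic shared duplication at the root
  g2 <- ape::read.tree(text = "((A_g1:1,B_g1:1):9,(A_g2:1,B_g2:1):9);")
  m2 <- lca_map(g2, sp2)
  root_row <- m2[!m2$is_tip, ][1, ]
  expect_equal(root_row$map_label, "R")
  expect_true(root_row$duplication)

  # congruent single-copy tree: no duplications anywhere
  fam <- simulate_gene_family(tree6, bd_rates(0, 0), seed = 1)
  m3 <- lca_map(fam$tree, tree6)
  expect_false(any(m3$duplication))

  # unknown species labels are fatal and name the gene
  bad <- ape::read.tree(text = "((A_g1:1,Z_g1:1):2,B_g1:3);")
  expect_error(lca_map(bad, sp2), "Z_g1")
})

test_that("LCA mapping agrees with the brute-force oracle on random trees", {
  sp <- make_ladder_tree(6, 100)
  set.seed(31)
  for (i in 1:500) {
    n <- sample(3:6, 1)
    gt <- random_gene_tree(sp$tip.label, n)
    mine <- lca_map(gt, sp)
    orc <- oracle_lca(gt, sp)
    expect_identical(mine$map_node, orc$map)
    expect_identical(mine$duplication, orc$dup)
  }
})

test_that("occupancy and outgroup filters reject the right trees", {
  gts <- list(
    ape::read.tree(text = "(t5_g1:1,t6_g1:1);"),              # 2/6 species
    ape::read.tree(text = "((t2_g1:1,t3_g1:1):1,(t4_g1:1,t5_g1:1):1);"), # no outgroup
    ape::read.tree(text = "((t1_g1:1,t2_g1:1):1,(t4_g1:1,t6_g1:1):1);")  # keep
  )
  out <- filter_and_root(gts, tree6, occupancy = 0.45)
  expect_equal(out$kept, 3L)
  expect_equal(nrow(out$log[out$log$status == "rejected", ]), 2)
  expect_match(out$log$reason[1], "occupancy")
  expect_match(out$log$reason[2], "outgroup")
  # rooted on the outgroup gene
  rooted <- out$trees[[1]]
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 length(rooted$tip.label) + 1L, 2]
  og_side <- vapply(root_children, function(nd) {
    tips <- if (nd <= length(rooted$tip.label)) rooted$tip.label[nd]
            else ape::extract.clade(rooted, nd)$tip.label
    all(species_from_gene(tips) == "t1")
  }, logical(1))
  expect_true(any(og_side))
  expect_error(filter_and_root(gts[1:2], tree6), "no gene tree")
})

test_that("duplication profiles match forced and binomial expectations", {
  # forced: retention 1 on the branch above N4 puts proportion 1 there
  out <- simulate_family_set(tree6, bd_rates(0, 0),
                             list(wgd_event("N4", retention_rate = 1)),
                             200, seed = 41)
  prof <- duplication_profile(lapply(out$families, `[[`, "tree"), tree6)
  expect_equal(prof$proportion[prof$label == "N4"], 1.0)
  expect_equal(sum(prof$n_duplicated[prof$label != "N4"]), 0)

  # binomial: retention 0.2 over 2000 families
  out2 <- simulate_family_set(tree6, bd_rates(0, 0),
                              list(wgd_event("N4", retention_rate = 0.2)),
                              2000, seed = 42)
  prof2 <- duplication_profile(lapply(out2$families, `[[`, "tree"),
                               tree6)
  p_n4 <- prof2$proportion[prof2$label == "N4"]
  expect_lt(abs(p_n4 - 0.2), 0.025)
  expect_equal(sum(prof2$n_duplicated[prof2$label != "N4"]), 0)

  # all-congruent trees: all proportions zero
  out3 <- simulate_family_set(tree6, bd_rates(0, 0), list(), 50,
                              seed = 43)
  prof3 <- duplication_profile(lapply(out3$families, `[[`, "tree"),
                               tree6)
  expect_true(all(prof3$proportion == 0))
})

test_that("profiles are invariant to within-species tip relabelling", {
  out <- simulate_family_set(tree6, bd_rates(0.003, 0.003),
                             list(wgd_event("N3", retention_rate = 0.3)),
                             300, seed = 44)
  trees <- lapply(out$families, `[[`, "tree")
  prof <- duplication_profile(trees, tree6)
  # permute conspecific gene indices: t4_g1 <-> t4_g2 etc.
  swapped <- lapply(trees, function(phy) {
    labs <- phy$tip.label
    sp <- species_from_gene(labs)
    for (s in unique(sp)) {
      idx <- which(sp == s)
      if (length(idx) > 1) {
        labs[idx] <- labs[rev(idx)]
      }
    }
    phy$tip.label <- labs
    phy
  })
  prof2 <- duplication_profile(swapped, tree6)
  expect_identical(prof$n_mapped, prof2$n_mapped)
  expect_identical(prof$n_duplicated, prof2$n_duplicated)
})

test_that("collapsing to one conspecific sample barely moves the profile", {
  # mirrors the single-sample robustness check: represent each species
  # by one retained gene copy chosen either way at multi-copy tips
  out <- simulate_family_set(tree6, bd_rates(0.002, 0.002),
                             list(wgd_event("N4", retention_rate = 0.2)),
                             1500, seed = 45)
  trees <- lapply(out$families, `[[`, "tree")
  # collapse one species (t6) to a single representative copy, chosen
  # either as the first or the last conspecific gene; all other
  # species keep their full copy sets
  pick <- function(phy, take_first) {
    sp <- species_from_gene(phy$tip.label)
    idx <- which(sp == "t6")
    if (length(idx) < 2) return(phy)
    drop <- if (take_first) idx[-1] else idx[-length(idx)]
    if (length(phy$tip.label) - length(drop) < 2) return(NULL)
    ape::drop.tip(phy, drop)
  }
  prof_a <- duplication_profile(Filter(Negate(is.null),
                                       lapply(trees, pick, TRUE)), tree6)
  prof_b <- duplication_profile(Filter(Negate(is.null),
                                       lapply(trees, pick, FALSE)), tree6)
  # sampled-copy swap changes node proportions by < 1 percentage point
  delta <- abs(prof_a$proportion - prof_b$proportion)
  expect_true(all(delta[is.finite(delta)] < 0.01 + 1e-9))
})
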