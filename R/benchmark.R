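#' Planted-WGD recovery benchmark
#'
#' End-to-end synthetic benchmark for the gene-tree sorting WGD test:
#' on a ladderized species tree, birth/death rates are estimated from
#' a conditioned null family set, null and positive gene-tree pools
#' are simulated at the protocol sizes, and a series of independent
#' empirical datasets — simulated with the planted WGD
#' (`with_wgd = TRUE`) or without it (`with_wgd = FALSE`, the
#' specificity benchmark) — are profiled and tested with
#' [call_wgd_all()]. A replicate is a success when the planted node
#' (and only it) is called "supported"; under the null, when no node
#' is called "supported".
#'
#' @param seed integer seed driving every stage (required).
#' @param with_wgd plant the WGD in the empirical datasets?
#' @param n_seeds number of empirical replicates (default 20).
#' @param n_families empirical families per replicate (default 2000).
#' @param lambda,mu true background rates per gene per time unit.
#' @param branch species-tree branch carrying the planted/candidate
#'   WGD (child-node label).
#' @param retention planted retention rate (default 0.2, matching the
#'   positive-simulation convention).
#' @param n_tips,depth ladder-tree shape.
#' @param design a [simulation_design()] for the null/positive pools.
#' @param rate_families,rate_subsets,rate_subset_size size of the
#'   rate-estimation stage (desk-scale defaults).
#' @param alpha significance level for the calls.
#' @return list with `success` (logical per replicate), `rate`
#'   (success fraction), `calls` (per-replicate verdict tables),
#'   `rate_estimate` and `pools`.
#' @export
benchmark_recovery <- function(seed, with_wgd = TRUE, n_seeds = 20L,
                               n_families = 2000L, lambda = 0.002,
                               mu = 0.002, branch = "N4",
                               retention = 0.2, n_tips = 6L,
                               depth = 300, design = simulation_design(),
                               rate_families = 600L, rate_subsets = 3L,
                               rate_subset_size = 200L, alpha = 0.05) {
  .require_seed(seed)
  tree <- make_ladder_tree(n_tips, depth)
  truth <- bd_rates(lambda, mu)
  wgd <- list(wgd_event(branch, retention_rate = retention))
  null_set <- simulate_family_set(tree, truth, list(), rate_families,
                                  seed = seed + 1L)
  cnt <- family_count_matrix(null_set$families, tree$tip.label)
  re <- suppressWarnings(
    estimate_rates(cnt, tree, subsets = rate_subsets,
                   subset_size = rate_subset_size, seed = seed + 2L,
                   root_prior_mean = 1))
  pools <- build_null_and_positive(
    tree, bd_rates(re$lambda_hat, re$mu_hat), design, wgd,
    seed = seed + 3L)
  calls <- vector("list", n_seeds)
  success <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    emp <- simulate_family_set(tree, truth, if (with_wgd) wgd else
      list(), n_families, seed = seed + 10L + s)
    prof <- duplication_profile(lapply(emp$families, `[[`, "tree"),
                                tree)
    cl <- call_wgd_all(prof, pools$null, pools$positive_ml, alpha)
    calls[[s]] <- cl
    supported <- cl$node[cl$verdict == "supported"]
    success[s] <- if (with_wgd) {
      identical(supported, branch)
    } else {
      length(supported) == 0L
    }
  }
  list(success = success, rate = mean(success), calls = calls,
       rate_estimate = re, pools = pools)
}

#' Sequence-level Ks peak recovery benchmark
#'
#' Simulates gene families with a planted WGD on the pendant branch of
#' a focal species, evolves codon sequences for the retained duplicate
#' pairs, builds the focal paralog Ks distribution and fits the
#' mixture model. The planted peak sits at `2 * t_wgd * syn_rate`;
#' the benchmark reports the best-fit component mean closest to the
#' expectation and its relative error.
#'
#' @param seed integer seed (required).
#' @param n_families families to simulate (retained pairs are roughly
#'   `retention * n_families`).
#' @param retention planted retention rate.
#' @param syn_rate synonymous substitution rate per site per time
#'   unit.
#' @param n_codons gene length.
#' @param depth tree depth; the WGD sits at the midpoint of the focal
#'   species' pendant branch, which on the 3-taxon ladder places it at
#'   age `depth / 4`.
#' @param k_max,alpha mixture/selection settings.
#' @return list with `expected_ks`, `fitted_mean`, `relative_error`,
#'   `n_pairs`, and the mixture `fit`.
#' @export
benchmark_ks_peak <- function(seed, n_families = 2800L,
                              retention = 0.2, syn_rate = 0.01,
                              n_codons = 500L, depth = 100,
                              k_max = 3L, alpha = 0.05) {
  .require_seed(seed)
  tree <- make_ladder_tree(3, depth)
  focal <- "t3"
  wgd <- list(wgd_event(focal, retention_rate = retention))
  out <- simulate_family_set(tree, bd_rates(0, 0), wgd, n_families,
                             seed = seed + 1L)
  params <- seq_sim_params(syn_rate, 0.2, n_codons)
  fams <- list()
  for (i in seq_along(out$families)) {
    f <- out$families[[i]]
    g <- f$genes$gene_id[f$genes$species == focal]
    if (length(g) != 2L) next
    # the pair's divergence only involves the subtree below the WGD
    # node; restrict sequence evolution to it
    f$tree <- ape::keep.tip(f$tree, g)
    f$genes <- f$genes[f$genes$species == focal, , drop = FALSE]
    f$cds <- evolve_codon_sequences(f, params, seed = seed + 100L + i)
    fams[[length(fams) + 1L]] <- f
  }
  dist <- build_paralog_distribution(fams, focal)
  fit <- fit_mixture(dist, k_max = k_max, seed = seed + 2L)
  expected <- 2 * (depth / 4) * syn_rate   # WGD age = depth/4
  best <- fit$means[which.min(abs(fit$means - expected))]
  list(expected_ks = expected, fitted_mean = best,
       relative_error = best / expected - 1, n_pairs = nrow(dist$pairs),
       fit = fit)
}
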