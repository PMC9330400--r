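#' Validate pipeline input files
#'
#' Checks the flat-file inputs of a run before any stage executes:
#' newick files must parse and gene labels must resolve to species-tree
#' tips; FASTA sequences must be in frame (length divisible by 3) and
#' free of internal stop codons; TSV tables must carry the expected
#' columns. Problems are returned as a report distinguishing errors
#' (stage would fail) from warnings (records would be skipped).
#'
#' @param paths named list with any of `species_tree`, `gene_trees`
#'   (newick, possibly multi-tree), `fasta`, `families` (TSV), `go`
#'   (TSV).
#' @return data frame with columns `item`, `severity`, `message`
#'   (zero rows when everything is clean).
#' @export
validate_inputs <- function(paths) {
  report <- list()
  add <- function(item, severity, message) {
    report[[length(report) + 1L]] <<- data.frame(
      item = item, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  sp_tree <- NULL
  if (!is.null(paths$species_tree)) {
    sp_tree <- tryCatch(ape::read.tree(paths$species_tree),
                        error = function(e) e)
    if (inherits(sp_tree, "error") || is.null(sp_tree)) {
      add("species_tree", "error",
          paste("malformed newick:",
                if (inherits(sp_tree, "error"))
                  conditionMessage(sp_tree) else "parse returned NULL"))
      sp_tree <- NULL
    }
  }
  if (!is.null(paths$gene_trees)) {
    gt <- tryCatch(ape::read.tree(paths$gene_trees),
                   error = function(e) e)
    if (inherits(gt, "error") || is.null(gt)) {
      add("gene_trees", "error",
          paste("malformed newick:",
                if (inherits(gt, "error")) conditionMessage(gt)
                else "parse returned NULL"))
    } else {
      if (inherits(gt, "phylo")) gt <- list(gt)
      if (!is.null(sp_tree)) {
        for (i in seq_along(gt)) {
          sp <- species_from_gene(gt[[i]]$tip.label)
          bad <- setdiff(unique(sp), sp_tree$tip.label)
          if (length(bad)) {
            add("gene_trees", "error",
                sprintf("tree %d: species %s absent from species tree",
                        i, paste(bad, collapse = ",")))
          }
        }
      }
    }
  }
  if (!is.null(paths$fasta)) {
    seqs <- tryCatch(read_fasta(paths$fasta), error = function(e) e)
    if (inherits(seqs, "error")) {
      add("fasta", "error", conditionMessage(seqs))
    } else {
      bad_len <- names(seqs)[nchar(seqs) %% 3 != 0]
      if (length(bad_len)) {
        add("fasta", "error",
            paste("length not divisible by 3:",
                  paste(bad_len, collapse = ",")))
      }
      with_stop <- names(seqs)[vapply(seqs, function(s) {
        if (nchar(s) %% 3 != 0) return(FALSE)
        ci <- .seq_to_codons(s)
        n <- length(ci)
        any(.codon_tables$is_stop[ci[-n]], na.rm = TRUE)
      }, logical(1))]
      if (length(with_stop)) {
        add("fasta", "warning",
            paste("internal stop codon in:",
                  paste(with_stop, collapse = ",")))
      }
    }
  }
  if (!is.null(paths$families)) {
    fam <- tryCatch(read_family_table(paths$families),
                    error = function(e) e)
    if (inherits(fam, "error")) {
      add("families", "error", conditionMessage(fam))
    } else if (!is.null(sp_tree)) {
      bad <- setdiff(unique(fam$species), sp_tree$tip.label)
      if (length(bad)) {
        add("families", "error",
            paste("species absent from species tree:",
                  paste(bad, collapse = ",")))
      }
    }
  }
  if (!is.null(paths$go)) {
    go <- tryCatch(read_go_table(paths$go), error = function(e) e)
    if (inherits(go, "error")) add("go", "error", conditionMessage(go))
  }
  if (length(report)) do.call(rbind, report) else
    data.frame(item = character(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Bundled demonstration scenario
#'
#' A small synthetic study used by the examples and the smoke tests:
#' a 6-taxon ladder tree of depth 300, background birth/death rates
#' 0.002/0.002 per gene per MY, one WGD at the midpoint of the branch
#' leading to node N4 with 20% retention, 200 conditioned families,
#' 200-codon genes at a synonymous rate tuned to put the WGD peak
#' near Ks 0.5.
#'
#' @param seed integer seed stored in the scenario.
#' @return scenario list, see [read_scenario()].
#' @export
demo_scenario <- function(seed = 42L) {
  list(
    tree = list(n_tips = 6L, depth = 300),
    rates = list(lambda = 0.002, mu = 0.002),
    wgds = list(list(branch = "N4", position = 0.5,
                     retention_rate = 0.2)),
    n_families = 200L,
    filters = list(outgroup_min = 1L, other_min = 1L,
                   max_per_taxon = 100L),
    seq = list(syn_rate = 0.0025, omega = 0.2, n_codons = 200L),
    go = list(n_categories = 10L, biased_categories = "GO:0001",
              enrichment_factor = 3),
    focal_species = "t6",
    ks = list(window = c(0.01, 5), k_max = 3L),
    # root prior matched to the simulator's single root copy; omit it
    # to fall back on the geometric-mean-of-family-size convention
    bd = list(subsets = 3L, subset_size = 60L, root_prior_mean = 1),
    design = list(n_trees_per_regime = 150L, positive_n_trees = 450L),
    alpha = 0.05,
    seed = as.integer(seed))
}

#' Run the WGD-placement pipeline on a scenario
#'
#' Executes the stages in dependency order on a synthetic scenario:
#' `simulate` (species tree, conditioned gene families, codon
#' sequences, GO table), `ks` (paralog Ks distribution of the focal
#' species, mixture fit, slope scan), `maps` (empirical duplication
#' profile), `bdtest` (rate estimation, null/positive pools, per-node
#' WGD calls) and `retention` (paralog assignment, retention rate, GO
#' enrichment). Outputs are written to `out_dir` as TSV/JSON and a run
#' manifest with input/output checksums is returned and written
#' alongside.
#'
#' @param config scenario list (see [demo_scenario()],
#'   [read_scenario()]) or path to a scenario YAML.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "ks", "maps", "bdtest", "retention")`; stages are
#'   always run in dependency order and later stages require the
#'   earlier ones in the same call.
#' @return a `run_manifest`: list with `package_version`,
#'   `config_hash`, `outputs` (named md5 checksums), `warnings`, and
#'   the in-memory `results`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "ks", "maps", "bdtest",
                                    "retention")) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- read_scenario(config)
  }
  .validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  results <- list()
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs[[name]] <<- unname(tools::md5sum(path))
  }
  seed <- config$seed

  tree <- make_ladder_tree(config$tree$n_tips, config$tree$depth)
  rates <- bd_rates(config$rates$lambda, config$rates$mu)
  wgds <- lapply(config$wgds, function(w) {
    wgd_event(w$branch, w$position %||% 0.5, w$retention_rate %||% 0.2)
  })

  if ("simulate" %in% stages) {
    sim <- simulate_family_set(tree, rates, wgds, config$n_families,
                               filters = config$filters %||% list(),
                               seed = seed)
    params <- seq_sim_params(config$seq$syn_rate,
                             config$seq$omega %||% 0.2,
                             config$seq$n_codons)
    for (i in seq_along(sim$families)) {
      f <- sim$families[[i]]
      if (!is.null(f$tree)) {
        sim$families[[i]]$cds <- evolve_codon_sequences(
          f, params, seed = seed + i)
      }
    }
    go_tab <- plant_go_bias(sim$families, config$go$n_categories,
                            config$go$biased_categories %||% character(0),
                            config$go$enrichment_factor %||% 1,
                            seed = seed + 1L)
    results$simulate <- list(tree = tree, families = sim$families,
                             rejections = sim$rejections,
                             go_table = go_tab)
    emit("species_tree.nwk", function(p) ape::write.tree(tree, p))
    emit("families.tsv", function(p)
      write_family_table(sim$families, p))
    emit("go.tsv", function(p) write_go_table(go_tab, p))
  }
  fams <- results$simulate$families
  if (is.null(fams) && length(setdiff(stages, "simulate"))) {
    stop("later stages require the simulate stage in the same call",
         call. = FALSE)
  }

  if ("ks" %in% stages) {
    dist <- build_paralog_distribution(fams, config$focal_species,
                                       window = config$ks$window %||%
                                         c(0.01, 5))
    fit <- fit_mixture(dist, k_max = config$ks$k_max %||% 4L,
                       seed = seed + 2L)
    scan <- sizer_scan(dist, alpha = config$alpha %||% 0.05)
    results$ks <- list(dist = dist, fit = fit, sizer = scan)
    emit("ks_pairs.tsv", function(p) write_ks_table(dist, p))
    emit("mixture.json", function(p) write_mixture_json(fit, p))
    emit("sizer.tsv", function(p)
      .write_tsv(as.data.frame.table(scan$class,
                                     responseName = "class"), p))
  }

  if ("maps" %in% stages) {
    trees <- lapply(fams, `[[`, "tree")
    prof <- duplication_profile(trees, tree)
    results$maps <- list(profile = prof)
    emit("profile.tsv", function(p) write_profile(prof, p))
  }

  if ("bdtest" %in% stages) {
    cnt <- family_count_matrix(fams, tree$tip.label)
    bd_cfg <- config$bd %||% list()
    re <- estimate_rates(cnt, tree,
                         subsets = bd_cfg$subsets %||% 10L,
                         subset_size = bd_cfg$subset_size %||% 500L,
                         seed = seed + 3L,
                         root_prior_mean = bd_cfg$root_prior_mean)
    dz <- config$design %||% list()
    npr <- dz$n_trees_per_regime %||% 1000L
    design <- simulation_design(
      regimes = data.frame(multiplier = c(1, 0.5, 3),
                           n_trees = rep(as.integer(npr), 3)),
      positive_n_trees = dz$positive_n_trees %||% 3000L,
      retention = dz$retention %||% 0.2)
    pools <- build_null_and_positive(
      tree, bd_rates(re$lambda_hat, re$mu_hat), design, wgds,
      seed = seed + 4L)
    calls <- call_wgd_all(results$maps$profile, pools$null,
                          pools$positive_ml, config$alpha %||% 0.05)
    results$bdtest <- list(rates = re, pools = pools, calls = calls)
    emit("rates.json", function(p)
      jsonlite::write_json(list(lambda_hat = re$lambda_hat,
                                mu_hat = re$mu_hat,
                                estimates = re$estimates),
                           p, auto_unbox = TRUE, digits = NA))
    emit("calls.tsv", function(p) .write_tsv(calls, p))
  }

  if ("retention" %in% stages) {
    fit <- results$ks$fit
    dist <- results$ks$dist
    comp <- which.max(fit$weights)
    asn <- assign_paralogs(dist, fit, comp)
    focal_genes <- unlist(lapply(fams, function(f)
      f$genes$gene_id[f$genes$species == config$focal_species]))
    rr <- retention_rate(asn, length(focal_genes))
    go_tab <- results$simulate$go_table
    par_genes <- unique(c(asn$gene1[asn$assigned],
                          asn$gene2[asn$assigned]))
    enr <- go_bias(go_tally(go_tab, par_genes), go_tally(go_tab))
    results$retention <- list(assignments = asn, rate = rr,
                              enrichment = enr)
    emit("assignments.tsv", function(p) .write_tsv(asn, p))
    emit("retention.json", function(p)
      jsonlite::write_json(rr, p, auto_unbox = TRUE, digits = NA))
    emit("enrichment.tsv", function(p)
      .write_tsv(as.data.frame(enr), p))
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("wgdplacer")),
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = as.list(outputs), warnings = warnings,
    results = results)
  unlink(cfg_file)
  class(manifest) <- "run_manifest"
  jsonlite::write_json(manifest[c("package_version", "config_hash",
                                  "outputs", "warnings")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

.validate_config <- function(config) {
  need <- c("tree", "rates", "n_families", "focal_species", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$tree$n_tips) || is.null(config$tree$depth)) {
    stop("config$tree needs n_tips and depth", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
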