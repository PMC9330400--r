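#' Gene birth/death rates
#'
#' @param lambda gene birth (duplication) rate, per gene per time unit.
#' @param mu gene death (loss) rate, per gene per time unit.
#' @return a `bd_rates` object.
#' @export
bd_rates <- function(lambda, mu) {
  if (lambda < 0 || mu < 0) stop("rates must be non-negative", call. = FALSE)
  structure(list(lambda = lambda, mu = mu), class = "bd_rates")
}

#' A hypothesized whole genome duplication event
#'
#' A WGD is placed on a species-tree branch, identified by the label of
#' the node the branch leads to (or `"root"` for the root branch), at a
#' relative position along the branch. Every gene lineage alive at the
#' event duplicates independently with probability `retention_rate`;
#' duplicates that are not retained leave no trace (any later loss of
#' retained copies is carried by the background death rate).
#'
#' @param branch child-node label of the species-tree branch carrying
#'   the event, or `"root"`.
#' @param position fraction along the branch, in (0, 1); midpoint by
#'   default, matching the usual positive-simulation protocol.
#' @param retention_rate per-lineage duplicate retention probability in
#'   \[0, 1\]; 0.2 is the conventional positive-simulation value.
#' @param id event identifier used to label duplication nodes.
#' @return a `wgd_event` object.
#' @export
wgd_event <- function(branch, position = 0.5, retention_rate = 0.2,
                      id = NULL) {
  if (position <= 0 || position >= 1) {
    stop("position must be strictly inside (0, 1)", call. = FALSE)
  }
  if (retention_rate < 0 || retention_rate > 1) {
    stop("retention_rate must be in [0, 1]", call. = FALSE)
  }
  if (is.null(id)) id <- paste0("wgd_", branch)
  structure(list(branch = branch, position = position,
                 retention_rate = retention_rate, id = id),
            class = "wgd_event")
}

# internal: index WGD events by species-tree child node, with absolute
# event times; root-branch events are returned separately.
.index_wgds <- function(prep, wgds) {
  by_edge <- vector("list", prep$n_node)
  root_events <- list()
  for (w in wgds) {
    stopifnot(inherits(w, "wgd_event"))
    ch <- .branch_child(prep, w$branch)
    if (identical(ch, "root")) {
      root_events <- c(root_events, list(w))
      next
    }
    t0 <- prep$times[prep$parent[ch]]
    t1 <- prep$times[ch]
    ev <- list(time = t0 + w$position * (t1 - t0),
               retention = w$retention_rate, id = w$id)
    by_edge[[ch]] <- c(by_edge[[ch]], list(ev))
  }
  for (ch in seq_along(by_edge)) {
    if (length(by_edge[[ch]]) > 1) {
      ord <- order(vapply(by_edge[[ch]], `[[`, numeric(1), "time"))
      by_edge[[ch]] <- by_edge[[ch]][ord]
    }
  }
  list(by_edge = by_edge, root = root_events)
}

# --- core forward simulation ----------------------------------------------

# Simulate one gene lineage entering the branch that leads to species
# node `node_to` at absolute time `t`, under a linear birth-death
# process with WGD episodes. Returns a nested-list gene subtree of the
# surviving descendants, or NULL if the lineage leaves none.
.walk_edge <- function(t, node_to, sim) {
  .walk_subedge(t, node_to, sim, 1L)
}

# as .walk_edge, but considering only WGD events from index `ev_from`
# onwards (a copy created at a WGD must not re-experience that WGD)
.walk_subedge <- function(t, node_to, sim, ev_from) {
  prep <- sim$prep
  t_end <- prep$times[node_to]
  events <- sim$wgds$by_edge[[node_to]]
  ev_idx <- ev_from
  rate <- sim$lambda + sim$mu
  repeat {
    t_wgd <- if (ev_idx <= length(events)) events[[ev_idx]]$time else Inf
    t_bd <- if (rate > 0) t + stats::rexp(1L, rate) else Inf
    if (t_bd < t_wgd && t_bd < t_end) {
      if (stats::runif(1L) < sim$lambda / rate) {
        a <- .walk_subedge(t_bd, node_to, sim, ev_idx)
        b <- .walk_subedge(t_bd, node_to, sim, ev_idx)
        return(.join2(a, b, t_bd, "dup", "background"))
      }
      return(NULL)
    }
    if (t_wgd < t_end) {
      ev <- events[[ev_idx]]
      ev_idx <- ev_idx + 1L
      if (stats::runif(1L) < ev$retention) {
        a <- .walk_subedge(ev$time, node_to, sim, ev_idx)
        b <- .walk_subedge(ev$time, node_to, sim, ev_idx)
        return(.join2(a, b, ev$time, "dup", ev$id))
      }
      t <- ev$time
      next
    }
    return(.at_node(node_to, sim))
  }
}

.at_node <- function(node, sim) {
  prep <- sim$prep
  if (node <= prep$n_tip) {
    return(list(time = prep$times[node], type = "tip",
                species = prep$labels[node], children = NULL))
  }
  ch <- prep$children[[node]]
  a <- .walk_edge(prep$times[node], ch[1], sim)
  b <- .walk_edge(prep$times[node], ch[2], sim)
  .join2(a, b, prep$times[node], "spec", NA_character_)
}

.join2 <- function(a, b, time, type, origin) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(time = time, type = type, origin = origin, children = list(a, b))
}

# apply root-branch WGDs, then speciate at the root
.walk_root <- function(sim, ev_idx) {
  events <- sim$wgds$root
  if (ev_idx > length(events)) return(.at_node(sim$prep$root, sim))
  ev <- events[[ev_idx]]
  if (stats::runif(1L) < ev$retention_rate) {
    a <- .walk_root(sim, ev_idx + 1L)
    b <- .walk_root(sim, ev_idx + 1L)
    return(.join2(a, b, 0, "dup", ev$id))
  }
  .walk_root(sim, ev_idx + 1L)
}

# --- subtree -> phylo conversion ------------------------------------------

.count_tips <- function(st) {
  if (is.null(st$children)) return(1L)
  sum(vapply(st$children, .count_tips, integer(1)))
}

.subtree_to_family <- function(st, id, prep) {
  if (is.null(st)) {
    return(structure(list(id = id, genes = data.frame(
      gene_id = character(0), species = character(0),
      stringsAsFactors = FALSE), tree = NULL, extinct = TRUE),
      class = "gene_family"))
  }
  n_tip <- .count_tips(st)
  sp_counter <- new.env(parent = emptyenv())
  tip_lab <- character(n_tip)
  tip_sp <- character(n_tip)
  if (n_tip == 1L) {
    # single surviving gene: no internal structure representable
    sp <- .leaf_species(st)
    gene <- paste0(sp, "_g1")
    return(structure(list(id = id, genes = data.frame(
      gene_id = gene, species = sp, stringsAsFactors = FALSE),
      tree = NULL, extinct = FALSE), class = "gene_family"))
  }
  # recursive preorder build
  build <- local({
    edges_l <- list(); len_l <- list(); labs <- list()
    tip_i <- 0L; node_i <- n_tip
    rec <- function(node, parent_idx, parent_time) {
      if (is.null(node$children)) {
        tip_i <<- tip_i + 1L
        k <- get0(node$species, envir = sp_counter, ifnotfound = 0L) + 1L
        assign(node$species, k, envir = sp_counter)
        tip_lab[tip_i] <<- paste0(node$species, "_g", k)
        tip_sp[tip_i] <<- node$species
        if (parent_idx > 0L) {
          edges_l[[length(edges_l) + 1L]] <<- c(parent_idx, tip_i)
          len_l[[length(len_l) + 1L]] <<- node$time - parent_time
        }
        return(invisible(NULL))
      }
      node_i <<- node_i + 1L
      me <- node_i
      labs[[me - n_tip]] <<- if (identical(node$type, "dup")) {
        paste0("D:", node$origin)
      } else if (identical(node$type, "root")) "R" else "S"
      if (parent_idx > 0L) {
        edges_l[[length(edges_l) + 1L]] <<- c(parent_idx, me)
        len_l[[length(len_l) + 1L]] <<- node$time - parent_time
      }
      for (ch in node$children) rec(ch, me, node$time)
      invisible(NULL)
    }
    rec(st, 0L, st$time)
    list(edge = do.call(rbind, edges_l), len = unlist(len_l),
         labs = unlist(labs), n_node = node_i - n_tip)
  })
  phy <- structure(list(edge = build$edge, edge.length = build$len,
                        Nnode = build$n_node, tip.label = tip_lab,
                        node.label = build$labs),
                   class = "phylo", order = "cladewise")
  genes <- data.frame(gene_id = tip_lab, species = tip_sp,
                      stringsAsFactors = FALSE)
  structure(list(id = id, genes = genes, tree = phy, extinct = FALSE),
            class = "gene_family")
}

.leaf_species <- function(st) {
  while (!is.null(st$children)) st <- st$children[[1]]
  st$species
}

#' Simulate one gene family along a species tree
#'
#' Forward simulation of a gene family under a linear birth-death
#' process: each gene lineage duplicates at rate lambda and dies at
#' rate mu along every branch, lineages follow both daughter lineages
#' at speciations, and at each [wgd_event()] every lineage alive at the
#' event duplicates independently with probability equal to the event's
#' retention rate. The returned family carries the true gene tree, with
#' every duplication node labelled by its origin (`D:background` or
#' `D:<wgd id>`); speciation nodes are labelled `S`.
#'
#' @param tree species tree ([ape::phylo], ultrametric, branch lengths
#'   in time units).
#' @param rates a [bd_rates()] object.
#' @param wgds list of [wgd_event()] objects (possibly empty).
#' @param root_copies number of independent gene copies at the root
#'   (they are joined by a root polytomy labelled `R` when more than
#'   one survives).
#' @param seed integer seed; required, all stochastic generators in
#'   this package refuse to run unseeded.
#' @param id family identifier.
#' @return a `gene_family`: list with `id`, `genes` (data frame of
#'   `gene_id`, `species`), `tree` (phylo, or `NULL` when fewer than
#'   two genes survive) and `extinct` flag.
#' @export
simulate_gene_family <- function(tree, rates, wgds = list(),
                                 root_copies = 1L, seed, id = "fam1") {
  .require_seed(seed)
  withr::with_seed(seed, {
    prep <- .tree_prep(tree)
    sim <- list(prep = prep, lambda = rates$lambda, mu = rates$mu,
                wgds = .index_wgds(prep, wgds))
    .simulate_family_core(sim, root_copies, id)
  })
}

.require_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
}

.simulate_family_core <- function(sim, root_copies, id) {
  if (root_copies < 1) stop("root_copies must be at least 1", call. = FALSE)
  copies <- vector("list", root_copies)
  for (i in seq_len(root_copies)) copies[[i]] <- .walk_root(sim, 1L)
  copies <- Filter(Negate(is.null), copies)
  st <- if (length(copies) == 0L) NULL
        else if (length(copies) == 1L) copies[[1]]
        else list(time = 0, type = "root", origin = NA_character_,
                  children = copies)
  .subtree_to_family(st, id, sim$prep)
}

#' Simulate a conditioned set of gene families
#'
#' Repeatedly simulates gene families and keeps only those passing the
#' conditioning filter used for rate estimation and gene-tree sorting:
#' at least one surviving copy in the outgroup, at least one copy in
#' some non-outgroup taxon, and no taxon exceeding the per-taxon copy
#' cap (100 by default). Rejected families are tallied by reason.
#'
#' @inheritParams simulate_gene_family
#' @param n_families number of surviving families to collect.
#' @param filters list with `outgroup_min` (default 1), `other_min`
#'   (default 1) and `max_per_taxon` (default 100).
#' @param outgroup outgroup tip label; defaults to the tree attribute.
#' @param root_copies gene copies at the root, as in
#'   [simulate_gene_family()].
#' @return list with `families` (list of `gene_family`), `rejections`
#'   (named counts by reason) and `attempts`.
#' @export
simulate_family_set <- function(tree, rates, wgds = list(), n_families,
                                filters = list(), seed, outgroup = NULL,
                                root_copies = 1L) {
  .require_seed(seed)
  if (n_families < 1) stop("n_families must be at least 1", call. = FALSE)
  f <- utils::modifyList(list(outgroup_min = 1L, other_min = 1L,
                              max_per_taxon = 100L), filters)
  og <- .resolve_outgroup(tree, outgroup)
  withr::with_seed(seed, {
    prep <- .tree_prep(tree)
    sim <- list(prep = prep, lambda = rates$lambda, mu = rates$mu,
                wgds = .index_wgds(prep, wgds))
    fams <- vector("list", n_families)
    got <- 0L
    attempts <- 0L
    rej <- c(extinct = 0L, no_outgroup = 0L, no_other = 0L, over_cap = 0L)
    while (got < n_families) {
      attempts <- attempts + 1L
      fam <- .simulate_family_core(sim, root_copies,
                                   paste0("fam", got + 1L))
      reason <- .filter_family(fam, og, f)
      if (is.null(reason)) {
        got <- got + 1L
        fams[[got]] <- fam
      } else {
        rej[reason] <- rej[reason] + 1L
      }
      if (attempts == 1e5L && got < attempts * 1e-4) {
        stop("degenerate parameters: acceptance probability below 1e-4",
             call. = FALSE)
      }
    }
    list(families = fams, rejections = rej, attempts = attempts)
  })
}

# NULL if the family passes, otherwise the rejection reason
.filter_family <- function(fam, outgroup, f) {
  if (fam$extinct) return("extinct")
  cnt <- table(fam$genes$species)
  n_og <- if (outgroup %in% names(cnt)) cnt[[outgroup]] else 0L
  n_other <- sum(cnt[names(cnt) != outgroup])
  if (n_og < f$outgroup_min) return("no_outgroup")
  if (n_other < f$other_min) return("no_other")
  if (any(cnt > f$max_per_taxon)) return("over_cap")
  NULL
}

#' Family-by-species gene count matrix
#'
#' @param families list of `gene_family` objects.
#' @param species character vector of species (columns); defaults to
#'   all species seen.
#' @return integer matrix, one row per family.
#' @export
family_count_matrix <- function(families, species = NULL) {
  if (is.null(species)) {
    species <- sort(unique(unlist(lapply(families, function(f)
      f$genes$species))))
  }
  m <- matrix(0L, length(families), length(species),
              dimnames = list(vapply(families, `[[`, character(1), "id"),
                              species))
  for (i in seq_along(families)) {
    cnt <- table(factor(families[[i]]$genes$species, levels = species))
    m[i, ] <- as.integer(cnt)
  }
  m
}

#' Genes descended from a named WGD event
#'
#' Walks the family's gene tree and returns the tips having at least
#' one ancestral duplication node attributed to the given WGD (or to
#' any WGD when `wgd_id` is `NULL`).
#'
#' @param family a `gene_family` with a gene tree.
#' @param wgd_id WGD event id, or `NULL` for any non-background event.
#' @return character vector of gene ids (possibly empty).
#' @export
wgd_genes <- function(family, wgd_id = NULL) {
  phy <- family$tree
  if (is.null(phy)) return(character(0))
  n_tip <- length(phy$tip.label)
  is_wgd_node <- vapply(phy$node.label, function(l) {
    startsWith(l, "D:") && !identical(l, "D:background") &&
      (is.null(wgd_id) || identical(l, paste0("D:", wgd_id)))
  }, logical(1))
  if (!any(is_wgd_node)) return(character(0))
  marked <- which(is_wgd_node) + n_tip
  hit <- logical(n_tip)
  # propagate: a tip is a WGD descendant if any ancestor is marked
  anc_marked <- logical(n_tip + phy$Nnode)
  anc_marked[marked] <- TRUE
  for (e in seq_len(nrow(phy$edge))) {   # cladewise: parents first
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    anc_marked[ch] <- anc_marked[ch] || anc_marked[p]
  }
  phy$tip.label[anc_marked[seq_len(n_tip)]]
}
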