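#' Extract species tags from gene-tree tip labels
#'
#' The package convention names genes `<species>_<suffix>`; the species
#' is everything before the final underscore. Supply a custom function
#' or named vector to [lca_map()]/[filter_and_root()] for other naming
#' schemes.
#'
#' @param labels character vector of gene labels.
#' @return character vector of species ids.
#' @export
species_from_gene <- function(labels) {
  sub("_[^_]*$", "", labels)
}

.species_of <- function(labels, species_map) {
  if (is.null(species_map)) return(species_from_gene(labels))
  if (is.function(species_map)) return(species_map(labels))
  out <- unname(species_map[labels])
  if (anyNA(out)) stop("species_map does not cover gene(s): ",
                       paste(labels[is.na(out)], collapse = ", "),
                       call. = FALSE)
  out
}

#' Filter gene trees by occupancy and root them on the outgroup
#'
#' Keeps gene trees whose species occupancy (fraction of species-tree
#' tips represented at least once) meets the threshold and which
#' contain at least one outgroup gene; each survivor is rooted on its
#' outgroup genes. When the outgroup genes are not monophyletic the
#' tree is rooted on the largest outgroup-only clade and a warning is
#' recorded. Polytomies are resolved deterministically to zero-length
#' ladders before mapping.
#'
#' @param gene_trees list of [ape::phylo] gene trees.
#' @param species_tree ladderized species tree (checked with
#'   [check_ladder()]).
#' @param occupancy minimum fraction of species present (default 0.45).
#' @param outgroup outgroup tip label; defaults to the species-tree
#'   attribute.
#' @param species_map optional gene-to-species map (function or named
#'   vector); see [species_from_gene()].
#' @return list with `trees` (rooted, binary gene trees), `log` (data
#'   frame of rejected/warned trees with reasons), `kept` (indices of
#'   survivors).
#' @export
filter_and_root <- function(gene_trees, species_tree, occupancy = 0.45,
                            outgroup = NULL, species_map = NULL) {
  check_ladder(species_tree)
  og <- .resolve_outgroup(species_tree, outgroup)
  n_sp <- length(species_tree$tip.label)
  kept <- integer(0)
  trees <- list()
  log <- list()
  note <- function(i, status, reason) {
    log[[length(log) + 1L]] <<- data.frame(tree = i, status = status,
                                           reason = reason,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_along(gene_trees)) {
    phy <- gene_trees[[i]]
    sp <- .species_of(phy$tip.label, species_map)
    unknown <- setdiff(unique(sp), species_tree$tip.label)
    if (length(unknown)) {
      note(i, "rejected", paste0("unknown species: ",
                                 paste(unknown, collapse = ",")))
      next
    }
    occ <- length(unique(sp)) / n_sp
    if (occ < occupancy) {
      note(i, "rejected", sprintf("occupancy %.2f < %.2f", occ,
                                  occupancy))
      next
    }
    og_tips <- phy$tip.label[sp == og]
    if (length(og_tips) == 0L) {
      note(i, "rejected", "no outgroup gene; rooting impossible")
      next
    }
    rooted <- .root_on_outgroup(phy, og_tips)
    if (!is.null(rooted$warning)) note(i, "warning", rooted$warning)
    phy <- rooted$tree
    if (!ape::is.binary(phy)) {
      phy <- ape::multi2di(phy, random = FALSE)
      phy$edge.length[is.na(phy$edge.length)] <- 0
      note(i, "warning", "polytomy resolved deterministically")
    }
    kept <- c(kept, i)
    trees[[length(trees) + 1L]] <- phy
  }
  if (length(trees) == 0L) stop("no gene tree survives filtering",
                                call. = FALSE)
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(tree = integer(0), status = character(0),
               reason = character(0))
  list(trees = trees, log = log_df, kept = kept)
}

# Root a gene tree on its outgroup genes; falls back to the largest
# outgroup-only clade when they are not monophyletic.
.root_on_outgroup <- function(phy, og_tips) {
  if (length(og_tips) == length(phy$tip.label)) {
    return(list(tree = phy, warning = "all genes are outgroup genes"))
  }
  un <- ape::unroot(phy)
  if (length(og_tips) == 1L ||
      ape::is.monophyletic(un, og_tips)) {
    return(list(tree = ape::root(un, outgroup = og_tips,
                                 resolve.root = TRUE),
                warning = NULL))
  }
  # root at a non-outgroup tip: every outgroup-only split then shows
  # up as a clade; take the largest
  other <- setdiff(phy$tip.label, og_tips)[1]
  tmp <- ape::root(un, outgroup = other, resolve.root = TRUE)
  clades <- ape::prop.part(tmp)
  labs <- attr(clades, "labels")
  sizes <- vapply(clades, function(cl) {
    tips <- labs[cl]
    if (all(tips %in% og_tips)) length(tips) else 0L
  }, integer(1))
  best <- which.max(sizes)
  pick <- if (sizes[best] > 0) labs[clades[[best]]] else og_tips[1]
  list(tree = ape::root(un, outgroup = pick, resolve.root = TRUE),
       warning = "outgroup genes non-monophyletic; rooted on largest outgroup-only clade")
}

#' LCA-map a gene tree onto a species tree
#'
#' Standard soft-parsimony reconciliation: every gene-tree node is
#' mapped to the most recent species-tree node whose clade contains
#' all the node's descendant species, and an internal gene-tree node
#' is a duplication iff its map equals the map of at least one child.
#'
#' @param gene_tree rooted [ape::phylo] gene tree.
#' @param species_tree rooted species tree.
#' @param species_map optional gene-to-species map; see
#'   [species_from_gene()].
#' @return data frame with one row per gene-tree node (tips included):
#'   `node`, `is_tip`, `map_node` (species-tree node index),
#'   `map_label`, `duplication`.
#' @export
lca_map <- function(gene_tree, species_tree, species_map = NULL) {
  ctx <- .lca_context(species_tree)
  res <- .lca_map_core(gene_tree, ctx, species_map)
  n_node <- length(res$map_node)
  data.frame(
    node = seq_len(n_node), is_tip = seq_len(n_node) <= res$n_tip,
    map_node = res$map_node,
    map_label = ctx$sprep$labels[res$map_node],
    duplication = res$dup, stringsAsFactors = FALSE)
}

# reusable reconciliation context: species-tree prep + clade bitmasks
# (species sets are encoded as integer bitmasks; up to 30 species)
.lca_context <- function(species_tree) {
  sprep <- .tree_prep(species_tree)
  n_sp <- sprep$n_tip
  if (n_sp > 30L) stop("more than 30 species not supported by the ",
                       "bitmask mapper", call. = FALSE)
  clade <- integer(sprep$n_node)
  clade[seq_len(n_sp)] <- bitwShiftL(1L, seq_len(n_sp) - 1L)
  po <- rev(ape::reorder.phylo(species_tree, "cladewise")$edge[, 2])
  for (nd in po) {
    p <- sprep$parent[nd]
    clade[p] <- bitwOr(clade[p], clade[nd])
  }
  list(sprep = sprep, clade = clade, n_sp = n_sp)
}

.lca_map_core <- function(gene_tree, ctx, species_map = NULL) {
  sprep <- ctx$sprep
  sp <- .species_of(gene_tree$tip.label, species_map)
  sp_idx <- match(sp, sprep$phy$tip.label)
  if (anyNA(sp_idx)) {
    bad <- gene_tree$tip.label[is.na(sp_idx)]
    stop("unknown species label for gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gt <- gene_tree
  if (!identical(attr(gt, "order"), "cladewise")) {
    gt <- ape::reorder.phylo(gt, "cladewise")
  }
  n_tip <- length(gt$tip.label)
  n_node <- n_tip + gt$Nnode
  masks <- integer(n_node)
  masks[seq_len(n_tip)] <- bitwShiftL(1L, sp_idx - 1L)
  ne <- nrow(gt$edge)
  ep <- gt$edge[, 1]; ec <- gt$edge[, 2]
  for (e in ne:1) {                       # postorder accumulation
    masks[ep[e]] <- bitwOr(masks[ep[e]], masks[ec[e]])
  }
  clade <- ctx$clade
  parent <- sprep$parent
  map_node <- integer(n_node)
  for (nd in seq_len(n_node)) {
    m <- masks[nd]
    s <- which(clade == m)[1]             # exact clade match is common
    if (is.na(s)) {
      s <- sprep$root
      # walk down: descend while a child clade still covers the set
      repeat {
        ch <- sprep$children[[s]]
        nxt <- NA_integer_
        for (c2 in ch) {
          if (bitwAnd(clade[c2], m) == m) { nxt <- c2; break }
        }
        if (is.na(nxt)) break
        s <- nxt
      }
    }
    map_node[nd] <- s
  }
  dup <- logical(n_node)
  dup_e <- map_node[ep] == map_node[ec]
  if (any(dup_e)) dup[unique(ep[dup_e])] <- TRUE
  list(map_node = map_node, dup = dup, n_tip = n_tip)
}

#' Per-node duplication profile over a set of gene trees
#'
#' Aggregates [lca_map()] across gene trees, MAPS-style: for each
#' internal species-tree node, `n_mapped` counts the gene trees with at
#' least one internal node mapping there, and `n_duplicated` counts
#' those in which at least one such node is a duplication. The
#' proportion `n_duplicated / n_mapped` is the subtree duplication
#' statistic compared between empirical and simulated tree sets.
#' Within-species expansions (duplications mapping to species tips)
#' are tallied separately and excluded from the internal-node profile.
#'
#' @param gene_trees list of rooted gene trees (e.g. `$trees` from
#'   [filter_and_root()], or simulated family trees).
#' @param species_tree rooted species tree.
#' @param species_map optional gene-to-species map.
#' @return a `dup_profile`: data frame with `node` (species-tree node
#'   index), `label`, `n_mapped`, `n_duplicated`, `proportion`, plus
#'   attributes `tip_expansions` (named counts of gene trees with
#'   tip-mapped duplications) and `n_trees`.
#' @export
duplication_profile <- function(gene_trees, species_tree,
                                species_map = NULL) {
  sprep <- .tree_prep(species_tree)
  internal <- (sprep$n_tip + 1L):sprep$n_node
  n_mapped <- n_dup <- stats::setNames(integer(length(internal)),
                                       sprep$labels[internal])
  tip_exp <- stats::setNames(integer(sprep$n_tip),
                             sprep$labels[seq_len(sprep$n_tip)])
  n_used <- 0L
  ctx <- .lca_context(species_tree)
  for (phy in gene_trees) {
    if (is.null(phy)) next
    n_used <- n_used + 1L
    mp <- .lca_map_core(phy, ctx, species_map)
    int_nodes <- (mp$n_tip + 1L):length(mp$map_node)
    map <- mp$map_node[int_nodes]
    dup <- mp$dup[int_nodes]
    at_internal <- map > sprep$n_tip
    mapped_nodes <- unique(map[at_internal])
    dup_nodes <- unique(map[at_internal & dup])
    idx <- match(mapped_nodes, internal)
    n_mapped[idx] <- n_mapped[idx] + 1L
    idx <- match(dup_nodes, internal)
    if (length(idx)) n_dup[idx] <- n_dup[idx] + 1L
    t_ex <- unique(map[!at_internal & dup])
    if (length(t_ex)) tip_exp[t_ex] <- tip_exp[t_ex] + 1L
  }
  prop <- ifelse(n_mapped > 0, n_dup / n_mapped, NA_real_)
  out <- data.frame(node = internal,
                    label = sprep$labels[internal],
                    n_mapped = as.integer(n_mapped),
                    n_duplicated = as.integer(n_dup),
                    proportion = prop, stringsAsFactors = FALSE)
  attr(out, "tip_expansions") <- tip_exp
  attr(out, "n_trees") <- n_used
  class(out) <- c("dup_profile", "data.frame")
  out
}
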