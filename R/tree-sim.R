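#' Build a ladderized (caterpillar) ultrametric species tree
#'
#' Constructs a fully pectinate rooted ultrametric tree with `n_tips`
#' tips and the given root depth. Divergence times are evenly spaced
#' between the root and the shallowest split. Tip `t1` diverges at the
#' root and is designated the outgroup; internal nodes are labelled
#' `N1` (root) through `N<n_tips - 1>` from root to shallowest.
#'
#' Gene-tree sorting analyses of ancient polyploidy (the MAPS family of
#' methods) require exactly this tree shape as input, which is why the
#' generator only produces caterpillars.
#'
#' @param n_tips number of tips (at least 3).
#' @param depth root age, in arbitrary time units (e.g. MY).
#' @param seed optional integer; the construction is deterministic, the
#'   argument exists for signature uniformity with the stochastic
#'   generators and is ignored.
#' @return an [ape::phylo] object with node labels and an `"outgroup"`
#'   attribute naming the outgroup tip.
#' @examples
#' phy <- make_ladder_tree(6, 300)
#' attr(phy, "outgroup")
#' @export
make_ladder_tree <- function(n_tips, depth, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 3) {
    stop("n_tips must be at least 3", call. = FALSE)
  }
  n_tips <- as.integer(n_tips)
  if (!is.numeric(depth) || depth <= 0) {
    stop("depth must be positive", call. = FALSE)
  }
  # split time of node Nk, measured from the root
  s <- depth * (seq_len(n_tips - 1) - 1) / (n_tips - 1)
  fmt <- function(x) sprintf("%.12g", x)
  k <- n_tips - 1
  core <- paste0("(t", n_tips, ":", fmt(depth - s[k]),
                 ",t", k, ":", fmt(depth - s[k]), ")N", k)
  if (n_tips > 3) {
    for (j in seq(n_tips - 2, 2)) {
      core <- paste0("(", core, ":", fmt(s[j + 1] - s[j]),
                     ",t", j, ":", fmt(depth - s[j]), ")N", j)
    }
  }
  nwk <- paste0("(", core, ":", fmt(s[2]), ",t1:", fmt(depth), ")N1;")
  phy <- ape::read.tree(text = nwk)
  attr(phy, "outgroup") <- "t1"
  phy
}

#' Check that a species tree is ladderized
#'
#' A caterpillar tree is required by the duplication-mapping engine:
#' every internal node must have at least one tip child (the deepest
#' node has two). Returns `TRUE` invisibly on success and raises an
#' error naming the first violating node otherwise.
#'
#' @param tree a rooted [ape::phylo] species tree.
#' @return `TRUE`, invisibly.
#' @export
check_ladder <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  for (nd in seq_len(tree$Nnode) + n_tip) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    if (!any(ch <= n_tip)) {
      lab <- .node_label(tree, nd)
      stop("tree is not ladderized: internal node ", lab,
           " has no tip child", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# --- internal species-tree bookkeeping ------------------------------------

.node_label <- function(phy, nd) {
  n_tip <- length(phy$tip.label)
  if (nd <= n_tip) return(phy$tip.label[nd])
  if (!is.null(phy$node.label) && nzchar(phy$node.label[nd - n_tip])) {
    return(phy$node.label[nd - n_tip])
  }
  paste0("node", nd)
}

# distance of every node from the root, in branch-length units
.node_times <- function(phy) {
  ape::node.depth.edgelength(phy)
}

# Resolve the outgroup tip: explicit argument, then tree attribute.
.resolve_outgroup <- function(tree, outgroup = NULL) {
  og <- if (is.null(outgroup)) attr(tree, "outgroup") else outgroup
  if (is.null(og)) stop("no outgroup given and tree carries none",
                        call. = FALSE)
  if (!og %in% tree$tip.label) stop("outgroup '", og,
                                    "' is not a tip of the tree",
                                    call. = FALSE)
  og
}

# Per-node traversal structure used by the simulator and the mapper.
.tree_prep <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  children <- vector("list", n_node)
  parent <- integer(n_node)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    c <- phy$edge[e, 2]
    children[[p]] <- c(children[[p]], c)
    parent[c] <- p
  }
  labels <- vapply(seq_len(n_node), function(nd) .node_label(phy, nd),
                   character(1))
  list(phy = phy, n_tip = n_tip, n_node = n_node, root = n_tip + 1L,
       children = children, parent = parent, times = .node_times(phy),
       labels = labels)
}

# Map a branch id (child-node label, or "root") to the child node index.
.branch_child <- function(prep, branch) {
  if (identical(branch, "root")) return("root")
  hit <- which(prep$labels == branch)
  if (length(hit) != 1L) {
    stop("branch '", branch, "' does not name a node of the species tree",
         call. = FALSE)
  }
  if (hit == prep$root) stop("branch '", branch, "' is the root node; ",
                             "use branch = \"root\" for the root branch",
                             call. = FALSE)
  hit
}
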