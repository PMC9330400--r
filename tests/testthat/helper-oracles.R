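# Independent oracles used to cross-check the package's own
# implementations on small inputs.

# --- NG86 brute-force counter ---------------------------------------------
# Written from first principles against the published convention:
# per-position synonymous site fraction = syn changes / non-stop
# changes; differences averaged over all mutational pathways that do
# not pass through a stop codon (all pathways, stop steps counted as
# nonsynonymous, if every pathway is blocked); JC correction per site
# class.

oracle_gc <- Biostrings::GENETIC_CODE
oracle_bases <- c("A", "C", "G", "T")

oracle_translate <- function(codon) unname(oracle_gc[codon])

oracle_site_counts <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(oracle_bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) == "*") next
      nonstop <- nonstop + 1
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(S = s, N = 3 - s)
}

oracle_pair_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(Sd = 0, Nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) {
        out[[length(out) + 1]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
      }
      out
    }
  }
  score <- function(order, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate(nxt) == "*" && !allow_stop) return(NULL)
      if (oracle_translate(cur) != "*" && oracle_translate(nxt) != "*" &&
          oracle_translate(cur) == oracle_translate(nxt)) {
        sd <- sd + 1
      } else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, score, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms, score, allow_stop = TRUE)
  avg <- Reduce(`+`, res) / length(res)
  c(Sd = avg[1], Nd = avg[2])
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  keep <- oracle_translate(ca) != "*" & oracle_translate(cb) != "*"
  ca <- ca[keep]; cb <- cb[keep]
  Sa <- sum(vapply(ca, function(c) oracle_site_counts(c)["S"], numeric(1)))
  Sb <- sum(vapply(cb, function(c) oracle_site_counts(c)["S"], numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- unname(rowSums(vapply(seq_along(ca), function(i)
    oracle_pair_diff(ca[i], cb[i]), numeric(2))))
  jc <- function(p) if (1 - 4 * p / 3 <= 1e-12) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = unname(d[1]), Nd = unname(d[2]),
       Ks = jc(if (S > 0) d[1] / S else 0),
       Ka = jc(if (N > 0) d[2] / N else 0))
}

random_sense_codon_seq <- function(n_codons) {
  codons <- names(oracle_gc)[oracle_gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# --- exact Fisher oracle ---------------------------------------------------
# Two-sided Fisher p for a 2x2 table by exhaustive enumeration of all
# tables with the observed margins, summing the probabilities of
# tables no more probable than the observed one (with the customary
# 1 + 1e-7 tolerance on the probability comparison).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
  }
  all_lp <- vapply(lo:hi, logp, numeric(1))
  obs_lp <- logp(tab[1, 1])
  sum(exp(all_lp[all_lp <= obs_lp + log(1 + 1e-7)]))
}

# --- LCA reconciliation oracle --------------------------------------------
# Maps every gene-tree node to the species-tree MRCA of its descendant
# species using ape's getMRCA, independently of the package's bitmask
# walker; duplication iff the map equals a child's map.
oracle_lca <- function(gene_tree, species_tree) {
  n_tip <- length(gene_tree$tip.label)
  n_node <- n_tip + gene_tree$Nnode
  tipsets <- vector("list", n_node)
  for (i in seq_len(n_tip)) tipsets[[i]] <- gene_tree$tip.label[i]
  clades <- ape::prop.part(gene_tree)
  labs <- attr(clades, "labels")
  for (nd in (n_tip + 1):n_node) {
    tipsets[[nd]] <- labs[clades[[nd - n_tip]]]
  }
  map <- integer(n_node)
  for (nd in seq_len(n_node)) {
    sp <- unique(species_from_gene(tipsets[[nd]]))
    map[nd] <- if (length(sp) == 1) {
      which(species_tree$tip.label == sp)
    } else ape::getMRCA(species_tree, sp)
  }
  dup <- logical(n_node)
  for (nd in (n_tip + 1):n_node) {
    ch <- gene_tree$edge[gene_tree$edge[, 1] == nd, 2]
    dup[nd] <- any(map[ch] == map[nd])
  }
  list(map = map, dup = dup)
}

# random rooted binary gene tree over a species set, with possibly
# repeated species (multi-copy genes)
random_gene_tree <- function(species, n_leaves) {
  sp <- sample(species, n_leaves, replace = TRUE)
  labs <- paste0(sp, "_g", seq_len(n_leaves))
  phy <- ape::rtree(n_leaves, tip.label = labs)
  phy
}

# --- chi-squared residual oracle ------------------------------------------
oracle_residuals <- function(obs, bg) {
  expected <- sum(obs) * bg / sum(bg)
  list(expected = expected,
       residual = (obs - expected) / sqrt(expected),
       statistic = sum((obs - expected)^2 / expected))
}
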