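#' Pairwise Ka/Ks by NG86 counting with Jukes-Cantor correction
#'
#' Estimates synonymous (Ks) and nonsynonymous (Ka) substitutions per
#' site between two in-frame coding sequences using Nei-Gojobori (1986)
#' site and difference counting (pathway-averaged for codons differing
#' at more than one position, stop-codon pathways excluded) followed by
#' the Jukes-Cantor multiple-hit correction applied separately to each
#' site class. Codons containing non-ACGT characters or stop codons in
#' either sequence are excluded from the counts.
#'
#' When the proportion of differences in a site class reaches the
#' Jukes-Cantor domain boundary (p >= 3/4) the corrected estimate is
#' undefined and returned as `NA` with the corresponding `saturated`
#' flag set; such pairs are the "saturated counting" cases that Ks
#' analysis windows are designed to exclude.
#'
#' @param cds_a,cds_b nucleotide strings of equal length, divisible
#'   by 3.
#' @return list with `Ka`, `Ks`, site counts `N`, `S`, difference
#'   counts `Nd`, `Sd`, the number of codons used, and logical flags
#'   `saturated_ka`, `saturated_ks`.
#' @export
estimate_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  a <- .seq_to_codons(cds_a)
  b <- .seq_to_codons(cds_b)
  tb <- .codon_tables
  ok <- !is.na(a) & !is.na(b) & !tb$is_stop[a] & !tb$is_stop[b]
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0L) stop("no scorable codons", call. = FALSE)
  # NG86 sites: average of the two sequences' site counts
  S <- (sum(tb$syn_sites[a]) + sum(tb$syn_sites[b])) / 2
  N <- (sum(tb$nonsyn_sites[a]) + sum(tb$nonsyn_sites[b])) / 2
  Sd <- 0; Nd <- 0
  diff <- which(a != b)
  for (i in diff) {
    d <- .codon_pair_diff(a[i], b[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    # the 1e-12 guard keeps exact-saturation cases (p = 3/4 in rational
    # arithmetic) from flipping on summation-order float error
    if (arg <= 1e-12) return(NA_real_)
    -3 / 4 * log(arg)
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jc(pS); Ka <- jc(pN)
  list(Ka = Ka, Ks = Ks, S = S, N = N, Sd = Sd, Nd = Nd,
       n_codons = length(a),
       saturated_ks = is.na(Ks), saturated_ka = is.na(Ka))
}

#' Paralog Ks age distribution for one species
#'
#' Scores every within-family, within-species gene pair with
#' [estimate_ks()] and retains pairs whose Ks falls inside the analysis
#' window (\[0.01, 5\] by default; values below the lower bound are
#' mostly alleles/assembly artefacts, values above it are saturated).
#'
#' With `dedup = TRUE` the non-independence of pairs within large
#' families is corrected by node weighting: genes of a family are
#' clustered by average linkage on their Ks matrix, each of the m - 1
#' cluster joins is treated as one inferred duplication node, and its
#' unit weight is split equally among the gene pairs first joined
#' there, so weights sum to the number of duplication nodes rather than
#' the number of pairs.
#'
#' @param families list of `gene_family` objects carrying sequences in
#'   `$cds` (named character vectors), or supply `sequences`.
#' @param species species id whose paralogs are scored.
#' @param window numeric length-2 analysis window on Ks.
#' @param dedup logical; apply node weighting (off by default).
#' @param sequences optional named character vector of CDS covering all
#'   genes (overrides per-family `$cds`).
#' @return a `ks_distribution`: list with `species`, `pairs` data frame
#'   (`gene1`, `gene2`, `family`, `Ka`, `Ks`, `weight`), `window`, and
#'   an `empty` flag when no scorable pair survives.
#' @export
build_paralog_distribution <- function(families, species,
                                       window = c(0.01, 5),
                                       dedup = FALSE, sequences = NULL) {
  stopifnot(length(window) == 2, window[1] >= 0, window[1] < window[2])
  rows <- list()
  for (fam in families) {
    g <- fam$genes$gene_id[fam$genes$species == species]
    if (length(g) < 2) next
    cds <- if (!is.null(sequences)) sequences else fam$cds
    if (is.null(cds) || !all(g %in% names(cds))) next
    pr <- utils::combn(g, 2)
    ks <- matrix(NA_real_, length(g), length(g),
                 dimnames = list(g, g))
    est <- vector("list", ncol(pr))
    for (j in seq_len(ncol(pr))) {
      e <- estimate_ks(cds[[pr[1, j]]], cds[[pr[2, j]]])
      est[[j]] <- e
      ks[pr[1, j], pr[2, j]] <- ks[pr[2, j], pr[1, j]] <- e$Ks
    }
    w <- if (dedup) .node_weights(g, ks, pr) else rep(1, ncol(pr))
    for (j in seq_len(ncol(pr))) {
      e <- est[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = pr[1, j], gene2 = pr[2, j], family = fam$id,
        Ka = e$Ka, Ks = e$Ks, weight = w[j], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene1 = character(0), gene2 = character(0),
               family = character(0), Ka = numeric(0), Ks = numeric(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  keep <- !is.na(pairs$Ks) & pairs$Ks >= window[1] & pairs$Ks <= window[2]
  pairs <- pairs[keep, , drop = FALSE]
  structure(list(species = species, pairs = pairs, window = window,
                 empty = nrow(pairs) == 0L),
            class = "ks_distribution")
}

# Node weighting: average-linkage clustering of a family's genes on Ks;
# each of the m-1 merges distributes weight 1 over the gene pairs that
# first become linked at that merge. Pairs with undefined Ks get the
# family's maximum finite Ks for clustering purposes.
.node_weights <- function(genes, ks, pr) {
  m <- length(genes)
  w <- numeric(ncol(pr))
  if (m == 2L) return(1)
  kmat <- ks
  mx <- max(kmat[is.finite(kmat)], 0, na.rm = TRUE)
  kmat[!is.finite(kmat)] <- mx + 1
  diag(kmat) <- 0
  hc <- stats::hclust(stats::as.dist(kmat), method = "average")
  members <- lapply(seq_len(m), function(i) genes[i])
  key <- function(x, y) paste(sort(c(x, y)), collapse = "\r")
  pair_key <- vapply(seq_len(ncol(pr)), function(j)
    key(pr[1, j], pr[2, j]), character(1))
  merged <- vector("list", m - 1)
  for (s in seq_len(m - 1)) {
    pick <- function(idx) if (idx < 0) members[[-idx]] else merged[[idx]]
    left <- pick(hc$merge[s, 1]); right <- pick(hc$merge[s, 2])
    new_pairs <- as.vector(outer(left, right, Vectorize(key)))
    hitk <- match(new_pairs, pair_key)
    hitk <- hitk[!is.na(hitk)]
    if (length(hitk)) w[hitk] <- w[hitk] + 1 / length(hitk)
    merged[[s]] <- c(left, right)
  }
  w
}

#' One-to-one ortholog Ks distribution for a species pair
#'
#' Families with exactly one gene in each of the two species contribute
#' one cross-species pair; all other families are excluded (no best-hit
#' rescue). The summary statistic is the mode of a Gaussian kernel
#' density estimate of the retained Ks values (with the median reported
#' alongside); the mode of one-to-one ortholog Ks dates the speciation
#' of the two lineages on the synonymous-divergence scale.
#'
#' @inheritParams build_paralog_distribution
#' @param species_a,species_b the two species.
#' @return an `ortholog_ks_set`: list with `species`, `pairs` data
#'   frame, `mode`, `median`, `n`, `empty` flag.
#' @export
ortholog_ks <- function(families, species_a, species_b,
                        window = c(0.01, 5), sequences = NULL) {
  rows <- list()
  for (fam in families) {
    ga <- fam$genes$gene_id[fam$genes$species == species_a]
    gb <- fam$genes$gene_id[fam$genes$species == species_b]
    if (length(ga) != 1L || length(gb) != 1L) next
    cds <- if (!is.null(sequences)) sequences else fam$cds
    if (is.null(cds) || !all(c(ga, gb) %in% names(cds))) next
    e <- estimate_ks(cds[[ga]], cds[[gb]])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, family = fam$id, Ka = e$Ka, Ks = e$Ks,
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               family = character(0), Ka = numeric(0), Ks = numeric(0))
  keep <- !is.na(pairs$Ks) & pairs$Ks >= window[1] & pairs$Ks <= window[2]
  pairs <- pairs[keep, , drop = FALSE]
  md <- if (nrow(pairs) >= 2) {
    d <- stats::density(pairs$Ks)
    d$x[which.max(d$y)]
  } else if (nrow(pairs) == 1) pairs$Ks else NA_real_
  structure(list(species = c(species_a, species_b), pairs = pairs,
                 mode = md, median = stats::median(pairs$Ks),
                 n = nrow(pairs), empty = nrow(pairs) == 0L),
            class = "ortholog_ks_set")
}

#' Focal/sister/outgroup divergence trio
#'
#' Holds the three pairwise synonymous divergence estimates among a
#' focal species F, its sister S and an outgroup O, and the relative
#' rate decomposition of the focal branch,
#' `d_F = (d_FS + d_FO - d_SO) / 2`. A negative `d_F` marks the trio
#' inconsistent.
#'
#' @param focal,sister,outgroup species ids.
#' @param d_fs,d_fo,d_so pairwise divergence estimates (typically modes
#'   of [ortholog_ks()] sets).
#' @return a `correction_trio`.
#' @export
correction_trio <- function(focal, sister, outgroup, d_fs, d_fo, d_so) {
  if (any(c(d_fs, d_fo, d_so) < 0)) {
    stop("divergences must be non-negative", call. = FALSE)
  }
  d_f <- (d_fs + d_fo - d_so) / 2
  structure(list(focal = focal, sister = sister, outgroup = outgroup,
                 d_fs = d_fs, d_fo = d_fo, d_so = d_so, d_f = d_f,
                 inconsistent = d_f < 0),
            class = "correction_trio")
}

#' Rate-corrected comparison of a paralog peak with a speciation
#'
#' Lineage-specific substitution rate variation shifts ortholog Ks
#' modes away from the focal species' own paralog Ks scale. The
#' relative-rate decomposition over one or more focal/sister/outgroup
#' trios places the focal-sister speciation on the focal paralog scale
#' at `2 * d_F`; a paralog peak older than that corrected divergence is
#' a candidate WGD shared with the sister lineage, a younger peak is
#' lineage specific.
#'
#' @param trios a [correction_trio()] or list of them (one per
#'   outgroup).
#' @param paralog_peak_ks Ks of the focal paralog peak under test.
#' @return list with per-trio corrected divergences, their mean and SD,
#'   and `verdict` (`"shared"`, `"lineage_specific"`, or
#'   `"inconsistent"` when no trio is usable).
#' @export
rate_correct_peak <- function(trios, paralog_peak_ks) {
  if (inherits(trios, "correction_trio")) trios <- list(trios)
  ok <- !vapply(trios, `[[`, logical(1), "inconsistent")
  corrected <- 2 * vapply(trios, `[[`, numeric(1), "d_f")
  use <- corrected[ok]
  if (length(use) == 0L) {
    return(list(corrected = corrected, usable = ok, mean = NA_real_,
                sd = NA_real_, paralog_peak_ks = paralog_peak_ks,
                verdict = "inconsistent"))
  }
  m <- mean(use)
  verdict <- if (paralog_peak_ks > m) "shared" else "lineage_specific"
  list(corrected = corrected, usable = ok, mean = m,
       sd = if (length(use) > 1) stats::sd(use) else NA_real_,
       paralog_peak_ks = paralog_peak_ks, verdict = verdict)
}
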