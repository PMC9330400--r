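#' Assign paralog pairs to a mixture component (putative WGD peak)
#'
#' A pair is assigned to the component iff both criteria hold: its Ks
#' lies within +/- `sd_window` fitted SDs of the component mean, and
#' the component has the pair's highest posterior responsibility.
#' Posterior ties are conservatively left unassigned (and logged in
#' the result).
#'
#' @param dist the `ks_distribution` whose pairs were fitted.
#' @param fit the `ks_mixture` fitted to `dist`.
#' @param component component index (components are sorted by
#'   increasing mean).
#' @param sd_window half-width of the Ks window in component SDs
#'   (default 1).
#' @return data frame with one row per pair: `gene1`, `gene2`,
#'   `family`, `Ks`, `in_window`, `max_posterior`, `tie`, `assigned`;
#'   attributes `n_in_window`, `n_max_posterior`, `n_assigned`,
#'   `component_mean`, `component_sd`.
#' @export
assign_paralogs <- function(dist, fit, component, sd_window = 1) {
  stopifnot(inherits(fit, "ks_mixture"))
  if (component < 1 || component > fit$k) {
    stop("component ", component, " not in fit (k = ", fit$k, ")",
         call. = FALSE)
  }
  pairs <- dist$pairs
  ks <- pairs$Ks
  if (length(ks) != nrow(fit$posteriors) ||
      any(abs(ks - fit$x) > 1e-12)) {
    stop("fit does not match the distribution's pairs", call. = FALSE)
  }
  m <- fit$means[component]
  s <- fit$sds[component]
  in_window <- abs(ks - m) <= sd_window * s
  post <- fit$posteriors
  best <- apply(post, 1, max)
  is_best <- post[, component] >= best - 1e-12
  tie <- is_best & (rowSums(post >= best - 1e-12) > 1L)
  max_posterior <- is_best & !tie
  out <- data.frame(pairs[, c("gene1", "gene2", "family")], Ks = ks,
                    in_window = in_window,
                    max_posterior = max_posterior, tie = tie,
                    assigned = in_window & max_posterior,
                    stringsAsFactors = FALSE)
  attr(out, "n_in_window") <- sum(in_window)
  attr(out, "n_max_posterior") <- sum(max_posterior)
  attr(out, "n_assigned") <- sum(out$assigned)
  attr(out, "component_mean") <- m
  attr(out, "component_sd") <- s
  out
}

#' Duplicate retention rate
#'
#' Percentage of a transcriptome's predicted genes that remain in
#' duplicate from the focal WGD: the number of distinct genes among
#' the assigned paralog pairs over the number of predicted genes.
#'
#' @param assignments output of [assign_paralogs()].
#' @param n_predicted_genes total predicted genes (> 0).
#' @return list with `n_paralog_genes`, `n_pairs_assigned`,
#'   `n_predicted_genes`, `percent_retained`.
#' @export
retention_rate <- function(assignments, n_predicted_genes) {
  if (n_predicted_genes <= 0) stop("n_predicted_genes must be positive",
                                   call. = FALSE)
  a <- assignments[assignments$assigned, , drop = FALSE]
  genes <- unique(c(a$gene1, a$gene2))
  list(n_paralog_genes = length(genes), n_pairs_assigned = nrow(a),
       n_predicted_genes = n_predicted_genes,
       percent_retained = 100 * length(genes) / n_predicted_genes)
}

#' GO Slim enrichment of retained paralogs
#'
#' Chi-squared goodness-of-fit comparison of the GO Slim composition
#' of retained paralogs against the whole gene set: expected paralog
#' counts follow the background proportions, and each category's
#' standardized (Pearson) residual `(O - E) / sqrt(E)` is called
#' overrepresented above `+2`, underrepresented below `-2`, and `ns`
#' otherwise. Categories with zero expected count are excluded (and
#' recorded in the `excluded` attribute).
#'
#' @param paralog_go_counts,background_go_counts named integer vectors
#'   of annotation tallies per GO Slim category (multi-label genes
#'   contribute one tally per annotation).
#' @param residual_threshold call threshold on the standardized
#'   residual (default 2).
#' @return an `enrichment_result`: data frame with `category`,
#'   `observed`, `background`, `expected`, `residual`, `call`; the
#'   global chi-squared `statistic`, `df` and `p_value` as attributes.
#' @export
go_bias <- function(paralog_go_counts, background_go_counts,
                    residual_threshold = 2) {
  bg <- background_go_counts
  if (length(bg) < 2) stop("need at least 2 categories", call. = FALSE)
  if (sum(bg) <= 0) stop("background totals must be positive",
                         call. = FALSE)
  cats <- names(bg)
  obs <- stats::setNames(numeric(length(cats)), cats)
  hit <- intersect(names(paralog_go_counts), cats)
  obs[hit] <- paralog_go_counts[hit]
  excluded <- cats[bg == 0]
  keep <- bg > 0
  obs <- obs[keep]; bg <- bg[keep]; cats <- cats[keep]
  total <- sum(obs)
  expected <- total * bg / sum(bg)
  residual <- (obs - expected) / sqrt(expected)
  call <- ifelse(residual > residual_threshold, "over",
                 ifelse(residual < -residual_threshold, "under", "ns"))
  stat <- sum(residual^2)
  df <- length(cats) - 1L
  out <- data.frame(category = cats, observed = as.numeric(obs),
                    background = as.numeric(bg), expected = expected,
                    residual = residual, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "statistic") <- stat
  attr(out, "df") <- df
  attr(out, "p_value") <- stats::pchisq(stat, df, lower.tail = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Tally GO annotations for a set of genes
#'
#' @param go_table data frame with columns `gene_id`, `go_slim_term`.
#' @param genes optional gene subset; default all genes in the table.
#' @return named integer vector of per-category tallies.
#' @export
go_tally <- function(go_table, genes = NULL) {
  if (!is.null(genes)) {
    go_table <- go_table[go_table$gene_id %in% genes, , drop = FALSE]
  }
  tab <- table(go_table$go_slim_term)
  stats::setNames(as.integer(tab), names(tab))
}

#' Cross-event matrix of GO Slim enrichment calls
#'
#' Collates enrichment calls across WGD events into a category-by-event
#' matrix, with events ordered by the median Ks of their mixture
#' component (ascending, i.e. youngest first). The convergence summary
#' per category is the fraction of event pairs sharing the same call
#' (`NA` with a single event).
#'
#' @param results named list of `enrichment_result`s, one per WGD
#'   event.
#' @param event_median_ks numeric vector of component median Ks, one
#'   per event (used for ordering; default keeps input order).
#' @return list with `matrix` (category x event calls) and
#'   `convergence` (per-category pairwise agreement fraction).
#' @export
cross_event_matrix <- function(results, event_median_ks = NULL) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results))) {
    names(results) <- paste0("event", seq_along(results))
  }
  if (!is.null(event_median_ks)) {
    results <- results[order(event_median_ks)]
  }
  cats <- sort(unique(unlist(lapply(results, `[[`, "category"))))
  m <- matrix("ns", length(cats), length(results),
              dimnames = list(cats, names(results)))
  for (j in seq_along(results)) {
    r <- results[[j]]
    m[match(r$category, cats), j] <- r$call
  }
  conv <- apply(m, 1, function(calls) {
    k <- length(calls)
    if (k < 2) return(NA_real_)
    pairs <- utils::combn(k, 2)
    mean(calls[pairs[1, ]] == calls[pairs[2, ]])
  })
  list(matrix = m, convergence = conv)
}
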