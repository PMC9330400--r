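#' Plant category bias into a synthetic GO annotation table
#'
#' Assigns one GO Slim category per annotation to every gene of the
#' given families. Genes retained in duplicate by a named WGD (tips
#' descending from a WGD duplication node, see [wgd_genes()]) draw the
#' biased categories with probability multiplied by
#' `enrichment_factor` and renormalized; all other genes draw
#' uniformly. With `enrichment_factor = 1` paralog and background
#' category frequencies are equal in expectation — the null fixture
#' for enrichment calibration.
#'
#' @param families list of `gene_family` objects.
#' @param n_categories size of the GO Slim universe (categories are
#'   named `GO:0001` ...).
#' @param biased_categories character vector of biased categories
#'   (must be in the universe; may be empty).
#' @param enrichment_factor multiplicative bias (> 0).
#' @param seed integer seed (required).
#' @param wgd_id restrict "paralog" status to descendants of this WGD
#'   id (default: any WGD).
#' @param annotations_per_gene number of category draws per gene
#'   (default 1; draws are with replacement and deduplicated).
#' @return data frame with columns `gene_id`, `go_slim_term` and a
#'   logical attribute vector `paralog_genes` naming the biased genes.
#' @export
plant_go_bias <- function(families, n_categories, biased_categories =
                            character(0), enrichment_factor = 1, seed,
                          wgd_id = NULL, annotations_per_gene = 1L) {
  .require_seed(seed)
  if (enrichment_factor <= 0) stop("enrichment_factor must be positive",
                                   call. = FALSE)
  universe <- sprintf("GO:%04d", seq_len(n_categories))
  if (!all(biased_categories %in% universe)) {
    stop("biased category not in universe", call. = FALSE)
  }
  genes <- unlist(lapply(families, function(f) f$genes$gene_id))
  paralogs <- unlist(lapply(families, wgd_genes, wgd_id = wgd_id))
  w_bg <- rep(1, n_categories)
  w_par <- w_bg
  w_par[universe %in% biased_categories] <- enrichment_factor
  withr::with_seed(seed, {
    is_par <- genes %in% paralogs
    gene_rep <- rep(genes, each = annotations_per_gene)
    par_rep <- rep(is_par, each = annotations_per_gene)
    terms <- character(length(gene_rep))
    if (any(!par_rep)) {
      terms[!par_rep] <- sample(universe, sum(!par_rep),
                                replace = TRUE, prob = w_bg)
    }
    if (any(par_rep)) {
      terms[par_rep] <- sample(universe, sum(par_rep), replace = TRUE,
                               prob = w_par)
    }
    out <- data.frame(gene_id = gene_rep, go_slim_term = terms,
                      stringsAsFactors = FALSE)
    if (annotations_per_gene > 1L) {
      out <- unique(out)
    }
    attr(out, "paralog_genes") <- paralogs
    out
  })
}
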