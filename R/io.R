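# Flat-file interfaces: family membership TSV (family_id, gene_id,
# species), GO TSV (gene_id, go_slim_term), Ks pair TSV, duplication
# profile TSV, mixture JSON, scenario YAML.

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a gene-family membership table
#'
#' Tab-separated, with header columns `family_id`, `gene_id`,
#' `species` (the orthogroup-table dialect consumed by the pipeline).
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_family_table <- function(path) {
  .read_tsv(path, c("family_id", "gene_id", "species"))
}

#' @rdname read_family_table
#' @param families list of `gene_family` objects to serialize.
#' @export
write_family_table <- function(families, path) {
  rows <- lapply(families, function(f) {
    if (nrow(f$genes) == 0) return(NULL)
    data.frame(family_id = f$id, f$genes, stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' Convert a membership table to `gene_family` objects (no trees)
#'
#' @param df data frame as returned by [read_family_table()].
#' @return list of `gene_family` objects (tree slots are `NULL`).
#' @export
families_from_table <- function(df) {
  lapply(split(df, df$family_id), function(d) {
    structure(list(id = d$family_id[1],
                   genes = data.frame(gene_id = d$gene_id,
                                      species = d$species,
                                      stringsAsFactors = FALSE),
                   tree = NULL, extinct = FALSE),
              class = "gene_family")
  })
}

#' Read/write a GO Slim annotation table
#'
#' Tab-separated with header columns `gene_id`, `go_slim_term`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_go_table <- function(path) {
  .read_tsv(path, c("gene_id", "go_slim_term"))
}

#' @rdname read_go_table
#' @param go_table data frame to write.
#' @export
write_go_table <- function(go_table, path) {
  .write_tsv(go_table[, c("gene_id", "go_slim_term")], path)
}

#' Write a Ks distribution's pair table
#'
#' @param dist a `ks_distribution`.
#' @param path output TSV.
#' @export
write_ks_table <- function(dist, path) {
  .write_tsv(dist$pairs, path)
}

#' Write a duplication profile
#'
#' @param profile a `dup_profile`.
#' @param path output TSV.
#' @export
write_profile <- function(profile, path) {
  .write_tsv(as.data.frame(profile), path)
}

#' Serialize a mixture fit to JSON
#'
#' @param fit a `ks_mixture`.
#' @param path output JSON file.
#' @export
write_mixture_json <- function(fit, path) {
  obj <- list(k = fit$k, means = fit$means, sds = fit$sds,
              weights = fit$weights, loglik = fit$loglik,
              aic = fit$aic, component_medians = fit$component_medians,
              peak_evidence = fit$peak_evidence,
              aic_table = fit$table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write simulation scenario files
#'
#' A scenario YAML describes the synthetic study: tree shape
#' (`n_tips`, `depth`), birth/death `rates`, `wgds` (list of `branch`,
#' `position`, `retention_rate`), `n_families`, conditioning
#' `filters`, sequence parameters (`seq`: `syn_rate`, `omega`,
#' `n_codons`), GO parameters (`go`: `n_categories`,
#' `biased_categories`, `enrichment_factor`) and a `seed`.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_scenario <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_scenario
#' @param scenario named list to write.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(scenario, path)
  invisible(path)
}
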