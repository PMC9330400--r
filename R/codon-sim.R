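#' Parameters for codon sequence simulation
#'
#' The simulator is a mutation-selection codon process: every
#' nucleotide position mutates at rate `syn_rate` per time unit, the
#' target is uniform among the non-stop single-nucleotide neighbours of
#' the current codon, synonymous changes are always accepted and
#' nonsynonymous changes are accepted with probability `omega`. Under
#' this scheme the synonymous substitution rate per NG86 synonymous
#' site equals `syn_rate` exactly, so the expected pairwise Ks of two
#' genes is, to first order, `2 * (time to common ancestor) * syn_rate`.
#'
#' @param syn_rate synonymous substitution rate per synonymous site per
#'   time unit.
#' @param omega nonsynonymous/synonymous rate ratio (dN/dS); 0.2 is a
#'   typical genome-wide value for plant nuclear genes.
#' @param n_codons gene length in codons.
#' @return a `seq_sim_params` object.
#' @export
seq_sim_params <- function(syn_rate, omega = 0.2, n_codons = 500L) {
  if (syn_rate < 0 || omega < 0) stop("rates must be non-negative",
                                      call. = FALSE)
  if (n_codons < 1) stop("n_codons must be at least 1", call. = FALSE)
  structure(list(syn_rate = syn_rate, omega = omega,
                 n_codons = as.integer(n_codons)),
            class = "seq_sim_params")
}

# mutate a codon-index sequence over a branch of duration t
.mutate_seq <- function(ci, t, rate, omega) {
  tb <- .codon_tables
  L <- length(ci)
  n_ev <- stats::rpois(1L, 3 * L * rate * t)
  if (n_ev == 0L) return(ci)
  pos <- sample.int(3L * L, n_ev, replace = TRUE)
  cp <- (pos - 1L) %/% 3L + 1L     # codon index in sequence
  wp <- (pos - 1L) %% 3L + 1L      # position within codon
  u_acc <- stats::runif(n_ev)
  for (k in seq_len(n_ev)) {
    cur <- ci[cp[k]]
    nb <- tb$neigh[[cur]][[wp[k]]]
    if (length(nb) == 0L) next
    j <- if (length(nb) == 1L) 1L else sample.int(length(nb), 1L)
    if (tb$synf[[cur]][[wp[k]]][j] || u_acc[k] < omega) {
      ci[cp[k]] <- nb[j]
    }
  }
  ci
}

#' Simulate in-frame codon sequences down a gene tree
#'
#' Evolves a random ancestral sequence of sense codons along the
#' family's gene tree (branch lengths in time units) under the
#' mutation-selection process described in [seq_sim_params()]. No
#' indels are introduced and stop codons never occur.
#'
#' @param family a `gene_family` with a non-`NULL` gene tree, or any
#'   [ape::phylo] with tip labels.
#' @param params a [seq_sim_params()] object.
#' @param seed integer seed (required).
#' @return named character vector of nucleotide sequences, one per
#'   gene, in tip-label order.
#' @export
evolve_codon_sequences <- function(family, params, seed) {
  .require_seed(seed)
  phy <- if (inherits(family, "phylo")) family else family$tree
  if (is.null(phy)) stop("family has no gene tree", call. = FALSE)
  stopifnot(inherits(params, "seq_sim_params"))
  withr::with_seed(seed, {
    tb <- .codon_tables
    n_tip <- length(phy$tip.label)
    n_node <- n_tip + phy$Nnode
    seqs <- vector("list", n_node)
    root <- n_tip + 1L
    seqs[[root]] <- sample(tb$sense, params$n_codons, replace = TRUE)
    phy <- ape::reorder.phylo(phy, "cladewise")
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      seqs[[ch]] <- .mutate_seq(seqs[[p]], phy$edge.length[e],
                                params$syn_rate, params$omega)
    }
    out <- vapply(seq_len(n_tip), function(i) .codons_to_seq(seqs[[i]]),
                  character(1))
    names(out) <- phy$tip.label
    out
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
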