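# Precomputed codon bookkeeping for the NG86 estimator and the codon
# simulator. Site fractions follow the Nei-Gojobori (1986) convention:
# at each codon position the synonymous site fraction is the proportion
# of synonymous changes among the possible single-nucleotide changes,
# with changes to stop codons excluded from both numerator and
# denominator.

.codon_bases <- c("T", "C", "A", "G")

.codon_tables <- local({
  bases <- .codon_bases
  idx3 <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
  codons <- paste0(bases[idx3$b1], bases[idx3$b2], bases[idx3$b3])
  # codon index = ((b1-1)*4 + (b2-1))*4 + b3
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  is_stop <- aa == "*"
  sense <- which(!is_stop)

  pos_mult <- c(16L, 4L, 1L)
  base_of <- function(ci, pos) ((ci - 1L) %/% pos_mult[pos]) %% 4L + 1L
  mutate_codon <- function(ci, pos, new_base) {
    ci + (new_base - base_of(ci, pos)) * pos_mult[pos]
  }

  sfrac <- matrix(0, 64, 3)          # synonymous site fraction per position
  neigh <- vector("list", 64)        # non-stop neighbours, per position
  synf <- vector("list", 64)         # parallel synonymy flags
  syn_neigh <- vector("list", 64)    # all synonymous neighbours (flat)
  for (ci in sense) {
    neigh[[ci]] <- vector("list", 3)
    synf[[ci]] <- vector("list", 3)
    sn <- integer(0)
    for (pos in 1:3) {
      tgt <- setdiff(1:4, base_of(ci, pos))
      cand <- vapply(tgt, function(b) mutate_codon(ci, pos, b), integer(1))
      keep <- !is_stop[cand]
      cand <- cand[keep]
      s <- aa[cand] == aa[ci]
      neigh[[ci]][[pos]] <- cand
      synf[[ci]][[pos]] <- s
      if (length(cand) > 0) sfrac[ci, pos] <- sum(s) / length(cand)
      sn <- c(sn, cand[s])
    }
    syn_neigh[[ci]] <- sn
  }
  syn_sites <- rowSums(sfrac)
  syn_sites[is_stop] <- NA_real_
  nonsyn_sites <- 3 - syn_sites

  list(codons = codons, aa = aa, is_stop = is_stop, sense = sense,
       sfrac = sfrac, syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       neigh = neigh, synf = synf, syn_neigh = syn_neigh,
       base_of = base_of, mutate_codon = mutate_codon)
})

# cache for pathway-averaged difference counts between codon pairs
.codon_diff_cache <- new.env(parent = emptyenv())

.perm_list <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Average synonymous/nonsynonymous difference counts between two codons
# over all mutational pathways; pathways through stop codons are
# excluded (if every pathway is blocked, all pathways are used with
# stop-steps counted as nonsynonymous).
.codon_pair_diff <- function(c1, c2) {
  key <- paste0(c1, "_", c2)
  hit <- .codon_diff_cache[[key]]
  if (!is.null(hit)) return(hit)
  tb <- .codon_tables
  pos_diff <- which(vapply(1:3, function(p) {
    tb$base_of(c1, p) != tb$base_of(c2, p)
  }, logical(1)))
  d <- length(pos_diff)
  if (d == 0L) return(c(0, 0))
  paths <- .perm_list[[d]]
  walk <- function(order, allow_stop) {
    cur <- c1
    sd <- 0
    nd <- 0
    for (k in order) {
      pos <- pos_diff[k]
      nxt <- tb$mutate_codon(cur, pos, tb$base_of(c2, pos))
      if (tb$is_stop[nxt] && !allow_stop) return(NULL)
      if (!tb$is_stop[cur] && !tb$is_stop[nxt] &&
          tb$aa[cur] == tb$aa[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(paths, walk, allow_stop = TRUE)
  out <- Reduce(`+`, res) / length(res)
  assign(key, out, envir = .codon_diff_cache)
  out
}

# string <-> codon-index helpers -------------------------------------------

.seq_to_codons <- function(x) {
  x <- toupper(gsub("U", "T", x, fixed = TRUE))
  n <- nchar(x)
  if (n %% 3 != 0) stop("sequence length not divisible by 3", call. = FALSE)
  nt <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- match(nt, .codon_bases)  # non-ACGT -> NA codon, dropped pairwise
  m <- matrix(b, nrow = 3)
  ci <- (m[1, ] - 1L) * 16L + (m[2, ] - 1L) * 4L + m[3, ]
  ci
}

.codons_to_seq <- function(ci) {
  paste0(.codon_tables$codons[ci], collapse = "")
}
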