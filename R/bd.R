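#' Linear birth-death transition probabilities
#'
#' Transition probability matrix of a linear birth-death process
#' (per-gene birth rate lambda, death rate mu) over elapsed time `t`,
#' for 0..`trunc` starting and ending copies. Row `i+1`, column `j+1`
#' is P(j copies at time t | i copies at time 0). The single-ancestor
#' distribution is the classical Kendall geometric form
#' `P(0) = alpha`, `P(n) = (1 - alpha)(1 - beta) beta^(n-1)` with
#' `alpha = mu (e^((lambda-mu)t) - 1) / (lambda e^((lambda-mu)t) - mu)`
#' and `beta = alpha * lambda / mu`; the critical case lambda = mu uses
#' the limit `alpha = beta = lambda t / (1 + lambda t)`. Rows for
#' several ancestors are built by iterated convolution. Probability
#' mass beyond `trunc` is simply truncated; rows therefore sum to at
#' most 1 and the deficit is available to the caller for a
#' mass-conservation check.
#'
#' @param lambda,mu rates per gene per time unit.
#' @param t elapsed time (branch length).
#' @param trunc state-space truncation bound.
#' @return a `(trunc + 1) x (trunc + 1)` matrix.
#' @export
bd_transition_matrix <- function(lambda, mu, t, trunc = 200L) {
  N <- as.integer(trunc)
  if (lambda + mu == 0 || t == 0) {
    P <- diag(N + 1L)
    return(P)
  }
  if (abs(lambda - mu) < 1e-12 * max(lambda, mu)) {
    a <- b <- lambda * t / (1 + lambda * t)
  } else {
    egt <- exp((lambda - mu) * t)
    den <- lambda * egt - mu
    a <- mu * (egt - 1) / den
    b <- lambda * (egt - 1) / den
  }
  # single-ancestor distribution over 0..N
  p1 <- numeric(N + 1L)
  p1[1] <- a
  if (b == 0) {
    p1[2] <- 1 - a
  } else {
    p1[-1] <- (1 - a) * (1 - b) * b^(0:(N - 1L))
  }
  if (any(!is.finite(p1))) {
    stop("non-finite transition probability (lambda=", lambda, ", mu=",
         mu, ", t=", t, ")", call. = FALSE)
  }
  # convolution operator: (v %*% Tp)[j] = sum_m v[m] p1[j - m]
  idx <- outer(0:N, 0:N, function(m, j) j - m)
  Tp <- matrix(0, N + 1L, N + 1L)
  pos <- idx >= 0L
  Tp[pos] <- p1[idx[pos] + 1L]
  P <- matrix(0, N + 1L, N + 1L)
  P[1, 1] <- 1
  P[2, ] <- p1
  if (N >= 2L) {
    for (i in 3:(N + 1L)) P[i, ] <- P[i - 1L, , drop = FALSE] %*% Tp
  }
  P
}

# extinction probability of a single gene lineage entering the branch
# above `node`: probability of zero surviving copies at the tips below
.extinction_below <- function(node, sprep, Pmats) {
  if (node <= sprep$n_tip) {
    return(Pmats[[node]][2, 1])
  }
  x <- prod(vapply(sprep$children[[node]], .extinction_below,
                   numeric(1), sprep = sprep, Pmats = Pmats))
  p1 <- Pmats[[node]][2, ]
  sum(p1 * x^(0:(length(p1) - 1L)))
}

#' Birth-death likelihood of a family count matrix
#'
#' Pruning-algorithm log-likelihood of observed per-species gene
#' counts under a linear birth-death process along the species tree,
#' with a geometric prior on the (unobserved, >= 1) root copy number
#' and likelihood conditioning on at least one surviving copy in each
#' of the two clades descending from the root (the standard
#' conditioning for families ascertained to be present on both sides
#' of the root).
#'
#' @param counts families x species integer matrix (column names must
#'   match species-tree tips).
#' @param tree ultrametric species tree.
#' @param rates a [bd_rates()] object.
#' @param root_prior_mean mean of the geometric root-size prior;
#'   default the geometric mean of observed family sizes (clamped to
#'   be at least 1).
#' @param trunc state-space truncation (default 200, twice the
#'   conventional 100-copy family cap); a warning is issued when the
#'   truncated mass visible at the root exceeds 1e-8.
#' @param condition `"oneInBothClades"` (default) or `"none"`.
#' @return total log-likelihood (sum over families).
#' @export
bd_loglik <- function(counts, tree, rates, root_prior_mean = NULL,
                      trunc = 200L, condition = "oneInBothClades") {
  counts <- as.matrix(counts)
  sprep <- .tree_prep(tree)
  tips <- tree$tip.label
  if (is.null(colnames(counts)) || !all(tips %in% colnames(counts))) {
    stop("counts must have one column per species-tree tip",
         call. = FALSE)
  }
  counts <- counts[, tips, drop = FALSE]
  if (max(counts) > trunc) stop("observed count exceeds truncation bound",
                                call. = FALSE)
  if (is.null(root_prior_mean)) {
    sz <- rowSums(counts)
    root_prior_mean <- max(exp(mean(log(pmax(sz, 1)))), 1)
  }
  N <- as.integer(trunc)
  nf <- nrow(counts)
  # per-node transition matrix for the branch above each non-root node
  Pmats <- vector("list", sprep$n_node)
  for (nd in seq_len(sprep$n_node)) {
    if (nd == sprep$root) next
    bl <- sprep$times[nd] - sprep$times[sprep$parent[nd]]
    Pmats[[nd]] <- bd_transition_matrix(rates$lambda, rates$mu, bl, N)
  }
  logscale <- numeric(nf)
  # conditional likelihood vectors, (N+1) x nf, bottom-up
  below <- function(node) {
    if (node <= sprep$n_tip) {
      L <- matrix(0, N + 1L, nf)
      L[cbind(counts[, node] + 1L, seq_len(nf))] <- 1
    } else {
      ch <- sprep$children[[node]]
      L <- Reduce(`*`, lapply(ch, function(c2) Pmats[[c2]] %*% below(c2)))
      cs <- apply(L, 2, max)
      cs[cs == 0] <- 1
      L <- sweep(L, 2, cs, "/")
      logscale <<- logscale + log(cs)
    }
    L
  }
  root_ch <- sprep$children[[sprep$root]]
  M <- lapply(root_ch, function(c2) Pmats[[c2]] %*% below(c2))
  q <- 1 / root_prior_mean
  prior <- numeric(N + 1L)
  prior[-1] <- q * (1 - q)^(0:(N - 1L))   # geometric on 1, 2, ...
  if (1 - sum(prior) > 1e-8) {
    warning("root prior mass beyond truncation bound exceeds 1e-8")
  }
  lik <- as.vector(crossprod(Reduce(`*`, M), prior))
  if (any(!is.finite(lik))) stop("non-finite family likelihood",
                                 call. = FALSE)
  if (identical(condition, "oneInBothClades")) {
    eL <- .extinction_below(root_ch[1], sprep, Pmats)
    eR <- .extinction_below(root_ch[2], sprep, Pmats)
    s <- 0:(N)
    cond <- sum(prior * (1 - eL^s - eR^s + (eL * eR)^s))
    if (cond <= 0) stop("conditioning probability underflow",
                        call. = FALSE)
  } else {
    cond <- 1
  }
  ll <- log(lik) + logscale - log(cond)
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

#' Estimate gene birth and death rates from family counts
#'
#' Maximises [bd_loglik()] over (lambda, mu) on random subsets of
#' families (ten subsets of 500 by default, the conventional design)
#' and reports the per-subset maximum-likelihood estimates with their
#' mean and SD. Optimisation is Nelder-Mead on log-rates.
#'
#' @inheritParams bd_loglik
#' @param subsets number of random subsets.
#' @param subset_size families per subset (sampled without
#'   replacement).
#' @param seed integer seed (required).
#' @param trunc state-space truncation; `"auto"` (default) adapts to
#'   the largest observed count (at least 40, at most 200).
#' @param init optional initial `c(lambda, mu)`; default 0.5 / tree
#'   height for both.
#' @return a `rate_estimate`: list with `estimates` (data frame of
#'   per-subset lambda_hat, mu_hat, loglik, convergence), `lambda_hat`,
#'   `mu_hat` (means over successful subsets), `sd` and the settings.
#' @export
estimate_rates <- function(counts, tree, subsets = 10L,
                           subset_size = 500L, seed, trunc = "auto",
                           root_prior_mean = NULL, init = NULL) {
  .require_seed(seed)
  counts <- as.matrix(counts)
  if (nrow(counts) < subset_size) {
    stop("need at least subset_size families", call. = FALSE)
  }
  if (identical(trunc, "auto")) {
    trunc <- min(200L, max(40L, 4L * max(counts)))
  }
  height <- max(.node_times(.tree_prep(tree)$phy))
  if (is.null(init)) init <- c(0.5, 0.5) / height
  withr::with_seed(seed, {
    est <- vector("list", subsets)
    for (s in seq_len(subsets)) {
      rows <- sample.int(nrow(counts), subset_size)
      sub <- counts[rows, , drop = FALSE]
      nll <- function(lp) {
        r <- bd_rates(exp(lp[1]), exp(lp[2]))
        -bd_loglik(sub, tree, r, root_prior_mean = root_prior_mean,
                   trunc = trunc)
      }
      fit <- tryCatch(
        stats::optim(log(init), nll, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-8)),
        error = function(e) NULL)
      est[[s]] <- if (is.null(fit)) {
        data.frame(subset = s, lambda_hat = NA_real_, mu_hat = NA_real_,
                   loglik = NA_real_, converged = FALSE)
      } else {
        data.frame(subset = s, lambda_hat = exp(fit$par[1]),
                   mu_hat = exp(fit$par[2]), loglik = -fit$value,
                   converged = fit$convergence == 0)
      }
    }
    tab <- do.call(rbind, est)
    ok <- tab$converged & is.finite(tab$lambda_hat)
    if (!any(ok)) stop("rate optimisation failed on every subset",
                       call. = FALSE)
    structure(list(estimates = tab,
                   lambda_hat = mean(tab$lambda_hat[ok]),
                   mu_hat = mean(tab$mu_hat[ok]),
                   sd = c(lambda = stats::sd(tab$lambda_hat[ok]),
                          mu = stats::sd(tab$mu_hat[ok])),
                   subsets = subsets, subset_size = subset_size,
                   trunc = trunc),
              class = "rate_estimate")
  })
}
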