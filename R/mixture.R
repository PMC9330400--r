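#' Fit Gaussian mixtures to a Ks distribution with AIC selection
#'
#' Fits normal mixture models with k = 1..`k_max` components to the Ks
#' values of a paralog age distribution by EM (multiple restarts per
#' k), selects the best k by minimum AIC (ties go to the smaller k),
#' and reports a peak as statistically supported only when a k > 1
#' model beats the single-component model by more than `delta_aic`
#' AIC units. Mixtures are fitted on raw Ks within the distribution's
#' analysis window, not log-transformed values.
#'
#' The EM log-likelihood is asserted to be non-decreasing at every
#' iteration; a k whose restarts all fail to converge is flagged and
#' excluded from model selection.
#'
#' @param dist a `ks_distribution` (or a bare numeric vector of Ks
#'   values).
#' @param k_max maximum number of components (default 4).
#' @param n_restarts EM restarts per k. The default single restart
#'   uses deterministic quantile-spread initial means; additional
#'   restarts are random. The deterministic default is deliberate:
#'   aggressive random restarts let EM find degenerate narrow-spike
#'   components that plain AIC then rewards, inflating the selected k
#'   on unimodal data.
#' @param seed integer seed (required; initialisation is stochastic).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param delta_aic AIC margin required to prefer a multi-component
#'   model over k = 1 when declaring peak evidence (default 2).
#' @return a `ks_mixture`: list with `k` (selected), `means`, `sds`,
#'   `weights` (sorted by mean), `posteriors` (n x k responsibilities),
#'   `loglik`, `aic`, `component_medians` (median Ks of observations
#'   assigned to each component by maximum posterior), `peak_evidence`,
#'   `table` (per-k fit summary) and the data `x`.
#' @export
fit_mixture <- function(dist, k_max = 4L, n_restarts = 1L, seed,
                        max_iter = 250L, tol = 1e-7, delta_aic = 2) {
  .require_seed(seed)
  x <- if (inherits(dist, "ks_distribution")) dist$pairs$Ks else
    as.numeric(dist)
  x <- x[is.finite(x)]
  if (length(x) < 10 * k_max) {
    stop("need at least 10 * k_max observations", call. = FALSE)
  }
  withr::with_seed(seed, {
    fits <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      best <- NULL
      for (r in seq_len(if (k == 1L) 1L else n_restarts)) {
        init <- .em_init(x, k, random = r > 1)
        f <- tryCatch(.em_gauss(x, init, max_iter, tol),
                      error = function(e) NULL)
        if (is.null(f) || !f$converged) next
        if (is.null(best) || f$loglik > best$loglik) best <- f
      }
      fits[k] <- list(best)   # keeps the slot even when NULL
    }
    tab <- data.frame(
      k = seq_len(k_max),
      loglik = vapply(fits, function(f)
        if (is.null(f)) NA_real_ else f$loglik, numeric(1)),
      converged = !vapply(fits, is.null, logical(1)))
    tab$aic <- -2 * tab$loglik + 2 * (3 * tab$k - 1)
    ok <- which(tab$converged)
    if (length(ok) == 0L) stop("EM failed to converge for every k",
                               call. = FALSE)
    sel <- ok[which.min(tab$aic[ok])]   # which.min takes first = smallest k
    f <- fits[[sel]]
    ord <- order(f$mean)
    post <- f$post[, ord, drop = FALSE]
    assigned <- max.col(post, ties.method = "first")
    comp_med <- vapply(seq_len(sel), function(j) {
      xs <- x[assigned == j]
      if (length(xs)) stats::median(xs) else NA_real_
    }, numeric(1))
    peak <- sel > 1L && tab$converged[1] &&
      (tab$aic[1] - tab$aic[sel]) > delta_aic
    structure(list(k = sel, means = f$mean[ord], sds = f$sd[ord],
                   weights = f$w[ord], posteriors = post,
                   loglik = f$loglik, aic = tab$aic[sel],
                   component_medians = comp_med, peak_evidence = peak,
                   table = tab, x = x),
              class = "ks_mixture")
  })
}

.em_init <- function(x, k, random) {
  if (k == 1L) return(list(mean = mean(x), sd = stats::sd(x), w = 1))
  mu <- if (random) sort(sample(x, k)) else
    stats::quantile(x, probs = seq(0.1, 0.9, length.out = k),
                    names = FALSE)
  list(mean = mu, sd = rep(stats::sd(x) / k, k), w = rep(1 / k, k))
}

.em_gauss <- function(x, init, max_iter, tol) {
  n <- length(x)
  k <- length(init$mean)
  mu <- init$mean; sg <- pmax(init$sd, 1e-6); w <- init$w
  sd_floor <- max(1e-4 * stats::sd(x), 1e-8)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sg[j], log = TRUE),
      numeric(n))
    m <- lg[, 1]
    if (k > 1) for (j in 2:k) m <- pmax(m, lg[, j])
    lse <- m + log(rowSums(exp(lg - m)))
    ll <- sum(lse)
    # EM guarantee: the observed-data log-likelihood never decreases
    stopifnot(ll >= ll_old - 1e-6 * (1 + abs(ll)))
    post <- exp(lg - lse)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    nk <- colSums(post)
    if (any(nk < 1e-8)) stop("component collapsed")
    w <- nk / n
    mu <- colSums(post * x) / nk
    sg <- sqrt(colSums(post * (outer(x, mu, "-")^2)) / nk)
    sg <- pmax(sg, sd_floor)
  }
  list(mean = mu, sd = sg, w = w, loglik = ll_old, post = post,
       converged = converged)
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat("Gaussian mixture on", length(x$x), "Ks values; selected k =",
      x$k, "(AIC", round(x$aic, 2), ")\n")
  print(data.frame(mean = round(x$means, 4), sd = round(x$sds, 4),
                   weight = round(x$weights, 4),
                   median_ks = round(x$component_medians, 4)))
  cat("peak evidence (multi-component AIC support):", x$peak_evidence,
      "\n")
  invisible(x)
}

#' Flag mixture components in the Ks saturation zone
#'
#' Components whose fitted mean Ks exceeds 2 (strictly) fall where
#' accumulated multiple substitutions can masquerade as a duplication
#' peak; such "saturation peaks" need corroborating evidence from
#' gene-tree reconciliation before being read as WGDs.
#'
#' @param fit a `ks_mixture`.
#' @param threshold saturation threshold on the component mean
#'   (default 2).
#' @return data frame with `component`, `mean`, `flagged` and a `note`
#'   for flagged components.
#' @export
flag_saturation <- function(fit, threshold = 2) {
  stopifnot(inherits(fit, "ks_mixture"))
  flagged <- fit$means > threshold
  data.frame(
    component = seq_along(fit$means), mean = fit$means,
    flagged = flagged,
    note = ifelse(flagged,
                  "possible saturation; require corroborating evidence (reconciliation)",
                  ""),
    stringsAsFactors = FALSE)
}
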