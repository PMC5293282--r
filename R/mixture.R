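# Two-component Gaussian mixture over relative inter-focus separations and
# the posterior classification of focus pairs.
#
# The separation distribution of multi-focus cells has two roughly Gaussian
# sub-populations: transiently resolved sister forks at small relative
# separation (~0.2 cell lengths) and quarter-cell-positioned focus pairs at
# large separation (~0.45).  A maximum-likelihood two-Gaussian mixture
# (means, variances and mixing fractions free) separates them; pairs are
# assigned by posterior probability.

#' All unique within-cell focus pairs and their separations
#'
#' Every unordered pair of retained foci in one cell and frame; the
#' relative separation is the difference of relative long-axis positions
#' (the long-axis separation divided by cell length).
#'
#' @param foci data.frame of retained foci with columns `cell`, `frame`,
#'   `rel_pos`, `cell_length_um` (and optionally `fov`).
#' @return data.frame with one row per pair: `fov`, `frame`, `cell`, `i`,
#'   `j` (row indices into `foci`), `rel_sep`, `sep_um`, `cell_length_um`.
#' @export
pair_separations <- function(foci) {
  if (!nrow(foci)) {
    return(data.frame(fov = integer(), frame = integer(), cell = integer(),
                      i = integer(), j = integer(), rel_sep = numeric(),
                      sep_um = numeric(), cell_length_um = numeric()))
  }
  if (is.null(foci$fov)) foci$fov <- 1L
  foci$.row <- seq_len(nrow(foci))
  keys <- split(foci, list(foci$fov, foci$frame, foci$cell), drop = TRUE)
  out <- lapply(keys, function(g) {
    n <- nrow(g)
    if (n < 2L) return(NULL)
    cmb <- utils::combn(n, 2L)
    data.frame(fov = g$fov[1], frame = g$frame[1], cell = g$cell[1],
               i = g$.row[cmb[1, ]], j = g$.row[cmb[2, ]],
               rel_sep = abs(g$rel_pos[cmb[1, ]] - g$rel_pos[cmb[2, ]]),
               sep_um = abs(g$rel_pos[cmb[1, ]] - g$rel_pos[cmb[2, ]]) *
                 g$cell_length_um[1],
               cell_length_um = g$cell_length_um[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- pair_separations(foci[0, ])
  rownames(out) <- NULL
  out
}

em_once <- function(x, mu, sg, lam, max_iter, tol) {
  n <- length(x)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- lam[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- lam[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                 sum((1 - g1) * (x - mu[2])^2) / n2))
    if (any(sg < 1e-5)) return(NULL)  # degenerate component
    lam <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, lambda = lam, loglik = ll, iters = it,
       trace = trace)
}

#' Fit a two-Gaussian mixture to relative separations
#'
#' Maximum likelihood by EM; deterministic quantile-based initialization
#' with deterministic jittered restarts if a component degenerates.
#' Components are ordered so the first is the low-separation population.
#'
#' @param rel_seps numeric vector of relative separations (>= 50 values).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param max_restarts restarts on degenerate components.
#' @return object of class `sep_mixture`: `mu`, `sigma`, `lambda` (each
#'   length 2, low component first), `loglik`, `iters`, `trace`, `n`.
#' @export
fit_sep_mixture <- function(rel_seps, max_iter = 2000L, tol = 1e-8,
                            max_restarts = 10L) {
  x <- rel_seps[is.finite(rel_seps)]
  if (length(x) < 50L)
    stop("insufficient data: need >= 50 pair separations, got ", length(x))
  mu0 <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
  if (diff(mu0) < 1e-6) mu0 <- mu0 + c(-0.05, 0.05)
  sg0 <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  fit <- NULL
  for (r in 0:max_restarts) {
    jit <- 0.02 * r * c(-1, 1)
    fit <- em_once(x, mu0 + jit, sg0 * (1 + 0.3 * r), c(0.5, 0.5),
                   max_iter, tol)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("mixture fit degenerate after restarts")
  o <- order(fit$mu)
  structure(list(mu = fit$mu[o], sigma = fit$sigma[o], lambda = fit$lambda[o],
                 loglik = fit$loglik, iters = fit$iters, trace = fit$trace,
                 n = length(x)),
            class = "sep_mixture")
}

#' @export
print.sep_mixture <- function(x, ...) {
  cat(sprintf(paste0("sep_mixture (n=%d): low N(%.3f, %.3f) pi=%.2f | ",
                     "high N(%.3f, %.3f) pi=%.2f | loglik %.2f\n"),
              x$n, x$mu[1], x$sigma[1], x$lambda[1],
              x$mu[2], x$sigma[2], x$lambda[2], x$loglik))
  invisible(x)
}

#' Posterior probability of the low-separation population
#'
#' @param mixture a `sep_mixture`.
#' @param rel_sep numeric vector.
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_low <- function(mixture, rel_sep) {
  d1 <- mixture$lambda[1] * stats::dnorm(rel_sep, mixture$mu[1], mixture$sigma[1])
  d2 <- mixture$lambda[2] * stats::dnorm(rel_sep, mixture$mu[2], mixture$sigma[2])
  tot <- d1 + d2
  ifelse(tot <= 0, 0.5, d1 / tot)
}

#' Classify focus pairs and pick disjoint resolved-sister pairs
#'
#' Each pair gets the posterior probability of the low-separation
#' population; pairs with posterior > 0.5 are candidate resolved-sister
#' pairs (exactly 0.5 goes to the high population).  Within a cell-frame,
#' candidates are accepted greedily in order of decreasing posterior under
#' the constraint that each focus belongs to at most one accepted pair.
#'
#' @param pairs output of [pair_separations()].
#' @param mixture a `sep_mixture`.
#' @return `pairs` with `posterior_low`, `label`
#'   (`"resolved_sisters"`/`"high_separation"`) and `accepted` columns.
#' @export
classify_pairs <- function(pairs, mixture) {
  if (!nrow(pairs)) {
    pairs$posterior_low <- numeric(0); pairs$label <- character(0)
    pairs$accepted <- logical(0)
    return(pairs)
  }
  pairs$posterior_low <- posterior_low(mixture, pairs$rel_sep)
  pairs$label <- ifelse(pairs$posterior_low > 0.5,
                        "resolved_sisters", "high_separation")
  pairs$accepted <- FALSE
  key <- paste(pairs$fov, pairs$frame, pairs$cell)
  for (k in unique(key[pairs$label == "resolved_sisters"])) {
    sel <- which(key == k & pairs$label == "resolved_sisters")
    ## deterministic order: posterior desc, then separation, then indices
    sel <- sel[order(-pairs$posterior_low[sel], pairs$rel_sep[sel],
                     pairs$i[sel], pairs$j[sel])]
    used <- integer(0)
    for (s in sel) {
      if (pairs$i[s] %in% used || pairs$j[s] %in% used) next
      pairs$accepted[s] <- TRUE
      used <- c(used, pairs$i[s], pairs$j[s])
    }
  }
  pairs
}
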