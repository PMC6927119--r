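#' Neighbour indicator matrix
#'
#' Binary matrix marking, for each entity, its \code{floor(pn * N)} most
#' similar others (self excluded, ties broken by ascending index). Row i has
#' exactly \code{min(floor(pn * N), N - 1)} ones and a zero diagonal.
#'
#' @param sim square base similarity matrix.
#' @param pn neighbour proportion in (0, 1].
#' @return 0/1 matrix of the same shape as \code{sim}.
#' @export
neighbor_indicator <- function(sim, pn) {
  stopifnot(pn > 0, pn <= 1)
  n <- nrow(sim)
  nk <- min(floor(pn * n), n - 1L)
  cmat <- matrix(0, n, n, dimnames = dimnames(sim))
  if (nk == 0L) {
    warning("floor(pn * N) = 0: empty neighbourhoods, ",
            "similarity reduces to pure kernel reconstruction")
    return(cmat)
  }
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf
    cmat[i, order(s, decreasing = TRUE)[seq_len(nk)]] <- 1
  }
  cmat
}

#' Gaussian kernel over sample profiles
#'
#' Kernel matrix \code{exp(-||x_i - x_j||^2 / gamma)} over the rows of a
#' profile matrix, with the bandwidth set from the data as
#' \code{gamma = sum_i ||x_i||^2 / N}.
#'
#' @param profiles matrix with one sample profile per row.
#' @return list with \code{k} (symmetric kernel matrix, unit diagonal) and
#'   \code{gamma}.
#' @export
gaussian_kernel <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least two samples")
  sq <- rowSums(profiles^2)
  gamma <- sum(sq) / n
  if (gamma <= 0) stop("degenerate input: all profiles are zero")
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2 <- pmax(d2, 0)
  diag(d2) <- 0
  k <- exp(-d2 / gamma)
  k <- (k + t(k)) / 2
  list(k = k, gamma = gamma)
}

#' Optimize kernel reconstruction weights by multiplicative updates
#'
#' Minimizes the kernel-space reconstruction error of each sample from the
#' others, with a quadratic penalty \code{mu1} on weights outside the declared
#' neighbourhood and a ridge penalty \code{mu2} on all weights, subject to
#' nonnegativity and a zero diagonal. The multiplicative update
#' \deqn{W \gets W \odot (K + \mu_1 W \odot C) \oslash (K W + \mu_1 W + \mu_2 W)}
#' preserves both constraints from a strictly positive off-diagonal start
#' \code{W0 = 1/(N-1)}.
#'
#' @param kernel kernel matrix (e.g. from \code{\link{gaussian_kernel}}).
#' @param c_ind neighbour indicator from \code{\link{neighbor_indicator}}.
#' @param mu1 non-neighbourhood control parameter (> 0).
#' @param mu2 similarity regularization parameter (> 0).
#' @param tol stop when the maximum change of W relative to its largest entry
#'   falls below this (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return list with \code{w} (nonnegative weights, zero diagonal),
#'   \code{iterations}, \code{converged}.
#' @export
ksns_optimize <- function(kernel, c_ind, mu1, mu2, tol = 1e-6, max_iter = 500) {
  stopifnot(mu1 > 0, mu2 > 0)
  k <- if (is.list(kernel)) kernel$k else kernel
  n <- nrow(k)
  stopifnot(all(dim(c_ind) == c(n, n)))
  eps <- 1e-12
  w <- matrix(1 / (n - 1), n, n, dimnames = dimnames(k))
  diag(w) <- 0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    num <- k + mu1 * (w * c_ind)
    den <- k %*% w + (mu1 + mu2) * w + eps
    wn <- w * num / den
    diag(wn) <- 0
    delta <- max(abs(wn - w)) / max(max(abs(w)), eps)
    w <- wn
    if (delta < tol) { converged <- TRUE; break }
  }
  list(w = w, iterations = it, converged = converged)
}

#' Objective value of the kernel reconstruction problem
#'
#' The quantity the multiplicative updates of \code{\link{ksns_optimize}}
#' decrease (nonnegativity and zero diagonal enforced by the update itself):
#' \code{0.5||Phi W - Phi||_F^2 + mu1/2 ||W o (1-C)||_F^2 + mu2/2 ||W||_F^2},
#' evaluated through the kernel trick.
#'
#' @inheritParams ksns_optimize
#' @param w weight matrix.
#' @return scalar objective value.
#' @export
ksns_objective <- function(w, kernel, c_ind, mu1, mu2) {
  k <- if (is.list(kernel)) kernel$k else kernel
  recon <- 0.5 * (sum(diag(t(w) %*% k %*% w)) - 2 * sum(diag(k %*% w)) +
                  sum(diag(k)))
  recon + mu1 / 2 * sum((w * (1 - c_ind))^2) + mu2 / 2 * sum(w^2)
}

#' Symmetrically normalized kernel neighbourhood similarity
#'
#' Scales the transposed weight matrix by the inverse square roots of its
#' column sums, \code{D^{-1/2} W' D^{-1/2}} (zero column sums replaced by 1),
#' then symmetrizes by averaging with the transpose so the result can serve
#' as a similarity network downstream.
#'
#' @param w nonnegative weight matrix (from \code{\link{ksns_optimize}}).
#' @return symmetric nonnegative similarity matrix.
#' @export
normalize_weight <- function(w) {
  w <- if (is.list(w)) w$w else w
  stopifnot(all(w >= 0))
  d <- colSums(w)
  d[d == 0] <- 1
  si <- t(w) / sqrt(d) / rep(sqrt(d), each = nrow(w))
  (si + t(si)) / 2
}

#' Kernel neighbourhood similarity of interaction profiles
#'
#' End-to-end KSNS for one side of the interaction matrix: Gaussian kernel on
#' the profiles, neighbourhoods from the base similarity, multiplicative-update
#' optimization, symmetric normalization.
#'
#' @param profiles matrix of sample profiles in rows (miRNA side: rows of the
#'   modified interaction matrix; disease side: its transpose).
#' @param base_sim base similarity matrix defining neighbourhoods (miRNA
#'   functional or disease semantic similarity).
#' @param pn neighbour proportion parameter (default 0.5).
#' @param mu1,mu2 penalty parameters (default 4, the grid midpoint \code{2^2}).
#' @param tol,max_iter convergence controls for the multiplicative updates.
#' @return symmetric nonnegative similarity matrix.
#' @examples
#' x <- matrix(rbinom(40, 1, .3), 8, 5)
#' s <- crossprod(matrix(runif(64), 8, 8)); s <- s / max(s)
#' si <- ksns_similarity(x + 0, s)
#' @export
ksns_similarity <- function(profiles, base_sim, pn = 0.5, mu1 = 4, mu2 = 4,
                            tol = 1e-6, max_iter = 500) {
  kern <- gaussian_kernel(profiles)
  c_ind <- neighbor_indicator(base_sim, pn)
  opt <- ksns_optimize(kern, c_ind, mu1 = mu1, mu2 = mu2,
                       tol = tol, max_iter = max_iter)
  normalize_weight(opt$w)
}
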