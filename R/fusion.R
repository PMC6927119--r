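#' Random-walk-with-restart diffusion states
#'
#' Stationary distributions of a random walk with restart from every node of
#' a similarity network: \code{Q = p (I - (1-p) P)^{-1}} with P the
#' row-normalized similarity (zero rows become uniform). Row i of Q is node
#' i's diffusion state; rows sum to one.
#'
#' @param sim symmetric nonnegative similarity matrix.
#' @param restart_p restart probability in (0, 1].
#' @return row-stochastic matrix of diffusion states.
#' @examples
#' rwr_diffusion(matrix(c(0, 1, 1, 0), 2, 2), restart_p = 0.5)
#' @export
rwr_diffusion <- function(sim, restart_p = 0.5) {
  stopifnot(restart_p > 0, restart_p <= 1)
  if (any(sim < 0)) stop("similarity must be nonnegative")
  n <- nrow(sim)
  rs <- rowSums(sim)
  p <- sim / ifelse(rs == 0, 1, rs)
  p[rs == 0, ] <- 1 / n
  q <- restart_p * solve(diag(n) - (1 - restart_p) * p)
  dimnames(q) <- dimnames(sim)
  q
}

#' Low-dimensional embedding of diffusion states
#'
#' Diffusion-component embedding: diffusion states are averaged across the
#' networks (or column-concatenated, see \code{mode}), shifted into log space
#' with a small floor \code{eps}, and factored by a rank-\code{d} truncated
#' singular value decomposition. Node vectors are \code{U_d S_d^{1/2}}.
#'
#' @param states a single diffusion-state matrix or a list of them over the
#'   same node set (from \code{\link{rwr_diffusion}}).
#' @param d embedding dimension (clamped to the number of nodes with a
#'   warning).
#' @param eps log floor; defaults to \code{1/N}.
#' @param mode \code{"average"} (default) averages the states before the log;
#'   \code{"concatenate"} concatenates per-network log matrices column-wise.
#' @return list with \code{node} and \code{context} (N x d matrices), \code{d},
#'   and the singular values \code{values}.
#' @export
dca_embed <- function(states, d, eps = NULL,
                      mode = c("average", "concatenate")) {
  mode <- match.arg(mode)
  if (is.matrix(states)) states <- list(states)
  n <- nrow(states[[1]])
  stopifnot(d >= 1,
            all(vapply(states, nrow, integer(1)) == n))
  if (d > n) {
    warning("embedding dimension ", d, " > number of nodes; clamped to ", n)
    d <- n
  }
  if (is.null(eps)) eps <- 1 / n
  l <- if (mode == "average") {
    log(Reduce(`+`, states) / length(states) + eps)
  } else {
    do.call(cbind, lapply(states, function(q) log(q + eps)))
  }
  sv <- svd(l, nu = d, nv = d)
  scale <- sqrt(sv$d[seq_len(d)])
  list(node = sv$u %*% diag(scale, d),
       context = sv$v %*% diag(scale, d),
       d = d, values = sv$d)
}

#' Fuse similarity networks by diffusion-component embedding
#'
#' Integrates one or more similarity networks over the same entities: each is
#' diffused by random walk with restart, the diffusion states are embedded
#' jointly (\code{\link{dca_embed}}), and the inner products of the node
#' vectors are rescaled to [0, 1] with unit diagonal to yield the fused
#' similarity.
#'
#' @param networks a similarity matrix or list of conformable symmetric
#'   similarity matrices.
#' @param d embedding dimension; default \code{min(100, N - 1)}.
#' @param restart_p restart probability (default 0.5).
#' @param mode state integration mode, see \code{\link{dca_embed}}.
#' @return fused symmetric similarity matrix, entries in [0, 1], diagonal 1.
#' @examples
#' s <- crossprod(matrix(runif(25), 5, 5)); s <- s / max(s)
#' fuse_similarity(list(s, s), d = 3)
#' @export
fuse_similarity <- function(networks, d = NULL, restart_p = 0.5,
                            mode = c("average", "concatenate")) {
  mode <- match.arg(mode)
  if (is.matrix(networks)) networks <- list(networks)
  if (!length(networks)) stop("empty network list")
  n <- nrow(networks[[1]])
  stopifnot(all(vapply(networks, nrow, integer(1)) == n))
  if (is.null(d)) d <- max(1L, min(100L, n - 1L))
  states <- lapply(networks, rwr_diffusion, restart_p = restart_p)
  emb <- dca_embed(states, d = d, mode = mode)
  fused <- tcrossprod(emb$node)
  rng <- range(fused)
  fused <- if (rng[2] > rng[1]) (fused - rng[1]) / (rng[2] - rng[1])
           else fused * 0
  fused <- (fused + t(fused)) / 2
  diag(fused) <- 1
  dimnames(fused) <- dimnames(networks[[1]])
  fused
}
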