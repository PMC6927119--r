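#' Weighted k-nearest-neighbour correction along one axis
#'
#' Replaces each entity's sparse interaction profile with a decayed,
#' similarity-weighted average of its K most similar neighbours' profiles.
#' The k-th neighbour (in descending similarity, self excluded, ties broken
#' by ascending index) carries weight \code{alpha^(k-1) * s_k} where
#' \code{s_k} is its similarity to the entity; the sum is divided by the
#' total neighbour similarity, so at \code{alpha = 1} this is the plain
#' similarity-weighted neighbour mean. Entities with zero total neighbour
#' similarity get an all-zero corrected profile.
#'
#' @param x interaction matrix (miRNAs in rows, diseases in columns).
#' @param sim square similarity matrix for the chosen axis, labels matching
#'   that axis of \code{x}.
#' @param k number of neighbours (default 15; truncated with a warning when
#'   fewer others exist).
#' @param alpha decay factor in [0, 1] (default 0.8).
#' @param axis \code{"rows"} corrects miRNA profiles, \code{"cols"} disease
#'   profiles.
#' @param weight \code{"similarity"} (default) uses
#'   \code{alpha^(k-1) * s_k}; \code{"rank"} uses \code{alpha^(k-1)} alone
#'   (similarity then enters only through the normalizer).
#' @return matrix of the same shape as \code{x} with corrected profiles along
#'   the chosen axis.
#' @export
wknnp_axis <- function(x, sim, k = 15, alpha = 0.8,
                       axis = c("rows", "cols"),
                       weight = c("similarity", "rank")) {
  axis <- match.arg(axis)
  weight <- match.arg(weight)
  stopifnot(alpha >= 0, alpha <= 1, k >= 1)
  p <- if (axis == "rows") x else t(x)
  n <- nrow(p)
  if (!is.null(rownames(p)) && !is.null(rownames(sim)) &&
      !identical(rownames(p), rownames(sim)))
    stop("similarity labels do not match the chosen axis labels")
  if (nrow(sim) != n) stop("similarity matrix does not match axis length")
  if (k >= n) {
    warning("k = ", k, " >= number of entities (", n, "); truncated to ", n - 1L)
    k <- n - 1L
  }
  out <- matrix(0, n, ncol(p), dimnames = dimnames(p))
  decay <- alpha^(seq_len(k) - 1)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(k)]   # stable: ties by index
    q <- sum(sim[i, nb])
    if (q <= 0) next
    w <- if (weight == "similarity") decay * sim[i, nb] else decay
    out[i, ] <- (w %*% p[nb, , drop = FALSE]) / q
  }
  if (axis == "rows") out else t(out)
}

#' Combine raw and neighbour-corrected interaction profiles
#'
#' Elementwise maximum of the raw binary matrix and the mean of the row-wise
#' and column-wise corrected matrices; known interactions always stay 1.
#'
#' @param x binary interaction matrix.
#' @param x_m row-corrected matrix (\code{\link{wknnp_axis}} with
#'   \code{axis = "rows"}).
#' @param x_d column-corrected matrix (\code{axis = "cols"}).
#' @return modified profile matrix with entries in [0, 1], elementwise >= x.
#' @export
combine_profiles <- function(x, x_m, x_d) {
  if (!all(dim(x) == dim(x_m)) || !all(dim(x) == dim(x_d)))
    stop("shape mismatch between interaction and corrected matrices")
  pmin(pmax(x, (x_m + x_d) / 2), 1)
}

#' Full WKNNP correction of an interaction matrix
#'
#' Convenience wrapper: corrects rows with the miRNA similarity, columns with
#' the disease similarity, and combines with the raw matrix by elementwise
#' maximum.
#'
#' @inheritParams wknnp_axis
#' @param mirna_sim,disease_sim similarity matrices for rows and columns.
#' @return modified profile matrix in [0, 1].
#' @examples
#' x <- matrix(c(1, 0, 0, 1), 2, 2)
#' s <- matrix(c(1, .5, .5, 1), 2, 2)
#' wknnp(x, s, s, k = 1)
#' @export
wknnp <- function(x, mirna_sim, disease_sim, k = 15, alpha = 0.8,
                  weight = c("similarity", "rank")) {
  weight <- match.arg(weight)
  x_m <- wknnp_axis(x, mirna_sim, k = k, alpha = alpha, axis = "rows",
                    weight = weight)
  x_d <- wknnp_axis(x, disease_sim, k = k, alpha = alpha, axis = "cols",
                    weight = weight)
  combine_profiles(x, x_m, x_d)
}
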