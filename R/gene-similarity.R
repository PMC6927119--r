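#' Normalize a weighted gene functional network
#'
#' Converts an edge list of log-likelihood scores (LLS, as distributed by
#' functional gene networks such as HumanNet) into a symmetric gene--gene
#' similarity matrix: each score is divided by the maximum score, a pair
#' stored in either direction gets the same value, absent pairs score 0.
#' Negative scores are clamped to 0 before normalization. Self-similarity is
#' set to 1 so that a gene always matches itself when scanning a target set.
#'
#' @param edges three-column data frame (gene_a, gene_b, score).
#' @param genes optional gene universe for the output matrix (defaults to all
#'   genes appearing in \code{edges}).
#' @param max_lls normalization constant; defaults to the maximum score in
#'   \code{edges}. Must be positive.
#' @return object of class \code{"gene_network"}: list with \code{sim} (the
#'   symmetric similarity matrix, unit diagonal), \code{genes}, \code{max_lls}.
#' @examples
#' net <- gene_network(data.frame(a = "g1", b = "g2", score = 2), max_lls = 4)
#' net$sim
#' @export
gene_network <- function(edges, genes = NULL, max_lls = NULL) {
  edges <- as.data.frame(edges)[, 1:3]
  names(edges) <- c("a", "b", "score")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$score <- pmax(as.numeric(edges$score), 0)
  if (is.null(max_lls)) max_lls <- max(edges$score)
  if (!is.finite(max_lls) || max_lls <= 0)
    stop("invalid gene network: maximum log-likelihood score must be positive")
  if (is.null(genes)) genes <- sort(unique(c(edges$a, edges$b)))
  n <- length(genes)
  sim <- matrix(0, n, n, dimnames = list(genes, genes))
  ia <- match(edges$a, genes); ib <- match(edges$b, genes)
  keep <- !is.na(ia) & !is.na(ib) & ia != ib
  v <- pmin(edges$score[keep] / max_lls, 1)
  # last write wins for duplicates; stored direction and its mirror get the value
  sim[cbind(ia[keep], ib[keep])] <- v
  sim[cbind(ib[keep], ia[keep])] <- pmax(sim[cbind(ib[keep], ia[keep])], v)
  sim <- pmax(sim, t(sim))
  diag(sim) <- 1
  structure(list(sim = sim, genes = genes, max_lls = max_lls),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene functional network:", length(x$genes), "genes, max LLS",
      format(x$max_lls), "\n")
  invisible(x)
}

#' Similarity of a gene to a gene set
#'
#' The best normalized similarity between \code{g} and any member of
#' \code{set}; 1 when \code{g} itself belongs to the set.
#'
#' @param g a gene identifier.
#' @param set nonempty character vector of gene identifiers.
#' @param net a \code{\link{gene_network}}.
#' @return score in [0, 1].
#' @export
gene_set_similarity <- function(g, set, net) {
  stopifnot(inherits(net, "gene_network"))
  if (!length(set)) stop("gene set must be nonempty")
  if (g %in% set) return(1)
  hits <- intersect(set, net$genes)
  if (!g %in% net$genes || !length(hits)) return(0)
  max(net$sim[g, hits])
}

#' miRNA functional similarity from target sets and a gene network
#'
#' The functional similarity of two miRNAs averages the best-match
#' similarities across their target sets: every target of one miRNA is
#' matched against the other miRNA's target set and vice versa, and the sum
#' is divided by the total number of targets. Identical target sets score 1;
#' sets with no scored cross pair score 0. miRNAs with empty target sets are
#' excluded with a warning.
#'
#' @param targets named list mapping miRNA id to a character vector of target
#'   genes, or a two-column data frame (mirna_id, gene_id).
#' @param net a \code{\link{gene_network}}.
#' @return symmetric similarity matrix with unit diagonal, entries in [0, 1].
#' @examples
#' net <- gene_network(data.frame(a = c("g1", "g1"), b = c("g2", "g3"),
#'                                score = c(3, 2)), max_lls = 5)
#' mirna_functional_similarity(list(m1 = "g1", m2 = c("g2", "g3")), net)
#' @export
mirna_functional_similarity <- function(targets, net) {
  stopifnot(inherits(net, "gene_network"))
  if (is.data.frame(targets) || is.matrix(targets)) {
    df <- as.data.frame(targets)[, 1:2]
    targets <- split(as.character(df[[2]]), as.character(df[[1]]))
  }
  targets <- lapply(targets, unique)
  empty <- vapply(targets, length, integer(1)) == 0L
  if (any(empty)) {
    warning("excluding miRNAs with empty target sets: ",
            paste(names(targets)[empty], collapse = ", "))
    targets <- targets[!empty]
  }
  if (!length(targets)) stop("no miRNA with a nonempty target set")

  mirnas <- names(targets)
  n <- length(mirnas)
  # augment the similarity matrix with unknown genes (rows/cols of zeros,
  # unit diagonal) so self-hits still count
  allg <- unique(c(net$genes, unlist(targets, use.names = FALSE)))
  sim <- matrix(0, length(allg), length(allg), dimnames = list(allg, allg))
  sim[net$genes, net$genes] <- net$sim
  diag(sim) <- 1

  idx <- lapply(targets, function(g) match(g, allg))
  # best[g, j] = similarity of gene g to miRNA j's target set
  best <- vapply(idx, function(gj) {
    do.call(pmax, c(lapply(gj, function(k) sim[, k]), list(0)))
  }, numeric(length(allg)))
  sizes <- vapply(idx, length, integer(1))
  # cross[i, j] = sum over g in G_i of best-match of g against G_j
  cross <- vapply(seq_len(n), function(j)
    vapply(idx, function(gi) sum(best[gi, j]), numeric(1)), numeric(n))
  sf <- (cross + t(cross)) / outer(sizes, sizes, "+")
  dimnames(sf) <- list(mirnas, mirnas)
  pmin(pmax(sf, 0), 1)
}
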