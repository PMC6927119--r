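#' Disease ontology as a rooted directed acyclic graph
#'
#' Builds a validated DAG of disease terms from a child--parent edge table,
#' the structure underlying MeSH-style disease vocabularies. Every term must
#' reach a single root through its parent edges; when the input has several
#' maximal terms a virtual root (\code{"ROOT*"}) is inserted as their common
#' parent so that annotation frequencies can be normalized against a unique
#' top term.
#'
#' @param edges two-column data frame (or matrix) of \code{child}, \code{parent}
#'   term identifiers. Self-loops are rejected, duplicate edges collapsed.
#' @param root optional identifier of the intended root term. If \code{NULL}
#'   the unique maximal term is used, or a virtual root is inserted when
#'   several maximal terms exist.
#'
#' @return An object of class \code{"disease_dag"}: a list with
#'   \describe{
#'     \item{terms}{character vector of all term identifiers}
#'     \item{parents, children}{named lists of direct parents / direct children}
#'     \item{root}{the root identifier}
#'     \item{topo}{terms in topological order (root first)}
#'     \item{ancestors}{named list: all ancestors of each term, including the
#'       term itself}
#'   }
#' @examples
#' dag <- disease_dag(data.frame(child = c("a", "b"), parent = c("root", "a")))
#' dag$root
#' @export
disease_dag <- function(edges, root = NULL) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("child", "parent")
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  if (any(edges$child == edges$parent))
    stop("ontology edge table contains self-loops: ",
         edges$child[edges$child == edges$parent][1])
  edges <- unique(edges)

  terms <- unique(c(edges$child, edges$parent))
  maximal <- setdiff(terms, edges$child)
  if (is.null(root)) {
    if (length(maximal) == 1L) {
      root <- maximal
    } else if (length(maximal) == 0L) {
      stop("no maximal term: the parent relation contains a cycle")
    } else {
      root <- "ROOT*"
      edges <- rbind(edges, data.frame(child = maximal, parent = root))
      terms <- c(terms, root)
    }
  } else {
    root <- as.character(root)
    if (!root %in% terms) stop("declared root '", root, "' not among terms")
    orphan <- setdiff(maximal, root)
    if (length(orphan))
      edges <- rbind(edges, data.frame(child = orphan, parent = root))
  }

  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))

  topo <- .topological_order(terms, parents, edges)

  # reachability of the root from every term
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in topo) {                       # root first: parents precede children
    ps <- parents[[t]]
    anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
  }
  unreachable <- terms[!vapply(anc, function(a) root %in% a, logical(1))]
  if (length(unreachable))
    stop("terms cannot reach the root via parent edges: ",
         paste(utils::head(unreachable, 5), collapse = ", "))

  structure(list(terms = terms, parents = parents, children = children,
                 root = root, topo = topo, ancestors = anc),
            class = "disease_dag")
}

# Kahn topological sort, root first; names one offending edge on a cycle.
.topological_order <- function(terms, parents, edges) {
  indeg <- vapply(parents, length, integer(1))  # number of parents still unplaced
  placed <- character(0)
  queue <- terms[indeg == 0L]
  child_of <- split(edges$child, factor(edges$parent, levels = terms))
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    placed <- c(placed, t)
    for (ch in child_of[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(placed) < length(terms)) {
    left <- setdiff(terms, placed)
    bad <- edges[edges$child %in% left & edges$parent %in% left, , drop = FALSE]
    stop("cycle detected in ontology (e.g. edge ",
         bad$child[1], " -> ", bad$parent[1], ")")
  }
  placed
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("Disease ontology DAG:", length(x$terms), "terms, root:", x$root, "\n")
  cat("  max depth:",
      max(vapply(x$ancestors, length, integer(1))) - 1L, "\n")
  invisible(x)
}

#' Annotation corpus for an ontology
#'
#' Per-disease annotation counts from one interaction corpus (for example
#' disease--gene or disease--GO-process edge lists): the count of a disease is
#' the number of corpus records mentioning it. Terms absent from \code{counts}
#' have count zero.
#'
#' @param counts named nonnegative integer vector (names are disease ids), or a
#'   two-column data frame of (disease_id, object_id) records which is
#'   tabulated into counts.
#' @param corpus_id label for the corpus (e.g. \code{"D-G"}).
#' @return object of class \code{"corpus_annotation"} with fields
#'   \code{corpus_id} and \code{counts}.
#' @export
corpus_annotation <- function(counts, corpus_id = "corpus") {
  if (is.data.frame(counts) || (is.matrix(counts) && ncol(counts) >= 2)) {
    ids <- as.character(as.data.frame(counts)[[1]])
    counts <- table(ids)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  if (is.null(names(counts))) stop("counts must be named by disease id")
  if (any(counts < 0)) stop("annotation counts must be nonnegative")
  structure(list(corpus_id = corpus_id, counts = counts),
            class = "corpus_annotation")
}

#' Propagate annotation frequencies up a disease DAG
#'
#' The DAG frequency of a term is its own corpus count plus the sum of the
#' DAG frequencies of its direct children, evaluated in reverse topological
#' order. A term with several parents contributes to every parent lineage
#' (each child is summed once per direct parent); see
#' \code{\link{disease_semantic_similarity}} for the alternative union mode.
#'
#' @param dag a \code{\link{disease_dag}}.
#' @param ann a \code{\link{corpus_annotation}} (or a named count vector).
#' @return named numeric vector of propagated frequencies over all terms.
#' @examples
#' dag <- disease_dag(data.frame(child = c("a", "b"), parent = c("r", "a")))
#' propagate_frequency(dag, corpus_annotation(c(r = 1, a = 2, b = 4)))
#' @export
propagate_frequency <- function(dag, ann) {
  stopifnot(inherits(dag, "disease_dag"))
  counts <- if (inherits(ann, "corpus_annotation")) ann$counts else ann
  f <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  known <- intersect(names(counts), dag$terms)
  f[known] <- counts[known]
  ft <- f
  for (t in rev(dag$topo)) {              # children come after parents in topo
    ch <- dag$children[[t]]
    if (length(ch)) ft[t] <- f[t] + sum(ft[ch])
  }
  ft
}

#' Normalize propagated frequencies against the root
#'
#' Divides every propagated frequency by the root's, giving each term a value
#' in [0, 1] interpretable as its annotation probability; the root maps to 1.
#'
#' @param ft named vector from \code{\link{propagate_frequency}}.
#' @param dag the \code{\link{disease_dag}} the frequencies were computed on.
#' @return named numeric vector of normalized frequencies in [0, 1].
#' @export
normalize_frequency <- function(ft, dag) {
  stopifnot(inherits(dag, "disease_dag"))
  froot <- ft[[dag$root]]
  if (!is.finite(froot) || froot <= 0)
    stop("degenerate corpus: the root has zero propagated frequency; ",
         "no semantic similarity can be computed for this corpus")
  ft / froot
}

#' Information-content semantic similarity of a disease pair
#'
#' Similarity of two terms is the maximum over their common ancestors
#' (each term counts as its own ancestor) of
#' \code{2 log PT(a) / (log PT(d1) + log PT(d2))}, where PT is the normalized
#' annotation frequency. The maximum is attained at a most specific common
#' ancestor. Conventions: if either term has PT = 0 the similarity is 0 (no
#' information content); the root (PT = 1) contributes 0; a pair whose
#' denominator is 0 (both at the root) scores 0.
#'
#' @param pt named normalized-frequency vector
#'   (from \code{\link{normalize_frequency}}).
#' @param dag a \code{\link{disease_dag}}.
#' @param d1,d2 term identifiers.
#' @return similarity score in [0, 1].
#' @export
semantic_similarity_pair <- function(pt, dag, d1, d2) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!d1 %in% dag$terms) stop("unknown term: ", d1)
  if (!d2 %in% dag$terms) stop("unknown term: ", d2)
  p1 <- pt[[d1]]; p2 <- pt[[d2]]
  if (p1 <= 0 || p2 <= 0) return(0)
  denom <- log(p1) + log(p2)
  if (denom == 0) return(0)               # both at the root
  com <- intersect(dag$ancestors[[d1]], dag$ancestors[[d2]])
  num <- 2 * min(log(pt[com]))            # deepest common ancestor wins
  min(max(num / denom, 0), 1)
}

#' Disease semantic similarity matrices from annotation corpora
#'
#' One symmetric similarity matrix per corpus: annotation counts are
#' propagated up the DAG, normalized against the root, and every term pair is
#' scored by the information content of its most specific common ancestor.
#'
#' @param dag a \code{\link{disease_dag}}.
#' @param corpora a single \code{\link{corpus_annotation}} or a list of them.
#' @param mode \code{"as-written"} (default) sums each child's propagated
#'   frequency once per direct parent, so multi-parent terms contribute to
#'   every lineage; \code{"union"} counts each term's own annotation once per
#'   ancestor (set-union propagation).
#' @param terms optional subset/order of terms for the output matrices
#'   (defaults to all DAG terms).
#' @return a named list of symmetric matrices with entries in [0, 1], one per
#'   corpus.
#' @examples
#' dag <- disease_dag(data.frame(child = c("a", "b", "c", "c"),
#'                               parent = c("r", "r", "a", "b")))
#' ann <- corpus_annotation(c(a = 2, b = 1, c = 4))
#' disease_semantic_similarity(dag, ann)
#' @export
disease_semantic_similarity <- function(dag, corpora,
                                        mode = c("as-written", "union"),
                                        terms = NULL) {
  stopifnot(inherits(dag, "disease_dag"))
  mode <- match.arg(mode)
  if (inherits(corpora, "corpus_annotation")) corpora <- list(corpora)
  if (!length(corpora)) stop("at least one annotation corpus is required")
  if (is.null(terms)) terms <- dag$terms
  stopifnot(all(terms %in% dag$terms))

  out <- lapply(corpora, function(ann) {
    ft <- if (mode == "as-written") propagate_frequency(dag, ann)
          else .propagate_frequency_union(dag, ann)
    pt <- normalize_frequency(ft, dag)
    .semantic_similarity_matrix(pt, dag, terms)
  })
  names(out) <- vapply(seq_along(corpora), function(i) {
    ann <- corpora[[i]]
    if (inherits(ann, "corpus_annotation") && nzchar(ann$corpus_id))
      ann$corpus_id else paste0("corpus", i)
  }, character(1))
  out
}

# union-mode propagation: each term's own count reaches every ancestor once
.propagate_frequency_union <- function(dag, ann) {
  counts <- if (inherits(ann, "corpus_annotation")) ann$counts else ann
  f <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  known <- intersect(names(counts), dag$terms)
  f[known] <- counts[known]
  ft <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (t in dag$terms) ft[dag$ancestors[[t]]] <- ft[dag$ancestors[[t]]] + f[t]
  ft
}

# Vectorized pairwise similarity: sweep ancestors from shallow to deep,
# overwriting the stored log PT for every pair they cover, so each pair ends
# with its deepest (most specific) common ancestor's log PT.
.semantic_similarity_matrix <- function(pt, dag, terms) {
  n <- length(terms)
  lpt <- log(pmax(pt[terms], .Machine$double.xmin))
  is_anc <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  for (t in terms)
    is_anc[t, intersect(dag$ancestors[[t]], terms)] <- TRUE
  # ancestors outside `terms` still matter for pairs within `terms`
  extra <- setdiff(unique(unlist(dag$ancestors[terms], use.names = FALSE)), terms)
  anc_all <- c(terms, extra)
  cover <- matrix(FALSE, n, length(anc_all), dimnames = list(terms, anc_all))
  for (t in terms) cover[t, dag$ancestors[[t]]] <- TRUE
  lanc <- log(pmax(pt[anc_all], .Machine$double.xmin))

  minlog <- matrix(NA_real_, n, n, dimnames = list(terms, terms))
  for (a in anc_all[order(lanc, decreasing = TRUE)]) {
    idx <- which(cover[, a])
    if (length(idx)) minlog[idx, idx] <- lanc[[a]]
  }
  denom <- outer(lpt, lpt, "+")
  s <- 2 * minlog / denom
  s[!is.finite(s)] <- 0                   # denom 0 (both at root) or no overlap
  zero <- pt[terms] <= 0
  s[zero, ] <- 0
  s[, zero] <- 0
  s[is.na(s)] <- 0
  s <- pmin(pmax(s, 0), 1)
  diag(s)[pt[terms] < 1 & pt[terms] > 0] <- 1
  s
}
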