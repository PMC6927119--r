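# Independent oracle implementations used to validate the package's fast
# paths. Each deliberately follows a different route than the implementation.

# Pairwise semantic similarity by literal enumeration: common ancestors,
# reduced to the most specific ones (no descendant also a common ancestor),
# then the max information-content ratio.
oracle_semantic_pair <- function(pt, dag, d1, d2) {
  p1 <- pt[[d1]]; p2 <- pt[[d2]]
  if (p1 <= 0 || p2 <= 0) return(0)
  common <- intersect(dag$ancestors[[d1]], dag$ancestors[[d2]])
  com <- Filter(function(a) {
    # most specific: no other common ancestor has a among its proper ancestors
    !any(vapply(setdiff(common, a),
                function(b) a %in% dag$ancestors[[b]], logical(1)))
  }, common)
  denom <- log(p1) + log(p2)
  if (denom == 0) return(0)
  best <- max(vapply(com, function(a) 2 * log(pt[[a]]) / denom, numeric(1)))
  min(max(best, 0), 1)
}

oracle_semantic_matrix <- function(pt, dag, terms = dag$terms) {
  n <- length(terms)
  s <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n))
    for (j in seq_len(n))
      s[i, j] <- oracle_semantic_pair(pt, dag, terms[i], terms[j])
  s
}

# Brute-force miRNA functional similarity: double loop over target sets.
oracle_mirna_similarity <- function(targets, sim_with_unit_diag) {
  sg <- function(g, set) {
    if (g %in% set) return(1)
    hits <- intersect(set, rownames(sim_with_unit_diag))
    if (!g %in% rownames(sim_with_unit_diag) || !length(hits)) return(0)
    max(sim_with_unit_diag[g, hits])
  }
  n <- length(targets)
  out <- matrix(0, n, n, dimnames = list(names(targets), names(targets)))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      gi <- targets[[i]]; gj <- targets[[j]]
      out[i, j] <- (sum(vapply(gi, sg, numeric(1), set = gj)) +
                    sum(vapply(gj, sg, numeric(1), set = gi))) /
        (length(gi) + length(gj))
    }
  out
}

# Generic constrained QP oracle for the kernel reconstruction weights:
# column-wise bound-constrained minimization by L-BFGS-B, independent of the
# multiplicative-update path.
oracle_ksns_qp <- function(k, c_ind, mu1, mu2) {
  n <- nrow(k)
  w <- matrix(0, n, n)
  for (j in seq_len(n)) {
    free <- setdiff(seq_len(n), j)
    fn <- function(wf) {
      wj <- numeric(n); wj[free] <- wf
      0.5 * drop(t(wj) %*% k %*% wj) - sum(k[, j] * wj) + 0.5 * k[j, j] +
        mu1 / 2 * sum(((1 - c_ind[, j]) * wj)^2) + mu2 / 2 * sum(wj^2)
    }
    gr <- function(wf) {
      wj <- numeric(n); wj[free] <- wf
      g <- drop(k %*% wj) - k[, j] + mu1 * (1 - c_ind[, j])^2 * wj + mu2 * wj
      g[free]
    }
    res <- stats::optim(rep(1 / n, n - 1), fn, gr, method = "L-BFGS-B",
                        lower = 0, control = list(factr = 1e1, maxit = 2000))
    w[free, j] <- res$par
  }
  dimnames(w) <- dimnames(k)
  w
}

# Rank-statistic (Mann-Whitney) AUC with tie correction.
oracle_rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Exhaustive two-sided Fisher p-value: sum hypergeometric probabilities of
# all tables with the observed margins whose probability does not exceed the
# observed table's (within fisher.test's relative tolerance).
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  d <- stats::dhyper(support, m, n, kk)
  obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(d[d <= obs * (1 + 1e-7)])
}

# small random symmetric similarity matrix in [0,1] with unit diagonal
random_similarity <- function(n, seed = 1) {
  set.seed(seed)
  s <- matrix(stats::runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("e", seq_len(n)), paste0("e", seq_len(n)))
  s
}

# tiny fixture DAG: root <- {a, b}; c under both a and b; d under a
fixture_dag <- function() {
  disease_dag(data.frame(
    child  = c("a", "b", "c", "c", "d"),
    parent = c("root", "root", "a", "b", "a")))
}

fixture_counts <- c(root = 1, a = 1, b = 0, c = 1, d = 2)
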