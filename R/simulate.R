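#' Simulate a disease ontology with annotation corpora
#'
#' Generates a rooted MeSH-style DAG by attaching each new term to one or two
#' already-placed parents, plus per-term annotation counts for each corpus
#' drawn from a zero-inflated Poisson (emulating disease--gene and
#' disease--GO-process corpora of different densities). Deterministic per
#' seed.
#'
#' @param n_terms number of disease terms including the root (>= 2).
#' @param branching mean children per term; controls DAG width (default 3).
#' @param n_corpora number of annotation corpora (default 2).
#' @param corpus_density probability that a term is annotated at all in a
#'   corpus (default 0.8).
#' @param mean_count mean annotation count of annotated terms (default 5).
#' @param multi_parent_p probability that a term gets a second parent
#'   (default 0.15).
#' @param seed integer seed.
#' @return list with \code{dag} (a \code{\link{disease_dag}}), \code{edges}
#'   (the child--parent table) and \code{corpora} (list of
#'   \code{\link{corpus_annotation}}).
#' @export
simulate_disease_ontology <- function(n_terms = 150, branching = 3,
                                      n_corpora = 2, corpus_density = 0.8,
                                      mean_count = 5, multi_parent_p = 0.15,
                                      seed = 1) {
  stopifnot(n_terms >= 2)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  terms <- c("ROOT", sprintf("D%03d", seq_len(n_terms - 1)))
  child <- parent <- character(0)
  for (i in 2:n_terms) {
    # prefer recent terms as parents, giving depth ~ log(n)/log(branching)
    cand <- seq_len(i - 1)
    w <- (cand / (i - 1))^(branching - 1)
    p1 <- sample(cand, 1, prob = w)
    child <- c(child, terms[i]); parent <- c(parent, terms[p1])
    if (i > 2 && stats::runif(1) < multi_parent_p) {
      p2 <- sample(setdiff(cand, p1), 1)
      child <- c(child, terms[i]); parent <- c(parent, terms[p2])
    }
  }
  edges <- data.frame(child = child, parent = parent)
  dag <- disease_dag(edges, root = "ROOT")
  corpora <- lapply(seq_len(n_corpora), function(ci) {
    annotated <- stats::runif(n_terms) < corpus_density
    counts <- ifelse(annotated, stats::rpois(n_terms, mean_count) + 1L, 0L)
    corpus_annotation(stats::setNames(counts, terms),
                      corpus_id = paste0("corpus", ci))
  })
  list(dag = dag, edges = edges, corpora = corpora)
}

#' Simulate a weighted gene network with miRNA target sets
#'
#' Random symmetric gene graph with positive log-likelihood-style edge scores
#' at the requested density (emulating a functional gene network), plus a
#' nonempty random target-gene set per miRNA. Deterministic per seed.
#'
#' @param n_mirnas number of miRNAs.
#' @param n_genes number of genes (>= 2).
#' @param network_density fraction of gene pairs carrying an edge
#'   (default 0.05).
#' @param target_set_size mean targets per miRNA (default 10; at least one is
#'   guaranteed).
#' @param seed integer seed.
#' @return list with \code{network} (a \code{\link{gene_network}}),
#'   \code{edges} (the score table) and \code{targets} (named list of target
#'   sets).
#' @export
simulate_gene_side <- function(n_mirnas = 200, n_genes = 400,
                               network_density = 0.05, target_set_size = 10,
                               seed = 1) {
  stopifnot(n_genes >= 2, network_density > 0, network_density <= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  pairs <- utils::combn(n_genes, 2)
  keep <- stats::runif(ncol(pairs)) < network_density
  if (!any(keep)) keep[1] <- TRUE
  edges <- data.frame(a = genes[pairs[1, keep]], b = genes[pairs[2, keep]],
                      score = stats::rgamma(sum(keep), shape = 2, rate = 1))
  net <- gene_network(edges, genes = genes)
  mirnas <- sprintf("M%04d", seq_len(n_mirnas))
  targets <- lapply(mirnas, function(m) {
    sz <- max(1L, stats::rpois(1, target_set_size))
    sample(genes, min(sz, n_genes))
  })
  names(targets) <- mirnas
  list(network = net, edges = edges, targets = targets)
}

#' Plant a low-rank interaction structure on similarity networks
#'
#' Latent factors for miRNAs and diseases are random rotations of the leading
#' non-trivial eigenvectors of the respective similarity matrices, i.e. the
#' smoothest graph signals -- so similar entities carry similar factors, the
#' assumption the propagation model exploits, and the planted structure is
#' recoverable from the similarity networks by construction. The
#' rank-\code{latent_rank} factor product is passed through a steep logistic
#' gate whose offset is calibrated so the expected interaction density equals
#' \code{density}: a small set of "hot" miRNA--disease pairs interacts with
#' probability near \code{p_high} against a \code{p_low} background. With
#' probability \code{noise} a cell ignores the planted signal and is drawn at
#' the background density (mixture noise). A fraction \code{holdout} of the
#' sampled true pairs is removed from the observed matrix and returned as
#' held-out evaluation positives. Deterministic per seed.
#'
#' @param mirna_sim,disease_sim similarity matrices defining the smoothing
#'   graphs (typically from the other simulators).
#' @param latent_rank rank of the planted structure (default 5).
#' @param density target fraction of observed interactions (default 0.05).
#' @param noise probability that a cell ignores the planted signal
#'   (default 0.05).
#' @param holdout fraction of sampled true pairs hidden from the observed
#'   matrix (default 0.1).
#' @param p_high,p_low interaction probability of hot pairs and of the
#'   background (defaults 0.7 and 0.003).
#' @param gate_width logistic width of the hot/cold transition on the
#'   standardized latent score (default 0.25).
#' @param seed integer seed.
#' @return list with \code{x} (observed binary matrix), \code{heldout}
#'   (cell indices of hidden positives), \code{prob} (the probability matrix).
#' @export
simulate_interactions <- function(mirna_sim, disease_sim, latent_rank = 5,
                                  density = 0.05, noise = 0.05, holdout = 0.1,
                                  p_high = 0.7, p_low = 0.003,
                                  gate_width = 0.25, seed = 1) {
  nm <- nrow(mirna_sim); nd <- nrow(disease_sim)
  stopifnot(latent_rank <= min(nm, nd) - 1L, density > 0, density <= 1,
            noise >= 0, noise <= 1, p_low < density, density < p_high)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  factors <- function(s, r) {
    ev <- eigen(s, symmetric = TRUE)$vectors[, 1 + seq_len(r), drop = FALSE]
    ev %*% matrix(stats::rnorm(r * r), r)
  }
  a <- factors(mirna_sim, latent_rank)
  b <- factors(disease_sim, latent_rank)
  z <- tcrossprod(scale(a), scale(b)) / latent_rank
  z <- (z - mean(z)) / stats::sd(z)
  gate <- function(t) p_low + (p_high - p_low) * stats::plogis((z - t) / gate_width)
  zq <- stats::uniroot(function(t) mean(gate(t)) - density, c(-50, 50))$root
  prob <- (1 - noise) * gate(zq) + noise * density
  x <- matrix(stats::rbinom(nm * nd, 1, prob), nm, nd,
              dimnames = list(rownames(mirna_sim), rownames(disease_sim)))
  ones <- which(x == 1)
  heldout <- sort(sample(ones, round(holdout * length(ones))))
  x[heldout] <- 0
  list(x = x, heldout = heldout, prob = prob)
}

#' Simulate a complete input bundle
#'
#' Generates, with one seed, everything the prediction pipeline consumes: a
#' disease ontology with annotation corpora (fused into the disease semantic
#' similarity), a weighted gene network with miRNA target sets (giving the
#' miRNA functional similarity), and an interaction matrix with structure
#' planted on those very similarities so that held-out interactions are
#' recoverable in principle.
#'
#' @inheritParams simulate_interactions
#' @inheritParams simulate_gene_side
#' @param n_diseases number of disease terms (default 150).
#' @param dag_branching,corpus_density,multi_parent_p forwarded to
#'   \code{\link{simulate_disease_ontology}}.
#' @param fusion_dim,restart_p fusion settings used when building the disease
#'   semantic similarity from the per-corpus matrices.
#' @param seed integer seed controlling the whole bundle.
#' @return list with \code{x}, \code{heldout}, \code{prob},
#'   \code{mirna_sim} (functional similarity), \code{disease_sim} (fused
#'   semantic similarity), \code{corpus_sims} (per-corpus matrices),
#'   \code{ontology}, \code{gene_side}, and \code{config}.
#' @examples
#' dat <- simulate_knmbp_data(n_mirnas = 20, n_diseases = 15, n_genes = 30,
#'                            latent_rank = 2, seed = 7)
#' dim(dat$x)
#' @export
simulate_knmbp_data <- function(n_mirnas = 200, n_diseases = 150,
                                n_genes = 400, latent_rank = 5,
                                density = 0.05, noise = 0.05, holdout = 0.1,
                                dag_branching = 3, corpus_density = 0.8,
                                multi_parent_p = 0.15,
                                network_density = 0.05, target_set_size = 10,
                                fusion_dim = NULL, restart_p = 0.5,
                                seed = 1) {
  ont <- simulate_disease_ontology(n_terms = n_diseases,
                                   branching = dag_branching,
                                   corpus_density = corpus_density,
                                   multi_parent_p = multi_parent_p,
                                   seed = seed)
  corpus_sims <- disease_semantic_similarity(ont$dag, ont$corpora)
  disease_sim <- fuse_similarity(corpus_sims, d = fusion_dim,
                                 restart_p = restart_p)
  gs <- simulate_gene_side(n_mirnas = n_mirnas, n_genes = n_genes,
                           network_density = network_density,
                           target_set_size = target_set_size,
                           seed = seed + 1L)
  mirna_sim <- mirna_functional_similarity(gs$targets, gs$network)
  inter <- simulate_interactions(mirna_sim, disease_sim,
                                 latent_rank = latent_rank, density = density,
                                 noise = noise, holdout = holdout,
                                 seed = seed + 2L)
  c(inter,
    list(mirna_sim = mirna_sim, disease_sim = disease_sim,
         corpus_sims = corpus_sims, ontology = ont, gene_side = gs,
         config = list(n_mirnas = n_mirnas, n_diseases = n_diseases,
                       n_genes = n_genes, latent_rank = latent_rank,
                       density = density, noise = noise, holdout = holdout,
                       seed = seed)))
}
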