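#' Cross-validation fold plan for a bipartite interaction matrix
#'
#' Three schemes: \code{"pairs"} partitions the cells (known 1-entries and
#' 0-entries stratified separately so each fold holds an equal share of both),
#' probing new interactions; \code{"mirnas"} partitions whole rows, probing
#' new miRNAs; \code{"diseases"} partitions whole columns. Fold sizes differ
#' by at most one within each stratum. Deterministic given the seed.
#'
#' @param x binary interaction matrix.
#' @param mode \code{"pairs"}, \code{"mirnas"} or \code{"diseases"}.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return object of class \code{"cv_plan"}: list with \code{mode}, \code{k},
#'   \code{seed} and \code{fold} (a matrix of cell fold ids for pairs mode, a
#'   vector of row/column fold ids otherwise).
#' @export
cv_folds <- function(x, mode = c("pairs", "mirnas", "diseases"), k = 5,
                     seed = 1) {
  mode <- match.arg(mode)
  stopifnot(k >= 2)
  n_units <- switch(mode, pairs = length(x), mirnas = nrow(x),
                    diseases = ncol(x))
  if (k > n_units) stop("more folds than units")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  balanced <- function(n) sample(rep_len(sample(k), n))
  if (mode == "pairs") {
    fold <- matrix(NA_integer_, nrow(x), ncol(x), dimnames = dimnames(x))
    pos <- which(x == 1)
    neg <- which(x != 1)
    fold[pos] <- balanced(length(pos))
    fold[neg] <- balanced(length(neg))
  } else {
    n <- if (mode == "mirnas") nrow(x) else ncol(x)
    fold <- balanced(n)
    names(fold) <- if (mode == "mirnas") rownames(x) else colnames(x)
  }
  structure(list(mode = mode, k = k, seed = seed, fold = fold),
            class = "cv_plan")
}

#' Training matrix and test index set for one fold
#'
#' Masks the fold's test cells (or whole rows/columns) to zero in the
#' training matrix, so every interaction-derived quantity downstream is
#' recomputed without any test information.
#'
#' @param x binary interaction matrix.
#' @param plan a \code{\link{cv_folds}} plan.
#' @param fold fold number in \code{1..k}.
#' @return list with \code{train} (masked matrix) and \code{test} (integer
#'   cell indices into \code{x}).
#' @export
cv_split <- function(x, plan, fold) {
  stopifnot(inherits(plan, "cv_plan"), fold >= 1, fold <= plan$k)
  test <- switch(plan$mode,
    pairs = which(plan$fold == fold),
    mirnas = which(row(x) %in% which(plan$fold == fold)),
    diseases = which(col(x) %in% which(plan$fold == fold)))
  train <- x
  train[test] <- 0L        # integer zero: does not promote integer matrices
  list(train = train, test = test)
}

.save_seed <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
.restore_seed <- function(old) {
  if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
  else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Min--max normalization of prediction scores
#'
#' Maps scores linearly onto [0, 1]. Constant inputs map to all zeros with a
#' warning.
#'
#' @param ps numeric vector (or matrix) of prediction scores.
#' @return normalized scores of the same shape.
#' @export
minmax_normalize <- function(ps) {
  rng <- range(ps)
  if (rng[1] == rng[2]) {
    warning("constant scores: normalized to 0")
    return(ps * 0)
  }
  (ps - rng[1]) / (rng[2] - rng[1])
}

#' Threshold-grid ROC curve and AUC
#'
#' Evaluates the classifier over an even grid of thresholds on [0, 1]
#' (\code{n_thresholds} intervals, so \code{n_thresholds + 1} grid points
#' including both endpoints); a pair is called positive when its normalized
#' score is \code{>=} the threshold. With per-fold inputs the TPR and FPR are
#' computed per fold and averaged at each threshold; the AUC is the
#' trapezoidal area under the mean curve (anchored at (0, 0)).
#'
#' @param scores numeric vector of scores, or a list of per-fold score
#'   vectors. Scores are min--max normalized (per fold) before thresholding.
#' @param labels 0/1 vector, or list matching \code{scores}.
#' @param n_thresholds number of grid intervals (default 1000).
#' @return object of class \code{"knmbp_roc"}: list with \code{thresholds},
#'   \code{tpr}, \code{fpr} (mean curves), \code{auc}, \code{folds}.
#' @examples
#' r <- roc_auc(c(.9, .8, .4, .2), c(1, 1, 0, 0))
#' r$auc
#' @export
roc_auc <- function(scores, labels, n_thresholds = 1000) {
  if (!is.list(scores)) { scores <- list(scores); labels <- list(labels) }
  stopifnot(length(scores) == length(labels))
  thr <- seq(0, 1, length.out = n_thresholds + 1)
  curves <- Map(function(s, l) {
    l <- as.numeric(l)
    if (length(unique(l)) < 2)
      stop("AUC undefined: both classes must be present")
    s <- minmax_normalize(as.numeric(s))
    np <- sum(l == 1); nn <- sum(l == 0)
    # counts of scores >= t (sorted scores + binary search per threshold)
    sp <- sort(s[l == 1]); sn <- sort(s[l == 0])
    tp <- np - findInterval(thr, sp, left.open = TRUE)
    fp <- nn - findInterval(thr, sn, left.open = TRUE)
    cbind(tpr = tp / np, fpr = fp / nn)
  }, scores, labels)
  tpr <- rowMeans(vapply(curves, function(cu) cu[, "tpr"], numeric(length(thr))))
  fpr <- rowMeans(vapply(curves, function(cu) cu[, "fpr"], numeric(length(thr))))
  # thresholds descend left to right on the ROC plane; anchor at (0, 0)
  ox <- c(0, rev(fpr)); oy <- c(0, rev(tpr))
  auc <- sum(diff(ox) * (utils::head(oy, -1) + utils::tail(oy, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 folds = length(curves)),
            class = "knmbp_roc")
}

#' @export
print.knmbp_roc <- function(x, ...) {
  cat(sprintf("Threshold-grid ROC over %d fold(s): AUC = %.5f\n",
              x$folds, x$auc))
  invisible(x)
}

#' @export
plot.knmbp_roc <- function(x, ...) {
  graphics::plot(c(0, rev(x$fpr)), c(0, rev(x$tpr)), type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.4f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Top/bottom Fisher enrichment of ranked candidates
#'
#' Splits a ranked candidate list into a Top group (first \code{group_size})
#' and a Bottom group (last \code{group_size}) and tests, by a two-sided
#' Fisher exact test on the 2x2 confirmed-by-group table, whether confirmed
#' candidates concentrate in the Top group.
#'
#' @param ranked candidate identifiers in decreasing score order (a character
#'   vector), or a named numeric score vector which is sorted internally.
#' @param confirmed character vector of externally confirmed identifiers.
#' @param group_size candidates per group (default 20).
#' @return list with \code{table} (2x2 counts), \code{p_value},
#'   \code{proportions} (confirmed fraction in each group).
#' @examples
#' fisher_top_bottom(paste0("m", 1:40), paste0("m", c(1:18, 39, 40)))
#' @export
fisher_top_bottom <- function(ranked, confirmed, group_size = 20) {
  if (is.numeric(ranked)) {
    if (is.null(names(ranked))) stop("numeric scores must be named")
    ranked <- names(sort(ranked, decreasing = TRUE))
  }
  n <- length(ranked)
  if (n < 2 * group_size)
    stop("need at least ", 2 * group_size, " candidates, got ", n)
  top <- ranked[seq_len(group_size)]
  bottom <- ranked[seq.int(n - group_size + 1L, n)]
  tab <- rbind(confirmed = c(top = sum(top %in% confirmed),
                             bottom = sum(bottom %in% confirmed)),
               unconfirmed = c(group_size - sum(top %in% confirmed),
                               group_size - sum(bottom %in% confirmed)))
  colnames(tab) <- c("top", "bottom")
  list(table = tab,
       p_value = stats::fisher.test(tab)$p.value,
       proportions = tab["confirmed", ] / group_size)
}

#' Cross-validated evaluation of the propagation model
#'
#' Runs k-fold cross-validation under one of the three schemes of
#' \code{\link{cv_folds}}, refitting the entire pipeline (profile correction,
#' kernel neighbourhood similarity, fusion, propagation) on each training
#' matrix, and scores the held-out cells by the threshold-grid ROC. The AUC
#' is averaged over seed repetitions (four by default).
#'
#' @inheritParams knmbp
#' @param mode cross-validation scheme, see \code{\link{cv_folds}}.
#' @param folds number of folds (default 5).
#' @param seeds integer vector of seeds; one complete CV per seed.
#' @param n_thresholds ROC grid intervals (default 1000).
#' @param ... further arguments passed to \code{\link{knmbp}}.
#' @return object of class \code{"knmbp_cv"}: list with \code{auc} (mean over
#'   seeds), \code{seed_aucs}, \code{roc} (per-seed ROC objects), \code{mode},
#'   \code{k}, \code{seeds}.
#' @export
cv_knmbp <- function(x, mirna_sim, disease_sim,
                     mode = c("pairs", "mirnas", "diseases"),
                     folds = 5, seeds = 1:4, n_thresholds = 1000, ...) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  rocs <- lapply(seeds, function(seed) {
    plan <- cv_folds(x, mode = mode, k = folds, seed = seed)
    sc <- vector("list", folds); lb <- vector("list", folds)
    for (fold in seq_len(folds)) {
      sp <- cv_split(x, plan, fold)
      fit <- knmbp(sp$train, mirna_sim, disease_sim, ...)
      sc[[fold]] <- fit$scores[sp$test]
      lb[[fold]] <- x[sp$test]
    }
    roc_auc(sc, lb, n_thresholds = n_thresholds)
  })
  seed_aucs <- vapply(rocs, function(r) r$auc, numeric(1))
  structure(list(auc = mean(seed_aucs), seed_aucs = seed_aucs, roc = rocs,
                 mode = mode, folds = folds, seeds = seeds),
            class = "knmbp_cv")
}

#' @export
print.knmbp_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s), %d seed(s)\n",
              x$folds, x$mode, length(x$seeds)))
  cat(sprintf("  AUC per seed: %s\n",
              paste(sprintf("%.4f", x$seed_aucs), collapse = ", ")))
  cat(sprintf("  mean AUC: %.5f\n", x$auc))
  invisible(x)
}

#' @export
plot.knmbp_cv <- function(x, ...) {
  plot(x$roc[[1]], ...)
  if (length(x$roc) > 1)
    for (r in x$roc[-1])
      graphics::lines(c(0, rev(r$fpr)), c(0, rev(r$tpr)), col = "grey60")
  invisible(x)
}

#' Exhaustive grid search over model parameters
#'
#' Evaluates every combination of the supplied parameter values by
#' cross-validation and returns the full AUC table with the best combination.
#' Defaults cover the standard search ranges (neighbour proportion 10--90%,
#' penalties \code{2^0..2^4}, Laplacian weight \code{2^-2..2^2} with the two
#' graph weights tied).
#'
#' @inheritParams cv_knmbp
#' @param pn,mu1,mu2,lambda parameter value vectors defining the grid.
#' @param ... passed on to \code{\link{cv_knmbp}} / \code{\link{knmbp}}.
#' @return object of class \code{"knmbp_grid"}: list with \code{table} (one
#'   row per combination with its AUC) and \code{best} (the arg-max row).
#' @export
grid_search_knmbp <- function(x, mirna_sim, disease_sim,
                              pn = c(.1, .3, .5, .7, .9),
                              mu1 = 2^(0:4), mu2 = 2^(0:4),
                              lambda = 2^(-2:2),
                              mode = "pairs", folds = 5, seeds = 1, ...) {
  grid <- expand.grid(pn = pn, mu1 = mu1, mu2 = mu2, lambda = lambda)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_knmbp(x, mirna_sim, disease_sim, mode = mode, folds = folds, seeds = seeds,
             pn = grid$pn[i], mu1 = grid$mu1[i], mu2 = grid$mu2[i],
             lambda = grid$lambda[i], ...)$auc
  }, numeric(1))
  best <- grid[which.max(grid$auc), , drop = FALSE]
  structure(list(table = grid, best = best), class = "knmbp_grid")
}

#' @export
print.knmbp_grid <- function(x, ...) {
  cat("Grid search over", nrow(x$table), "parameter combinations\n")
  cat("Best:\n"); print(x$best, row.names = FALSE)
  invisible(x)
}

#' Marginal AUC summaries of a grid-search table
#'
#' For every combination of the two focal parameters, the max, mean and min
#' AUC over all values of the remaining parameters - the standard pairwise
#' sensitivity summary.
#'
#' @param grid a \code{\link{grid_search_knmbp}} result (or its table).
#' @param by two parameter names out of \code{pn}, \code{mu1}, \code{mu2},
#'   \code{lambda}.
#' @return data frame with the focal parameters and \code{max_auc},
#'   \code{mean_auc}, \code{min_auc}.
#' @export
auc_margins <- function(grid, by = c("pn", "lambda")) {
  tab <- if (inherits(grid, "knmbp_grid")) grid$table else grid
  stopifnot(all(by %in% names(tab)), length(by) == 2)
  agg <- function(f) stats::aggregate(tab$auc, tab[by], f)
  out <- agg(max)
  names(out)[3] <- "max_auc"
  out$mean_auc <- agg(mean)$x
  out$min_auc <- agg(min)$x
  out
}
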