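test_that("pair folds stratify known and unknown cells evenly", {
  set.seed(1)
  x <- matrix(0, 10, 10)
  x[sample(100, 10)] <- 1
  plan <- cv_folds(x, "pairs", k = 5, seed = 3)
  for (fold in 1:5) {
    test <- which(plan$fold == fold)
    expect_equal(sum(x[test] == 1), 2)
    expect_equal(sum(x[test] == 0), 18)
  }
  # partition: disjoint and exhaustive
  expect_setequal(unlist(lapply(1:5, function(f) which(plan$fold == f))),
                  seq_len(100))
  # determinism
  expect_identical(cv_folds(x, "pairs", k = 5, seed = 3)$fold, plan$fold)
  expect_false(identical(cv_folds(x, "pairs", k = 5, seed = 4)$fold,
                         plan$fold))
})

test_that("row/column folds partition entities with near-equal sizes", {
  x <- matrix(rbinom(12 * 7, 1, .3), 12, 7)
  pm <- cv_folds(x, "mirnas", k = 5, seed = 1)
  expect_setequal(unlist(lapply(1:5, function(f) which(pm$fold == f))), 1:12)
  expect_lte(diff(range(table(pm$fold))), 1)
  pd <- cv_folds(x, "diseases", k = 5, seed = 1)
  expect_lte(diff(range(table(pd$fold))), 1)
  expect_error(cv_folds(x, "diseases", k = 9, seed = 1), "more folds")
})

test_that("cv_split masks exactly the test cells", {
  x <- matrix(rbinom(30, 1, .4), 6, 5)
  plan <- cv_folds(x, "mirnas", k = 3, seed = 2)
  sp <- cv_split(x, plan, 1)
  expect_true(all(sp$train[sp$test] == 0))
  expect_identical(sp$train[-sp$test], x[-sp$test])
  # poisoning the test cells does not change the training matrix
  x2 <- x
  x2[sp$test] <- 99
  expect_equal(cv_split(x2, plan, 1)$train, sp$train, ignore_attr = TRUE)
})

test_that("min-max normalization maps onto [0,1] exactly", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_equal(minmax_normalize(c(0, .4, 1)), c(0, .4, 1))
  expect_warning(out <- minmax_normalize(c(2, 2, 2)), "constant")
  expect_equal(out, c(0, 0, 0))
})

test_that("grid AUC is exact for perfect ranking and matches rank AUC", {
  expect_equal(roc_auc(c(.9, .8, .4, .2), c(1, 1, 0, 0))$auc, 1.0)
  # 6-point fixture with a tie across classes
  s <- c(.9, .7, .5, .5, .3, .1)
  l <- c(1, 1, 1, 0, 0, 0)
  expect_lt(abs(roc_auc(s, l)$auc - oracle_rank_auc(s, l)), 1 / 1000)
  # random scores, larger n
  set.seed(8)
  s2 <- runif(2000)
  l2 <- rbinom(2000, 1, .3)
  expect_lt(abs(roc_auc(s2, l2)$auc - oracle_rank_auc(s2, l2)), 1 / 1000)
  expect_lt(abs(roc_auc(s2, l2)$auc - 0.5), 0.05)
  # invariance under strictly increasing transforms (within grid resolution)
  expect_lt(abs(roc_auc(exp(3 * s2), l2)$auc - roc_auc(s2, l2)$auc), 2 / 1000)
  expect_error(roc_auc(s2, rep(1, 2000)), "both classes")
})

test_that("ROC curves are monotone in the threshold", {
  set.seed(9)
  r <- roc_auc(runif(300), rbinom(300, 1, .4))
  expect_true(all(diff(r$tpr) <= 0))
  expect_true(all(diff(r$fpr) <= 0))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
})

test_that("fold-mean ROC averages per-fold rates", {
  s <- list(c(.9, .1), c(.8, .2))
  l <- list(c(1, 0), c(1, 0))
  r <- roc_auc(s, l, n_thresholds = 10)
  expect_equal(r$auc, 1)
  expect_equal(r$folds, 2)
})

test_that("top/bottom Fisher test reproduces exact hypergeometric enumeration", {
  # all 2x2 tables with margins up to 12 against the enumeration oracle
  for (m in c(6, 12)) for (k1 in 0:m) for (k2 in 0:m) {
    tab <- rbind(c(k1, k2), c(m - k1, m - k2))
    expect_equal(stats::fisher.test(tab)$p.value,
                 oracle_fisher_two_sided(tab), tolerance = 1e-10)
  }
})

test_that("ranked-candidate Fisher groups split top and bottom correctly", {
  ranked <- paste0("m", 1:50)
  confirmed <- paste0("m", c(1:18, 49, 50))   # 18 in top-20, 2 in bottom-20
  ft <- fisher_top_bottom(ranked, confirmed, group_size = 20)
  expect_equal(unname(ft$table["confirmed", ]), c(18, 2))
  expect_equal(ft$proportions, c(top = 0.9, bottom = 0.1))
  # identical confirmation counts -> no association
  even <- fisher_top_bottom(ranked, paste0("m", c(1:5, 46:50)), 20)
  expect_equal(even$p_value, 1)
  # named scores are sorted internally
  sc <- stats::setNames(seq(50, 1), paste0("m", 1:50))
  expect_equal(fisher_top_bottom(sc, confirmed, 20)$p_value, ft$p_value)
  expect_error(fisher_top_bottom(ranked[1:30], confirmed, 20), "at least")
})

test_that("grid search covers the grid and marginal summaries recompute", {
  set.seed(10)
  dat <- simulate_knmbp_data(n_mirnas = 20, n_diseases = 15, n_genes = 30,
                             latent_rank = 2, density = 0.15, seed = 21)
  gr <- grid_search_knmbp(dat$x, dat$mirna_sim, dat$disease_sim,
                          pn = c(.3, .7), mu1 = 2, mu2 = 2, lambda = c(.5, 2),
                          folds = 3, k = 5, seeds = 1, control = list(solver_max_iter = 200))
  expect_equal(nrow(gr$table), 4)
  expect_equal(gr$best$auc, max(gr$table$auc))
  m <- auc_margins(gr, by = c("pn", "lambda"))
  for (i in seq_len(nrow(m))) {
    sub <- gr$table[gr$table$pn == m$pn[i] & gr$table$lambda == m$lambda[i], ]
    expect_equal(m$max_auc[i], max(sub$auc))
    expect_equal(m$mean_auc[i], mean(sub$auc))
    expect_equal(m$min_auc[i], min(sub$auc))
  }
  # singleton grid returns that combination
  g1 <- grid_search_knmbp(dat$x, dat$mirna_sim, dat$disease_sim, pn = .5,
                          mu1 = 4, mu2 = 4, lambda = 1, folds = 3, k = 5, seeds = 1,
                          control = list(solver_max_iter = 200))
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best$pn, .5)
})
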