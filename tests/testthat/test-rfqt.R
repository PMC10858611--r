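test_that("a one-tree forest without bootstrap reproduces the single Q tree", {
  sim <- simulate_dataset(4000, "A", 0.5, seed = 51)
  f <- fit_rfqt(sim$data, qtree_control(min_node_size = 500), n_trees = 1,
                mtry_fraction = 1, bootstrap = FALSE, seed = 7)
  tree <- f$trees[[1]]
  expect_equal(predict(f, sim$data$M), predict(tree, sim$data$M))
})

test_that("the per-node candidate count matches the configured fraction", {
  # 28 covariates at 40% -> 11 candidates per node
  expect_equal(max(1L, as.integer(round(0.4 * 28))), 11L)
  # the forest draws that many distinct candidates at each node: check
  # indirectly on a small fit where mtry < p
  sim <- simulate_dataset(3000, "A", 0.5, seed = 52)
  f <- fit_rfqt(sim$data, qtree_control(min_node_size = 600), n_trees = 5,
                mtry_fraction = 0.4, seed = 8)
  expect_equal(f$mtry_fraction, 0.4)
  split_covs <- unlist(lapply(f$trees, function(t) {
    t$nodes$covariate[!t$nodes$is_leaf]
  }))
  expect_true(all(split_covs %in% colnames(sim$data$M)))
})

test_that("fits are reproducible from the master seed", {
  sim <- simulate_dataset(3000, "A", 0.5, seed = 53)
  f1 <- fit_rfqt(sim$data, qtree_control(min_node_size = 600), n_trees = 4,
                 seed = 9)
  f2 <- fit_rfqt(sim$data, qtree_control(min_node_size = 600), n_trees = 4,
                 seed = 9)
  expect_equal(predict(f1, sim$data$M), predict(f2, sim$data$M))
  expect_identical(f1$bootstrap_ids, f2$bootstrap_ids)
})

test_that("forest predictions are the arithmetic mean of tree predictions", {
  sim <- simulate_dataset(4000, "A", 0.5, seed = 54)
  f <- fit_rfqt(sim$data, qtree_control(min_node_size = 500), n_trees = 6,
                seed = 10)
  per_tree <- sapply(f$trees, predict, newdata = sim$data$M)
  expect_equal(predict(f, sim$data$M), rowMeans(per_tree))
})

test_that("out-of-bag sets have the expected size and drive OOB predictions", {
  sim <- simulate_dataset(2000, "A", 0.5, seed = 55)
  f1 <- fit_rfqt(sim$data, qtree_control(min_node_size = 500), n_trees = 1,
                 seed = 11)
  oob <- oob_predict(f1, sim$data)
  frac <- mean(oob$n_trees_oob > 0)
  # P(never drawn in n draws) = (1 - 1/n)^n ~ exp(-1)
  expect_lt(abs(frac - exp(-1)), 0.04)
  in_bag <- tabulate(f1$bootstrap_ids[[1]], 2000) > 0
  expect_true(all(is.na(oob$oob[in_bag])))
  expect_true(all(!is.na(oob$oob[!in_bag])))
  # without bootstrap there is no OOB information
  f0 <- fit_rfqt(sim$data, qtree_control(min_node_size = 500), n_trees = 2,
                 bootstrap = FALSE, seed = 12)
  oob0 <- oob_predict(f0, sim$data)
  expect_equal(oob0$n_never_oob, 2000)
  expect_true(all(is.na(oob0$oob)))
})

test_that("held-out forest predictions track the true individual effects", {
  sim <- simulate_dataset(12000, "A", 0.5, seed = 56)
  train <- sim$data[1:10000]
  test_idx <- 10001:12000
  f <- fit_rfqt(train, qtree_control(), n_trees = 50, mtry_fraction = 0.4,
                seed = 13)
  pred <- predict(f, sim$data$M[test_idx, ])
  expect_gt(cor(pred, sim$true_effect[test_idx]), 0.5)
})

test_that("variable importance is zero for unused covariates and under identity permutation", {
  sim <- simulate_dataset(4000, "A", 0.5, seed = 57)
  f <- fit_rfqt(sim$data, qtree_control(min_node_size = 500), n_trees = 5,
                seed = 14)
  vi_noop <- variable_importance(f, sim$data, seed = 1,
                                 permute = seq_len)
  expect_true(all(vi_noop$importance == 0))
  vi <- variable_importance(f, sim$data, seed = 2)
  expect_true(all(vi$importance >= 0))
  expect_setequal(vi$rank, seq_len(ncol(sim$data$M)))
  used <- unique(unlist(lapply(f$trees, function(t) {
    t$nodes$covariate[!t$nodes$is_leaf]
  })))
  unused <- setdiff(colnames(sim$data$M), used)
  expect_true(all(vi$importance[match(unused, vi$covariate)] == 0))
})

test_that("S1 and S2 match hand-built leaf tables", {
  # synthetic one-tree forest: two equal leaves with estimates 0 and 1
  leaf <- function(id, n, theta, bx = 1, sx = 0, by = theta, sy = 1) {
    data.frame(id = id, depth = 1, n = n, is_leaf = TRUE,
               covariate = NA_character_, proportion = NA_real_,
               boundary = NA_real_, q_value = NA_real_,
               mean_lower = NA_real_, mean_upper = NA_real_,
               left = NA_integer_, right = NA_integer_, theta = theta,
               beta_x = bx, se_x = sx, beta_y = by, se_y = sy,
               sigma_xy = NA_real_)
  }
  rootrow <- data.frame(id = 1, depth = 0, n = 100, is_leaf = FALSE,
                        covariate = "M1", proportion = 0.5, boundary = 0,
                        q_value = 5, mean_lower = -1, mean_upper = 1,
                        left = 2, right = 3, theta = NA_real_,
                        beta_x = NA_real_, se_x = NA_real_,
                        beta_y = NA_real_, se_y = NA_real_,
                        sigma_xy = NA_real_)
  tree <- structure(list(nodes = rbind(rootrow, leaf(2, 50, 0), leaf(3, 50, 1)),
                         control = qtree_control(), n_fit = 100,
                         theta_root = 0.5), class = "qtree")
  forest <- structure(list(trees = list(tree), bootstrap_ids = list(1:100),
                           n_train = 100, mtry_fraction = 1,
                           control = qtree_control(), bootstrap = TRUE,
                           seed = 1), class = "rfqt_forest")
  expect_equal(s1_statistic(forest), 0.25)
  # S2 with beta_y (0,1), beta_x (1,1), se_y (1,1), se_x (0,0): Q = 0.5
  expect_equal(s2_statistic(forest), 0.5, tolerance = 1e-6)
  # duplicating every tree leaves both statistics unchanged
  forest2 <- forest
  forest2$trees <- c(forest$trees, forest$trees)
  forest2$bootstrap_ids <- c(forest$bootstrap_ids, forest$bootstrap_ids)
  expect_equal(s1_statistic(forest2), s1_statistic(forest))
  expect_equal(s2_statistic(forest2), s2_statistic(forest))
  # single-leaf trees carry no heterogeneity
  solo <- structure(list(trees = list(structure(
    list(nodes = leaf(1, 100, 0.4), control = qtree_control(),
         n_fit = 100, theta_root = 0.4), class = "qtree")),
    bootstrap_ids = list(1:100), n_train = 100, mtry_fraction = 1,
    control = qtree_control(), bootstrap = TRUE, seed = 1),
    class = "rfqt_forest")
  expect_equal(s1_statistic(solo), 0)
  expect_equal(s2_statistic(solo), 0)
})

test_that("S2 of a fitted one-tree forest equals the Q statistic of its leaf strata", {
  sim <- simulate_dataset(6000, "A", 0.5, seed = 58)
  f <- fit_rfqt(sim$data, qtree_control(min_node_size = 600), n_trees = 1,
                mtry_fraction = 1, bootstrap = FALSE, seed = 15)
  lv <- f$trees[[1]]$nodes
  lv <- lv[lv$is_leaf, ]
  expect_gt(nrow(lv), 1)
  est <- make_estimates(beta_x = lv$beta_x, se_x = lv$se_x,
                        beta_y = lv$beta_y, se_y = lv$se_y,
                        n = lv$n, sigma_xy = lv$sigma_xy)
  expect_equal(s2_statistic(f), q_statistic(est)$Q, tolerance = 1e-4)
})

test_that("forest and tree JSON bundles round-trip predictions", {
  sim <- simulate_dataset(3000, "A", 0.5, seed = 59)
  f <- fit_rfqt(sim$data, qtree_control(min_node_size = 600), n_trees = 3,
                seed = 16)
  path <- tempfile(fileext = ".json")
  rfqt_to_json(f, path)
  f2 <- rfqt_from_json(path)
  expect_equal(predict(f2, sim$data$M), predict(f, sim$data$M))
  expect_equal(s2_statistic(f2), s2_statistic(f))
})

test_that("permutation p-values follow the counting rule", {
  sim <- simulate_dataset(800, "A", 0.5, seed = 60)
  ctl <- qtree_control(min_node_size = 150)
  pt <- permutation_test(sim$data, ctl, n_trees = 2, n_perm = 9, seed = 17)
  expect_equal(pt$p1, mean(pt$s1_null >= pt$s1_observed))
  expect_equal(pt$p2, mean(pt$s2_null >= pt$s2_observed))
  expect_length(pt$s1_null, 9)
  expect_true(all(c(pt$s1_null, pt$s2_null, pt$s1_observed, pt$s2_observed) >= 0))
  ptc <- permutation_test(sim$data, ctl, n_trees = 2, n_perm = 9,
                          small_sample_correction = TRUE, seed = 17)
  expect_equal(ptc$p2, (sum(ptc$s2_null >= ptc$s2_observed) + 1) / 10)
  expect_gt(ptc$p1, 0)
})
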