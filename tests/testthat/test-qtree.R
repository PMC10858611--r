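test_that("boundary value is the size-weighted average of child means", {
  expect_equal(boundary_value(5, 5, 1, 3), 2)
  expect_equal(boundary_value(3, 7, 1, 2), 1.7)
  expect_equal(boundary_value(4, 9, 2.5, 2.5), 2.5)
})

test_that("no split is offered when every child would undercut the minimum size", {
  sim <- simulate_dataset(1500, "A", 0.5, seed = 41)
  # 5:5 gives 750, 3:7 gives 450/1050 - every candidate child < 1000
  sp <- best_split(sim$data, control = qtree_control(min_node_size = 1000),
                   seed = 1)
  expect_null(sp)
})

test_that("a strong modifier is selected as the splitting covariate", {
  hits <- vapply(1:8, function(r) {
    sim <- simulate_dataset(8000, "A", 0.5, seed = 410 + r)
    sp <- best_split(sim$data, control = qtree_control(min_node_size = 1000),
                     seed = r)
    !is.null(sp) && sp$covariate %in% paste0("M", 1:5)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("split search returns the argmax over covariate-proportion pairs", {
  sim <- simulate_dataset(4000, "A", 0.5, seed = 42)
  ctl <- qtree_control(min_node_size = 500)
  sp <- best_split(sim$data, control = ctl, seed = 3)
  expect_false(is.null(sp))
  expect_true(sp$proportion %in% c(0.3, 0.5, 0.7))
  expect_gte(sp$q_value, ctl$q_threshold)
  # boundary lies between the child means
  expect_true(sp$boundary >= min(sp$mean_lower, sp$mean_upper) &&
                sp$boundary <= max(sp$mean_lower, sp$mean_upper))
  # and equals the size-weighted mean of the child means
  expect_equal(sp$boundary,
               boundary_value(sp$n1, sp$n2, sp$mean_lower, sp$mean_upper))
})

test_that("max_depth 0 yields a single leaf carrying the overall estimate", {
  sim <- simulate_dataset(3000, "A", 0.5, seed = 43)
  tree <- grow_qtree(sim$data, qtree_control(max_depth = 0), seed = 1)
  expect_equal(nrow(tree$nodes), 1)
  expect_true(tree$nodes$is_leaf[1])
  est <- stratum_associations(
    sim$data,
    structure(list(labels = rep(1L, 3000), K = 1L, proportions = 1,
                   method = "naive", covariate_name = NA_character_,
                   prestratum_size = NA_integer_),
              class = "stratum_assignment"))
  expect_equal(tree$nodes$theta[1], est$theta[1])
  expect_equal(unique(predict(tree, sim$data$M)), tree$nodes$theta[1])
})

test_that("a tree grown on strongly modified data splits on a true modifier", {
  hits <- vapply(1:5, function(r) {
    sim <- simulate_dataset(10000, "A", 0.5, seed = 430 + r)
    tree <- grow_qtree(sim$data, qtree_control(), seed = r)
    root <- tree$nodes[1, ]
    !root$is_leaf && root$covariate %in% paste0("M", 1:5)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("leaves partition the fitted sample and respect the stopping rules", {
  sim <- simulate_dataset(10000, "A", 0.5, seed = 44)
  ctl <- qtree_control(min_node_size = 800)
  tree <- grow_qtree(sim$data, ctl, seed = 2)
  nd <- tree$nodes
  leaves <- nd[nd$is_leaf, ]
  internals <- nd[!nd$is_leaf, ]
  expect_equal(sum(leaves$n), 10000)
  expect_true(all(leaves$n >= ctl$min_node_size))
  expect_true(all(internals$q_value >= ctl$q_threshold))
  expect_true(all(nd$depth <= ctl$max_depth))
  # every internal node has exactly two children, consistent sizes
  for (r in seq_len(nrow(internals))) {
    kids <- nd$n[match(c(internals$left[r], internals$right[r]), nd$id)]
    expect_equal(sum(kids), internals$n[r])
  }
})

test_that("routing sends boundary ties to the lower child and reproduces leaf estimates", {
  sim <- simulate_dataset(6000, "A", 0.5, seed = 45)
  tree <- grow_qtree(sim$data, qtree_control(min_node_size = 600), seed = 3)
  nd <- tree$nodes
  root <- nd[1, ]
  expect_false(root$is_leaf)
  # leaf set reachable from a given node
  leaves_under <- function(id) {
    r <- nd[match(id, nd$id), ]
    if (r$is_leaf) return(r$theta)
    c(leaves_under(r$left), leaves_under(r$right))
  }
  probe <- matrix(0, 1, ncol(sim$data$M),
                  dimnames = list(NULL, colnames(sim$data$M)))
  probe[1, root$covariate] <- root$boundary
  expect_true(predict(tree, probe) %in% leaves_under(root$left))
  probe[1, root$covariate] <- root$boundary + 1e-6
  expect_true(predict(tree, probe) %in% leaves_under(root$right))
  # every prediction is one of the leaf estimates
  preds <- predict(tree, sim$data$M)
  expect_true(all(preds %in% nd$theta[nd$is_leaf]))
})

test_that("pure-null data frequently admits no split over a few candidates", {
  nulls <- vapply(1:20, function(r) {
    sim <- simulate_dataset(4000, "A", 0, pure_null = TRUE, seed = 450 + r)
    sp <- best_split(sim$data, candidates = c("M1", "M2", "M3"),
                     control = qtree_control(min_node_size = 1000),
                     seed = r)
    is.null(sp)
  }, TRUE)
  # with 3 candidate covariates the chance that the maximum split Q stays
  # under 3.84 is roughly (1 - 0.05)^9 or better given the correlation
  # between the three proportions of one covariate
  expect_gte(mean(nulls), 0.3)
})

test_that("JSON serialization round-trips trees and their predictions", {
  sim <- simulate_dataset(4000, "A", 0.5, seed = 46)
  tree <- grow_qtree(sim$data, qtree_control(min_node_size = 500), seed = 4)
  path <- tempfile(fileext = ".json")
  qtree_to_json(tree, path)
  tree2 <- qtree_from_json(path)
  expect_equal(predict(tree2, sim$data$M), predict(tree, sim$data$M))
  expect_equal(tree2$nodes$q_value, tree$nodes$q_value)
})
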