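fake_tree <- function(efficiency, aicc, rss = rep(1, length(aicc))) {
  structure(
    list(
      level_stats = tibble::tibble(efficiency = efficiency),
      tree_stats = tibble::tibble(aicc = aicc, rss_tree_modelling = rss),
      s = length(aicc),
      config = list(sigma_opt_range = "validated")
    ),
    class = "motif_tree"
  )
}

test_that("sigma_prime returns the deepest predictable level of each ecosystem", {
  tree <- build_tree(toy3_sample())
  # e1 and e4 are sole representatives of their motifs from sigma = 2 on
  expect_equal(sigma_prime(tree, 2), c(1L, 2L, 2L, 1L, 2L))
  # at sigma = 3 all compositions are unique: nothing gains a deeper level
  expect_equal(sigma_prime(tree, 3), c(1L, 2L, 2L, 1L, 2L))
  expect_equal(sigma_prime(tree, 1), rep(1L, 5))
  expect_error(sigma_prime(tree, 9), "between 1")
})

test_that("identical replicate ecosystems stay predictable at every depth", {
  smp <- eco_sample(tibble::tibble(
    id = paste0("e", 1:4),
    X = c(1, 1, 1, 0), Y = c(1, 1, 0, 1), Z = c(0, 0, 1, 1),
    f = c(3, 4, 8, 9)
  ))
  tree <- build_tree(smp)
  sp <- sigma_prime(tree, 3)
  expect_equal(sp[1:2], c(3L, 3L))
})

test_that("tree statistics chain the per-level fits through sigma_prime", {
  s <- toy3_sample()
  tree <- build_tree(s)
  P <- s$presence
  F <- s$function_values

  # oracle: evaluate each ecosystem at its own deepest predictable level
  levels2 <- sigma_prime(tree, 2)
  parts <- list(c(1, 1, 1), c(1, 2, 2))
  mod <- vapply(
    1:5,
    function(a) oracle_modelled_one(P, F, parts[[levels2[a]]], a), numeric(1)
  )
  pred <- vapply(1:5, function(a) {
    oracle_modelled_one(P, F, parts[[levels2[a]]], a, exclude = a)
  }, numeric(1))
  tss <- sum((F - mean(F))^2)

  st <- tree_stats(tree, 2)
  expect_equal(st$rss_tree_modelling, sum((F - mod)^2))
  expect_equal(st$rss_tree_predicting, sum((F - pred)^2))
  expect_equal(st$r2_tree, 1 - sum((F - mod)^2) / tss)
  expect_equal(st$e_tree, 1 - sum((F - pred)^2) / tss)
  expect_equal(st$predicting_ratio_tree, 1)

  # frozen hand values for the same quantities
  expect_equal(st$rss_tree_modelling, 172.6111, tolerance = 1e-6)
  expect_equal(st$e_tree, 1 - 352.5 / 212.8)

  # at the base the tree statistics equal the single-level fit
  st1 <- tree_stats(tree, 1)
  expect_equal(st1$r2_tree, tree$level_stats$r_squared[1])
  expect_equal(st1$e_tree, tree$level_stats$efficiency[1])
})

test_that("tree-level statistics respect their model-level bounds on simulated data", {
  for (seed in c(2, 4)) {
    vd <- generate_dataset(
      simulation_config(c(2, 2, 2), c(0.4, 1.4), cv = 0.15, seed = seed)
    )
    tree <- build_tree(vd$sample)
    td <- tidy(tree)
    expect_true(all(td$predicting_ratio_tree == 1))
    expect_true(all(td$r2_tree <= td$r_squared + 1e-12))
    expect_true(all(td$r2_tree <= 1))
    expect_true(all(td$r2_tree[-1] >= 0)) # the trunk level can dip below 0
    expect_true(all(td$e_tree <= 1))
    expect_true(all(diff(td$r_squared) >= -1e-12)) # R^2 monotone along the tree
    expect_lte(tree$sigma_opt, tree$sigma_max)
  }
})

test_that("sigma_max stops at the first efficiency decrease", {
  expect_equal(sigma_max(c(0.2, 0.5, 0.4, 0.6)), 2)
  expect_equal(sigma_max(c(0.1, 0.2, 0.3)), 3) # strictly increasing: full depth
  expect_equal(sigma_max(c(0.2, 0.5, NA, 0.9)), 2) # undefined counts as decrease
  expect_equal(sigma_max(c(0.3)), 1)
})

test_that("the tree AICc follows the printed small-sample formula", {
  expect_equal(
    motifclust:::aicc_value(5, 3, 4.5),
    5 * log(4.5 / 5) + 2 * 3 + 2 * 3 * 4 / (5 - 3 + 1)
  )
  expect_equal(motifclust:::aicc_value(5, 3, 4.5), 13.473197, tolerance = 1e-6)
  # undefined for a perfect fit and for a non-positive correction denominator
  expect_true(is.na(motifclust:::aicc_value(5, 3, 0)))
  expect_true(is.na(motifclust:::aicc_value(5, 6, 4.5)))
  # m = n keeps the denominator positive: still defined
  expect_false(is.na(motifclust:::aicc_value(5, 5, 4.5)))
  # textbook denominator variant
  expect_equal(
    motifclust:::aicc_value(10, 3, 4.5, denominator = "n-m-1"),
    10 * log(0.45) + 6 + 24 / 6
  )
})

test_that("sigma_opt takes the AICc argmin over validated levels, ties to parsimony", {
  tr <- fake_tree(efficiency = c(0.1, 0.2, 0.3), aicc = c(10, 4, 7))
  expect_equal(sigma_opt(tr), 2)
  # tie -> smallest sigma
  tr <- fake_tree(efficiency = c(0.1, 0.2, 0.3, 0.4), aicc = c(9, 5, 5, 2))
  expect_equal(sigma_opt(tr, range = "full"), 2)
  # validation cuts the search: efficiency drops after level 1
  tr <- fake_tree(efficiency = c(0.5, 0.1, 0.9), aicc = c(10, 1, 0.5))
  expect_equal(sigma_opt(tr), 1)
  # a perfect fit dominates any finite AICc
  tr <- fake_tree(
    efficiency = c(0.1, 0.2, 0.3),
    aicc = c(10, 4, NA), rss = c(3, 2, 0)
  )
  expect_equal(sigma_opt(tr), 3)
  tr <- fake_tree(efficiency = c(0.1, 0.2), aicc = c(NA, NA))
  expect_error(sigma_opt(tr), "undefined")
})

test_that("aicc_tree exposes the per-level criterion of a built tree", {
  tree <- build_tree(toy3_sample())
  expect_equal(
    aicc_tree(tree, 2),
    5 * log(tree$tree_stats$rss_tree_modelling[2] / 5) + 6 + 8
  )
  expect_length(aicc_tree(tree), 3)
})
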