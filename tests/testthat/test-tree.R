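test_that("the toy tree has the expected levels and nondecreasing R^2", {
  s <- toy3_sample()
  tree <- build_tree(s)
  expect_equal(tree$s, 3)
  expect_length(tree$partitions, 3)
  expect_identical(tree$partitions[[1]], c(X = 1L, Y = 1L, Z = 1L))
  # level 2 is the best 2-group model {X | Y,Z}, as by exhaustive search
  expect_identical(tree$partitions[[2]], c(X = 1L, Y = 2L, Z = 2L))
  expect_identical(tree$partitions[[3]], c(X = 1L, Y = 2L, Z = 3L))
  expect_true(all(diff(tree$level_stats$r_squared) >= 0))
  expect_equal(tree$evaluation_count, 7)
  expect_lte(tree$evaluation_count, max_evaluations(3))
})

test_that("each level refines the previous by splitting exactly one group", {
  set.seed(11)
  smp <- random_sample(14, 6)
  tree <- build_tree(smp)
  for (sigma in 2:6) {
    g_prev <- tree$partitions[[sigma - 1]]
    g_cur <- tree$partitions[[sigma]]
    expect_equal(n_groups(g_cur), sigma)
    # refinement: co-grouped at sigma implies co-grouped at sigma - 1
    for (grp in partition_groups(g_cur)) {
      expect_length(unique(g_prev[grp]), 1)
    }
    # exactly one parent group is divided
    n_children <- vapply(
      partition_groups(g_prev),
      function(grp) length(unique(g_cur[grp])), integer(1)
    )
    expect_equal(sum(n_children == 2), 1)
    expect_true(all(n_children <= 2))
  }
})

test_that("splitting a group of two species is forced, singletons refuse", {
  s <- toy3_sample()
  res <- split_group(s, c(X = 1, Y = 2, Z = 2), group = 2)
  expect_equal(n_groups(res$partition), 3)
  expect_equal(res$evaluations, 2)
  expect_error(split_group(s, c(X = 1, Y = 2, Z = 2), group = 1), "singleton")
})

test_that("greedy level-2 split never beats exhaustive search and matches it on structured data", {
  set.seed(202)
  for (i in 1:12) {
    sp <- sample(4:5, 1)
    smp <- random_sample(sample(6:12, 1), sp)
    tree <- build_tree(smp)
    exhaustive <- oracle_best_2split(smp$presence, smp$function_values)
    expect_lte(tree$level_stats$r_squared[2], exhaustive$r_squared + 1e-12)
  }
  # zero-noise 2-group data: greedy attains the exhaustive optimum exactly
  for (seed in 1:6) {
    vd <- generate_dataset(
      simulation_config(c(2, 3), c(1, 2), cv = 0, seed = seed)
    )
    tree <- build_tree(vd$sample)
    exhaustive <- oracle_best_2split(vd$sample$presence, vd$sample$function_values)
    expect_equal(tree$level_stats$r_squared[2], exhaustive$r_squared)
    expect_equal(
      jaccard_partitions(tree$partitions[[2]], vd$true_partition), 1
    )
  }
})

test_that("zero-noise data with true groups {A},{B,C} recover the boundary with R^2 = 1", {
  vd <- generate_dataset(
    simulation_config(c(1, 2), c(1, 2), cv = 0, seed = 9)
  )
  res <- split_group(vd$sample, rep(1, 3), group = 1)
  expect_equal(jaccard_partitions(res$partition, vd$true_partition), 1)
  expect_equal(res$r_squared, 1)
})

test_that("evaluation counts stay within the worst-case bound", {
  vd <- generate_dataset(
    simulation_config(c(1, 2, 3), c(0.4, 1.4), cv = 0.08, seed = 3)
  )
  tree <- build_tree(vd$sample)
  expect_lte(tree$evaluation_count, max_evaluations(6)) # 50
  expect_equal(max_evaluations(6), 50)
  expect_equal(max_evaluations(16), 800)
  expect_equal(max_evaluations(34), 7106)
  expect_error(max_evaluations(1), "at least 2")
})

test_that("Bell numbers count all partitions (cross-checked by enumeration)", {
  for (s in 1:6) {
    expect_equal(count_partitions(s), length(enumerate_partitions(s)))
  }
  expect_equal(count_partitions(5), 52)
  expect_equal(count_partitions(6), 203)
  expect_equal(count_partitions(1), 1)
})

test_that("tree building is deterministic for identical input", {
  vd <- generate_dataset(
    simulation_config(c(2, 2, 2), c(0.4, 1.4), cv = 0.2, seed = 21)
  )
  t1 <- build_tree(vd$sample)
  t2 <- build_tree(vd$sample)
  expect_identical(t1$partitions, t2$partitions)
  expect_identical(t1$level_stats, t2$level_stats)
  expect_identical(t1$tree_stats, t2$tree_stats)
  expect_identical(t1$evaluation_count, t2$evaluation_count)
})

test_that("a two-species sample yields a two-level tree", {
  smp <- eco_sample(tibble::tibble(
    id = c("a", "b", "c"), X = c(1, 0, 1), Y = c(0, 1, 1), f = c(1, 2, 4)
  ))
  tree <- build_tree(smp)
  expect_length(tree$partitions, 2)
  expect_equal(tree$s, 2)
})
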