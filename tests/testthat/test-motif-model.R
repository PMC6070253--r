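test_that("assembly motifs are assigned by the groups present in each ecosystem", {
  s <- toy3_sample()
  cls <- assign_motifs(s, toy3_p2)
  expect_equal(unname(cls$motif_key), c("1", "1+2", "1+2", "2", "1+2"))
  expect_equal(cls$m, 3)
  expect_equal(unname(cls$clusters), list(1L, c(2L, 3L, 5L), 4L))

  # degenerate single-group partition: one universal motif
  cls1 <- assign_motifs(s, c(X = 1, Y = 1, Z = 1))
  expect_equal(cls1$m, 1)
  expect_equal(length(cls1$clusters[["1"]]), 5)

  expect_error(assign_motifs(s, c(X = 1, Y = 2)), "each species")
})

test_that("species-motif clusters contain exactly the motif peers with the species", {
  s <- toy3_sample()
  cls <- assign_motifs(s, toy3_p2)
  expect_equal(species_motif_cluster(s, cls, "X", "1+2"), c(2L, 3L, 5L))
  expect_equal(species_motif_cluster(s, cls, "Y", "1+2"), c(2L, 5L))
  expect_equal(species_motif_cluster(s, cls, "Y", "2"), 4L)
  expect_equal(species_motif_cluster(s, cls, "X", "2"), integer(0))
})

test_that("modelled function reproduces the hand-computed toy values", {
  s <- toy3_sample()
  cls <- assign_motifs(s, toy3_p2)
  mod <- modelled_function(s, cls)
  # e2: (mean{20,24,22} + mean{20,22}) / 2 = 21.5; e1 is alone in motif {1}
  expect_equal(unname(mod), c(10, 21.5, 22.5, 8, 22))
})

test_that("fit statistics match the hand-derived toy values", {
  s <- toy3_sample()
  fit <- motif_fit(s, toy3_p2)
  expect_equal(fit$tss, 212.8)
  expect_equal(fit$rss_modelling, 4.5)
  expect_equal(fit$r_squared, 1 - 4.5 / 212.8)
  # LOO: e2 -> (mean{24,22} + mean{22})/2 = 22.5; e1, e4 undefined
  expect_equal(unname(fit$predicted), c(NA, 22.5, 21.5, NA, 22))
  expect_equal(fit$predicting_ratio, 3 / 5)
  # efficiency over predictable subset {e2,e3,e5}: RSS 12.5, subset TSS 8
  expect_equal(fit$rss_predicting, 12.5)
  expect_equal(fit$efficiency, -0.5625)
  # full-TSS variant
  fit_full <- motif_fit(s, toy3_p2, tss = "full")
  expect_equal(fit_full$efficiency, 1 - 12.5 / 212.8)

  glance_row <- glance(fit)
  expect_equal(glance_row$sigma, 2)
  expect_equal(glance_row$m, 3)
  tidy_rows <- tidy(fit)
  expect_equal(nrow(tidy_rows), 5)
  expect_equal(sum(tidy_rows$defined), 3)
})

test_that("a constant function vector raises a degenerate-variance error", {
  tbl <- toy3_tbl()
  tbl$f <- 7
  expect_error(motif_fit(eco_sample(tbl), toy3_p2), "Degenerate variance")
})

test_that("with one universal motif, predictions condition on shared species", {
  s <- toy3_sample()
  cls <- assign_motifs(s, c(X = 1, Y = 1, Z = 1))
  loo <- loo_predictions(s, cls)
  # e1 = {X}: mean F over the other ecosystems containing X = mean(20,24,22)
  expect_equal(loo$predicted[[1]], 22)
  expect_equal(loo$predicting_ratio, 1)
})

test_that("two identical replicate ecosystems predict each other exactly", {
  s <- eco_sample(tibble::tibble(
    id = c("a", "b", "c"), X = c(1, 1, 1), Y = c(1, 1, 0), f = c(5, 5, 9)
  ))
  fit <- motif_fit(s, c(X = 1, Y = 2))
  expect_equal(unname(fit$predicted[1:2]), c(5, 5))
})

test_that("within-motif constant function is modelled exactly (R^2 = 1 at truth)", {
  # zero-noise virtual data: modelled == observed at the true partition
  vd <- generate_dataset(
    simulation_config(c(2, 2), c(1, 2), cv = 0, seed = 5)
  )
  fit <- motif_fit(vd$sample, vd$true_partition)
  expect_equal(unname(fit$modelled), vd$sample$function_values)
  expect_equal(fit$r_squared, 1)
})

test_that("all-distinct compositions at sigma = s give R^2 = 1", {
  s <- toy3_sample()
  fit <- motif_fit(s, c(X = 1, Y = 2, Z = 3))
  expect_equal(fit$r_squared, 1)
})

test_that("model quantities agree with brute-force oracles on random samples", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    sp <- sample(3:5, 1)
    smp <- random_sample(n, sp)
    g <- random_partition(sp, sample(2:sp, 1))
    P <- smp$presence
    F <- smp$function_values

    cls <- assign_motifs(smp, g)
    loo <- loo_predictions(smp, cls)
    expect_equal(unname(cls$motif_key), oracle_motif_key(P, g))
    expect_equal(unname(modelled_function(smp, cls)), oracle_modelled(P, F, g))
    expect_equal(unname(loo$predicted), oracle_loo(P, F, g))

    # motif count bound
    expect_lte(cls$m, min(n, 2^n_groups(g) - 1))

    # prediction undefined exactly for sole representatives / empty terms
    expect_identical(unname(is.na(loo$predicted)), is.na(oracle_loo(P, F, g)))
  }
})

test_that("replicating the whole sample leaves every cluster mean and R^2 unchanged", {
  set.seed(77)
  for (i in 1:10) {
    smp <- random_sample(8, 4)
    g <- random_partition(4, 2)
    fit1 <- motif_fit(smp, g)
    df <- as_tibble(smp)
    dup <- df
    dup$ecosystem_id <- paste0(dup$ecosystem_id, "_bis")
    smp2 <- eco_sample(dplyr::bind_rows(df, dup))
    fit2 <- motif_fit(smp2, g)
    expect_equal(unname(fit2$modelled), rep(unname(fit1$modelled), 2))
    expect_equal(fit2$r_squared, fit1$r_squared)
  }
})

test_that("efficiency bounds hold across random fits", {
  set.seed(303)
  for (i in 1:15) {
    smp <- random_sample(10, 4)
    g <- random_partition(4, sample(2:4, 1))
    fit <- motif_fit(smp, g)
    if (!is.na(fit$efficiency)) expect_lte(fit$efficiency, 1)
    expect_gte(fit$rss_modelling, 0)
    expect_gte(fit$predicting_ratio, 0)
    expect_lte(fit$predicting_ratio, 1)
  }
})
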