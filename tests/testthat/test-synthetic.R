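two_layers <- function(n = 5L) {
  list(synthetic_layer("L1", "target_disease", n, n),
       synthetic_layer("L2", "treatment", n, n))
}

test_that("zero effect and zero noise give identical group means", {
  sim <- simulate_study(two_layers(), n_genes = 50,
                        modules = list(synthetic_module(
                          10, 0, c(L1 = "up", L2 = "none"))),
                        noise_sd = 0, seed = 1)
  l <- sim$dataset$layers$L1
  tg <- rowMeans(l$values[, l$sample_group == "target"])
  rf <- rowMeans(l$values[, l$sample_group == "reference"])
  expect_equal(tg, rf)
})

test_that("the generator is deterministic given the seed", {
  s1 <- simulate_study(two_layers(), n_genes = 100, seed = 99,
                       modules = list(synthetic_module(
                         20, 1, c(L1 = "up", L2 = "down"))))
  s2 <- simulate_study(two_layers(), n_genes = 100, seed = 99,
                       modules = list(synthetic_module(
                         20, 1, c(L1 = "up", L2 = "down"))))
  expect_identical(s1$dataset$layers$L1$values, s2$dataset$layers$L1$values)
  expect_identical(s1$truth$modules[[1]]$genes, s2$truth$modules[[1]]$genes)
  s3 <- simulate_study(two_layers(), n_genes = 100, seed = 100,
                       modules = list(synthetic_module(
                         20, 1, c(L1 = "up", L2 = "down"))))
  expect_false(identical(s1$dataset$layers$L1$values,
                         s3$dataset$layers$L1$values))
})

test_that("planted effects are recovered within sampling error", {
  sim <- simulate_study(two_layers(10L), n_genes = 500,
                        modules = list(synthetic_module(
                          100, 1.0, c(L1 = "up", L2 = "down"))),
                        seed = 3)
  mod <- sim$truth$modules[[1]]$genes
  eff <- function(layer) {
    l <- sim$dataset$layers[[layer]]
    mean(l$values[mod, l$sample_group == "target"]) -
      mean(l$values[mod, l$sample_group == "reference"])
  }
  # group-centred factor: residual noise dominates the standard error
  se <- 0.5 * sqrt(2 / (10 * 100))
  expect_lt(abs(eff("L1") - 1.0), 3 * se + 0.02)
  expect_lt(abs(eff("L2") + 1.0), 3 * se + 0.02)
})

test_that("module genes are correlated through the shared factor", {
  sim <- simulate_study(two_layers(15L), n_genes = 200,
                        modules = list(synthetic_module(
                          50, 0, c(L1 = "none", L2 = "none"))),
                        seed = 4)
  mod <- sim$truth$modules[[1]]$genes
  v <- sim$dataset$layers$L1$values
  cm <- cor(t(v[mod[1:20], ]))
  mean_r <- mean(cm[upper.tri(cm)])
  # loading 0.8 implies pairwise correlation ~ 0.64
  expect_gt(mean_r, 0.45)
  bg <- setdiff(rownames(v), mod)[1:20]
  cb <- cor(t(v[bg, ]))
  expect_lt(abs(mean(cb[upper.tri(cb)])), 0.15)
})

test_that("overlapping module gene lists are rejected", {
  mods <- list(
    synthetic_module(5, 1, c(L1 = "up"), genes = paste0("G0000", 1:5)),
    synthetic_module(5, 1, c(L2 = "up"), genes = paste0("G0000", 3:7)))
  expect_error(simulate_study(two_layers(), n_genes = 50, modules = mods),
               "disjoint")
})

test_that("written studies re-read identically through the standard readers", {
  sim <- simulate_study(two_layers(), n_genes = 60, seed = 6,
                        modules = list(synthetic_module(
                          10, 1, c(L1 = "up", L2 = "none"))))
  dir <- tempfile("study")
  paths <- write_study(sim, dir)
  m <- read_expression_matrix(file.path(dir, "L1.tsv"), "L1")
  expect_identical(m$values, sim$dataset$layers$L1$values)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_identical(nrow(sheet), 20L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$noise_sd, 0.5)
  expect_length(truth$modules[[1]]$genes, 10L)
})
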