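# Build one shared small model for the file
fx <- small_model()

test_that("a 1x1 grid reduces to the per-sample mean profile", {
  model <- train_som(fx$joint, ml_config(grid_size = 1))
  expect_equal(as.vector(model$prototypes),
               unname(colMeans(fx$joint$values)), tolerance = 1e-12)
  expect_true(all(model$assignment == 1L))
})

test_that("a 2x1 grid on two separated clusters recovers the 2-means solution", {
  set.seed(11)
  n <- 60
  centers <- rbind(c(1, 1, -1, -1), c(-1, -1, 1, 1))
  truth <- rep(1:2, each = n)
  X <- centers[truth, ] + matrix(rnorm(2 * n * 4, sd = 0.1), 2 * n, 4)
  dimnames(X) <- list(paste0("g", seq_len(2 * n)), paste0("s", 1:4))
  joint <- structure(list(values = X, genes = rownames(X),
                          samples = colnames(X),
                          layer = structure(rep("L", 4), names = colnames(X)),
                          sample_group = structure(
                            rep(c("target", "reference"), 2),
                            names = colnames(X)),
                          sample_subgroup = structure(
                            rep(NA_character_, 4), names = colnames(X)),
                          roles = c(L = "target_disease")),
                     class = "JointMatrix")
  model <- train_som(joint, ml_config(grid_size = c(2, 1)))
  km <- kmeans(X, centers = centers, iter.max = 50)
  # match each prototype to its nearest k-means centroid
  d <- as.matrix(dist(rbind(model$prototypes, km$centers)))[1:2, 3:4]
  pick <- unname(apply(d, 1, which.min))
  expect_identical(sort(pick), 1:2)
  expect_lt(max(d[cbind(1:2, pick)]), 0.1)
  purity <- max(mean((model$assignment == 1) == (truth == pick[1])),
                mean((model$assignment == 1) == (truth == pick[2])))
  expect_gte(purity, 0.95)
})

test_that("training is deterministic for identical input", {
  m2 <- train_som(fx$joint, ml_config(grid_size = 10))
  expect_identical(m2$assignment, fx$model$assignment)
  expect_identical(m2$prototypes, fx$model$prototypes)
})

test_that("quantization error does not increase during the fine phase", {
  log <- fx$model$training_log
  qe <- c(log$qe[log$phase == "fine"], fx$model$final_qe)
  expect_lte(max(diff(qe)), 1e-6)
})

test_that("portraits are prototype slices and group portraits their means", {
  s <- fx$model$samples[1:3]
  p1 <- portrait(fx$model, s[1])
  expect_equal(as.vector(t(p1$values)), unname(fx$model$prototypes[, s[1]]))
  pg <- portrait(fx$model, s)
  pm <- (portrait(fx$model, s[1])$values + portrait(fx$model, s[2])$values +
           portrait(fx$model, s[3])$values) / 3
  expect_equal(pg$values, pm, tolerance = 1e-12)
  expect_error(portrait(fx$model, "nope"), "unknown sample")
})

test_that("support maps conserve the gene population", {
  masks <- list(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10))
  sm <- support_maps(fx$model, masks)
  expect_identical(sum(sm$population), length(fx$model$genes))
  expect_true(all(sm$overexpression_frequency %in% c(1L)))
  expect_equal(as.vector(t(sm$variance)),
               unname(apply(fx$model$prototypes, 1, var)))
})

test_that("well-separated planted modules occupy compact grid patches", {
  sim <- simulate_study(
    layout = list(synthetic_layer("L1", "target_disease", 8, 8),
                  synthetic_layer("L2", "treatment", 8, 8)),
    n_genes = 2000,
    modules = list(
      synthetic_module(40, 3, c(L1 = "up", L2 = "none")),
      synthetic_module(40, 3, c(L1 = "down", L2 = "none")),
      synthetic_module(40, 3, c(L1 = "none", L2 = "up")),
      synthetic_module(40, 3, c(L1 = "none", L2 = "down"))),
    noise_sd = 0.3, factor_loading = 0.9, seed = 5)
  joint <- preprocess_dataset(sim$dataset, quiet = TRUE)
  model <- train_som(joint, ml_config(grid_size = 20))
  for (mod in sim$truth$modules) {
    units <- unique(model$assignment[mod$genes])
    coords <- model$coords[units, , drop = FALSE]
    cheb <- max(dist(coords, method = "maximum"))
    expect_lte(cheb, 3)
  }
})

test_that("an underpopulated grid warns", {
  tiny <- fx$joint
  keep <- tiny$genes[1:30]
  tiny$values <- tiny$values[keep, ]
  tiny$genes <- keep
  expect_warning(train_som(tiny, ml_config(grid_size = 20)),
                 "underpopulated")
})
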