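test_that("overexpression masks flag strictly above the type-7 quantile", {
  p <- matrix(c(1, 3, 2, 10), 2, 2)  # [[1,2],[3,10]]
  m <- overexpression_mask(p, 0.95)
  expect_equal(type7_oracle(c(1, 2, 3, 10), 0.95), 8.95)
  expect_identical(which(m), which(p == 10))

  expect_false(any(overexpression_mask(matrix(5, 3, 3), 0.95)))

  m0 <- overexpression_mask(matrix(c(1, 1, 2, 3), 2, 2), 0)
  expect_identical(sum(m0), 2L)  # everything except the tied minimum

  mu <- overexpression_mask(p, 0.95, underexpression = TRUE)
  expect_identical(which(mu), which(p == 1))
})

fx <- small_model()

test_that("segmentation respects connectivity and row-major labelling", {
  g <- matrix(FALSE, 10, 10)
  g[2, 2] <- g[3, 3] <- TRUE  # diagonal contact
  s8 <- segment_spots(g, fx$model, connectivity = 8)
  s4 <- segment_spots(g, fx$model, connectivity = 4)
  expect_length(s8$spots, 1L)
  expect_length(s4$spots, 2L)

  corners <- matrix(FALSE, 10, 10)
  corners[9:10, 9:10] <- TRUE
  corners[1:2, 1:2] <- TRUE
  sc <- segment_spots(corners, fx$model, connectivity = 8)
  expect_identical(names(sc$spots), c("A", "B"))
  expect_equal(mean(sc$spots$A$units[, "r"]), 1.5)

  empty <- suppressMessages(
    segment_spots(matrix(FALSE, 10, 10), fx$model))
  expect_length(empty$spots, 0L)
})

test_that("spots partition the flagged units", {
  set.seed(8)
  masks <- replicate(3, matrix(runif(100) < 0.2, 10, 10), simplify = FALSE)
  ss <- segment_spots(masks, fx$model, connectivity = 8)
  u <- Reduce(`|`, masks)
  covered <- ss$summary > 0
  expect_identical(covered, u)
  all_units <- unlist(lapply(ss$spots, `[[`, "unit_index"))
  expect_identical(anyDuplicated(all_units), 0L)
})

test_that("portrait input segments the thresholded max summary map", {
  gp <- group_portraits(fx$model)
  ss <- segment_spots(gp, fx$model, connectivity = 8, quantile = 0.95)
  sm <- summary_map(gp)
  manual <- sm > quantile(as.vector(sm), 0.95, type = 7)
  expect_identical(ss$summary > 0, manual)
})

test_that("presence/absence voting thresholds the group difference symmetrically", {
  expect_identical(pa_vote(0.8, 0.0, 0.5), "up")
  expect_identical(pa_vote(0.3, 0.3, 0.5), "none")
  expect_identical(pa_vote(-0.8, 0.9, 0.5), "down")
  expect_warning(v <- pa_vote(1, 0, 0), "none")
  expect_identical(v, "none")

  flip <- c(up = "down", down = "up", none = "none")
  set.seed(9)
  for (i in 1:50) {
    tm <- rnorm(1); rm_ <- rnorm(1); s <- runif(1, 0.1, 2)
    expect_identical(pa_vote(rm_, tm, s), unname(flip[pa_vote(tm, rm_, s)]))
  }
})

test_that("the t-test call gates on both p-value and fold change", {
  sp <- fake_spot(c(a = 2, b = 2.1, c = 1.9, x = 1, y = 1.1, z = 0.9))
  res <- ttest_call(sp, c("a", "b", "c"), c("x", "y", "z"))
  o <- welch_oracle(c(2, 2.1, 1.9), c(1, 1.1, 0.9))
  expect_equal(res$p_value, o$p, tolerance = 1e-12)
  expect_equal(o$t, 12.24745, tolerance = 1e-5)
  expect_equal(res$linear_fc, 2)
  expect_identical(res$vote, "up")

  # identical groups: p in the 1 region, fc = 1
  sp2 <- fake_spot(c(a = 1, b = 2, c = 3, x = 1, y = 2, z = 3))
  res2 <- ttest_call(sp2, c("a", "b", "c"), c("x", "y", "z"))
  expect_identical(res2$vote, "none")
  expect_equal(res2$linear_fc, 1)

  # small shift: significant but below the fc gate
  set.seed(10)
  base <- rnorm(20, sd = 0.01)
  sp3 <- fake_spot(structure(c(base + 0.3, base),
                             names = c(paste0("t", 1:20), paste0("r", 1:20))))
  res3 <- ttest_call(sp3, paste0("t", 1:20), paste0("r", 1:20))
  expect_lt(res3$p_value, 1e-6)
  expect_lt(res3$linear_fc, 1.5)
  expect_identical(res3$vote, "none")

  # swapping target and reference flips the vote
  res_sw <- ttest_call(sp, c("x", "y", "z"), c("a", "b", "c"))
  expect_identical(res_sw$vote, "down")

  expect_warning(
    r1 <- ttest_call(fake_spot(c(a = 1, x = 0, y = 0.1)), "a", c("x", "y")),
    "fewer than two")
  expect_identical(r1$vote, "none")
})

test_that("the joint vote is a conservative AND by default", {
  expect_identical(joint_vote("up", "up"), "up")
  expect_identical(joint_vote("down", "down"), "down")
  expect_identical(joint_vote("up", "none"), "none")
  expect_identical(joint_vote("none", "down"), "none")
  expect_identical(joint_vote("up", "down"), "none")
  expect_identical(joint_vote("up", "none", mode = "any"), "up")
  expect_identical(joint_vote("none", "down", mode = "any"), "down")
  expect_identical(joint_vote("up", "down", mode = "any"), "none")
})

test_that("antagonistic disease/drug spots drive the repositioning verdict", {
  # toy perturbation matrix: one immune spot upregulated in three diseases
  # and reversed by the drug, one disease with no dysregulated spots at all
  mk <- function(spot, contrast, dir) data.frame(
    spot = spot, contrast = contrast, layer = contrast, pa_vote = dir,
    t_vote = dir, direction = dir, p_value = NA_real_,
    p_adjusted = NA_real_, linear_fc = NA_real_)
  pm <- rbind(
    mk("U", "UC", "up"), mk("U", "CD", "up"), mk("U", "sarcoidosis", "up"),
    mk("U", "COPD", "none"), mk("U", "drug", "down"),
    mk("F", "UC", "up"), mk("F", "CD", "none"),
    mk("F", "sarcoidosis", "none"), mk("F", "COPD", "none"),
    mk("F", "drug", "none"),
    mk("A", "UC", "down"), mk("A", "CD", "down"),
    mk("A", "sarcoidosis", "none"), mk("A", "COPD", "none"),
    mk("A", "drug", "none"))
  class(pm) <- c("PerturbationMatrix", "data.frame")
  for (dz in c("UC", "CD", "sarcoidosis")) {
    v <- repositioning_call(pm, "drug", dz)
    expect_identical(v$verdict, "candidate")
    expect_identical(v$antagonistic_spots$spot, "U")
  }
  v_copd <- repositioning_call(pm, "drug", "COPD")
  expect_identical(v_copd$verdict, "not_supported")
  expect_identical(nrow(v_copd$antagonistic_spots), 0L)
  # disease-only spots are reported as unopposed
  v_uc <- repositioning_call(pm, "drug", "UC")
  expect_setequal(v_uc$unopposed_disease_spots, c("F", "A"))

  # same-direction change is not antagonistic
  pm2 <- rbind(mk("U", "dz", "up"), mk("U", "drug", "up"))
  class(pm2) <- c("PerturbationMatrix", "data.frame")
  expect_identical(repositioning_call(pm2, "drug", "dz")$verdict,
                   "not_supported")

  # an empty matrix supports nothing
  empty <- pm[0, ]
  expect_identical(repositioning_call(empty, "drug", "UC")$verdict,
                   "not_supported")
  expect_error(repositioning_call(pm, "drug", "nope"), "unknown contrast")
})

test_that("perturbation matrices carry calls for every spot and contrast", {
  gp <- group_portraits(fx$model)
  ss <- segment_spots(gp, fx$model)
  cts <- enumerate_contrasts(fx$model)
  pm <- perturbation_matrix(ss, fx$model, cts, ml_config(grid_size = 10))
  expect_identical(nrow(pm), length(ss$spots) * length(cts))
  expect_true(all(pm$direction %in% c("up", "down", "none")))
  # the planted module is recovered as an upregulated spot in L1
  mod <- fx$sim$truth$modules[[1]]$genes
  ov <- vapply(ss$spots, function(s) length(intersect(s$genes, mod)), 1)
  lab <- names(which.max(ov))
  expect_gt(max(ov), 20)
  expect_identical(
    pm$direction[pm$spot == lab & pm$layer == "L1"], "up")
  expect_identical(
    pm$direction[pm$spot == lab & pm$layer == "L2"], "none")
})
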