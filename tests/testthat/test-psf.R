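chain <- function(sign, fc) {
  pathway_graph(data.frame(source = "A", sign = sign, sink = "B"), fc)
}

test_that("signal flow multiplies through activations and divides through inhibitions", {
  r1 <- psf_propagate(chain("activation", c(A = 2, B = 3)))
  expect_equal(unname(r1$signal["B"]), 6)
  expect_equal(unname(r1$sink_values["B"]), 6)

  r2 <- psf_propagate(chain("inhibition", c(A = 2, B = 3)))
  expect_equal(unname(r2$signal["B"]), 1.5)

  # two activating parents combine multiplicatively
  g3 <- pathway_graph(
    data.frame(source = c("P1", "P2"), sign = "activation",
               sink = c("C", "C")),
    c(P1 = 2, P2 = 3, C = 1))
  expect_equal(unname(psf_propagate(g3)$signal["C"]), 6)
  # mean combination behind the flag
  expect_equal(unname(psf_propagate(g3, combination = "mean")$signal["C"]),
               2.5)
})

test_that("all-ones fold changes are neutral on any acyclic topology", {
  set.seed(21)
  for (i in 1:100) {
    g <- random_dag(sample(3:12, 1), p_edge = 0.4,
                    signs = c("activation", "inhibition"))
    res <- psf_propagate(g)
    expect_equal(max(abs(res$signal - 1)), 0, tolerance = 1e-12)
  }
})

test_that("raising an activating ancestor never lowers a sink", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    fc <- structure(exp(runif(n, -1, 1)), names = paste0("n", seq_len(n)))
    g <- random_dag(n, p_edge = 0.5, signs = "activation", fc = fc)
    before <- psf_propagate(g)$sink_values
    boost <- sample(g$input_nodes, 1)
    fc2 <- fc
    fc2[boost] <- fc2[boost] * 2
    g2 <- pathway_graph(g$edges, fc2)
    after <- psf_propagate(g2)$sink_values
    expect_true(all(after >= before - 1e-12))
  }
})

test_that("flipping an edge sign inverts its contribution exactly", {
  fc <- c(A = 2.5, B = 1.7, C = 0.9)
  edges <- data.frame(source = c("A", "B"), sign = "activation",
                      sink = c("B", "C"))
  act <- psf_propagate(pathway_graph(edges, fc))$signal
  edges$sign[1] <- "inhibition"
  inh <- psf_propagate(pathway_graph(edges, fc))$signal
  expect_equal(unname(inh["B"] * fc["A"]^2), unname(act["B"] * 1),
               tolerance = 1e-12)
  expect_equal(unname(inh["B"]), unname(act["B"]) / fc[["A"]]^2)
})

test_that("cycles are resolved by fixed-point iteration", {
  # feedback loop fed by an input: A -> B -> C -> B
  edges <- data.frame(source = c("A", "B", "C"),
                      sign = c("activation", "activation", "inhibition"),
                      sink = c("B", "C", "B"))
  g <- pathway_graph(edges, c(A = 2, B = 1, C = 1))
  res <- psf_propagate(g)
  expect_true(res$converged)
  # fixed point: B = 2 / C, C = B  =>  B = C = sqrt(2)
  expect_equal(unname(res$signal["B"]), sqrt(2), tolerance = 1e-4)
  expect_equal(unname(res$signal["C"]), sqrt(2), tolerance = 1e-4)

  # a strongly connected graph with no inputs is rejected
  loop <- pathway_graph(data.frame(source = c("A", "B"),
                                   sign = "activation",
                                   sink = c("B", "A")),
                        c(A = 2, B = 3))
  expect_error(psf_propagate(loop), "no input")
})

test_that("isolated nodes carry their own fold change to the sinks", {
  edges <- data.frame(source = "A", sign = "activation", sink = "B")
  g <- pathway_graph(edges, c(A = 1, B = 1, D = 4))
  res <- psf_propagate(g)
  expect_equal(unname(res$sink_values["D"]), 4)
})

test_that("contrast fold changes are linear-scale ratios of log2 means", {
  m <- matrix(c(1, 2, 3, 5), 2, 2,
              dimnames = list(c("g1", "g2"), c("t", "r")))
  fc <- node_fc_from_contrast(m, "t", "r")
  expect_equal(unname(fc), c(2^(1 - 3), 2^(2 - 5)))
})
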