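# Independent textbook oracles used to cross-check the package's numerics.

# quantile normalization: per-rank means of the sorted columns, mapped back
# by rank (tie-free inputs only)
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# Welch two-sample t-test from first principles
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# type-7 quantile: linear interpolation between order statistics
type7_oracle <- function(v, q) {
  s <- sort(v)
  h <- (length(v) - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(v))] - s[lo])
}

# right-tailed hypergeometric p by explicit summation over the tail
hyper_tail_oracle <- function(N, K, n, k) {
  js <- seq(k, min(K, n))
  if (!length(js) || k < max(0, n - (N - K))) js <- seq(max(k, 0), min(K, n))
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# stack-based flood fill labeling of a logical grid
flood_fill_oracle <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    stack <- list(c(i, j))
    lab[i, j] <- k
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        r <- cur[1] + offs[o, 1]; c <- cur[2] + offs[o, 2]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# canonical signature of a labeling: the partition of flagged cells,
# independent of label order
partition_signature <- function(lab) {
  cells <- which(lab > 0)
  unname(sort(vapply(split(cells, lab[cells]),
                     function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

# random layered acyclic pathway: every edge goes from an earlier to a
# later node
random_dag <- function(n_nodes, p_edge = 0.3, signs = "activation",
                       fc = NULL) {
  nodes <- paste0("n", seq_len(n_nodes))
  from <- c(); to <- c()
  for (i in seq_len(n_nodes - 1)) for (j in seq(i + 1, n_nodes)) {
    if (runif(1) < p_edge) { from <- c(from, i); to <- c(to, j) }
  }
  if (!length(from)) { from <- 1L; to <- 2L }
  edges <- data.frame(source = nodes[from],
                      sign = sample(signs, length(from), replace = TRUE),
                      sink = nodes[to])
  if (is.null(fc)) fc <- structure(rep(1, n_nodes), names = nodes)
  pathway_graph(edges, fc)
}
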