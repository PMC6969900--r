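# Shared fixtures built in code.

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_matrix_path <- function() {
  write_tsv_lines(c("gene\tS1\tS2",
                    "TNF\t1.5\t2.5",
                    "IL6\t0.25\t-1",
                    "ACTB\t3\t4"))
}

tiny_sheet_path <- function() {
  write_tsv_lines(c("sample\tlayer\tgroup\tsubgroup",
                    "S1\tUC\ttarget\tresponder",
                    "S2\tUC\treference\t"))
}

# a small two-layer dataset with one planted up-module, built via the
# generator; cheap enough to rebuild per test file
small_sim <- function(seed = 7, effect = 1.5) {
  simulate_study(
    layout = list(synthetic_layer("L1", "target_disease", 6, 6),
                  synthetic_layer("L2", "repositioning_disease", 6, 6)),
    n_genes = 400,
    modules = list(
      synthetic_module(40, effect, c(L1 = "up", L2 = "none")),
      synthetic_module(40, 0, c(L1 = "none", L2 = "none"))),
    seed = seed)
}

small_model <- function(seed = 7, grid = 10, effect = 1.5) {
  sim <- small_sim(seed, effect)
  joint <- preprocess_dataset(sim$dataset, quiet = TRUE)
  list(sim = sim, joint = joint,
       model = train_som(joint, ml_config(grid_size = grid)))
}

# a minimal Spot carrying only a profile, for direct calling tests
fake_spot <- function(profile) {
  structure(list(label = "A", units = cbind(r = 1L, c = 1L),
                 unit_index = 1L, genes = character(0), profile = profile),
            class = "Spot")
}
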