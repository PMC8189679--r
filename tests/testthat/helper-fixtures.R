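# Small programmatic fixtures shared across test files.

make_expr <- function(genes, samples, values) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

# a tiny complete benchmark instance (ground truth + two expression draws)
tiny_instance <- function(n_tfs = 6, n_genes = 60, noise_sd = 0, seed = 42,
                          ...) {
  cfg <- generator_config(n_tfs = n_tfs, n_genes = n_genes,
                          targets_per_tf = c(3, 8), noise_sd = noise_sd,
                          seed = seed, ...)
  gt <- generate_ground_truth(cfg)
  list(gt = gt,
       e1 = generate_expression(gt, noise_sd = noise_sd, seed = seed + 1),
       e2 = generate_expression(gt, noise_sd = noise_sd, seed = seed + 2))
}

# brute-force 1-D least squares for a single constrained coefficient:
# minimize sum((y - b - cs*a)^2) over cs in [lo, hi] with b profiled out
brute_cs_1d <- function(a, y, lo, hi, n_grid = 20001) {
  grid <- seq(lo, hi, length.out = n_grid)
  sse <- vapply(grid, function(cs) {
    b <- mean(y - cs * a)
    sum((y - b - cs * a)^2)
  }, 0.0)
  i <- which.min(sse)
  list(cs = grid[i], b = mean(y - grid[i] * a), sse = sse[i])
}
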