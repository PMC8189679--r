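test_that("standardize_activities gives exact z-scores of log2 activity", {
  tfa <- rbind(A = c(1, 2, 4), B = c(3, 3, 3))
  colnames(tfa) <- paste0("s", 1:3)
  z <- standardize_activities(tfa)
  expect_equal(unname(z["A", ]), c(-1, 0, 1))       # log2 -> (0,1,2)
  expect_equal(unname(z["B", ]), c(0, 0, 0))        # constant row
  set.seed(2)
  big <- matrix(rlnorm(200), 10, dimnames = list(paste0("T", 1:10),
                                                 paste0("s", 1:20)))
  zb <- standardize_activities(big)
  expect_lt(max(abs(rowMeans(zb))), 1e-9)
  expect_lt(max(abs(apply(zb, 1, sd) - 1)), 1e-9)
})

test_that("direction metric scores deletions below and OEs above reference", {
  key <- perturbation_key(tibble::tibble(
    sample = c("WT", "KO_A", "OE_B"), tf = c(NA, "A", "B"),
    direction = c("none", "deletion", "overexpression")))
  tfa <- rbind(A = c(1, 0, 1), B = c(1, 1, 4))
  colnames(tfa) <- c("WT", "KO_A", "OE_B")
  d <- direction_metric(tfa, key)
  expect_equal(d$fraction, 1)
  # ties count as incorrect
  tfa2 <- tfa; tfa2["B", "OE_B"] <- 1
  expect_equal(direction_metric(tfa2, key)$fraction, 0.5)
})

test_that("direction metric sits at chance for random activities", {
  set.seed(8)
  n <- 400
  key <- perturbation_key(tibble::tibble(
    sample = c("WT", paste0("p", 1:n)),
    tf = c(NA, rep(paste0("T", 1:10), length.out = n)),
    direction = c("none", sample(c("deletion", "overexpression"), n, TRUE))))
  tfa <- matrix(rlnorm(11 * (n + 1)), 11,
                dimnames = list(c(paste0("T", 1:10), "X"),
                                c("WT", paste0("p", 1:n))))
  d <- direction_metric(tfa[1:10, , drop = FALSE], key)
  expect_gt(d$p_value, 0.01)
  expect_lt(abs(d$fraction - 0.5), 0.08)
})

test_that("rank percentile follows 100*(1-(r-1)/n) with mean-rank ties", {
  z <- matrix(0, 50, 2, dimnames = list(sprintf("T%02d", 1:50),
                                        c("KO_T01", "KO_T26")))
  z[, 1] <- seq(-2, 2, length.out = 50)          # T01 lowest -> rank 1
  z[, 2] <- seq(-2, 2, length.out = 50)          # T26 is rank 26
  key <- perturbation_key(tibble::tibble(
    sample = c("KO_T01", "KO_T26"), tf = c("T01", "T26"),
    direction = "deletion"))
  r <- rank_percentile_metric(z, key)
  ps <- r$per_sample
  expect_equal(ps$percentile[ps$tf == "T01"], 100)
  expect_equal(ps$percentile[ps$tf == "T26"], 50)
})

test_that("rank percentile is near 50 under the null", {
  set.seed(12)
  n <- 300
  z <- matrix(rnorm(20 * n), 20,
              dimnames = list(paste0("T", 1:20), paste0("s", 1:n)))
  key <- perturbation_key(tibble::tibble(
    sample = paste0("s", 1:n),
    tf = rep(paste0("T", 1:20), length.out = n),
    direction = rep(c("deletion", "overexpression"), length.out = n)))
  r <- rank_percentile_metric(z, key)
  expect_lt(abs(r$median_percentile - 50), 8)
})

test_that("positive-correlation metric hits 1 on self, 0.5 on noise, and is reproducible", {
  set.seed(5)
  tfa <- matrix(rlnorm(15 * 40), 15,
                dimnames = list(paste0("T", 1:15), paste0("s", 1:40)))
  self <- positive_correlation_metric(tfa, tfa, n_boot = 100, seed = 3)
  expect_equal(self$median_fraction, 1)
  noise <- matrix(rnorm(15 * 40, 8), 15, dimnames = dimnames(tfa))
  null <- positive_correlation_metric(tfa, noise, n_boot = 200, seed = 3)
  expect_lt(abs(null$median_fraction - 0.5), 0.2)
  again <- positive_correlation_metric(tfa, noise, n_boot = 200, seed = 3)
  expect_identical(null$median_fraction, again$median_fraction)
})

test_that("fisher_combine matches the closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12)  # df=2 identity
  x <- -2 * sum(log(c(0.05, 0.05)))
  closed <- (1 + x / 2) * exp(-x / 2)                        # df=4 survival
  expect_equal(fisher_combine(c(0.05, 0.05)), closed, tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "p-values")
})

test_that("averaging standardized activities reduces estimation noise", {
  set.seed(6)
  truth <- matrix(rnorm(8 * 30), 8,
                  dimnames = list(paste0("T", 1:8), paste0("s", 1:30)))
  noisy <- function() truth + matrix(rnorm(length(truth), 0, 1), nrow(truth))
  z1 <- standardize_activities(2^noisy(), floor = 1e-9)
  z2 <- standardize_activities(2^noisy(), floor = 1e-9)
  avg <- average_standardized_tfas(list(z1, z2))
  cor_of <- function(z) median(vapply(1:8, function(i)
    cor(z[i, ], truth[i, ]), 0.0))
  expect_gt(cor_of(avg), max(cor_of(z1), cor_of(z2)) - 0.02)
  # identical inputs pass through; single-matrix TFs are copied
  same <- average_standardized_tfas(list(z1, z1))
  expect_equal(same, z1, tolerance = 1e-9)
  z3 <- z2[1:3, , drop = FALSE]
  rownames(z3) <- paste0("U", 1:3)
  both <- average_standardized_tfas(list(z1, z3))
  expect_equal(both["U2", ], z3["U2", ], tolerance = 1e-9)
})

test_that("regulator recovery curve starts at 1 and dominates a permuted gold", {
  set.seed(44)
  tfs <- paste0("T", 1:12)
  samples <- c("WT", paste0("KO_R", 1:4))
  z <- matrix(rnorm(length(tfs) * length(samples), 0, 0.3),
              length(tfs), dimnames = list(tfs, samples))
  gold <- tibble::tibble(regulator = paste0("R", 1:4),
                         target = c("T1", "T2", "T3", "T4"))
  # regulators strongly move their gold target
  for (i in 1:4) z[gold$target[i], i + 1] <- z[gold$target[i], 1] + 5
  key <- perturbation_key(tibble::tibble(
    sample = samples, tf = c(NA, paste0("R", 1:4)),
    direction = c("none", rep("deletion", 4))))
  curve <- regulator_recovery_curve(z, key, gold)
  expect_equal(curve$fraction_recovered[curve$threshold == 0], 1)
  perm <- gold
  perm$target <- c("T9", "T10", "T11", "T12")
  curve_null <- regulator_recovery_curve(z, key, perm)
  expect_gt(mean(curve$fraction_recovered), mean(curve_null$fraction_recovered))
})

test_that("bootstrap CS correlation scores self at 1 and permutations near 0", {
  x <- tiny_instance(n_tfs = 5, n_genes = 60, seed = 51)
  gt <- x$gt
  self <- bootstrap_cs_correlation(gt$cs, gt$cs, gt$net, min_targets = 3,
                                   n_boot = 50, seed = 2)
  expect_true(all(self$median_cor == 1))
  set.seed(9)
  cov <- setNames(rnorm(nrow(gt$cs$cs)), rownames(gt$cs$cs))
  null <- bootstrap_cs_correlation(gt$cs, cov, gt$net, min_targets = 3,
                                   n_boot = 200, seed = 2)
  expect_lt(abs(median(null$median_cor)), 0.45)
  again <- bootstrap_cs_correlation(gt$cs, cov, gt$net, min_targets = 3,
                                    n_boot = 200, seed = 2)
  expect_identical(null$median_cor, again$median_cor)
})
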