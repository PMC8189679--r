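test_that("tfa_step pins deletions at zero and honours OE reference bounds", {
  x <- tiny_instance(n_tfs = 4, n_genes = 40, noise_sd = 0, seed = 11)
  gt <- x$gt
  bounds <- activity_bounds(gt$key, rownames(gt$tfa), colnames(x$e1))
  tfa <- tfa_step(x$e1, gt$cs, bounds)
  del <- dplyr::filter(key_records(gt$key), direction == "deletion")
  expect_true(all(tfa[cbind(del$tf, del$sample)] == 0))
  oe <- dplyr::filter(key_records(gt$key), direction == "overexpression")
  ref <- key_reference(gt$key)
  expect_true(all(tfa[cbind(oe$tf, oe$sample)] >=
                    tfa[oe$tf, ref] + bounds$floor - 1e-12))
  # noiseless expression from the true CS recovers the true activities
  expect_equal(unname(tfa), unname(gt$tfa), tolerance = 1e-6)
})

test_that("an active OE bound lands on reference + floor (1-D brute check)", {
  genes <- paste0("g", 1:8)
  net <- tf_network(tibble::tibble(tf = "A", target = genes))
  cs <- cs_matrix(matrix(1, 8, 1, dimnames = list(genes, "A")),
                  setNames(rep(5, 8), genes))
  key <- perturbation_key(tibble::tibble(
    sample = c("WT", "OE_A"), tf = c(NA, "A"),
    direction = c("none", "overexpression")))
  # WT expression puts the reference activity at 1; the OE sample's
  # unconstrained optimum (0.4) is below it, so the bound binds
  expr <- make_expr(genes, c("WT", "OE_A"), cbind(rep(6, 8), rep(5.4, 8)))
  b <- activity_bounds(key, "A", c("WT", "OE_A"))
  tfa <- tfa_step(expr, cs, b)
  expect_equal(tfa["A", "WT"], 1, tolerance = 1e-9)
  expect_equal(tfa["A", "OE_A"], 1 + b$floor, tolerance = 1e-9)
  # 1-D brute force over the feasible region cannot do better
  obj <- function(a) sum((expr[, "OE_A"] - 5 - a)^2)
  brute <- optimize(obj, c(1 + b$floor, 10))
  expect_lte(obj(tfa["A", "OE_A"]), obj(brute$minimum) + 1e-9)
  expect_gte(tfa["A", "OE_A"], 1 + b$floor - 1e-12)
})

test_that("mean-one normalization preserves predictions and is idempotent", {
  x <- tiny_instance(n_tfs = 4, n_genes = 40, noise_sd = 0.2, seed = 13)
  gt <- x$gt
  tfa <- gt$tfa * runif(nrow(gt$tfa), 0.5, 3)  # break mean-1
  pred0 <- predict_expression(gt$cs, tfa)
  nrm <- normalize_mean_activity(gt$cs, tfa)
  expect_equal(unname(rowMeans(nrm$tfa)), rep(1, nrow(tfa)))
  expect_lt(max(abs(predict_expression(nrm$cs, nrm$tfa) - pred0)), 1e-10)
  again <- normalize_mean_activity(nrm$cs, nrm$tfa)
  expect_equal(again$tfa, nrm$tfa, tolerance = 1e-12)

  zero <- tfa; zero[1, ] <- 0
  expect_error(normalize_mean_activity(gt$cs, zero), "zero mean")
})

test_that("alternating fit never increases training SSE", {
  x <- tiny_instance(n_tfs = 5, n_genes = 50, noise_sd = 0.3, seed = 17)
  fit <- fit_model(x$e1, x$gt$net, x$gt$signs, x$gt$key,
                   fit_config(n_inits = 2, max_iter = 25, seed = 3,
                              stopping = "train_converge",
                              train_tol = 1e-12))
  expect_true(all(diff(fit$r2_train) >= -1e-9))
})

test_that("noiseless fit recovers the ground truth model", {
  x <- tiny_instance(n_tfs = 5, n_genes = 60, noise_sd = 0, seed = 19)
  fit <- fit_model(x$e1, x$gt$net, x$gt$signs, x$gt$key,
                   fit_config(n_inits = 4, max_iter = 150, seed = 5,
                              stopping = "train_converge",
                              train_tol = 1e-12))
  expect_gte(tail(fit$r2_train, 1), 0.999)
  # per-TF correlation with the (already mean-one) true activities
  tr <- x$gt$tfa[rownames(fit$tfa), colnames(fit$tfa)]
  cors <- vapply(seq_len(nrow(tr)),
                 function(i) cor(fit$tfa[i, ], tr[i, ]), 0.0)
  expect_gte(min(cors), 0.99)
  # fitted CS signs match truth on every edge
  td <- tidy(fit)
  expect_true(all(td$cs * td$sign >= 0))
})

test_that("fit is invariant to inverse rescaling of a TF's truth (scale invariance)", {
  x <- tiny_instance(n_tfs = 4, n_genes = 40, noise_sd = 0, seed = 23)
  gt <- x$gt
  cfgf <- fit_config(n_inits = 2, max_iter = 80, seed = 9,
                     stopping = "train_converge", train_tol = 1e-12)
  fit1 <- fit_model(x$e1, gt$net, gt$signs, gt$key, cfgf)
  # rescale truth: CS column x2, TFA row /2 -> identical data
  gt2 <- gt
  gt2$cs$cs[, 1] <- gt2$cs$cs[, 1] * 2
  gt2$tfa[1, ] <- gt2$tfa[1, ] / 2
  e_alt <- generate_expression(gt2, noise_sd = 0, seed = 43)
  expect_equal(e_alt, x$e1, tolerance = 1e-10)
  fit2 <- fit_model(e_alt, gt$net, gt$signs, gt$key, cfgf)
  expect_equal(fit1$tfa, fit2$tfa, tolerance = 1e-8)
})

test_that("refit holds CS fixed, absorbs dataset shifts in baselines", {
  x <- tiny_instance(n_tfs = 5, n_genes = 50, noise_sd = 0, seed = 29)
  fit <- fit_model(x$e1, x$gt$net, x$gt$signs, x$gt$key,
                   fit_config(n_inits = 2, max_iter = 100, seed = 1,
                              stopping = "train_converge",
                              train_tol = 1e-12))
  r1 <- refit_activities(x$e2, fit$cs)
  tr <- x$gt$tfa[rownames(r1$tfa), colnames(r1$tfa)]
  cors <- vapply(seq_len(nrow(tr)),
                 function(i) cor(r1$tfa[i, ], tr[i, ]), 0.0)
  expect_gte(median(cors), 0.99)
  # constant shift moves baselines, not activities
  r2 <- refit_activities(x$e2 + 3, fit$cs)
  expect_equal(r2$tfa, r1$tfa, tolerance = 1e-6)
  expect_equal(unname(r2$baselines - r1$baselines),
               rep(3, length(r1$baselines)), tolerance = 1e-6)

  bad <- x$e2
  rownames(bad) <- paste0("x", rownames(bad))
  expect_error(refit_activities(bad, fit$cs), "shared")
})

test_that("signed-binary CS mirrors the sign constraints", {
  net <- tf_network(tibble::tibble(tf = c("A", "A", "B", "B"),
                                   target = c("g1", "g2", "g2", "g3")))
  signs <- sign_constraints(tibble::tibble(
    tf = net$tf, target = net$target, sign = c(1, -1, 1, 1)), net)
  cs <- signed_binary_cs(signs, genes = c("g1", "g2", "g3"),
                         tfs = c("A", "B"))
  expect_equal(cs$cs["g1", "A"], 1)
  expect_equal(cs$cs["g2", "A"], -1)
  expect_equal(cs$cs["g1", "B"], 0)
  expect_equal(unname(cs$baselines), rep(0, 3))
})

test_that("variance_explained is 1 at perfect fit and 0 for gene means", {
  x <- tiny_instance(n_tfs = 4, n_genes = 30, noise_sd = 0, seed = 31)
  gt <- x$gt
  expect_equal(variance_explained(x$e1, gt$cs, gt$tfa), 1, tolerance = 1e-12)
  zero_tfa <- gt$tfa * 0
  means_cs <- cs_matrix(gt$cs$cs * 0, setNames(rowMeans(x$e1), rownames(x$e1)))
  expect_equal(variance_explained(x$e1, means_cs, zero_tfa), 0,
               tolerance = 1e-12)
  # a fitted model explains more variance than the random initialization
  fit <- fit_model(x$e1, gt$net, gt$signs, gt$key,
                   fit_config(n_inits = 1, max_iter = 30, seed = 2,
                              stopping = "train_converge"))
  set.seed(4)
  rnd_cs <- cs_matrix(sign_matrix(gt$signs, rownames(gt$cs$cs),
                                  colnames(gt$cs$cs)) *
                        matrix(runif(length(gt$cs$cs), 0.2, 2),
                               nrow(gt$cs$cs)),
                      setNames(rowMeans(x$e1), rownames(x$e1)))
  rnd_tfa <- gt$tfa * matrix(rlnorm(length(gt$tfa)), nrow(gt$tfa))
  expect_gt(variance_explained(x$e1[rownames(fit$cs$cs), ], fit$cs, fit$tfa),
            variance_explained(x$e1, rnd_cs, rnd_tfa))
})

test_that("identical seeds give identical fits", {
  x <- tiny_instance(n_tfs = 4, n_genes = 40, noise_sd = 0.2, seed = 37)
  cfgf <- fit_config(n_inits = 2, max_iter = 15, seed = 123,
                     stopping = "train_converge")
  f1 <- fit_model(x$e1, x$gt$net, x$gt$signs, x$gt$key, cfgf)
  f2 <- fit_model(x$e1, x$gt$net, x$gt$signs, x$gt$key, cfgf)
  expect_identical(f1$cs, f2$cs)
  expect_identical(f1$tfa, f2$tfa)
})
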