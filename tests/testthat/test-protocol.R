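protocol_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- tiny_instance(n_tfs = 6, n_genes = 80, noise_sd = 0.2, seed = 91)
      ds1 <- list(expr = x$e1, key = x$gt$key, tf_mrna = x$gt$tf_mrna)
      ds2 <- list(expr = x$e2, key = x$gt$key, tf_mrna = x$gt$tf_mrna)
      cache <<- list(x = x, ds1 = ds1, ds2 = ds2)
    }
    cache
  }
})

test_that("the two-direction protocol beats chance on generator data", {
  f <- protocol_fixture()
  pr <- run_protocol(f$ds1, f$ds2, f$x$gt$net, "perturbation", "optimized",
                     config = fit_config(n_inits = 2, max_iter = 40,
                                         seed = 19),
                     n_boot = 200, eval_seed = 7)
  g <- glance(pr)
  expect_gt(g$direction_fraction, 0.8)
  expect_lt(g$direction_p, 1e-3)
  expect_gt(g$median_rank_percentile, 80)
  expect_gt(g$positive_corr_fraction, 0.6)
  # combined fractions lie between the two per-direction values
  d <- vapply(pr$per_direction, function(m) m$direction_fraction, 0.0)
  expect_gte(g$direction_fraction, min(d))
  expect_lte(g$direction_fraction, max(d))
})

test_that("signed-binary control strengths stay close to optimized ones", {
  f <- protocol_fixture()
  pr <- run_protocol(f$ds1, f$ds2, f$x$gt$net, "perturbation",
                     "signed_binary", config = fit_config(seed = 19),
                     n_boot = 200, eval_seed = 7)
  g <- glance(pr)
  expect_gt(g$direction_fraction, 0.8)
  expect_lt(g$direction_p, 1e-3)
})

test_that("uncoupled TF mRNA sends correlation-based signs toward chance", {
  # with mrna_coupling = 0 the correlation constraints carry no signal,
  # while perturbation constraints still do
  x <- tiny_instance(n_tfs = 6, n_genes = 80, noise_sd = 0.2, seed = 93,
                     mrna_coupling = 0)
  ds1 <- list(expr = x$e1, key = x$gt$key, tf_mrna = x$gt$tf_mrna)
  ds2 <- list(expr = x$e2, key = x$gt$key, tf_mrna = x$gt$tf_mrna)
  cfgf <- fit_config(n_inits = 2, max_iter = 30, seed = 3)
  pr_corr <- run_protocol(ds1, ds2, x$gt$net, "correlation", "optimized",
                          config = cfgf, n_boot = 100, eval_seed = 2)
  pr_pert <- run_protocol(ds1, ds2, x$gt$net, "perturbation", "optimized",
                          config = cfgf, n_boot = 100, eval_seed = 2)
  expect_gt(glance(pr_pert)$direction_fraction,
            glance(pr_corr)$direction_fraction)
})

test_that("the protocol is deterministic under fixed seeds", {
  f <- protocol_fixture()
  cfgf <- fit_config(n_inits = 1, max_iter = 10, seed = 5)
  a <- run_protocol(f$ds1, f$ds2, f$x$gt$net, "perturbation", "optimized",
                    config = cfgf, n_boot = 50, eval_seed = 3)
  b <- run_protocol(f$ds1, f$ds2, f$x$gt$net, "perturbation", "optimized",
                    config = cfgf, n_boot = 50, eval_seed = 3)
  expect_identical(glance(a), glance(b))
})

test_that("tidiers and autoplots cover the main result types", {
  f <- protocol_fixture()
  fit <- fit_model(f$ds1$expr, f$x$gt$net, f$x$gt$signs, f$ds1$key,
                   fit_config(n_inits = 1, max_iter = 10, seed = 2,
                              stopping = "train_converge"))
  td <- tidy(fit)
  expect_true(all(c("tf", "target", "sign", "cs") %in% names(td)))
  expect_true(all(td$cs * td$sign >= 0))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
  m <- evaluate_activities(fit$tfa, f$ds1$key, n_boot = 10, seed = 1)
  expect_s3_class(tidy(m), "tbl_df")
  expect_s3_class(autoplot(m), "ggplot")
  ts <- generate_timecourse("sigmoid4",
                            list(y0 = 0, A = 1, k = 0.2, t0 = 15),
                            c(2.5, 5, 10, 15, 20, 30, 45, 60, 90))
  cf <- fit_sigmoid(ts)
  expect_s3_class(tidy(cf), "tbl_df")
  expect_s3_class(autoplot(cf), "ggplot")
})
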