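toy_ranked <- function(df) ranked_edges(df)

test_that("prune_network removes single-target TFs and identical-set groups, cascading", {
  # {A -> g1} -> empty
  n1 <- prune_network(tibble::tibble(tf = "A", target = "g1"))
  expect_equal(nrow(n1), 0)

  # identical sets removed with their targets, cascade kills C
  n2 <- prune_network(tibble::tibble(
    tf = c("A", "A", "B", "B", "C", "C"),
    target = c("g1", "g2", "g1", "g2", "g2", "g3")))
  expect_equal(nrow(n2), 0)

  # all-distinct multi-target TFs are a fixed point
  df <- tibble::tibble(tf = c("A", "A", "B", "B", "B"),
                       target = c("g1", "g2", "g2", "g3", "g4"))
  expect_equal(as.data.frame(prune_network(df)), as.data.frame(df))
})

test_that("prune_network is idempotent on random networks", {
  set.seed(7)
  for (i in 1:20) {
    df <- tibble::tibble(
      tf = sample(LETTERS[1:6], 25, replace = TRUE),
      target = sample(paste0("g", 1:10), 25, replace = TRUE))
    df <- df[!duplicated(df), ]
    once <- prune_network(df)
    twice <- prune_network(once)
    expect_equal(as.data.frame(twice), as.data.frame(once))
  }
})

test_that("build_network executes the rank-order construction on a toy list", {
  # A and B share identical target sets {g1,g2,g3}; C has a single target;
  # D survives with {g5,g6}; interleaved so A,B,C,D each appear by rank 4
  df <- tibble::tibble(
    tf     = c("A", "B", "C", "D", "A", "B", "A", "B", "D"),
    target = c("g1", "g1", "g4", "g5", "g2", "g2", "g3", "g3", "g6"),
    score  = 9:1)
  net <- suppressWarnings(
    build_network(toy_ranked(df),
                  network_build_config(n_tfs = 2, max_rank = 9)))
  expect_setequal(network_tfs(net), "D")
  expect_setequal(net$target, c("g5", "g6"))
})

test_that("build_network returns the first-pass selection when nothing prunes", {
  df <- tibble::tibble(
    tf     = c("A", "B", "A", "B", "C", "C"),
    target = c("g1", "g2", "g3", "g4", "g5", "g6"),
    score  = 6:1)
  net <- build_network(toy_ranked(df),
                       network_build_config(n_tfs = 2, max_rank = 6))
  # seed pass stops at 2 TFs; A and B keep all their edges, C never enters
  expect_setequal(network_tfs(net), c("A", "B"))
  expect_equal(nrow(net), 4)
})

test_that("build_network errors when too few TFs are reachable", {
  df <- tibble::tibble(tf = c("A", "A"), target = c("g1", "g2"), score = 2:1)
  expect_error(build_network(toy_ranked(df),
                             network_build_config(n_tfs = 2, max_rank = 4)),
               "1 distinct TFs")
})

test_that("every edge of a built network comes from the ranked list", {
  set.seed(3)
  df <- tibble::tibble(
    tf = sample(paste0("T", 1:8), 120, replace = TRUE),
    target = sample(paste0("g", 1:40), 120, replace = TRUE),
    score = runif(120))
  df <- df[!duplicated(df[c("tf", "target")]), ]
  r <- toy_ranked(df)
  net <- suppressWarnings(
    build_network(r, network_build_config(n_tfs = 5, max_rank = 80)))
  in_list <- paste(net$tf, net$target) %in% paste(r$tf, r$target)
  expect_true(all(in_list))
  # deterministic given the list
  net2 <- suppressWarnings(
    build_network(r, network_build_config(n_tfs = 5, max_rank = 80)))
  expect_identical(as.data.frame(net), as.data.frame(net2))
})

test_that("select_block restricts to the block's rank window", {
  df <- tibble::tibble(tf = rep(paste0("T", 1:4), each = 5),
                       target = paste0("g", 1:20), score = 20:1)
  r <- toy_ranked(df)
  b1 <- select_block(r, 1, network_build_config(n_tfs = 2, max_rank = 10,
                                                block_size = 10))
  expect_true(all(paste(b1$tf, b1$target) %in%
                    paste(df$tf[1:10], df$target[1:10])))
  b2 <- select_block(r, 2, network_build_config(n_tfs = 2, max_rank = 10,
                                                block_size = 10))
  expect_true(all(paste(b2$tf, b2$target) %in%
                    paste(df$tf[11:20], df$target[11:20])))
  expect_error(select_block(r, 3, network_build_config(n_tfs = 2,
                                                       max_rank = 10,
                                                       block_size = 10)),
               "empty")
})

test_that("merge_networks drops sign conflicts and cascades single targets", {
  net1 <- tf_network(tibble::tibble(tf = c("A", "A", "B", "B"),
                                    target = c("g1", "g2", "g3", "g4")))
  s1 <- sign_constraints(tibble::tibble(tf = c("A", "A", "B", "B"),
                                        target = c("g1", "g2", "g3", "g4"),
                                        sign = c(1, 1, 1, -1)), net1)
  # identical inputs: union equals either input
  m_same <- merge_networks(list(list(net = net1, signs = s1),
                                list(net = net1, signs = s1)))
  expect_setequal(paste(m_same$net$tf, m_same$net$target),
                  paste(net1$tf, net1$target))

  # conflict on A->g1 drops the edge, leaving A with one target, which
  # cascades A and g2 out
  s2 <- sign_constraints(tibble::tibble(tf = c("A", "A", "B", "B"),
                                        target = c("g1", "g2", "g3", "g4"),
                                        sign = c(-1, 1, 1, -1)), net1)
  m <- merge_networks(list(list(net = net1, signs = s1),
                           list(net = net1, signs = s2)))
  expect_false("g1" %in% m$net$target)
  expect_false("A" %in% network_tfs(m$net))
  expect_setequal(network_tfs(m$net), "B")
  expect_equal(sort(m$signs$sign), c(-1, 1))
})
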