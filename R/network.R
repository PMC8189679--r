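#' Prune a TF network map
#'
#' Repeatedly removes (1) every TF with exactly one target and (2) every
#' maximal group of two or more TFs with identical target sets, together
#' with those shared target genes (the genes leave the network entirely, so
#' other TFs' edges to them are removed too). Removals can create new
#' single-target TFs, so the two rules are applied until neither fires;
#' the operation is idempotent.
#'
#' @param net A `tf_network` (possibly non-validated intermediate).
#' @return A pruned `tf_network`; may be empty.
#' @export
prune_network <- function(net) {
  edges <- as_tibble(net)[, c("tf", "target")]
  repeat {
    if (nrow(edges) == 0) break
    cnt <- table(edges$tf)
    singles <- names(cnt)[cnt == 1]
    if (length(singles) > 0) {
      edges <- edges[!(edges$tf %in% singles), , drop = FALSE]
      next
    }
    sets <- split(edges$target, edges$tf)
    keys <- vapply(sets, function(s) paste(sort(unique(s)), collapse = "\r"), "")
    dup_keys <- unique(keys[duplicated(keys)])
    if (length(dup_keys) > 0) {
      bad_tfs <- names(keys)[keys %in% dup_keys]
      bad_targets <- unique(unlist(sets[bad_tfs], use.names = FALSE))
      edges <- edges[!(edges$tf %in% bad_tfs) &
                       !(edges$target %in% bad_targets), , drop = FALSE]
      next
    }
    break
  }
  tf_network(edges, validate = FALSE)
}

#' Configuration for network construction from a ranked edge list
#'
#' @param n_tfs Number of distinct TFs the seed pass aims for (default 50).
#' @param max_rank Deepest edge rank considered (default 1250).
#' @param block_size Block width for [select_block()] (default 2000).
#' @param max_rounds Cap on re-add/re-prune rounds if the TF set oscillates.
#' @return A list of class `network_build_config`.
#' @export
network_build_config <- function(n_tfs = 50, max_rank = 1250,
                                 block_size = 2000, max_rounds = 25) {
  if (n_tfs < 2) abort_input("n_tfs must be >= 2")
  if (max_rank < n_tfs) abort_input("max_rank must be >= n_tfs")
  structure(list(n_tfs = n_tfs, max_rank = max_rank,
                 block_size = block_size, max_rounds = max_rounds),
            class = "network_build_config")
}

#' Build a qualitative TF network from a ranked edge list
#'
#' Implements the rank-based construction: (1) take edges in rank order
#' until `n_tfs` distinct TFs are represented; (2) add all lower-ranked
#' edges of those TFs down to rank `max_rank`; (3) prune single-target TFs
#' and identical-target-set TF groups ([prune_network()]); (4) iteratively
#' re-admit previously passed-over edges within `max_rank` whose TF is in
#' the current TF set and re-prune, until the TF set is unchanged between
#' rounds. If the stable network has fewer than `n_tfs` TFs a warning
#' reports the achieved count.
#'
#' @param ranked A `ranked_edges` tibble.
#' @param config A [network_build_config()].
#' @return A validated `tf_network`.
#' @export
build_network <- function(ranked, config = network_build_config()) {
  edges <- as_tibble(ranked)
  if (!"rank" %in% names(edges)) edges$rank <- seq_len(nrow(edges))
  pool <- edges[edges$rank <= config$max_rank, , drop = FALSE]
  tfs_in_order <- unique(pool$tf)  # first-appearance (rank) order
  if (length(tfs_in_order) < config$n_tfs)
    abort_input("only %d distinct TFs reachable within max_rank %d (need %d)",
                length(tfs_in_order), config$max_rank, config$n_tfs)
  # TFs eliminated by pruning never re-enter (re-admitting an
  # identical-target-set TF would oscillate forever); their former targets
  # remain ordinary genes for other TFs.
  blacklist <- character(0)
  current_tfs <- character(0)
  net <- tf_network(pool[0, c("tf", "target")], validate = FALSE)
  rounds <- 0
  repeat {
    rounds <- rounds + 1
    # selection pass: survivors keep their place; new TFs join in rank
    # order until n_tfs are represented or the list is exhausted
    candidates <- setdiff(tfs_in_order, c(blacklist, current_tfs))
    need <- max(0, config$n_tfs - length(current_tfs))
    sel_tfs <- c(current_tfs, utils::head(candidates, need))
    net <- prune_network(pool[pool$tf %in% sel_tfs, , drop = FALSE])
    new_tfs <- network_tfs(net)
    blacklist <- union(blacklist, setdiff(sel_tfs, new_tfs))
    stable <- setequal(new_tfs, sel_tfs)  # nothing pruned, nothing addable
    current_tfs <- new_tfs
    if (stable || rounds >= config$max_rounds) break
  }
  if (rounds >= config$max_rounds)
    warn(sprintf("network TF set did not stabilize in %d rounds; returning last",
                 config$max_rounds))
  if (length(current_tfs) != config$n_tfs)
    warn(sprintf("network stabilized at %d TFs (requested %d)",
                 length(current_tfs), config$n_tfs))
  tf_network(net, validate = TRUE)
}

#' Build a network from one fixed-rank block of the edge list
#'
#' Restricts the ranked list to ranks ((block_index-1)*block_size,
#' block_index*block_size], e.g. block 1 is ranks 1-2000 and block 4 is
#' ranks 6001-8000 at the default width, then runs [build_network()] within
#' the block (max_rank = block_size).
#'
#' @param ranked A `ranked_edges` tibble.
#' @param block_index 1-based block number.
#' @param config A [network_build_config()].
#' @return A validated `tf_network`.
#' @export
select_block <- function(ranked, block_index, config = network_build_config()) {
  edges <- as_tibble(ranked)
  if (!"rank" %in% names(edges)) edges$rank <- seq_len(nrow(edges))
  lo <- (block_index - 1) * config$block_size
  hi <- block_index * config$block_size
  block <- edges[edges$rank > lo & edges$rank <= hi, , drop = FALSE]
  if (nrow(block) == 0)
    abort_input("block %d (ranks %d-%d) is empty", block_index, lo + 1, hi)
  block$rank <- seq_len(nrow(block))  # re-rank within the block
  cfg <- network_build_config(n_tfs = config$n_tfs,
                              max_rank = config$block_size,
                              block_size = config$block_size,
                              max_rounds = config$max_rounds)
  build_network(ranked_edges(block[, c("tf", "target", "score")]), cfg)
}

#' Merge signed networks into a union network
#'
#' Takes the union of all edges across the input networks; edges whose sign
#' constraint differs between inputs are dropped; then TFs left with a
#' single target are removed together with that target, repeatedly. The
#' identical-target-set rule is *not* re-applied here.
#'
#' @param nets List of `list(net = tf_network, signs = sign_constraints)`
#'   pairs.
#' @return `list(net, signs)` covering exactly the surviving edges.
#' @export
merge_networks <- function(nets) {
  if (length(nets) < 2) abort_input("merge_networks needs >= 2 networks")
  all_signs <- dplyr::bind_rows(lapply(nets, function(x) {
    as_tibble(x$signs)[, c("tf", "target", "sign")]
  }))
  merged <- all_signs |>
    dplyr::group_by(.data$tf, .data$target) |>
    dplyr::summarise(n_sign = dplyr::n_distinct(.data$sign),
                     sign = .data$sign[1], .groups = "drop") |>
    dplyr::filter(.data$n_sign == 1) |>
    dplyr::select("tf", "target", "sign")
  # iterated single-target removal (targets leave the network too)
  repeat {
    cnt <- table(merged$tf)
    singles <- names(cnt)[cnt == 1]
    if (length(singles) == 0) break
    lone_targets <- merged$target[merged$tf %in% singles]
    merged <- merged[!(merged$tf %in% singles) &
                       !(merged$target %in% lone_targets), , drop = FALSE]
  }
  net <- tf_network(merged[, c("tf", "target")], validate = FALSE)
  list(net = net, signs = sign_constraints(merged, net = net))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
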