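# Shared fixtures and independent oracles used across test files.

# A fixed 6-leaf tree whose first node spans leaves 1-6 under an
# MTG-style naming, mirroring the canonical worked example.
mtg_toy_tree <- function() {
  leaf <- function(i, lab) dend_node(paste0("l", i), original_label = lab)
  dend_node("root", list(
    dend_node("n_lamp5_pax6", list(
      dend_node("n_a", list(leaf(1, "Inh L1-2 PAX6 CDH12"),
                            leaf(2, "Inh L1 LAMP5 NMBR"))),
      dend_node("n_b", list(
        leaf(3, "Inh L1-4 LAMP5 LCP2"),
        dend_node("n_c", list(leaf(4, "Inh L1-2 LAMP5 DBP"),
                              dend_node("n_d", list(
                                leaf(5, "Inh L1-2 PAX6 TNFAIP8L3"),
                                leaf(6, "Inh L1 SST CHRNA4"))))))))),
    dend_node("n_rest", list(leaf(7, "Inh L2-4 VIP SPAG17"),
                             leaf(8, "Exc L2 LAMP5 LTK")))
  ))
}

mtg_toy_taxonomy <- function() {
  build_taxonomy(ccn_examples()$mtg_defaults, mtg_toy_tree())
}

# independent random tree generator (distinct code path from
# simulate_taxonomy): grows a multifurcating tree by repeatedly attaching
# leaves, then relabels leaves left-to-right
random_test_tree <- function(n_leaves, seed) {
  stopifnot(n_leaves >= 2)
  set.seed(seed)
  counter <- 0
  new_id <- function() {
    counter <<- counter + 1
    paste0("t", counter)
  }
  grow <- function(n) {
    if (n == 1) return(dend_node(new_id(), original_label = "x"))
    k <- if (n == 2) 2 else sample(2:min(3, n), 1)
    sizes <- as.vector(stats::rmultinom(1, n - k, rep(1, k))) + 1
    dend_node(new_id(), children = lapply(sizes, grow))
  }
  root <- grow(n_leaves)
  i <- 0
  relabel <- function(node) {
    if (length(node$children) == 0) {
      i <<- i + 1
      node$original_label <- sprintf("type %03d", i)
    } else {
      node$children <- lapply(node$children, relabel)
    }
    node
  }
  relabel(root)
}

# brute-force oracle: left-to-right leaf labels by plain recursion
oracle_leaf_labels <- function(node) {
  if (length(node$children) == 0) return(node$original_label)
  unlist(lapply(node$children, oracle_leaf_labels))
}

# brute-force oracle: per-node descendant leaf labels
oracle_descendants <- function(root) {
  out <- list()
  walk <- function(node) {
    out[[node$node_id]] <<- oracle_leaf_labels(node)
    for (ch in node$children) walk(ch)
  }
  walk(root)
  out
}

# run-length oracle: number of maximal consecutive runs in a sorted set
oracle_n_runs <- function(s) {
  s <- sort(unique(s))
  as.integer(sum(diff(s) != 1) + 1)
}

# connected components by boolean-matrix transitive closure
oracle_components <- function(nodes, edges) {
  A <- diag(TRUE, length(nodes))
  dimnames(A) <- list(nodes, nodes)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      A[edges[k, 1], edges[k, 2]] <- TRUE
      A[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  membership <- integer(length(nodes))
  names(membership) <- nodes
  comp <- 0
  for (v in nodes) {
    if (membership[v] == 0) {
      comp <- comp + 1
      membership[names(which(A[v, ]))] <- comp
    }
  }
  membership
}

sst_chodl_registry <- function() {
  read_cell_set_records(system.file("extdata", "sst_chodl_cell_sets.csv",
                                    package = "ccntax"))
}
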