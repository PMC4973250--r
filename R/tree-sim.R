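#' Simulate a duplication burst as a timed branching process
#'
#' Kinetic Monte Carlo simulation of the burst phase: starting from a single
#' active founder, every active element duplicates at rate `gamma`; waiting
#' times are drawn from an exponential with the aggregate rate
#' `gamma * (number of active elements)` and a uniformly random active element
#' is chosen to duplicate. A duplication is a binary node whose first child
#' continues the parent's identity (and keeps its active status) and whose
#' second child is the new copy, active with probability `delta`. The
#' simulation stops at the first event that brings the total element count to
#' `target_n`; all edge lengths are then rescaled by a common factor so the
#' root-to-last-event height equals `T1`, and every terminal edge is extended
#' by `T2`, so all leaves sit at depth `T1 + T2`.
#'
#' Because the founder always stays active, `target_n` is reachable for any
#' `delta` (with `delta = 0` the tree is a caterpillar: the master-gene
#' limit).
#'
#' @param params A [burst_params()] object.
#' @param target_n Number of present-day elements (leaves) to stop at.
#' @param seed Optional integer seed; identical `params`, `target_n` and
#'   `seed` give a byte-identical tree (and Newick export).
#' @return A `burst_tree` object: an ape-compatible edge matrix plus per-edge
#'   active flags, scaled node times and bookkeeping. Convert with
#'   [ape::as.phylo()] or export with [write_newick()].
#' @examples
#' tr <- simulate_burst(burst_params(gamma = 10, delta = 1, T1 = 0.5, T2 = 0.1),
#'                      target_n = 50, seed = 1)
#' tr
#' @export
simulate_burst <- function(params, target_n, seed = NULL) {
  stop_domain_if(!is.numeric(target_n) || length(target_n) != 1 || target_n < 1,
                 "`target_n` must be a single integer >= 1.")
  target_n <- as.integer(target_n)
  with_seed(seed, {
    sim <- burst_kmc(params$gamma, params$delta, target_n = target_n)
    finalize_burst_tree(sim, params, seed)
  })
}

# Core KMC loop. Each lineage is one edge of the final tree; a duplication
# replaces the chosen lineage with a continuation (same active status, which
# is always TRUE since only active lineages duplicate) and a new copy.
# Stops at the first event that makes the total element count `target_n`.
burst_kmc <- function(gamma, delta, target_n) {
  n_events_max <- target_n - 1L
  cap <- 100L * target_n
  n_lin_max <- 1L + 2L * n_events_max

  birth <- numeric(n_lin_max)        # per lineage: birth time
  active <- logical(n_lin_max)       # per lineage: active flag
  parent_ev <- integer(n_lin_max)    # event that created the lineage (0 root)
  split_ev <- integer(n_lin_max)     # event at which it split (0 = leaf)
  ev_time <- numeric(n_events_max)
  ev_cont <- integer(n_events_max)   # continuation-child lineage id
  ev_copy <- integer(n_events_max)   # new-copy lineage id
  ev_copy_active <- logical(n_events_max)

  active[1] <- TRUE
  n_lin <- 1L
  act_ids <- integer(n_lin_max)
  act_ids[1] <- 1L
  n_act <- 1L
  t <- 0
  e <- 0L

  while (e < n_events_max) {
    if (e >= cap) {
      stop_simulation(sprintf(
        "burst did not reach the target within %d events (gamma=%g, delta=%g).",
        cap, gamma, delta))
    }
    t <- t + stats::rexp(1) / (gamma * n_act)
    e <- e + 1L
    idx <- if (n_act == 1L) 1L else sample.int(n_act, 1L)
    lin <- act_ids[idx]
    split_ev[lin] <- e
    ev_time[e] <- t
    cont <- n_lin + 1L
    copy <- n_lin + 2L
    n_lin <- copy
    birth[cont] <- t; birth[copy] <- t
    parent_ev[cont] <- e; parent_ev[copy] <- e
    active[cont] <- TRUE
    copy_active <- stats::runif(1) < delta
    active[copy] <- copy_active
    ev_cont[e] <- cont; ev_copy[e] <- copy
    ev_copy_active[e] <- copy_active
    act_ids[idx] <- cont
    if (copy_active) {
      n_act <- n_act + 1L
      act_ids[n_act] <- copy
    }
  }

  list(
    n_events = e, t_last = if (e > 0L) ev_time[e] else 0, t_end = t,
    birth = birth[seq_len(n_lin)], active = active[seq_len(n_lin)],
    parent_ev = parent_ev[seq_len(n_lin)], split_ev = split_ev[seq_len(n_lin)],
    ev_time = ev_time[seq_len(e)], ev_cont = ev_cont[seq_len(e)],
    ev_copy = ev_copy[seq_len(e)], ev_copy_active = ev_copy_active[seq_len(e)],
    n_total = e + 1L, n_active = n_act
  )
}

# Turn a raw KMC record into an ape-style numbered tree rescaled to height
# T1 and with terminal edges extended by T2. Leaves are numbered 1..n in
# lineage-creation order; internal nodes n+1..2n-1 in event (time) order, so
# the root internal node is n+1.
finalize_burst_tree <- function(sim, params, seed = NULL) {
  n <- sim$n_events + 1L
  scale <- if (sim$n_events > 0L && sim$t_last > 0) params$T1 / sim$t_last else 1
  ev_time_scaled <- sim$ev_time * scale

  if (sim$n_events == 0L) {
    tree <- structure(list(
      edge = matrix(integer(0), 0, 2), edge.length = numeric(0),
      edge.active = logical(0), n_leaves = 1L, Nnode = 0L,
      node_time = numeric(0), copy_node = integer(0),
      copy_active = logical(0), leaf_active = TRUE,
      root_edge = params$T1 + params$T2, params = params, seed = seed,
      t_last_raw = 0, ev_time_raw = numeric(0)
    ), class = "burst_tree")
    return(tree)
  }

  is_leaf <- sim$split_ev == 0L
  leaf_no <- integer(length(is_leaf))
  leaf_no[is_leaf] <- seq_len(sum(is_leaf))
  node_of_lineage <- ifelse(is_leaf, leaf_no, n + sim$split_ev)

  # one edge per non-founder lineage; the founder edge becomes the root edge
  lin <- which(sim$parent_ev > 0L)
  parent_node <- n + sim$parent_ev[lin]
  child_node <- node_of_lineage[lin]
  start_t <- sim$birth[lin] * scale
  leaf_edge <- is_leaf[lin]
  end_t <- numeric(length(lin))
  end_t[leaf_edge] <- params$T1 + params$T2
  end_t[!leaf_edge] <- ev_time_scaled[sim$split_ev[lin[!leaf_edge]]]
  structure(list(
    edge = cbind(parent_node, child_node, deparse.level = 0),
    edge.length = end_t - start_t,
    edge.active = sim$active[lin],
    n_leaves = n, Nnode = sim$n_events,
    node_time = ev_time_scaled,                  # internal nodes, time order
    copy_node = node_of_lineage[sim$ev_copy],    # new-copy child per event
    copy_active = sim$ev_copy_active,
    leaf_active = sim$active[is_leaf][order(leaf_no[is_leaf])],
    root_edge = ev_time_scaled[1],
    params = params, seed = seed,
    t_last_raw = sim$t_last,
    ev_time_raw = sim$ev_time
  ), class = "burst_tree")
}

#' @export
print.burst_tree <- function(x, ...) {
  cat("<burst_tree>\n")
  cat(sprintf("  %d leaves (%d active), height T1 + T2 = %g + %g\n",
              x$n_leaves, sum(x$leaf_active), x$params$T1, x$params$T2))
  cat(sprintf("  gamma = %g, delta = %g; raw burst duration %g\n",
              x$params$gamma, x$params$delta, x$t_last_raw))
  invisible(x)
}

#' Element counts through time in a simulated burst
#'
#' @param tree A [simulate_burst()] tree.
#' @param t Times in `[0, T1 + T2]` (model units); vectorised. With
#'   `time_scale = "raw"`, times on the unscaled simulation clock (used to
#'   check the exponential growth rate before rescaling).
#' @param time_scale `"model"` (default, after rescaling to height `T1`) or
#'   `"raw"`.
#' @return A tibble with columns `t`, `total` and `active`. Both counts are
#'   non-decreasing in `t` and constant after `T1`.
#' @examples
#' tr <- simulate_burst(burst_params(gamma = 10, T1 = 1, T2 = 0.5),
#'                      target_n = 20, seed = 1)
#' counts_at_time(tr, c(0, 0.5, 1.5))
#' @export
counts_at_time <- function(tree, t, time_scale = c("model", "raw")) {
  time_scale <- match.arg(time_scale)
  if (time_scale == "model") {
    stop_domain_if(any(t < 0 | t > tree$params$T1 + tree$params$T2),
                   "`t` must lie in [0, T1 + T2].")
    times <- tree$node_time
  } else {
    stop_domain_if(any(t < 0), "`t` must be non-negative.")
    times <- tree$ev_time_raw
  }
  total <- 1L + vapply(t, function(ti) sum(times <= ti), integer(1))
  active <- 1L + vapply(t, function(ti) {
    sum(times <= ti & tree$copy_active)
  }, integer(1))
  tibble::tibble(t = t, total = total, active = active)
}

#' Present-day descendants of every duplication event
#'
#' For each duplication event, the number of leaves that descend from the
#' event's new copy. In a fully active burst (`delta = 1`) the tail of this
#' clone-size distribution is the Yule power law with exponent 2 — the
#' mutation-free, small-k limit of the abundance-tail exponent.
#'
#' @param tree A [simulate_burst()] tree.
#' @return A tibble with columns `node` (internal node id of the event) and
#'   `size` (leaf count of the new copy's subtree). One row per duplication
#'   event.
#' @examples
#' tr <- simulate_burst(burst_params(gamma = 10, T1 = 1, T2 = 0), 100, seed = 2)
#' subtree_sizes(tr)
#' @export
subtree_sizes <- function(tree) {
  n <- tree$n_leaves
  if (tree$Nnode == 0L) {
    return(tibble::tibble(node = integer(0), size = integer(0)))
  }
  counts <- leaf_counts(tree)
  tibble::tibble(node = n + seq_len(tree$Nnode),
                 size = counts[tree$copy_node])
}

# leaf count per node (leaves 1..n = 1). Internal nodes are numbered in
# event-time order, so every child has a larger number than its parent and a
# single reverse sweep over events suffices.
leaf_counts <- function(tree) {
  n <- tree$n_leaves
  counts <- c(rep(1L, n), integer(tree$Nnode))
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  ord <- order(parent, decreasing = TRUE)
  for (i in ord) {
    counts[parent[i]] <- counts[parent[i]] + counts[child[i]]
  }
  counts
}

#' Ensemble of burst sizes at a fixed (unscaled) time
#'
#' Runs the burst KMC to a fixed stopping time instead of a target element
#' count, recording the total and active element counts. The ensemble mean of
#' `total` is the Monte-Carlo counterpart of [expected_copies()].
#'
#' @param params A [burst_params()] object.
#' @param t_stop Stopping time on the raw simulation clock (units `1/mu0`).
#' @param n_rep Number of independent replicates.
#' @param seed Optional integer seed.
#' @param max_events Safety cap on events per replicate.
#' @return A tibble with columns `rep`, `total`, `active`.
#' @examples
#' sample_burst_counts(burst_params(gamma = 10, delta = 0.5), 0.25, 100, seed = 1)
#' @export
sample_burst_counts <- function(params, t_stop, n_rep, seed = NULL,
                                max_events = 1e6) {
  stop_domain_if(t_stop < 0, "`t_stop` must be non-negative.")
  with_seed(seed, {
    gamma <- params$gamma
    delta <- params$delta
    one_rep <- function(i) {
      t <- 0
      n_tot <- 1L
      n_act <- 1L
      repeat {
        t <- t + stats::rexp(1) / (gamma * n_act)
        if (t > t_stop) break
        if (n_tot >= max_events) {
          stop_simulation("burst exceeded `max_events` before `t_stop`.")
        }
        n_tot <- n_tot + 1L
        if (stats::runif(1) < delta) n_act <- n_act + 1L
      }
      c(n_tot, n_act)
    }
    m <- vapply(seq_len(n_rep), one_rep, numeric(2))
    tibble::tibble(rep = seq_len(n_rep), total = as.integer(m[1, ]),
                   active = as.integer(m[2, ]))
  })
}

#' Convert a burst tree to an ape "phylo" object
#'
#' Leaves are labelled `L1..Ln`; internal nodes carry no labels. The
#' founder's pre-first-duplication time is kept as the `root.edge`.
#'
#' @param x A `burst_tree`.
#' @param ... Unused.
#' @return An [ape::as.phylo] tree.
#' @export
#' @method as.phylo burst_tree
as.phylo.burst_tree <- function(x, ...) {
  if (x$Nnode == 0L) {
    # single-leaf degenerate tree: represent as a root edge only
    stop_domain("a single-element tree has no internal node; ape cannot represent it.")
  }
  structure(list(
    edge = x$edge, edge.length = x$edge.length,
    tip.label = paste0("L", seq_len(x$n_leaves)),
    Nnode = x$Nnode, root.edge = x$root_edge
  ), class = "phylo", order = "cladewise")
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Write a burst tree in Newick format with active-state comments
#'
#' The active flag of every edge is emitted as a comment in bracket syntax
#' immediately after the child node's label, e.g. `L3[&active=1]:0.012`.
#' Branch lengths are in model units (`1/mu0`). The founder's root edge is
#' written as a trailing length on the root node.
#'
#' @param tree A `burst_tree`.
#' @param path Optional file path; with `NULL` the Newick string is returned.
#' @param comments Emit `[&active=0/1]` comments (default TRUE).
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to `path`.
#' @examples
#' tr <- simulate_burst(burst_params(gamma = 5, T1 = 1, T2 = 0.2), 4, seed = 1)
#' cat(write_newick(tr))
#' @export
write_newick <- function(tree, path = NULL, comments = TRUE, digits = 10) {
  n <- tree$n_leaves
  fmt_len <- function(l) sprintf(paste0("%.", digits, "g"), l)
  flag <- function(a) if (comments) sprintf("[&active=%d]", as.integer(a)) else ""
  if (tree$Nnode == 0L) {
    s <- paste0("L1", flag(tree$leaf_active),
                ":", fmt_len(tree$root_edge), ";")
  } else {
    # children of each internal node, copy child second for determinism
    kids <- vector("list", n + tree$Nnode)
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]
      kids[[p]] <- c(kids[[p]], i)
    }
    elen <- tree$edge.length
    eact <- tree$edge.active
    child <- tree$edge[, 2]
    tokens <- character(0)
    buf <- character(6L * (n + tree$Nnode))
    nb <- 0L
    emit <- function(s) {
      nb <<- nb + 1L
      buf[nb] <<- s
    }
    # iterative DFS; stack of (edge index into tree$edge, state)
    # virtual root frame handled separately
    root <- n + 1L
    stack_node <- integer(2L * n)
    stack_edge <- integer(2L * n)
    stack_state <- integer(2L * n)
    top <- 1L
    stack_node[1] <- root; stack_edge[1] <- 0L; stack_state[1] <- 0L
    while (top > 0L) {
      v <- stack_node[top]; st <- stack_state[top]; ei <- stack_edge[top]
      if (v <= n) { # leaf
        emit(paste0("L", v, flag(eact[ei]), ":", fmt_len(elen[ei])))
        top <- top - 1L
      } else if (st == 0L) {
        emit("(")
        stack_state[top] <- 1L
        k <- kids[[v]][1]
        top <- top + 1L
        stack_node[top] <- child[k]; stack_edge[top] <- k; stack_state[top] <- 0L
      } else if (st == 1L) {
        emit(",")
        stack_state[top] <- 2L
        k <- kids[[v]][2]
        top <- top + 1L
        stack_node[top] <- child[k]; stack_edge[top] <- k; stack_state[top] <- 0L
      } else {
        if (ei == 0L) { # root: annotate with founder edge length
          emit(paste0(")", if (comments) "[&active=1]" else "",
                      ":", fmt_len(tree$root_edge)))
        } else {
          emit(paste0(")", flag(eact[ei]), ":", fmt_len(elen[ei])))
        }
        top <- top - 1L
      }
    }
    s <- paste0(paste(buf[seq_len(nb)], collapse = ""), ";")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
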