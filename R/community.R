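#' Signed modularity of a partition
#'
#' Modularity extended to networks with attractive and repulsive edges:
#' within-module excess positive weight is rewarded and within-module excess
#' negative weight penalized, each sign layer against its own
#' strength-preserving null model,
#' \deqn{Q = \frac{1}{2(v^+ + v^-)} \sum_{ij}
#'   \left[(w^+_{ij} - e^+_{ij}) - (w^-_{ij} - e^-_{ij})\right]
#'   \delta_{M_i M_j},}
#' summing over ordered pairs, with \eqn{e^\pm_{ij} = s^\pm_i s^\pm_j / (2
#' v^\pm)} and \eqn{v^\pm} the total (undirected) weight per layer. On a
#' purely positive network this reduces exactly to Newman-Girvan modularity;
#' placing all nodes in one module always gives Q = 0.
#'
#' @param net A `coop_network`, or a symmetric signed adjacency matrix.
#' @param partition A `coop_partition`, a tibble with columns `token` and
#'   `module`, or a bare membership vector aligned with the nodes.
#' @return Scalar Q in `[-1, 1]`.
#' @export
signed_modularity <- function(net, partition) {
  if (inherits(net, "coop_network")) {
    W <- as_adjacency(net)
  } else {
    W <- as.matrix(net)
    stopifnot(nrow(W) == ncol(W))
  }
  if (nrow(W) == 0) {
    abort("Modularity is undefined for an empty network.", class = "coop_degenerate_error")
  }
  comm <- membership_vector(partition, rownames(W))
  modularity_signed_matrix(pmax(W, 0), pmax(-W, 0), comm)
}

# resolve the various partition representations into an integer vector aligned
# with `tokens` (or, for a bare vector, checked for length)
membership_vector <- function(partition, tokens) {
  if (inherits(partition, "coop_partition") || is.data.frame(partition)) {
    p <- as_tibble(partition)
    stopifnot(all(c("token", "module") %in% names(p)))
    if (!is.null(tokens)) {
      idx <- match(tokens, p$token)
      if (anyNA(idx)) {
        abort("Partition does not cover all network nodes.", class = "coop_consistency_error")
      }
      return(as.integer(p$module[idx]))
    }
    return(as.integer(p$module))
  }
  comm <- as.integer(partition)
  if (!is.null(tokens) && length(comm) != length(tokens)) {
    abort("Membership vector length does not match the node count.",
          class = "coop_consistency_error")
  }
  if (anyNA(comm)) abort("Membership contains NA.", class = "coop_consistency_error")
  comm
}

# Q from split layers; Wp/Wn may carry aggregated self-loops on the diagonal
# (diagonal = full ordered within-weight). 2*vp == sum(Wp) by construction.
modularity_signed_matrix <- function(Wp, Wn, comm) {
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  two_vp <- sum(sp)
  two_vn <- sum(sn)
  tot <- two_vp + two_vn
  if (tot == 0) {
    return(0)
  }
  q <- 0
  for (c in unique(comm)) {
    idx <- comm == c
    q <- q +
      (sum(Wp[idx, idx]) - if (two_vp > 0) sum(sp[idx])^2 / two_vp else 0) -
      (sum(Wn[idx, idx]) - if (two_vn > 0) sum(sn[idx])^2 / two_vn else 0)
  }
  q / tot
}

# one Louvain level: greedy local moves on the (possibly aggregated) graph.
# Wp/Wn symmetric, diagonals = self-loop ordered weight. Returns the local
# membership (1..n ids, not contiguous) and whether anything moved.
louvain_local_moves <- function(Wp, Wn, tol = 1e-12) {
  n <- nrow(Wp)
  comm <- seq_len(n)
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  two_vp <- sum(sp)
  two_vn <- sum(sn)
  Sp <- sp
  Sn <- sn
  csize <- rep(1L, n)
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      # strength of i towards every community
      kp <- bucket_sum(Wp[, i], comm, n)
      kn <- bucket_sum(Wn[, i], comm, n)
      kp[ci] <- kp[ci] - Wp[i, i]
      kn[ci] <- kn[ci] - Wn[i, i]
      Sp[ci] <- Sp[ci] - sp[i]
      Sn[ci] <- Sn[ci] - sn[i]
      csize[ci] <- csize[ci] - 1L
      gain <- kp - (if (two_vp > 0) sp[i] * Sp / two_vp else 0) -
        kn + (if (two_vn > 0) sn[i] * Sn / two_vn else 0)
      # candidates: every populated community, plus splitting off into the
      # lowest-numbered empty slot (gain 0 by definition)
      gain_stay <- if (csize[ci] > 0L) gain[ci] else 0
      cand <- which(csize > 0L)
      cand_gain <- gain[cand]
      empty_id <- if (csize[ci] == 0L) ci else which(csize == 0L)[1]
      cand <- c(cand, empty_id)
      cand_gain <- c(cand_gain, 0)
      mx <- max(cand_gain)
      if (mx > gain_stay + tol) {
        # deterministic tie-break: lowest module id among maximal gains
        target <- min(cand[cand_gain >= mx - tol])
      } else {
        target <- ci
      }
      comm[i] <- target
      Sp[target] <- Sp[target] + sp[i]
      Sn[target] <- Sn[target] + sn[i]
      csize[target] <- csize[target] + 1L
      if (target != ci) {
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}

bucket_sum <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg
  out
}

# collapse a sign layer by community (ordered-pair convention: aggregated
# diagonal = 2 * internal weight + old self-loops)
aggregate_layer <- function(W, f, k) {
  B <- matrix(0, nrow(W), k)
  B[cbind(seq_along(f), f)] <- 1
  crossprod(B, W %*% B)
}

#' Louvain optimization of signed modularity
#'
#' Greedy two-phase heuristic: nodes are repeatedly moved to the neighboring
#' module with the highest signed-modularity gain (ties to the lowest module
#' id; node visiting order is shuffled from `seed`), then modules are
#' aggregated into super-nodes and the process repeats. The modularity of the
#' induced partition on the original network is recorded after every phase and
#' never decreases.
#'
#' @param net A `coop_network` (or signed adjacency matrix).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return A `coop_partition`: tibble `token`, `module` (module ids contiguous
#'   in order of appearance) with attributes `modularity`, `phase_modularity`
#'   and `seed`.
#' @export
louvain_signed <- function(net, seed = 1L) {
  if (inherits(net, "coop_network")) {
    W <- as_adjacency(net)
  } else {
    W <- as.matrix(net)
  }
  n <- nrow(W)
  if (n < 1) abort("Network has no nodes.", class = "coop_degenerate_error")
  tokens <- rownames(W) %||% paste0("v", seq_len(n))
  withr::with_seed(seed, {
    Wp <- pmax(W, 0)
    Wn <- pmax(-W, 0)
    membership <- seq_len(n)
    phase_q <- numeric()
    Wp_cur <- Wp
    Wn_cur <- Wn
    repeat {
      res <- louvain_local_moves(Wp_cur, Wn_cur)
      ids <- sort(unique(res$comm))
      f <- match(res$comm, ids)
      membership <- f[membership]
      phase_q <- c(phase_q, modularity_signed_matrix(Wp, Wn, membership))
      if (!res$moved || length(ids) == nrow(Wp_cur)) break
      Wp_cur <- aggregate_layer(Wp_cur, f, length(ids))
      Wn_cur <- aggregate_layer(Wn_cur, f, length(ids))
    }
    new_partition(tokens, membership,
                  modularity = phase_q[length(phase_q)],
                  phase_modularity = phase_q, seed = seed)
  })
}

new_partition <- function(tokens, membership, modularity = NA_real_,
                          phase_modularity = NULL, seed = NULL) {
  membership <- match(membership, unique(membership)) # contiguous, stable order
  out <- tibble(token = tokens, module = as.integer(membership))
  class(out) <- c("coop_partition", class(out))
  attr(out, "modularity") <- modularity
  attr(out, "phase_modularity") <- phase_modularity
  attr(out, "seed") <- seed
  out
}

#' Number of modules of a partition
#' @param partition A `coop_partition` (or token/module tibble).
#' @return Integer count.
#' @export
n_modules <- function(partition) {
  length(unique(as_tibble(partition)$module))
}

#' Consensus clustering of repeated Louvain runs
#'
#' Runs [louvain_signed()] `runs` times with distinct sub-seeds and records,
#' for every node pair, the fraction of runs placing the pair in a common
#' module (the co-classification matrix). Entries below `threshold` are set to
#' zero and the resulting consensus graph is re-clustered the same way,
#' iterating until every run returns the same partition (the co-classification
#' matrix is block diagonal) or `max_iter` is reached, in which case the
#' result is flagged unconverged and the best-modularity partition of the last
#' iteration is reported.
#'
#' @param net A `coop_network` (or signed adjacency matrix).
#' @param runs Number of Louvain restarts per iteration (>= 2). Default 100.
#' @param threshold Co-classification fraction below which pairs are
#'   disconnected; strictly between 0 and 1. Pairs at or above the threshold
#'   are kept ("at least" is inclusive). Default 0.4.
#' @param seed Integer seed for the whole procedure.
#' @param max_iter Iteration cap. Default 20.
#' @return A `coop_consensus`: list with `co_classification` (the first-pass
#'   node-by-node fraction matrix), `final_partition`, `runs`, `threshold`,
#'   `iterations`, `converged` and `modularity` (of the final partition on the
#'   original network).
#' @export
consensus_cluster <- function(net, runs = 100, threshold = 0.4, seed = 1L,
                              max_iter = 20) {
  stopifnot(runs >= 2, threshold > 0, threshold < 1, max_iter >= 1)
  if (inherits(net, "coop_network")) {
    W0 <- as_adjacency(net)
  } else {
    W0 <- as.matrix(net)
  }
  n <- nrow(W0)
  tokens <- rownames(W0) %||% paste0("v", seq_len(n))
  subseeds <- withr::with_seed(seed, matrix(
    sample.int(2147483646L, runs * max_iter), nrow = runs
  ))

  W <- W0
  co1 <- NULL
  converged <- FALSE
  final <- NULL
  for (iter in seq_len(max_iter)) {
    members <- lapply(seq_len(runs), function(r) {
      membership_vector(louvain_signed(W, seed = subseeds[r, iter]), tokens)
    })
    canon <- lapply(members, function(m) match(m, unique(m)))
    D <- matrix(0, n, n)
    for (m in members) D <- D + outer(m, m, "==")
    D <- D / runs
    dimnames(D) <- list(tokens, tokens)
    if (is.null(co1)) co1 <- D
    if (all(vapply(canon[-1], identical, logical(1), canon[[1]]))) {
      converged <- TRUE
      final <- canon[[1]]
      break
    }
    if (iter == max_iter) {
      qs <- vapply(members, function(m) {
        modularity_signed_matrix(pmax(W0, 0), pmax(-W0, 0), m)
      }, numeric(1))
      final <- canon[[which.max(qs)]]
      break
    }
    W <- D
    W[W < threshold] <- 0
    diag(W) <- 0
  }
  partition <- new_partition(tokens, final,
                             modularity = modularity_signed_matrix(
                               pmax(W0, 0), pmax(-W0, 0), final
                             ),
                             seed = seed)
  structure(
    list(
      co_classification = co1,
      final_partition = partition,
      runs = as.integer(runs),
      threshold = threshold,
      iterations = iter,
      converged = converged,
      modularity = attr(partition, "modularity")
    ),
    class = "coop_consensus"
  )
}

#' @export
print.coop_consensus <- function(x, ...) {
  cat("<coop_consensus>\n")
  cat("  runs:      ", x$runs, "per iteration\n")
  cat("  threshold: ", x$threshold, "\n")
  cat(sprintf(
    "  %s after %d iteration(s)\n",
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  cat("  modules:   ", n_modules(x$final_partition), "\n")
  cat("  modularity:", format(x$modularity, digits = 4), "\n")
  invisible(x)
}

#' @export
print.coop_partition <- function(x, ...) {
  cat("<coop_partition> ", nrow(x), " nodes in ", n_modules(x), " modules",
      sep = "")
  q <- attr(x, "modularity")
  if (!is.null(q) && !is.na(q)) cat(", Q = ", format(q, digits = 4), sep = "")
  cat("\n")
  NextMethod()
}
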