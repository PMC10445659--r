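# Hierarchical density-based clustering (HDBSCAN) over a feature matrix or
# distance matrix: mutual-reachability distances, minimum spanning tree,
# condensed cluster tree and excess-of-mass cluster selection, with noise
# reported as label -1. Written in-package; kept deliberately compact.

#' Density-based clustering with noise (HDBSCAN)
#'
#' @param x numeric matrix/data.frame of observations, or a `dist`.
#' @param min_samples neighbourhood size for the core distance (the
#'   `min_samples`-th nearest neighbour including the point itself).
#' @param min_cluster_size smallest cluster retained in the condensed tree.
#' @param allow_single_cluster if no valid split exists below the root,
#'   label everything one cluster instead of noise (default TRUE, which
#'   makes degenerate inputs such as duplicated rows come back as a single
#'   cluster).
#' @return list `labels` (integer, -1 = noise), `n_clusters`,
#'   `stabilities`.
#' @export
hdbscan_fit <- function(x, min_samples = 3, min_cluster_size = 10,
                        allow_single_cluster = TRUE) {
  d <- if (inherits(x, "dist")) as.matrix(x) else
    as.matrix(stats::dist(as.matrix(x)))
  n <- nrow(d)
  if (n < min_cluster_size) stop("fewer observations than min_cluster_size")
  # core distance: k-th smallest including self (self distance 0)
  core <- apply(d, 1, function(r) sort(r, partial = min_samples)[min_samples])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0
  # zero weights would read as absent edges in the adjacency representation
  mreach[mreach == 0] <- 1e-300
  diag(mreach) <- 0
  # MST of the mutual-reachability graph
  g <- igraph::graph_from_adjacency_matrix(mreach, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mst, names = FALSE)
  w <- igraph::E(mst)$weight
  ord <- order(w)
  el <- el[ord, , drop = FALSE]; w <- w[ord]

  # single-linkage merge tree via union-find; node ids: 1..n leaves,
  # n+1 .. 2n-1 internal merges
  parent_uf <- seq_len(2L * n - 1L)
  uf_find <- function(i) {
    while (parent_uf[i] != i) {
      parent_uf[i] <<- parent_uf[parent_uf[i]]
      i <- parent_uf[i]
    }
    i
  }
  child_l <- integer(n - 1L); child_r <- integer(n - 1L)
  height <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    a <- uf_find(el[k, 1]); b <- uf_find(el[k, 2])
    node <- n + k
    child_l[k] <- a; child_r[k] <- b
    height[k] <- w[k]
    parent_uf[a] <- node; parent_uf[b] <- node
  }

  # size of each merge-tree node
  sizes <- c(rep(1L, n), integer(n - 1L))
  for (k in seq_len(n - 1L)) {
    sizes[n + k] <- sizes[child_l[k]] + sizes[child_r[k]]
  }

  # condense: walk from the root, creating condensed clusters only at splits
  # where both children reach min_cluster_size
  eps <- 1e-12
  lam <- function(h) 1 / max(h, eps)
  n_cond <- 0L
  cond_parent <- integer(0)   # condensed parent of each condensed cluster
  birth <- numeric(0)         # lambda at which the cluster appears
  stability <- numeric(0)
  pt_cluster <- integer(n)    # condensed cluster each point fell out of
  pt_lambda <- numeric(n)     # lambda at fall-out
  new_cluster <- function(par, l) {
    n_cond <<- n_cond + 1L
    cond_parent[n_cond] <<- par
    birth[n_cond] <<- l
    stability[n_cond] <<- 0
    n_cond
  }
  leaves_of <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v) else {
        k <- v - n
        stack <- c(stack, child_l[k], child_r[k])
      }
    }
    out
  }
  root_cl <- new_cluster(0L, lam(height[n - 1L]))
  # iterative walk: stack of (merge-node, condensed cluster)
  stack_node <- 2L * n - 1L
  stack_cl <- root_cl
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    if (v <= n) {
      pt_cluster[v] <- cl
      pt_lambda[v] <- Inf  # singleton persists to infinite density
      next
    }
    k <- v - n
    l_here <- lam(height[k])
    s_l <- sizes[child_l[k]]; s_r <- sizes[child_r[k]]
    big_l <- s_l >= min_cluster_size; big_r <- s_r >= min_cluster_size
    if (big_l && big_r) {
      # true split: cluster cl dies here; children are born
      stability[cl] <- stability[cl] +
        (s_l + s_r) * (min(l_here, 1 / eps) - birth[cl])
      cl_l <- new_cluster(cl, l_here)
      cl_r <- new_cluster(cl, l_here)
      stack_node <- c(stack_node, child_l[k], child_r[k])
      stack_cl <- c(stack_cl, cl_l, cl_r)
    } else if (big_l || big_r) {
      # the small side falls out of cl as noise at this lambda
      small <- if (big_l) child_r[k] else child_l[k]
      big <- if (big_l) child_l[k] else child_r[k]
      for (p in leaves_of(small)) {
        pt_cluster[p] <- cl
        pt_lambda[p] <- l_here
        stability[cl] <- stability[cl] + (min(l_here, 1 / eps) - birth[cl])
      }
      stack_node <- c(stack_node, big)
      stack_cl <- c(stack_cl, cl)
    } else {
      # whole subtree falls out
      for (p in leaves_of(v)) {
        pt_cluster[p] <- cl
        pt_lambda[p] <- l_here
        stability[cl] <- stability[cl] + (min(l_here, 1 / eps) - birth[cl])
      }
    }
  }

  # excess-of-mass selection (root excluded unless it is the only cluster)
  children_of <- split(seq_len(n_cond), cond_parent[seq_len(n_cond)])
  selected <- logical(n_cond)
  subtree_stab <- numeric(n_cond)
  for (cl in rev(seq_len(n_cond))) {  # children have larger ids than parents
    kids <- children_of[[as.character(cl)]]
    if (is.null(kids) || !length(kids)) {
      subtree_stab[cl] <- stability[cl]
      selected[cl] <- TRUE
    } else {
      kid_sum <- sum(subtree_stab[kids])
      if (cl == root_cl || kid_sum >= stability[cl]) {
        subtree_stab[cl] <- kid_sum
      } else {
        subtree_stab[cl] <- stability[cl]
        selected[cl] <- TRUE
        # unselect all descendants
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(children_of[as.character(desc)], use.names = FALSE)
        }
      }
    }
  }
  if (!any(selected) || (sum(selected) == 1 && selected[root_cl] &&
                         !allow_single_cluster && n_cond > 1)) {
    selected[] <- FALSE
  }
  if (!any(selected) && allow_single_cluster) selected[root_cl] <- TRUE

  # labelling: walk from each point's fall-out cluster up to a selected one
  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  lab_of <- integer(n_cond)
  lab_of[sel_ids] <- seq_along(sel_ids)
  for (p in seq_len(n)) {
    cl <- pt_cluster[p]
    while (cl != 0L && !selected[cl]) cl <- cond_parent[cl]
    if (cl != 0L) labels[p] <- lab_of[cl]
  }
  list(labels = labels, n_clusters = length(sel_ids),
       stabilities = stability[sel_ids])
}
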