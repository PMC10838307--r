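# Classification and regression tree (CART) engine: Gini-impurity binary
# trees, weakest-link cost-complexity pruning, and bagged forests with
# per-split feature sampling. Written against base R because no tree
# package is assumed at run time.
#
# Split determinism: features are scanned in column order and a candidate
# split replaces the incumbent only on a strictly larger impurity decrease,
# so ties resolve to the lowest feature index, then the lowest threshold.
# Rows with x <= threshold go left.

# Grow a tree on a numeric matrix X and binary labels y (0/1).
# Nodes are nested lists: leaf(n, n1, prob, pred) or
# split(var, val, left, right, n, n1).
grow_cart <- function(X, y, min_split = 20L, min_bucket = 7L,
                      max_depth = 30L, mtry = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0L, 1L)))
  grow_node(X, y, seq_len(nrow(X)), 0L, min_split, min_bucket, max_depth, mtry)
}

node_leaf <- function(y_idx_count, n1) {
  n <- y_idx_count
  prob <- if (n > 0) n1 / n else 0
  list(leaf = TRUE, n = n, n1 = n1, prob = prob,
       pred = as.integer(prob > 0.5)) # majority; exact tie -> class 0
}

grow_node <- function(X, y, idx, depth, min_split, min_bucket, max_depth,
                      mtry) {
  n <- length(idx)
  n1 <- sum(y[idx])
  if (n < min_split || n1 == 0L || n1 == n || depth >= max_depth) {
    return(node_leaf(n, n1))
  }
  p <- ncol(X)
  cand <- if (is.null(mtry) || mtry >= p) seq_len(p) else
    sort(sample.int(p, mtry))
  gini_parent <- 2 * (n1 / n) * (1 - n1 / n)
  best <- list(gain = 0, var = NA_integer_, val = NA_real_)
  for (j in cand) {
    x <- X[idx, j]
    o <- order(x, method = "radix")
    xs <- x[o]; ys <- y[idx][o]
    # candidate cut after position i (1..n-1) where value changes
    cum1 <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L] & i >= min_bucket & (n - i) >= min_bucket
    if (!any(valid)) next
    nl <- i[valid]; nl1 <- cum1[i][valid]
    nr <- n - nl; nr1 <- n1 - nl1
    gl <- 2 * (nl1 / nl) * (1 - nl1 / nl)
    gr <- 2 * (nr1 / nr) * (1 - nr1 / nr)
    gain <- gini_parent - (nl * gl + nr * gr) / n
    k <- which.max(gain) # first maximum -> lowest threshold
    if (gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], var = j,
                   val = (xs[nl[k]] + xs[nl[k] + 1L]) / 2)
    }
  }
  if (is.na(best$var)) return(node_leaf(n, n1))
  go_left <- X[idx, best$var] <= best$val
  list(leaf = FALSE, var = best$var, val = best$val, n = n, n1 = n1,
       left = grow_node(X, y, idx[go_left], depth + 1L, min_split,
                        min_bucket, max_depth, mtry),
       right = grow_node(X, y, idx[!go_left], depth + 1L, min_split,
                         min_bucket, max_depth, mtry))
}

# per-row class-1 probability (leaf class-1 fraction)
predict_cart <- function(node, X, out = NULL, idx = NULL) {
  if (is.null(out)) {
    out <- numeric(nrow(X))
    idx <- seq_len(nrow(X))
  }
  if (length(idx) == 0L) return(out)
  if (isTRUE(node$leaf)) {
    out[idx] <- node$prob
    return(out)
  }
  go_left <- X[idx, node$var] <= node$val
  out <- predict_cart(node$left, X, out, idx[go_left])
  predict_cart(node$right, X, out, idx[!go_left])
}

cart_n_leaves <- function(node) {
  if (isTRUE(node$leaf)) 1L else
    cart_n_leaves(node$left) + cart_n_leaves(node$right)
}

cart_depth <- function(node) {
  if (isTRUE(node$leaf)) 0L else
    1L + max(cart_depth(node$left), cart_depth(node$right))
}

# node training misclassification mass (count of errors if collapsed)
node_risk <- function(node) min(node$n1, node$n - node$n1)

subtree_risk <- function(node) {
  if (isTRUE(node$leaf)) node_risk(node) else
    subtree_risk(node$left) + subtree_risk(node$right)
}

# weakest link: minimum over internal nodes of
# g(t) = (R(t) - R(T_t)) / (leaves(T_t) - 1), risks as error counts
min_g <- function(node) {
  if (isTRUE(node$leaf)) return(Inf)
  g_here <- (node_risk(node) - subtree_risk(node)) /
    (cart_n_leaves(node) - 1L)
  min(g_here, min_g(node$left), min_g(node$right))
}

prune_at_g <- function(node, g) {
  if (isTRUE(node$leaf)) return(node)
  g_here <- (node_risk(node) - subtree_risk(node)) /
    (cart_n_leaves(node) - 1L)
  if (g_here <= g + 1e-12) return(node_leaf(node$n, node$n1))
  node$left <- prune_at_g(node$left, g)
  node$right <- prune_at_g(node$right, g)
  # collapsing children can change this node's g; re-check
  if (!isTRUE(node$left$leaf) || !isTRUE(node$right$leaf)) return(node)
  g_new <- (node_risk(node) - subtree_risk(node)) / (cart_n_leaves(node) - 1L)
  if (g_new <= g + 1e-12) node_leaf(node$n, node$n1) else node
}

# nested cost-complexity sequence: list of list(alpha=, tree=), from the
# full tree (alpha 0) up to the root leaf. Alphas are error counts
# normalised by the training size (misclassification rate units).
cart_ccp_sequence <- function(tree, n_total) {
  seqs <- list(list(alpha = 0, tree = tree))
  current <- tree
  while (!isTRUE(current$leaf)) {
    g <- min_g(current)
    current <- prune_at_g(current, g)
    seqs[[length(seqs) + 1L]] <- list(alpha = g / n_total, tree = current)
  }
  seqs
}
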