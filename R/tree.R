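## Minimal CART decision tree (binary classification, continuous features,
## Gini impurity, unlimited depth by default). Implemented here because no
## tree package ships with this R stack; the tree is the base learner of
## the bagged detector and its behaviour (tie-breaks, determinism) is part
## of the detector's contract.

# best Gini split of one feature column; returns NULL when no valid split
best_split_feature <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(y)
  cut_ok <- which(diff(xs) > 0)          # split between distinct values only
  if (!length(cut_ok)) return(NULL)
  n1 <- cumsum(ys)                        # positives in left block 1..i
  i <- cut_ok
  nl <- i; nr <- n - i
  pl <- n1[i] / nl; pr <- (n1[n] - n1[i]) / nr
  imp <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
  b <- which.min(imp)
  list(threshold = (xs[i[b]] + xs[i[b] + 1L]) / 2, impurity = imp[b])
}

# grow a CART tree; nodes stored row-wise in a matrix for fast prediction:
# columns feature, threshold, left, right, pred (leaf: feature = 0)
fit_tree <- function(X, y, max_depth = Inf, min_split = 2L) {
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- numeric(5L)          # reserve slot
    ypos <- sum(y[idx])
    # majority prediction; tie favours the negative class (NS)
    pred <- as.numeric(ypos > length(idx) / 2)
    leaf <- c(feature = 0, threshold = 0, left = 0, right = 0, pred = pred)
    if (ypos == 0L || ypos == length(idx) || depth >= max_depth ||
        length(idx) < min_split) {
      nodes[[id]] <<- leaf
      return(id)
    }
    best <- NULL; best_j <- 0L
    for (j in seq_len(ncol(X))) {
      s <- best_split_feature(X[idx, j], y[idx])
      if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
        best <- s; best_j <- j
      }
    }
    if (is.null(best)) {
      nodes[[id]] <<- leaf
      return(id)
    }
    go_left <- X[idx, best_j] <= best$threshold
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes[[id]] <<- c(feature = best_j, threshold = best$threshold,
                      left = left, right = right, pred = pred)
    id
  }
  grow(seq_len(nrow(X)), 0L)
  do.call(rbind, nodes)
}

predict_tree <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(r) {
    id <- 1L
    repeat {
      node <- tree[id, ]
      if (node["feature"] == 0) return(node[["pred"]])
      id <- if (X[r, node["feature"]] <= node["threshold"])
        node[["left"]] else node[["right"]]
    }
  }, numeric(1))
}
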