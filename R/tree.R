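# CART regression trees with cost-complexity pruning and the
# one-standard-error rule, used to detect threshold structure (e.g. a
# soil-N value above which the NPK response on leaf Si disappears).

## Best single split of (X, y): exhaustive over every predictor and every
## midpoint between adjacent distinct sorted values. Ties broken by
## lowest predictor index, then smallest threshold (the first maximum in
## ascending threshold order within a predictor).
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  if (n < 2 * min_leaf) return(NULL)
  tot <- sum(y)
  sse_parent <- sum(y^2) - tot^2 / n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j], method = "radix")
    xs <- X[ord, j]; ys <- y[ord]
    cs <- cumsum(ys)
    i <- seq_len(n - 1L)
    valid <- i >= min_leaf & (n - i) >= min_leaf &
      xs[i] < xs[i + 1L]
    if (!any(valid)) next
    score <- cs[i]^2 / i + (tot - cs[i])^2 / (n - i)
    score[!valid] <- -Inf
    k <- which.max(score)
    red <- score[k] - tot^2 / n
    if (is.null(best) || red > best$sse_reduction + 1e-12) {
      best <- list(var = j, threshold = (xs[k] + xs[k + 1L]) / 2,
                   sse_reduction = red,
                   left = ord[seq_len(k)], right = ord[(k + 1L):n])
    }
  }
  if (!is.null(best) && best$sse_reduction <= 1e-12) return(NULL)
  best
}

#' Grow a CART regression tree
#'
#' Greedy binary recursive partitioning minimising pooled within-node
#' SSE. Split thresholds sit at the midpoint between adjacent sorted
#' predictor values. Splitting stops when a node is smaller than
#' `2 * min_leaf`, when no split reduces SSE, or when the relative SSE
#' improvement (scaled by the root SSE, the rpart `cp` convention) falls
#' below `cp_min`. A constant response yields a single-node tree.
#'
#' @param x data.frame or matrix of numeric predictors.
#' @param y numeric response.
#' @param min_leaf minimum observations per leaf.
#' @param cp_min complexity threshold for growing.
#' @param site optional site labels used to stratify cross-validation
#'   folds in [prune_one_se()].
#' @return an object of class `si_tree`.
#' @examples
#' x <- data.frame(soil_n = runif(60))
#' y <- ifelse(x$soil_n < 0.43, 5, 1) + rnorm(60, 0, 0.1)
#' grow_tree(x, y, min_leaf = 5)
#' @export
grow_tree <- function(x, y, min_leaf = 7L, cp_min = 0.01, site = NULL) {
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("predictors must be numeric", call. = FALSE)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (min_leaf < 1) stop("min_leaf must be >= 1", call. = FALSE)
  root_sse <- sum((y - mean(y))^2)
  nodes <- list()
  new_node <- function(obs, depth) {
    id <- length(nodes) + 1L
    m <- mean(y[obs])
    nodes[[id]] <<- list(id = id, depth = depth, n = length(obs),
                         mean = m, sse = sum((y[obs] - m)^2),
                         var = NA_character_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         obs = obs)
    id
  }
  grow <- function(id) {
    force(id)   # ids come from new_node(); run its side effect first
    nd <- nodes[[id]]
    if (nd$sse <= 0 || nd$n < 2 * min_leaf) return(invisible())
    sp <- best_split(X[nd$obs, , drop = FALSE], y[nd$obs], min_leaf)
    if (is.null(sp)) return(invisible())
    if (root_sse <= 0 || sp$sse_reduction < cp_min * root_sse)
      return(invisible())
    nodes[[id]]$var <<- colnames(X)[sp$var]
    nodes[[id]]$threshold <<- sp$threshold
    l <- new_node(nd$obs[sp$left], nd$depth + 1L)
    r <- new_node(nd$obs[sp$right], nd$depth + 1L)
    nodes[[id]]$left <<- l; nodes[[id]]$right <<- r
    grow(l); grow(r)
    invisible()
  }
  grow(new_node(seq_along(y), 0L))
  structure(list(nodes = nodes, root_sse = root_sse, min_leaf = min_leaf,
                 cp_min = cp_min, x = X, y = y, site = site,
                 cp_table = NULL, selected_cp = NULL),
            class = "si_tree")
}

tree_is_leaf <- function(nd) is.na(nd$left)

tree_n_splits <- function(tree)
  sum(!vapply(tree$nodes, tree_is_leaf, logical(1)))

## leaf SSE total and leaf count under each node (bottom-up)
subtree_stats <- function(tree) {
  nn <- length(tree$nodes)
  leaves <- integer(nn); rleaf <- numeric(nn)
  for (id in rev(seq_len(nn))) {
    nd <- tree$nodes[[id]]
    if (tree_is_leaf(nd)) {
      leaves[id] <- 1L; rleaf[id] <- nd$sse
    } else {
      leaves[id] <- leaves[nd$left] + leaves[nd$right]
      rleaf[id] <- rleaf[nd$left] + rleaf[nd$right]
    }
  }
  list(leaves = leaves, rleaf = rleaf)
}

## Weakest-link cost-complexity sequence. Returns a data.frame with one
## row per nested tree: cp (the dimensionless complexity at which the
## tree becomes optimal, scaled by root SSE), nsplit, rel_error.
cc_sequence <- function(tree) {
  scale <- if (tree$root_sse > 0) tree$root_sse else 1
  work <- tree
  out <- data.frame(cp = 0, nsplit = tree_n_splits(work),
                    rel_error = subtree_stats(work)$rleaf[1] / scale)
  while (tree_n_splits(work) > 0) {
    st <- subtree_stats(work)
    internal <- which(!vapply(work$nodes, tree_is_leaf, logical(1)))
    g <- vapply(internal, function(id) {
      nd <- work$nodes[[id]]
      (nd$sse - st$rleaf[id]) / (st$leaves[id] - 1) / scale
    }, numeric(1))
    gmin <- min(g)
    prune_ids <- internal[g <= gmin + 1e-12]
    work <- prune_nodes(work, prune_ids)
    out <- rbind(out, data.frame(cp = gmin, nsplit = tree_n_splits(work),
                                 rel_error = subtree_stats(work)$rleaf[1] /
                                   scale))
  }
  out
}

## Make the given nodes (and their subtrees) leaves.
prune_nodes <- function(tree, ids) {
  drop <- logical(length(tree$nodes))
  mark <- function(id) {
    nd <- tree$nodes[[id]]
    if (!tree_is_leaf(nd)) { mark(nd$left); mark(nd$right) }
    drop[id] <<- TRUE
  }
  for (id in ids) {
    nd <- tree$nodes[[id]]
    if (!tree_is_leaf(nd)) { mark(nd$left); mark(nd$right) }
    tree$nodes[[id]]$var <- NA_character_
    tree$nodes[[id]]$threshold <- NA_real_
    tree$nodes[[id]]$left <- NA_integer_
    tree$nodes[[id]]$right <- NA_integer_
  }
  keep <- which(!drop)
  remap <- integer(length(tree$nodes)); remap[keep] <- seq_along(keep)
  tree$nodes <- lapply(tree$nodes[keep], function(nd) {
    if (!is.na(nd$left)) { nd$left <- remap[nd$left]; nd$right <- remap[nd$right] }
    nd$id <- remap[nd$id]
    nd
  })
  tree
}

## Prune to the nested tree optimal at complexity alpha: repeatedly
## collapse weakest links with g <= alpha.
prune_at <- function(tree, alpha) {
  scale <- if (tree$root_sse > 0) tree$root_sse else 1
  repeat {
    if (tree_n_splits(tree) == 0) return(tree)
    st <- subtree_stats(tree)
    internal <- which(!vapply(tree$nodes, tree_is_leaf, logical(1)))
    g <- vapply(internal, function(id) {
      nd <- tree$nodes[[id]]
      (nd$sse - st$rleaf[id]) / (st$leaves[id] - 1) / scale
    }, numeric(1))
    gmin <- min(g)
    if (gmin > alpha + 1e-12) return(tree)
    tree <- prune_nodes(tree, internal[g <= gmin + 1e-12])
  }
}

#' Predict from a regression tree
#'
#' Piecewise-constant predictions: each observation is routed to a leaf
#' and receives that leaf's training mean.
#'
#' @param object an `si_tree`.
#' @param newdata data.frame/matrix with the predictor columns; defaults
#'   to the training data.
#' @param ... unused.
#' @export
predict.si_tree <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$x else as.matrix(newdata)
  assign_id <- rep(1L, nrow(X))
  for (id in seq_along(object$nodes)) {
    nd <- object$nodes[[id]]
    if (tree_is_leaf(nd)) next
    here <- assign_id == id
    if (!any(here)) next
    goes_left <- X[, nd$var] < nd$threshold
    assign_id[here & goes_left] <- nd$left
    assign_id[here & !goes_left] <- nd$right
  }
  vapply(object$nodes, `[[`, numeric(1), "mean")[assign_id]
}

#' Cross-validated cost-complexity pruning with the one-SE rule
#'
#' Computes the weakest-link pruning sequence of a grown tree, estimates
#' the prediction error of each nested tree by k-fold cross-validation
#' (folds assigned by seeded shuffling, stratified by site when site
#' labels were given), and selects the most parsimonious tree whose CV
#' error lies within one standard error of the minimum. Fold trees are
#' evaluated at the geometric means of successive cp values, as in
#' rpart.
#'
#' @param tree an [grow_tree()] result.
#' @param k_folds number of folds (2..n).
#' @param seed RNG seed for fold assignment.
#' @return the pruned `si_tree`, with `cp_table` (cp, nsplit, rel_error,
#'   xerror, xstd) and `selected_cp` filled in.
#' @export
prune_one_se <- function(tree, k_folds = 10L, seed = 1L) {
  stopifnot(inherits(tree, "si_tree"))
  n <- length(tree$y)
  if (k_folds < 2 || k_folds > n)
    stop("k_folds must be between 2 and n", call. = FALSE)
  cp_tab <- cc_sequence(tree)
  m <- nrow(cp_tab)
  ## evaluation points between successive cp values
  ## tree k is optimal for alpha in [cp_k, cp_{k+1}); evaluate each
  ## interval at the geometric mean of its endpoints (root: at infinity)
  beta <- cp_tab$cp
  if (m > 1) {
    if (m > 2)
      for (k in 2:(m - 1)) beta[k] <- sqrt(cp_tab$cp[k] * cp_tab$cp[k + 1])
    beta[m] <- Inf
  }
  folds <- with_seed(seed, {
    f <- integer(n)
    groups <- if (is.null(tree$site)) list(seq_len(n)) else
      split(seq_len(n), tree$site)
    pos <- 0L
    for (gr in groups) {
      gr <- gr[sample.int(length(gr))]
      f[gr] <- ((pos + seq_along(gr) - 1L) %% k_folds) + 1L
      pos <- pos + length(gr)
    }
    f
  })
  err <- matrix(NA_real_, n, m)
  for (fold in seq_len(k_folds)) {
    test <- which(folds == fold)
    if (!length(test)) next
    train <- setdiff(seq_len(n), test)
    ft <- grow_tree(tree$x[train, , drop = FALSE], tree$y[train],
                    min_leaf = tree$min_leaf, cp_min = tree$cp_min)
    for (k in seq_len(m)) {
      pk <- prune_at(ft, beta[k])
      pred <- predict(pk, tree$x[test, , drop = FALSE])
      err[test, k] <- (tree$y[test] - pred)^2
    }
  }
  scale <- if (tree$root_sse > 0) tree$root_sse else 1
  cp_tab$xerror <- colSums(err) / scale
  cp_tab$xstd <- apply(err, 2, stats::sd) * sqrt(n) / scale
  k_min <- which.min(cp_tab$xerror)
  thresh <- cp_tab$xerror[k_min] + cp_tab$xstd[k_min]
  k_sel <- max(which(cp_tab$xerror <= thresh))  # smallest tree within 1 SE
  pruned <- prune_at(tree, cp_tab$cp[k_sel])
  pruned$cp_table <- cp_tab
  pruned$selected_cp <- cp_tab$cp[k_sel]
  pruned
}

#' @export
print.si_tree <- function(x, ...) {
  cat(sprintf("CART regression tree: %d node(s), %d split(s)\n",
              length(x$nodes), tree_n_splits(x)))
  show <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (tree_is_leaf(nd)) {
      cat(sprintf("%s* leaf: n=%d mean=%.4g\n", pad, nd$n, nd$mean))
    } else {
      cat(sprintf("%s%s < %.4g (n=%d mean=%.4g)\n", pad, nd$var,
                  nd$threshold, nd$n, nd$mean))
      show(nd$left, indent + 1L)
      show(nd$right, indent + 1L)
    }
  }
  show(1L, 0L)
  if (!is.null(x$selected_cp))
    cat(sprintf("selected cp (one-SE rule): %.4g\n", x$selected_cp))
  invisible(x)
}

#' Serialise a tree to JSON
#'
#' @param tree an `si_tree`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @export
tree_to_json <- function(tree, path = NULL) {
  strip <- lapply(tree$nodes, function(nd) nd[setdiff(names(nd), "obs")])
  js <- jsonlite::toJSON(list(nodes = strip, selected_cp = tree$selected_cp,
                              cp_table = tree$cp_table),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
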