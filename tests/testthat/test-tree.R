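test_that("a noiseless step is recovered exactly", {
  x <- data.frame(soil_n = c(seq(0.1, 0.42, length.out = 20),
                             seq(0.44, 0.9, length.out = 20)))
  y <- ifelse(x$soil_n < 0.43, 1, 5)
  tr <- grow_tree(x, y, min_leaf = 5)
  nd <- tr$nodes[[1]]
  expect_equal(nd$var, "soil_n")
  expect_equal(nd$threshold, (0.42 + 0.44) / 2)
  kids <- c(tr$nodes[[nd$left]]$mean, tr$nodes[[nd$right]]$mean)
  expect_equal(sort(kids), c(1, 5))
  expect_equal(tree_n_splits(tr), 1)   # children are pure, no more splits
})

test_that("first split matches the brute-force exhaustive oracle", {
  for (s in 1:10) {
    dat <- withr::with_seed(s, {
      n <- 80
      X <- data.frame(a = runif(n), b = rnorm(n),
                      f = sample(0:1, n, TRUE))
      y <- 2 * (X$a > 0.6) + 0.8 * X$f + rnorm(n, 0, 0.7)
      list(X = X, y = y)
    })
    tr <- grow_tree(dat$X, dat$y, min_leaf = 7)
    or <- oracle_best_split(dat$X, dat$y, 7)
    nd <- tr$nodes[[1]]
    expect_equal(nd$var, or$var)
    expect_equal(nd$threshold, or$threshold)
  }
})

test_that("constant response yields a single-node tree", {
  x <- data.frame(a = runif(30))
  tr <- grow_tree(x, rep(2.5, 30))
  expect_length(tr$nodes, 1)
  expect_equal(tr$nodes[[1]]$mean, 2.5)
  expect_equal(unique(predict(tr, x)), 2.5)
})

test_that("constant predictors are never split on", {
  dat <- withr::with_seed(3, {
    X <- data.frame(const = rep(1, 60), real = runif(60))
    list(X = X, y = 3 * (X$real > 0.5) + rnorm(60, 0, 0.2))
  })
  tr <- grow_tree(dat$X, dat$y, min_leaf = 5)
  vars <- na.omit(vapply(tr$nodes, `[[`, character(1), "var"))
  expect_false("const" %in% vars)
})

test_that("structural invariants hold on a grown tree", {
  dat <- withr::with_seed(11, {
    X <- data.frame(a = runif(150), b = runif(150))
    list(X = X, y = sin(6 * X$a) + rnorm(150, 0, 0.3))
  })
  tr <- grow_tree(dat$X, dat$y, min_leaf = 7, cp_min = 0.005)
  for (nd in tr$nodes) {
    if (is.na(nd$left)) next
    l <- tr$nodes[[nd$left]]; r <- tr$nodes[[nd$right]]
    ## children partition the parent's samples
    expect_setequal(c(l$obs, r$obs), nd$obs)
    ## pooled child SSE never exceeds the parent's
    expect_lte(l$sse + r$sse, nd$sse + 1e-9)
  }
  ## predictions reproduce leaf means exactly
  pred <- predict(tr)
  leaves <- tr$nodes[vapply(tr$nodes, grassSi:::tree_is_leaf, logical(1))]
  for (lf in leaves)
    expect_equal(unique(pred[lf$obs]), lf$mean)
  ## resubstitution error is non-increasing along the cc-sequence sizes
  cs <- grassSi:::cc_sequence(tr)
  expect_true(all(diff(cs$rel_error) >= -1e-9))  # smaller trees fit worse
  expect_true(all(diff(cs$nsplit) < 0))
})

test_that("first split agrees with rpart on shared settings", {
  skip_if_not_installed("rpart")
  dat <- withr::with_seed(21, {
    X <- data.frame(a = runif(200), b = rnorm(200))
    list(X = X, y = 1.5 * (X$a > 0.43) + rnorm(200, 0, 0.5))
  })
  tr <- grow_tree(dat$X, dat$y, min_leaf = 7, cp_min = 0.01)
  rp <- rpart::rpart(y ~ a + b, data = cbind(dat$X, y = dat$y),
                     control = rpart::rpart.control(minbucket = 7,
                                                    cp = 0.01, xval = 0))
  expect_equal(tr$nodes[[1]]$var,
               as.character(rp$frame$var[1]))
  expect_equal(tr$nodes[[1]]$threshold,
               unname(rp$splits[1, "index"]), tolerance = 1e-9)
})

test_that("pruning keeps a subtree and honours the one-SE bound", {
  dat <- withr::with_seed(31, {
    X <- data.frame(a = runif(200), b = runif(200))
    list(X = X, y = 2 * (X$a > 0.5) + rnorm(200, 0, 0.4))
  })
  tr <- grow_tree(dat$X, dat$y, min_leaf = 7, cp_min = 0.003)
  pr <- prune_one_se(tr, k_folds = 5, seed = 7)
  ## pruned tree is a subtree: every pruned split exists in the full tree
  full_splits <- vapply(tr$nodes, function(nd)
    paste(nd$var, nd$threshold), character(1))
  for (nd in pr$nodes)
    if (!is.na(nd$var))
      expect_true(paste(nd$var, nd$threshold) %in% full_splits)
  tab <- pr$cp_table
  k <- which(tab$cp == pr$selected_cp)
  expect_lte(tab$xerror[k], min(tab$xerror) + tab$xstd[which.min(tab$xerror)])
  ## deterministic given the seed
  pr2 <- prune_one_se(tr, k_folds = 5, seed = 7)
  expect_identical(pr$cp_table, pr2$cp_table)
  expect_error(prune_one_se(tr, k_folds = 1), "k_folds")
})

test_that("pure-noise responses are pruned to the root", {
  hits <- vapply(1:30, function(s) {
    dat <- withr::with_seed(s, {
      X <- data.frame(a = runif(120), b = runif(120))
      list(X = X, y = rnorm(120))
    })
    tr <- grow_tree(dat$X, dat$y, min_leaf = 7, cp_min = 0.01)
    pr <- prune_one_se(tr, k_folds = 5, seed = s + 1000)
    grassSi:::tree_n_splits(pr) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("JSON serialisation round-trips the structure", {
  dat <- withr::with_seed(41, {
    X <- data.frame(a = runif(60))
    list(X = X, y = 2 * (X$a > 0.5) + rnorm(60, 0, 0.3))
  })
  tr <- prune_one_se(grow_tree(dat$X, dat$y, min_leaf = 5), 5, seed = 2)
  js <- jsonlite::fromJSON(tree_to_json(tr), simplifyVector = TRUE)
  expect_equal(nrow(js$nodes), length(tr$nodes))
  expect_equal(js$selected_cp, tr$selected_cp)
})
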