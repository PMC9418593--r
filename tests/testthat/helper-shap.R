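## Independent exhaustive-coalition Shapley oracle for small tree
## ensembles, using the same cover-weighted conditional expectation the
## tree algorithm defines. Exponential in the number of features: keep
## p <= 10.

## Expected tree output when only the features in `known` take their value
## from x; at an unknown split the children are averaged by cover.
expectedTreeValue <- function(tree, x, known, node = 1L) {
  f <- tree$feature[node]
  if (f < 0L) return(tree$value[node])
  yes <- tree$yes[node] + 1L
  no <- tree$no[node] + 1L
  if ((f + 1L) %in% known) {
    child <- if (x[f + 1L] < tree$threshold[node]) yes else no
    return(expectedTreeValue(tree, x, known, child))
  }
  (tree$cover[yes] * expectedTreeValue(tree, x, known, yes) +
   tree$cover[no] * expectedTreeValue(tree, x, known, no)) /
    tree$cover[node]
}

ensembleValue <- function(trees, x, known) {
  sum(vapply(trees, expectedTreeValue, numeric(1), x = x, known = known))
}

## Brute-force Shapley values over the features the ensemble actually uses.
bruteForceShap <- function(trees, x, p) {
  used <- sort(unique(unlist(lapply(trees, function(t)
    t$feature[t$feature >= 0L] + 1L))))
  phi <- numeric(p)
  n <- length(used)
  stopifnot(n <= 10)
  others <- function(i) used[used != i]
  for (i in used) {
    rest <- others(i)
    for (sz in 0:length(rest)) {
      combos <- if (sz == 0) list(integer(0)) else
        asplit(utils::combn(rest, sz), 2)
      w <- factorial(sz) * factorial(n - sz - 1) / factorial(n)
      for (S in combos) {
        S <- as.integer(S)
        phi[i] <- phi[i] + w * (ensembleValue(trees, x, c(S, i)) -
                                ensembleValue(trees, x, S))
      }
    }
  }
  phi
}

## Hand-built stump ensembles for direct tests: a single split on feature
## `f` (1-based) at `thr` with leaf values (vYes, vNo) and covers.
stumpTree <- function(f, thr, vYes, vNo, cYes = 5, cNo = 5) {
  list(feature = as.integer(c(f - 1, -1, -1)),
       threshold = as.numeric(c(thr, NA, NA)),
       yes = c(1L, -1L, -1L), no = c(2L, -1L, -1L),
       value = as.numeric(c(0, vYes, vNo)),
       cover = as.numeric(c(cYes + cNo, cYes, cNo)))
}

## Train a tiny xgboost model and return its parsed trees.
tinyXgbTrees <- function(X, y, nrounds = 8, max_depth = 3) {
  bst <- xgboost::xgb.train(
    params = list(max_depth = max_depth, eta = 0.5, objective =
                    "reg:squarederror", nthread = 1, min_child_weight = 1,
                  lambda = 0),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds,
    verbose = 0)
  list(bst = bst,
       trees = tapage:::.parseTrees(bst, colnames(X)),
       base = tapage:::.baseScore(bst))
}

## Random full binary tree of the given depth where level d always splits
## feature d: no path repeats a feature, the regime in which the
## polynomial-time tree algorithm provably equals the exhaustive Shapley
## value. Covers are random but consistent (children sum to the parent).
randomUniqueTree <- function(depth, p, seed) {
  set.seed(seed)
  nInternal <- 2^depth - 1
  nNodes <- 2^(depth + 1) - 1
  levFeat <- sample.int(p, depth)   # one feature per level
  feature <- integer(nNodes); threshold <- numeric(nNodes)
  yes <- no <- integer(nNodes); value <- numeric(nNodes)
  cover <- numeric(nNodes)
  cover[1] <- 100
  for (i in seq_len(nNodes)) {
    if (i <= nInternal) {
      lev <- floor(log2(i))
      feature[i] <- levFeat[lev + 1] - 1L
      threshold[i] <- rnorm(1)
      yes[i] <- 2L * i - 1L      # 0-based children
      no[i] <- 2L * i
      frac <- runif(1, 0.2, 0.8)
      cover[2 * i] <- cover[i] * frac
      cover[2 * i + 1] <- cover[i] * (1 - frac)
    } else {
      feature[i] <- -1L
      yes[i] <- no[i] <- -1L
      value[i] <- rnorm(1, 0, 2)
    }
  }
  list(feature = as.integer(feature), threshold = threshold,
       yes = as.integer(yes), no = as.integer(no), value = value,
       cover = cover)
}
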