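# The C4.5/C5.0-style rule learner

test_that("median discretisation splits evenly with ties to low", {
  expect_identical(as.character(discretize_outcome(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  y <- c(1, 2, 2, 5)                       # 2 equals the median -> low
  expect_identical(as.character(discretize_outcome(y)),
                   c("low", "low", "low", "high"))
  set.seed(1)
  yn <- rnorm(5000)
  lab <- discretize_outcome(yn)
  expect_lt(abs(mean(lab == "high") - 0.5), 0.01)
  expect_error(discretize_outcome(rep(1, 5)), "constant")
  q4 <- discretize_outcome(1:100, scheme = "quantile", k = 4)
  expect_identical(as.integer(table(q4)), rep(25L, 4))
})

test_that("entropy matches direct evaluation", {
  expect_identical(entropy(c(10, 0)), 0)
  expect_identical(entropy(c(5, 5)), 1)
  expect_equal(entropy(c(1, 3)), 0.8112781244591328, tolerance = 1e-12)
  expect_error(entropy(c(-1, 2)), "non-negative")
})

test_that("gain ratio follows the weighted-entropy definition", {
  perfect <- gain_ratio(c(5, 5), list(c(5, 0), c(0, 5)))
  expect_equal(perfect$gain, 1)
  expect_equal(perfect$split_info, 1)
  expect_equal(perfect$ratio, 1)
  mirror <- gain_ratio(c(6, 6), list(c(3, 3), c(3, 3)))
  expect_equal(mirror$gain, 0)
  gr <- gain_ratio(c(4, 4), list(c(3, 1), c(1, 3)))
  expect_equal(gr$gain, 1 - 0.8112781244591328, tolerance = 1e-12)
  expect_equal(gr$ratio, gr$gain, tolerance = 1e-12)   # balanced split info = 1
  empty <- gain_ratio(c(4, 4), list(c(4, 4), c(0, 0)))
  expect_equal(empty$gain, 0)                          # empty partition contributes 0
  expect_error(gain_ratio(c(4, 4), list(c(3, 1), c(2, 3))), "partition")
})

test_that("tree growth handles pure nodes and forced splits", {
  X <- matrix(rbinom(200 * 8, 1, 0.5), 200, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  pure <- grow_tree(list(X = X, labels = factor(rep("a", 200), levels = c("a", "b"))))
  expect_identical(pure$type, "leaf")
  lab <- factor(ifelse(X[, 7] == 1, "high", "low"))
  tr <- grow_tree(list(X = X, labels = lab))
  expect_identical(tr$type, "split")
  expect_identical(tr$split_predictor, "x7")
  expect_identical(tr$children[["0"]]$type, "leaf")
  expect_identical(tr$children[["1"]]$type, "leaf")
})

test_that("greedy growth finds the XOR interaction and matches the depth-2 oracle", {
  set.seed(33)
  n <- 400
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  lab <- factor(ifelse(xor(X[, "a"] == 1, X[, "b"] == 1), "high", "low"))
  tr <- grow_tree(list(X = X, labels = lab), sig_level = 1)
  used <- unique(unlist(lapply(tree_to_rules(tr)$rules,
                               function(r) r$conditions$predictor)))
  expect_setequal(used, c("a", "b"))
  expect_equal(tree_train_accuracy(tr, X, lab), 1)
  expect_equal(oracle_depth2_accuracy(X, lab), 1)
})

test_that("growth matches the exhaustive depth-2 oracle on small separable cases", {
  for (s in 1:6) {
    set.seed(s)
    n <- 64
    X <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                dimnames = list(NULL, paste0("x", 1:4)))
    truth <- X[, 1] == 1 & X[, 2] == 1     # monotone conjunction: greedy-findable
    lab <- factor(ifelse(truth, "high", "low"), levels = c("low", "high"))
    tr <- grow_tree(list(X = X, labels = lab), sig_level = 1)
    expect_equal(tree_train_accuracy(tr, X, lab), oracle_depth2_accuracy(X, lab),
                 info = paste("seed", s))
  }
})

test_that("rule collapse yields one rule per leaf with covers partitioning n", {
  single <- list(type = "leaf", class_counts = c(low = 7, high = 3))
  rs <- tree_to_rules(single)
  expect_length(rs$rules, 0)
  expect_identical(rs$default_class, "low")
  set.seed(34)
  n <- 400
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  lab <- factor(ifelse(xor(X[, "a"] == 1, X[, "b"] == 1), "high", "low"))
  tr <- grow_tree(list(X = X, labels = lab), sig_level = 1)
  rs2 <- tree_to_rules(tr)
  expect_length(rs2$rules, 4)
  expect_true(all(vapply(rs2$rules, function(r) nrow(r$conditions), integer(1)) == 2))
  expect_identical(sum(vapply(rs2$rules, function(r) r$cover, numeric(1))), as.numeric(n))
  # depth-1 tree: two one-condition rules
  lab1 <- factor(ifelse(X[, "a"] == 1, "high", "low"))
  tr1 <- grow_tree(list(X = X[, "a", drop = FALSE], labels = lab1))
  rs1 <- tree_to_rules(tr1)
  expect_length(rs1$rules, 2)
  expect_true(all(vapply(rs1$rules, function(r) nrow(r$conditions), integer(1)) == 1))
})

test_that("the pessimistic bound matches binomial theory", {
  expect_equal(pessimistic_error(0, 100), 1 - 0.25^(1 / 100), tolerance = 1e-12)
  expect_equal(pessimistic_error(0, 1), 0.75, tolerance = 1e-12)
  # upper bound: P(X <= e | p = bound) = cf
  u <- pessimistic_error(5, 50)
  expect_equal(pbinom(5, 50, u), 0.25, tolerance = 1e-9)
  expect_gt(pessimistic_error(10, 50), pessimistic_error(5, 50))
})

test_that("pruning removes irrelevant conditions and hopeless rules", {
  # x2 is constant 1, so dropping the x2-condition never changes cover/errors
  n <- 200
  set.seed(35)
  x1 <- rbinom(n, 1, 0.5)
  X <- cbind(x1 = x1, x2 = rep(1L, n))
  lab <- factor(ifelse(x1 == 1, "high", "low"), levels = c("low", "high"))
  rs <- structure(list(
    rules = list(list(
      conditions = data.frame(predictor = c("x1", "x2"), value = c(1L, 1L),
                              stringsAsFactors = FALSE),
      predicted_class = "high", cover = sum(x1), errors = 0,
      pessimistic_error = NA_real_)),
    default_class = "low", classes = c("low", "high")), class = "c5_ruleset")
  pr <- prune_rules(rs, list(X = X, labels = lab))
  expect_length(pr$rules, 1)
  expect_identical(pr$rules[[1]]$conditions$predictor, "x1")
  # 0 errors over ~100 covered survives against a 40%-error default
  expect_lt(pessimistic_error(0, 100), pessimistic_error(80, 200))
  # rules no better than the default are dropped entirely
  set.seed(36)
  Xn <- matrix(rbinom(n * 3, 1, 0.5), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  labn <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
  rs_bad <- structure(list(
    rules = list(list(
      conditions = data.frame(predictor = "x1", value = 1L, stringsAsFactors = FALSE),
      predicted_class = "high", cover = 0, errors = 0, pessimistic_error = NA_real_)),
    default_class = "low", classes = c("low", "high")), class = "c5_ruleset")
  pr_bad <- prune_rules(rs_bad, list(X = Xn, labels = labn))
  expect_length(pr_bad$rules, 0)
  expect_false(ruleset_detected(pr_bad))
})

test_that("pruning never increases the ruleset's pessimistic error", {
  pn <- small_panel(n = 600, m = 10, seed = 37)
  spec <- effect_spec(pn$G$snps$snp_id[1:2], level = "strong")
  y <- simulate_interaction(pn$G, spec, seed = 5)$y
  lab <- discretize_outcome(y)
  data <- list(X = pn$enc$values, labels = lab)
  tr <- grow_tree(data, sig_level = 1)
  before <- tree_to_rules(tr)
  # recompute each raw rule's pessimistic error on the training data
  ind <- stats::model.matrix(~ l - 1, data.frame(l = factor(lab, levels = before$classes)))
  colnames(ind) <- before$classes
  pess_before <- vapply(before$rules, function(r) {
    st <- epistree:::rule_stats(r$conditions, data$X, ind, r$predicted_class)
    pessimistic_error(st$errors, st$cover)
  }, numeric(1))
  after <- prune_rules(before, data)
  if (length(after$rules)) {
    expect_lte(min(vapply(after$rules, function(r) r$pessimistic_error, numeric(1))),
               min(pess_before) + 1e-12)
  }
  expect_true(TRUE)  # reaching here means pruning ran cleanly
})

test_that("prediction follows weighted voting with default fallback", {
  classes <- c("low", "high")
  mkrule <- function(pred, val, cls, cover, errors) {
    list(conditions = data.frame(predictor = pred, value = val,
                                 stringsAsFactors = FALSE),
         predicted_class = cls, cover = cover, errors = errors,
         pessimistic_error = 0.1)
  }
  X <- cbind(x1 = c(1L, 0L, 1L), x2 = c(1L, 1L, 0L))
  empty <- structure(list(rules = list(), default_class = "low", classes = classes),
                     class = "c5_ruleset")
  expect_identical(as.character(predict(empty, X)), rep("low", 3))
  # conflicting matching rules: weights 10 vs 3 -> heavier rule wins
  rs <- structure(list(rules = list(
    mkrule("x1", 1L, "high", 10, 1),     # weight 10
    mkrule("x2", 1L, "low", 3, 1)        # weight 3
  ), default_class = "low", classes = classes), class = "c5_ruleset")
  out <- predict(rs, X)
  expect_identical(as.character(out), c("high", "low", "high"))
  # exact tie in votes -> default class
  rs_tie <- structure(list(rules = list(
    mkrule("x1", 1L, "high", 5, 1),
    mkrule("x2", 1L, "low", 5, 1)
  ), default_class = "low", classes = classes), class = "c5_ruleset")
  expect_identical(as.character(predict(rs_tie, X))[1], "low")
})

test_that("selected SNPs deduplicate dominant and recessive columns", {
  pn <- small_panel(n = 100, m = 3, seed = 38)
  empty <- structure(list(rules = list(), default_class = "low",
                          classes = c("low", "high")), class = "c5_ruleset")
  expect_length(c5_selected_snps(empty, pn$enc), 0)
  rs <- structure(list(rules = list(list(
    conditions = data.frame(predictor = c("snp0001_dom", "snp0001_rec"),
                            value = c(1L, 0L), stringsAsFactors = FALSE),
    predicted_class = "high", cover = 10, errors = 0, pessimistic_error = 0.1)),
    default_class = "low", classes = c("low", "high")), class = "c5_ruleset")
  expect_identical(c5_selected_snps(rs, pn$enc), "snp0001")
  bad <- rs
  bad$rules[[1]]$conditions$predictor[1] <- "nope"
  expect_error(c5_selected_snps(bad, pn$enc), "unknown predictor")
})

test_that("the fitted ruleset is deterministic byte for byte", {
  pn <- small_panel(n = 500, m = 10, seed = 39)
  spec <- effect_spec(pn$G$snps$snp_id[1:2], level = "strong")
  y <- simulate_interaction(pn$G, spec, seed = 6)$y
  lab <- discretize_outcome(y)
  r1 <- c5_fit(pn$enc, lab)
  r2 <- c5_fit(pn$enc, lab)
  expect_identical(as.character(ruleset_to_json(r1, pn$enc)),
                   as.character(ruleset_to_json(r2, pn$enc)))
})

test_that("pure-noise phenotypes almost never yield a ruleset", {
  G <- generate_genotypes(2000, snp_panel(200, seed = 40), seed = 41)
  enc <- dichotomize(G)
  detections <- vapply(1:100, function(r) {
    y <- simulate_null(G, derive_seed(700, r))$y
    ruleset_detected(c5_fit(enc, discretize_outcome(y)))
  }, logical(1))
  expect_lte(mean(detections), 0.02)
})
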