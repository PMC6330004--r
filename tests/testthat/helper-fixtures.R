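# Shared fixture builders; everything is generated in code at test time.

# a genotype_matrix with exactly specified columns (bypasses the generator)
manual_genotypes <- function(cols, pos_bp = NULL, chrom = "19") {
  vals <- do.call(cbind, lapply(cols, as.integer))
  m <- ncol(vals)
  snps <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(m)),
    chrom = chrom,
    pos_bp = if (is.null(pos_bp)) seq_len(m) * 2000L else as.integer(pos_bp),
    maf = colMeans(vals, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE
  )
  colnames(vals) <- snps$snp_id
  epistree:::new_genotype_matrix(vals, snps, sprintf("i%03d", seq_len(nrow(vals))))
}

# small LE panel + encoding used across learner tests
small_panel <- function(n = 400, m = 20, seed = 1) {
  G <- generate_genotypes(n, snp_panel(m, maf_range = c(0.2, 0.5), seed = seed),
                          seed = seed + 1)
  list(G = G, enc = dichotomize(G))
}

# independent truth-table evaluator for logic trees: renders the tree as an
# R logical expression and evaluates it row by row (no shared code with
# evaluate_tree's recursion over matrices)
oracle_eval_tree <- function(tree, X) {
  expr_of <- function(node) {
    if (node$type == "leaf") {
      e <- sprintf("(row[%d] == 1)", node$col)
      if (node$neg) e <- paste0("!", e)
      return(e)
    }
    op <- if (node$type == "and") "&&" else "||"
    sprintf("(%s %s %s)", expr_of(node$left), op, expr_of(node$right))
  }
  ex <- parse(text = expr_of(tree))[[1]]
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    row <- X[i, ]
    out[i] <- as.integer(eval(ex))
  }
  out
}

# random logic tree with k leaves over p predictors
random_logic_tree <- function(k, p) {
  nodes <- lapply(sample.int(p, k, replace = TRUE), function(q) {
    logic_leaf(q, neg = runif(1) < 0.5)
  })
  while (length(nodes) > 1) {
    i <- sample.int(length(nodes), 1)
    j <- sample.int(length(nodes) - 1, 1)
    rest <- nodes[-i]
    combine <- if (runif(1) < 0.5) logic_and else logic_or
    merged <- combine(nodes[[i]], rest[[j]])
    nodes <- c(rest[-j], list(merged))
  }
  nodes[[1]]
}

# exhaustive best training accuracy over all depth<=2 trees on binary
# predictors (oracle for greedy growth); majority class in each cell
oracle_depth2_accuracy <- function(X, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  acc_leaf <- function(idx) {
    if (!length(idx)) return(0L)
    max(table(labels[idx]))
  }
  best <- acc_leaf(seq_len(n))  # depth 0
  p <- ncol(X)
  for (r in seq_len(p)) {
    side0 <- which(X[, r] == 0); side1 <- which(X[, r] == 1)
    for (a in c(0L, seq_len(p))) {      # 0 = leave child as a leaf
      acc0 <- if (a == 0L) acc_leaf(side0) else {
        acc_leaf(side0[X[side0, a] == 0]) + acc_leaf(side0[X[side0, a] == 1])
      }
      for (b in c(0L, seq_len(p))) {
        acc1 <- if (b == 0L) acc_leaf(side1) else {
          acc_leaf(side1[X[side1, b] == 0]) + acc_leaf(side1[X[side1, b] == 1])
        }
        best <- max(best, acc0 + acc1)
      }
    }
  }
  best / n
}

# training accuracy of a grown tree via direct path-following
tree_train_accuracy <- function(tree, X, labels) {
  labels <- as.character(labels)
  classify <- function(node, i) {
    while (node$type == "split") {
      v <- as.character(X[i, node$split_predictor])
      node <- node$children[[v]]
    }
    names(node$class_counts)[which.max(node$class_counts)]
  }
  mean(vapply(seq_len(nrow(X)), function(i) classify(tree, i), character(1)) == labels)
}
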