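#' Logic trees: Boolean combinations of binary SNP predictors
#'
#' A logic tree is a strictly binary tree whose internal nodes carry AND/OR
#' and whose leaves are (possibly negated) binary predictors, e.g.
#' `SNP3_dom OR (SNP1_dom AND (NOT SNP4_rec AND NOT SNP2_dom))`.  Evaluated
#' on a binary predictor matrix it yields a 0/1 vector that enters a linear
#' model as a regressor (see [greedy_fit()]).
#'
#' Leaves reference predictors by column index into the `binary_encoding`.
#'
#' @name logictree
NULL

#' @rdname logictree
#' @param col Predictor column index (into the encoding's columns).
#' @param neg Negate the predictor (NOT)?
#' @export
logic_leaf <- function(col, neg = FALSE) {
  stopifnot(length(col) == 1L, col >= 1)
  list(type = "leaf", col = as.integer(col), neg = isTRUE(neg))
}

#' @rdname logictree
#' @param left,right Child trees.
#' @export
logic_and <- function(left, right) list(type = "and", left = left, right = right)

#' @rdname logictree
#' @export
logic_or <- function(left, right) list(type = "or", left = left, right = right)

#' Number of leaves of a logic tree
#' @param tree A logic tree.
#' @return Integer leaf count.
#' @export
tree_size <- function(tree) {
  if (tree$type == "leaf" || tree$type == "const") return(1L)
  tree_size(tree$left) + tree_size(tree$right)
}

#' Evaluate a logic tree on binary predictors
#'
#' Recursive elementwise evaluation: NOT applies at leaves, AND/OR
#' elementwise on the children.
#'
#' @param tree A logic tree ([logic_leaf()], [logic_and()], [logic_or()]).
#' @param X A `binary_encoding` or an n x p 0/1 matrix.
#' @return Integer 0/1 vector of length n.
#' @export
evaluate_tree <- function(tree, X) {
  if (inherits(X, "binary_encoding")) X <- X$values
  eval_node(tree, X)
}

eval_node <- function(node, X) {
  switch(node$type,
    leaf = {
      if (node$col > ncol(X)) stop("unknown predictor column ", node$col)
      v <- X[, node$col]
      if (node$neg) 1L - v else v
    },
    const = rep.int(as.integer(node$value), nrow(X)),
    and = eval_node(node$left, X) * eval_node(node$right, X),
    or = {
      l <- eval_node(node$left, X)
      r <- eval_node(node$right, X)
      l + r - l * r
    },
    stop("unknown node type: ", node$type)
  )
}

# ---- structural helpers (preorder indexing of leaves / internal nodes) ----

# replace the k-th preorder leaf; returns list(tree, remaining counter)
replace_leaf_k <- function(node, k, newnode) {
  if (node$type == "leaf" || node$type == "const") {
    if (k == 1L) return(list(node = newnode, k = 0L))
    return(list(node = node, k = k - 1L))
  }
  l <- replace_leaf_k(node$left, k, newnode)
  if (l$k == 0L) return(list(node = list(type = node$type, left = l$node, right = node$right), k = 0L))
  r <- replace_leaf_k(node$right, l$k, newnode)
  list(node = list(type = node$type, left = node$left, right = r$node), k = r$k)
}

replace_leaf <- function(tree, k, newnode) replace_leaf_k(tree, k, newnode)$node

get_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (node$type == "leaf" || node$type == "const") {
      out[[length(out) + 1L]] <<- node
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree)
  out
}

# internal nodes in preorder
get_internal <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (node$type %in% c("and", "or")) {
      out[[length(out) + 1L]] <<- list(node = node, path = path)
      walk(node$left, c(path, "left"))
      walk(node$right, c(path, "right"))
    }
  }
  walk(tree, character())
  out
}

modify_at_path <- function(tree, path, f) {
  if (!length(path)) return(f(tree))
  tree[[path[1]]] <- modify_at_path(tree[[path[1]]], path[-1], f)
  tree
}

#' Render a logic tree as a readable Boolean expression
#'
#' @param tree A logic tree.
#' @param encoding Optional `binary_encoding` for predictor names.
#' @return A character scalar like `"(a AND NOT b) OR c"`.
#' @export
format_logic_tree <- function(tree, encoding = NULL) {
  nm <- function(col) {
    if (is.null(encoding)) paste0("x", col) else encoding$columns$col_id[col]
  }
  fmt <- function(node) {
    switch(node$type,
      leaf = paste0(if (node$neg) "NOT " else "", nm(node$col)),
      const = as.character(node$value),
      and = paste0("(", fmt(node$left), " AND ", fmt(node$right), ")"),
      or = paste0("(", fmt(node$left), " OR ", fmt(node$right), ")")
    )
  }
  fmt(tree)
}

#' Least-squares coefficients for a set of logic trees
#'
#' Ordinary least squares of `y` on the evaluated tree columns plus an
#' intercept; the score is the residual sum of squares.  Collinear or
#' constant tree columns are resolved by the minimum-norm solution rather
#' than rejected.
#'
#' @param trees List of logic trees.
#' @param X A `binary_encoding` or 0/1 matrix.
#' @param y Quantitative outcome.
#' @return List with `intercept`, `coefficients` (one per tree), `score`.
#' @export
fit_coefficients <- function(trees, X, y) {
  if (inherits(X, "binary_encoding")) X <- X$values
  stopifnot(nrow(X) == length(y), length(y) > length(trees) + 1)
  L <- vapply(trees, function(tr) as.numeric(eval_node(tr, X)), numeric(nrow(X)))
  D <- cbind(1, L)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    beta <- as.vector(MASS::ginv(D) %*% y)  # minimum-norm for degenerate designs
  } else {
    beta <- qr.coef(qrD, y)
  }
  res <- y - as.vector(D %*% beta)
  list(intercept = beta[1], coefficients = beta[-1], score = sum(res^2))
}

new_logic_model <- function(trees, intercept, coefficients, score) {
  structure(list(trees = trees, intercept = intercept,
                 coefficients = coefficients, score = score),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat(sprintf("logic_model: %d tree(s), RSS = %.4f\n", length(x$trees), x$score))
  for (t in seq_along(x$trees)) {
    cat(sprintf("  L%d (beta = %.4f): %s\n", t, x$coefficients[t],
                format_logic_tree(x$trees[[t]])))
  }
  invisible(x)
}

#' Search parameters for the greedy logic-regression fit
#'
#' @param n_trees Number of logic trees in the model (default 1; the fitted
#'   models in the simulation study use one tree).
#' @param max_leaves Total leaf budget across trees (default 8, matching
#'   the eight-SNP models the study reports).
#' @param max_iterations Cap on accepted moves (default 25).
#' @param seed Seed for the random start (and, in [randomization_test()],
#'   for the permutations).
#' @return A `fit_params` list.
#' @export
fit_params <- function(n_trees = 1L, max_leaves = 8L, max_iterations = 25L,
                       seed = 1L) {
  stopifnot(max_leaves >= n_trees, n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), max_leaves = as.integer(max_leaves),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "fit_params")
}

#' Enumerate all single-move neighbours of a logic model
#'
#' The move set follows the logic-regression literature: per leaf (preorder)
#' alternate the predictor (keeping negation), toggle negation, and grow
#' (replace the leaf by `op(leaf, new leaf)` for AND/OR and both negation
#' states of every predictor, when the leaf budget permits); per internal
#' node (preorder) alternate AND/OR; and prune (replace an internal node by
#' either child).  The order of the returned list is fixed and is the tie-
#' breaking order of [greedy_fit()].
#'
#' @param model A `logic_model` (coefficients may be unset).
#' @param encoding A `binary_encoding` or 0/1 matrix (only the number of
#'   predictor columns is used).
#' @param max_leaves Total leaf budget; grow moves beyond it are excluded.
#' @return List of candidate models (trees only; scores unset).
#' @export
propose_moves <- function(model, encoding, max_leaves = 8L) {
  p <- if (inherits(encoding, "binary_encoding")) ncol(encoding$values) else ncol(encoding)
  total_leaves <- sum(vapply(model$trees, tree_size, integer(1)))
  cands <- list()
  add <- function(trees) cands[[length(cands) + 1L]] <<- new_logic_model(trees, NA, NA, NA)
  for (t in seq_along(model$trees)) {
    tree <- model$trees[[t]]
    leaves <- get_leaves(tree)
    with_tree <- function(newtree) {
      trs <- model$trees; trs[[t]] <- newtree; trs
    }
    for (k in seq_along(leaves)) {
      leaf <- leaves[[k]]
      for (q in seq_len(p)) {                     # alternate predictor
        if (q == leaf$col) next
        add(with_tree(replace_leaf(tree, k, logic_leaf(q, leaf$neg))))
      }
      add(with_tree(replace_leaf(tree, k, logic_leaf(leaf$col, !leaf$neg))))  # toggle NOT
      if (total_leaves < max_leaves) {            # grow
        for (op in c("and", "or")) {
          for (negflag in c(FALSE, TRUE)) {
            for (q in seq_len(p)) {
              newnode <- list(type = op, left = leaf, right = logic_leaf(q, negflag))
              add(with_tree(replace_leaf(tree, k, newnode)))
            }
          }
        }
      }
    }
    internals <- get_internal(tree)
    for (nd in internals) {                       # alternate operator
      flip <- function(node) {
        node$type <- if (node$type == "and") "or" else "and"
        node
      }
      add(with_tree(modify_at_path(tree, nd$path, flip)))
    }
    for (nd in internals) {                       # prune to either child
      add(with_tree(modify_at_path(tree, nd$path, function(node) node$left)))
      add(with_tree(modify_at_path(tree, nd$path, function(node) node$right)))
    }
  }
  cands
}

#' SNPs appearing in a logic model
#'
#' Union of the SNP identities behind all leaf predictors; dominant and
#' recessive columns collapse to one SNP id.
#'
#' @param model A `logic_model`.
#' @param encoding The `binary_encoding` the model was fitted on.
#' @return Character vector of snp_ids.
#' @export
logic_selected_snps <- function(model, encoding) {
  cols <- unlist(lapply(model$trees, function(tr) {
    vapply(get_leaves(tr), function(l) l$col, integer(1))
  }))
  unique(encoding$columns$snp_id[unique(cols)])
}

#' Serialise a logic model to JSON
#'
#' @param model A `logic_model`.
#' @param encoding Optional `binary_encoding` for predictor annotation.
#' @return JSON string with the nested tree, coefficients and score.
#' @export
logic_model_to_json <- function(model, encoding = NULL) {
  ser <- function(node) {
    if (node$type == "leaf") {
      out <- list(type = "leaf", col = node$col, negated = node$neg)
      if (!is.null(encoding)) {
        out$col_id <- encoding$columns$col_id[node$col]
        out$snp_id <- encoding$columns$snp_id[node$col]
        out$mode <- encoding$columns$mode[node$col]
      }
      out
    } else {
      list(type = node$type, left = ser(node$left), right = ser(node$right))
    }
  }
  jsonlite::toJSON(list(
    intercept = model$intercept,
    coefficients = model$coefficients,
    score = model$score,
    trees = lapply(model$trees, ser)
  ), auto_unbox = TRUE, digits = NA)
}
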