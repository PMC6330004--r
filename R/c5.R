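#' A C4.5/C5.0-style rule learner for binary SNP predictors
#'
#' The learner grows a decision tree on binary (dominant/recessive)
#' predictors by maximising the gain ratio (information gain divided by the
#' split's own entropy), collapses every root-to-leaf path into a
#' conjunctive rule, simplifies each rule by pessimistic pruning (an upper
#' binomial confidence bound on its training error), discards rules that do
#' not beat the default class, and predicts by weighted voting among the
#' matching rules.
#'
#' Because the learner is used here to screen thousands of markers, tree
#' growth additionally applies a per-node significance guard: the selected
#' split must pass a Bonferroni-adjusted independence test (adjusted for
#' the number of candidate predictors at the node) at level `sig_level`.
#' Without such a guard a best-of-thousands chance split always looks
#' informative on training data and the learner would flag spurious
#' markers on pure-noise phenotypes; with it, the whole-panel type I error
#' is controlled at roughly `sig_level` family-wise.  Set `sig_level = 1`
#' to disable the guard and obtain classic C4.5 growth.
#'
#' @name c5rules
NULL

#' Discretise a quantitative outcome into classes
#'
#' Default scheme: median split into `low`/`high`, with values equal to the
#' median assigned to `low`.  Alternatively an equal-frequency k-quantile
#' split (`scheme = "quantile"`, `k` classes `q1 < q2 < ...`).
#'
#' @param y Quantitative vector (length >= 2, non-constant).
#' @param scheme `"median"` or `"quantile"`.
#' @param k Number of classes for the quantile scheme.
#' @return Factor of class labels.
#' @export
discretize_outcome <- function(y, scheme = c("median", "quantile"), k = 2L) {
  scheme <- match.arg(scheme)
  if (length(y) < 2) stop("need at least two observations")
  if (stats::var(y) == 0) stop("outcome is constant; cannot discretise")
  if (scheme == "median") {
    med <- stats::median(y)
    factor(ifelse(y <= med, "low", "high"), levels = c("low", "high"))
  } else {
    qs <- stats::quantile(y, probs = seq_len(k - 1) / k, names = FALSE)
    cut(y, breaks = c(-Inf, qs, Inf), labels = paste0("q", seq_len(k)),
        right = TRUE)
  }
}

#' Information entropy of class counts, in bits
#'
#' `-sum(p_i log2 p_i)` with the convention `0 * log 0 = 0`.
#'
#' @param class_counts Non-negative per-class counts, total >= 1.
#' @return Entropy in bits, in `[0, log2(m)]`.
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  tot <- sum(class_counts)
  if (tot < 1) stop("total count must be >= 1")
  p <- class_counts[class_counts > 0] / tot
  -sum(p * log2(p))
}

# entropy of each row of a count matrix (vectorised over candidate splits)
ent_rows <- function(M) {
  tot <- rowSums(M)
  P <- M / pmax(tot, 1)
  terms <- ifelse(M > 0, P * log2(P), 0)
  H <- -rowSums(terms)
  H[tot == 0] <- 0
  H
}

#' Information gain and gain ratio of a split
#'
#' The post-split entropy is the partition-size-weighted sum of child
#' entropies; the gain is the parent entropy minus it; the normalised gain
#' (gain ratio) divides by the split information, the entropy of the
#' partition sizes themselves.  Empty partitions contribute zero.
#'
#' @param parent_counts Per-class counts at the node.
#' @param child_counts List of per-class count vectors, one per partition;
#'   they must sum to `parent_counts`.
#' @return List with `gain`, `split_info`, `ratio` (0 when the split
#'   information is zero).
#' @export
gain_ratio <- function(parent_counts, child_counts) {
  tot <- Reduce(`+`, child_counts)
  if (!isTRUE(all.equal(as.numeric(tot), as.numeric(parent_counts)))) {
    stop("child counts do not partition the parent counts")
  }
  n <- sum(parent_counts)
  info_before <- entropy(parent_counts)
  ni <- vapply(child_counts, sum, numeric(1))
  info_after <- 0
  for (k in seq_along(child_counts)) {
    if (ni[k] > 0) info_after <- info_after + (ni[k] / n) * entropy(child_counts[[k]])
  }
  gain <- info_before - info_after
  pk <- ni[ni > 0] / n
  split_info <- -sum(pk * log2(pk))
  list(gain = gain, split_info = split_info,
       ratio = if (split_info > 0) gain / split_info else 0)
}

# p-value of independence between a binary split and the class labels:
# Fisher's exact test for two classes, chi-square otherwise
split_p_value <- function(tab) {
  if (all(dim(tab) == c(2L, 2L))) {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }
}

# vectorised chi-square independence p-values for all candidate binary
# splits at a node (cnt1/cnt0: candidate x class count matrices); used as a
# cheap screen before the exact test on the chosen split
chisq_p_rows <- function(cnt1, cnt0) {
  n1 <- rowSums(cnt1); n0 <- rowSums(cnt0); n <- n1 + n0
  tot_class <- cnt1[1, ] + cnt0[1, ]  # identical across candidates
  stat <- numeric(nrow(cnt1))
  for (k in which(tot_class > 0)) {
    e1 <- n1 * tot_class[k] / n
    e0 <- n0 * tot_class[k] / n
    stat <- stat + ifelse(e1 > 0, (cnt1[, k] - e1)^2 / e1, 0) +
      ifelse(e0 > 0, (cnt0[, k] - e0)^2 / e0, 0)
  }
  df <- max(sum(tot_class > 0) - 1L, 1L)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Grow a gain-ratio decision tree on binary predictors
#'
#' At each node the predictor maximising the gain ratio (among predictors
#' whose gain is positive and at least the node-average positive gain, the
#' classic C4.5 eligibility rule) is chosen; ties go to the lowest column
#' index, so growth is deterministic.  Growth stops at a node when it is
#' pure, fewer than `2 * min_cases` samples remain, no unused predictor
#' has positive gain, a child would fall below `min_cases`, or the chosen
#' split fails the Bonferroni-adjusted significance guard (see
#' [c5rules]).
#'
#' @param data List with `X` (n x p 0/1 matrix, column names required) and
#'   `labels` (factor of length n).
#' @param min_cases Minimum samples per child (default 2, the C4.5 default).
#' @param sig_level Family-wise significance level of the per-node split
#'   guard; `1` disables it.
#' @param seed Unused except as a documented fallback for tie-breaking;
#'   ties are resolved deterministically by column order.
#' @return A nested tree: leaves are `list(type = "leaf", class_counts)`;
#'   internal nodes add `split_predictor` and `children` (`"0"`/`"1"`).
#' @export
grow_tree <- function(data, min_cases = 2L, sig_level = 0.01, seed = NULL) {
  X <- data$X
  labels <- data$labels
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(labels))
  if (!is.factor(labels)) labels <- factor(labels)
  storage.mode(X) <- "double"
  ind <- stats::model.matrix(~ lab - 1, data.frame(lab = labels))
  colnames(ind) <- levels(labels)
  grow_node(X, ind, seq_len(nrow(X)), seq_len(ncol(X)), min_cases, sig_level)
}

grow_node <- function(X, ind, idx, avail, min_cases, sig_level) {
  counts <- colSums(ind[idx, , drop = FALSE])
  names(counts) <- colnames(ind)
  leaf <- list(type = "leaf", class_counts = counts)
  n <- length(idx)
  if (sum(counts > 0) <= 1L || n < 2L * min_cases || !length(avail)) return(leaf)
  Xs <- X[idx, avail, drop = FALSE]
  cnt1 <- crossprod(Xs, ind[idx, , drop = FALSE])  # p_avail x m counts in child "1"
  cnt0 <- matrix(counts, nrow(cnt1), ncol(cnt1), byrow = TRUE) - cnt1
  n1 <- rowSums(cnt1); n0 <- n - n1
  H_parent <- entropy(counts)
  info_after <- (n1 / n) * ent_rows(cnt1) + (n0 / n) * ent_rows(cnt0)
  gain <- H_parent - info_after
  p1 <- n1 / n
  split_info <- ifelse(p1 > 0 & p1 < 1,
                       -(p1 * log2(p1) + (1 - p1) * log2(1 - p1)), 0)
  valid <- gain > 1e-12 & n1 >= min_cases & n0 >= min_cases & split_info > 0
  if (!any(valid)) return(leaf)
  if (sig_level < 1) {
    # candidate screen: only splits significant after Bonferroni adjustment
    # for the number of predictors examined at this node may compete
    p_scr <- chisq_p_rows(cnt1, cnt0)
    valid <- valid & (p_scr * length(avail) <= sig_level)
    if (!any(valid)) return(leaf)
  }
  avg_gain <- mean(gain[valid])
  eligible <- valid & gain >= avg_gain - 1e-12
  ratio <- ifelse(eligible, gain / split_info, -Inf)
  best <- which.max(ratio)  # ties -> lowest column index
  if (sig_level < 1) {
    # confirm the chosen split with the exact test (the screen is a
    # chi-square approximation)
    tab <- rbind(cnt0[best, ], cnt1[best, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    p_adj <- split_p_value(tab) * length(avail)
    if (!is.finite(p_adj) || p_adj > sig_level) return(leaf)
  }
  col <- avail[best]
  in1 <- X[idx, col] == 1
  list(
    type = "split",
    split_predictor = colnames(X)[col],
    class_counts = counts,
    children = list(
      "0" = grow_node(X, ind, idx[!in1], setdiff(avail, col), min_cases, sig_level),
      "1" = grow_node(X, ind, idx[in1], setdiff(avail, col), min_cases, sig_level)
    )
  )
}

#' Collapse a tree into a ruleset
#'
#' One conjunctive rule per leaf, conditions in root-to-leaf order, each
#' predicting the leaf's majority class; the default class is the majority
#' class at the root.  A single-leaf tree yields an empty rule list (the
#' "no tree constructed" outcome).
#'
#' @param tree A tree from [grow_tree()].
#' @return A `c5_ruleset`: list with `rules`, `default_class`, `classes`.
#' @export
tree_to_rules <- function(tree) {
  classes <- names(tree$class_counts)
  default_class <- classes[which.max(tree$class_counts)]
  rules <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      if (nrow(conds) > 0L) {
        cls <- classes[which.max(node$class_counts)]
        cover <- sum(node$class_counts)
        errors <- cover - max(node$class_counts)
        rules[[length(rules) + 1L]] <<- list(
          conditions = conds, predicted_class = cls,
          cover = cover, errors = errors,
          pessimistic_error = NA_real_
        )
      }
      return(invisible())
    }
    for (v in c("0", "1")) {
      walk(node$children[[v]],
           rbind(conds, data.frame(predictor = node$split_predictor,
                                   value = as.integer(v),
                                   stringsAsFactors = FALSE)))
    }
  }
  walk(tree, data.frame(predictor = character(), value = integer(),
                        stringsAsFactors = FALSE))
  structure(list(rules = rules, default_class = default_class,
                 classes = classes),
            class = "c5_ruleset")
}

#' Upper confidence bound on a binomial error rate
#'
#' The Clopper-Pearson-style upper bound at confidence `cf` used as the
#' pessimistic error of a rule with `errors` mistakes over `cover` covered
#' cases: the largest error rate under which observing at most `errors`
#' mistakes still has probability `cf`.  For zero errors this is
#' `1 - cf^(1/cover)`.
#'
#' @param errors,cover Error and cover counts (`cover >= errors >= 0`).
#' @param cf Confidence level of the bound (C4.5 default 0.25).
#' @return Pessimistic error rate in `[0, 1]`.
#' @export
pessimistic_error <- function(errors, cover, cf = 0.25) {
  stopifnot(all(cover >= errors), all(errors >= 0))
  ifelse(cover == 0, 1,
         ifelse(errors >= cover, 1, stats::qbeta(1 - cf, errors + 1, cover - errors)))
}

rule_stats <- function(conds, X, ind, cls) {
  match <- rep(TRUE, nrow(X))
  for (k in seq_len(nrow(conds))) {
    match <- match & (X[, conds$predictor[k]] == conds$value[k])
  }
  cover <- sum(match)
  errors <- cover - sum(ind[match, cls])
  list(cover = cover, errors = errors)
}

#' Pessimistic pruning of a ruleset
#'
#' Each rule is generalised greedily: a condition is deleted whenever the
#' rule's pessimistic error ([pessimistic_error()]) does not increase.
#' Rules whose pessimistic error is not below that of the default class,
#' rules reduced to zero conditions, and duplicate rules are dropped.
#'
#' @param ruleset A `c5_ruleset` from [tree_to_rules()].
#' @param data The training data (list with `X`, `labels`) the ruleset was
#'   derived from.
#' @param cf Confidence level of the pessimistic bound (default 0.25).
#' @return The pruned `c5_ruleset`, with per-rule `cover`, `errors` and
#'   `pessimistic_error` recomputed on `data`.
#' @export
prune_rules <- function(ruleset, data, cf = 0.25) {
  X <- data$X
  labels <- factor(data$labels, levels = ruleset$classes)
  ind <- stats::model.matrix(~ lab - 1, data.frame(lab = labels))
  colnames(ind) <- ruleset$classes
  n <- nrow(X)
  def_errors <- n - max(colSums(ind))
  def_pess <- pessimistic_error(def_errors, n, cf)

  pruned <- list()
  for (rule in ruleset$rules) {
    conds <- rule$conditions
    st <- rule_stats(conds, X, ind, rule$predicted_class)
    pess <- pessimistic_error(st$errors, st$cover, cf)
    repeat {
      if (nrow(conds) == 0L) break
      cand_pess <- rep(Inf, nrow(conds))
      cand_st <- vector("list", nrow(conds))
      for (k in seq_len(nrow(conds))) {
        st_k <- rule_stats(conds[-k, , drop = FALSE], X, ind, rule$predicted_class)
        cand_st[[k]] <- st_k
        cand_pess[k] <- pessimistic_error(st_k$errors, st_k$cover, cf)
      }
      best <- which.min(cand_pess)
      if (cand_pess[best] <= pess + 1e-12) {
        conds <- conds[-best, , drop = FALSE]
        st <- cand_st[[best]]
        pess <- cand_pess[best]
      } else break
    }
    if (nrow(conds) == 0L) next        # generalised away: it is the default
    if (pess >= def_pess) next         # no better than predicting the default
    pruned[[length(pruned) + 1L]] <- list(
      conditions = conds, predicted_class = rule$predicted_class,
      cover = st$cover, errors = st$errors, pessimistic_error = pess
    )
  }
  # merge duplicates (same conditions as a set, same class)
  if (length(pruned) > 1L) {
    sig <- vapply(pruned, function(r) {
      o <- order(r$conditions$predictor, r$conditions$value)
      paste(r$predicted_class,
            paste(r$conditions$predictor[o], r$conditions$value[o],
                  sep = "=", collapse = "&"), sep = ":")
    }, character(1))
    pruned <- pruned[!duplicated(sig)]
  }
  ruleset$rules <- pruned
  ruleset
}

#' Did the learner construct a tree?
#'
#' Detection (the type-I accounting unit) means the pruned ruleset contains
#' at least one rule with at least one condition.
#'
#' @param ruleset A `c5_ruleset`.
#' @return Logical flag.
#' @export
ruleset_detected <- function(ruleset) {
  any(vapply(ruleset$rules, function(r) nrow(r$conditions) >= 1L, logical(1)))
}

#' Predict classes by rule voting
#'
#' Every rule matching a row votes for its class with weight
#' `cover - errors + 1`; the class with the highest vote total wins.  Rows
#' matched by no rule, and vote ties, get the default class.
#'
#' @param object A `c5_ruleset`.
#' @param newdata An n x p 0/1 matrix with the training predictor columns,
#'   or a `binary_encoding`.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.c5_ruleset <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "binary_encoding")) newdata$values else newdata
  n <- nrow(X)
  votes <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (rule in object$rules) {
    match <- rep(TRUE, n)
    for (k in seq_len(nrow(rule$conditions))) {
      match <- match & (X[, rule$conditions$predictor[k]] == rule$conditions$value[k])
    }
    w <- rule$cover - rule$errors + 1
    votes[match, rule$predicted_class] <- votes[match, rule$predicted_class] + w
  }
  top <- max.col(votes, ties.method = "first")
  best <- votes[cbind(seq_len(n), top)]
  n_at_max <- rowSums(votes == best)
  out <- object$classes[top]
  out[best == 0 | n_at_max > 1L] <- object$default_class
  factor(out, levels = object$classes)
}

#' SNPs used by a ruleset
#'
#' Union, over all rules, of the SNP identities behind each condition's
#' predictor column; the dominant and recessive columns of one SNP map to
#' the same id.
#'
#' @param ruleset A `c5_ruleset`.
#' @param encoding The `binary_encoding` whose columns the ruleset uses.
#' @return Character vector of snp_ids (empty for an empty ruleset).
#' @export
c5_selected_snps <- function(ruleset, encoding) {
  preds <- unique(unlist(lapply(ruleset$rules, function(r) r$conditions$predictor)))
  if (!length(preds)) return(character())
  j <- match(preds, encoding$columns$col_id)
  if (anyNA(j)) stop("unknown predictor column: ", preds[which(is.na(j))[1]])
  unique(encoding$columns$snp_id[j])
}

#' Fit the rule learner end to end
#'
#' Grows the tree, collapses it to rules and applies pessimistic pruning.
#'
#' @param encoding A complete `binary_encoding` (see [dichotomize()],
#'   [impute_median()]).
#' @param labels Class factor (e.g. from [discretize_outcome()]).
#' @param min_cases,cf,sig_level See [grow_tree()] and [prune_rules()].
#' @return A pruned `c5_ruleset`.
#' @export
c5_fit <- function(encoding, labels, min_cases = 2L, cf = 0.25, sig_level = 0.01) {
  X <- encoding$values
  if (anyNA(X)) stop("encoding contains missing values; impute first")
  data <- list(X = X, labels = labels)
  tree <- grow_tree(data, min_cases = min_cases, sig_level = sig_level)
  prune_rules(tree_to_rules(tree), data, cf = cf)
}

#' Serialise a ruleset to JSON
#'
#' @param ruleset A `c5_ruleset`.
#' @param encoding Optional `binary_encoding` used to annotate conditions
#'   with snp_id and dominant/recessive mode.
#' @return A JSON string (deterministic for identical rulesets).
#' @export
ruleset_to_json <- function(ruleset, encoding = NULL) {
  rules <- lapply(ruleset$rules, function(r) {
    conds <- r$conditions
    if (!is.null(encoding)) {
      j <- match(conds$predictor, encoding$columns$col_id)
      conds$snp_id <- encoding$columns$snp_id[j]
      conds$mode <- encoding$columns$mode[j]
    }
    list(conditions = conds, class = r$predicted_class, cover = r$cover,
         errors = r$errors,
         pessimistic_error = round(r$pessimistic_error, 10),
         vote_weight = r$cover - r$errors + 1)
  })
  jsonlite::toJSON(list(rules = rules, default_class = ruleset$default_class,
                        classes = ruleset$classes),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
print.c5_ruleset <- function(x, ...) {
  cat(sprintf("c5_ruleset: %d rule(s), default class '%s'\n",
              length(x$rules), x$default_class))
  for (r in x$rules) {
    cat(sprintf("  IF %s THEN %s  (cover %d, errors %d, pess %.3f)\n",
                paste(r$conditions$predictor, "=", r$conditions$value,
                      collapse = " & "),
                r$predicted_class, r$cover, r$errors, r$pessimistic_error))
  }
  invisible(x)
}
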