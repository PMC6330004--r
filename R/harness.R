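#' Study harness: replicate-level power and type I error estimation
#'
#' [run_condition()] generates a genotype panel once, then per replicate
#' draws causal SNPs from the high-MAF pool, simulates the phenotype, runs
#' the requested learner and records a replicate outcome; the aggregate is
#' a power summary.  Power for the rule learner is the fraction of
#' replicates whose pruned ruleset contains every interacting SNP; for
#' logic regression a replicate counts only if it also passes the
#' randomisation test.  Type I error is the fraction of null replicates
#' with any detection (a non-empty ruleset, or a passed randomisation
#' test).
#'
#' @name evalharness
NULL

#' Configuration of one study condition
#'
#' @param method `"c5"` or `"logicreg"`.
#' @param model `"null"`, `"polygenic"`, `"2snp"`, `"3snp"`, or
#'   `"main_effect"`.
#' @param level Interaction preset level (2snp: weak/intermediate/strong;
#'   3snp: weak/strong/pure); ignored otherwise.
#' @param polygenic Add the 200-SNP polygenic background to an interaction
#'   or main-effect model?
#' @param ld_condition `"pruned"` (linkage-equilibrium panel) or
#'   `"unpruned"` (block-LD panel; a qualitative stand-in for real LD).
#' @param n_individuals,n_snps Panel dimensions (desk-scale defaults 5000 x
#'   500).
#' @param n_reps Replicates (the full study uses 500 per condition).
#' @param seed Master seed; every panel, causal draw, phenotype and fit
#'   seed derives from it.
#' @param n_polygenic Number of polygenic SNPs (default 200).
#' @param maf_range MAF sampling range of the panel.
#' @param causal_maf Causal-pool MAF band (default 0.4-0.5).
#' @param fix_causals Draw the causal SNPs once per condition (the original
#'   design) instead of redrawing per replicate (default FALSE: redrawing
#'   averages over the arbitrary draw).
#' @param block_len,rho Block-LD parameters for the unpruned condition.
#' @param c5_control List of [c5_fit()] arguments (min_cases, cf, sig_level).
#' @param lr_control List with `max_leaves`, `max_iterations`, `n_perm`,
#'   `alpha` for the logic-regression stage.
#' @return A `condition_config` list.
#' @export
condition_config <- function(method = c("c5", "logicreg"),
                             model = c("null", "polygenic", "2snp", "3snp", "main_effect"),
                             level = NULL, polygenic = FALSE,
                             ld_condition = c("pruned", "unpruned"),
                             n_individuals = 5000L, n_snps = 500L,
                             n_reps = 100L, seed = 1L,
                             n_polygenic = 200L,
                             maf_range = c(0.01, 0.5),
                             causal_maf = c(0.4, 0.5),
                             fix_causals = FALSE,
                             block_len = 10L, rho = 0.9,
                             c5_control = list(),
                             lr_control = list()) {
  method <- match.arg(method)
  model <- match.arg(model)
  ld_condition <- match.arg(ld_condition)
  if (model %in% c("2snp", "3snp")) {
    interaction_preset(as.integer(substr(model, 1, 1)), level)  # validates the preset
  }
  structure(as.list(environment()), class = "condition_config")
}

condition_label <- function(config) {
  paste0(config$method, ":", config$model,
         if (!is.null(config$level)) paste0("_", config$level) else "",
         if (config$polygenic) "+polygenic" else "",
         ":", config$ld_condition)
}

#' Replicate outcome for the rule learner
#'
#' Detection means the pruned ruleset has at least one rule with a
#' condition; success-for-power additionally requires every interacting
#' SNP to appear in the ruleset.
#'
#' @param ruleset A `c5_ruleset` fitted on the replicate.
#' @param truth The `truth` element of the `phenotype_replicate`.
#' @param encoding The `binary_encoding` used.
#' @return A `replicate_outcome` list.
#' @export
c5_outcome <- function(ruleset, truth, encoding) {
  selected <- c5_selected_snps(ruleset, encoding)
  detected <- ruleset_detected(ruleset)
  new_outcome(detected, selected, truth)
}

#' Replicate outcome for logic regression
#'
#' Detection is the randomisation-test verdict; success-for-power requires
#' the verdict AND every interacting SNP among the model's leaves.
#'
#' @param model The fitted `logic_model`.
#' @param randtest The `rand_test` result for the replicate.
#' @param truth The `truth` element of the `phenotype_replicate`.
#' @param encoding The `binary_encoding` used.
#' @return A `replicate_outcome` list.
#' @export
logicreg_outcome <- function(model, randtest, truth, encoding) {
  selected <- logic_selected_snps(model, encoding)
  new_outcome(randtest$passed, selected, truth)
}

new_outcome <- function(detected, selected, truth) {
  n_int <- length(truth$interacting)
  structure(list(
    detected = detected,
    selected = selected,
    truth = truth,
    n_truth_recovered = length(intersect(selected, truth$interacting)),
    success = detected && n_int > 0L && all(truth$interacting %in% selected)
  ), class = "replicate_outcome")
}

#' Classify selected non-causal SNPs as LD-linked or spurious
#'
#' Each selected SNP that is not itself causal is `in_ld` when its maximum
#' r-squared against any causal SNP exceeds `r2_threshold` (0.25, chosen
#' for consistency with the LD-pruning threshold), otherwise spurious.
#'
#' @param selected Character vector of selected snp_ids.
#' @param truth Truth list (interacting, polygenic, main_effect ids).
#' @param G The [genotype_matrix] of the panel.
#' @param r2_threshold LD threshold (default 0.25).
#' @return List with `n_true`, `n_in_ld`, `n_spurious`.
#' @export
fp_accounting <- function(selected, truth, G, r2_threshold = 0.25) {
  truth_ids <- unique(c(truth$interacting, truth$polygenic, truth$main_effect))
  n_true <- length(intersect(selected, truth_ids))
  extra <- setdiff(selected, truth_ids)
  n_in_ld <- 0L
  for (s in extra) {
    r2s <- vapply(truth_ids, function(t) genotype_r2(G, s, t), numeric(1))
    if (length(r2s) && max(r2s) > r2_threshold) n_in_ld <- n_in_ld + 1L
  }
  list(n_true = n_true, n_in_ld = n_in_ld,
       n_spurious = length(extra) - n_in_ld)
}

draw_causals <- function(pool, config, rep_seed) {
  set.seed(derive_seed(rep_seed, 5L))
  poly_ids <- character()
  if (config$model == "polygenic" || config$polygenic) {
    if (length(pool) < config$n_polygenic + 3L) {
      stop("causal pool too small for the polygenic component")
    }
    poly_ids <- sample(pool, config$n_polygenic)
  }
  rest <- setdiff(pool, poly_ids)
  k <- switch(config$model, "2snp" = 2L, "3snp" = 3L, "main_effect" = 2L, 0L)
  int_ids <- if (k > 0L) sample(rest, k) else character()
  list(polygenic = poly_ids, interacting = int_ids)
}

simulate_condition_phenotype <- function(G, config, causals, rep_seed) {
  switch(config$model,
    null = simulate_null(G, rep_seed),
    polygenic = simulate_polygenic(
      G, polygenic_spec(causals$polygenic), rep_seed),
    main_effect = {
      rep <- simulate_main_effect(G, causals$interacting, rep_seed)
      if (config$polygenic) {
        # main effects + polygenic background share one noise draw
        pg <- polygenic_signal(G, polygenic_spec(causals$polygenic))
        rep$y <- rep$y + pg
        rep$truth$polygenic <- causals$polygenic
      }
      rep
    },
    {
      spec <- effect_spec(causals$interacting, level = config$level)
      if (config$polygenic) {
        simulate_combined(G, polygenic_spec(causals$polygenic), spec, rep_seed)
      } else {
        simulate_interaction(G, spec, rep_seed)
      }
    }
  )
}

#' Run one study condition
#'
#' Generates (or accepts) the panel, runs all replicates and aggregates
#' them; fully reproducible from the master seed.  A learner failure on a
#' replicate is recorded, not fatal.
#'
#' @param config A [condition_config()].
#' @param G Optional pre-built [genotype_matrix] (shared across conditions);
#'   generated from the config when `NULL`.
#' @param verbose Print per-replicate progress?
#' @return A `power_summary` (see [summarize_outcomes()]), with the
#'   replicate outcomes attached as `$outcomes`.
#' @export
run_condition <- function(config, G = NULL, verbose = FALSE) {
  if (is.null(G)) {
    panel <- snp_panel(config$n_snps, maf_range = config$maf_range,
                       seed = derive_seed(config$seed, 1L))
    ld <- if (config$ld_condition == "pruned") {
      ld_spec("linkage_equilibrium")
    } else {
      ld_spec("blocks", block_len = config$block_len, rho = config$rho)
    }
    G <- generate_genotypes(config$n_individuals, panel, ld,
                            seed = derive_seed(config$seed, 2L))
  }
  encoding <- dichotomize(G)
  need_pool <- config$model != "null"
  pool <- if (need_pool) {
    select_causal_pool(G, config$causal_maf[1], config$causal_maf[2])
  } else character()
  causals0 <- if (need_pool && config$fix_causals) {
    draw_causals(pool, config, derive_seed(config$seed, 10000L))
  } else NULL
  outcomes <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    rep_seed <- derive_seed(config$seed, 10000L + r)
    outcomes[[r]] <- tryCatch({
      causals <- if (need_pool) {
        if (config$fix_causals) causals0 else draw_causals(pool, config, rep_seed)
      } else list(polygenic = character(), interacting = character())
      rep <- simulate_condition_phenotype(G, config, causals, rep_seed)
      if (config$method == "c5") {
        ctl <- utils::modifyList(list(min_cases = 2L, cf = 0.25, sig_level = 0.01),
                                 config$c5_control)
        labels <- discretize_outcome(rep$y)
        rs <- c5_fit(encoding, labels, min_cases = ctl$min_cases,
                     cf = ctl$cf, sig_level = ctl$sig_level)
        c5_outcome(rs, rep$truth, encoding)
      } else {
        ctl <- utils::modifyList(list(max_leaves = 8L, max_iterations = 25L,
                                      n_perm = 100L, alpha = 0.05),
                                 config$lr_control)
        params <- fit_params(n_trees = 1L, max_leaves = ctl$max_leaves,
                             max_iterations = ctl$max_iterations,
                             seed = derive_seed(rep_seed, 9L))
        rt <- randomization_test(encoding, rep$y, params,
                                 n_perm = ctl$n_perm, alpha = ctl$alpha)
        logicreg_outcome(rt$model, rt, rep$truth, encoding)
      }
    }, error = function(e) {
      structure(list(detected = NA, selected = character(),
                     truth = NULL, n_truth_recovered = NA_integer_,
                     success = NA, error = conditionMessage(e)),
                class = "replicate_outcome")
    })
    if (verbose) {
      message(sprintf("[%s] replicate %d/%d: detected=%s",
                      condition_label(config), r, config$n_reps,
                      outcomes[[r]]$detected))
    }
  }
  summ <- summarize_outcomes(outcomes, config)
  summ$outcomes <- outcomes
  summ
}

#' Aggregate replicate outcomes into a power summary
#'
#' Power and type I error are exact functions of the persisted outcomes, so
#' a summary can be recomputed without re-running any learner.
#'
#' @param outcomes List of `replicate_outcome`s.
#' @param config The generating [condition_config()].
#' @return A `power_summary`: percentages, the recovery histogram (counts
#'   of replicates by number of interacting SNPs recovered), and failures.
#' @export
summarize_outcomes <- function(outcomes, config) {
  ok <- vapply(outcomes, function(o) is.null(o$error), logical(1))
  det <- vapply(outcomes[ok], function(o) isTRUE(o$detected), logical(1))
  suc <- vapply(outcomes[ok], function(o) isTRUE(o$success), logical(1))
  rec <- vapply(outcomes[ok], function(o) o$n_truth_recovered, integer(1))
  n_int <- switch(config$model, "2snp" = 2L, "3snp" = 3L, 0L)
  hist <- table(factor(rec, levels = 0:max(n_int, 0L)))
  structure(list(
    condition = condition_label(config),
    config = config,
    n_reps = length(outcomes),
    n_failed = sum(!ok),
    detected_pct = 100 * mean(det),
    power_pct = 100 * mean(suc),
    type1_pct = if (config$model == "null") 100 * mean(det) else NA_real_,
    recovery_counts = as.integer(hist),
    recovery_levels = as.integer(names(hist))
  ), class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("power_summary [%s]: %d reps, detected %.1f%%, power %.1f%%%s\n",
              x$condition, x$n_reps, x$detected_pct, x$power_pct,
              if (!is.na(x$type1_pct)) sprintf(", type I %.1f%%", x$type1_pct) else ""))
  invisible(x)
}

#' Write study tables
#'
#' Writes a TSV with one row per condition (percentages to one decimal), a
#' JSON file with the full summaries including recovery histograms, and
#' returns the paths.  Output is deterministic for identical summaries.
#'
#' @param summaries List of `power_summary` objects.
#' @param path Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
report <- function(summaries, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    condition = vapply(summaries, function(s) s$condition, character(1)),
    n_reps = vapply(summaries, function(s) s$n_reps, numeric(1)),
    detected_pct = sprintf("%.1f", vapply(summaries, function(s) s$detected_pct, numeric(1))),
    power_pct = sprintf("%.1f", vapply(summaries, function(s) s$power_pct, numeric(1))),
    type1_pct = ifelse(
      vapply(summaries, function(s) is.na(s$type1_pct), logical(1)), "",
      sprintf("%.1f", vapply(summaries, function(s) s$type1_pct, numeric(1)))),
    n_failed = vapply(summaries, function(s) s$n_failed, numeric(1)),
    stringsAsFactors = FALSE
  )
  tsv <- file.path(path, "summary.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(path, "summary.json")
  payload <- lapply(summaries, function(s) {
    s$outcomes <- NULL
    s$config <- s$config[c("method", "model", "level", "polygenic", "ld_condition",
                           "n_individuals", "n_snps", "n_reps", "seed")]
    unclass(s)
  })
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = js))
}
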