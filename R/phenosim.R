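#' Phenotype simulation specs
#'
#' Quantitative phenotypes are simulated as linear combinations of additive
#' genotype codes (and their products, for interaction models) plus
#' standard-normal noise:
#'
#' * polygenic: y = sum_j beta_j g_j + eps over 200 SNPs, each contributing
#'   the same variance share (per-SNP R^2 = 1.5e-3, total 0.3);
#' * 2-SNP interaction: y = b1 g1 + b2 g2 + b3 g1 g2 + eps;
#' * 3-SNP interaction: y = mains + all pairwise products + triple product
#'   + eps;
#' * combined: polygenic + interaction signal with a single shared eps;
#' * null: y = eps; main-effect: two mains at beta = 0.2 and no interaction.
#'
#' Interaction regressors are products of the unstandardised 0/1/2 codes;
#' the same symbols carry the main effects.
#'
#' @name phenosim
NULL

#' Named coefficient presets for the interaction models
#'
#' Three strengths of the 2-SNP model (`strong`, `intermediate`, `weak`)
#' and three of the 3-SNP model (`pure`, `strong`, `weak`).  The 2-SNP
#' levels set (b1 = b2, b3) to (0.2, 0.24), (0.125, 0.15), (0.07, 0.09).
#' The 3-SNP levels set (mains, pairs, triple) to (0, 0, 0.4) for `pure`,
#' (0.05, 0.1, 0.2) for `strong` and half that for `weak`.
#'
#' @param order 2 or 3 (number of interacting SNPs).
#' @param level Preset name.
#' @return List with elements `main`, `pair`, `triple` (per-term betas).
#' @export
interaction_preset <- function(order, level) {
  key <- paste0(order, ":", level)
  presets <- list(
    "2:strong" = list(main = c(0.2, 0.2), pair = 0.24, triple = numeric()),
    "2:intermediate" = list(main = c(0.125, 0.125), pair = 0.15, triple = numeric()),
    "2:weak" = list(main = c(0.07, 0.07), pair = 0.09, triple = numeric()),
    "3:pure" = list(main = c(0, 0, 0), pair = c(0, 0, 0), triple = 0.4),
    "3:strong" = list(main = c(0.05, 0.05, 0.05), pair = c(0.1, 0.1, 0.1), triple = 0.2),
    "3:weak" = list(main = c(0.025, 0.025, 0.025), pair = c(0.05, 0.05, 0.05), triple = 0.1)
  )
  if (is.null(presets[[key]])) {
    stop("unknown preset '", key, "'; available: ", paste(names(presets), collapse = ", "))
  }
  presets[[key]]
}

#' Interaction effect specification
#'
#' @param snp_ids Two or three SNP identifiers carrying the interaction.
#' @param level Preset name passed to [interaction_preset()]; ignored when
#'   `betas` is given.
#' @param betas Optional explicit list with elements `main`, `pair`,
#'   `triple` (betas per term; pairs ordered (1,2), (1,3), (2,3)).
#' @param noise_sd Standard deviation of the noise term (default 1).
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(snp_ids, level = NULL, betas = NULL, noise_sd = 1) {
  stopifnot(length(snp_ids) %in% c(2L, 3L), !anyDuplicated(snp_ids), noise_sd > 0)
  if (is.null(betas)) betas <- interaction_preset(length(snp_ids), level)
  k <- length(snp_ids)
  pairs <- if (k == 2L) list(c(1L, 2L)) else list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  stopifnot(length(betas$main) == k, length(betas$pair) == length(pairs))
  structure(list(
    snp_ids = snp_ids,
    main = betas$main,
    pair = betas$pair,
    pair_idx = pairs,
    triple = if (k == 3L) betas$triple else numeric(),
    noise_sd = noise_sd,
    level = level
  ), class = "effect_spec")
}

#' Polygenic effect specification
#'
#' @param snp_ids SNPs forming the polygenic component (the study uses 200).
#' @param per_snp_r2 Variance fraction each SNP explains (default 1.5e-3).
#' @param noise_sd Noise standard deviation (default 1).
#' @return A `polygenic_spec` object; total R^2 is `per_snp_r2 *
#'   length(snp_ids)` and must be < 1.
#' @export
polygenic_spec <- function(snp_ids, per_snp_r2 = 1.5e-3, noise_sd = 1) {
  total <- per_snp_r2 * length(snp_ids)
  if (total >= 1) stop("total R^2 = ", total, " must be < 1")
  structure(list(snp_ids = snp_ids, per_snp_r2 = per_snp_r2,
                 total_r2 = total, noise_sd = noise_sd),
            class = "polygenic_spec")
}

#' Per-SNP betas that fix each SNP's variance share
#'
#' With unstandardised HWE genotypes, Var(g_j) = 2 maf_j (1 - maf_j).  To
#' give each SNP the variance share `per_snp_r2` of a phenotype with total
#' variance sigma_y^2 = noise_sd^2 / (1 - total R^2), the coefficient is
#' beta_j = sqrt(per_snp_r2 * sigma_y^2 / Var(g_j)).
#'
#' @param mafs Minor allele frequencies of the polygenic SNPs.
#' @param per_snp_r2 Variance share per SNP.
#' @param noise_sd Noise standard deviation.
#' @return Numeric vector of betas on the allele-count scale.
#' @export
polygenic_betas <- function(mafs, per_snp_r2 = 1.5e-3, noise_sd = 1) {
  total <- per_snp_r2 * length(mafs)
  if (total >= 1) stop("total R^2 = ", total, " must be < 1")
  if (per_snp_r2 == 0) return(rep(0, length(mafs)))
  var_y <- noise_sd^2 / (1 - total)
  sqrt(per_snp_r2 * var_y / (2 * mafs * (1 - mafs)))
}

new_replicate <- function(y, model, interacting = character(),
                          polygenic = character(), main_effect = character(),
                          betas = NULL, seed = NA_integer_) {
  structure(list(
    y = as.numeric(y),
    truth = list(model = model, interacting = interacting,
                 polygenic = polygenic, main_effect = main_effect,
                 betas = betas),
    seed = seed
  ), class = "phenotype_replicate")
}

#' @export
print.phenotype_replicate <- function(x, ...) {
  cat(sprintf("phenotype_replicate: model=%s, n=%d, %d interacting / %d polygenic SNPs\n",
              x$truth$model, length(x$y), length(x$truth$interacting),
              length(x$truth$polygenic)))
  invisible(x)
}

geno_cols <- function(G, snp_ids) {
  j <- match(snp_ids, G$snps$snp_id)
  if (anyNA(j)) stop("unknown snp_id: ", snp_ids[which(is.na(j))[1]])
  v <- G$values[, j, drop = FALSE]
  if (anyNA(v)) stop("phenotype simulation requires complete genotypes; impute first")
  storage.mode(v) <- "double"
  v
}

interaction_signal <- function(G, spec) {
  g <- geno_cols(G, spec$snp_ids)
  sig <- as.vector(g %*% spec$main)
  for (t in seq_along(spec$pair_idx)) {
    ij <- spec$pair_idx[[t]]
    sig <- sig + spec$pair[t] * g[, ij[1]] * g[, ij[2]]
  }
  if (length(spec$triple)) sig <- sig + spec$triple * g[, 1] * g[, 2] * g[, 3]
  sig
}

polygenic_signal <- function(G, spec) {
  g <- geno_cols(G, spec$snp_ids)
  mafs <- colMeans(g) / 2
  betas <- polygenic_betas(mafs, spec$per_snp_r2, spec$noise_sd)
  as.vector(g %*% betas)
}

# every simulator draws its noise from the same derived stream so that
# degenerate specs reproduce each other exactly at equal seeds
sim_noise <- function(n, noise_sd, seed) {
  set.seed(derive_seed(seed, 303L))
  stats::rnorm(n, 0, noise_sd)
}

#' Simulate a polygenic phenotype
#'
#' y is the sum of per-SNP additive contributions (betas from
#' [polygenic_betas()], computed from the observed MAFs so each SNP's
#' expected variance share is exactly `per_snp_r2`) plus N(0, noise_sd^2)
#' noise.
#'
#' @param G A complete [genotype_matrix].
#' @param spec A [polygenic_spec()].
#' @param seed Seed; the draw is deterministic given it.
#' @return A `phenotype_replicate`.
#' @export
simulate_polygenic <- function(G, spec, seed) {
  sig <- polygenic_signal(G, spec)
  y <- sig + sim_noise(length(sig), spec$noise_sd, seed)
  new_replicate(y, "polygenic", polygenic = spec$snp_ids, seed = seed)
}

#' Simulate a 2- or 3-SNP interaction phenotype
#'
#' @param G A complete [genotype_matrix].
#' @param spec An [effect_spec()].
#' @param seed Seed.
#' @return A `phenotype_replicate`.
#' @export
simulate_interaction <- function(G, spec, seed) {
  sig <- interaction_signal(G, spec)
  y <- sig + sim_noise(length(sig), spec$noise_sd, seed)
  model <- paste0(length(spec$snp_ids), "snp",
                  if (!is.null(spec$level)) paste0("_", spec$level) else "")
  new_replicate(y, model, interacting = spec$snp_ids,
                betas = spec[c("main", "pair", "triple")], seed = seed)
}

#' Simulate a combined polygenic + interaction phenotype
#'
#' The two signals are added and a single noise draw is applied (two
#' separate draws would deflate the stated variance shares).  The causal
#' sets must be disjoint.
#'
#' @param G A complete [genotype_matrix].
#' @param pspec A [polygenic_spec()].
#' @param ispec An [effect_spec()].
#' @param seed Seed.
#' @return A `phenotype_replicate`.
#' @export
simulate_combined <- function(G, pspec, ispec, seed) {
  if (length(intersect(pspec$snp_ids, ispec$snp_ids))) {
    stop("polygenic and interaction causal sets must be disjoint")
  }
  if (!isTRUE(all.equal(pspec$noise_sd, ispec$noise_sd))) {
    stop("combined simulation uses a single noise term; specs disagree on noise_sd")
  }
  n <- nrow(G$values)
  sig <- (if (length(pspec$snp_ids)) polygenic_signal(G, pspec) else rep(0, n)) +
    interaction_signal(G, ispec)
  y <- sig + sim_noise(n, ispec$noise_sd, seed)
  model <- paste0("combined_", length(ispec$snp_ids), "snp",
                  if (!is.null(ispec$level)) paste0("_", ispec$level) else "")
  new_replicate(y, model, interacting = ispec$snp_ids,
                polygenic = pspec$snp_ids,
                betas = ispec[c("main", "pair", "triple")], seed = seed)
}

#' Simulate the null phenotype (y = eps)
#'
#' @param G A [genotype_matrix] (only its sample size is used).
#' @param seed Seed.
#' @param noise_sd Noise standard deviation (default 1).
#' @return A `phenotype_replicate` with empty truth sets.
#' @export
simulate_null <- function(G, seed, noise_sd = 1) {
  y <- sim_noise(nrow(G$values), noise_sd, seed)
  new_replicate(y, "null", seed = seed)
}

#' Simulate the main-effect-only control phenotype
#'
#' Two SNPs with beta = 0.2 each and no interaction term; used to check
#' that interaction detections are not driven by strong main effects.
#'
#' @param G A complete [genotype_matrix].
#' @param snp_ids The two main-effect SNPs.
#' @param seed Seed.
#' @param beta Main-effect size (default 0.2, the strong level).
#' @param noise_sd Noise standard deviation.
#' @return A `phenotype_replicate`; the SNPs are recorded as main-effect,
#'   not interacting.
#' @export
simulate_main_effect <- function(G, snp_ids, seed, beta = 0.2, noise_sd = 1) {
  stopifnot(length(snp_ids) == 2L)
  g <- geno_cols(G, snp_ids)
  y <- as.vector(g %*% c(beta, beta)) + sim_noise(nrow(g), noise_sd, seed)
  new_replicate(y, "main_effect", main_effect = snp_ids,
                betas = list(main = c(beta, beta)), seed = seed)
}

#' Spec wrapper for the main-effect control model (used by the fidelity audit)
#'
#' @param snp_ids The two main-effect SNPs.
#' @param beta Shared main-effect size.
#' @return A `main_effect_spec` object.
#' @export
main_effect_spec <- function(snp_ids, beta = 0.2) {
  stopifnot(length(snp_ids) == 2L)
  structure(list(snp_ids = snp_ids, betas = c(beta, beta)),
            class = "main_effect_spec")
}

# Design matrix of the true generating model (no intercept column; the OLS
# fit in assess_fidelity adds one).
true_model_design <- function(G, spec) {
  if (inherits(spec, "polygenic_spec")) {
    return(geno_cols(G, spec$snp_ids))
  }
  if (inherits(spec, "effect_spec")) {
    g <- geno_cols(G, spec$snp_ids)
    cols <- list()
    for (k in seq_along(spec$snp_ids)) cols[[length(cols) + 1L]] <- g[, k]
    for (ij in spec$pair_idx) cols[[length(cols) + 1L]] <- g[, ij[1]] * g[, ij[2]]
    if (length(spec$triple)) cols[[length(cols) + 1L]] <- g[, 1] * g[, 2] * g[, 3]
    return(do.call(cbind, cols))
  }
  if (inherits(spec, "main_effect_spec")) {
    return(geno_cols(G, spec$snp_ids))
  }
  stop("unsupported spec for fidelity assessment")
}

true_model_betas <- function(G, spec) {
  if (inherits(spec, "polygenic_spec")) {
    mafs <- colMeans(geno_cols(G, spec$snp_ids)) / 2
    return(polygenic_betas(mafs, spec$per_snp_r2, spec$noise_sd))
  }
  if (inherits(spec, "effect_spec")) {
    return(c(spec$main, spec$pair, spec$triple))
  }
  if (inherits(spec, "main_effect_spec")) return(spec$betas)
  stop("unsupported spec")
}

#' Bias and coverage audit of a simulator
#'
#' For each replicate the true generating linear model is refit by OLS
#' (with intercept).  Bias is the mean over replicates of the difference
#' between the estimated and true coefficient sums (intercept excluded);
#' coverage is the fraction of replicates whose 95% confidence interval for
#' the coefficient sum (linear-combination standard error, t reference)
#' contains the true sum.
#'
#' @param replicates List of `phenotype_replicate`s from the same generator.
#' @param G The [genotype_matrix] they were simulated on.
#' @param spec The generating spec ([effect_spec()], [polygenic_spec()]); for
#'   the null model pass `NULL`, in which case the audited quantity is the
#'   intercept of an intercept-only fit (true value 0).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `bias`, `coverage`, `n_reps`.
#' @export
assess_fidelity <- function(replicates, G, spec = NULL, conf_level = 0.95) {
  stopifnot(length(replicates) >= 2)
  n <- length(replicates[[1]]$y)
  if (is.null(spec)) {
    X <- matrix(1, n, 1)
    true_sum <- 0
    a <- 1
  } else {
    Xs <- true_model_design(G, spec)
    X <- cbind(1, Xs)
    true_sum <- sum(true_model_betas(G, spec))
    a <- c(0, rep(1, ncol(Xs)))
  }
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) stop("singular design in fidelity audit"))
  XtXinv <- chol2inv(R)
  avar_unit <- drop(t(a) %*% XtXinv %*% a)
  df <- n - ncol(X)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  sums <- covered <- numeric(length(replicates))
  for (r in seq_along(replicates)) {
    y <- replicates[[r]]$y
    beta <- drop(XtXinv %*% crossprod(X, y))
    res <- y - drop(X %*% beta)
    s2 <- sum(res^2) / df
    est <- sum(a * beta)
    se <- sqrt(avar_unit * s2)
    sums[r] <- est
    covered[r] <- abs(est - true_sum) <= tq * se
  }
  list(bias = mean(sums) - true_sum, coverage = mean(covered),
       n_reps = length(replicates))
}
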