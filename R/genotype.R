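#' Genotype containers and the Hardy-Weinberg genotype generator
#'
#' A `genotype_matrix` holds additive minor-allele counts (0/1/2, `NA` for
#' missing) for n individuals at m biallelic SNPs, together with per-SNP
#' metadata (identifier, chromosome label, physical position, minor allele
#' frequency).  Positions are required for window-based LD pruning.
#'
#' @name genotype_matrix
NULL

#' Build a SNP metadata panel
#'
#' Metadata for a synthetic marker panel.  MAFs are either supplied or drawn
#' uniformly from `maf_range`; positions are laid out on a uniform grid
#' (default one SNP per 2 kb) so that window arithmetic in [ld_prune()] is
#' exercised even though no real genetic map is attached.
#'
#' @param m Number of SNPs.
#' @param maf Optional numeric vector of minor allele frequencies, recycled
#'   to length `m`.  If `NULL`, drawn uniformly from `maf_range`.
#' @param maf_range Length-2 range for uniform MAF sampling, each in (0, 0.5].
#' @param spacing_bp Base pairs between adjacent SNPs on the synthetic map.
#' @param chrom Chromosome label.
#' @param seed Seed used when MAFs are sampled.
#' @return A data.frame with columns `snp_id`, `chrom`, `pos_bp`, `maf`.
#' @export
snp_panel <- function(m, maf = NULL, maf_range = c(0.01, 0.5),
                      spacing_bp = 2000L, chrom = "19", seed = 1L) {
  stopifnot(m >= 1)
  if (is.null(maf)) {
    set.seed(derive_seed(seed, 101L))
    maf <- stats::runif(m, maf_range[1], maf_range[2])
  } else {
    maf <- rep_len(maf, m)
  }
  if (any(maf <= 0 | maf > 0.5)) {
    bad <- which(maf <= 0 | maf > 0.5)[1]
    stop(sprintf("MAF outside (0, 0.5] for SNP %d (maf = %g)", bad, maf[bad]))
  }
  data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)),
    chrom = chrom,
    pos_bp = as.integer(seq_len(m)) * as.integer(spacing_bp),
    maf = maf,
    stringsAsFactors = FALSE
  )
}

new_genotype_matrix <- function(values, snps, individual_ids) {
  structure(
    list(values = values, snps = snps, individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' Validate a genotype matrix
#'
#' Checks the container invariants: all non-missing entries in {0,1,2},
#' metadata aligned with columns, strictly increasing positions within each
#' chromosome.
#'
#' @param G A `genotype_matrix`.
#' @return `G`, invisibly; stops on violation.
#' @export
validate_genotype_matrix <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$values
  if (!is.matrix(v) || nrow(v) < 1) stop("values must be a matrix with >= 1 row")
  if (ncol(v) != nrow(G$snps)) stop("SNP metadata rows must match genotype columns")
  if (length(G$individual_ids) != nrow(v)) stop("individual_ids length mismatch")
  obs <- v[!is.na(v)]
  if (length(obs) && !all(obs %in% c(0L, 1L, 2L))) {
    stop("non-missing genotype entries must be in {0, 1, 2}")
  }
  for (chr in unique(G$snps$chrom)) {
    p <- G$snps$pos_bp[G$snps$chrom == chr]
    if (any(diff(p) <= 0)) stop("pos_bp must be strictly increasing within a chromosome")
  }
  invisible(G)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d SNPs (%.1f%% missing)\n",
    nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Generate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP's genotypes are drawn from the HWE genotype distribution
#' (p^2, 2pq, q^2 for minor allele frequency q).  Under `ld$mode = "blocks"`
#' a latent Gaussian copula with AR(1) correlation `rho` inside consecutive
#' blocks of `block_len` SNPs induces linkage disequilibrium; the latent
#' normal is thresholded at the HWE genotype quantiles so the marginal
#' distribution of every SNP is unchanged.  `mode = "linkage_equilibrium"`
#' (`rho = 0`) gives independent SNPs.
#'
#' @param n Number of individuals (>= 2).
#' @param snps SNP metadata data.frame as from [snp_panel()], or a single
#'   count `m` (a default panel is then built with seed `seed`).
#' @param ld LD specification from [ld_spec()].
#' @param seed Master seed; generation is deterministic given it.
#' @param missing_rate Fraction of entries set to `NA` at random (default 0;
#'   the study's quality-control filter removes high-missingness markers
#'   before analysis, so missingness is opt-in).
#' @return A [genotype_matrix].
#' @export
generate_genotypes <- function(n, snps, ld = ld_spec("linkage_equilibrium"),
                               seed = 1L, missing_rate = 0) {
  if (length(n) != 1 || !is.finite(n) || n < 2) stop("n must be a single value >= 2")
  n <- as.integer(n)
  if (is.numeric(snps) && length(snps) == 1) snps <- snp_panel(snps, seed = seed)
  stopifnot(is.data.frame(snps), all(c("snp_id", "chrom", "pos_bp", "maf") %in% names(snps)))
  bad <- which(snps$maf <= 0 | snps$maf > 0.5)
  if (length(bad)) {
    stop(sprintf("MAF outside (0, 0.5] for SNP %s", snps$snp_id[bad[1]]))
  }
  m <- nrow(snps)
  q <- snps$maf
  set.seed(derive_seed(seed, 202L))
  if (identical(ld$mode, "linkage_equilibrium")) {
    vals <- matrix(stats::rbinom(n * m, 2L, rep(q, each = n)), nrow = n, ncol = m)
  } else {
    # latent AR(1) within blocks, thresholded at HWE quantiles
    blk <- ld$block_len
    rho <- ld$rho
    z <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
    if (m >= 2) {
      w <- sqrt(1 - rho^2)
      for (j in 2:m) {
        same_block <- ((j - 1L) %/% blk) == ((j - 2L) %/% blk)
        if (same_block) z[, j] <- rho * z[, j - 1L] + w * z[, j]
      }
    }
    # P(G=0) = (1-q)^2, P(G<=1) = 1 - q^2 under HWE
    vals <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      c0 <- stats::qnorm((1 - q[j])^2)
      c1 <- stats::qnorm(1 - q[j]^2)
      vals[, j] <- (z[, j] > c0) + (z[, j] > c1)
    }
  }
  storage.mode(vals) <- "integer"
  if (missing_rate > 0) {
    miss <- stats::runif(n * m) < missing_rate
    vals[miss] <- NA_integer_
  }
  colnames(vals) <- snps$snp_id
  G <- new_genotype_matrix(vals, snps, sprintf("ind%05d", seq_len(n)))
  validate_genotype_matrix(G)
  G
}

#' LD specification for the genotype generator
#'
#' @param mode `"linkage_equilibrium"` (independent SNPs) or `"blocks"`
#'   (AR(1) latent correlation within consecutive blocks).
#' @param block_len SNPs per block (blocks mode).
#' @param rho Latent within-block correlation in `[0, 1)`; must be 0 in
#'   linkage-equilibrium mode.
#' @return A list with class `ld_spec`.
#' @export
ld_spec <- function(mode = c("linkage_equilibrium", "blocks"),
                    block_len = 1L, rho = 0) {
  mode <- match.arg(mode)
  stopifnot(rho >= 0, rho < 1, block_len >= 1)
  if (mode == "linkage_equilibrium" && rho != 0) {
    stop("linkage_equilibrium mode requires rho = 0")
  }
  if (mode == "blocks" && rho == 0) mode <- "linkage_equilibrium"
  structure(list(mode = mode, block_len = as.integer(block_len), rho = rho),
            class = "ld_spec")
}

#' Recompute per-column minor allele frequencies
#'
#' Allele frequency of the minor allele as coded (mean(g)/2 over observed
#' entries).  Columns are assumed polarised to the minor allele; values
#' above 0.5 indicate the coded allele drifted above 0.5 in this sample and
#' are returned as-is so callers can detect them.
#'
#' @param G A [genotype_matrix].
#' @return Numeric vector of length m.
#' @export
observed_maf <- function(G) {
  colMeans(G$values, na.rm = TRUE) / 2
}

#' Select the causal SNP pool by MAF band
#'
#' SNPs whose recomputed (observed) minor allele frequency lies in
#' `[maf_lo, maf_hi]`, minus an exclusion set.  The study draws its causal
#' SNPs from a high-MAF band (0.4-0.5) so all simulations have comparable
#' statistical power.
#'
#' @param G A [genotype_matrix].
#' @param maf_lo,maf_hi MAF band bounds.
#' @param exclude Character vector of snp_ids to drop from the pool.
#' @return Character vector of snp_ids.
#' @export
select_causal_pool <- function(G, maf_lo = 0.4, maf_hi = 0.5, exclude = character()) {
  stopifnot(maf_lo <= maf_hi)
  maf <- observed_maf(G)
  ids <- G$snps$snp_id[maf >= maf_lo & maf <= maf_hi]
  ids <- setdiff(ids, exclude)
  if (!length(ids)) {
    stop(sprintf(
      "empty causal pool: no SNP has observed MAF in [%g, %g]; relax the bounds",
      maf_lo, maf_hi
    ))
  }
  ids
}

#' Dichotomise additive genotypes into dominant/recessive predictors
#'
#' Each SNP column g in {0,1,2} becomes two binary predictors: dominant
#' `1{g >= 1}` (carrier of at least one minor allele, i.e. {0,1,2} ->
#' {0,1,1}) and recessive `1{g == 2}` ({0,1,2} -> {0,0,1}).  Missing values
#' propagate to both.  Dominant + recessive reconstructs the additive code.
#'
#' @param G A [genotype_matrix].
#' @return A `binary_encoding`: list with `values` (n x 2m 0/1 matrix) and
#'   `columns` (data.frame `col_id`, `snp_id`, `mode`).
#' @export
dichotomize <- function(G) {
  v <- G$values
  m <- ncol(v)
  out <- matrix(NA_integer_, nrow(v), 2L * m)
  out[, 2L * seq_len(m) - 1L] <- (v >= 1L) + 0L
  out[, 2L * seq_len(m)] <- (v == 2L) + 0L
  cols <- data.frame(
    col_id = paste0(rep(G$snps$snp_id, each = 2L), c("_dom", "_rec")),
    snp_id = rep(G$snps$snp_id, each = 2L),
    mode = rep(c("dominant", "recessive"), m),
    stringsAsFactors = FALSE
  )
  colnames(out) <- cols$col_id
  structure(list(values = out, columns = cols), class = "binary_encoding")
}

#' @export
print.binary_encoding <- function(x, ...) {
  cat(sprintf(
    "binary_encoding: %d individuals x %d predictors (%d SNPs, dominant+recessive)\n",
    nrow(x$values), ncol(x$values), nrow(x$columns) / 2L
  ))
  invisible(x)
}

#' Median imputation of missing entries
#'
#' Replaces each missing entry by the per-column median of the observed
#' entries.  Non-integral medians (only x.5 can occur for integer codes)
#' are rounded half-down so the imputed value stays in the code alphabet;
#' observed entries are untouched.
#'
#' @param X A [genotype_matrix] or `binary_encoding`.
#' @return Same type with no missing values.
#' @export
impute_median <- function(X) {
  v <- X$values
  nmiss <- colSums(is.na(v))
  if (any(nmiss == nrow(v))) {
    stop(sprintf("column %d is entirely missing; cannot impute", which(nmiss == nrow(v))[1]))
  }
  for (j in which(nmiss > 0L)) {
    med <- stats::median(v[, j], na.rm = TRUE)
    med <- as.integer(floor(med))  # half-down tie rule: 0.5 -> 0, 1.5 -> 1
    v[is.na(v[, j]), j] <- med
  }
  X$values <- v
  X
}
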