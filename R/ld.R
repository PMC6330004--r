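#' Pairwise linkage disequilibrium as squared genotype correlation
#'
#' Composite LD: the squared Pearson correlation of additive 0/1/2 genotype
#' codes, as computed by PLINK's `--r2` on unphased data.  Individuals
#' missing at either SNP are dropped (pairwise-complete).
#'
#' @param G A [genotype_matrix].
#' @param i,j SNP column indices or snp_ids.
#' @return Squared correlation in `[0, 1]`.
#' @export
genotype_r2 <- function(G, i, j) {
  if (is.character(i)) i <- match(i, G$snps$snp_id)
  if (is.character(j)) j <- match(j, G$snps$snp_id)
  x <- G$values[, i]
  y <- G$values[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0) {
    stop(sprintf("SNP %s is monomorphic after missing-data removal", G$snps$snp_id[i]))
  }
  if (stats::var(y) == 0) {
    stop(sprintf("SNP %s is monomorphic after missing-data removal", G$snps$snp_id[j]))
  }
  stats::cor(x, y)^2
}

# r^2 matrix among a set of columns (complete-data fast path; falls back to
# pairwise-complete when missing values are present)
r2_matrix <- function(vals) {
  if (anyNA(vals)) {
    cc <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  } else {
    cc <- suppressWarnings(stats::cor(vals))
  }
  cc[is.na(cc)] <- 0
  cc^2
}

#' Greedy window-based LD pruning
#'
#' PLINK-style `--indep-pairwise` pruning: a window of `window_kb` kilobases
#' slides along each chromosome in steps of `step_kb`; within a window,
#' while any pair of retained SNPs has r-squared above `r2_threshold`, one
#' member of the worst offending pair is removed.  The member removed is
#' the one with the lower observed MAF (tie: the later position), a fixed
#' deterministic rule.  Among the SNPs kept, no pair closer than
#' `window_kb` has r-squared above the threshold.
#'
#' @param G A [genotype_matrix]; positions must be sorted.
#' @param window_kb,step_kb Window and step sizes in kb (defaults 50 / 5).
#' @param r2_threshold Pairwise r-squared above which one SNP is removed
#'   (default 0.1).
#' @return Character vector of retained snp_ids, in input order.
#' @export
ld_prune <- function(G, window_kb = 50, step_kb = 5, r2_threshold = 0.1) {
  snps <- G$snps
  maf <- observed_maf(G)
  keep <- rep(TRUE, nrow(snps))
  # monomorphic columns carry no LD information; they are retained untouched
  poly <- apply(G$values, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
  for (chr in unique(snps$chrom)) {
    idx <- which(snps$chrom == chr)
    pos <- snps$pos_bp[idx]
    if (any(diff(pos) <= 0)) stop("pos_bp must be sorted within chromosome ", chr)
    starts <- seq(min(pos), max(pos), by = step_kb * 1000)
    for (s in starts) {
      win <- idx[pos >= s & pos < s + window_kb * 1000]
      win <- win[keep[win] & poly[win]]
      if (length(win) < 2L) next
      r2 <- r2_matrix(G$values[, win, drop = FALSE])
      active <- rep(TRUE, length(win))
      repeat {
        r2a <- r2
        r2a[!active, ] <- 0
        r2a[, !active] <- 0
        diag(r2a) <- 0
        mx <- max(r2a)
        if (mx <= r2_threshold) break
        pair <- which(r2a == mx, arr.ind = TRUE)[1, ]
        a <- win[pair[1]]; b <- win[pair[2]]
        drop_snp <- if (maf[a] < maf[b]) pair[1]
                    else if (maf[b] < maf[a]) pair[2]
                    else if (snps$pos_bp[a] > snps$pos_bp[b]) pair[1] else pair[2]
        active[drop_snp] <- FALSE
        keep[win[drop_snp]] <- FALSE
      }
    }
  }
  snps$snp_id[keep]
}

#' Subset a genotype matrix by SNP ids
#'
#' @param G A [genotype_matrix].
#' @param snp_ids Character vector of SNPs to retain (input order preserved).
#' @return A [genotype_matrix] restricted to those SNPs.
#' @export
subset_snps <- function(G, snp_ids) {
  j <- match(snp_ids, G$snps$snp_id)
  if (anyNA(j)) stop("unknown snp_id: ", snp_ids[which(is.na(j))[1]])
  j <- sort(j)
  new_genotype_matrix(G$values[, j, drop = FALSE],
                      G$snps[j, , drop = FALSE],
                      G$individual_ids)
}
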