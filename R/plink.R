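#' Read and write PLINK text genotype files
#'
#' Minimal interoperability with the PLINK text formats: `.ped`
#' (whitespace-delimited, six leading pedigree columns, then two allele
#' columns per SNP, missing allele coded "0") and `.map` (chromosome,
#' snp_id, genetic distance, base-pair position).  Alleles are written as
#' A (major) and B (minor); on reading, arbitrary allele symbols are
#' accepted and the rarer allele at each SNP is counted, so a round trip
#' reproduces the additive codes exactly.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return [read_plink_text()] returns a [genotype_matrix];
#'   [write_plink_text()] returns the two file paths, invisibly.
#' @name plink_text
NULL

#' @rdname plink_text
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n < 1) stop("ped file has no genotype rows")
  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      stop(sprintf("ped line %d has %d fields, expected %d (6 + 2 x %d SNPs)",
                   i, length(f), 6L + 2L * m, m))
    }
    ids[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[c(TRUE, FALSE)]
    a2[i, ] <- al[c(FALSE, TRUE)]
  }
  vals <- matrix(NA_integer_, n, m)
  maf <- numeric(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L) {
      stop(sprintf("SNP %s has %d alleles (%s); only biallelic SNPs are supported",
                   map$snp_id[j], length(alleles), paste(alleles, collapse = ",")))
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    if (length(alleles) == 0L) {
      maf[j] <- 0
      next
    }
    # count the rarer allele; tie -> the later symbol in sort order
    cnt <- table(factor(obs, levels = alleles))
    minor <- if (length(alleles) == 1L) NA_character_
             else if (cnt[1] < cnt[2]) alleles[1] else alleles[2]
    g <- if (is.na(minor)) rep(0L, n)
         else (a1[, j] == minor) + (a2[, j] == minor)
    g[miss] <- NA_integer_
    vals[, j] <- as.integer(g)
    maf[j] <- mean(g, na.rm = TRUE) / 2
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = as.character(map$chrom),
                     pos_bp = as.integer(map$pos_bp), maf = maf,
                     stringsAsFactors = FALSE)
  colnames(vals) <- snps$snp_id
  G <- new_genotype_matrix(vals, snps, ids)
  validate_genotype_matrix(G)
  G
}

#' @rdname plink_text
#' @param G A [genotype_matrix] to write.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   created.
#' @export
write_plink_text <- function(G, prefix) {
  validate_genotype_matrix(G)
  v <- G$values
  n <- nrow(v); m <- ncol(v)
  map <- data.frame(G$snps$chrom, G$snps$snp_id, 0, G$snps$pos_bp)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  # additive code g = count of minor allele "B"; 0 -> "A A", 1 -> "A B",
  # 2 -> "B B", NA -> "0 0"
  ped <- character(n)
  for (i in seq_len(n)) {
    g <- v[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, "B", "A"))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, "B", "A"))
    ped[i] <- paste(c("FAM", G$individual_ids[i], "0", "0", "0", "-9",
                      as.vector(rbind(al1, al2))), collapse = " ")
  }
  writeLines(ped, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}
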