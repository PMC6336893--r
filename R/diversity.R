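#' Nucleotide diversity per site
#'
#' Average pairwise difference per site within a population:
#' pi = sum over sites of n/(n-1) * 2*p*(1-p) divided by the effective
#' sequence length, with the per-site complete-case haploid sample size n.
#' The n/(n-1) factor makes the per-site term the unbiased estimator of
#' expected heterozygosity.
#'
#' @param x a [genotype_matrix()].
#' @param pop population label.
#' @param l_eff effective sequence length; defaults to `x$l_eff`.
#' @return pi per site (numeric scalar).
#' @export
nucleotide_diversity <- function(x, pop, l_eff = x$l_eff) {
  if (!is.finite(l_eff) || l_eff <= 0) stop("positive l_eff required")
  g <- x$geno[, pop_cols(x, pop), drop = FALSE]
  if (n_sites(x) == 0L) return(0)
  ns <- 2 * rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  ok <- ns >= 2
  p <- ac[ok] / ns[ok]
  sum(ns[ok] / (ns[ok] - 1) * 2 * p * (1 - p)) / l_eff
}

#' Watterson's theta per site
#'
#' theta_W = S / (a_n * L) with a_n = sum_{i=1}^{n-1} 1/i.
#'
#' @param S number of segregating sites.
#' @param n haploid sample size (n >= 2).
#' @param l_eff effective sequence length in bp.
#' @return theta_W per site.
#' @export
watterson_theta <- function(S, n, l_eff) {
  if (n < 2) stop("n >= 2 required")
  if (!is.finite(l_eff) || l_eff <= 0) stop("positive l_eff required")
  S / (sum(1 / seq_len(n - 1)) * l_eff)
}

#' Count sites segregating within a population
#'
#' Complete-case: sites with any missing genotype in the population are
#' skipped so the sample size is constant.
#'
#' @inheritParams nucleotide_diversity
#' @return Integer count of polymorphic sites.
#' @export
segregating_sites <- function(x, pop) {
  g <- x$geno[, pop_cols(x, pop), drop = FALSE]
  n <- 2L * length(pop_cols(x, pop))
  complete <- rowSums(is.na(g)) == 0L
  ac <- rowSums(g[complete, , drop = FALSE])
  sum(ac > 0 & ac < n)
}

#' Principal component analysis of a genotype matrix
#'
#' smartpca-style: sites with any missing genotype are excluded, genotypes
#' are centred by twice the allele frequency and scaled by
#' sqrt(2*p*(1-p)), and the individual-by-individual covariance matrix is
#' eigendecomposed. Eigenvalues are returned in decreasing order.
#'
#' @param x a [genotype_matrix()].
#' @param snps_only drop indel records first (default `TRUE`).
#' @return List with `values` (eigenvalues), `vectors` (individuals x PCs),
#'   `samples`, `pops`, and `n_sites_used`.
#' @export
pca_genotypes <- function(x, snps_only = TRUE) {
  if (length(x$samples) < 2) stop("need at least 2 individuals")
  g <- x$geno
  if (snps_only) g <- g[x$type == "SNP", , drop = FALSE]
  g <- g[rowSums(is.na(g)) == 0L, , drop = FALSE]
  p <- rowMeans(g) / 2
  poly <- p > 0 & p < 1
  g <- g[poly, , drop = FALSE]
  p <- p[poly]
  if (nrow(g) == 0L) {
    k <- length(x$samples)
    return(list(values = rep(0, k), vectors = diag(k), samples = x$samples,
                pops = x$pops, n_sites_used = 0L))
  }
  z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  cv <- crossprod(z) / nrow(z)            # individuals x individuals
  e <- eigen(cv, symmetric = TRUE)
  rownames(e$vectors) <- x$samples
  list(values = e$values, vectors = e$vectors, samples = x$samples,
       pops = x$pops, n_sites_used = nrow(z))
}
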