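#' Biallelic variant sites by individuals
#'
#' The central container: one row per biallelic variant record, one genotype
#' column per diploid individual coded as the number of alternate-allele
#' copies (0, 1, 2 or `NA` for missing), with a population label per
#' individual. Coordinates are 1-based inclusive (VCF convention).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt allele strings (single-base for SNPs).
#' @param geno integer matrix, sites x individuals, values 0/1/2/`NA`.
#' @param samples character vector of individual ids (columns of `geno`).
#' @param pops factor or character of population labels, one per individual.
#' @param info data frame of per-record annotations (QUAL, QD, FS, MQ0, DP,
#'   SB, HRun, ReadPosRankSum, ...), or `NULL`.
#' @param l_eff effective sequence length in bp (monomorphic sites are never
#'   stored, so per-site diversity statistics need this denominator).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, samples, pops,
                            info = NULL, l_eff = NA_real_) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos))
  geno <- as.matrix(geno)
  if (length(pos) != nrow(geno) && length(pos) > 0)
    stop("geno must have one row per site")
  if (ncol(geno) != length(samples)) stop("one genotype column per sample")
  if (length(pops) != length(samples)) stop("one population label per sample")
  colnames(geno) <- samples
  type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "indel")
  structure(list(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    type = type, geno = geno, samples = as.character(samples),
    pops = factor(pops), info = info, l_eff = l_eff
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_sites(x), "sites x", length(x$samples),
      "individuals\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", levels(x$pops), tabulate(x$pops)),
            collapse = ", "), "\n")
  cat("  types:", sum(x$type == "SNP"), "SNPs,", sum(x$type == "indel"),
      "indels; L_eff =", format(x$l_eff, big.mark = ","), "bp\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(n_sites(x), length(x$samples))

#' Number of variant records
#' @param x a [genotype_matrix()].
#' @return Integer count of sites.
#' @export
n_sites <- function(x) length(x$pos)

#' Subset variant records
#' @param x a [genotype_matrix()].
#' @param i row (site) index.
#' @return A `genotype_matrix` with the selected sites.
#' @export
subset_sites <- function(x, i) {
  genotype_matrix(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                  x$geno[i, , drop = FALSE], x$samples, x$pops,
                  info = if (!is.null(x$info)) x$info[i, , drop = FALSE],
                  l_eff = x$l_eff)
}

#' Allele-aware site keys
#' @param x a [genotype_matrix()].
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
site_keys <- function(x) site_key(x$chrom, x$pos, x$ref, x$alt)

# column indices of the individuals belonging to one population
pop_cols <- function(x, pop) {
  idx <- which(as.character(x$pops) == pop)
  if (length(idx) == 0L) stop("no individuals in population '", pop, "'")
  idx
}
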