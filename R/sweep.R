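#' Sweep-transformed site frequency spectrum
#'
#' SweepFinder-style model of a hard sweep: a lineage sampled at distance
#' `d` bp from the sweep site escapes the sweep by recombination with
#' probability p_e = 1 - exp(-alpha * d). Given B ~ Binomial(n, p_e)
#' escaped lineages, the B escapees plus the single ancestor of the swept
#' lineages form a sample of B + 1 drawn from the background spectrum
#' (hypergeometric projection of its symmetric unfolded extension); the
#' ancestor is derived with probability i/(B+1) given i derived among the
#' B + 1, in which case the n - B swept lineages copy its derived type
#' (total derived = i + n - B - 1), otherwise the total stays i. When all
#' lineages escape (B = n) the sample is plain background. The resulting
#' derived-count distribution is folded and renormalized over polymorphic
#' classes.
#'
#' @param background folded background spectrum: a [sfs()] or a proportion
#'   vector over minor classes 1..floor(n/2).
#' @param d distance from the sweep in bp (>= 0).
#' @param alpha sweep intensity per bp (> 0).
#' @param n haploid sample size (required when `background` is a plain
#'   vector).
#' @return Probability vector over folded classes 1..floor(n/2). At d = 0
#'   all mass is monomorphic; a zero vector is returned.
#' @export
sweep_spectrum <- function(background, d, alpha, n = NULL) {
  if (inherits(background, "norpop_sfs")) {
    n <- background$n
    phi <- sfs_proportions(background)
  } else {
    if (is.null(n)) stop("n required with a plain background vector")
    phi <- background / sum(background)
  }
  if (alpha <= 0) stop("alpha must be > 0")
  if (d < 0) stop("d must be >= 0")
  if (d == 0 && alpha == 0) stop("d and alpha cannot both be 0")
  FM <- sweep_full_matrix(phi, n)
  pe <- -expm1(-alpha * d)
  w <- dbinom(0:n, n, pe)
  full <- as.vector(w %*% FM)            # derived-count distribution 0..n
  folded <- fold_spectrum(full[2:n], n)
  tot <- sum(folded)
  if (tot <= 0) return(rep(0, floor(n / 2)))
  folded / tot
}

# rows B = 0..n: distribution over total derived count 0..n given B escaped
# lineages; the B = n row is the unfolded background itself.
sweep_full_matrix <- function(phi, n) {
  psi <- unfold_spectrum(phi, n)
  FM <- matrix(0, n + 1, n + 1)
  for (B in 0:(n - 1)) {
    m <- B + 1
    # hypergeometric projection of the background to m lineages, i = 0..m
    q <- vapply(0:m, function(i) {
      sum(psi * dhyper(i, seq_len(n - 1), n - seq_len(n - 1), m))
    }, numeric(1))
    for (i in 0:m) {
      p_anc <- i / m
      if (i > 0)
        FM[B + 1, (i + n - B - 1) + 1] <- FM[B + 1, (i + n - B - 1) + 1] +
          q[i + 1] * p_anc
      FM[B + 1, i + 1] <- FM[B + 1, i + 1] + q[i + 1] * (1 - p_anc)
    }
  }
  FM[n + 1, 2:n] <- psi
  FM
}

# folded-class mixture components used by the scan: M[B+1, j] is the
# unnormalized probability of folded class j given B escapees; mB the
# polymorphic mass per row. eps-smoothing keeps every log finite.
sweep_class_matrices <- function(phi, n, eps) {
  FM <- sweep_full_matrix(phi, n)
  K <- floor(n / 2)
  M <- t(apply(FM, 1, function(row) fold_spectrum(row[2:n], n)))
  if (K == 1) M <- matrix(M, ncol = 1)
  M <- M + eps
  list(M = M, mB = rowSums(M))
}

#' Composite likelihood ratio sweep scan
#'
#' Evaluates, at every grid position, CLR = 2 times the difference between
#' the composite log likelihood of the observed folded classes under the
#' sweep-transformed spectrum, maximized over alpha, and the log likelihood
#' under the background spectrum. Sites far enough away that the escape probability exceeds
#' 1 - 1e-6 contribute a neutral factor that cancels. Maximization is over
#' a log-spaced alpha grid (its upper end is effectively neutral, so CLR is
#' never negative) followed by golden-section refinement.
#'
#' @param x a [genotype_matrix()] (single population used as given), or a
#'   data frame with `pos` and `minor` (folded class) columns plus `n`.
#' @param pop population label (for a `genotype_matrix`).
#' @param background folded background spectrum; default: the empirical
#'   folded SFS of the scanned sites (standard practice for genome scans).
#' @param grid_spacing grid spacing in bp (default 5000, i.e. one point per
#'   5 kb: chromosome size / 5 kb points).
#' @param alpha_grid log-spaced candidate sweep intensities per bp.
#' @param chrom_length chromosome length (default: max site position).
#' @param n haploid sample size when `x` is a data frame.
#' @return A `sweep_scan` data frame: `chrom`, `pos`, `CLR`, `alpha_hat`.
#' @export
clr_scan <- function(x, pop = NULL, background = NULL, grid_spacing = 5000,
                     alpha_grid = 10^seq(-6, -1, length.out = 11),
                     chrom_length = NULL, n = NULL) {
  if (inherits(x, "genotype_matrix")) {
    pop <- pop %||% levels(x$pops)[1]
    cols <- pop_cols(x, pop)
    g <- x$geno[, cols, drop = FALSE]
    n <- 2L * length(cols)
    complete <- rowSums(is.na(g)) == 0L
    ac <- rowSums(g[complete, , drop = FALSE])
    minor <- pmin(ac, n - ac)
    keep <- minor > 0
    sites <- data.frame(chrom = x$chrom[complete][keep],
                        pos = x$pos[complete][keep], minor = minor[keep])
  } else {
    if (is.null(n)) stop("n required with a site data frame")
    sites <- data.frame(chrom = x$chrom %||% "chr1", pos = x$pos,
                        minor = x$minor)
  }
  if (nrow(sites) == 0) stop("no polymorphic sites to scan")
  K <- floor(n / 2)
  phi <- if (is.null(background)) {
    tabulate(sites$minor, nbins = K) / nrow(sites)
  } else if (inherits(background, "norpop_sfs")) sfs_proportions(background)
  else background / sum(background)
  eps <- 1 / (2 * nrow(sites))
  if (any(phi[tabulate(sites$minor, nbins = K) > 0] == 0))
    message("background classes with zero probability observed; ",
            "eps-smoothing applied (eps = ", signif(eps, 3), ")")
  phi_s <- (phi + eps) / sum(phi + eps)
  mats <- sweep_class_matrices(phi_s, n, eps)
  out <- NULL
  for (ch in unique(sites$chrom)) {
    ss <- sites[sites$chrom == ch, , drop = FALSE]
    ss <- ss[order(ss$pos), , drop = FALSE]
    len <- chrom_length %||% max(ss$pos)
    grid <- seq(grid_spacing, len, by = grid_spacing)
    res <- .cpp_clr_scan(grid, as.numeric(ss$pos), as.integer(ss$minor),
                         mats$M, mats$mB, log(phi_s), alpha_grid)
    out <- rbind(out, data.frame(chrom = ch, pos = grid, CLR = res[, 1],
                                 alpha_hat = res[, 2]))
  }
  class(out) <- c("sweep_scan", "data.frame")
  out
}

#' CLR at a single grid position
#'
#' @inheritParams clr_scan
#' @param grid_x position to evaluate (bp).
#' @param sites data frame with `pos` and `minor` columns.
#' @return List with `CLR` and `alpha_hat`.
#' @export
clr_at <- function(grid_x, sites, background, n,
                   alpha_grid = 10^seq(-6, -1, length.out = 11)) {
  phi <- if (inherits(background, "norpop_sfs")) sfs_proportions(background)
         else background / sum(background)
  eps <- 1 / (2 * nrow(sites))
  phi_s <- (phi + eps) / sum(phi + eps)
  mats <- sweep_class_matrices(phi_s, n, eps)
  ord <- order(sites$pos)
  res <- .cpp_clr_scan(grid_x, as.numeric(sites$pos[ord]),
                       as.integer(sites$minor[ord]), mats$M, mats$mB,
                       log(phi_s), alpha_grid)
  list(CLR = res[1, 1], alpha_hat = res[1, 2])
}

#' Call outliers in a sweep scan
#'
#' Outliers are grid points with CLR at or above the (1 - top_fraction)
#' empirical quantile, computed per chromosome by default (genome-wide with
#' `per_chromosome = FALSE`). Ties at the cutoff are included.
#'
#' @param scan a `sweep_scan` from [clr_scan()].
#' @param top_fraction outlier fraction (default 0.005, the top 0.5%).
#' @param per_chromosome compute the cutoff within each chromosome.
#' @return The scan with logical `outlier` and `cutoff` columns added.
#' @export
call_outliers <- function(scan, top_fraction = 0.005, per_chromosome = TRUE) {
  if (nrow(scan) == 0) stop("empty scan")
  grp <- if (per_chromosome) scan$chrom else rep("genome", nrow(scan))
  cutoff <- numeric(nrow(scan))
  for (gv in unique(grp)) {
    i <- grp == gv
    cutoff[i] <- quantile(scan$CLR[i], 1 - top_fraction, names = FALSE)
  }
  scan$cutoff <- cutoff
  scan$outlier <- scan$CLR >= cutoff
  scan
}

#' Genes within a window around each outlier
#'
#' Lists genes overlapping a window (default 150 kb) centred on every
#' outlier grid point by at least 1 bp, plus the deduplicated union used as
#' enrichment input.
#'
#' @param outliers data frame with `chrom` and `pos` of outlier grid points
#'   (e.g. the flagged rows from [call_outliers()]).
#' @param model a `gene_model`.
#' @param window window width in bp, centred on the outlier.
#' @return List with `per_outlier` (list of gene-id vectors) and `genes`
#'   (union).
#' @export
annotate_windows <- function(outliers, model, window = 150000) {
  if (is.null(model$genes) || nrow(model$genes) == 0)
    return(list(per_outlier = rep(list(character(0)), nrow(outliers)),
                genes = character(0)))
  half <- window / 2
  gr_win <- GenomicRanges::GRanges(
    outliers$chrom,
    IRanges::IRanges(pmax(1, outliers$pos - half), outliers$pos + half))
  gr_genes <- GenomicRanges::GRanges(
    model$genes$chrom,
    IRanges::IRanges(model$genes$start, model$genes$end))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_genes, minoverlap = 1L)
  per <- lapply(seq_len(nrow(outliers)), function(i) {
    model$genes$gene_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
  })
  list(per_outlier = per, genes = unique(unlist(per)))
}
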