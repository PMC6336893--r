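#' Folded site frequency spectrum
#'
#' Counts of polymorphic sites by minor-allele count class 1..floor(n/2).
#' Ties at exactly n/2 are counted once in the floor(n/2) class.
#'
#' @param counts numeric vector of class counts; names are ignored.
#' @param n haploid sample size.
#' @param l_eff effective sequence length in bp.
#' @return An object of class `norpop_sfs`.
#' @export
sfs <- function(counts, n, l_eff = NA_real_) {
  k <- floor(n / 2)
  if (length(counts) != k) stop("expected ", k, " folded classes for n = ", n)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = setNames(as.numeric(counts), seq_len(k)),
                 n = as.integer(n), l_eff = l_eff),
            class = "norpop_sfs")
}

#' @export
print.norpop_sfs <- function(x, ...) {
  cat("folded SFS, n =", x$n, "haploids,", sum(x$counts), "sites\n")
  print(x$counts)
  invisible(x)
}

#' Normalized view of a folded spectrum
#' @param x a [sfs()].
#' @return Numeric vector of class proportions summing to 1.
#' @export
sfs_proportions <- function(x) x$counts / sum(x$counts)

#' Fold and unfold one-dimensional spectra
#'
#' `unfold_spectrum()` spreads a folded spectrum over minor classes
#' 1..floor(n/2) onto derived classes 1..n-1 symmetrically (each folded
#' class splits evenly between its two unfolded images, except the n/2
#' class for even n); `fold_spectrum()` is its inverse.
#'
#' @param phi folded spectrum over minor classes 1..floor(n/2).
#' @param psi unfolded spectrum over derived classes 1..n-1.
#' @param n haploid sample size.
#' @return Numeric vector over derived (unfold) or minor (fold) classes.
#' @export
unfold_spectrum <- function(phi, n) {
  k <- floor(n / 2)
  psi <- numeric(n - 1)
  for (j in seq_len(k)) {
    if (j == n - j) psi[j] <- phi[j]
    else { psi[j] <- phi[j] / 2; psi[n - j] <- phi[j] / 2 }
  }
  psi
}

#' @rdname unfold_spectrum
#' @export
fold_spectrum <- function(psi, n) {
  k <- floor(n / 2)
  vapply(seq_len(k), function(j) {
    if (j == n - j) psi[j] else psi[j] + psi[n - j]
  }, numeric(1))
}

#' Build the folded SFS of one population
#'
#' Only sites with complete genotypes within the population contribute (so
#' the haploid sample size is constant); sites monomorphic within the
#' population are skipped.
#'
#' @param x a [genotype_matrix()].
#' @param pop population label.
#' @return A [sfs()].
#' @export
build_folded_sfs <- function(x, pop) {
  cols <- pop_cols(x, pop)
  g <- x$geno[, cols, drop = FALSE]
  n <- 2L * length(cols)
  complete <- rowSums(is.na(g)) == 0L
  ac <- rowSums(g[complete, , drop = FALSE])
  minor <- pmin(ac, n - ac)
  minor <- minor[minor > 0]
  sfs(tabulate(minor, nbins = floor(n / 2)), n, l_eff = x$l_eff)
}

#' Folded joint site frequency spectrum of two populations
#'
#' Matrix over alternate-allele count pairs (i, j), folded by total minor
#' allele count following the usual convention: cells with i + j above
#' (n1 + n2)/2 are masked and their mass added to the mirror cell; cells on
#' the fold diagonal carry half weight from each mirror image. The
#' monomorphic corners are masked.
#'
#' @param x a [genotype_matrix()].
#' @param popA,popB population labels.
#' @return An object of class `norpop_jsfs` with fields `matrix`
#'   ((n1+1) x (n2+1) folded counts), `mask` (logical, `TRUE` = excluded),
#'   `n1`, `n2`, `l_eff`.
#' @export
build_joint_sfs <- function(x, popA, popB) {
  ca <- pop_cols(x, popA); cb <- pop_cols(x, popB)
  ga <- x$geno[, ca, drop = FALSE]; gb <- x$geno[, cb, drop = FALSE]
  n1 <- 2L * length(ca); n2 <- 2L * length(cb)
  complete <- rowSums(is.na(ga)) == 0L & rowSums(is.na(gb)) == 0L
  i <- rowSums(ga[complete, , drop = FALSE])
  j <- rowSums(gb[complete, , drop = FALSE])
  u <- matrix(0, n1 + 1, n2 + 1)
  for (s in seq_along(i)) u[i[s] + 1, j[s] + 1] <- u[i[s] + 1, j[s] + 1] + 1
  joint_sfs(u, n1, n2, l_eff = x$l_eff, folded = FALSE)
}

#' Construct (and fold) a joint SFS from a raw count matrix
#'
#' @param mat (n1+1) x (n2+1) matrix of site counts by alternate (or derived)
#'   allele count pair.
#' @param n1,n2 haploid sample sizes.
#' @param l_eff effective sequence length in bp.
#' @param folded set to `TRUE` if `mat` is already folded.
#' @return A `norpop_jsfs` object.
#' @export
joint_sfs <- function(mat, n1, n2, l_eff = NA_real_, folded = FALSE) {
  stopifnot(nrow(mat) == n1 + 1, ncol(mat) == n2 + 1)
  if (!folded) mat <- fold_joint_matrix(mat, n1, n2)
  structure(list(matrix = mat, mask = joint_mask(n1, n2),
                 n1 = as.integer(n1), n2 = as.integer(n2), l_eff = l_eff),
            class = "norpop_jsfs")
}

joint_mask <- function(n1, n2) {
  tot <- outer(0:n1, 0:n2, `+`)
  mask <- tot > (n1 + n2) / 2
  mask[1, 1] <- TRUE          # monomorphic reference corner
  mask[n1 + 1, n2 + 1] <- TRUE
  mask
}

fold_joint_matrix <- function(u, n1, n2) {
  rev_u <- u[(n1 + 1):1, (n2 + 1):1, drop = FALSE]
  tot <- outer(0:n1, 0:n2, `+`)
  f <- u + rev_u
  f[tot == (n1 + n2) / 2] <- f[tot == (n1 + n2) / 2] / 2
  f[tot > (n1 + n2) / 2] <- 0
  f
}

#' @export
print.norpop_jsfs <- function(x, ...) {
  cat("folded joint SFS, n1 =", x$n1, ", n2 =", x$n2, ",",
      sum(x$matrix[!x$mask]), "sites\n")
  invisible(x)
}

#' Project a folded SFS to a smaller sample size
#'
#' Hypergeometric (expected subsampling) projection: the folded input is
#' unfolded by symmetry, each derived class is redistributed over subsample
#' counts with hypergeometric weights, classes that become monomorphic in
#' the subsample are dropped, and the result is re-folded.
#'
#' @param x a [sfs()].
#' @param m target haploid sample size (m <= n).
#' @return A [sfs()] with sample size `m`.
#' @export
project_sfs <- function(x, m) {
  n <- x$n
  if (m > n) stop("m must not exceed n")
  if (m == n) return(x)
  psi <- unfold_spectrum(x$counts, n)
  q <- vapply(seq_len(m - 1), function(i) {
    sum(psi * dhyper(i, seq_len(n - 1), n - seq_len(n - 1), m))
  }, numeric(1))
  sfs(fold_spectrum(q, m), m, l_eff = x$l_eff)
}

#' Write / read a spectrum in dadi-style text format
#'
#' One header line `n+1 folded`, one line of flattened values over derived
#' classes 0..n, one line of mask flags (1 = masked).
#'
#' @param x a [sfs()].
#' @param path output file.
#' @return `write_sfs_dadi` returns `path` invisibly; `read_sfs_dadi`
#'   returns a [sfs()].
#' @export
write_sfs_dadi <- function(x, path) {
  n <- x$n
  vals <- numeric(n + 1)
  vals[seq_len(floor(n / 2)) + 1] <- x$counts
  mask <- as.integer(c(TRUE, seq_len(n - 1) > floor(n / 2), TRUE))
  writeLines(c(paste(n + 1, "folded"),
               paste(format(vals, scientific = FALSE, trim = TRUE),
                     collapse = " "),
               paste(mask, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs_dadi
#' @export
read_sfs_dadi <- function(path) {
  ln <- readLines(path)
  n <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]][1]) - 1L
  vals <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  sfs(vals[seq_len(floor(n / 2)) + 1], n)
}
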