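#' Per-population variant site sets
#'
#' A site belongs to a population's set if the alternate allele segregates
#' in that population's complete-case genotypes (`mode = "segregating"`,
#' strictly polymorphic within the population) or if at least one alternate
#' copy is present (`mode = "nonref"`). Site identity is allele-aware
#' (chrom, pos, ref, alt).
#'
#' @param x a [genotype_matrix()].
#' @param mode membership rule, see above.
#' @return Named list of character key sets, one per population.
#' @export
breed_variant_sets <- function(x, mode = c("segregating", "nonref")) {
  mode <- match.arg(mode)
  keys <- site_keys(x)
  lapply(setNames(levels(x$pops), levels(x$pops)), function(p) {
    cols <- pop_cols(x, p)
    g <- x$geno[, cols, drop = FALSE]
    complete <- rowSums(is.na(g)) == 0L
    ac <- rowSums(g, na.rm = TRUE)
    nmax <- 2 * rowSums(!is.na(g))
    inset <- if (mode == "segregating") complete & ac > 0 & ac < nmax
             else ac > 0
    keys[inset]
  })
}

#' Venn-region accounting of shared and private variants
#'
#' For two or three populations, counts every exclusive region of the Venn
#' diagram plus each percentage of the union.
#'
#' @param sets named list of site-key sets (see [breed_variant_sets()]).
#' @return Data frame with columns `region`, `count`, `pct`.
#' @export
venn_sharing <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 populations")
  if (length(sets) > 3) stop("at most 3 populations supported")
  nm <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0)
    member <- matrix(logical(0), 0, length(sets), dimnames = list(NULL, nm))
  if (length(universe) == 1) member <- matrix(member, 1,
                                              dimnames = list(NULL, nm))
  pat <- if (length(universe)) apply(member, 1, function(r)
    paste(as.integer(r), collapse = "")) else character(0)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  combos <- combos[order(rowSums(combos)), , drop = FALSE]
  region <- apply(combos, 1, function(r) paste(nm[unlist(r)], collapse = " & "))
  codes <- apply(combos, 1, function(r) paste(as.integer(unlist(r)),
                                              collapse = ""))
  count <- vapply(codes, function(cd) sum(pat == cd), numeric(1))
  data.frame(region = region, count = unname(count),
             pct = venn_percentage(unname(count), length(universe)),
             row.names = NULL)
}

#' Percentage of a Venn region against the union
#'
#' @param count region count(s).
#' @param union_total size of the union of all sets.
#' @param digits rounding applied at the reporting layer.
#' @return Percentages.
#' @export
venn_percentage <- function(count, union_total, digits = 1) {
  round(100 * count / union_total, digits)
}

#' Homozygous/heterozygous genotype accounting
#'
#' Counts homozygous-alternate (genotype 2) and heterozygous (genotype 1)
#' calls per individual within a population and in total; the ratio is
#' het/hom (reported rounded to 2 decimals).
#'
#' @param x a [genotype_matrix()].
#' @param pop population label.
#' @return List with `per_individual` (data frame), `hom`, `het`, `ratio`
#'   (`Inf` when there are no homozygous-alternate calls).
#' @export
hom_het_ratio <- function(x, pop) {
  cols <- pop_cols(x, pop)
  g <- x$geno[, cols, drop = FALSE]
  hom_i <- colSums(g == 2L, na.rm = TRUE)
  het_i <- colSums(g == 1L, na.rm = TRUE)
  hom <- sum(hom_i); het <- sum(het_i)
  list(per_individual = data.frame(sample = x$samples[cols], hom = hom_i,
                                   het = het_i, row.names = NULL),
       hom = hom, het = het,
       ratio = if (hom == 0) Inf else round(het / hom, 2))
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T. All-transversion input gives 0; input
#' with transitions but no transversions gives `Inf`; no SNPs at all gives
#' `NaN` (undefined).
#'
#' @param x a [genotype_matrix()], or a data frame with `REF`/`ALT` columns.
#' @return ts/tv ratio.
#' @export
tstv_ratio <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    snp <- x$type == "SNP"
    ref <- x$ref[snp]; alt <- x$alt[snp]
  } else { ref <- toupper(x$REF); alt <- toupper(x$ALT) }
  pair <- paste0(ref, alt)
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- length(pair) - ts
  if (tv == 0 && ts == 0) return(NaN)
  ts / tv
}

#' Split sites into known and novel against a catalogue
#'
#' Matching is allele-aware: a site with the same position but a different
#' alternate allele than a catalogue entry is novel.
#'
#' @param x a [genotype_matrix()].
#' @param known_sites data frame with CHROM, POS, REF, ALT.
#' @param sets optional [breed_variant_sets()] result for per-population
#'   novel fractions.
#' @return List with `known`/`novel` key vectors, `novel_fraction` (of the
#'   union) and `per_population` novel fractions when `sets` is given.
#' @export
classify_novel <- function(x, known_sites, sets = NULL) {
  keys <- site_keys(x)
  kk <- site_key(known_sites$CHROM, known_sites$POS, known_sites$REF,
                 known_sites$ALT)
  is_known <- keys %in% kk
  out <- list(known = keys[is_known], novel = keys[!is_known],
              novel_fraction = mean(!is_known))
  if (!is.null(sets)) {
    out$per_population <- vapply(sets, function(s) {
      if (length(s) == 0) return(NA_real_)
      mean(!(s %in% kk))
    }, numeric(1))
  }
  out
}

#' Genotype concordance with an array-genotype table
#'
#' Fraction of matching genotype calls over (sample, site) pairs present in
#' both the sequencing matrix and the array table; missing genotypes are
#' excluded from the denominator.
#'
#' @param x a [genotype_matrix()].
#' @param array_table data frame like [make_array_genotypes()] output.
#' @return List with `concordance` (percent), `n_compared`.
#' @export
genotype_concordance <- function(x, array_table) {
  keys <- site_keys(x)
  ak <- site_key(array_table$CHROM, array_table$POS, array_table$REF,
                 array_table$ALT)
  row <- match(ak, keys)
  col <- match(array_table$sample, x$samples)
  ok <- !is.na(row) & !is.na(col)
  seq_gt <- x$geno[cbind(row[ok], col[ok])]
  arr_gt <- array_table$gt[ok]
  keep <- !is.na(seq_gt) & !is.na(arr_gt)
  if (!any(keep)) stop("no overlapping genotyped (sample, site) pairs")
  list(concordance = 100 * mean(seq_gt[keep] == arr_gt[keep]),
       n_compared = sum(keep))
}
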