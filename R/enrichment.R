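#' Gene-to-GO annotation container
#'
#' @param map data frame with columns `gene` and `term`.
#' @param universe background gene universe (all genes in the gene model).
#' @param terms optional term metadata (`term`, `description`, `namespace`).
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(map, universe, terms = NULL) {
  stopifnot(all(c("gene", "term") %in% colnames(map)))
  map <- unique(map[, c("gene", "term")])
  structure(list(map = map, universe = unique(universe), terms = terms),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("go_annotation:", length(unique(x$map$term)), "terms over",
      length(x$universe), "genes\n")
  invisible(x)
}

#' GO term over-representation by Fisher's exact test
#'
#' One-sided (over-representation) hypergeometric test per term on the
#' 2x2 table (study with term, study without, background-rest with term,
#' background-rest without), Bonferroni-corrected by the number of terms
#' actually tested. Terms mapped by fewer than `min_mapped` study genes
#' (or background genes, with `min_mapped_on = "background"`) are excluded
#' before testing, mirroring the usual "at least 5 mapping entries" setting.
#' Only over-representation is tested; annotations are used as given (no
#' ontology-graph propagation).
#'
#' @param study_genes character vector of study genes (subset of the
#'   universe).
#' @param annotation a [go_annotation()].
#' @param p_threshold significance threshold on the adjusted p (default
#'   0.05).
#' @param min_mapped minimum mapping entries for a term to be tested.
#' @param min_mapped_on whether `min_mapped` counts study or background
#'   mappings.
#' @return Data frame sorted by adjusted p: `term`, `a`, `b`, `c`, `d`,
#'   `p`, `p_adj`, `significant`.
#' @export
enrich <- function(study_genes, annotation, p_threshold = 0.05,
                   min_mapped = 5, min_mapped_on = c("study", "background")) {
  min_mapped_on <- match.arg(min_mapped_on)
  study_genes <- unique(study_genes)
  if (length(study_genes) == 0) stop("empty study set")
  universe <- annotation$universe
  extra <- setdiff(study_genes, universe)
  if (length(extra))
    stop("study genes outside the background universe: ",
         paste(head(extra, 5), collapse = ", "))
  map <- annotation$map[annotation$map$gene %in% universe, , drop = FALSE]
  n_univ <- length(universe)
  n_study <- length(study_genes)
  term_genes <- split(map$gene, map$term)
  rows <- lapply(names(term_genes), function(tm) {
    tg <- unique(term_genes[[tm]])
    a <- sum(study_genes %in% tg)
    size_bg <- length(tg)
    mapped <- if (min_mapped_on == "study") a else size_bg
    if (mapped < min_mapped) return(NULL)
    b <- n_study - a
    c_ <- size_bg - a
    d <- n_univ - n_study - c_
    # one-sided over-representation tail P(X >= a)
    p <- phyper(a - 1, size_bg, n_univ - size_bg, n_study,
                lower.tail = FALSE)
    data.frame(term = tm, a = a, b = b, c = c_, d = d, p = p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  rows$p_adj <- pmin(1, rows$p * nrow(rows))   # Bonferroni over tested terms
  rows$significant <- rows$p_adj < p_threshold
  rows <- rows[order(rows$p_adj, rows$p), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
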