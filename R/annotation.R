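#' Classify variants against a gene model
#'
#' Assigns each variant exactly one top-level functional category with
#' precedence (high to low): splicing > exonic > UTR > intronic >
#' upstream/downstream > ncRNA > intergenic. Splicing means within 2 bp of
#' an intron boundary; upstream/downstream means within 1,000 bp of a
#' transcript start/end respecting strand ("upstream;downstream" when a site
#' sits within 1 kb of two different transcripts on opposite sides). Coding
#' SNP effects come from single-codon translation with the standard genetic
#' code, strand aware; coding indels are frameshift when the length
#' difference is not a multiple of 3, otherwise non-frameshift, upgraded to
#' stopgain/stoploss when an in-frame inserted/deleted block adds/removes a
#' stop codon. With several overlapping genes the most severe call wins.
#'
#' @param x a [genotype_matrix()] (left-aligned, normalized indels).
#' @param model a `gene_model` with genome sequence.
#' @param flank upstream/downstream window in bp.
#' @param splice_bp splice-region width inside the intron, in bp.
#' @return Data frame: `key`, `chrom`, `pos`, `category`, `effect`, `gene`.
#' @export
classify_variants <- function(x, model, flank = 1000, splice_bp = 2) {
  n <- n_sites(x)
  chroms <- unique(model$genes$chrom)
  if (n > 0 && !all(x$chrom %in% c(chroms, names(model$seq))))
    stop("site chromosome absent from the gene model registry")
  out <- data.frame(key = site_keys(x), chrom = x$chrom, pos = x$pos,
                    category = rep("intergenic", n),
                    effect = rep(NA_character_, n),
                    gene = rep(NA_character_, n))
  if (n == 0 || nrow(model$genes) == 0) return(out)

  g <- model$genes
  # plain interval overlap: few genes, possibly many sites, called per site
  # in classify_site, so avoid any per-call object-construction overhead
  site_end <- x$pos + pmax(nchar(x$ref) - 1, 0)
  hits <- do.call(rbind, lapply(seq_len(nrow(g)), function(gi) {
    s <- which(x$chrom == g$chrom[gi] &
                 site_end >= max(1, g$start[gi] - flank) &
                 x$pos <= g$end[gi] + flank)
    if (length(s)) data.frame(queryHits = s, subjectHits = gi) else NULL
  }))
  if (is.null(hits)) hits <- data.frame(queryHits = integer(), subjectHits = integer())

  cds_cache <- lapply(setNames(g$gene_id, g$gene_id), function(id) {
    cd <- model$cds[model$cds$gene_id == id, , drop = FALSE]
    if (nrow(cd) == 0) return(NULL)
    cd <- cd[order(cd$start), , drop = FALSE]
    ch <- cd$chrom[1]
    seq_plus <- paste(substring(model$seq[[ch]], cd$start, cd$end),
                      collapse = "")
    list(cd = cd, seq_plus = seq_plus, total = nchar(seq_plus))
  })

  rank <- c(splicing = 1, exonic = 2, UTR = 3, intronic = 4, upstream = 5,
            downstream = 5, ncRNA = 6, intergenic = 7)
  best_rank <- rep(7, n)
  best_cat <- rep("intergenic", n)
  best_eff <- rep(NA_character_, n)
  best_gene <- vector("list", n)
  updown <- matrix(FALSE, n, 2, dimnames = list(NULL, c("up", "down")))

  for (h in seq_len(nrow(hits))) {
    s <- hits$queryHits[h]; gi <- hits$subjectHits[h]
    call <- classify_pair(x, s, g[gi, ], model, cds_cache[[g$gene_id[gi]]],
                          flank, splice_bp)
    if (call$category == "upstream") updown[s, "up"] <- TRUE
    if (call$category == "downstream") updown[s, "down"] <- TRUE
    r <- rank[[call$category]]
    if (r < best_rank[s]) {
      best_rank[s] <- r; best_cat[s] <- call$category
      best_eff[s] <- call$effect; best_gene[s] <- list(g$gene_id[gi])
    } else if (r == best_rank[s] && best_cat[s] != "intergenic") {
      best_gene[[s]] <- unique(c(best_gene[[s]], g$gene_id[gi]))
    }
  }
  both <- best_rank == 5 & updown[, "up"] & updown[, "down"]
  best_cat[both] <- "upstream;downstream"
  out$category <- best_cat
  out$effect <- best_eff
  out$gene <- vapply(best_gene, function(v)
    if (is.null(v)) NA_character_ else paste(v, collapse = ";"), character(1))
  out
}

# one (variant, gene) call; cds = cached CDS info or NULL for ncRNA
classify_pair <- function(x, s, gene, model, cds, flank, splice_bp) {
  pos <- x$pos[s]; ref <- x$ref[s]; alt <- x$alt[s]
  end <- pos + max(nchar(ref) - 1, 0)
  none <- list(category = "intergenic", effect = NA_character_)
  inside <- end >= gene$start && pos <= gene$end
  if (!inside) {
    before <- end < gene$start && end >= gene$start - flank
    after <- pos > gene$end && pos <= gene$end + flank
    if (before) return(list(category = if (gene$strand == "+") "upstream"
                            else "downstream", effect = NA_character_))
    if (after) return(list(category = if (gene$strand == "+") "downstream"
                           else "upstream", effect = NA_character_))
    return(none)
  }
  if (gene$biotype != "protein_coding")
    return(list(category = "ncRNA", effect = NA_character_))
  ex <- model$exons[model$exons$gene_id == gene$gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  in_exon <- any(pos <= ex$end & end >= ex$start)
  if (!in_exon) {
    # intron boundaries are the bases adjacent to exon edges
    near <- any(abs(pos - (ex$end + 1)) < splice_bp |
                  abs(pos - (ex$start - 1)) < splice_bp)
    return(list(category = if (near) "splicing" else "intronic",
                effect = NA_character_))
  }
  cd <- cds$cd
  in_cds <- !is.null(cd) && any(pos <= cd$end & end >= cd$start)
  if (!in_cds) return(list(category = "UTR", effect = NA_character_))
  eff <- if (x$type[s] == "SNP")
    snp_effect(pos, ref, alt, gene$strand, cds)
  else indel_effect(pos, ref, alt, gene$strand, cds)
  list(category = "exonic", effect = eff)
}

# 1-based offset of a genomic position within the plus-strand concatenated CDS
cds_offset_plus <- function(pos, cd) {
  i <- which(pos >= cd$start & pos <= cd$end)
  if (length(i) == 0) return(NA_integer_)
  before <- if (i > 1) sum(cd$end[seq_len(i - 1)] - cd$start[seq_len(i - 1)] + 1)
            else 0
  before + (pos - cd$start[i] + 1)
}

# fetch the standard genetic code once: `::` access re-reads the exported
# value from the lazy-load database on every call, which dominates the cost
# of per-site classification
genetic_code <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

translate_codon <- function(codon) {
  unname(genetic_code()[codon])
}

snp_effect <- function(pos, ref, alt, strand, cds) {
  offp <- cds_offset_plus(pos, cds$cd)
  off <- if (strand == "+") offp else cds$total - offp + 1
  base_alt <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
  cds_seq <- if (strand == "+") cds$seq_plus else revcomp(cds$seq_plus)
  ci <- (off - 1) %/% 3
  wi <- (off - 1) %% 3 + 1
  codon <- substring(cds_seq, 3 * ci + 1, 3 * ci + 3)
  if (nchar(codon) < 3) return(NA_character_)  # trailing partial codon
  mut <- codon
  substr(mut, wi, wi) <- base_alt
  aa_ref <- translate_codon(codon); aa_alt <- translate_codon(mut)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*" && aa_ref != "*") "stopgain"
  else if (aa_ref == "*" && aa_alt != "*") "stoploss"
  else "nonsynonymous"
}

indel_effect <- function(pos, ref, alt, strand, cds) {
  len <- abs(nchar(ref) - nchar(alt))
  if (len %% 3 != 0) return("frameshift")
  cds_seq <- if (strand == "+") cds$seq_plus else revcomp(cds$seq_plus)
  has_stop <- function(s) {
    if (nchar(s) < 3) return(FALSE)
    codons <- substring(s, seq(1, nchar(s) - 2, by = 3),
                        seq(3, nchar(s), by = 3))
    any(codons %in% c("TAA", "TAG", "TGA"))
  }
  if (nchar(ref) > nchar(alt)) {          # deletion of bases pos+1..pos+len
    offp <- cds_offset_plus(pos + 1, cds$cd)
    if (is.na(offp)) return("non-frameshift")
    off <- if (strand == "+") offp else cds$total - (offp + len - 1) + 1
    if (!is.na(off) && off >= 1 && (off - 1) %% 3 == 0 &&
        has_stop(substring(cds_seq, off, off + len - 1)))
      return("stoploss")
    "non-frameshift"
  } else {                                # insertion after pos
    offp <- cds_offset_plus(pos, cds$cd)
    ins <- substring(alt, 2)
    if (strand == "-") ins <- revcomp(ins)
    off <- if (strand == "+") offp else cds$total - offp + 1
    if (!is.na(off) && off %% 3 == 0 && has_stop(ins)) return("stopgain")
    "non-frameshift"
  }
}

#' Classify a single variant
#'
#' @param chrom,pos,ref,alt the variant.
#' @param model a `gene_model`.
#' @param ... passed to [classify_variants()].
#' @return One-row data frame (see [classify_variants()]).
#' @export
classify_site <- function(chrom, pos, ref, alt, model, ...) {
  gm <- genotype_matrix(chrom, pos, ref, alt,
                        matrix(0L, 1, 1), "s1", "p1")
  classify_variants(gm, model, ...)
}

#' Per-gene nonsynonymous SNP burden
#'
#' @param calls output of [classify_variants()].
#' @return Named integer vector of nsSNP counts per gene.
#' @export
gene_nssnp_burden <- function(calls) {
  ns <- calls[!is.na(calls$effect) & calls$effect == "nonsynonymous", ,
              drop = FALSE]
  genes <- unlist(strsplit(ns$gene, ";"))
  tab <- table(genes)
  setNames(as.integer(tab), names(tab))
}

#' Select genes exceeding a nonsynonymous burden threshold
#'
#' @param counts named vector from [gene_nssnp_burden()].
#' @param threshold burden cutoff (default 5).
#' @param strict_greater require count > threshold (default) rather than >=.
#' @return Character vector of gene ids.
#' @export
select_genes <- function(counts, threshold = 5, strict_greater = TRUE) {
  keep <- if (strict_greater) counts > threshold else counts >= threshold
  names(counts)[keep]
}

#' Tabulate functional categories
#'
#' @param calls output of [classify_variants()].
#' @param types optional vector ("SNP"/"indel") aligned with `calls` to
#'   split the table by variant type.
#' @return Data frame of category (and effect) counts.
#' @export
category_summary <- function(calls, types = NULL) {
  cat2 <- ifelse(calls$category == "exonic" & !is.na(calls$effect),
                 paste0("exonic:", calls$effect), calls$category)
  if (is.null(types)) {
    as.data.frame(table(category = cat2), responseName = "count")
  } else {
    as.data.frame(table(type = types, category = cat2),
                  responseName = "count")
  }
}
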