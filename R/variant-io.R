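#' Read a multi-sample VCF into a genotype matrix
#'
#' Biallelic records only: multi-allelic records (ALT containing a comma)
#' are dropped with a warning count. Genotypes are converted to
#' alternate-allele copy counts; `./.` becomes `NA`. INFO keys used by the
#' hard filters (QD, FS, MQ0, DP, SB, HRun, ReadPosRankSum) are parsed when
#' present, along with the QUAL column.
#'
#' @param path VCF 4.2 file.
#' @param pop_map named character vector or data frame (`sample`, `pop`)
#'   assigning every sample to a population.
#' @param l_eff effective sequence length to attach (bp).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_map, l_eff = NA_real_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.data.frame(pop_map)) pop_map <- setNames(pop_map$pop, pop_map$sample)
  missing_s <- setdiff(samples, names(pop_map))
  if (length(missing_s))
    stop("samples absent from pop_map: ", paste(missing_s, collapse = ", "))
  multi <- grepl(",", fx$ALT)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) dropped")
  keep <- !multi
  fx <- fx[keep, , drop = FALSE]
  if (nrow(fx) == 0) {
    geno <- matrix(integer(0), 0, length(samples))
  } else {
    gt <- v@gt[keep, -1, drop = FALSE]
    # strip FORMAT payload beyond GT; count alt alleles
    gtc <- sub(":.*", "", gt)
    geno <- matrix(NA_integer_, nrow(fx), length(samples))
    known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
               "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
    geno[] <- known[gtc]
  }
  info_keys <- c("QD", "FS", "MQ0", "DP", "SB", "HRun", "ReadPosRankSum")
  info <- data.frame(QUAL = suppressWarnings(as.numeric(fx$QUAL)))
  for (k in info_keys) {
    val <- rep(NA_real_, nrow(fx))
    hit <- regmatches(fx$INFO,
                      regexpr(paste0("(^|;)", k, "=[^;]*"), fx$INFO))
    has <- grepl(paste0("(^|;)", k, "="), fx$INFO)
    if (any(has)) val[has] <- as.numeric(sub(paste0(".*", k, "="), "", hit))
    info[[k]] <- val
  }
  genotype_matrix(fx$CHROM, as.integer(fx$POS), fx$REF, fx$ALT, geno,
                  samples, pop_map[samples], info = info, l_eff = l_eff)
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param x a [genotype_matrix()].
#' @param path output file (plain text).
#' @param filter optional character vector of FILTER values per record
#'   (e.g. the first firing hard-filter rule); default `PASS`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, filter = NULL) {
  n <- n_sites(x)
  filter <- filter %||% rep("PASS", n)
  info_keys <- setdiff(colnames(x$info), "QUAL")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=norpop",
           paste0("##contig=<ID=", unique(x$chrom), ">"),
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   info_keys, info_keys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  qual <- if (!is.null(x$info) && "QUAL" %in% colnames(x$info))
    format(x$info$QUAL, trim = TRUE) else rep(".", n)
  info_str <- if (length(info_keys)) {
    do.call(paste, c(lapply(info_keys, function(k) {
      paste0(k, "=", format(x$info[[k]], trim = TRUE, scientific = FALSE))
    }), sep = ";"))
  } else rep(".", n)
  gt <- matrix(".|.", n, length(x$samples))
  gt[!is.na(x$geno)] <- c("0/0", "0/1", "1/1")[x$geno[!is.na(x$geno)] + 1L]
  gt[is.na(x$geno)] <- "./."
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, qual, filter, info_str,
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Hard-filter thresholds for raw variant records
#'
#' The GATK-style reject rules applied to called records. A record fails if
#' any applicable rule fires. SNP rules: (1) `MQ0 >= 4 AND MQ0/(1.0*DP) >
#' 0.1`; (2) `SB >= -1.0 AND QUAL < 10` (the conjunction reading; a
#' disjunction would reject nearly everything); (3) `QUAL < 30 OR QD < 5 OR
#' HRun > 5 OR SB > -0.10`. Indel rules: `QD < 2`, `FS > 200`,
#' `ReadPosRankSum < -20`. All thresholds can be overridden.
#'
#' @param snp_qual_min,snp_qd_min,snp_hrun_max,snp_sb_max thresholds of SNP
#'   rule 3.
#' @param snp_mq0_min,snp_mq0_frac SNP rule 1 thresholds.
#' @param snp_sb_lowqual,snp_lowqual SNP rule 2 thresholds.
#' @param indel_qd_min,indel_fs_max,indel_rprs_min indel rule thresholds.
#' @return An object of class `hard_filter_config`.
#' @export
hard_filter_config <- function(snp_qual_min = 30, snp_qd_min = 5,
                               snp_hrun_max = 5, snp_sb_max = -0.10,
                               snp_mq0_min = 4, snp_mq0_frac = 0.1,
                               snp_sb_lowqual = -1.0, snp_lowqual = 10,
                               indel_qd_min = 2.0, indel_fs_max = 200.0,
                               indel_rprs_min = -20.0) {
  cfg <- as.list(environment())
  if (!all(vapply(cfg, is.finite, logical(1)))) stop("thresholds must be finite")
  structure(cfg, class = "hard_filter_config")
}

#' Apply hard filters to variant records
#'
#' Partitions records into passed and failed (a record fails iff any
#' applicable rule fires); a rule whose annotation keys are missing on a
#' record is skipped for that record and logged as a warning. Filtering is
#' idempotent.
#'
#' @param x a [genotype_matrix()] with an `info` table.
#' @param cfg a [hard_filter_config()].
#' @return List with `passed` and `failed` (genotype matrices), `filter`
#'   (per input record: `PASS` or first firing rule name) and `reasons`
#'   (data frame of every firing rule per failed record).
#' @export
apply_hard_filters <- function(x, cfg = hard_filter_config()) {
  info <- x$info
  if (is.null(info)) stop("records carry no INFO annotations")
  n <- n_sites(x)
  get <- function(k) if (k %in% colnames(info)) info[[k]] else rep(NA_real_, n)
  QUAL <- get("QUAL"); QD <- get("QD"); HRun <- get("HRun"); SB <- get("SB")
  MQ0 <- get("MQ0"); DP <- get("DP"); FS <- get("FS")
  RPRS <- get("ReadPosRankSum")
  snp <- x$type == "SNP"

  rules <- list(
    snp_mq0 = snp & (MQ0 >= cfg$snp_mq0_min) & (MQ0 / (1.0 * DP) > cfg$snp_mq0_frac),
    snp_sb_lowqual = snp & (SB >= cfg$snp_sb_lowqual) & (QUAL < cfg$snp_lowqual),
    snp_qual = snp & (QUAL < cfg$snp_qual_min | QD < cfg$snp_qd_min |
                        HRun > cfg$snp_hrun_max | SB > cfg$snp_sb_max),
    indel_qd = !snp & (QD < cfg$indel_qd_min),
    indel_fs = !snp & (FS > cfg$indel_fs_max),
    indel_rprs = !snp & (RPRS < cfg$indel_rprs_min)
  )
  n_skipped <- sum(vapply(rules, function(r) sum(is.na(r)), numeric(1)))
  if (n_skipped > 0)
    warning(n_skipped, " rule evaluation(s) skipped for missing annotations")
  fired <- vapply(rules, function(r) !is.na(r) & r, logical(max(n, 1)))
  if (n == 0) fired <- matrix(logical(0), 0, length(rules),
                              dimnames = list(NULL, names(rules)))
  if (n == 1) fired <- matrix(fired, 1, dimnames = list(NULL, names(rules)))
  fails <- rowSums(fired) > 0
  first_rule <- rep("PASS", n)
  if (any(fails))
    first_rule[fails] <- names(rules)[apply(fired[fails, , drop = FALSE], 1,
                                            which.max)]
  reasons <- data.frame(
    site = rep(site_keys(x), ncol(fired))[as.vector(fired)],
    rule = rep(names(rules), each = n)[as.vector(fired)])
  list(passed = subset_sites(x, which(!fails)),
       failed = subset_sites(x, which(fails)),
       filter = first_rule, reasons = reasons)
}

#' Write a gene model as GFF3 (plus genome FASTA)
#'
#' @param model a [make_gene_model()] result.
#' @param path GFF3 output file.
#' @param fasta_path optional FASTA output for the genome sequence.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path, fasta_path = NULL) {
  lines <- "##gff-version 3"
  g <- model$genes
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    tx <- paste0(id, ".t1")
    ttype <- if (g$biotype[i] == "protein_coding") "mRNA" else "ncRNA"
    lines <- c(lines,
      paste(g$chrom[i], "norpop", "gene", g$start[i], g$end[i], ".",
            g$strand[i], ".",
            paste0("ID=", id, ";biotype=", g$biotype[i]), sep = "\t"),
      paste(g$chrom[i], "norpop", ttype, g$start[i], g$end[i], ".",
            g$strand[i], ".", paste0("ID=", tx, ";Parent=", id), sep = "\t"))
    ex <- model$exons[model$exons$gene_id == id, , drop = FALSE]
    for (e in seq_len(nrow(ex)))
      lines <- c(lines, paste(ex$chrom[e], "norpop", "exon", ex$start[e],
                              ex$end[e], ".", g$strand[i], ".",
                              paste0("Parent=", tx), sep = "\t"))
    cd <- model$cds[model$cds$gene_id == id, , drop = FALSE]
    if (nrow(cd)) {
      ord <- if (g$strand[i] == "+") order(cd$start) else order(-cd$start)
      cd <- cd[ord, , drop = FALSE]
      lens <- cd$end - cd$start + 1
      phase <- (3 - cumsum(c(0, head(lens, -1))) %% 3) %% 3
      for (e in seq_len(nrow(cd)))
        lines <- c(lines, paste(cd$chrom[e], "norpop", "CDS", cd$start[e],
                                cd$end[e], ".", g$strand[i], phase[e],
                                paste0("Parent=", tx), sep = "\t"))
    }
  }
  writeLines(lines, path)
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(model$seq),
                                fasta_path)
  }
  invisible(path)
}

#' Read a gene model from GFF3 (plus genome FASTA)
#'
#' @param path GFF3 file with gene/mRNA-or-ncRNA/exon/CDS features.
#' @param fasta_path optional genome FASTA; without it codon-level
#'   classification is unavailable.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path, fasta_path = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  genes <- df[df$type == "gene", , drop = FALSE]
  tx <- df[df$type %in% c("mRNA", "ncRNA"), , drop = FALSE]
  tx_parent <- setNames(vapply(tx$Parent, `[`, character(1), 1), tx$ID)
  gdf <- data.frame(gene_id = genes$ID, chrom = genes$seqnames,
                    start = genes$start, end = genes$end,
                    strand = genes$strand,
                    biotype = if ("biotype" %in% names(genes)) genes$biotype
                              else ifelse(genes$ID %in%
                                tx_parent[tx$type == "mRNA"],
                                "protein_coding", "ncRNA"))
  feat_gene <- function(type) {
    f <- df[df$type == type, , drop = FALSE]
    if (nrow(f) == 0)
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer()))
    parent_tx <- vapply(f$Parent, `[`, character(1), 1)
    out <- data.frame(gene_id = unname(tx_parent[parent_tx]),
                      chrom = f$seqnames, start = f$start, end = f$end)
    out[order(out$gene_id, out$start), , drop = FALSE]
  }
  seqs <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seqs <- setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  }
  structure(list(genes = gdf[order(gdf$chrom, gdf$start), , drop = FALSE],
                 exons = feat_gene("exon"), cds = feat_gene("CDS"),
                 seq = seqs),
            class = "gene_model")
}

#' Write / read a gene-to-GO map as two-column TSV
#'
#' @param annotation a `go_annotation` (see [make_go_map()]).
#' @param path TSV file with columns `gene`, `term`.
#' @param universe background gene universe; when reading, defaults to the
#'   genes present in the file.
#' @return `write_go_map` returns `path` invisibly; `read_go_map` a
#'   `go_annotation`.
#' @export
write_go_map <- function(annotation, path) {
  write.table(annotation$map, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_go_map
#' @export
read_go_map <- function(path, universe = NULL) {
  map <- read.delim(path, colClasses = "character")
  go_annotation(map, universe = universe %||% unique(map$gene))
}
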