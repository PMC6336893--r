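#' Configuration for the synthetic-data generator
#'
#' Defaults describe the simulated study: 1-3 populations related by the
#' ancestral-change-plus-split model, diploid individuals formed by pairing
#' consecutive haplotypes, neutral infinite-sites mutation at
#' mu = 1.1e-8 per generation per site, and fully independent sites (no
#' recombination is modelled; every implemented statistic depends only on
#' per-site count distributions).
#'
#' With three populations the first two are drawn from the same daughter
#' deme of the split (two closely related "Finnish-like" populations) and
#' the third from the other deme.
#'
#' @param n_pops number of populations (1-3).
#' @param haploids_per_pop haploid sample size per population (even).
#' @param seq_length number of independent sites (bp).
#' @param mu mutation rate per generation per site.
#' @param demography a [demographic_params()].
#' @param sweep optional list with `center_bp`, `alpha_true` (per-bp sweep
#'   intensity) and optionally `affected_radius_bp`; used by
#'   [simulate_sweep_field()].
#' @param n_sites number of variant positions drawn by
#'   [simulate_sweep_field()] before monomorphic thinning.
#' @param seed integer seed; a fixed seed gives byte-identical fixtures.
#' @param known_fraction fraction of sites written to the known-sites file.
#' @param array_error_rate fraction of array genotypes flipped.
#' @param tstv_weight transition:transversion mutation weight (2 gives an
#'   expected Ts/Tv ratio of 2, the mammalian ballpark).
#' @param rec_off kept for the record: sites are always independent.
#' @param pop_names population labels.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, haploids_per_pop = 10, seq_length = 1e6,
                       mu = 1.1e-8,
                       demography = demographic_params(
                         nua = 2, Ta = 0.4, Td = 0.05,
                         nu1F = 1, nu2Y = 0.5, mu = mu),
                       sweep = NULL, n_sites = 1e5, seed = 1,
                       known_fraction = 0.9, array_error_rate = 0.1,
                       tstv_weight = 2, rec_off = TRUE,
                       pop_names = c("pop1", "pop2", "pop3")[seq_len(n_pops)]) {
  if (!n_pops %in% 1:3) stop("n_pops must be 1, 2 or 3")
  if (haploids_per_pop %% 2 != 0) stop("haploids_per_pop must be even")
  if (known_fraction < 0 || known_fraction > 1) stop("known_fraction in [0,1]")
  if (array_error_rate < 0 || array_error_rate > 1)
    stop("array_error_rate in [0,1]")
  if (n_pops * haploids_per_pop > 64) stop("at most 64 haplotypes in total")
  stopifnot(inherits(demography, "demographic_params"))
  structure(list(n_pops = n_pops, haploids_per_pop = haploids_per_pop,
                 seq_length = seq_length, mu = mu, demography = demography,
                 sweep = sweep, n_sites = n_sites, seed = as.integer(seed),
                 known_fraction = known_fraction,
                 array_error_rate = array_error_rate,
                 tstv_weight = tstv_weight, rec_off = TRUE,
                 pop_names = pop_names),
            class = "sim_config")
}

# deme membership of each haplotype (0 = daughter deme F, 1 = deme Y)
config_demes <- function(config) {
  h <- config$haploids_per_pop
  switch(config$n_pops,
         rep(0L, h),
         rep(c(0L, 1L), each = h),
         rep(c(0L, 0L, 1L), each = h))
}

config_pops <- function(config) {
  rep(config$pop_names, each = config$haploids_per_pop / 2)
}

# REF/ALT pairs with transition:transversion weighting; R RNG
draw_alleles <- function(n, tstv_weight) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  ref <- sample(bases, n, replace = TRUE)
  is_ts <- runif(n) < tstv_weight / (1 + tstv_weight)
  alt <- ifelse(is_ts, transition[ref], NA)
  tv <- is.na(alt)
  if (any(tv)) {
    alt[tv] <- vapply(ref[tv], function(r) {
      sample(setdiff(bases, c(r, transition[r])), 1)
    }, character(1))
  }
  list(ref = ref, alt = unname(alt))
}

# INFO annotations with values that pass every hard-filter rule, so the
# filtering stage is exercisable end-to-end on synthetic records
passing_info <- function(n) {
  data.frame(QUAL = rep(100, n), QD = 20, FS = 0, MQ0 = 0, DP = 30,
             SB = -1.5, HRun = 0, ReadPosRankSum = 0)
}

finish_sim <- function(config, pos, hap, sweep_center = NULL,
                       alpha_true = NULL, n_multi = 0) {
  n_hap <- config$n_pops * config$haploids_per_pop
  S <- length(pos)
  al <- draw_alleles(S, config$tstv_weight)
  geno <- hap[, seq(1, n_hap, by = 2), drop = FALSE] +
    hap[, seq(2, n_hap, by = 2), drop = FALSE]
  samples <- paste0(config_pops(config), "_",
                    sequence(rep(config$haploids_per_pop / 2, config$n_pops)))
  gm <- genotype_matrix(rep("chr1", S), pos, al$ref, al$alt, geno,
                        samples, config_pops(config),
                        info = passing_info(S), l_eff = config$seq_length)
  minor <- lapply(setNames(config$pop_names, config$pop_names), function(p) {
    cols <- which(config_pops(config) == p)
    ac <- rowSums(geno[, cols, drop = FALSE])
    unname(pmin(ac, 2 * length(cols) - ac))
  })
  truth <- list(params = unclass(config$demography),
                theta_site = 4 * config$demography$Na * config$mu,
                L_eff = config$seq_length, seed = config$seed,
                sweep_center = sweep_center, alpha_true = alpha_true,
                minor_counts = minor, n_multiallelic_dropped = n_multi)
  structure(list(matrix = gm, truth = truth, config = config),
            class = "norpop_sim")
}

#' Simulate neutral data under the demographic model
#'
#' Hudson coalescent per independent site: backward in time, two demes of
#' relative sizes `nu1F`, `nu2Y` merge at `Td` into one deme of size `nua`,
#' which reverts to the reference size at `Ta`; Poisson mutations on
#' branches; only biallelic sites are emitted (multi-hit sites are dropped
#' and counted). Within a constant-size control the expected pairwise
#' diversity per site is 4*Na*mu.
#'
#' @param config a [sim_config()].
#' @return A `norpop_sim` list: `matrix` (a [genotype_matrix()]), `truth`
#'   (true parameters, effective length, per-population minor-allele counts;
#'   written alongside fixtures, never read by analysis code), `config`.
#' @export
simulate_neutral <- function(config) {
  dem <- config$demography
  theta2 <- 2 * dem$Na * config$mu   # mutation rate per lineage per 2Na gens
  res <- .cpp_simulate_sites(config_demes(config), dem$nua, dem$Ta, dem$Td,
                             dem$nu1F, dem$nu2Y, theta2, config$seq_length,
                             config$seed)
  set.seed(config$seed)
  finish_sim(config, as.integer(res$site), res$haplotypes,
             n_multi = res$n_multiallelic_dropped)
}

#' Simulate a field of sites around a planted selective sweep
#'
#' Sites within the affected radius draw their folded minor-allele class
#' from the sweep-transformed spectrum at their distance from the center
#' (see [sweep_spectrum()]); sites beyond it draw from the background
#' spectrum. Sites rendered monomorphic by the sweep are not emitted, which
#' produces the characteristic trough of diversity around the center.
#'
#' @param config a [sim_config()] with `n_pops = 1` and a `sweep` block
#'   containing `center_bp` and `alpha_true`.
#' @param background_sfs a normalized folded background spectrum ([sfs()] or
#'   a plain proportion vector over classes 1..n/2).
#' @return A `norpop_sim` (see [simulate_neutral()]).
#' @export
simulate_sweep_field <- function(config, background_sfs) {
  if (config$n_pops != 1) stop("sweep fields are simulated per population")
  sw <- config$sweep
  if (is.null(sw)) stop("config$sweep block required")
  if (is.null(sw$alpha_true) || sw$alpha_true <= 0)
    stop("alpha_true must be > 0")
  n <- config$haploids_per_pop
  phi <- if (inherits(background_sfs, "norpop_sfs")) {
    stopifnot(background_sfs$n == n)
    sfs_proportions(background_sfs)
  } else background_sfs / sum(background_sfs)
  radius <- sw$affected_radius_bp %||% (-log(1e-6) / sw$alpha_true)

  set.seed(config$seed)
  pos <- sort(sample.int(config$seq_length, config$n_sites))
  d <- abs(pos - sw$center_bp)
  affected <- d <= radius
  k <- integer(length(pos))

  if (any(affected)) {
    FM <- sweep_full_matrix(phi, n)      # (n+1) x (n+1): rows B, cols derived
    pe <- -expm1(-sw$alpha_true * d[affected])
    W <- vapply(0:n, function(B) dbinom(B, n, pe), numeric(sum(affected)))
    if (sum(affected) == 1) W <- matrix(W, nrow = 1)
    P <- W %*% FM                        # full derived-count distribution
    cs <- P %*% upper.tri(diag(n + 1), diag = TRUE)   # row cumsums
    u <- runif(nrow(P)) * cs[, n + 1]
    k[affected] <- (n + 1) - as.integer(rowSums(cs >= u))
  }
  bg <- !affected
  if (any(bg)) {
    j <- sample.int(length(phi), sum(bg), replace = TRUE, prob = phi)
    flip <- runif(sum(bg)) < 0.5
    k[bg] <- ifelse(flip & j < n - j, n - j, j)
  }
  keep <- k > 0 & k < n
  pos <- pos[keep]; k <- k[keep]
  hap <- matrix(0L, length(pos), n)
  for (s in seq_along(pos)) hap[s, sample.int(n, k[s])] <- 1L
  finish_sim(config, pos, hap, sweep_center = sw$center_bp,
             alpha_true = sw$alpha_true)
}

#' @export
print.norpop_sim <- function(x, ...) {
  cat("synthetic dataset (seed", x$truth$seed, "):\n")
  print(x$matrix)
  invisible(x)
}

#' Generate a toy gene model over a toy genome
#'
#' Genes are placed non-overlapping with intergenic gaps, each with one
#' transcript of 1-3 exons; coding genes get UTR margins and a CDS whose
#' total length is divisible by 3 and whose sequence is rewritten with
#' stop-free codons plus a terminal stop (strand aware); the remainder are
#' marked non-coding (ncRNA).
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param genome named integer vector of chromosome lengths in bp.
#' @param coding_fraction fraction of genes that are protein coding.
#' @return An object of class `gene_model` with data frames `genes`,
#'   `exons`, `cds` and the genome sequence `seq` (named character vector).
#' @export
make_gene_model <- function(seed, n_genes, genome = c(chr1 = 100000),
                            coding_fraction = 0.8) {
  set.seed(seed)
  seqs <- vapply(genome, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  genes <- exons <- cds <- NULL
  if (n_genes > 0) {
    chrom_of <- sort(sample(rep(names(genome), length.out = max(n_genes, 1)))[
      seq_len(n_genes)])
    for (ch in unique(chrom_of)) {
      ng <- sum(chrom_of == ch)
      cursor <- 2500
      for (gi in seq_len(ng)) {
        gene_id <- sprintf("gene%03d", nrow(genes %||% data.frame()) + 1)
        n_ex <- sample(1:3, 1)
        ex_len <- sample(150:500, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) sample(50:300, n_ex - 1, replace = TRUE) else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (cursor + span + 2500 > genome[[ch]])
          stop("genome too small for requested genes")
        strand <- sample(c("+", "-"), 1)
        ex_start <- cursor + cumsum(c(0, head(ex_len, -1) + in_len))
        ex_end <- ex_start + ex_len - 1
        coding <- runif(1) < coding_fraction
        genes <- rbind(genes, data.frame(
          gene_id = gene_id, chrom = ch, start = cursor,
          end = cursor + span - 1, strand = strand,
          biotype = if (coding) "protein_coding" else "ncRNA"))
        exons <- rbind(exons, data.frame(gene_id = gene_id, chrom = ch,
                                         start = ex_start, end = ex_end))
        if (coding) {
          u5 <- sample(10:60, 1); u3 <- sample(10:60, 1)
          cds_len <- sum(ex_len) - u5 - u3
          u3 <- u3 + cds_len %% 3
          cds_len <- cds_len - cds_len %% 3
          # trim UTR margins off the transcript ends (strand aware)
          lead <- if (strand == "+") u5 else u3
          trail <- if (strand == "+") u3 else u5
          cd_start <- ex_start; cd_end <- ex_end
          cd_start[1] <- cd_start[1] + lead
          cd_end[n_ex] <- cd_end[n_ex] - trail
          cds <- rbind(cds, data.frame(gene_id = gene_id, chrom = ch,
                                       start = cd_start, end = cd_end))
          # rewrite the CDS with stop-free codons ending in a stop
          codons <- setdiff(apply(expand.grid(c("A","C","G","T"),
                                              c("A","C","G","T"),
                                              c("A","C","G","T")),
                                  1, paste, collapse = ""),
                            c("TAA", "TAG", "TGA"))
          body <- c("ATG", sample(codons, cds_len / 3 - 2, replace = TRUE),
                    sample(c("TAA", "TAG", "TGA"), 1))
          cds_seq <- paste(body, collapse = "")
          if (strand == "-") cds_seq <- revcomp(cds_seq)
          offset <- 0
          for (e in seq_len(n_ex)) {
            w <- cd_end[e] - cd_start[e] + 1
            substr(seqs[[ch]], cd_start[e], cd_end[e]) <-
              substr(cds_seq, offset + 1, offset + w)
            offset <- offset + w
          }
        }
        cursor <- cursor + span + sample(2200:3500, 1)
      }
    }
  }
  structure(list(genes = genes %||% data.frame(gene_id = character(),
                                               chrom = character(),
                                               start = integer(),
                                               end = integer(),
                                               strand = character(),
                                               biotype = character()),
                 exons = exons %||% data.frame(gene_id = character(),
                                               chrom = character(),
                                               start = integer(),
                                               end = integer()),
                 cds = cds %||% data.frame(gene_id = character(),
                                           chrom = character(),
                                           start = integer(),
                                           end = integer()),
                 seq = seqs),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "protein_coding"), "coding ) on",
      length(x$seq), "chromosome(s)\n")
  invisible(x)
}

#' Generate a toy gene-to-GO annotation
#'
#' @param seed integer seed.
#' @param genes character vector of gene ids (the background universe).
#' @param n_terms number of GO terms.
#' @param mean_size mean number of genes per term.
#' @return An object of class `go_annotation`: `map` (data frame gene,
#'   term), `terms` (term metadata), `universe`.
#' @export
make_go_map <- function(seed, genes, n_terms = 20, mean_size = NULL) {
  set.seed(seed)
  mean_size <- mean_size %||% max(2, round(length(genes) / 4))
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  map <- do.call(rbind, lapply(term_ids, function(tm) {
    size <- min(length(genes), max(1, rpois(1, mean_size)))
    data.frame(gene = sample(genes, size), term = tm)
  }))
  if (is.null(map)) map <- data.frame(gene = character(), term = character())
  go_annotation(map, universe = genes,
                terms = data.frame(term = term_ids,
                                   description = paste("synthetic term",
                                                       seq_len(n_terms)),
                                   namespace = "biological_process"))
}

#' Known-sites catalogue emulating a dbSNP extract
#'
#' @param x a [genotype_matrix()].
#' @param fraction fraction of sites included.
#' @param seed integer seed.
#' @return Data frame with columns CHROM, POS, REF, ALT.
#' @export
make_known_sites <- function(x, fraction, seed) {
  set.seed(seed)
  keep <- runif(n_sites(x)) < fraction
  data.frame(CHROM = x$chrom[keep], POS = x$pos[keep], REF = x$ref[keep],
             ALT = x$alt[keep])
}

#' Array-genotype table with a controlled error rate
#'
#' A long table of (sample, site, genotype) entries copied from the
#' sequencing genotypes, with a fraction flipped to one of the other two
#' genotype codes to emulate array error.
#'
#' @param x a [genotype_matrix()].
#' @param n_array_sites number of sites on the "array".
#' @param error_rate fraction of genotypes flipped.
#' @param seed integer seed.
#' @return Data frame sample, CHROM, POS, REF, ALT, gt.
#' @export
make_array_genotypes <- function(x, n_array_sites, error_rate, seed) {
  set.seed(seed)
  sel <- sort(sample.int(n_sites(x), min(n_array_sites, n_sites(x))))
  tab <- expand.grid(row = sel, sample = x$samples, stringsAsFactors = FALSE)
  gt <- x$geno[cbind(tab$row, match(tab$sample, x$samples))]
  flip <- !is.na(gt) & runif(length(gt)) < error_rate
  gt[flip] <- (gt[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3
  data.frame(sample = tab$sample, CHROM = x$chrom[tab$row],
             POS = x$pos[tab$row], REF = x$ref[tab$row],
             ALT = x$alt[tab$row], gt = gt)
}

#' Write all fixture files for a simulated dataset
#'
#' Emits VCF, truth JSON (never read by analysis code), known-sites TSV and
#' array-genotype TSV into a directory.
#'
#' @param sim a `norpop_sim` from [simulate_neutral()] /
#'   [simulate_sweep_field()].
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             truth = file.path(dir, "truth.json"),
             known = file.path(dir, "known_sites.tsv"),
             array = file.path(dir, "array_genotypes.tsv"))
  write_vcf(sim$matrix, paths["vcf"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  known <- make_known_sites(sim$matrix, cfg$known_fraction, cfg$seed + 1L)
  write.table(known, paths["known"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  arr <- make_array_genotypes(sim$matrix,
                              n_array_sites = min(5000, n_sites(sim$matrix)),
                              error_rate = cfg$array_error_rate,
                              seed = cfg$seed + 2L)
  write.table(arr, paths["array"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a known-sites TSV
#' @param path file with columns CHROM, POS, REF, ALT.
#' @return Data frame.
#' @export
read_known_sites <- function(path) {
  read.delim(path, colClasses = c(CHROM = "character", REF = "character",
                                  ALT = "character"))
}

#' Read an array-genotype TSV
#' @param path file written like [make_array_genotypes()] output.
#' @return Data frame.
#' @export
read_array_genotypes <- function(path) {
  read.delim(path, colClasses = c(sample = "character", CHROM = "character",
                                  REF = "character", ALT = "character"))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
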