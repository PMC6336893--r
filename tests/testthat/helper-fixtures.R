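# Shared in-code fixtures: tiny, deterministic datasets built at load time.

# 6 sites x 4 individuals (2 per population), hand-written genotypes
tiny_gm <- function() {
  genotype_matrix(
    chrom = rep("chr1", 6),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = c("A", "C", "G", "T", "A", "AT"),
    alt = c("G", "T", "C", "A", "C", "A"),
    geno = rbind(c(0L, 1L, 0L, 0L),   # segregates only in popA
                 c(1L, 1L, 1L, 1L),   # segregates in both
                 c(0L, 0L, 2L, 2L),   # fixed alt in popB
                 c(2L, 2L, 2L, 2L),   # fixed alt everywhere
                 c(0L, NA, 1L, 0L),   # missing genotype in popA
                 c(0L, 1L, 0L, 1L)),  # indel
    samples = c("a1", "a2", "b1", "b2"),
    pops = c("popA", "popA", "popB", "popB"),
    info = data.frame(QUAL = c(100, 5, 100, 100, 100, 100),
                      QD = c(20, 20, 2, 20, 20, 1),
                      FS = c(0, 0, 0, 0, 0, 250),
                      MQ0 = c(0, 0, 5, 0, 0, 0),
                      DP = c(30, 30, 10, 30, 30, 30),
                      SB = c(-1.5, -0.5, -1.5, -0.05, -1.5, -1.5),
                      HRun = c(0, 0, 0, 0, 7, 0),
                      ReadPosRankSum = c(0, 0, 0, 0, 0, -25)),
    l_eff = 10000)
}

# deterministic single-gene model on a 1 kb toy genome: one coding gene with
# two exons, used by annotation tests (plus strand); a fresh seed makes the
# CDS stop-free by construction.
toy_gene_model <- function(seed = 401, strand_pick = NULL) {
  m <- make_gene_model(seed, n_genes = 1, genome = c(chr1 = 20000))
  if (!is.null(strand_pick)) {
    tries <- 0
    while (m$genes$strand[1] != strand_pick && tries < 50) {
      seed <- seed + 1; tries <- tries + 1
      m <- make_gene_model(seed, n_genes = 1, genome = c(chr1 = 20000))
    }
  }
  m
}

# brute-force oracle: apply a SNP to the genome, rebuild the full CDS,
# translate whole protein before/after, and categorize the change.
oracle_snp_effect <- function(model, gene_id, pos, alt) {
  g <- model$genes[model$genes$gene_id == gene_id, ]
  cd <- model$cds[model$cds$gene_id == gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  seqs <- model$seq
  mutated <- seqs[[g$chrom]]
  substr(mutated, pos, pos) <- alt
  cds_of <- function(genome) {
    s <- paste(substring(genome, cd$start, cd$end), collapse = "")
    if (g$strand == "-") s <- norpop:::revcomp(s)
    s
  }
  translate <- function(s) {
    paste(Biostrings::GENETIC_CODE[substring(
      s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))], collapse = "")
  }
  p0 <- translate(cds_of(seqs[[g$chrom]]))
  p1 <- translate(cds_of(mutated))
  if (p0 == p1) return("synonymous")
  i <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  a0 <- substring(p0, i[1], i[1]); a1 <- substring(p1, i[1], i[1])
  if (a1 == "*") "stopgain" else if (a0 == "*") "stoploss"
  else "nonsynonymous"
}

# exhaustive sweep-spectrum oracle for small n: enumerate escape sets and
# every background configuration explicitly, no matrix shortcuts.
oracle_sweep_spectrum <- function(phi, d, alpha, n) {
  psi <- numeric(n - 1)
  for (j in seq_len(floor(n / 2))) {
    if (j == n - j) psi[j] <- phi[j]
    else { psi[j] <- phi[j] / 2; psi[n - j] <- phi[j] / 2 }
  }
  pe <- 1 - exp(-alpha * d)
  full <- numeric(n + 1)   # P(total derived = 0..n)
  for (B in 0:n) {
    wB <- choose(n, B) * pe^B * (1 - pe)^(n - B)
    if (B == n) {
      for (i in 1:(n - 1)) full[i + 1] <- full[i + 1] + wB * psi[i]
      next
    }
    m <- B + 1
    for (i in 0:m) {
      # P(i derived among m) by hypergeometric draw from each psi class
      q <- 0
      for (kk in 1:(n - 1))
        q <- q + psi[kk] * dhyper(i, kk, n - kk, m)
      p_anc <- i / m
      if (i > 0) {
        tot <- i + n - B - 1
        full[tot + 1] <- full[tot + 1] + wB * q * p_anc
      }
      full[i + 1] <- full[i + 1] + wB * q * (1 - p_anc)
    }
  }
  folded <- vapply(seq_len(floor(n / 2)), function(j) {
    if (j == n - j) full[j + 1] else full[j + 1] + full[n - j + 1]
  }, numeric(1))
  s <- sum(folded)
  if (s <= 0) rep(0, floor(n / 2)) else folded / s
}
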