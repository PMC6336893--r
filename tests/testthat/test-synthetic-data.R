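test_that("simulation is deterministic in the seed and seeds differ", {
  cfg <- sim_config(n_pops = 2, seq_length = 3e4, seed = 5)
  s1 <- simulate_neutral(cfg)
  s2 <- simulate_neutral(cfg)
  expect_identical(s1$matrix$pos, s2$matrix$pos)
  expect_identical(s1$matrix$geno, s2$matrix$geno)
  expect_identical(s1$matrix$ref, s2$matrix$ref)
  s3 <- simulate_neutral(sim_config(n_pops = 2, seq_length = 3e4, seed = 6))
  expect_false(identical(s1$matrix$pos, s3$matrix$pos))
})

test_that("constant-size neutral simulation matches theta in expectation", {
  # nua = nu1F = 1 with one population is a constant-size coalescent;
  # E[pi] = 4*Na*mu = 0.001 per site
  cfg <- sim_config(
    n_pops = 1, seq_length = 2e5, seed = 61,
    demography = demographic_params(nua = 1, Ta = 0.4, Td = 0.05,
                                    nu1F = 1, nu2Y = 1))
  sim <- simulate_neutral(cfg)
  pi_hat <- nucleotide_diversity(sim$matrix, "pop1")
  theta <- 4 * cfg$demography$Na * cfg$mu
  expect_equal(pi_hat, theta, tolerance = 0.1)
  n <- cfg$haploids_per_pop
  tw <- watterson_theta(segregating_sites(sim$matrix, "pop1"), n,
                        sim$matrix$l_eff)
  expect_equal(tw, theta, tolerance = 0.1)
})

test_that("constant-size folded SFS matches the 1/k + 1/(n-k) expectation", {
  cfg <- sim_config(
    n_pops = 1, seq_length = 3e5, seed = 62,
    demography = demographic_params(nua = 1, Ta = 0.4, Td = 0.05,
                                    nu1F = 1, nu2Y = 1))
  sim <- simulate_neutral(cfg)
  fs <- build_folded_sfs(sim$matrix, "pop1")
  n <- 10
  theory <- vapply(1:5, function(k)
    if (k == n - k) 1 / k else 1 / k + 1 / (n - k), numeric(1))
  expect_equal(unname(sfs_proportions(fs)), theory / sum(theory),
               tolerance = 0.08)
})

test_that("Ts/Tv of generated alleles reflects the mutation weighting", {
  cfg <- sim_config(n_pops = 1, seq_length = 3e5, seed = 63, tstv_weight = 2)
  sim <- simulate_neutral(cfg)
  expect_equal(tstv_ratio(sim$matrix), 2, tolerance = 0.15)
  cfg1 <- sim_config(n_pops = 1, seq_length = 3e5, seed = 63,
                     tstv_weight = 0.5)
  expect_equal(tstv_ratio(simulate_neutral(cfg1)$matrix), 0.5,
               tolerance = 0.15)
})

test_that("truth block records the generating parameters and minor counts", {
  cfg <- sim_config(n_pops = 2, seq_length = 3e4, seed = 9)
  sim <- simulate_neutral(cfg)
  expect_equal(sim$truth$params$nua, 2)
  expect_equal(sim$truth$theta_site, 4 * 22727 * 1.1e-8)
  g <- sim$matrix$geno[, sim$matrix$pops == "pop1", drop = FALSE]
  ac <- rowSums(g)
  expect_equal(sim$truth$minor_counts$pop1, unname(pmin(ac, 10 - ac)))
})

test_that("sweep field thins monomorphic sites around the center", {
  n <- 10
  phi <- fold_spectrum(1 / (1:(n - 1)), n); phi <- phi / sum(phi)
  cfg <- sim_config(n_pops = 1, seq_length = 4e5, seed = 71, n_sites = 2e4,
                    sweep = list(alpha_true = 3e-4, center_bp = 2e5))
  sw <- simulate_sweep_field(cfg, phi)
  pos <- sw$matrix$pos
  # expected retention within 1 kb of the center is ~35% (the escape
  # probability at alpha = 3e-4 reaches 0.26 by d = 1 kb), ~100% far away
  near <- sum(abs(pos - 2e5) < 1e3)
  far <- sum(abs(pos - 3.5e5) < 1e3)
  expect_lt(near, 0.6 * far)   # diversity trough at the center
  expect_equal(sw$truth$sweep_center, 2e5)
})

test_that("fixture files are written, re-readable and small", {
  cfg <- sim_config(n_pops = 2, seq_length = 2e4, seed = 15)
  sim <- simulate_neutral(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_fixtures(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_vcf(paths[["vcf"]],
                   setNames(as.character(sim$matrix$pops),
                            sim$matrix$samples),
                   l_eff = cfg$seq_length)
  expect_equal(unname(back$geno), unname(sim$matrix$geno))
  known <- read_known_sites(paths[["known"]])
  expect_lt(nrow(known), n_sites(sim$matrix))
  arr <- read_array_genotypes(paths[["array"]])
  expect_true(all(arr$sample %in% sim$matrix$samples))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$params$nua, 2)
})

test_that("gene model invariants: CDS in frame, stop-free body, ATG start", {
  for (seed in c(1, 2, 3)) {
    m <- make_gene_model(seed, n_genes = 5, genome = c(chr1 = 60000))
    for (id in m$genes$gene_id[m$genes$biotype == "protein_coding"]) {
      cd <- m$cds[m$cds$gene_id == id, , drop = FALSE]
      cd <- cd[order(cd$start), ]
      s <- paste(substring(m$seq[["chr1"]], cd$start, cd$end), collapse = "")
      if (m$genes$strand[m$genes$gene_id == id] == "-")
        s <- norpop:::revcomp(s)
      expect_equal(nchar(s) %% 3, 0)
      codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
      expect_equal(codons[1], "ATG")
      expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
      expect_false(any(head(codons, -1) %in% c("TAA", "TAG", "TGA")))
      # CDS nested in exons, exons in gene
      ex <- m$exons[m$exons$gene_id == id, ]
      g <- m$genes[m$genes$gene_id == id, ]
      expect_true(all(ex$start >= g$start & ex$end <= g$end))
      for (i in seq_len(nrow(cd)))
        expect_true(any(cd$start[i] >= ex$start & cd$end[i] <= ex$end))
    }
    # genes do not overlap
    g <- m$genes[order(m$genes$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("configuration validation", {
  expect_error(sim_config(n_pops = 4), "n_pops")
  expect_error(sim_config(haploids_per_pop = 5), "even")
  expect_error(sim_config(n_pops = 3, haploids_per_pop = 30), "64")
  expect_error(sim_config(known_fraction = 1.5), "known_fraction")
})
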