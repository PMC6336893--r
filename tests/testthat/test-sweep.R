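test_that("sweep spectrum equals exhaustive enumeration for n <= 6", {
  elapsed <- system.time({
    for (n in 3:6) {
      k <- floor(n / 2)
      set.seed(n)
      phi <- runif(k); phi <- phi / sum(phi)
      for (d in c(0, 1, 100, 5000, 2e5)) {
        for (alpha in c(1e-5, 1e-4, 1e-3)) {
          expect_equal(sweep_spectrum(phi, d, alpha, n),
                       oracle_sweep_spectrum(phi, d, alpha, n),
                       tolerance = 1e-12,
                       info = sprintf("n=%d d=%g alpha=%g", n, d, alpha))
        }
      }
    }
  })["elapsed"]
  expect_lt(elapsed, 5)
})

test_that("sweep spectrum limits: background far away, monomorphic at d = 0", {
  phi <- c(0.55, 0.25, 0.12, 0.05, 0.03)
  far <- sweep_spectrum(phi, d = 1e9, alpha = 1e-4, n = 10)
  expect_equal(far, phi, tolerance = 1e-9)
  at0 <- sweep_spectrum(phi, d = 0, alpha = 1e-4, n = 10)
  expect_equal(at0, rep(0, 5))
  near <- sweep_spectrum(phi, d = 10, alpha = 1e-4, n = 10)
  # close to the sweep, singletons dominate the polymorphic mass
  expect_gt(near[1], phi[1])
})

test_that("sweep spectrum is a probability vector and varies smoothly in d", {
  phi <- c(0.5, 0.3, 0.2)
  prev <- NULL
  ds <- seq(100, 1e5, length.out = 300)
  for (d in ds) {
    s <- sweep_spectrum(phi, d, 1e-4, n = 6)
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_true(all(s >= 0))
    # ~333 bp steps: the spectrum is continuous in d, so neighbouring
    # evaluations stay close
    if (!is.null(prev)) expect_lt(max(abs(s - prev)), 0.06)
    prev <- s
  }
})

test_that("clr_at agrees with a direct R implementation", {
  n <- 10
  phi <- c(0.5, 0.22, 0.13, 0.09, 0.06)
  set.seed(3)
  sites <- data.frame(pos = sort(sample.int(2e5, 400)),
                      minor = sample(1:5, 400, replace = TRUE,
                                     prob = phi))
  eps <- 1 / (2 * nrow(sites))
  phi_s <- (phi + eps) / sum(phi + eps)
  r_llr <- function(x, alpha) {
    ll <- 0
    for (s in seq_len(nrow(sites))) {
      d <- abs(sites$pos[s] - x)
      pe <- 1 - exp(-alpha * d)
      if (pe >= 1 - 1e-6) next
      # eps-smoothed per-class probability as used by the scan
      FM <- norpop:::sweep_full_matrix(phi_s, n)
      w <- dbinom(0:n, n, pe)
      folded <- fold_spectrum(as.vector(w %*% FM)[2:n], n) + eps
      p <- folded / sum(folded)
      ll <- ll + log(p[sites$minor[s]]) - log(phi_s[sites$minor[s]])
    }
    ll
  }
  alphas <- c(1e-5, 1e-4, 1e-3)
  res <- clr_at(1e5, sites, phi, n, alpha_grid = alphas)
  direct <- max(vapply(alphas, function(a) r_llr(1e5, a), numeric(1)))
  # golden-section refinement can only raise the maximum
  expect_gte(res$CLR + 1e-6, 2 * max(0, direct))
  # and the grid value itself matches to interpolation accuracy
  one <- clr_at(1e5, sites, phi, n, alpha_grid = c(1e-4, 1e-4, 1e-4))
  expect_equal(one$CLR, 2 * max(0, r_llr(1e5, 1e-4)), tolerance = 1e-4)
})

test_that("planted sweep is localized by the scan", {
  n <- 10
  psi <- 1 / (1:(n - 1))
  phi <- fold_spectrum(psi, n); phi <- phi / sum(phi)
  cfg <- sim_config(n_pops = 1, seq_length = 1e6, seed = 301, n_sites = 2e4,
                    sweep = list(alpha_true = 1e-4, center_bp = 6e5))
  sw <- simulate_sweep_field(cfg, phi)
  scan <- clr_scan(sw$matrix, chrom_length = 1e6)
  expect_s3_class(scan, "sweep_scan")
  expect_equal(nrow(scan), 200)
  expect_lt(abs(scan$pos[which.max(scan$CLR)] - 6e5), 1e5)
})

test_that("outlier calling flags the top fraction with ties included", {
  scan <- structure(data.frame(chrom = "chr1", pos = 5000 * (1:1000),
                               CLR = c(1000:2, 999)),
                    class = c("sweep_scan", "data.frame"))
  out <- call_outliers(scan, top_fraction = 0.005)
  expect_equal(sum(out$outlier), 5)
  tied <- structure(data.frame(chrom = "chr1", pos = 5000 * (1:100),
                               CLR = rep(7, 100)),
                    class = c("sweep_scan", "data.frame"))
  out2 <- call_outliers(tied, top_fraction = 0.005)
  expect_true(all(out2$outlier))
})

test_that("outlier cutoffs are per chromosome by default", {
  scan <- structure(data.frame(chrom = rep(c("chr1", "chr2"), each = 200),
                               pos = rep(5000 * (1:200), 2),
                               CLR = c(1:200, 1001:1200)),
                    class = c("sweep_scan", "data.frame"))
  out <- call_outliers(scan, top_fraction = 0.01)
  expect_equal(sum(out$outlier[out$chrom == "chr1"]), 2)
  expect_equal(sum(out$outlier[out$chrom == "chr2"]), 2)
  glob <- call_outliers(scan, top_fraction = 0.01, per_chromosome = FALSE)
  expect_equal(sum(glob$outlier[glob$chrom == "chr1"]), 0)
})

test_that("window annotation reports genes within 150 kb windows", {
  model <- make_gene_model(77, n_genes = 4, genome = c(chr1 = 100000))
  g <- model$genes
  out <- data.frame(chrom = "chr1", pos = g$start[2])
  ann <- annotate_windows(out, model, window = 150000)
  # every gene within 75 kb of the outlier must be reported
  expected <- g$gene_id[g$end >= g$start[2] - 75000 &
                          g$start <= g$start[2] + 75000]
  expect_setequal(ann$per_outlier[[1]], expected)
  expect_setequal(ann$genes, expected)
  narrow <- annotate_windows(out, model, window = 10)
  expect_equal(narrow$genes, g$gene_id[2])
})
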