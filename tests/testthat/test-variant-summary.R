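test_that("breed variant sets follow the segregating rule", {
  gm <- tiny_gm()
  keys <- site_keys(gm)
  sets <- breed_variant_sets(gm)
  # popA: site1 (1/4 alt), site2 (2/4), site6 (1/4); site5 has a missing
  # genotype (complete-case excluded); site4 fixed alt (not segregating)
  expect_setequal(sets$popA, keys[c(1, 2, 6)])
  # popB: site2, site5 (1/4), site6; site3 fixed alt in popB
  expect_setequal(sets$popB, keys[c(2, 5, 6)])
})

test_that("nonref mode counts any alternate copy", {
  gm <- tiny_gm()
  sets <- breed_variant_sets(gm, mode = "nonref")
  expect_setequal(sets$popA, site_keys(gm)[c(1, 2, 4, 6)])
  expect_setequal(sets$popB, site_keys(gm)[c(2, 3, 4, 5, 6)])
})

test_that("venn regions partition the union for 3 sets", {
  sets <- list(A = c("s1", "s2", "s3", "s7"),
               B = c("s2", "s3", "s4", "s7"),
               C = c("s3", "s5", "s7"))
  v <- venn_sharing(sets)
  expect_equal(sum(v$count), length(unique(unlist(sets))))
  expect_equal(v$count[v$region == "A & B & C"], 2)   # s3, s7
  expect_equal(v$count[v$region == "A & B"], 1)       # s2
  expect_equal(v$count[v$region == "A"], 1)           # s1
  expect_equal(v$count[v$region == "C"], 1)           # s5
  expect_equal(sum(v$pct), 100, tolerance = 0.5)
})

test_that("venn percentages reproduce the published sharing arithmetic", {
  # 4,089,049 of 11,328,383 shared by all three = 36.1%
  expect_equal(venn_percentage(4089049, 11328383), 36.1)
  # private fractions: 1,896,026 / 10,836,904 whole-genome SNPs in one breed
  expect_equal(venn_percentage(5229270, 11328383), 46.2)
})

test_that("hom/het accounting and ratio", {
  gm <- tiny_gm()
  hhA <- hom_het_ratio(gm, "popA")
  # popA genotypes: a1 = (0,1,0,2,0,0) -> hom 1, het 1;
  #                 a2 = (1,1,0,2,NA,1) -> hom 1, het 3
  expect_equal(hhA$per_individual$hom, c(1, 1))
  expect_equal(hhA$per_individual$het, c(1, 3))
  expect_equal(hhA$hom, 2)
  expect_equal(hhA$het, 4)
  expect_equal(hhA$ratio, 2)
  # published whole-genome ratio: 2,556,546 het / 2,078,342 hom = 1.23
  expect_equal(round(2556546 / 2078342, 2), 1.23)
})

test_that("Ts/Tv counts transitions correctly", {
  gm <- tiny_gm()
  # SNP pairs: AG (ts), CT (ts), GC (tv), TA (tv), AC (tv); indel excluded
  expect_equal(tstv_ratio(gm), 2 / 3)
  expect_equal(tstv_ratio(data.frame(REF = c("A", "G"), ALT = c("G", "A"))),
               Inf)
  expect_equal(tstv_ratio(data.frame(REF = "A", ALT = "T")), 0)
  expect_true(is.nan(tstv_ratio(data.frame(REF = character(),
                                           ALT = character()))))
})

test_that("novel classification is allele-aware", {
  gm <- tiny_gm()
  known <- data.frame(CHROM = c("chr1", "chr1", "chr1"),
                      POS = c(100L, 200L, 300L),
                      REF = c("A", "C", "G"),
                      ALT = c("G", "T", "T"))   # site 3 has different ALT
  res <- classify_novel(gm, known)
  expect_setequal(res$known, site_keys(gm)[1:2])
  expect_equal(res$novel_fraction, 4 / 6)
  # published: 664,494 novel of 10,836,904 = 6.13%
  expect_equal(round(100 * 664494 / 10836904, 2), 6.13)
})

test_that("per-population novel fractions use the population sets", {
  gm <- tiny_gm()
  sets <- breed_variant_sets(gm)
  known <- data.frame(CHROM = "chr1", POS = 200L, REF = "C", ALT = "T")
  res <- classify_novel(gm, known, sets)
  expect_equal(unname(res$per_population["popA"]), 2 / 3)  # sites 1,6 novel
  expect_equal(unname(res$per_population["popB"]), 2 / 3)
})

test_that("genotype concordance matches a hand computation", {
  gm <- tiny_gm()
  arr <- data.frame(sample = c("a1", "a1", "b2", "b2", "a2"),
                    CHROM = "chr1",
                    POS = c(100L, 200L, 200L, 300L, 500L),
                    REF = c("A", "C", "C", "G", "A"),
                    ALT = c("G", "T", "T", "C", "C"),
                    gt = c(0L, 1L, 0L, 2L, 1L))
  # truth: a1@100 = 0 (match), a1@200 = 1 (match), b2@200 = 1 (mismatch),
  # b2@300 = 2 (match), a2@500 = NA (excluded)
  res <- genotype_concordance(gm, arr)
  expect_equal(res$n_compared, 4)
  expect_equal(res$concordance, 75)
  expect_error(genotype_concordance(gm, transform(arr, sample = "zz")),
               "no overlapping")
})

test_that("simulated array concordance reflects the planted error rate", {
  cfg <- sim_config(n_pops = 1, seq_length = 5e4, seed = 91,
                    array_error_rate = 0.1)
  sim <- simulate_neutral(cfg)
  arr <- make_array_genotypes(sim$matrix, 5000, 0.1, seed = 92)
  res <- genotype_concordance(sim$matrix, arr)
  expect_gt(res$concordance, 85)
  expect_lt(res$concordance, 95)
})
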