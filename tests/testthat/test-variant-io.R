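test_that("VCF round-trip preserves sites, genotypes and INFO", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, pop_map = setNames(as.character(gm$pops),
                                            gm$samples),
                   l_eff = gm$l_eff)
  expect_identical(back$chrom, gm$chrom)
  expect_identical(back$pos, gm$pos)
  expect_identical(back$ref, gm$ref)
  expect_identical(back$alt, gm$alt)
  expect_identical(back$type, gm$type)
  expect_equal(unname(back$geno), unname(gm$geno))
  for (k in colnames(gm$info))
    expect_equal(back$info[[k]], gm$info[[k]], tolerance = 1e-9)
})

test_that("multi-allelic records are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t10\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "chr1\t20\t.\tC\tT,G\t50\tPASS\t.\tGT\t1/2"), path)
  expect_warning(gm <- read_vcf(path, c(s1 = "p1")), "multi-allelic")
  expect_equal(n_sites(gm), 1L)
  expect_equal(gm$pos, 10L)
})

test_that("missing genotypes round-trip as NA", {
  gm <- tiny_gm()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, setNames(as.character(gm$pops), gm$samples))
  expect_true(is.na(back$geno[5, 2]))
})

test_that("hard filters reproduce the documented reject rules", {
  gm <- tiny_gm()
  res <- apply_hard_filters(gm)
  # site 1 passes; site 2 fails snp_sb_lowqual (SB >= -1 AND QUAL < 10) and
  # snp_qual (QUAL < 30); site 3 fails snp_mq0 (MQ0 >= 4, MQ0/DP = 0.5) and
  # snp_qual (QD < 5); site 4 fails snp_qual (SB > -0.10); site 5 fails
  # snp_qual (HRun > 5); site 6 (indel) fails all three indel rules.
  expect_equal(res$filter,
               c("PASS", "snp_sb_lowqual", "snp_mq0", "snp_qual",
                 "snp_qual", "indel_qd"))
  expect_equal(n_sites(res$passed), 1L)
  expect_equal(n_sites(res$failed), 5L)
  expect_setequal(res$reasons$rule[res$reasons$site == site_keys(gm)[6]],
                  c("indel_qd", "indel_fs", "indel_rprs"))
})

test_that("indels are exempt from SNP rules and vice versa", {
  gm <- tiny_gm()
  # give the indel passing indel-annotations but failing SNP-annotations
  gm$info[6, ] <- list(5, 20, 0, 10, 30, -0.05, 10, 0)
  res <- apply_hard_filters(gm)
  expect_equal(res$filter[6], "PASS")
})

test_that("missing annotation keys skip the rule with a warning", {
  gm <- tiny_gm()
  gm$info$MQ0 <- NULL
  expect_warning(res <- apply_hard_filters(gm), "skipped")
  # site 3 no longer fails snp_mq0 but still fails snp_qual via QD < 5
  expect_equal(res$filter[3], "snp_qual")
})

test_that("filtering is idempotent", {
  gm <- tiny_gm()
  once <- apply_hard_filters(gm)
  twice <- apply_hard_filters(once$passed)
  expect_equal(n_sites(twice$passed), n_sites(once$passed))
  expect_equal(n_sites(twice$failed), 0L)
})

test_that("thresholds are overridable and validated", {
  gm <- tiny_gm()
  lax <- hard_filter_config(snp_qual_min = 0, snp_qd_min = 0,
                            snp_hrun_max = 100, snp_sb_max = 100,
                            snp_mq0_min = 100, snp_lowqual = 0,
                            indel_qd_min = 0, indel_fs_max = 1e6,
                            indel_rprs_min = -1e6)
  res <- apply_hard_filters(gm, lax)
  expect_equal(n_sites(res$failed), 0L)
  expect_error(hard_filter_config(snp_qual_min = NA), "finite")
})

test_that("gene model GFF3 + FASTA round-trip", {
  model <- make_gene_model(11, n_genes = 3, genome = c(chr1 = 30000))
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gff3(model, gff, fasta_path = fa)
  back <- read_gene_model(gff, fa)
  expect_equal(back$genes$gene_id, model$genes$gene_id)
  expect_equal(back$genes$start, model$genes$start)
  expect_equal(back$genes$end, model$genes$end)
  expect_equal(back$genes$strand, model$genes$strand)
  expect_equal(back$genes$biotype, model$genes$biotype)
  ord <- function(d) d[order(d$gene_id, d$start), c("gene_id", "start", "end")]
  expect_equal(unname(as.matrix(ord(back$exons))),
               unname(as.matrix(ord(model$exons))))
  expect_equal(unname(as.matrix(ord(back$cds))),
               unname(as.matrix(ord(model$cds))))
  expect_equal(back$seq[["chr1"]], model$seq[["chr1"]])
})

test_that("GO map TSV round-trip", {
  anno <- make_go_map(5, paste0("g", 1:10), n_terms = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_go_map(anno, path)
  back <- read_go_map(path, universe = paste0("g", 1:10))
  m1 <- anno$map[order(anno$map$term, anno$map$gene), ]
  m2 <- back$map[order(back$map$term, back$map$gene), ]
  expect_equal(m2$gene, m1$gene)
  expect_equal(m2$term, m1$term)
  expect_setequal(back$universe, anno$universe)
})
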