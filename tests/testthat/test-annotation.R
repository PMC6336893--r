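test_that("SNP effects match the brute-force translation oracle, plus strand", {
  model <- toy_gene_model(strand_pick = "+")
  g <- model$genes[1, ]
  cd <- model$cds[model$cds$gene_id == g$gene_id, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  cds_pos <- unlist(mapply(seq, cd$start, cd$end, SIMPLIFY = FALSE))
  for (pos in cds_pos) {
    ref <- substring(model$seq[["chr1"]], pos, pos)
    for (alt in setdiff(bases, ref)) {
      call <- classify_site("chr1", pos, ref, alt, model)
      expect_equal(call$category, "exonic")
      expect_equal(call$effect,
                   oracle_snp_effect(model, g$gene_id, pos, alt),
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
    }
  }
})

test_that("SNP effects match the brute-force translation oracle, minus strand", {
  model <- toy_gene_model(strand_pick = "-")
  g <- model$genes[1, ]
  cd <- model$cds[model$cds$gene_id == g$gene_id, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  cds_pos <- unlist(mapply(seq, cd$start, cd$end, SIMPLIFY = FALSE))
  for (pos in cds_pos) {
    ref <- substring(model$seq[["chr1"]], pos, pos)
    for (alt in setdiff(bases, ref)) {
      call <- classify_site("chr1", pos, ref, alt, model)
      expect_equal(call$category, "exonic")
      expect_equal(call$effect,
                   oracle_snp_effect(model, g$gene_id, pos, alt),
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
    }
  }
})

test_that("category precedence and regions are assigned correctly", {
  model <- toy_gene_model(strand_pick = "+")
  g <- model$genes[1, ]
  ex <- model$exons[model$exons$gene_id == g$gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  cd <- model$cds[model$cds$gene_id == g$gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), ]
  at <- function(pos) classify_site("chr1", pos,
                                    substring(model$seq[["chr1"]], pos, pos),
                                    "A", model)$category
  expect_equal(at(g$start - 500), "upstream")
  expect_equal(at(g$end + 500), "downstream")
  expect_equal(at(g$start - 1001), "intergenic")
  expect_equal(at(cd$start[1] - 1), "UTR")      # 5' UTR base before CDS
  if (nrow(ex) > 1) {
    expect_equal(at(ex$end[1] + 1), "splicing") # first intron base
    expect_equal(at(ex$end[1] + 2), "splicing")
    mid <- floor((ex$end[1] + ex$start[2]) / 2)
    if (mid > ex$end[1] + 2 && mid < ex$start[2] - 2)
      expect_equal(at(mid), "intronic")
  }
})

test_that("minus-strand flanks swap upstream and downstream", {
  model <- toy_gene_model(strand_pick = "-")
  g <- model$genes[1, ]
  at <- function(pos) classify_site("chr1", pos,
                                    substring(model$seq[["chr1"]], pos, pos),
                                    "A", model)$category
  expect_equal(at(g$start - 500), "downstream")
  expect_equal(at(g$end + 500), "upstream")
})

test_that("indel effects: frameshift, non-frameshift and stop changes", {
  model <- toy_gene_model(strand_pick = "+")
  g <- model$genes[1, ]
  cd <- model$cds[model$cds$gene_id == g$gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), ]
  seq1 <- model$seq[["chr1"]]
  # anchor at CDS offset 3 (end of the start codon): deletions remove the
  # codon-aligned block starting at offset 4, insertions land on a codon
  # boundary
  p <- cd$start[1] + 2
  base <- function(pos) substring(seq1, pos, pos)
  # 2-bp deletion -> frameshift
  del2 <- classify_site("chr1", p, substring(seq1, p, p + 2),
                        base(p), model)
  expect_equal(del2$effect, "frameshift")
  # 3-bp in-frame deletion of a non-stop codon -> non-frameshift
  del3 <- classify_site("chr1", p, substring(seq1, p, p + 3),
                        base(p), model)
  expect_equal(del3$effect, "non-frameshift")
  # 1-bp insertion -> frameshift
  ins1 <- classify_site("chr1", p, base(p), paste0(base(p), "A"), model)
  expect_equal(ins1$effect, "frameshift")
  # in-frame insertion of a stop codon at a codon boundary -> stopgain
  ins3 <- classify_site("chr1", p, base(p), paste0(base(p), "TAA"), model)
  expect_equal(ins3$effect, "stopgain")
  # in-frame deletion covering the terminal stop codon -> stoploss
  stop_start <- cd$end[nrow(cd)] - 2
  dl <- classify_site("chr1", stop_start - 1,
                      substring(seq1, stop_start - 1, stop_start + 2),
                      base(stop_start - 1), model)
  expect_equal(dl$effect, "stoploss")
})

test_that("overlap resolution keeps the most severe category", {
  model <- toy_gene_model(strand_pick = "+")
  g <- model$genes[1, ]
  gm <- genotype_matrix("chr1", g$start - 500,
                        substring(model$seq[["chr1"]], g$start - 500,
                                  g$start - 500),
                        "A", matrix(1L, 1, 1), "s1", "p1")
  calls <- classify_variants(gm, model)
  expect_equal(calls$category, "upstream")
  expect_equal(calls$gene, g$gene_id)
})

test_that("nsSNP burden counting and gene selection", {
  calls <- data.frame(
    key = paste0("k", 1:7), chrom = "chr1", pos = 1:7,
    category = c(rep("exonic", 6), "intronic"),
    effect = c("nonsynonymous", "nonsynonymous", "synonymous",
               "nonsynonymous", "nonsynonymous", "nonsynonymous", NA),
    gene = c("g1", "g1", "g1", "g1;g2", "g2", "g2", "g1"))
  burden <- gene_nssnp_burden(calls)
  expect_equal(unname(burden["g1"]), 3L)
  expect_equal(unname(burden["g2"]), 3L)
  expect_equal(select_genes(burden, threshold = 2), c("g1", "g2"))
  expect_equal(select_genes(burden, threshold = 3), character(0))
  expect_equal(select_genes(burden, threshold = 3, strict_greater = FALSE),
               c("g1", "g2"))
  # the analysis rule is "more than 5 nsSNPs"
  expect_equal(select_genes(c(a = 5L, b = 6L), threshold = 5), "b")
})

test_that("annotation oracle runs within the acceptance budget", {
  model <- toy_gene_model(strand_pick = "+")
  elapsed <- system.time({
    g <- model$genes[1, ]
    cd <- model$cds[model$cds$gene_id == g$gene_id, , drop = FALSE]
    pos <- cd$start[1]
    ref <- substring(model$seq[["chr1"]], pos, pos)
    classify_site("chr1", pos, ref, setdiff(c("A", "C"), ref)[1], model)
  })["elapsed"]
  expect_lt(elapsed, 10)
})
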