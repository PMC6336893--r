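#' Default pipeline configuration
#'
#' All stage parameters in one list: simulation settings, hard-filter
#' thresholds, sweep-scan settings (5-kb grid, top 0.5% outliers, 150-kb
#' windows), enrichment settings (p < 0.05, at least 5 mapping entries) and
#' demographic-fit settings. Every stochastic stage draws its own substream
#' from the single top-level seed.
#'
#' @param out_dir output directory.
#' @param seed top-level seed.
#' @param ... overrides for any default, e.g. `sim = list(seq_length = 1e5)`.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(out_dir, seed = 42, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    stages = c("simulate", "filter", "summarize", "annotate", "diversity",
               "sweep", "enrich", "demography"),
    sim = list(n_pops = 2, haploids_per_pop = 10, seq_length = 2e5,
               n_genes = 12, n_go_terms = 15),
    filter = list(),
    sweep = list(grid_spacing = 5000, top_fraction = 0.005, window = 150000,
                 per_chromosome = TRUE),
    enrich = list(p_threshold = 0.05, min_mapped = 5, nssnp_threshold = 5),
    demography = list(n_reps = 5000, n_reps_final = 2e4,
                      n_reps_hessian = 1e5, n_starts = 2),
    force = FALSE)
  modifyList(cfg, list(...))
}

stage_seed <- function(cfg, k) (cfg$seed + 1000L * k) %% 2147483647L

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' simulate -> hard-filter -> summarize -> annotate -> diversity -> sweep ->
#' enrich -> demography. Each stage writes TSV/JSON artifacts under its own
#' subdirectory; a run with the same configuration and seed reproduces the
#' same outputs (stages are skipped when their outputs already exist for an
#' identical configuration, unless `force`). Stages depending on a disabled
#' stage raise an error naming the missing dependency.
#'
#' @param config a [pipeline_config()] list (or path to a YAML file with the
#'   same structure).
#' @return List of stage results, invisibly; a `report.json` summary is
#'   written into `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- do.call(
    pipeline_config, yaml::read_yaml(config))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "config.json")
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  fresh <- cfg$force || !file.exists(cfg_path) ||
    !identical(as.character(cfg_json), readLines(cfg_path, warn = FALSE)[1])
  writeLines(as.character(cfg_json), cfg_path)
  has <- function(s) s %in% cfg$stages
  need <- function(s, from) if (!has(s))
    stop("stage '", from, "' requires stage '", s, "' to be enabled")
  res <- list()
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  # -- simulate -------------------------------------------------------------
  need("simulate", "everything downstream")
  sdir <- file.path(cfg$out_dir, "simulate")
  sim_cfg <- sim_config(n_pops = cfg$sim$n_pops,
                        haploids_per_pop = cfg$sim$haploids_per_pop,
                        seq_length = cfg$sim$seq_length,
                        seed = stage_seed(cfg, 1))
  sim <- simulate_neutral(sim_cfg)
  if (fresh || !dir.exists(sdir)) write_sim_fixtures(sim, sdir)
  model <- make_gene_model(stage_seed(cfg, 2), cfg$sim$n_genes,
                           genome = c(chr1 = cfg$sim$seq_length))
  write_gff3(model, file.path(sdir, "genes.gff3"),
             fasta_path = file.path(sdir, "genome.fa"))
  go <- make_go_map(stage_seed(cfg, 3), model$genes$gene_id,
                    n_terms = cfg$sim$n_go_terms)
  write_go_map(go, file.path(sdir, "go_map.tsv"))
  res$simulate <- list(n_sites = n_sites(sim$matrix), dir = sdir)
  say("simulate: ", n_sites(sim$matrix), " variant sites, seed ",
      sim_cfg$seed)

  # -- filter ---------------------------------------------------------------
  gm <- sim$matrix
  if (has("filter")) {
    fdir <- file.path(cfg$out_dir, "filter")
    dir.create(fdir, showWarnings = FALSE)
    flt <- apply_hard_filters(gm, do.call(hard_filter_config, cfg$filter))
    write_vcf(gm, file.path(fdir, "all_with_filter.vcf"),
              filter = flt$filter)
    write_tsv(flt$reasons, file.path(fdir, "filter_reasons.tsv"))
    say("filter: ", n_sites(flt$passed), " passed, ", n_sites(flt$failed),
        " failed (union of reject rules; conjunction reading of the ",
        "low-quality strand-bias rule)")
    gm <- flt$passed
    res$filter <- list(passed = n_sites(flt$passed),
                       failed = n_sites(flt$failed))
  }

  # -- summarize ------------------------------------------------------------
  if (has("summarize")) {
    mdir <- file.path(cfg$out_dir, "summarize")
    dir.create(mdir, showWarnings = FALSE)
    sets <- breed_variant_sets(gm)
    venn <- venn_sharing(sets)
    write_tsv(venn, file.path(mdir, "venn.tsv"))
    known <- read_known_sites(file.path(sdir, "known_sites.tsv"))
    nov <- classify_novel(gm, known, sets)
    arr <- read_array_genotypes(file.path(sdir, "array_genotypes.tsv"))
    conc <- genotype_concordance(gm, arr)
    hh <- lapply(setNames(levels(gm$pops), levels(gm$pops)),
                 function(p) hom_het_ratio(gm, p))
    res$summarize <- list(
      venn = venn, tstv = tstv_ratio(gm),
      novel_fraction = nov$novel_fraction,
      novel_per_population = nov$per_population,
      concordance = conc$concordance,
      het_hom = lapply(hh, function(h) h[c("hom", "het", "ratio")]))
    jsonlite::write_json(res$summarize, file.path(mdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    say("summarize: Ts/Tv ", round(res$summarize$tstv, 2), ", ",
        round(100 * nov$novel_fraction, 2), "% novel, concordance ",
        round(conc$concordance, 2), "%")
  }

  # -- annotate -------------------------------------------------------------
  calls <- burden <- NULL
  if (has("annotate")) {
    adir <- file.path(cfg$out_dir, "annotate")
    dir.create(adir, showWarnings = FALSE)
    calls <- classify_variants(gm, model)
    write_tsv(calls, file.path(adir, "functional_calls.tsv"))
    write_tsv(category_summary(calls, gm$type),
              file.path(adir, "category_summary.tsv"))
    burden <- gene_nssnp_burden(calls)
    write_tsv(data.frame(gene = names(burden), nssnp = as.integer(burden)),
              file.path(adir, "nssnp_burden.tsv"))
    res$annotate <- list(categories = table(calls$category),
                         n_ns_genes = length(
                           select_genes(burden, cfg$enrich$nssnp_threshold)))
    say("annotate: ", sum(calls$category == "exonic"), " exonic calls")
  }

  # -- diversity ------------------------------------------------------------
  if (has("diversity")) {
    ddir <- file.path(cfg$out_dir, "diversity")
    dir.create(ddir, showWarnings = FALSE)
    pops <- levels(gm$pops)
    div <- lapply(setNames(pops, pops), function(p) {
      n <- 2 * length(pop_cols(gm, p))
      fs <- build_folded_sfs(gm, p)
      write_sfs_dadi(fs, file.path(ddir, paste0("sfs_", p, ".fs")))
      list(pi = nucleotide_diversity(gm, p),
           theta_w = watterson_theta(segregating_sites(gm, p), n, gm$l_eff),
           S = segregating_sites(gm, p))
    })
    pc <- pca_genotypes(gm)
    write_tsv(data.frame(sample = pc$samples, pop = pc$pops,
                         pc$vectors[, seq_len(min(4, ncol(pc$vectors)))]),
              file.path(ddir, "pca_eigenvectors.tsv"))
    res$diversity <- list(per_pop = div,
                          eigenvalues = pc$values[seq_len(min(5,
                            length(pc$values)))])
    jsonlite::write_json(res$diversity, file.path(ddir, "diversity.json"),
                         auto_unbox = TRUE, digits = NA)
    say("diversity: pi = ",
        paste(signif(vapply(div, `[[`, numeric(1), "pi"), 3),
              collapse = " / "))
  }

  # -- sweep ----------------------------------------------------------------
  sweep_genes <- NULL
  if (has("sweep")) {
    wdir <- file.path(cfg$out_dir, "sweep")
    dir.create(wdir, showWarnings = FALSE)
    pops <- levels(gm$pops)
    res$sweep <- lapply(setNames(pops, pops), function(p) {
      scan <- clr_scan(gm, pop = p, grid_spacing = cfg$sweep$grid_spacing,
                       chrom_length = gm$l_eff)
      scan <- call_outliers(scan, cfg$sweep$top_fraction,
                            cfg$sweep$per_chromosome)
      write_tsv(scan, file.path(wdir, paste0("scan_", p, ".tsv")))
      out <- scan[scan$outlier, , drop = FALSE]
      bed <- data.frame(chrom = out$chrom, start = out$pos - 1L,
                        end = out$pos)
      write_tsv(bed, file.path(wdir, paste0("outliers_", p, ".bed")))
      ann <- annotate_windows(out, model, cfg$sweep$window)
      write_tsv(data.frame(gene = ann$genes %||% character(0)),
                file.path(wdir, paste0("sweep_genes_", p, ".tsv")))
      list(n_outliers = nrow(out), genes = ann$genes)
    })
    sweep_genes <- unique(unlist(lapply(res$sweep, `[[`, "genes")))
    say("sweep: outlier cutoff per ",
        if (cfg$sweep$per_chromosome) "chromosome" else "genome",
        ", top ", 100 * cfg$sweep$top_fraction, "%")
  }

  # -- enrich ---------------------------------------------------------------
  if (has("enrich")) {
    need("annotate", "enrich")
    need("sweep", "enrich")
    edir <- file.path(cfg$out_dir, "enrich")
    dir.create(edir, showWarnings = FALSE)
    go <- read_go_map(file.path(sdir, "go_map.tsv"),
                      universe = model$genes$gene_id)
    study_sets <- list(
      nssnp = select_genes(burden, cfg$enrich$nssnp_threshold),
      sweep = sweep_genes)
    res$enrich <- lapply(study_sets, function(gs) {
      if (length(gs) == 0) return(NULL)
      tab <- enrich(gs, go, cfg$enrich$p_threshold, cfg$enrich$min_mapped)
      tab
    })
    for (nm in names(res$enrich))
      if (!is.null(res$enrich[[nm]]))
        write_tsv(res$enrich[[nm]], file.path(edir, paste0(nm, ".tsv")))
    say("enrich: Fisher exact, Bonferroni over tested terms, >=",
        cfg$enrich$min_mapped, " study mapping entries")
  }

  # -- demography -----------------------------------------------------------
  if (has("demography")) {
    if (nlevels(gm$pops) < 2) stop("demography stage needs two populations")
    gdir <- file.path(cfg$out_dir, "demography")
    dir.create(gdir, showWarnings = FALSE)
    pops <- levels(gm$pops)[1:2]
    js <- build_joint_sfs(gm, pops[1], pops[2])
    fit <- fit_demography(js, mu = sim_cfg$mu, g = sim_cfg$demography$g,
                          seed = stage_seed(cfg, 8),
                          n_starts = cfg$demography$n_starts,
                          n_reps = cfg$demography$n_reps,
                          n_reps_final = cfg$demography$n_reps_final,
                          n_reps_hessian = cfg$demography$n_reps_hessian)
    jsonlite::write_json(
      list(par = as.list(fit$par), se = as.list(fit$se),
           ci = list(lower = as.list(fit$ci["lower", ]),
                     upper = as.list(fit$ci["upper", ])),
           loglik = fit$loglik, theta_hat = fit$theta_hat, Na = fit$Na,
           physical = fit$physical, seed = fit$seed),
      file.path(gdir, "fit.json"), auto_unbox = TRUE, digits = NA)
    res$demography <- fit
    say("demography: Na = ", round(fit$Na), ", split ",
        round(fit$physical$years[["Td"]]), " years ago")
  }

  writeLines(log, file.path(cfg$out_dir, "pipeline.log"))
  jsonlite::write_json(
    list(config = cfg, log = log,
         summary = res[setdiff(names(res), "demography")]),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(res)
}
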