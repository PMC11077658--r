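#' Run the full analysis pipeline
#'
#' Orchestrates the analysis stages in their dependency order: read (or
#' simulate) genotypes, filter SNPs, estimate kinship, select the
#' unrelated set, compute diversity statistics, downsample and build the
#' folded joint SFS, fit the divergence model family, select by AIC, and
#' (optionally) run the mtDNA analyses.  Unrelated-set selection precedes
#' the diversity and SFS stages, because relatives bias both.  Stage
#' outputs are written as tab-separated tables under `out_dir` together
#' with a JSON manifest recording inputs, settings, seed and package
#' version; a stage failure aborts with the stage name while earlier
#' outputs persist.
#'
#' @param cfg a configuration list (or path to a YAML file with the same
#'   structure): fields `vcf`, `popmap`, `fasta` (each optional if
#'   `simulate` is given), `simulate` (list with `model` parameters to
#'   forward to [demographic_model()] and [sim_config()]), `filters`
#'   (forwarded to [filter_config()]), `models` (character vector of model
#'   ids to fit), `theta_IQ`, `fit` (list of extra [fit_model()]
#'   arguments), `downsample` (fraction or named counts), `mu`,
#'   `generation_time`, `seed`, `out_dir`.
#' @return invisibly, a list with the stage results and the manifest path.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    cfg <- yaml::read_yaml(cfg)
  }
  stopifnot(is.list(cfg))
  if (is.null(cfg$out_dir)) stop("cfg$out_dir is required")
  if (is.null(cfg$seed)) stop("cfg$seed is required (stochastic stages)")
  has_input <- !is.null(cfg$vcf) || !is.null(cfg$simulate)
  if (!has_input) stop("cfg needs either `vcf` (+`popmap`) or `simulate`")
  if (!is.null(cfg$vcf) && is.null(cfg$popmap)) {
    stop("cfg$popmap is required when reading a VCF")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stages <- character(0)
  results <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }
  tsv <- function(x, name) {
    write.table(x, file.path(cfg$out_dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  G <- run_stage("input", {
    if (!is.null(cfg$vcf)) {
      pm <- read_popmap(cfg$popmap)
      read_vcf(cfg$vcf, pm)
    } else {
      sim <- cfg$simulate
      model <- do.call(demographic_model, sim$model)
      sc <- do.call(sim_config, c(sim$config %||% list(),
                                  list(seed = cfg$seed)))
      G <- simulate_dataset(model, sc)
      write_vcf(G, file.path(cfg$out_dir, "simulated.vcf"))
      write_popmap(G$pops, file.path(cfg$out_dir, "simulated.popmap.tsv"))
      G
    }
  })

  Gf <- run_stage("filter", {
    f <- do.call(filter_config, c(cfg$filters %||% list(),
                                  list(seed = cfg$seed)))
    out <- filter_loci(G, f)
    message("filter: retained ", ncol(out$calls), " of ", ncol(G$calls),
            " SNPs")
    out
  })

  kin <- run_stage("kinship", kinship_king(Gf))
  unrel <- run_stage("unrelated", {
    miss <- rowMeans(is.na(Gf$calls))
    ids <- select_unrelated(kin, miss, threshold = cfg$kin_threshold %||% 0)
    writeLines(ids, file.path(cfg$out_dir, "unrelated_ids.txt"))
    message("unrelated set: ", length(ids), " of ", nrow(Gf$calls),
            " individuals")
    ids
  })
  Gu <- genotype_matrix(Gf$calls[unrel, , drop = FALSE], Gf$locus_ids,
                        Gf$pops[unrel])

  div <- run_stage("diversity", {
    d <- diversity(Gu)
    tsv(d, "diversity")
    d
  })

  sfs <- run_stage("sfs", {
    Gd <- downsample_individuals(Gu, cfg$downsample %||% 0.5)
    pops <- unique(Gu$pops)
    s <- folded_joint_sfs(Gd, pops[seq_len(min(2, length(pops)))])
    write_sfs(s, file.path(cfg$out_dir, "joint_sfs.txt"))
    s
  })

  fits <- NULL
  sel <- NULL
  if (!is.null(cfg$models)) {
    fits <- run_stage("fit", {
      lapply(cfg$models, function(id) {
        do.call(fit_model,
                c(list(obs = sfs, model_id = id,
                       theta_IQ = cfg$theta_IQ,
                       seed = cfg$seed + match(id, cfg$models)),
                  cfg$fit %||% list()))
      })
    })
    sel <- run_stage("select", {
      tab <- model_selection(fits)
      tsv(tab, "model_selection")
      tab
    })
  }

  mt <- NULL
  if (!is.null(cfg$fasta)) {
    mt <- run_stage("mtdna", {
      pm <- read_popmap(cfg$popmap)
      aln <- read_fasta(cfg$fasta, pm)
      haps <- collapse_haplotypes(aln)
      hd <- hap_diversity(rowSums(haps$counts))
      data.frame(H = length(haps$labels), Hd = hd$Hd,
                 Hd_var = hd$variance, pi = nuc_diversity(aln))
    })
    tsv(mt, "mtdna_summary")
  }

  manifest <- list(package = "tealdemog",
                   version = as.character(packageVersion("tealdemog")),
                   seed = cfg$seed,
                   inputs = cfg[intersect(names(cfg),
                                          c("vcf", "popmap", "fasta"))],
                   settings = cfg[intersect(names(cfg),
                                            c("filters", "downsample",
                                              "models", "theta_IQ", "mu",
                                              "generation_time"))],
                   stages = stages,
                   timestamp = format(Sys.time(), tz = "UTC"))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(genotypes = Gu, diversity = div, sfs = sfs, fits = fits,
                 selection = sel, mtdna = mt, manifest = manifest_path))
}
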