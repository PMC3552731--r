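# End-to-end orchestration: a declarative YAML (or list) config drives
# simulate -> QC -> genome partition -> GWA -> cross-validation -> reports.
# The thin command-line wrapper in inst/cli/wgpr dispatches to these
# functions; they are equally usable from R.

#' Read and validate a run configuration
#'
#' The config has either an `input` block (paths to genotype, map and
#' phenotype TSVs, or a VCF) or a `simulation` block ([sim_config()]
#' fields), never both; plus optional `qc`, `partition`, `gwa`, `cv`,
#' `models` and `output` blocks.
#'
#' @param path Path to a YAML file, or a named list with the same structure.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim) {
    abort("config must contain exactly one of `input` or `simulation`.")
  }
  if (has_input) {
    files <- unlist(cfg$input[c("genotypes", "map", "phenotypes", "vcf")])
    missing_files <- files[!file.exists(files)]
    if (length(missing_files)) {
      abort(sprintf("input file(s) not found: %s",
                    paste(missing_files, collapse = ", ")))
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$output <- cfg$output %||% list()
  cfg$output$dir <- cfg$output$dir %||% "wgpr_output"
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

# every output file carries a provenance header
write_tsv_with_header <- function(df, file, cfg) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# wgpr %s | config %s | seed %s",
    as.character(utils::packageVersion("wgpr")), config_hash(cfg), cfg$seed
  ), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file
}

sim_config_from_block <- function(block, seed) {
  args <- block[intersect(names(block), names(formals(sim_config)))]
  if (is.null(args$seed)) args$seed <- seed
  do.call(sim_config, args)
}

#' Simulate a panel and trait to files
#'
#' Writes the genotype matrix, SNP map, phenotype table and ground-truth
#' JSON to the output directory (created if needed) and prints realized
#' summaries: mean adjacent-SNP r-squared, realized heritability, and the
#' realized QTL variance fraction.
#'
#' @param config A `run_config` (or list/path accepted by
#'   [read_run_config()]) with a `simulation` block.
#' @param quiet Suppress the summary printout.
#' @return Invisibly, a list with the panel, trait, truth and file paths.
#' @export
run_simulate <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$simulation)) abort("config has no `simulation` block.")
  sc <- sim_config_from_block(cfg$simulation, cfg$seed)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)

  panel <- simulate_genotypes(sc)
  st <- simulate_trait(panel, sc)
  ld <- ld_r2_profile(panel, max_dist_bp = 4 * sc$ld_decay_bp)

  paths <- list(
    genotypes = file.path(cfg$output$dir, "genotypes.tsv"),
    map = file.path(cfg$output$dir, "snp_map.tsv"),
    phenotypes = file.path(cfg$output$dir, "phenotypes.tsv"),
    truth = file.path(cfg$output$dir, "truth.json")
  )
  write_genotypes(panel, paths$genotypes, paths$map)
  write_phenotypes(st$trait, paths$phenotypes)
  write_sim_truth(st$truth, paths$truth)

  if (!quiet) {
    cat(sprintf("simulated %d lines x %d SNPs (seed %d)\n",
                nrow(panel$dosages), ncol(panel$dosages), sc$seed))
    cat(sprintf("  mean adjacent-SNP r2: %.3f\n", ld$mean_adjacent_r2))
    cat(sprintf("  realized h2: %.3f\n", st$truth$realized_h2))
    if (!is.na(st$truth$qtl_snp_id)) {
      cat(sprintf("  QTL %s, realized variance fraction: %.3f\n",
                  st$truth$qtl_snp_id, st$truth$realized_qtl_variance_fraction))
    }
  }
  invisible(list(panel = panel, trait = st$trait, truth = st$truth,
                 ld = ld, paths = paths))
}

load_or_simulate <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim <- run_simulate(cfg, quiet = TRUE)
    list(panel = sim$panel, trait = sim$trait, truth = sim$truth)
  } else {
    panel <- if (!is.null(cfg$input$vcf)) {
      read_vcf_panel(cfg$input$vcf)
    } else {
      read_genotypes(cfg$input$genotypes, cfg$input$map)
    }
    list(panel = panel, trait = read_phenotypes(cfg$input$phenotypes),
         truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' QC, optional genome partition and GWA scan, cross-validation over the
#' requested models, and tabular reports: QC counts, per-chromosome and
#' cumulative variance shares, GWA results, per-model SNP-effect profiles,
#' per-run CV abilities and the accuracy comparison table. A JSON manifest
#' lists every artifact and whether all stages completed.
#'
#' @param config A `run_config`, list, or YAML path.
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out_dir <- cfg$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   artifacts = character(), complete = FALSE)
  results <- list()

  data <- load_or_simulate(cfg)
  qc_cfg <- cfg$qc %||% list()
  qc <- apply_snp_qc(
    data$panel,
    max_missing = qc_cfg$max_missing %||% 0.10,
    min_maf = qc_cfg$min_maf %||% 0.025,
    max_het = qc_cfg$max_het %||% 3
  )
  panel <- qc$panel
  results$qc_report <- qc$report
  p_qc <- file.path(out_dir, "qc_report.tsv")
  write_tsv_with_header(qc$report, p_qc, cfg)
  manifest$artifacts <- c(manifest$artifacts, p_qc)

  traits <- split(data$trait, data$trait$trait)

  part_cfg <- cfg$partition %||% list(enabled = TRUE)
  if (isTRUE(part_cfg$enabled %||% TRUE)) {
    results$partition <- lapply(traits, function(tr) {
      partition_genome(panel, tr, n_pcs = part_cfg$n_pcs %||% 10)
    })
    part_tbl <- purrr::imap_dfr(results$partition, function(pr, nm) {
      dplyr::mutate(tidy(pr), trait = nm, .before = 1)
    })
    p_part <- file.path(out_dir, "partition.tsv")
    write_tsv_with_header(part_tbl, p_part, cfg)
    manifest$artifacts <- c(manifest$artifacts, p_part)
  }

  gwa_cfg <- cfg$gwa %||% list(enabled = TRUE)
  if (isTRUE(gwa_cfg$enabled %||% TRUE)) {
    std <- impute_and_standardize(panel, drop_monomorphic = TRUE)
    K <- build_grm(std)
    Q <- compute_pcs(std, k = gwa_cfg$n_pcs %||% 10)
    results$gwa <- lapply(traits, function(tr) {
      gwa_scan(std, tr, K, Q, alpha = gwa_cfg$alpha %||% 0.01)
    })
    gwa_tbl <- purrr::imap_dfr(results$gwa, function(g, nm) {
      dplyr::mutate(as_tibble(g), trait = nm, .before = 1)
    })
    p_gwa <- file.path(out_dir, "gwa.tsv")
    write_tsv_with_header(gwa_tbl, p_gwa, cfg)
    manifest$artifacts <- c(manifest$artifacts, p_gwa)
  }

  cv_cfg <- cfg$cv %||% list()
  models <- cfg$models %||% list("rrblup")
  model_names <- vapply(models, function(m) if (is.list(m)) m$name else m, "")
  cv_results <- list()
  for (tr_name in names(traits)) {
    tr <- traits[[tr_name]]
    plan <- make_cv_plan(
      rownames(panel$dosages),
      n_folds = cv_cfg$n_folds %||% 5,
      n_repeats = cv_cfg$n_repeats %||% 20,
      seed = cfg$seed
    )
    for (i in seq_along(models)) {
      m <- models[[i]]
      nm <- model_names[i]
      settings <- if (is.list(m)) m[setdiff(names(m), "name")] else list()
      cv_results[[paste(tr_name, nm, sep = ".")]] <-
        do.call(run_cv, c(list(panel, tr, nm, plan), settings))
    }
  }
  results$cv <- cv_results
  if (length(cv_results)) {
    per_run <- purrr::map_dfr(cv_results, tidy)
    p_runs <- file.path(out_dir, "cv_runs.tsv")
    write_tsv_with_header(per_run, p_runs, cfg)
    results$summary <- summarize_comparison(cv_results)
    p_sum <- file.path(out_dir, "summary.tsv")
    write_tsv_with_header(results$summary, p_sum, cfg)
    manifest$artifacts <- c(manifest$artifacts, p_runs, p_sum)
  }

  # Effect profiles from full-data fits of the effect-based models requested
  std_full <- impute_and_standardize(panel, drop_monomorphic = TRUE)
  for (tr_name in names(traits)) {
    for (nm in intersect(unique(model_names), c("rrblup", "lasso", "elastic_net"))) {
      fit <- fit_model_by_name(nm, panel, traits[[tr_name]], list())
      p_eff <- file.path(out_dir, sprintf("snp_effects_%s_%s.tsv", tr_name, nm))
      write_tsv_with_header(tidy(fit), p_eff, cfg)
      manifest$artifacts <- c(manifest$artifacts, p_eff)
    }
  }

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(results, list(manifest = manifest, out_dir = out_dir)))
}
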