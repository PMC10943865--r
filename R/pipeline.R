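# Workflow: input loading/validation and end-to-end orchestration of the
# pipeline stages, with per-stage artifacts and resumability.

#' Load and reconcile the pipeline inputs
#'
#' Reads the canonical TSV inputs (weights, genotypes, microbiome counts,
#' fixed effects), validates them, and inner-joins on animal identifiers.
#' Animals missing from the microbiome table are kept with missing microbial
#' phenotypes; the reconciliation report counts what was kept and dropped.
#'
#' @param weights_path,genotypes_path,counts_path,fixed_path file paths;
#'   `counts_path` may be `NULL`.
#' @param max_drop_frac failure threshold on the fraction of weight-recorded
#'   animals without genotypes (default 0.5).
#' @return list with `weights`, `genotypes` (matrix), `counts` (matrix or
#'   NULL), `fixed` (vector aligned with phenotyped animals), `animals`
#'   (phenotyped, genotyped), `report`.
#' @export
load_inputs <- function(weights_path, genotypes_path, counts_path = NULL,
                        fixed_path = NULL, max_drop_frac = 0.5) {
  weights <- read_tsv(weights_path)
  need <- c("animal", "day", "weight_kg")
  if (!all(need %in% names(weights)))
    stopf("weights file lacks columns: %s", paste(setdiff(need, names(weights)), collapse = ", "))
  if (!is.numeric(weights$weight_kg)) {
    bad <- which(is.na(suppressWarnings(as.numeric(weights$weight_kg))))
    stopf("non-numeric weight_kg at line(s) %s of %s",
          paste(utils::head(bad + 1L, 5L), collapse = ", "), weights_path)
  }
  gdf <- read_tsv(genotypes_path)
  geno <- as.matrix(gdf[, -1L, drop = FALSE])
  rownames(geno) <- gdf[[1L]]
  counts <- NULL
  if (!is.null(counts_path)) {
    cdf <- read_tsv(counts_path)
    counts <- as.matrix(cdf[, -1L, drop = FALSE])
    rownames(counts) <- cdf[[1L]]
  }
  fixed <- NULL
  if (!is.null(fixed_path)) {
    fdf <- read_tsv(fixed_path)
    fixed <- stats::setNames(fdf$level, fdf$animal)
  }
  w_animals <- unique(weights$animal)
  animals <- intersect(w_animals, rownames(geno))
  dropped <- setdiff(w_animals, animals)
  if (length(dropped) / max(1L, length(w_animals)) > max_drop_frac)
    stopf("%d of %d weighed animals lack genotypes", length(dropped), length(w_animals))
  no_mb <- if (!is.null(counts)) setdiff(animals, rownames(counts)) else character(0)
  list(weights = weights[weights$animal %in% animals, ],
       genotypes = geno, counts = counts,
       fixed = if (!is.null(fixed)) fixed[animals] else NULL,
       animals = animals,
       report = list(n_weighed = length(w_animals),
                     n_genotyped = nrow(geno),
                     n_joined = length(animals),
                     dropped_no_genotype = dropped,
                     missing_microbiome = no_mb))
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97)) %% 4294967291)
}

stage_cache <- function(dir, stage, compute, resume = TRUE) {
  path <- file.path(dir, "cache", paste0(stage, ".rds"))
  if (resume && file.exists(path)) return(readRDS(path))
  res <- compute()
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(res, path)
  res
}

univariate_gebv <- function(y_mat, fixed, grm, mcmc) {
  out <- sapply(colnames(y_mat), function(id) {
    m2 <- mcmc; m2$seed <- derive_seed(mcmc$seed, paste0("gebv:", id))
    fit <- gibbs_sample(y_mat[, id], fixed, grm, mcmc = m2)
    fit$u_mean[, 1L]
  })
  matrix(out, nrow = nrow(grm), dimnames = list(rownames(grm), colnames(y_mat)))
}

#' Run the full microbiome-assisted genomic evaluation pipeline
#'
#' Executes the stages in order: (optional) simulation, ADG computation, SNP
#' QC + GRM, compositional processing, MG scans, ADG genetic parameters,
#' covariance assembly + bending, MG subset selection, and the three breeding
#' strategies. Every stage's result is cached under `out_dir/cache` and its
#' tabular artifacts written under `out_dir`; rerunning with `resume = TRUE`
#' skips completed stages. A `summary.json` sidecar records the config hash,
#' master seed and headline numbers.
#'
#' @param config list of options: either `simulate = TRUE` with `sim` (a
#'   [sim_config()]), or input paths `weights_path`, `genotypes_path`,
#'   `counts_path`, `fixed_path`; plus optional `mcmc` ([mcmc_settings()]),
#'   `scan_mcmc`, `quota_per_trait` (default 2 at desk scale),
#'   `p0_min` (0.85), `min_rel_abundance` (1e-5), `selection_p` (0.10).
#'   May also be a path to a YAML file with these keys.
#' @param out_dir output directory.
#' @param resume reuse cached stage results (default TRUE).
#' @return invisible list with all stage results and the summary.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$sim)) config$sim <- do.call(sim_config, config$sim)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mcmc <- config$mcmc %||% mcmc_settings(4000, 1000, 5, seed = config$seed %||% 1)
  scan_mcmc <- config$scan_mcmc %||% mcmc
  hash <- config_hash(config[setdiff(names(config), "mcmc_runtime")])

  # -- inputs ---------------------------------------------------------------
  inp <- stage_cache(out_dir, "inputs", resume = resume, compute = function() {
    if (isTRUE(config$simulate)) {
      sim <- simulate_dataset(config$sim %||% sim_config())
      write_dataset(sim, file.path(out_dir, "data"))
      list(weights = sim$weights, genotypes = sim$genotypes,
           counts = sim$counts,
           fixed = stats::setNames(sim$fixed$level, sim$fixed$animal),
           animals = sim$fixed$animal, sim = sim)
    } else {
      load_inputs(config$weights_path, config$genotypes_path,
                  config$counts_path, config$fixed_path)
    }
  })
  animals <- inp$animals

  # -- growth traits --------------------------------------------------------
  adg <- stage_cache(out_dir, "adg", resume = resume, compute = function() {
    tab <- adg_table(inp$weights)
    write_tsv(tab, file.path(out_dir, "adg.tsv"))
    m <- as.matrix(tab[, -1L]); rownames(m) <- tab$animal
    m[animals, , drop = FALSE]
  })

  # -- QC + GRM -------------------------------------------------------------
  grm_res <- stage_cache(out_dir, "grm", resume = resume, compute = function() {
    qc <- qc_filter(inp$genotypes)
    grm <- compute_grm(qc$dosages)
    write_tsv(as.data.frame(grm), file.path(out_dir, "grm.tsv"), rownames_as = "animal")
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE)
    grm
  })
  grm_all <- grm_res
  grm <- grm_all[animals, animals]

  # -- compositions ---------------------------------------------------------
  comp <- NULL
  if (!is.null(inp$counts)) {
    comp <- stage_cache(out_dir, "compositions", resume = resume, compute = function() {
      core <- filter_core_mg(inp$counts, config$presence_frac %||% 0.70)
      prop <- impute_zeros_gbm(core$counts)
      ref <- select_alr_reference(prop, config$ref_top_quantile %||% 0.10)
      alr <- alr_transform(prop, ref$reference)
      write_tsv(ref$diagnostics, file.path(out_dir, "alr_reference_diagnostics.tsv"))
      write_tsv(as.data.frame(alr), file.path(out_dir, "alr.tsv"), rownames_as = "sample")
      list(alr = alr[animals, , drop = FALSE], reference = ref$reference,
           rel_abundance = colMeans(inp$counts / rowSums(inp$counts)),
           retained_fraction = core$retained_fraction)
    })
  }

  fixed <- factor(inp$fixed[animals])

  # -- MG scans -------------------------------------------------------------
  scans <- NULL
  if (!is.null(comp)) {
    scans <- stage_cache(out_dir, "scans", resume = resume, compute = function() {
      h2 <- scan_mg_heritability(comp$alr, grm, fixed, mcmc = scan_mcmc)
      rg <- scan_mg_adg_correlations(comp$alr, adg, grm, fixed, mcmc = scan_mcmc,
                                     p0_threshold = config$p0_min %||% 0.85,
                                     rel_abundance = comp$rel_abundance)
      write_tsv(h2, file.path(out_dir, "mg_h2.tsv"))
      write_tsv(rg$catalog, file.path(out_dir, "mg_adg_rg_catalog.tsv"))
      list(h2 = h2, rg = rg)
    })
  }

  # -- ADG parameters -------------------------------------------------------
  adg_par <- stage_cache(out_dir, "adg_params", resume = resume, compute = function() {
    res <- estimate_adg_parameters(adg, grm, fixed, mcmc = mcmc)
    write_tsv(res$h2_summary, file.path(out_dir, "adg_h2.tsv"))
    write_tsv(res$rg_summary, file.path(out_dir, "adg_rg.tsv"))
    res
  })

  # -- selection + assembly + strategies ------------------------------------
  strat <- NULL
  if (!is.null(scans)) {
    strat <- stage_cache(out_dir, "strategies", resume = resume, compute = function() {
      quota <- config$quota_per_trait %||% 2
      cands <- filter_candidates(scans$rg$catalog, config$p0_min %||% 0.85,
                                 config$min_rel_abundance %||% 1e-5)
      gebv_adg <- univariate_gebv(adg, fixed, grm, scan_mcmc)[animals, , drop = FALSE]
      gebv_mg <- univariate_gebv(comp$alr[, cands, drop = FALSE], fixed, grm,
                                 scan_mcmc)[animals, , drop = FALSE]
      sel <- stepwise_select(gebv_adg, gebv_mg, quota_per_trait = quota)
      write_tsv(sel$trace, file.path(out_dir, "selection_trace.tsv"))

      trait_order <- c(colnames(adg), sel$selected)
      pairs <- c(adg_par$G_pairs, list())
      pairsR <- c(adg_par$R_pairs, list())
      extra <- utils::combn(trait_order, 2L)
      have <- vapply(adg_par$G_pairs, function(p) paste(sort(p$traits), collapse = ":"),
                     character(1))
      for (m in seq_len(ncol(extra))) {
        pr <- extra[, m]
        key <- paste(sort(pr), collapse = ":")
        if (key %in% have) next
        ymat <- cbind(if (pr[1L] %in% colnames(adg)) adg[, pr[1L]] else comp$alr[, pr[1L]],
                      if (pr[2L] %in% colnames(adg)) adg[, pr[2L]] else comp$alr[, pr[2L]])
        colnames(ymat) <- pr
        m2 <- mcmc; m2$seed <- derive_seed(mcmc$seed, key)
        fit <- gibbs_sample(ymat, fixed, grm, mcmc = m2)
        med <- apply(fit$G_chain, 2L, stats::median)
        sdv <- apply(fit$G_chain, 2L, stats::sd)
        blk <- function(v) matrix(c(v["1.1"], v["1.2"], v["1.2"], v["2.2"]), 2L, 2L)
        pairs[[length(pairs) + 1L]] <- list(traits = pr, median = blk(med), se = blk(sdv))
        medR <- apply(fit$R_chain, 2L, stats::median)
        sdR <- apply(fit$R_chain, 2L, stats::sd)
        pairsR[[length(pairsR) + 1L]] <- list(traits = pr, median = blk(medR), se = blk(sdR))
      }
      Gasm <- assemble_covariances(pairs, trait_order)
      Rasm <- assemble_covariances(pairsR, trait_order)
      Gb <- bend_matrix(Gasm$matrix, config$min_eig %||% 1e-3)
      Rb <- bend_matrix(Rasm$matrix, config$min_eig %||% 1e-3)
      bend_check <- validate_bending(Gasm$matrix, Gb$matrix, Gasm$se,
                                     diag(Rb$matrix))
      jsonlite::write_json(list(G = Gb$report, R = Rb$report,
                                h2_shift = bend_check$h2_shift,
                                pass = bend_check$pass),
                           file.path(out_dir, "bending_report.json"),
                           auto_unbox = TRUE, digits = NA)

      alr_sel <- comp$alr[, sel$selected, drop = FALSE]
      modes <- c("direct", "microbiome", "combined")
      runs <- lapply(modes, function(md) {
        m2 <- mcmc; m2$seed <- derive_seed(mcmc$seed, paste0("strategy:", md))
        run_strategy(md, adg, alr_sel, fixed, grm, Gb$matrix, Rb$matrix, mcmc = m2)
      })
      names(runs) <- modes
      resp <- do.call(rbind, lapply(modes, function(md)
        cbind(data.frame(mode = md), predicted_response(runs[[md]],
                                                        config$selection_p %||% 0.10))))
      write_tsv(resp, file.path(out_dir, "responses.tsv"))
      gebv_long <- do.call(rbind, lapply(modes, function(md) {
        g <- runs[[md]]
        data.frame(mode = md, animal = rep(rownames(g$gebv), 4L),
                   trait = rep(colnames(g$gebv), each = nrow(g$gebv)),
                   gebv = as.numeric(g$gebv), sd = as.numeric(g$sd),
                   accuracy = as.numeric(g$accuracy), stringsAsFactors = FALSE)
      }))
      write_tsv(gebv_long, file.path(out_dir, "gebv.tsv"))
      list(selection = sel, G = Gb$matrix, R = Rb$matrix,
           bending = list(G = Gb$report, R = Rb$report, check = bend_check),
           runs = runs, responses = resp)
    })
  }

  summary <- list(config_hash = hash, seed = mcmc$seed,
                  n_animals = length(animals),
                  adg_h2_medians = stats::setNames(adg_par$h2_summary$median,
                                                   adg_par$h2_summary$trait),
                  alr_reference = if (!is.null(comp)) comp$reference else NULL,
                  mean_accuracy = if (!is.null(strat))
                    lapply(strat$runs, function(r) as.list(r$mean_accuracy)) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(inputs = inp, adg = adg, grm = grm_all, compositions = comp,
                 scans = scans, adg_params = adg_par, strategies = strat,
                 summary = summary))
}
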