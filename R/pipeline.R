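#' Run the full longitudinal proteome analysis pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> stability ->
#' trait/seasonal association -> co-expression modules -> cis-pQTL scan ->
#' individual signatures from one configuration, writing every stage's
#' report and a run manifest into `out_dir`. Re-running with an identical
#' configuration reproduces identical tables.
#'
#' @param config either a list (see Details) or a YAML file path. Fields:
#'   `seed`; `sim` (arguments to [sim_config()]) or `inputs` (paths:
#'   `intensities`, `meta`, `traits`, `genotypes`, `gene_windows`);
#'   `stages` (character subset of simulate, normalize, stability,
#'   associate, seasonal, modules, pqtl, signatures; default all); and
#'   optional `params` overriding thresholds (`icc_threshold` 0.8,
#'   `trait_fdr` 0.001, `seasonal_fdr` 0.01, `module_trait_fdr` 0.01,
#'   `flag_k` 3, `alpha` 0.05).
#' @param out_dir output directory, created if needed.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages))
    stages <- c("simulate", "normalize", "stability", "associate",
                "seasonal", "modules", "pqtl", "signatures")
  if ("signatures" %in% stages && !("stability" %in% stages))
    stop("signatures requires stability (the stable-set filter)")
  p <- list(icc_threshold = 0.8, trait_fdr = 0.001, seasonal_fdr = 0.01,
            module_trait_fdr = 0.01, flag_k = 3, alpha = 0.05)
  p[names(config$params)] <- config$params
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  set.seed(config$seed %||% 1L)

  if ("simulate" %in% stages) {
    sim_args <- config$sim %||% list()
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    cohort <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cohort)
    ds <- cohort$dataset
    genotypes <- cohort$genotypes
    traits <- cohort$traits
    res$truth <- cohort$truth
    write_protein_dataset(ds, file.path(out_dir, "intensities_raw.tsv"),
                          file.path(out_dir, "sample_meta.tsv"))
    write_report(traits, file.path(out_dir, "traits.tsv"))
  } else {
    inp <- config$inputs
    ds <- read_protein_dataset(inp$intensities, inp$meta)
    traits <- if (!is.null(inp$traits)) read_traits(inp$traits)
    genotypes <- if (!is.null(inp$genotypes))
      read_genotypes(inp$genotypes, inp$gene_windows,
                     individuals = unique(ds$meta$individual_id))
  }
  res$dataset_raw <- ds

  if ("normalize" %in% stages) {
    norm <- normalize_pipeline(ds)
    ds <- norm$dataset
    res$audit <- norm$audit
    write_report(norm$audit$sample_factors,
                 file.path(out_dir, "normalization_sample_factors.tsv"))
    write_report(norm$audit$variance_share,
                 file.path(out_dir, "normalization_variance_share.tsv"))
  }
  res$dataset <- ds

  if ("stability" %in% stages) {
    icc_a <- inter_assay_icc(ds)
    icc_v <- inter_visit_icc(ds)
    stab <- classify_stability(icc_a, icc_v, threshold = p$icc_threshold)
    res$stability <- stab
    write_report(stab$table, file.path(out_dir, "stability.tsv"))
    res$identifiability <- individual_identifiability(ds)
    write_report(res$identifiability$per_individual,
                 file.path(out_dir, "identifiability.tsv"))
  }

  if ("associate" %in% stages && !is.null(traits)) {
    res$associations <- association_scan(ds, traits,
                                         fdr_threshold = p$trait_fdr)
    write_report(res$associations, file.path(out_dir, "associations.tsv"))
  }
  if ("seasonal" %in% stages) {
    res$seasonal <- seasonal_scan(ds, fdr_threshold = p$seasonal_fdr)
    write_report(res$seasonal, file.path(out_dir, "seasonal.tsv"))
  }

  if ("modules" %in% stages) {
    vm <- modules_per_visit(ds)
    res$visit_modules <- vm
    res$core_modules <- match_core_modules(vm)
    write_report(res$core_modules$assignment,
                 file.path(out_dir, "core_modules.tsv"))
    if (!is.null(traits)) {
      res$module_traits <- module_trait_association(
        res$core_modules, ds, traits,
        trait_names = setdiff(names(traits),
                              c("individual_id", "visit")),
        fdr_threshold = p$module_trait_fdr)
      write_report(res$module_traits,
                   file.path(out_dir, "module_trait_associations.tsv"))
    }
  }

  if ("pqtl" %in% stages && !is.null(genotypes)) {
    gq <- hwe_maf_filter(genotypes)
    res$pqtl <- pqtl_scan(individual_levels(ds), gq, alpha = p$alpha,
                          target_map = ds$target_map)
    write_report(res$pqtl$top, file.path(out_dir, "pqtl_top.tsv"))
    write_report(res$pqtl$hits, file.path(out_dir, "pqtl_hits.tsv"))
  }

  if ("signatures" %in% stages) {
    stable_set <- res$stability$table$antibody[
      res$stability$table$class == "both_stable"]
    pz <- population_zscore(ds, proteins = stable_set)
    stats <- profile_statistics(pz$z, pz$info)
    res$signature_flags <- flag_deviations(stats, k = p$flag_k)
    res$signature_summary <- summarize_signatures(res$signature_flags)
    res$iqr <- interindividual_iqr(pz$z, pz$info)
    write_report(res$signature_flags$flags,
                 file.path(out_dir, "signature_flags.tsv"))
    write_report(res$signature_flags$per_individual,
                 file.path(out_dir, "signature_per_individual.tsv"))
    write_report(res$iqr, file.path(out_dir, "interindividual_iqr.tsv"))
    jsonlite::write_json(
      lapply(res$signature_summary$venn, unname),
      file.path(out_dir, "signature_venn.json"), auto_unbox = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("longiplasma")),
    seed = config$seed %||% 1L,
    stages = stages, params = p,
    config_hash = unname(tools::md5sum(write_tmp_json(config))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  x <- rapply(x, function(v) if (inherits(v, "Date")) as.character(v) else v,
              how = "replace")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  f
}
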