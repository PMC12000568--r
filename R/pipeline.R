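#' Write a complete synthetic demo dataset to disk
#'
#' Generates the scenario's metabolite table, property table, annotation
#' table, and a pipeline config, in the TSV formats the readers expect.
#'
#' @param dir output directory (created if needed).
#' @param seed master RNG seed.
#' @param scenario a [synthetic_scenario()]; its `rng_seed` is overridden by
#'   `seed`.
#' @return invisibly, a named list of the written file paths.
#' @export
make_demo <- function(dir, seed = 1L, scenario = synthetic_scenario()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scenario$rng_seed <- as.integer(seed)
  t <- generate_metabolite_matrix(scenario)
  p <- generate_properties(t, scenario)
  a <- generate_annotation(t, rng_seed = seed)
  paths <- list(
    metabolites = file.path(dir, "metabolites.tsv"),
    sample_metadata = file.path(dir, "sample_metadata.tsv"),
    properties = file.path(dir, "properties.tsv"),
    property_groups = file.path(dir, "property_groups.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    config = file.path(dir, "config.yaml"))
  write_metabolite_table(t, paths$metabolites, paths$sample_metadata)
  write_property_table(p, paths$properties, paths$property_groups)
  write_annotation_table(a, paths$annotation)
  cfg <- list(rng_seed = as.integer(seed),
              inputs = list(metabolites = paths$metabolites,
                            sample_metadata = paths$sample_metadata,
                            properties = paths$properties,
                            property_groups = paths$property_groups,
                            annotation = paths$annotation))
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in order: input parsing, seasonal screen, correlation analysis,
#' model complexity, overlap counting, structure diversity. Every reported
#' number is produced by the corresponding library function; this wrapper
#' only sequences them and writes the TSV report bundle plus a JSON run
#' manifest with input/output digests.
#'
#' @param config path to a YAML config (see [read_config()]) or an
#'   [analysis_config()] carrying an `inputs` attribute.
#' @param out_dir output directory; defaults to the config's `out_dir` or
#'   `"metabomat_run"`.
#' @param items optional subset of measurement items for the complexity
#'   stage (all items by default).
#' @return the run manifest (named list), invisibly; outputs live in
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, items = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  inputs <- attr(cfg, "inputs")
  need <- c("metabolites", "sample_metadata", "properties",
            "property_groups", "annotation")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("config is missing input fields: ", paste(miss, collapse = ", "))
  out_dir <- out_dir %||% attr(cfg, "out_dir") %||% "metabomat_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function(stage, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    timings[stage] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    message("[", stage, "] done in ", timings[stage], "s")
    v
  }

  met <- tic("io", {
    m <- read_metabolite_table(inputs$metabolites, inputs$sample_metadata)
    p0 <- read_property_table(inputs$properties, inputs$property_groups)
    a <- read_annotation_table(inputs$annotation)
    check_same_samples(m, p0)
    de <- drop_empty_items(p0)
    list(m = m, p = de$table, dropped = de$dropped, a = a)
  })

  screen <- tic("seasonal", seasonal_screen(met$m, cfg$fold_change_threshold,
                                            cfg$nondetect_policy))
  write_tsv(screen$table, file.path(out_dir, "seasonal_screen.tsv"))
  write_tsv(data.frame(sample_id = names(screen$detection$per_sample),
                       n_detected = screen$detection$per_sample),
            file.path(out_dir, "detection_counts.tsv"))
  write_tsv(data.frame(summary = names(screen$detection$summary),
                       count = screen$detection$summary),
            file.path(out_dir, "detection_summary.tsv"))
  write_tsv(data.frame(sample_id = rownames(screen$concordance),
                       screen$concordance, check.names = FALSE),
            file.path(out_dir, "concordance_matrix.tsv"))

  mi <- apply_nondetect_policy(met$m, cfg$nondetect_policy)
  corr <- tic("correlation", correlate_properties(mi, met$p, cfg$alpha))
  write_tsv(data.frame(metabolite_id = rownames(corr$rho), corr$rho,
                       check.names = FALSE),
            file.path(out_dir, "rho_matrix.tsv"))
  write_tsv(corr$kw, file.path(out_dir, "kw_results.tsv"))

  items <- items %||% met$p$item_ids
  cx <- tic("complexity", model_complexity(mi, met$p, cfg, items))
  write_tsv(fold_error_table(cx), file.path(out_dir, "fold_errors.tsv"))
  write_tsv(do.call(rbind, lapply(items, function(it)
    cbind(item_id = it, cx$per_item[[it]]$trace$trace))),
    file.path(out_dir, "selection_traces.tsv"))
  write_tsv(do.call(rbind, lapply(items, function(it)
    cbind(item_id = it, cx$per_item[[it]]$convergence))),
    file.path(out_dir, "convergence.tsv"))
  write_tsv(data.frame(item_id = items,
                       p_value = vapply(cx$per_item[items], `[[`, 0, "p_value")),
            file.path(out_dir, "comparison_pvalues.tsv"))

  selections <- lapply(cx$per_item, function(z) z$trace$selected)
  ov <- tic("overlap", overlap_count(selections, cx$groups, cfg$top_k_overlap))
  write_tsv(do.call(rbind, lapply(names(ov), function(g)
    data.frame(group = g, metabolite_id = names(ov[[g]]$counts),
               count = ov[[g]]$counts, row.names = NULL))),
    file.path(out_dir, "overlap_counts.tsv"))

  dv <- tic("diversity", diversity_analysis(met$a, selections, cx$groups, cfg))
  write_tsv(data.frame(metabolite_id = rownames(dv$coords), dv$coords),
            file.path(out_dir, "embedding_coords.tsv"))
  write_tsv(dv$axis_tests, file.path(out_dir, "axis_tests.tsv"))
  write_tsv(dv$sd_ratios_item, file.path(out_dir, "sd_ratios.tsv"))

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    config = unclass(cfg),
    inputs = as.list(unlist(inputs)),
    input_digests = as.list(tools::md5sum(unlist(inputs))),
    rng_seed = cfg$rng_seed,
    stage_timings_s = as.list(timings),
    outputs = as.list(tools::md5sum(outputs)),
    versions = list(metabomat = as.character(utils::packageVersion("metabomat")),
                    uwot = as.character(utils::packageVersion("uwot")),
                    openbabel = tryCatch(
                      system2("obabel", "-V", stdout = TRUE, stderr = FALSE)[1],
                      error = function(e) NA_character_),
                    R = R.version.string))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
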