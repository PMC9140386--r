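#' Full run configuration
#'
#' A nested list of every tunable parameter of the simulate -> map ->
#' annotate pipeline plus one master seed. Round-trips losslessly through
#' YAML ([write_run_config()] / [read_run_config()]); unknown keys are
#' rejected so a stale or misspelled configuration fails loudly.
#'
#' @param ... Named overrides of the defaults, nested as in the return
#'   value, e.g. `run_config(seed = 7, depth = list(mean_depth = 50))`.
#'   Partial sub-lists are merged over the defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    genome = list(chrom_id = c("chr1", "chr2"),
                  length_bp = c(30e6, 30e6),
                  map_length_cM = c(100, 100)),
    causal = list(chrom = "chr2", pos = 14682808, ref = "G", alt = "A"),
    mutation = list(snp_rate_per_Mb = 10, transition_fraction = 0.9),
    population = list(n_f2 = 200L, misclassification_rate = 0),
    design = list(n_mutant_bulk = 20L, n_wild_bulk = 20L),
    depth = list(mean_depth = 30, error_rate = 0.005),
    filter = list(min_index = 0.3, min_support = 7L,
                  drop_if_missing_one_bulk = TRUE),
    window = list(window_bp = 2e6, step_bp = 5e4, min_snps_per_window = 3L),
    thresholds = list(n_rep = 1000L, confidence = 0.95)
  )
  overrides <- list(...)
  cfg <- .merge_config(defaults, overrides, path = "")
  class(cfg) <- c("run_config", "list")
  cfg
}

# recursive merge rejecting keys absent from the template
.merge_config <- function(template, overrides, path) {
  if (length(overrides) == 0) return(template)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) stop("configuration entries must be named")
  unknown <- setdiff(nm, names(template))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in nm) {
    if (is.list(template[[k]])) {
      if (!is.list(overrides[[k]])) stop("configuration key ", path, k, " must be a list")
      template[[k]] <- .merge_config(template[[k]], overrides[[k]],
                                     paste0(path, k, "$"))
    } else {
      template[[k]] <- overrides[[k]]
    }
  }
  template
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

.stage <- function(name, log_con, expr) {
  line <- sprintf("[%s] stage %s: start", format(Sys.time(), "%H:%M:%OS2"), name)
  writeLines(line, log_con)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.log_count <- function(log_con, what, n) {
  writeLines(sprintf("[%s] %s: %d", format(Sys.time(), "%H:%M:%OS2"), what, n),
             log_con)
}

#' Run the whole pipeline from one configuration
#'
#' Simulates a mapping experiment, writes the dataset, maps it (SNP index
#' -> filters -> windows -> simulated null thresholds -> candidate
#' intervals), annotates the variants inside the top candidate interval
#' against the synthetic causal-gene fixture, and writes a report stating
#' whether the true locus was recovered and what consequence class it was
#' assigned. All tabular outputs are a pure function of the configuration;
#' `run.log` carries timestamps and is the only non-deterministic file.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `report` (named list), `mapping` (the
#'   `mutmap_report`) and `out_dir`. Files written: `config.yaml`,
#'   `data/dataset.vcf`, `data/truth.tsv`, `data/manifest.yaml`,
#'   `snps.tsv`, `windows.tsv`, `candidates.tsv`, `effects.tsv` (when a
#'   candidate interval exists), `report.yaml`, `run.log`.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  write_run_config(config, file.path(out_dir, "config.yaml"))

  genome <- genome_spec(config$genome$chrom_id, config$genome$length_bp,
                        config$genome$map_length_cM)
  causal <- causal_locus(config$causal$chrom, config$causal$pos,
                         config$causal$ref, config$causal$alt)
  design <- bulk_design(config$design$n_mutant_bulk, config$design$n_wild_bulk)
  if (config$window$window_bp > min(genome$length_bp)) {
    warning("window_bp exceeds a chromosome length; windows are truncated to whole chromosomes")
    writeLines("warning: window_bp exceeds a chromosome length", log_con)
  }

  ds <- .stage("simulate", log_con, {
    simulate_mapping_experiment(
      genome = genome, causal = causal,
      model = mutation_model(config$mutation$snp_rate_per_Mb,
                             config$mutation$transition_fraction),
      n_f2 = config$population$n_f2, design = design,
      depth = depth_model(config$depth$mean_depth, config$depth$error_rate),
      misclassification_rate = config$population$misclassification_rate,
      seed = config$seed
    )
  })
  .log_count(log_con, "simulated variant sites", nrow(ds$counts))
  write_dataset(ds, file.path(out_dir, "data"), manifest = unclass(config))

  mapping <- .stage("map", log_con, {
    map_dataset(ds$counts, genome = genome, design = design,
                filter_cfg = filter_config(config$filter$min_index,
                                           config$filter$min_support,
                                           config$filter$drop_if_missing_one_bulk),
                window_cfg = window_config(config$window$window_bp,
                                           config$window$step_bp,
                                           config$window$min_snps_per_window),
                n_rep = config$thresholds$n_rep,
                confidence = config$thresholds$confidence)
  })
  .log_count(log_con, "sites after filtering", mapping$log$n_retained)
  .log_count(log_con, "windows", mapping$log$n_windows)
  .log_count(log_con, "candidate intervals", mapping$log$n_candidates)

  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(mapping$snps, "snps.tsv")
  wt(mapping$windows, "windows.tsv")
  wt(mapping$candidates, "candidates.tsv")

  truth_recovered <- FALSE
  causal_effect <- NA_character_
  if (nrow(mapping$candidates) > 0) {
    top <- mapping$candidates[1, ]
    truth_recovered <- top$chrom == causal$chrom &&
      causal$pos >= top$start && causal$pos <= top$end
    effects <- .stage("annotate", log_con, {
      fix <- causal_gene_fixture(ds$counts, causal, genome)
      in_top <- ds$counts$chrom == causal$chrom &
        ds$counts$pos >= top$start & ds$counts$pos <= top$end &
        !(ds$counts$pos %in% fix$skipped)
      if (top$chrom != causal$chrom || !any(in_top)) NULL else {
        prioritize(annotate_variants(ds$counts[in_top, , drop = FALSE],
                                     fix$genes, fix$genome_seq))
      }
    })
    if (!is.null(effects)) {
      wt(effects, "effects.tsv")
      .log_count(log_con, "annotated variants in top interval", nrow(effects))
      hit <- effects$pos == causal$pos & effects$chrom == causal$chrom
      if (any(hit)) causal_effect <- effects$category[hit][1]
    }
  }

  report <- list(
    truth = list(chrom = causal$chrom, pos = causal$pos),
    truth_recovered = truth_recovered,
    causal_effect = causal_effect,
    n_sites = mapping$log$n_sites,
    n_retained = mapping$log$n_retained,
    n_candidates = mapping$log$n_candidates
  )
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  writeLines(sprintf("truth recovered: %s", truth_recovered), log_con)
  invisible(list(report = report, mapping = mapping, out_dir = out_dir))
}
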