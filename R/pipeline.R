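#' Run the analysis pipeline
#'
#' Orchestrates the stages end-to-end from a configuration list or YAML
#' file. Stages: `"simulate"` (synthetic dataset), `"preprocess"`
#' (abundance filter + rarefaction + alpha diversity), `"mechanisms"`
#' (betaNTI, RC-bray, classification, fractions), `"indices"` (SparCC,
#' TINA, PINA), `"decay"` (Bray-Curtis/geographic distance-decay curve),
#' `"stats"` (PERMANOVA screen), or `"all"` (preprocess through stats,
#' plus simulate when the config holds a scenario instead of input
#' paths). All tabular outputs are TSV under `outdir`, with a
#' `manifest.yml` recording the config echo, seed, package version and
#' per-stage status.
#'
#' Config fields: either `scenario` (a [scenario_config()] list) or
#' `counts`, `metadata`, `tree` paths; optional blocks `filter`
#' (filter_rule arguments), `rarefaction` (`depth`), `nulls` (`n_null`,
#' `pool_scope`), `sparcc` (sparcc_config arguments), `decay` (`span`,
#' `grid_size`), `stats` (`variables`, `n_perm`).
#'
#' @param config A named list or path to a YAML file.
#' @param stage One of `"simulate"`, `"preprocess"`, `"mechanisms"`,
#'   `"indices"`, `"decay"`, `"stats"`, `"all"`.
#' @param outdir Output directory (default a temporary directory).
#' @param seed Global seed; per-stage substreams are derived from it
#'   deterministically.
#' @return Invisibly, a list of stage results plus the manifest.
#' @export
run_pipeline <- function(config, stage = "all", outdir = tempfile("transectr_run_"),
                         seed = NULL) {
  stages <- c("simulate", "preprocess", "mechanisms", "indices", "decay",
              "stats", "all")
  if (!stage %in% stages) {
    abort(sprintf("Unknown stage '%s'; expected one of %s.", stage,
                  paste(stages, collapse = ", ")))
  }
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  if (is.null(seed)) seed <- config$seed %||% 1
  # per-stage substreams so stages reproduce in isolation
  stage_seed <- function(k) (seed * 101 + k * 7919) %% .Machine$integer.max
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("transectr")),
                   stages = list())
  results <- list()
  note <- function(name, status, secs) {
    manifest$stages[[name]] <<- list(status = status,
                                     wall_time_s = round(secs, 3))
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e) {
      note(name, paste("failed:", conditionMessage(e)), proc.time()[3] - t0)
      yaml::write_yaml(manifest, file.path(outdir, "manifest.yml"))
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    note(name, "ok", proc.time()[3] - t0)
    val
  }

  need_simulate <- !is.null(config$scenario)
  if (need_simulate) {
    results$dataset <- timed("simulate", {
      sc <- config$scenario
      sc$seed <- sc$seed %||% stage_seed(1)
      cfg <- do.call(scenario_config, sc)
      generate_dataset(cfg, dir = file.path(outdir, "simulated"))
    })
    if (stage == "simulate") {
      yaml::write_yaml(manifest, file.path(outdir, "manifest.yml"))
      return(invisible(c(results, list(manifest = manifest))))
    }
  }

  load_inputs <- function() {
    if (!is.null(results$dataset)) {
      return(list(counts = results$dataset$counts,
                  meta = results$dataset$metadata,
                  tree = results$dataset$tree))
    }
    for (f in c("counts", "metadata")) {
      if (is.null(config[[f]])) {
        abort(sprintf("Config field '%s' is missing (required for stage '%s').",
                      f, stage))
      }
      if (!file.exists(config[[f]])) {
        abort(sprintf("Config field '%s': file '%s' does not exist.", f, config[[f]]))
      }
    }
    tree <- NULL
    if (!is.null(config$tree)) {
      if (!file.exists(config$tree)) {
        abort(sprintf("Config field 'tree': file '%s' does not exist.", config$tree))
      }
      tree <- ape::read.tree(config$tree)
    }
    list(counts = read_count_table(config$counts),
         meta = read_sample_metadata(config$metadata), tree = tree)
  }

  inputs <- load_inputs()
  counts <- inputs$counts; meta <- inputs$meta; tree <- inputs$tree

  if (stage %in% c("preprocess", "all")) {
    results$preprocess <- timed("preprocess", {
      rule <- do.call(filter_rule, config$filter %||% list())
      filtered <- abundance_filter(counts, rule)
      depth <- (config$rarefaction %||% list())$depth %||% 8000
      depth <- min(depth, max(rowSums(count_matrix(filtered))))
      rare <- rarefy(filtered, depth = depth, seed = stage_seed(2))
      alpha <- inverse_simpson(rare)
      write_count_table(filtered, file.path(outdir, "counts_filtered.tsv"))
      write_count_table(rare, file.path(outdir, "counts_rarefied.tsv"))
      readr::write_tsv(alpha, file.path(outdir, "alpha_diversity.tsv"),
                       progress = FALSE)
      list(filtered = filtered, rarefied = rare, alpha = alpha)
    })
    counts <- results$preprocess$filtered
  }

  if (stage %in% c("mechanisms", "all")) {
    results$mechanisms <- timed("mechanisms", {
      if (is.null(tree)) {
        abort("Config field 'tree' is missing (required for stage 'mechanisms').")
      }
      nc <- config$nulls %||% list()
      cfg <- null_config(n_null = nc$n_null %||% 999,
                         seed = stage_seed(3),
                         pool_scope = nc$pool_scope %||% "whole_matrix")
      coph <- cophenetic_distances(tree)
      mech <- mechanism_table(counts, coph, cfg)
      frac <- mechanism_fractions(mech)
      readr::write_tsv(mech, file.path(outdir, "mechanisms.tsv"), progress = FALSE)
      readr::write_tsv(frac, file.path(outdir, "mechanism_fractions.tsv"),
                       progress = FALSE)
      if ("temperature" %in% names(meta)) {
        ft <- fractions_by_temperature_difference(mech, meta,
                                                  bin_width = nc$bin_width_C %||% 2)
        readr::write_tsv(ft, file.path(outdir, "mechanism_fractions_by_dT.tsv"),
                         progress = FALSE)
      }
      list(table = mech, fractions = frac)
    })
  }

  if (stage %in% c("indices", "all")) {
    results$indices <- timed("indices", {
      sp <- config$sparcc %||% list()
      sp$seed <- stage_seed(4)
      fit <- sparcc(counts, do.call(sparcc_config, sp))
      ti <- tina(counts, fit)
      readr::write_tsv(tidy(fit), file.path(outdir, "sparcc_correlations.tsv"),
                       progress = FALSE)
      readr::write_tsv(ti, file.path(outdir, "tina.tsv"), progress = FALSE)
      pi_t <- NULL
      if (!is.null(tree)) {
        pi_t <- pina(counts, cophenetic_distances(tree))
        readr::write_tsv(pi_t, file.path(outdir, "pina.tsv"), progress = FALSE)
      }
      list(sparcc = fit, tina = ti, pina = pi_t)
    })
  }

  if (stage %in% c("decay", "all")) {
    results$decay <- timed("decay", {
      dc <- config$decay %||% list()
      bc <- bray_curtis(counts)
      gd <- geo_distance(meta[match(count_matrix(counts) |> rownames(),
                                    meta$sample_id), ])
      curve <- distance_decay_curve(bc, gd, span = dc$span %||% 0.75,
                                    grid_size = dc$grid_size %||% 100)
      readr::write_tsv(curve, file.path(outdir, "decay_curve.tsv"),
                       progress = FALSE)
      curve
    })
  }

  if (stage %in% c("stats", "all")) {
    results$stats <- timed("stats", {
      st <- config$stats %||% list()
      vars <- st$variables %||% intersect(c("temperature", "NO_x", "oxygen",
                                            "salinity", "chlorophyll"),
                                          names(meta))
      bc <- bray_curtis(counts)
      pv <- permanova(bc, meta, vars, n_perm = st$n_perm %||% 999,
                      seed = stage_seed(5))
      readr::write_tsv(pv, file.path(outdir, "permanova.tsv"), progress = FALSE)
      pv
    })
  }

  yaml::write_yaml(manifest, file.path(outdir, "manifest.yml"))
  invisible(c(results, list(manifest = manifest, outdir = outdir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
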