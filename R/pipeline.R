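#' Pipeline configuration
#'
#' Collects every threshold of the analysis (the defaults are the study
#' settings: responder FDR 0.05 and 1.5 fold, atlas fold 2, PAGE quartile
#' 0.25, EPFP 0.5, rank window 300, correlation significance z 2) together
#' with either a [sim_config()] (synthetic mode) or input file paths.
#'
#' @param sim A [sim_config()]; when supplied, all inputs are simulated.
#' @param inputs Named list of paths for file mode: `matrix`, `samples`,
#'   `atlas`, `atlas_samples`, `gmt`, `models`, and `peaks` (named list:
#'   TF -> character vector of BED paths).
#' @param out_dir Output directory.
#' @param fdr_max,min_fold,atlas_min_fold,fraction,epfp_max,window,z_min
#'   Analysis thresholds.
#' @param min_samples,min_score Peak-filter settings; scalars or named
#'   per-TF vectors.
#' @param seed Seed used in synthetic mode.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL, out_dir = tempfile("tfinduce_"),
                            fdr_max = 0.05, min_fold = 1.5,
                            atlas_min_fold = 2, fraction = 0.25,
                            epfp_max = 0.5, window = 300, z_min = 2,
                            min_samples = 2, min_score = 0, seed = 1L) {
  thr <- list(fdr_max = fdr_max, min_fold = min_fold,
              atlas_min_fold = atlas_min_fold, fraction = fraction,
              epfp_max = epfp_max, window = window, z_min = z_min)
  for (nm in names(thr)) {
    if (!is.numeric(thr[[nm]]) || thr[[nm]] <= 0) {
      abort(sprintf("Threshold `%s` must be positive.", nm))
    }
  }
  if (is.null(sim) && is.null(inputs)) {
    abort("Provide either `sim` (synthetic mode) or `inputs` (file mode).")
  }
  structure(
    c(thr, list(sim = sim, inputs = inputs, out_dir = out_dir,
                min_samples = min_samples, min_score = min_score,
                seed = as.integer(seed))),
    class = "pipeline_config"
  )
}

per_tf_setting <- function(x, tf, default) {
  if (is.null(names(x))) return(x[1])
  if (tf %in% names(x)) x[[tf]] else default
}

#' Validate pipeline inputs
#'
#' Checks input files for existence and parseability, the expression matrix
#' against the sample table, BED intervals for `start < end`, and
#' gene-universe overlaps. Failures are reported, not raised.
#'
#' @param config A [pipeline_config()] in file mode.
#' @return Tibble report: `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, ok = ok, detail = detail)
  }
  if (!is.null(config$sim)) {
    add("config", TRUE, "synthetic mode: inputs are generated, nothing to validate")
    return(dplyr::bind_rows(checks))
  }
  inp <- config$inputs
  paths <- c(matrix = inp$matrix, samples = inp$samples, atlas = inp$atlas,
             atlas_samples = inp$atlas_samples, gmt = inp$gmt,
             models = inp$models, unlist(inp$peaks))
  for (nm in names(paths)) {
    add(paste0("exists:", nm), file.exists(paths[[nm]]), paths[[nm]])
  }
  if (!all(file.exists(unlist(paths)))) return(dplyr::bind_rows(checks))

  expr <- tryCatch(read_expression(inp$matrix), error = function(e) e)
  add("parse:matrix", !inherits(expr, "error"),
      if (inherits(expr, "error")) conditionMessage(expr) else "")
  samples <- tryCatch(read_sample_table(inp$samples), error = function(e) e)
  if (!inherits(expr, "error") && !inherits(samples, "error")) {
    orphan <- setdiff(samples$sample_id, expr_samples(expr))
    add("samples_in_matrix", length(orphan) == 0,
        paste(orphan, collapse = ", "))
  }
  gmt <- tryCatch(read_gmt(inp$gmt), error = function(e) e)
  add("parse:gmt", !inherits(gmt, "error"),
      if (inherits(gmt, "error")) conditionMessage(gmt) else "")
  models <- tryCatch(read_transcript_models(inp$models),
                     error = function(e) e)
  add("parse:models", !inherits(models, "error"),
      if (inherits(models, "error")) conditionMessage(models) else "")
  for (tf in names(inp$peaks)) {
    for (pth in inp$peaks[[tf]]) {
      pk <- tryCatch(read_peaks(pth), error = function(e) e)
      add(paste0("parse:peaks:", basename(pth)), !inherits(pk, "error"),
          if (inherits(pk, "error")) conditionMessage(pk) else "")
    }
  }
  dplyr::bind_rows(checks)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full induction-analysis pipeline
#'
#' Executes all stages in dependency order — inputs (simulated or read),
#' per-TF induction profiles, responder counts, profile PCA, tissue-atlas
#' correlation matrix, PAGE enrichment, peak filtering/matching/annotation,
#' and target calling with rank curves — writing TSV results plus a JSON
#' manifest (package version, config hash, seed, per-stage row counts) to
#' `config$out_dir`. A rerun with an identical configuration reproduces the
#' outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", {
      s <- simulate_experiment(config$sim)
      models <- simulate_transcript_models(config$sim)
      atlas_raw <- simulate_atlas(config$sim, s$truth)
      pk <- simulate_peaks(config$sim, s$truth, models)
      gmt <- simulate_gene_sets(config$sim, pk$truth)
      list(expr = s$expr, samples = s$samples, truth = pk$truth,
           models = models, atlas_raw = atlas_raw,
           peaks = split(pk$peaks, pk$peaks$tf), gmt = gmt)
    })
  } else {
    sim <- run_stage("read_inputs", {
      inp <- config$inputs
      list(
        expr = read_expression(inp$matrix),
        samples = read_sample_table(inp$samples),
        truth = NULL,
        models = read_transcript_models(inp$models),
        atlas_raw = list(expr = read_expression(inp$atlas),
                         samples = read_sample_table(inp$atlas_samples)),
        peaks = purrr::imap(inp$peaks, function(paths, tf) {
          purrr::map_dfr(paths, read_peaks)
        }),
        gmt = read_gmt(inp$gmt)
      )
    })
  }
  counts$genes <- nrow(sim$expr)
  counts$samples <- nrow(sim$samples)

  tfs <- unique(sim$samples$tf)
  profiles <- run_stage("induction_profiles", {
    purrr::map(setNames(tfs, tfs),
               ~ compute_induction_profile(sim$expr, sim$samples, .x))
  })
  dir.create(file.path(config$out_dir, "profiles"), showWarnings = FALSE)
  purrr::iwalk(profiles, function(p, tf) {
    write_profile(p, file.path(config$out_dir, "profiles",
                               paste0(tf, ".tsv")))
  })

  responders <- run_stage("responders", {
    count_responders(profiles, config$fdr_max, config$min_fold)
  })
  readr::write_tsv(responders, file.path(config$out_dir, "responders.tsv"),
                   progress = FALSE)
  counts$responders <- sum(responders$n_total)

  pca <- if (length(profiles) >= 2) {
    run_stage("pca", pca_profiles(profiles, config$fdr_max, config$min_fold))
  } else NULL
  if (!is.null(pca)) {
    readr::write_tsv(pca$scores, file.path(config$out_dir, "pca_scores.tsv"),
                     progress = FALSE)
  }

  atlas <- run_stage("atlas", {
    atlas_from_replicates(sim$atlas_raw$expr, sim$atlas_raw$samples,
                          fdr_max = config$fdr_max,
                          min_fold = config$atlas_min_fold)
  })
  cormat <- if (length(profiles) >= 2) {
    run_stage("correlation", {
      correlation_matrix(profiles, atlas, config$fdr_max, config$min_fold,
                         config$z_min)
    })
  } else NULL
  if (!is.null(cormat)) {
    readr::write_tsv(cormat$results,
                     file.path(config$out_dir, "correlations.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(tf_order = cormat$tf_order, tissue_order = cormat$tissue_order),
      file.path(config$out_dir, "correlation_order.json"))
    counts$correlation_cells <- nrow(cormat$results)
  }

  enrichment <- run_stage("enrichment", {
    purrr::imap_dfr(profiles, function(p, tf) {
      dplyr::bind_cols(tibble::tibble(tf = tf),
                       enrich_collection(p, sim$gmt, config$fraction))
    })
  })
  readr::write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"),
                   progress = FALSE)
  counts$enrichment_rows <- nrow(enrichment)

  bound <- run_stage("peak_annotation", {
    purrr::imap(sim$peaks, function(pk, tf) {
      pk |>
        filter_by_score(per_tf_setting(config$min_score, tf, 0)) |>
        match_across_samples(per_tf_setting(config$min_samples, tf, 2)) |>
        assign_peaks(sim$models) |>
        bound_gene_sets(tf = tf)
    })
  })
  dir.create(file.path(config$out_dir, "bound"), showWarnings = FALSE)
  purrr::iwalk(bound, function(b, tf) {
    readr::write_tsv(tibble::as_tibble(b),
                     file.path(config$out_dir, "bound", paste0(tf, ".tsv")),
                     progress = FALSE)
  })
  counts$bound_genes <- sum(purrr::map_int(bound, nrow))

  targets <- run_stage("targets", {
    purrr::imap(bound[intersect(names(bound), names(profiles))],
                function(b, tf) {
      suppressWarnings(
        call_targets(profiles[[tf]], b, config$epfp_max, config$min_fold)
      )
    })
  })
  dir.create(file.path(config$out_dir, "targets"), showWarnings = FALSE)
  purrr::iwalk(targets, function(tc, tf) {
    readr::write_tsv(tibble::as_tibble(tc),
                     file.path(config$out_dir, "targets",
                               paste0(tf, ".tsv")), progress = FALSE)
  })
  counts$targets <- sum(purrr::map_int(targets, ~ sum(.x$regulated)))

  curves <- run_stage("rank_plots", {
    purrr::imap(bound[intersect(names(bound), names(profiles))],
                function(b, tf) {
      w <- min(config$window, nrow(profiles[[tf]]))
      rank_plot(profiles[[tf]], b$gene, window = w)
    })
  })
  dir.create(file.path(config$out_dir, "rank_curves"), showWarnings = FALSE)
  purrr::iwalk(curves, function(cv, tf) {
    readr::write_tsv(tibble::as_tibble(cv),
                     file.path(config$out_dir, "rank_curves",
                               paste0(tf, ".tsv")), progress = FALSE)
  })

  cfg_json <- file.path(config$out_dir, "config.json")
  cfg_dump <- unclass_deep(config)
  cfg_dump$out_dir <- NULL  # identical analyses hash equal wherever they run
  jsonlite::write_json(cfg_dump, cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package = "tfinduce",
    version = as.character(utils::packageVersion("tfinduce")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_json)),
    stage_counts = counts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profiles = profiles, responders = responders, pca = pca,
                 atlas = atlas, correlation = cormat,
                 enrichment = enrichment, bound = bound, targets = targets,
                 curves = curves, truth = sim$truth, manifest = manifest,
                 out_dir = config$out_dir))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  if (is.object(x)) x <- unclass(x)
  x
}
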