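## End-to-end orchestration: simulate/load -> preprocess -> embed -> CCM ->
## S-map -> link properties -> sensitivity models, with per-stage seeding
## and an artifact manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis settings: embedding scan E in 2..6,
#' 1000 CCM library draws, 1000 seasonal surrogates, lagged CCM over
#' -2..+2 with 100 draws, the standard S-map theta/lambda grids, all three
#' pesticide contrasts.
#'
#' @param input Either `"synthetic"` (simulate with `synthetic`) or a path
#'   to a panel CSV.
#' @param synthetic A `synthetic_config` used when `input = "synthetic"`.
#' @param E_range Embedding scan range.
#' @param ccm List: `n_samples`, `n_surrogates`, `lag_samples`, `lags`,
#'   `delta_min`, `alpha`, `marginal_alpha`, `cycle`.
#' @param smap List: `grids` (see [smap_grids()]).
#' @param contrasts Pesticide contrasts to regress.
#' @param stages Character vector of stages to run (in pipeline order).
#' @param links Optional user-supplied edge list (data frame with `donor`,
#'   `recipient`) used when the `ccm` stage is disabled.
#' @param outdir Output directory for artifact tables (`NULL` = no files).
#' @param seed Master seed fanned out deterministically per stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "synthetic",
                            synthetic = synthetic_config(),
                            E_range = c(2L, 6L),
                            ccm = list(n_samples = 1000L,
                                       n_surrogates = 1000L,
                                       lag_samples = 100L, lags = -2:2,
                                       delta_min = 0.1, alpha = 0.05,
                                       marginal_alpha = 0.1, cycle = 10L),
                            smap = list(grids = smap_grids()),
                            contrasts = c("I", "H", "IH"),
                            stages = c("data", "embedding", "ccm", "smap",
                                       "properties", "stability"),
                            links = NULL,
                            outdir = NULL,
                            seed = 1L) {
  structure(list(input = input, synthetic = synthetic, E_range = E_range,
                 ccm = ccm, smap = smap, contrasts = contrasts,
                 stages = stages, links = links, outdir = outdir,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings are read from the file; unspecified entries keep the
#' defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(y), c("input", "contrasts", "stages", "outdir",
                                   "seed", "E_range"))) {
    cfg[[nm]] <- y[[nm]]
  }
  for (nm in intersect(names(y$ccm), names(cfg$ccm))) {
    cfg$ccm[[nm]] <- y$ccm[[nm]]
  }
  cfg
}

#' Run the full interaction-web analysis pipeline
#'
#' Executes, in order: data ingestion (or simulation), composite
#' preprocessing, embedding-dimension selection, CCM link detection,
#' regularized S-map interaction tracking, link-property reduction, and
#' the sensitivity regressions; writes every stage table to `outdir` when
#' given and returns an artifact manifest. A stage failure stops with the
#' stage name; completed artifacts are kept on the returned error.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_result` manifest: stage outputs, per-stage seeds
#'   and timings, and file paths when `outdir` was set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config, timings = list(), files = character(0))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(writer, name) {
    if (!is.null(outdir)) {
      path <- file.path(outdir, name)
      writer(path)
      res$files <<- c(res$files, path)
    }
  }
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    res$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  run <- function(name) name %in% config$stages

  ## data
  if (run("data")) {
    res$panel <- stage("data", {
      if (identical(config$input, "synthetic")) {
        sim <- simulate_community(config$synthetic,
                                  seed = derive_seed(config$seed, 1L))
        res$truth <- sim$truth
        sim$panel
      } else {
        load_panel(config$input)
      }
    })
    res$composites <- stage("preprocess", preprocess(res$panel))
    emit(function(p) utils::write.csv(res$panel, p, row.names = FALSE),
         "panel.csv")
    emit(function(p) write_composites(res$composites, p,
                                      sub("csv$", "json", p)),
         "composites.csv")
  }

  ## embedding dimensions
  if (run("embedding")) {
    res$E <- stage("embedding", {
      select_embeddings(res$composites, Emin = config$E_range[1L],
                        Emax = config$E_range[2L])
    })
    emit(function(p) jsonlite::write_json(as.list(res$E), p,
                                          auto_unbox = TRUE),
         "embedding_dimensions.json")
  }

  ## CCM link detection (or user-supplied edge list)
  if (run("ccm")) {
    res$ccm <- stage("ccm", {
      detect_links(res$composites, res$E,
                   n_samples = config$ccm$n_samples,
                   n_surrogates = config$ccm$n_surrogates,
                   lag_samples = config$ccm$lag_samples,
                   delta_min = config$ccm$delta_min,
                   alpha = config$ccm$alpha,
                   marginal_alpha = config$ccm$marginal_alpha,
                   cycle = config$ccm$cycle,
                   seed = derive_seed(config$seed, 3L))
    })
    res$links <- res$ccm$links[, c("donor", "recipient")]
    emit(function(p) write_ccm_scan(res$ccm, p, sub("csv$", "json", p)),
         "ccm_scan.csv")
  } else if (!is.null(config$links)) {
    res$links <- config$links
  }

  ## S-map interaction series
  if (run("smap")) {
    res$interactions <- stage("smap", {
      if (is.null(res$links) || nrow(res$links) == 0L) {
        NULL
      } else {
        interaction_timeseries(res$links, res$composites, res$E,
                               grids = config$smap$grids)
      }
    })
    if (!is.null(res$interactions)) {
      emit(function(p) write_interactions(res$interactions, p,
                                          sub("csv$", "json", p)),
           "interaction_series.csv")
    }
  }

  ## link properties
  if (run("properties") && !is.null(res$interactions)) {
    res$properties <- stage("properties",
                            link_properties(res$interactions,
                                            res$composites))
    emit(function(p) utils::write.csv(res$properties, p, row.names = FALSE),
         "link_properties.csv")
  }

  ## sensitivity analyses
  if (run("stability")) {
    res$sensitivity <- stage("sensitivity",
                             sensitivity_table(res$panel,
                                               contrasts = config$contrasts))
    emit(function(p) utils::write.csv(res$sensitivity, p, row.names = FALSE),
         "sensitivity.csv")
    if (!is.null(res$properties)) {
      res$regressions <- stage("stability", {
        out <- list()
        for (ct in config$contrasts) {
          dat <- assemble_sensitivity_data(res$properties, res$sensitivity,
                                           ct)
          out[[ct]] <- tryCatch(sensitivity_regression(dat),
                                error = function(e) e)
        }
        out
      })
      for (ct in names(res$regressions)) {
        if (inherits(res$regressions[[ct]], "sensitivity_fit")) {
          tb <- res$regressions[[ct]]$table
          emit(function(p) utils::write.csv(tb, p, row.names = FALSE),
               sprintf("regression_%s.csv", ct))
        }
      }
    }
  }

  res$seed <- config$seed
  class(res) <- "pipeline_result"
  if (!is.null(outdir)) {
    manifest <- list(seed = config$seed, stages = config$stages,
                     timings = res$timings, files = res$files,
                     n_links = if (is.null(res$links)) 0L else nrow(res$links))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  stages:",
      paste(names(x$timings), collapse = ", "), "\n")
  if (!is.null(x$links)) cat("  links:", nrow(x$links), "\n")
  invisible(x)
}

#' Summarize a pipeline run
#'
#' Tallies the reconstructed network: accepted links by interaction sign
#' (sign of the mean coefficient) and IDD direction, the
#' highest-variability links, and the per-contrast regression tables.
#'
#' @param result A `pipeline_result`.
#' @param top_n Number of top-variability links to list.
#' @return A `pipeline_report` list.
#' @export
make_report <- function(result, top_n = 5L) {
  stopifnot(inherits(result, "pipeline_result"))
  rep <- list()
  if (is.null(result$links) || nrow(result$links) == 0L) {
    rep$message <- "no links"
    rep$n_links <- 0L
  } else {
    rep$n_links <- nrow(result$links)
    if (!is.null(result$properties)) {
      pr <- result$properties
      ser <- result$interactions$series
      sgn <- tapply(ser$coefficient,
                    paste(ser$donor, ser$recipient, sep = "->"), mean)
      rep$n_positive_effect <- sum(sgn > 0)
      rep$n_negative_effect <- sum(sgn < 0)
      rep$idd_direction_counts <- table(pr$idd_direction)
      ord <- order(pr$temporal_variability, decreasing = TRUE)
      rep$top_variability <- pr[utils::head(ord, top_n),
                                c("donor", "recipient",
                                  "temporal_variability")]
    }
  }
  if (!is.null(result$regressions)) {
    rep$regressions <- lapply(result$regressions, function(r) {
      if (inherits(r, "sensitivity_fit")) r$table else
        paste("failed:", conditionMessage(r))
    })
  }
  class(rep) <- "pipeline_report"
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (!is.null(x$message)) cat(x$message, "\n")
  cat("links:", x$n_links, "\n")
  if (!is.null(x$idd_direction_counts)) {
    cat("IDD directions:\n")
    print(x$idd_direction_counts)
  }
  if (!is.null(x$regressions)) {
    for (nm in names(x$regressions)) {
      cat("\ncontrast", nm, ":\n")
      if (is.data.frame(x$regressions[[nm]])) {
        print(x$regressions[[nm]], row.names = FALSE)
      } else cat(x$regressions[[nm]], "\n")
    }
  }
  invisible(x)
}
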