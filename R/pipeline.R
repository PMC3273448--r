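#' Pipeline run configuration
#'
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "sava", "bym", "scm",
#'   "sensitivity", "compare")`.  `"compare"` requires both `"bym"` and
#'   `"scm"`.
#' @param counts_file,adjacency_file input paths when not simulating;
#'   `counts_file` must carry a `gender` column with values in
#'   `gender_labels`.
#' @param adjacency_format dialect for `adjacency_file`.
#' @param gender_labels values of the gender column for outcomes 1 and 2.
#' @param sim_params [simulation_params()] for the `"simulate"` stage.
#' @param priors [scm_priors()] for the `"scm"` stage.
#' @param mcmc an [mcmc_config()]; use [production_schedule()] for long runs.
#' @param n_boot bootstrap replicates for the `"sava"` stage.
#' @param seed master seed, recorded in every output header.
#' @param geojson optional GeoJSON path with an `area_id` property; used
#'   only to export choropleth files, never in computation.
#' @param verbose print stage progress.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir, stages = c("simulate", "sava", "bym",
                                           "scm", "compare"),
                       counts_file = NULL, adjacency_file = NULL,
                       adjacency_format = "adjacency-list",
                       gender_labels = c("men", "women"),
                       sim_params = NULL, priors = scm_priors(),
                       mcmc = NULL, n_boot = 1000, seed = 1,
                       geojson = NULL, verbose = TRUE) {
  stages <- match.arg(stages, c("simulate", "sava", "bym", "scm",
                                "sensitivity", "compare"),
                      several.ok = TRUE)
  seed <- as.integer(seed)
  if (is.null(sim_params)) sim_params <- simulation_params(seed = seed)
  if (is.null(mcmc)) mcmc <- mcmc_config(seed = seed)
  structure(list(out_dir = out_dir, stages = stages,
                 counts_file = counts_file,
                 adjacency_file = adjacency_file,
                 adjacency_format = adjacency_format,
                 gender_labels = gender_labels,
                 sim_params = sim_params, priors = priors, mcmc = mcmc,
                 n_boot = n_boot, seed = seed, geojson = geojson,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

config_fingerprint <- function(config) {
  keep <- config[c("stages", "gender_labels", "n_boot", "seed")]
  keep$mcmc <- unclass(config$mcmc)
  keep$sim <- unclass(config$sim_params)
  keep$priors <- list(lambda = config$priors$lambda,
                      beta = config$priors$beta,
                      precision = config$priors$precision$type,
                      delta = config$priors$delta$type)
  as.character(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = 8))
}

write_output_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed: ", config$seed),
               paste0("# config: ", config_fingerprint(config))), con)
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages — simulate (or load) a paired areal
#' dataset, classical variation statistics per gender, per-gender BYM
#' fits, the joint shared component fit, and the model comparison —
#' writing one tab-delimited table per product into `out_dir`.  Every
#' output file header records the seed and a JSON fingerprint of the
#' configuration, so a rerun with the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("[setup] cannot create output directory ", config$out_dir)
  say <- function(...) if (config$verbose) message("[", ..., "]")
  out <- list(config = config)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  opath <- function(f) file.path(config$out_dir, f)

  # --- data ---
  if ("simulate" %in% config$stages) {
    out$sim <- stage("simulate", simulate_scm(config$sim_params))
    out$dataset <- out$sim$dataset
    stage("simulate", {
      both <- do.call(rbind, lapply(
        stats::setNames(c("men", "women"), config$gender_labels),
        function(gn) {
          cc <- out$dataset[[gn]]
          data.frame(area_id = cc$area_ids,
                     observed = unname(cc$observed),
                     population = unname(cc$population),
                     expected = unname(cc$expected),
                     stringsAsFactors = FALSE)
        }))
      both <- cbind(both, gender = rep(config$gender_labels,
                                       each = out$dataset$adjacency$n_areas))
      utils::write.table(both, opath("counts.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      write_adjacency(out$dataset$adjacency, opath("adjacency.txt"))
      jsonlite::write_json(
        c(out$sim$truth$realized_variances,
          out$sim$truth$realized_fractions,
          list(delta = out$sim$truth$delta, seed = config$seed)),
        opath("truth.json"), auto_unbox = TRUE, digits = NA)
    })
  } else {
    out$dataset <- stage("load", {
      adj <- load_adjacency(config$adjacency_file,
                            config$adjacency_format)
      gender_paired_dataset(
        adj,
        read_counts(config$counts_file, config$gender_labels[1L]),
        read_counts(config$counts_file, config$gender_labels[2L]))
    })
  }
  ds <- out$dataset

  if ("sava" %in% config$stages) {
    out$sava <- stage("sava", {
      res <- lapply(stats::setNames(c("men", "women"),
                                    config$gender_labels), function(gn) {
        cc <- ds[[gn]]
        list(stats = variation_statistics(cc, n_boot = config$n_boot,
                                          seed = config$seed),
             iur = indirect_utilization_ratio(cc))
      })
      tab <- do.call(rbind, lapply(names(res), function(gl) {
        cbind(gender = gl, res[[gl]]$stats)
      }))
      write_output_table(tab, opath("variation_statistics.tsv"), config)
      iur <- do.call(rbind, lapply(names(res), function(gl) {
        cbind(gender = gl, res[[gl]]$iur)
      }))
      write_output_table(iur, opath("utilization_ratios.tsv"), config)
      res
    })
  }

  if ("bym" %in% config$stages) {
    out$bym <- stage("bym", {
      fits <- list(
        men = fit_bym(ds$men, ds$adjacency, config = config$mcmc),
        women = fit_bym(ds$women, ds$adjacency, config = config$mcmc))
      tab <- do.call(rbind, lapply(names(fits), function(gn) {
        f <- fits[[gn]]
        data.frame(gender = gn,
                   parameter = rownames(f$summary),
                   f$summary, dic = f$dic, pd = f$pd,
                   row.names = NULL, stringsAsFactors = FALSE)
      }))
      write_output_table(tab, opath("bym_summary.tsv"), config)
      per_area <- do.call(rbind, lapply(names(fits), function(gn)
        cbind(gender = gn, fits[[gn]]$rr)))
      write_output_table(per_area, opath("bym_per_area.tsv"), config)
      conv <- do.call(rbind, lapply(names(fits), function(gn)
        cbind(gender = gn, fits[[gn]]$convergence)))
      write_output_table(conv, opath("bym_convergence.tsv"), config)
      fits
    })
  }

  if ("scm" %in% config$stages) {
    out$scm <- stage("scm", {
      f <- fit_scm(ds, priors = config$priors, config = config$mcmc)
      s <- f$partition$summary
      tab <- data.frame(quantity = rownames(s), s, row.names = NULL,
                        stringsAsFactors = FALSE)
      tab <- rbind(tab, data.frame(quantity = "delta",
                                   median = f$delta$summary[1L],
                                   ci_low = f$delta$summary[2L],
                                   ci_high = f$delta$summary[3L]),
                   data.frame(quantity = "dic", median = f$dic,
                              ci_low = NA, ci_high = NA),
                   data.frame(quantity = "pd", median = f$pd,
                              ci_low = NA, ci_high = NA))
      write_output_table(tab, opath("scm_summary.tsv"), config)
      write_output_table(f$maps, opath("scm_components.tsv"), config)
      if (!is.null(f$convergence))
        write_output_table(f$convergence, opath("scm_convergence.tsv"),
                           config)
      if (!is.null(config$geojson))
        write_choropleth(config$geojson, f$maps, opath("scm_map.geojson"))
      f
    })
  }

  if ("sensitivity" %in% config$stages) {
    out$sensitivity <- stage("sensitivity", {
      grid <- default_sensitivity_grid()
      sg <- sensitivity_grid(ds, grid, config$mcmc)
      write_output_table(sg$table, opath("sensitivity.tsv"), config)
      sg
    })
  }

  if ("compare" %in% config$stages) {
    if (is.null(out$bym) || is.null(out$scm))
      stop("[compare] requires the bym and scm stages")
    out$compare <- stage("compare", {
      cmp <- compare_dic(out$bym$men, out$bym$women, out$scm)
      tab <- data.frame(
        quantity = c("dic_bym", "dic_scm", "delta_dic", "pd_bym",
                     "pd_scm", "mean_sd_log_rr_bym",
                     "mean_sd_log_rr_scm", "sd_reduction_pct"),
        value = c(cmp$dic_bym, cmp$dic_scm, cmp$delta_dic, cmp$pd_bym,
                  cmp$pd_scm, cmp$mean_sd_log_rr[["bym"]],
                  cmp$mean_sd_log_rr[["scm"]], cmp$sd_reduction_pct))
      write_output_table(tab, opath("model_comparison.tsv"), config)
      cmp
    })
  }
  invisible(out)
}

#' Standard prior-sensitivity grid
#'
#' The default configuration plus the usual alternatives: exchangeable
#' (non-spatial) priors on the shared and specific fields,
#' `Gamma(0.01, 0.01)` / uniform-sd / half-normal-sd hyperpriors on the
#' variances, and the bounded-uniform prior on `delta`.
#'
#' @return named list of [scm_priors()] configurations.
#' @export
default_sensitivity_grid <- function() {
  list(
    default = scm_priors(),
    exchangeable_fields = scm_priors(lambda = "exchangeable",
                                     beta = "exchangeable"),
    gamma_0.01 = scm_priors(precision = precision_hyperprior(
      "gamma", shape = 0.01, rate = 0.01)),
    uniform_sd = scm_priors(precision = precision_hyperprior(
      "uniform_sd")),
    halfnormal_sd = scm_priors(precision = precision_hyperprior(
      "halfnormal_sd")),
    uniform_delta = scm_priors(delta = delta_prior("uniform")))
}

#' Attach per-area values to a GeoJSON for choropleth export
#'
#' Geometry is never used in computation; this merely joins a table of
#' per-area values onto the features of a GeoJSON (matched on the
#' `area_id` property) and writes the result, ready for any GIS viewer.
#'
#' @param geojson_in path to a GeoJSON `FeatureCollection` whose
#'   features carry an `area_id` property.
#' @param values data.frame with an `area_id` column and numeric columns
#'   to attach.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_choropleth <- function(geojson_in, values, path) {
  gj <- jsonlite::read_json(geojson_in)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  cols <- setdiff(names(values), "area_id")
  for (k in seq_along(gj$features)) {
    aid <- gj$features[[k]]$properties$area_id
    row <- match(aid, values$area_id)
    if (!is.na(row))
      for (cl in cols)
        gj$features[[k]]$properties[[cl]] <- values[[cl]][row]
  }
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
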