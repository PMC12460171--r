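# End-to-end pipeline runs from a declarative YAML config.
#
# Every stage writes its intermediate table to the output directory, so any
# number in the final report can be traced to a named file. Stage failures
# abort with the stage name prepended.

#' Read and validate a run configuration
#'
#' The config is a single YAML file; relative input paths are resolved
#' against the config file's directory. Recognized keys: `pipeline`
#' (`"dnl"` or `"fao"`), `paths` (per-pipeline input files), `output_dir`,
#' `seed`, `na_correction` (`heavy_fraction_h2`, `heavy_fraction_c13`,
#' `tracer_purity`, `residual_warn_threshold`), `statistics` (`method`,
#' `alternative`, `fdr`), `fao` (`baseline_fraction`, `enrichment_floor`).
#'
#' @param path YAML file path.
#' @return Validated config list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config not found: '%s'", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pipeline) || !cfg$pipeline %in% c("dnl", "fao")) {
    stop("config must set pipeline: dnl or fao", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p) {
    p <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(p)) {
      stop(sprintf("input path does not exist: '%s'", p), call. = FALSE)
    }
    normalizePath(p)
  })
  required <- switch(cfg$pipeline,
                     dnl = c("peak_table", "sample_meta",
                             "body_water_standards"),
                     fao = c("co2_traces", "substrate"))
  missing <- setdiff(required, names(cfg$paths))
  if (length(missing)) {
    stop(sprintf("config missing path(s) for pipeline '%s': %s",
                 cfg$pipeline, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$output_dir)) cfg$output_dir <- file.path(base, "output")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

write_stage <- function(df, dir, file) {
  path <- file.path(dir, file)
  write.csv(df, path, row.names = FALSE)
  path
}

run_log <- function(cfg, dir, extra = character(0)) {
  lines <- c(sprintf("tracequant %s", as.character(packageVersion("tracequant"))),
             sprintf("pipeline: %s", cfg$pipeline),
             sprintf("seed: %s", cfg$seed),
             sprintf("config: %s", cfg$config_path),
             sprintf("config_md5: %s",
                     unname(tools::md5sum(cfg$config_path))),
             sprintf("run_time: %s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
             extra)
  writeLines(lines, file.path(dir, "run_log.txt"))
}

#' Run the heavy-water lipogenesis pipeline
#'
#' Stages, in order: read peak table, assemble MIDs, natural-abundance
#' correction, deuterium enrichment, body-water calibration,
#' exchangeable-hydrogen / DNL-fraction / rate calculation, IQR outlier
#' flagging per group, and group comparison on the DNL fraction. Every
#' stage's table is written to the output directory, plus a plain-text
#' summary and a run log (package version, seed, config hash).
#'
#' @param config Path to a YAML config or a [read_run_config()] object.
#' @return Invisibly, a list: `results` (per-sample table), `stats`
#'   (group comparisons), `body_water_curve`, `outliers`, `output_dir`.
#' @export
run_dnl_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  if (cfg$pipeline != "dnl") stop("config pipeline is not 'dnl'", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  nac <- cfg$na_correction
  model <- na_model("H",
                    heavy_fraction = nac$heavy_fraction_h2,
                    tracer_purity = if (is.null(nac$tracer_purity)) 1 else
                      nac$tracer_purity)
  warn_thr <- if (is.null(nac$residual_warn_threshold)) 0.01 else
    nac$residual_warn_threshold

  records <- stage("read_peak_table",
                   read_peak_table(cfg$paths$peak_table))
  write_stage(records, cfg$output_dir, "01_peak_records.csv")

  mids <- stage("assemble_mids", assemble_mids(records))
  raw_tab <- do.call(rbind, lapply(mids, function(m) {
    data.frame(sample_id = m$sample_id, metabolite = m$metabolite,
               isotopologue_index = seq_along(m$intensities) - 1L,
               intensity = m$intensities, stringsAsFactors = FALSE)
  }))
  write_stage(raw_tab, cfg$output_dir, "02_raw_mids.csv")

  corrected <- stage("na_correction", lapply(mids, function(m) {
    fr <- correct_mid(m$intensities, m$n_atoms, model,
                      residual_warn = warn_thr)
    m$fractions <- as.vector(fr)
    m$residual <- attr(fr, "residual")
    m
  }))
  corr_tab <- do.call(rbind, lapply(corrected, function(m) {
    data.frame(sample_id = m$sample_id, metabolite = m$metabolite,
               isotopologue_index = seq_along(m$fractions) - 1L,
               fraction = m$fractions, residual = m$residual,
               stringsAsFactors = FALSE)
  }))
  write_stage(corr_tab, cfg$output_dir, "03_corrected_mids.csv")

  enr_tab <- stage("enrichment", do.call(rbind, lapply(corrected, function(m) {
    e <- deuterium_enrichment(m$fractions)
    data.frame(sample_id = m$sample_id, metabolite = m$metabolite,
               h1 = e$h1, h2 = e$h2, h3 = e$h3,
               h2_enrichment = e$enrichment,
               h2_enrichment_untruncated = e$enrichment_untruncated,
               stringsAsFactors = FALSE)
  })))
  write_stage(enr_tab, cfg$output_dir, "04_enrichment.csv")

  meta <- stage("read_sample_meta", read_sample_meta(cfg$paths$sample_meta))
  curve <- stage("body_water_calibration", {
    std <- read.csv(cfg$paths$body_water_standards)
    fit_body_water_curve(std)
  })
  if (!"body_water_acetone_fraction" %in% names(meta)) {
    stop("stage 'body_water_calibration': sample metadata lacks ",
         "body_water_acetone_fraction", call. = FALSE)
  }
  meta$body_water <- body_water_enrichment(meta$body_water_acetone_fraction,
                                           curve)
  write_stage(meta[c("sample_id", "group", "body_water_acetone_fraction",
                     "body_water")],
              cfg$output_dir, "05_body_water.csv")

  results <- stage("dnl", {
    rows <- lapply(corrected, function(m) {
      i <- match(m$sample_id, meta$sample_id)
      if (is.na(i)) {
        stop(sprintf("sample '%s' absent from metadata", m$sample_id))
      }
      elapsed <- if (all(c("dose_time", "collection_time") %in% names(meta))) {
        as.numeric(difftime(meta$collection_time[i], meta$dose_time[i],
                            units = "hours"))
      } else {
        NA_real_
      }
      out <- dnl_from_mid(m$fractions, meta$body_water[i],
                          elapsed_hours = elapsed, sample_id = m$sample_id)
      out$group <- meta$group[i]
      out
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  excluded <- results[results$qc_flags == "h1_zero", , drop = FALSE]
  if (nrow(excluded)) {
    message(sprintf("%d sample(s) excluded (undefined H2/H1 ratio): %s",
                    nrow(excluded),
                    paste(excluded$sample_id, collapse = ", ")))
  }
  write_stage(results, cfg$output_dir, "06_dnl_results.csv")

  usable <- results[results$qc_flags != "h1_zero", , drop = FALSE]
  outliers <- stage("outlier_flagging", {
    flags <- unlist(lapply(split(seq_len(nrow(usable)), usable$group),
                           function(ix) {
      setNames(flag_outliers_iqr(usable$dnl_fraction[ix]),
               usable$sample_id[ix])
    }))
    data.frame(sample_id = names(flags), outlier = unname(flags),
               stringsAsFactors = FALSE)
  })
  write_stage(outliers, cfg$output_dir, "07_outliers.csv")

  stat_cfg <- cfg$statistics
  method <- if (is.null(stat_cfg$method)) "anova_tukey" else stat_cfg$method
  kept <- usable[!usable$sample_id %in%
                   outliers$sample_id[outliers$outlier %in% TRUE], ,
                 drop = FALSE]
  stats_tab <- stage("group_comparison",
                     compare_groups(kept$dnl_fraction, kept$group,
                                    method = method,
                                    alternative = stat_cfg$alternative))
  write_stage(stats_tab, cfg$output_dir, "08_group_stats.csv")

  summary_lines <- c(
    "DNL pipeline summary",
    sprintf("samples analysed: %d (excluded: %d, outliers: %d)",
            nrow(results), nrow(excluded),
            sum(outliers$outlier %in% TRUE)),
    sprintf("body-water curve: slope %.4f, intercept %.5f, r^2 %.4f",
            curve$slope, curve$intercept, curve$r_squared),
    "group mean DNL fraction:",
    vapply(split(kept$dnl_fraction, kept$group), function(v) {
      sprintf("  %.4f (n = %d)", mean(v), length(v))
    }, character(1)))
  writeLines(summary_lines, file.path(cfg$output_dir, "summary.txt"))
  run_log(cfg, cfg$output_dir)

  invisible(list(results = results, stats = stats_tab,
                 body_water_curve = curve, outliers = outliers,
                 output_dir = cfg$output_dir))
}

#' Run the 13CO2 oxidation pipeline
#'
#' Stages: read traces and substrate enrichment, baseline-corrected excess,
#' slope to the maximum per animal (flat traces abort, listing every animal
#' without a rising phase), per-timepoint normalization to substrate
#' enrichment, and group comparison of slopes and mean normalized
#' oxidation when a `group` column is present.
#'
#' @param config Path to a YAML config or a [read_run_config()] object.
#' @return Invisibly, a list: `slopes`, `normalized`, `stats`,
#'   `output_dir`.
#' @export
run_fao_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  if (cfg$pipeline != "fao") stop("config pipeline is not 'fao'", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  fao_cfg <- cfg$fao
  baseline <- if (is.null(fao_cfg$baseline_fraction)) 0.011 else
    fao_cfg$baseline_fraction
  floor_e <- if (is.null(fao_cfg$enrichment_floor)) 0.001 else
    fao_cfg$enrichment_floor

  trace_tab <- stage("read_traces", {
    tab <- read.csv(cfg$paths$co2_traces, stringsAsFactors = FALSE)
    req <- c("animal_id", "time_min", "co2_ratio")
    if (!all(req %in% names(tab))) {
      stop(sprintf("trace CSV needs columns %s", paste(req, collapse = ", ")))
    }
    tab
  })
  write_stage(trace_tab, cfg$output_dir, "01_traces.csv")
  sub_tab <- stage("read_substrate", {
    tab <- read.csv(cfg$paths$substrate, stringsAsFactors = FALSE)
    req <- c("animal_id", "time_min", "enrichment")
    if (!all(req %in% names(tab))) {
      stop(sprintf("substrate CSV needs columns %s",
                   paste(req, collapse = ", ")))
    }
    tab
  })

  groups <- if ("group" %in% names(trace_tab)) {
    g <- unique(trace_tab[c("animal_id", "group")])
    setNames(g$group, g$animal_id)
  } else {
    NULL
  }
  traces <- lapply(split(trace_tab, trace_tab$animal_id), function(d) {
    d <- d[order(d$time_min), ]
    co2_trace(d$animal_id[1L], d$time_min, d$co2_ratio, baseline)
  })
  substrates <- lapply(split(sub_tab, sub_tab$animal_id), function(d) {
    d <- d[order(d$time_min), ]
    substrate_trace(d$animal_id[1L], d$time_min, d$enrichment)
  })

  slopes <- stage("slope_to_max", {
    res <- lapply(traces, function(tr) {
      tryCatch(slope_to_max(tr), error = function(e) e)
    })
    failed <- names(res)[vapply(res, inherits, logical(1), "error")]
    if (length(failed)) {
      stop(sprintf("no rise for animal(s): %s",
                   paste(failed, collapse = ", ")))
    }
    do.call(rbind, lapply(names(res), function(id) {
      data.frame(animal_id = id,
                 group = if (is.null(groups)) NA_character_ else
                   groups[[id]],
                 slope = res[[id]]$slope,
                 time_of_max = res[[id]]$time_of_max,
                 n_points = res[[id]]$n_points, stringsAsFactors = FALSE)
    }))
  })
  write_stage(slopes, cfg$output_dir, "02_slopes.csv")

  normalized <- stage("normalize_oxidation", {
    rows <- lapply(names(traces), function(id) {
      if (!id %in% names(substrates)) {
        stop(sprintf("no substrate enrichment for animal '%s'", id))
      }
      out <- normalize_oxidation(traces[[id]], substrates[[id]],
                                 enrichment_floor = floor_e)
      out$animal_id <- id
      out$group <- if (is.null(groups)) NA_character_ else groups[[id]]
      out
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  write_stage(normalized, cfg$output_dir, "03_normalized_oxidation.csv")

  stats_tab <- NULL
  if (!is.null(groups) && length(unique(groups)) >= 2L) {
    stat_cfg <- cfg$statistics
    method <- if (is.null(stat_cfg$method)) "t_two_sided" else stat_cfg$method
    mean_norm <- vapply(split(normalized$normalized, normalized$animal_id),
                        mean, numeric(1))
    stats_tab <- stage("group_comparison", {
      s <- compare_groups(slopes$slope, slopes$group, method = method,
                          alternative = stat_cfg$alternative)
      s$metric <- "slope_to_max"
      n <- compare_groups(mean_norm[slopes$animal_id], slopes$group,
                          method = method,
                          alternative = stat_cfg$alternative)
      n$metric <- "mean_normalized_oxidation"
      rbind(s, n)
    })
    write_stage(stats_tab, cfg$output_dir, "04_group_stats.csv")
  }

  summary_lines <- c(
    "FAO pipeline summary",
    sprintf("animals: %d", nrow(slopes)),
    "mean slope by group:",
    if (!is.null(groups)) {
      vapply(split(slopes$slope, slopes$group), function(v) {
        sprintf("  %.3e per min (n = %d)", mean(v), length(v))
      }, character(1))
    } else {
      sprintf("  %.3e per min (all animals)", mean(slopes$slope))
    })
  writeLines(summary_lines, file.path(cfg$output_dir, "summary.txt"))
  run_log(cfg, cfg$output_dir)

  invisible(list(slopes = slopes, normalized = normalized,
                 stats = stats_tab, output_dir = cfg$output_dir))
}
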