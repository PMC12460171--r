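# Seeded synthetic-data generators.
#
# These emulate the generative model the estimators assume: palmitate from
# heavy-water tracing is a two-population mixture (pre-existing unlabelled
# molecules plus newly synthesized molecules whose n exchangeable hydrogens
# are each deuterated at the body-water fraction, i.e. binomial labelling),
# convolved with natural isotope abundance and measured with multiplicative
# log-normal intensity noise (the standard noise model for LC-MS ion
# counts). CO2 breath traces follow a rise-then-decay curve over a natural
# abundance baseline.

PALMITATE_FORMULA <- "C16H31O2"  # saponified palmitate anion composition

#' Design of a synthetic heavy-water tracing cohort
#'
#' Defaults mirror the study shape this package targets: three diet groups
#' (control + sugar water CF, inulin + sugar IF, delayed-inulin CIF) with
#' true newly-synthesized palmitate fractions 0.5 / 0.25 / 0.3 (plausible
#' effect directions: inulin suppresses lipogenesis), 10 animals per group,
#' 22 exchangeable hydrogens, 2.5% body-water enrichment (a 30 ul/g
#' intraperitoneal heavy-water dose), 5% multiplicative intensity CV, and a
#' 15 h dose-to-collection interval (18:00 to 09:00).
#'
#' @param groups Named numeric vector of per-group true DNL fractions.
#' @param n_per_group Animals per group.
#' @param n_sites True exchangeable hydrogens.
#' @param body_water True body-water 2H fraction.
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   intensity noise (0 = noise-free).
#' @param total_intensity Mean total ion count per sample.
#' @param na_model Natural-abundance model ([na_model()]); deuterium by
#'   default.
#' @param acetone_slope,acetone_intercept Forward acetone-exchange curve
#'   used to emit each sample's measured acetone fraction.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return Object of class `"synthetic_design"`.
#' @export
synthetic_design <- function(groups = c(CF = 0.5, IF = 0.25, CIF = 0.3),
                             n_per_group = 10, n_sites = 22,
                             body_water = 0.025, intensity_cv = 0.05,
                             total_intensity = 1e6,
                             na_model = tracequant::na_model("H"),
                             acetone_slope = 0.75,
                             acetone_intercept = 0.005,
                             seed = 1) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a named vector of true DNL fractions",
         call. = FALSE)
  }
  if (any(groups < 0 | groups > 1)) {
    stop("true DNL fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_per_group < 1) stop("'n_per_group' must be >= 1", call. = FALSE)
  if (intensity_cv < 0) stop("'intensity_cv' must be >= 0", call. = FALSE)
  if (body_water <= 0 || body_water >= 1) {
    stop("'body_water' must lie in (0, 1)", call. = FALSE)
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 n_sites = check_count(n_sites, "n_sites"),
                 body_water = body_water, intensity_cv = intensity_cv,
                 total_intensity = total_intensity, na_model = na_model,
                 acetone_slope = acetone_slope,
                 acetone_intercept = acetone_intercept,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' True mixture MID of partially renewed palmitate
#'
#' `(1 - f) * delta_0 + f * Binomial(n_sites, body_water)`, padded to
#' `length_out` entries: the MID of a pool in which a fraction f was newly
#' synthesized while body water was enriched.
#'
#' @param f Newly synthesized fraction.
#' @param n_sites Exchangeable hydrogens.
#' @param body_water Labelling probability per site.
#' @param length_out Output length (default `n_sites + 1`); extra entries
#'   are zero (isotopologues the molecule can carry but the model never
#'   populates).
#' @return Simplex vector of length `length_out`.
#' @export
true_palmitate_mid <- function(f, n_sites, body_water,
                               length_out = n_sites + 1) {
  mix <- dbinom(0:n_sites, n_sites, body_water) * f
  mix[1L] <- mix[1L] + (1 - f)
  c(mix, numeric(length_out - n_sites - 1L))
}

#' Simulate a heavy-water tracing cohort
#'
#' Generates, per animal, a palmitate MID from the two-population mixture
#' model, forward-convolves it with the natural-abundance matrix (the exact
#' model the correction inverts), scales to the design's total intensity
#' and applies multiplicative log-normal noise per isotopologue. Emits the
#' long peak table and sample metadata consumed by [read_peak_table()] /
#' [read_sample_meta()], noise-free acetone standards for the body-water
#' curve, and a truth table.
#'
#' @param design A [synthetic_design()].
#' @return List: `peaks` (long peak table), `meta` (sample metadata with
#'   `body_water_acetone_fraction`), `standards` (acetone standards),
#'   `truth` (`sample_id`, `group`, `f_true`, `n_sites`, `body_water`),
#'   `design`.
#' @export
simulate_dnl_cohort <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  n_h <- count_element(PALMITATE_FORMULA, "H")
  A <- build_correction_matrix(n_h, design$na_model)
  sdlog <- sqrt(log(1 + design$intensity_cv^2))
  dose <- as.POSIXct("2024-05-01 18:00:00", tz = "UTC")
  collect <- as.POSIXct("2024-05-02 09:00:00", tz = "UTC")  # 15 h later

  peaks <- list()
  meta <- list()
  truth <- list()
  for (gi in seq_along(design$groups)) {
    gname <- names(design$groups)[gi]
    f <- design$groups[[gi]]
    for (i in seq_len(design$n_per_group)) {
      sid <- sprintf("%s_%02d", gname, i)
      mid <- true_palmitate_mid(f, design$n_sites, design$body_water,
                                length_out = n_h + 1L)
      expected <- as.vector(A %*% mid) * design$total_intensity
      noise <- if (design$intensity_cv > 0) {
        rlnorm(n_h + 1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep(1, n_h + 1L)
      }
      peaks[[sid]] <- data.frame(
        sample_id = sid, metabolite = "palmitate",
        formula = PALMITATE_FORMULA, tracer_element = "H",
        isotopologue_index = 0:n_h, intensity = expected * noise,
        stringsAsFactors = FALSE)
      meta[[sid]] <- data.frame(
        sample_id = sid, group = gname,
        dose_time = format(dose, "%Y-%m-%dT%H:%M:%S"),
        collection_time = format(collect, "%Y-%m-%dT%H:%M:%S"),
        body_water_acetone_fraction = design$acetone_intercept +
          design$acetone_slope * design$body_water,
        stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(
        sample_id = sid, group = gname, f_true = f,
        n_sites = design$n_sites, body_water = design$body_water,
        stringsAsFactors = FALSE)
    }
  }
  standards <- simulate_body_water_standards(
    fractions = c(0, 0.005, 0.01, 0.02, 0.03, 0.04),
    slope = design$acetone_slope, intercept = design$acetone_intercept,
    noise_sd = 0, seed = design$seed)
  list(peaks = do.call(rbind, c(peaks, make.row.names = FALSE)),
       meta = do.call(rbind, c(meta, make.row.names = FALSE)),
       standards = standards,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       design = design)
}

#' Simulate acetone body-water calibration standards
#'
#' `acetone_h1 = slope * known_fraction + intercept + N(0, noise_sd)`,
#' emulating a heavy-water serial dilution in naturally labelled water.
#'
#' @param fractions Known heavy-water fractions (>= 2).
#' @param slope,intercept True forward curve.
#' @param noise_sd Gaussian measurement noise SD (0 = collinear).
#' @param seed Integer seed.
#' @return `data.frame`: `known_fraction`, `acetone_h1_fraction`.
#' @export
simulate_body_water_standards <- function(fractions = c(0, 0.005, 0.01,
                                                        0.02, 0.03, 0.04),
                                          slope = 0.75, intercept = 0.005,
                                          noise_sd = 0, seed = 1) {
  if (length(fractions) < 2L) {
    stop("need at least 2 standard fractions", call. = FALSE)
  }
  set.seed(seed)
  data.frame(known_fraction = fractions,
             acetone_h1_fraction = slope * fractions + intercept +
               rnorm(length(fractions), sd = noise_sd))
}

#' Simulate 13CO2 breath traces and substrate enrichment
#'
#' Per animal, excess above the natural-abundance baseline follows
#' `A * (1 - exp(-rise_rate * t)) * exp(-decay_rate * t)` with
#' multiplicative log-normal noise; circulating substrate enrichment decays
#' as `substrate_e0 * exp(-substrate_decay * t)` with the same noise model.
#' Defaults emulate an oral gavage breath test sampled every 40 minutes for
#' 6 hours with the excess peaking near 2 h, and a second group with 1.5x
#' the excretion amplitude.
#'
#' @param amplitudes Named numeric vector of per-group peak-scale
#'   amplitudes A.
#' @param n_per_group Animals per group.
#' @param rise_rate,decay_rate Rate constants, per minute (> 0).
#' @param noise_cv Multiplicative noise CV on excess and enrichment.
#' @param times Sampling times, minutes since dose.
#' @param baseline Natural-abundance 13CO2 fraction.
#' @param substrate_e0,substrate_decay Substrate enrichment curve
#'   parameters.
#' @param seed Integer seed.
#' @return List: `traces` (list of [co2_trace()]), `substrates` (list of
#'   [substrate_trace()]), `truth` (`animal_id`, `group`, `amplitude`,
#'   `rise_rate`, `decay_rate`).
#' @export
simulate_co2_traces <- function(amplitudes = c(A = 0.004, B = 0.006),
                                n_per_group = 8, rise_rate = 0.015,
                                decay_rate = 0.004, noise_cv = 0.10,
                                times = seq(0, 360, by = 40),
                                baseline = 0.011, substrate_e0 = 0.15,
                                substrate_decay = 0.003, seed = 1) {
  if (rise_rate <= 0 || decay_rate <= 0) {
    stop("rate constants must be > 0", call. = FALSE)
  }
  if (is.null(names(amplitudes))) {
    stop("'amplitudes' must be a named vector (one entry per group)",
         call. = FALSE)
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  traces <- list()
  substrates <- list()
  truth <- list()
  for (g in names(amplitudes)) {
    A <- amplitudes[[g]]
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      ex <- A * (1 - exp(-rise_rate * times)) * exp(-decay_rate * times)
      en <- substrate_e0 * exp(-substrate_decay * times)
      if (noise_cv > 0) {
        ex <- ex * rlnorm(length(times), -sdlog^2 / 2, sdlog)
        en <- en * rlnorm(length(times), -sdlog^2 / 2, sdlog)
      }
      traces[[id]] <- co2_trace(id, times, pmin(baseline + ex, 1), baseline)
      substrates[[id]] <- substrate_trace(id, times, pmin(en, 1))
      truth[[id]] <- data.frame(animal_id = id, group = g, amplitude = A,
                                rise_rate = rise_rate,
                                decay_rate = decay_rate,
                                stringsAsFactors = FALSE)
    }
  }
  list(traces = traces, substrates = substrates,
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Write a simulated DNL cohort to the pipeline's CSV schemas
#'
#' @param cohort Output of [simulate_dnl_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dnl_inputs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             meta = file.path(dir, "sample_meta.csv"),
             standards = file.path(dir, "body_water_standards.csv"),
             truth = file.path(dir, "truth.csv"))
  write_peak_table(cohort$peaks, paths[["peaks"]])
  write.csv(cohort$meta, paths[["meta"]], row.names = FALSE, quote = FALSE)
  write.csv(cohort$standards, paths[["standards"]], row.names = FALSE,
            quote = FALSE)
  write.csv(cohort$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write simulated CO2 traces to the pipeline's CSV schemas
#'
#' @param sim Output of [simulate_co2_traces()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fao_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grp <- setNames(sim$truth$group, sim$truth$animal_id)
  traces <- do.call(rbind, lapply(sim$traces, function(tr) {
    data.frame(animal_id = tr$animal_id, group = grp[[tr$animal_id]],
               time_min = tr$times, co2_ratio = tr$ratios,
               stringsAsFactors = FALSE)
  }))
  subs <- do.call(rbind, lapply(sim$substrates, function(s) {
    data.frame(animal_id = s$animal_id, time_min = s$times,
               enrichment = s$enrichments, stringsAsFactors = FALSE)
  }))
  paths <- c(traces = file.path(dir, "co2_traces.csv"),
             substrate = file.path(dir, "substrate_enrichment.csv"),
             truth = file.path(dir, "truth.csv"))
  write.csv(traces, paths[["traces"]], row.names = FALSE, quote = FALSE)
  write.csv(subs, paths[["substrate"]], row.names = FALSE, quote = FALSE)
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
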