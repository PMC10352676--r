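# Reproducible end-to-end pipeline:
# simulate (or load) -> validate -> fit A/Ci -> normalize to 25 degC ->
# allocate leaf N -> trait statistics. Every stage writes a CSV; identical
# config + seed gives byte-identical outputs.

#' Pipeline run configuration
#'
#' @param output_dir Directory for stage CSVs (created if absent).
#' @param seed Master seed for every stochastic stage.
#' @param input `"synthetic"` (default) to generate the season, or `"csv"`
#'   to load `curves_csv` / `traits_csv`.
#' @param curves_csv,traits_csv Paths to input CSVs when `input = "csv"`
#'   (schemas as written by the synthetic stage).
#' @param design,trait_cfg Season design and trajectory configuration for
#'   the synthetic stage; the configuration's own seed is overridden by
#'   `seed`.
#' @param noise_sd Gaussian noise on simulated A, umol m^-2 s^-1.
#' @param protocol Ca setpoint sequence for simulated curves.
#' @param ci_ca_ratio Ci/Ca operating ratio for simulated curves.
#' @param fit_options [aci_fit_options()] for the fitting stage.
#' @param a_sat_mode `"first"` or `"mean"`, see [a_sat_from_curve()].
#' @param rf_trees Trees for the importance stage.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(output_dir, seed = 1L, input = c("synthetic", "csv"),
                       curves_csv = NULL, traits_csv = NULL,
                       design = build_default_design(),
                       trait_cfg = trait_config(),
                       noise_sd = 0.3, protocol = default_protocol(),
                       ci_ca_ratio = 0.7,
                       fit_options = aci_fit_options(),
                       a_sat_mode = "first", rf_trees = 500) {
  input <- match.arg(input)
  if (input == "csv" && (is.null(curves_csv) || is.null(traits_csv))) {
    stop("`curves_csv` and `traits_csv` are required when input = \"csv\"",
         call. = FALSE)
  }
  trait_cfg$rng_seed <- as.integer(seed)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 input = input, curves_csv = curves_csv,
                 traits_csv = traits_csv, design = design,
                 trait_cfg = trait_cfg, noise_sd = noise_sd,
                 protocol = protocol, ci_ca_ratio = ci_ca_ratio,
                 fit_options = fit_options, a_sat_mode = a_sat_mode,
                 rf_trees = rf_trees),
            class = "run_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The file mirrors [run_config()] field-for-field; nested fields
#' `trait_cfg` (see [trait_config()]) and `fit_options` (see
#' [aci_fit_options()]) are passed through the respective constructors, and
#' `design` may be given as `{doys, sample_sizes}`.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$design)) {
    raw$design <- season_design(raw$design$doys, raw$design$sample_sizes)
  }
  if (!is.null(raw$trait_cfg)) raw$trait_cfg <- do.call(trait_config, raw$trait_cfg)
  if (!is.null(raw$fit_options)) raw$fit_options <- do.call(aci_fit_options, raw$fit_options)
  do.call(run_config, raw)
}

# CSV dialect: UTF-8, comma separator, '.' decimal, mandatory header,
# numerics at 6 significant digits for byte-stable reruns.
write_stage_csv <- function(df, path) {
  utils::write.csv(signif_df(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Check curve and trait tables against their invariants
#'
#' Report-only validation: nothing is mutated and violations never abort.
#' Curves are checked for point count (>= 5 per leaf), positive Ci and
#' in-range leaf temperature; traits for positivity, the Jmax25/Vcmax25
#' physiological band (1, 2.5), and — when `m_a_g_m2` and `n_mass_g_g` are
#' present — unit coherence of `n_area` with `m_a * n_mass`.
#'
#' @param curves Curve data frame (canonical columns), or `NULL`.
#' @param traits Leaf-trait data frame, or `NULL`.
#' @return Data frame with `record_id`, `rule`, `detail`; zero rows when
#'   everything passes.
#' @export
validate_inputs <- function(curves = NULL, traits = NULL) {
  bad <- list()
  note <- function(id, rule, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(record_id = id, rule = rule,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  if (!is.null(curves)) {
    for (id in unique(curves$leaf_id)) {
      cv <- curves[curves$leaf_id == id, ]
      if (nrow(cv) < 5) note(id, "curve_min_points",
                             sprintf("%d points < 5", nrow(cv)))
      if (any(cv$Ci_umol_mol <= 0)) note(id, "ci_positive",
                                         "non-positive Ci value")
      if ("Tleaf_K" %in% names(cv) &&
          any(cv$Tleaf_K < 273 | cv$Tleaf_K > 323)) {
        note(id, "tleaf_range", "leaf temperature outside [273, 323] K")
      }
    }
  }
  if (!is.null(traits)) {
    num_cols <- intersect(c("vcmax25", "jmax25", "rd25", "n_area_ug_cm2",
                            "chl_area_ug_cm2", "car_area_ug_cm2",
                            "sla_cm2_g", "m_a_g_m2", "n_mass_g_g"),
                          names(traits))
    for (i in seq_len(nrow(traits))) {
      id <- as.character(traits$leaf_id[i] %||% paste("row", i))
      vals <- unlist(traits[i, num_cols])
      if (any(!is.finite(vals) | vals <= 0)) {
        note(id, "trait_positive",
             paste("non-positive:", paste(num_cols[!is.finite(vals) | vals <= 0],
                                          collapse = ", ")))
      }
      if (all(c("vcmax25", "jmax25") %in% num_cols)) {
        ratio <- traits$jmax25[i] / traits$vcmax25[i]
        if (is.finite(ratio) && (ratio <= 1.0 || ratio >= 2.5)) {
          note(id, "jmax_vcmax_ratio",
               sprintf("Jmax25/Vcmax25 = %.2f outside (1.0, 2.5)", ratio))
        }
      }
      if (all(c("m_a_g_m2", "n_mass_g_g", "n_area_ug_cm2") %in% num_cols)) {
        expect <- 100 * traits$m_a_g_m2[i] * traits$n_mass_g_g[i]
        got <- traits$n_area_ug_cm2[i]
        if (abs(got - expect) > 1e-6 * max(abs(expect), 1)) {
          note(id, "n_area_unit_coherence",
               sprintf("n_area %.6g != m_a * n_mass = %.6g ug cm-2", got, expect))
        }
      }
    }
  }
  if (length(bad) == 0) {
    data.frame(record_id = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the six stages in order — simulate (or load), validate, fit A/Ci
#' curves, normalize capacities to 25 degC, allocate leaf nitrogen, trait
#' statistics — writing each stage's table as CSV into
#' `config$output_dir`. Identical config and seed reproduce byte-identical
#' files.
#'
#' @param config A [run_config()] object.
#' @return A `"run_manifest"`: per-stage record counts and warnings, the
#'   configuration echo and the package version.
#' @export
#' @examples
#' \donttest{
#' man <- run_pipeline(run_config(tempfile("run"), seed = 7))
#' man
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  warn <- character()
  mark <- function(name, n, note = NA_character_) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, n_records = n, note = note, stringsAsFactors = FALSE)
  }
  out <- function(name) file.path(config$output_dir, name)

  # -- stage 1: simulate or load ------------------------------------------
  if (config$input == "synthetic") {
    truth <- simulate_season(config$design, config$trait_cfg)
    curves <- simulate_curves(truth, protocol = config$protocol,
                              noise_sd = config$noise_sd, seed = config$seed,
                              ci_ca_ratio = config$ci_ca_ratio)
  } else {
    for (p in c(config$curves_csv, config$traits_csv)) {
      if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                                call. = FALSE)
    }
    curves <- utils::read.csv(config$curves_csv)
    truth <- utils::read.csv(config$traits_csv)
  }
  write_stage_csv(truth, out("truth.csv"))
  write_stage_csv(curves, out("curves.csv"))
  mark("simulate", nrow(truth),
       sprintf("%d leaves, %d curve points", nrow(truth), nrow(curves)))

  # -- stage 2: validate ---------------------------------------------------
  violations <- validate_inputs(curves, truth)
  write_stage_csv(violations, out("validation.csv"))
  if (nrow(violations) > 0) {
    warn <- c(warn, sprintf("%d input violation(s); see validation.csv",
                            nrow(violations)))
  }
  mark("validate", nrow(violations))

  # -- stage 3: fit A/Ci curves -------------------------------------------
  fits <- lapply(split(curves, curves$leaf_id), function(cv) {
    cv <- cv[order(cv$step_index), ]
    ft <- fit_aci(cv, options = config$fit_options)
    data.frame(leaf_id = ft$leaf_id, doy = ft$doy,
               vcmax = ft$vcmax, jmax = ft$jmax, rd = ft$rd,
               transition_ci = ft$transition_ci, rmse = ft$rmse,
               n_points_used = ft$n_points_used, converged = ft$converged,
               tleaf_k = ft$tleaf_k,
               a_sat = a_sat_from_curve(cv, mode = config$a_sat_mode),
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  fits <- fits[order(fits$doy, fits$leaf_id), ]
  rownames(fits) <- NULL
  if (any(!fits$converged)) {
    warn <- c(warn, sprintf("%d non-converged fit(s)", sum(!fits$converged)))
  }
  write_stage_csv(fits, out("fits.csv"))
  mark("fit_aci", nrow(fits))

  # -- stage 4: normalize to 25 degC --------------------------------------
  fits$vcmax25 <- normalize_to_25(fits$vcmax, fits$tleaf_k, arrhenius_preset("vcmax"))
  fits$jmax25 <- normalize_to_25(fits$jmax, fits$tleaf_k, arrhenius_preset("jmax"))
  write_stage_csv(fits, out("fits.csv"))
  mark("normalize", nrow(fits))

  # -- stage 5: allocate leaf nitrogen ------------------------------------
  trait_cols <- intersect(c("leaf_id", "n_area_ug_cm2", "chl_area_ug_cm2",
                            "car_area_ug_cm2", "sla_cm2_g", "m_a_g_m2",
                            "n_mass_g_g", "stage"), names(truth))
  samples <- merge(fits, truth[trait_cols], by = "leaf_id", sort = FALSE)
  samples <- samples[order(samples$doy, samples$leaf_id), ]
  alloc <- allocation_fractions(samples$vcmax25, samples$jmax25,
                                samples$chl_area_ug_cm2, samples$m_a_g_m2,
                                samples$n_mass_g_g, leaf_id = samples$leaf_id)
  samples <- cbind(samples, alloc)
  samples$chl_to_n <- samples$chl_area_ug_cm2 / samples$n_area_ug_cm2
  samples$n_area_g_m2 <- 0.01 * samples$n_area_ug_cm2
  rownames(samples) <- NULL
  write_stage_csv(samples, out("samples.csv"))
  mark("allocate", nrow(samples))

  # -- stage 6: trait statistics ------------------------------------------
  cors <- as_correlation_table(correlation_matrix(samples))
  write_stage_csv(cors, out("correlations.csv"))
  suite <- model_suite(samples)
  write_stage_csv(as_model_table(suite), out("models.csv"))
  imp <- tryCatch(
    rf_importance(samples, n_trees = config$rf_trees, seed = config$seed),
    error = function(e) {
      warn <<- c(warn, sprintf("importance stage skipped: %s", conditionMessage(e)))
      data.frame(predictor = character(), inc_mse_pct = numeric())
    })
  write_stage_csv(as.data.frame(imp), out("importance.csv"))
  doys <- sort(unique(samples$doy))
  peak_doy <- if (126 %in% doys) 126 else doys[which.max(tabulate(match(samples$doy, doys)))]
  seas <- seasonal_changes(samples,
                           traits = c("vcmax25", "jmax25", "a_sat",
                                      "n_area_ug_cm2", "chl_area_ug_cm2",
                                      "car_area_ug_cm2"),
                           doy_pair = c(min(doys), peak_doy))
  write_stage_csv(as.data.frame(seas), out("seasonal.csv"))
  mark("stats", nrow(cors) + nrow(suite$summary) + nrow(imp) + nrow(seas),
       sprintf("%d correlations, %d models, %d importances", nrow(cors),
               nrow(suite$summary), nrow(imp)))

  structure(list(stages = do.call(rbind, stages),
                 n_leaves = nrow(truth),
                 warnings = warn,
                 seed = config$seed,
                 output_dir = config$output_dir,
                 version = as.character(utils::packageVersion("photocap"))),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("photocap %s pipeline run (seed %d) -> %s\n",
              x$version, x$seed, x$output_dir))
  cat(sprintf("%d leaves; stages:\n", x$n_leaves))
  print(x$stages, row.names = FALSE)
  if (length(x$warnings) > 0) {
    cat("warnings:\n"); for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
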