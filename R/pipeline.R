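#' Run configuration
#'
#' Bundles the tunable constants of the pipeline. Values serialise
#' losslessly through YAML ([read_run_config()] / [write_run_config()]).
#'
#' @param temperature_K absolute temperature for thermodynamics (default 298).
#' @param hc_ev_nm wavelength/energy conversion constant.
#' @param ich_factors LOD and LOQ multipliers `c(3.3, 10)`.
#' @param rho_floor density floor for the RDG engine (a.u.).
#' @param popelier_range density window for the standard H-bond flag (a.u.).
#' @param seed integer RNG seed for simulation stages.
#' @param output_dir directory for result JSON files (`NULL`: do not write).
#' @return An object of class `ct_run_config` (a named list).
#' @export
run_config <- function(temperature_K = 298, hc_ev_nm = 1239.84,
                       ich_factors = c(3.3, 10), rho_floor = 1e-10,
                       popelier_range = c(0.002, 0.040), seed = 1L,
                       output_dir = NULL) {
  check_number(temperature_K, "temperature_K", positive = TRUE)
  check_number(rho_floor, "rho_floor", positive = TRUE)
  structure(list(temperature_K = temperature_K, hc_ev_nm = hc_ev_nm,
                 ich_factors = as.numeric(ich_factors),
                 rho_floor = rho_floor,
                 popelier_range = as.numeric(popelier_range),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "ct_run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `ct_run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "ct_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

input_digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) return(list())
  md5 <- tools::md5sum(unlist(paths))
  stats::setNames(as.list(unname(md5)), names(paths))
}

#' Run one analysis stage of the pipeline
#'
#' Dispatches to the stage functions and wraps the result with full
#' provenance: the exact configuration used and an MD5 digest of every
#' input file. When `config$output_dir` is set, the bundle is also written
#' as `<stage>_result.json`.
#'
#' Stages and their inputs:
#' \describe{
#'   \item{job}{`input`: Job CSV -> stoichiometry.}
#'   \item{titrate}{`input`: titration CSV -> molar-ratio breakpoint.}
#'   \item{bh}{`input`: titration CSV -> Benesi-Hildebrand fit + Gibbs energy.}
#'   \item{thermo}{`kc` (and `config$temperature_K`) -> Gibbs energy.}
#'   \item{validate}{`input`: calibration CSV (`conc_uM,absorbance`),
#'     optional `replicates` CSV (`taken_uM,found_uM,assay_day`).}
#'   \item{qtaim}{`input`: critical-point CSV -> classes, flags, counts.}
#'   \item{nci}{`input`: XYZ file -> RDG/signed-density cubes + scatter CSV
#'     (written next to `output_dir` using `out_prefix`).}
#'   \item{simulate}{writes a simulated titration and Job CSV from `spec`.}
#' }
#'
#' @param stage stage name.
#' @param input path to the stage's main input file (where applicable).
#' @param config a [run_config()].
#' @param kc association constant for the `thermo` stage.
#' @param replicates optional replicate CSV path for `validate`.
#' @param spec a [simulation_spec()] for `simulate`.
#' @param spacing_bohr,margin_A,rho_cut,out_prefix RDG engine parameters
#'   for `nci`.
#' @return A list with `stage`, `config`, `inputs` (digests), and `result`.
#' @export
run_pipeline <- function(stage, input = NULL, config = run_config(),
                         kc = NULL, replicates = NULL, spec = NULL,
                         spacing_bohr = 0.1, margin_A = 2.0, rho_cut = 0.05,
                         out_prefix = "nci") {
  stopifnot(inherits(config, "ct_run_config"))
  stages <- c("job", "titrate", "bh", "thermo", "validate", "qtaim", "nci",
              "simulate")
  if (!stage %in% stages)
    stop_input("unknown stage `%s`; expected one of %s", stage,
               paste(stages, collapse = ", "))
  inputs <- list(input = input, replicates = replicates)
  result <- switch(stage,
    job = {
      s <- read_job_csv(input)
      job_analysis(s)
    },
    titrate = {
      s <- read_titration_csv(input)
      molar_ratio_breakpoint(s$acceptor_conc_M / s$donor_conc_M,
                             s$absorbance)
    },
    bh = {
      s <- read_titration_csv(input)
      fit <- benesi_hildebrand_fit(s)
      th <- if (fit$kc_L_per_mol > 0)
        gibbs_free_energy(fit$kc_L_per_mol, config$temperature_K) else NULL
      c(unclass(fit),
        list(delta_g_kcal_per_mol = th$delta_g_kcal_per_mol,
             temperature_K = config$temperature_K))
    },
    thermo = {
      check_number(kc, "kc", positive = TRUE)
      unclass(gibbs_free_energy(kc, config$temperature_K))
    },
    validate = {
      df <- utils::read.csv(input, comment.char = "#")
      cal <- fit_calibration(df$conc_uM, df$absorbance)
      prec <- if (!is.null(replicates))
        precision_accuracy(utils::read.csv(replicates, comment.char = "#"))
      list(calibration = unclass(cal), precision = prec,
           report_md = validation_report_md(cal, prec))
    },
    qtaim = {
      cp <- read_cp_csv(input)
      cp <- check_virial_consistency(cp)
      counts <- if ("complex" %in% names(cp))
        lapply(split(cp, cp$complex), count_hbonds)
      list(table = cp, hbond_counts = counts)
    },
    nci = {
      geom <- read_xyz(input)
      field <- promolecular_field(geom, spacing_bohr = spacing_bohr,
                                  margin_A = margin_A)
      rf <- rdg_field(field, rho_floor = config$rho_floor)
      sc <- nci_scatter(rf, rho_cut = rho_cut)
      files <- NULL
      if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
        files <- file.path(config$output_dir,
                           paste0(out_prefix, c("-rdg.cube", "-signed-rho.cube",
                                                "-scatter.csv")))
        export_cube(rf$rdg, rf, files[1], comment = "reduced density gradient")
        export_cube(rf$signed_rho, rf, files[2],
                    comment = "sign(lambda2) * rho")
        export_scatter_csv(sc, files[3])
      }
      list(n_grid = prod(field$shape), n_scatter = nrow(sc),
           trough = nci_trough(sc), files = files)
    },
    simulate = {
      stopifnot(inherits(spec, "ct_sim_spec"))
      files <- NULL
      tit <- gen_titration(spec)
      job <- gen_job_series(spec)
      if (!is.null(config$output_dir)) {
        dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
        files <- file.path(config$output_dir,
                           c("titration_sim.csv", "job_sim.csv"))
        write_titration_csv(tit, files[1])
        write_job_csv(job, files[2])
      }
      list(titration = tit, job = job, files = files, seed = spec$seed)
    })
  bundle <- list(stage = stage, config = unclass(config),
                 inputs = input_digests(inputs), result = result)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(bundle,
                         file.path(config$output_dir,
                                   paste0(stage, "_result.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  bundle
}
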