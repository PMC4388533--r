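#' Read an age-rate table from CSV
#'
#' Expects a two-column CSV with header `age,rate`, one row per grid age,
#' ages strictly increasing and rates non-negative. Malformed rows are
#' reported with their line number (header = line 1).
#'
#' @param path path to the CSV file.
#' @return a [rate_schedule()].
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("rate table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(tab), c("age", "rate"))) {
    stop("expected header 'age,rate' in ", path)
  }
  tab$age <- suppressWarnings(as.numeric(tab$age))
  tab$rate <- suppressWarnings(as.numeric(tab$rate))
  line <- function(row) row + 1L  # header occupies line 1
  bad <- which(!is.finite(tab$age) | !is.finite(tab$rate))
  if (length(bad) > 0L) {
    stop(sprintf("malformed row in %s at line %d", path, line(bad[1L])))
  }
  bad <- which(tab$rate < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative rate in %s at line %d", path, line(bad[1L])))
  }
  bad <- which(diff(tab$age) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("ages not strictly increasing in %s at line %d", path,
                 line(bad[1L] + 1L)))
  }
  rate_schedule(tab$age, tab$rate)
}

#' Write an age-rate table to CSV
#'
#' Inverse of [read_rate_table()]; the written file reads back to an
#' identical schedule.
#'
#' @param schedule a [rate_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(schedule, path) {
  stopifnot(inherits(schedule, "rate_schedule"))
  utils::write.csv(data.frame(age = schedule$age, rate = schedule$rate),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Collects every knob of a full projection run: where the inputs come from
#' (the built-in synthetic study or external files), the intervention effect
#' distribution, cohort metadata, the numerical grid, and the uncertainty
#' settings. A configuration round-trips through YAML
#' ([read_run_config()] / [write_run_config()]) without change.
#'
#' @param input `"synthetic"` (default) or `"files"`.
#' @param synthetic named list of overrides passed to [synthetic_config()].
#' @param files for `input = "files"`: a named list with one entry per sex,
#'   each a list with `general_mortality` and `anchors` (CSV paths),
#'   `incidence_logparabola` (`c(c0, c1, c2)`) and
#'   `relative_mortality_logline` (`c(d0, d1)`). The anchors CSV needs
#'   columns `age,i,m1,p,m`. Referenced files must exist at load time.
#' @param anchor_noise_sd log-SD of observation noise added when generating
#'   synthetic anchors (default 0: the study's anchors are the exact planted
#'   values; the Monte-Carlo step adds its own sampling noise regardless).
#' @param anchor_seed seed for that observation noise.
#' @param K Monte-Carlo replicates for the uncertainty analysis (0 = point
#'   estimates only).
#' @param level confidence level for BCa intervals.
#' @param seed master seed of the uncertainty analysis.
#' @param grid_step,a_max numerical grid (years).
#' @param report_ages ages of the risk table rows.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input = c("synthetic", "files"),
                       synthetic = list(), files = NULL,
                       anchor_noise_sd = 0, anchor_seed = 1,
                       K = 0, level = 0.95, seed = 1,
                       grid_step = 0.05, a_max = 110,
                       report_ages = c(40, 50, 60, 70, 80, 90)) {
  input <- match.arg(input)
  stopifnot(grid_step > 0, a_max > 0, K >= 0, level > 0, level < 1,
            anchor_noise_sd >= 0)
  if (input == "files") {
    if (is.null(files)) stop("input = 'files' requires the 'files' list")
    for (s in names(files)) {
      for (f in c("general_mortality", "anchors")) {
        if (!file.exists(files[[s]][[f]])) {
          stop("configured input file does not exist: ", files[[s]][[f]])
        }
      }
      if (length(files[[s]]$incidence_logparabola) != 3L ||
          length(files[[s]]$relative_mortality_logline) != 2L) {
        stop("shape coefficients malformed for sex '", s, "'")
      }
    }
  }
  structure(list(input = input, synthetic = synthetic, files = files,
                 anchor_noise_sd = anchor_noise_sd, anchor_seed = anchor_seed,
                 K = K, level = level, seed = seed,
                 grid_step = grid_step, a_max = a_max,
                 report_ages = report_ages),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$report_ages <- as.numeric(raw$report_ages)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialise the study inputs a run_config describes.
load_study <- function(config) {
  if (config$input == "synthetic") {
    scfg <- do.call(synthetic_config,
                    utils::modifyList(list(a_max = config$a_max,
                                           grid_step = config$grid_step),
                                      config$synthetic))
    return(synthetic_study(scfg, noise_sd = config$anchor_noise_sd,
                           seed = config$anchor_seed))
  }
  scfg <- do.call(synthetic_config,
                  utils::modifyList(list(a_max = config$a_max,
                                         grid_step = config$grid_step),
                                    config$synthetic))
  sexes <- lapply(config$files, function(ff) {
    ic <- as.numeric(ff$incidence_logparabola)
    rc <- as.numeric(ff$relative_mortality_logline)
    anch <- utils::read.csv(ff$anchors, stringsAsFactors = FALSE)
    need <- c("age", "i", "m1", "p", "m")
    if (!all(need %in% names(anch))) {
      stop("anchors file ", ff$anchors, " must have columns ",
           paste(need, collapse = ","))
    }
    list(reference = list(incidence = log_parabola(ic[1L], ic[2L], ic[3L]),
                          relative_mortality = log_line(rc[1L], rc[2L])),
         general_mortality = read_rate_table(ff$general_mortality),
         anchors = anch[, need])
  })
  structure(list(config = scfg, sexes = sexes), class = "synthetic_study")
}

#' Run the full projection
#'
#' End-to-end orchestration for both sexes: load (or generate) the study
#' inputs, calibrate the parametric rate shapes to the anchor observations,
#' solve the prevalence equation for the business-as-usual and intervention
#' scenarios, tabulate lifetime risks and the absolute risk reduction at the
#' report ages, and compute prevented cases and the disease-free life
#' expectancy gain. With `K > 0`, input uncertainty is propagated by
#' Monte-Carlo resampling and every scalar outcome receives a BCa confidence
#' interval.
#'
#' @param config a [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return An object of class `"analysis_bundle"`: `risk_table` (per sex and
#'   report age, proportions), `scalars` (long data.frame of the scalar
#'   outcomes), `intervals` (if `K > 0`), `contrasts` (the per-sex
#'   [scenario_contrast()] objects), and a `manifest` recording seed, K, the
#'   configuration hash and the package version.
#' @export
run_full_analysis <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  study <- load_study(config)

  contrasts <- lapply(names(study$sexes), function(s) {
    contrast_from_anchors(study, s, study$sexes[[s]]$anchors,
                          study$config$h_mean, config$report_ages,
                          config$grid_step, config$a_max)
  })
  names(contrasts) <- names(study$sexes)

  risk_table <- do.call(rbind, lapply(contrasts, function(os) os$risk_table))
  rownames(risk_table) <- NULL
  scalars <- do.call(rbind, lapply(names(contrasts), function(s) {
    cbind(sex = s, outcome_scalars(contrasts[[s]], config$report_ages))
  }))

  intervals <- NULL
  if (config$K > 0) {
    dist <- run_resampling(study, K = config$K, seed = config$seed,
                           report_ages = config$report_ages,
                           grid_step = config$grid_step,
                           a_max = config$a_max)
    intervals <- summarize_uncertainty(dist, level = config$level)
  }

  manifest <- list(seed = config$seed, K = config$K,
                   level = config$level,
                   grid_step = config$grid_step, a_max = config$a_max,
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("illnessdeath")))

  structure(list(risk_table = risk_table, scalars = scalars,
                 intervals = intervals, contrasts = contrasts,
                 manifest = manifest, config = config),
            class = "analysis_bundle")
}

# Deterministic fingerprint of a configuration (md5 of its deparsed form).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("projection results\n==================\n")
  for (os in x$contrasts) print(os)
  if (!is.null(x$intervals)) {
    cat(sprintf("\n%g%% BCa intervals from K = %d replicates (seed %s)\n",
                100 * x$manifest$level, x$manifest$K, format(x$manifest$seed)))
    key <- c("prevented_fraction", "delta_disease_free", "relative_gain")
    print(x$intervals[x$intervals$outcome %in% key, ], row.names = FALSE)
  }
  invisible(x)
}

#' Plot the absolute risk reduction against age
#'
#' Simple base-graphics display of the ARR curves of an
#' [run_full_analysis()] bundle, one line per sex.
#'
#' @param x an `analysis_bundle`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.analysis_bundle <- function(x, ...) {
  cols <- c(male = "steelblue4", female = "firebrick3")
  arr <- lapply(x$contrasts, function(os) os$arr)
  ylim <- c(0, max(vapply(arr, function(a) max(a$risk), numeric(1))) * 105)
  graphics::plot(NULL, xlim = range(arr[[1L]]$age), ylim = ylim,
                 xlab = "age (years)", ylab = "absolute risk reduction (%)",
                 ...)
  for (s in names(arr)) {
    graphics::lines(arr[[s]]$age, 100 * arr[[s]]$risk,
                    col = cols[[s]], lwd = 2)
  }
  graphics::legend("topleft", legend = names(arr), col = cols[names(arr)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Writes `risk_table.csv` (risks and ARR per sex and age, as proportions),
#' `scalars.json` (full-precision scalar outcomes), `intervals.json` (when
#' an uncertainty analysis was run) and `manifest.json` to `dir`. Output is
#' deterministic: rerunning with the same configuration and seed reproduces
#' the files byte for byte.
#'
#' @param bundle an [run_full_analysis()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$risk_table, file.path(dir, "risk_table.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$scalars, file.path(dir, "scalars.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  if (!is.null(bundle$intervals)) {
    jsonlite::write_json(bundle$intervals, file.path(dir, "intervals.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @keywords internal
"_PACKAGE"

#' @useDynLib illnessdeath, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
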