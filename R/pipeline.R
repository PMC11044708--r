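#' Pipeline run configuration
#'
#' Collects every knob of the simulate -> classify -> summarize -> validate
#' chain. Either `scenario` (a [scenario_config()], simulated input) or
#' `accel_path` (a logger CSV on disk) must be given; a video ethogram
#' enables the agreement stage.
#'
#' @param out_dir run directory for artifact files.
#' @param scenario optional [scenario_config()] to simulate input from.
#' @param accel_path optional logger CSV path (used when no scenario).
#' @param ethogram_path optional video ethogram CSV path.
#' @param parturition_time POSIXct; required for summaries when no
#'   scenario is given.
#' @param critical_value,window,smooth,align classifier parameters, see
#'   [classify_samples()].
#' @param gap_tolerance seconds, see [read_accel_csv()].
#' @param sensor sensor model used to render simulated traces.
#' @param icc_form `"agreement"` or `"consistency"`.
#' @param adjacency_tolerance seconds, see [merge_transitional_sitting()].
#' @param seed integer master seed for the stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, scenario = NULL, accel_path = NULL,
                       ethogram_path = NULL, parturition_time = NULL,
                       critical_value = 0.75, window = 32,
                       smooth = "signal", align = "center",
                       gap_tolerance = 5, sensor = sensor_model(),
                       icc_form = "agreement", adjacency_tolerance = 1,
                       seed = 1L) {
  if (is.null(scenario) && is.null(accel_path)) {
    stop("run_config needs either a scenario or an accel_path", call. = FALSE)
  }
  structure(list(out_dir = out_dir, scenario = scenario,
                 accel_path = accel_path, ethogram_path = ethogram_path,
                 parturition_time = parturition_time,
                 critical_value = critical_value, window = window,
                 smooth = smooth, align = align,
                 gap_tolerance = gap_tolerance, sensor = sensor,
                 icc_form = icc_form,
                 adjacency_tolerance = adjacency_tolerance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when a scenario is configured) -> classify ->
#' extract bouts -> quarter-day summaries -> (when a video ethogram is
#' available) sitting-merge and ICC validation, writing every artifact
#' plus a machine-readable run manifest into the run directory. Identical
#' configuration and seed reproduce bit-identical artifacts.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  path <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- config$seed
    sim <- simulate_ethogram(sc)
    trace <- render_accel(sim$ethogram, config$sensor,
                          seed = config$seed + 1L)
    eth <- sim$ethogram
    parturition_time <- sc$parturition_time
    animal <- sc$animal_id
    write_ethogram(eth, art$ethogram <- path("ethogram.csv"))
    write_bouts(sim$truth, art$truth <- path("truth_bouts.csv"))
    write_accel_csv(trace, art$accel <- path("accel.csv"))
  } else {
    trace <- read_accel_csv(config$accel_path,
                            gap_tolerance = config$gap_tolerance)
    eth <- if (!is.null(config$ethogram_path))
      read_ethogram_csv(config$ethogram_path) else NULL
    parturition_time <- config$parturition_time
    animal <- trace$animal_id
  }
  if (is.null(parturition_time) || is.na(parturition_time)) {
    stop(sprintf("stage summarize: missing parturition_time for animal %s",
                 animal), call. = FALSE)
  }

  series <- classify_samples(trace, critical_value = config$critical_value,
                             window = config$window, smooth = config$smooth,
                             align = config$align)
  bouts <- extract_bouts(series)
  write_bouts(bouts, art$bouts <- path("bouts.csv"))

  coverage <- trace_coverage(trace)
  summaries <- summarize_quarters(bouts, coverage,
                                  meta = list(animal_id = animal,
                                              parturition_time = parturition_time))
  write_summaries(summaries, art$summaries <- path("quarters.csv"))

  icc <- NULL
  if (!is.null(eth)) {
    raw <- ethogram_bouts(eth)
    merged <- merge_transitional_sitting(eth, config$adjacency_tolerance)
    win0 <- as.numeric(eth$window[1])
    n_days <- max(1, floor((as.numeric(eth$window[2]) - win0) / 86400))
    windows <- data.frame(
      subject_id = paste0(animal, "_d", seq_len(n_days)),
      start = as.POSIXct(win0 + (seq_len(n_days) - 1) * 86400,
                         origin = "1970-01-01", tz = .tz),
      stop = as.POSIXct(win0 + seq_len(n_days) * 86400,
                        origin = "1970-01-01", tz = .tz))
    icc <- lapply(c(bout_count = "bout_count", lying_seconds = "lying_seconds"),
                  function(me) {
      lapply(list(raw = raw, merged = merged), function(vb) {
        r <- tryCatch(icc_agreement(build_ratings(vb, bouts, windows,
                                                  measure = me,
                                                  sensor_coverage = coverage),
                                    form = config$icc_form),
                      sowlying_degenerate = function(e) NULL,
                      error = function(e) NULL)
        if (is.null(r)) NULL
        else r[c("estimate", "ci_low", "ci_high", "n", "k", "form")]
      })
    })
    jsonlite::write_json(icc, art$icc <- path("icc.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  manifest <- list(
    package = "sowlying",
    package_version = as.character(utils::packageVersion("sowlying")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(critical_value = config$critical_value,
                      window = config$window, smooth = config$smooth,
                      align = config$align,
                      gap_tolerance = config$gap_tolerance,
                      icc_form = config$icc_form,
                      adjacency_tolerance = config$adjacency_tolerance,
                      quarter_hours = c(0, 6, 12, 18)),
    scenario = if (!is.null(config$scenario))
      list(housing = config$scenario$housing,
           days = range(config$scenario$days),
           sitting = config$scenario$sitting,
           min_episode_s = config$scenario$min_episode_s),
    inputs = if (is.null(config$scenario))
      lapply(Filter(Negate(is.null),
                    list(accel = config$accel_path,
                         ethogram = config$ethogram_path)),
             function(p) unname(tools::md5sum(p))),
    artifacts = lapply(art, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  art$manifest <- path("manifest.json")

  invisible(list(paths = art, bouts = bouts, summaries = summaries,
                 icc = icc, trace = trace, ethogram = eth))
}
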