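#' Load a versioned simulation preset
#'
#' Presets are YAML configuration files shipped under
#' `inst/extdata/presets`; they pin the generator parameterisations of the
#' study conditions (`"baseline-marmoset"`, `"mptp-acute"`,
#' `"mptp-hyperactive"`, `"ldopa-day"`, `"vehicle-day"`), so analyses and
#' tests reference configurations rather than code constants.
#'
#' @param name preset name, or a path to a preset YAML file.
#' @return a list with elements `name`, `activity`
#'   ([activity_sim_config()]), `effect` ([mptp_effect_config()] or
#'   `NULL`) and `dose` ([dose_sim_config()] or `NULL`).
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "marmact")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown preset: ", name, " (available: ",
         paste(available_presets(), collapse = ", "), ")", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  list(name = if (!is.null(raw$name)) raw$name else name,
       activity = do.call(activity_sim_config,
                          if (is.null(raw$activity)) list() else raw$activity),
       effect = if (!is.null(raw$effect)) {
         do.call(mptp_effect_config, raw$effect)
       },
       dose = if (!is.null(raw$dose)) do.call(dose_sim_config, raw$dose))
}

#' @rdname load_preset
#' @export
available_presets <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("extdata", "presets", package = "marmact"),
                 pattern = "\\.yaml$"))
}

#' Simulate a record from a named preset
#'
#' @param name preset name (see [load_preset()]).
#' @param seed integer seed.
#' @param n_days optional override of the preset's number of days.
#' @return an [epoch_series()]; dose presets return a single dose day with
#'   `meta$dose_time` set.
#' @export
simulate_preset <- function(name, seed = 1L, n_days = NULL) {
  p <- load_preset(name)
  if (!is.null(n_days)) p$activity$n_days <- as.integer(n_days)
  if (!is.null(p$dose)) {
    simulate_dose_day(p$activity, p$dose, p$effect, seed = seed,
                      subject_id = p$name)
  } else {
    simulate_activity(p$activity, p$effect, seed = seed, subject_id = p$name)
  }
}
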