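#' Default pipeline configuration
#'
#' Every tunable named by the pipeline modules, with its default.  User
#' files ([load_config()]) may override any key; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @return Nested named list of defaults (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    deer = list(
      r_min = 1.5, r_max = 8.0, r_step = 0.05,   # nm
      bg_dimension = 3,
      fit_start = 1 / 3,
      allow_unphysical = TRUE,
      alpha = NULL,                               # NULL = L-curve selection
      alpha_grid = list(log10_min = -3, log10_max = 1.5, n = 12),
      n_spins = 5),
    validation = list(
      n_steps = 16, start_lo = 0.05, start_hi = 0.80,
      trials_per_step = 50, noise_scale = 0.5, rmsd_cut = 1.15,
      noise_reference = "noise_sd"),              # vs "signal" (not default)
    eseem = list(
      zero_fill_factor = 2, detrend = FALSE,
      phase_band = c(0.5, 8), noise_band = c(3.5, 8),
      error_domain = "frequency"),                # vs "time"
    label = list(
      n_samples = 2000, tether_min = 0.4, tether_max = 1.0,
      vdw = "tight"),
    sim = list(
      n_subunits = 5, ring_radius = 2.5, width_sd = 0.1,   # nm
      mod_depth = 0.3, bg_rate = 0.05, noise_sd = 0.01,
      t_max = 2.5, dt = 0.01,                     # us
      eseem_k_2H = 0.3, eseem_k_1H = 0.2)),
    class = "run_config", user_set = character(0))
}

#' Load a configuration file
#'
#' Reads a YAML file of overrides and merges it into [default_config()].
#' Keys not present in the defaults are rejected.  The flattened names of
#' user-set keys are recorded in the `user_set` attribute (provenance:
#' default vs user).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file must contain a YAML mapping")
  merged <- merge_config(unclass(cfg), user, prefix = character(0))
  structure(merged$cfg, class = "run_config", user_set = merged$set)
}

merge_config <- function(base, user, prefix) {
  set <- character(0)
  for (key in names(user)) {
    path_name <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(base))
      stop("unknown configuration key: ", path_name)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", path_name, " must be a mapping")
      sub <- merge_config(base[[key]], user[[key]], c(prefix, key))
      base[[key]] <- sub$cfg
      set <- c(set, sub$set)
    } else {
      base[[key]] <- user[[key]]
      set <- c(set, path_name)
    }
  }
  list(cfg = base, set = set)
}

#' Write a configuration to YAML
#'
#' Round-trippable serialization of a `run_config`; reading the result
#' back with [load_config()] reproduces the values.
#'
#' @param cfg A `run_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(drop_nulls(unclass(cfg)), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, TRUE)]
  lapply(x, drop_nulls)
}

config_r_grid <- function(cfg) {
  seq(cfg$deer$r_min, cfg$deer$r_max, by = cfg$deer$r_step)
}

config_alpha_grid <- function(cfg) {
  g <- cfg$deer$alpha_grid
  10^seq(g$log10_min, g$log10_max, length.out = g$n)
}
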