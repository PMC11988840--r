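# Plain-text file formats: TSV payloads with JSON sidecars, YAML config.
# Angles are degrees and z is Angstrom on disk; decimal point, UTF-8.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else list()
}

#' Write / read a 1D diffractogram
#'
#' Three-column TSV (`two_theta_deg`, `counts`, `sigma_counts`) with a JSON
#' sidecar (`<path>.json`) holding the metadata (instrument, condition,
#' seed, warnings). Reading validates monotone 2-theta and nonnegative
#' counts, reporting the offending line on failure; a missing sigma column
#' is reconstructed as `sqrt(counts)` with a warning.
#'
#' @param diff A [diffractogram()].
#' @param path Output TSV path.
#' @return `write_diffractogram` returns `path` invisibly;
#'   `read_diffractogram` returns a [diffractogram()].
#' @export
write_diffractogram <- function(diff, path) {
  stopifnot(inherits(diff, "diffractogram"))
  tab <- data.frame(two_theta_deg = diff$two_theta, counts = diff$counts,
                    sigma_counts = diff$sigma)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_sidecar(path, diff$metadata)
  invisible(path)
}

#' @rdname write_diffractogram
#' @export
read_diffractogram <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("two_theta_deg", "counts")
  if (!all(need %in% names(tab))) {
    stop("expected columns two_theta_deg, counts in ", path)
  }
  bad <- which(tab$counts < 0)
  if (length(bad)) {
    stop(sprintf("negative counts at line %d of %s", bad[1L] + 1L, path))
  }
  bad <- which(diff(tab$two_theta_deg) <= 0)
  if (length(bad)) {
    stop(sprintf("two_theta_deg not strictly increasing at line %d of %s",
                 bad[1L] + 2L, path))
  }
  if (!"sigma_counts" %in% names(tab)) {
    warning("no sigma_counts column; using sqrt(counts)")
    tab$sigma_counts <- sqrt(pmax(tab$counts, 1))
  }
  diffractogram(tab$two_theta_deg, tab$counts, tab$sigma_counts,
                metadata = read_sidecar(path))
}

#' Write / read a reciprocal-space map
#'
#' TSV matrix: first column `omega_deg`, remaining columns one per 2-theta
#' bin (header holds the 2-theta values); JSON sidecar as for
#' diffractograms.
#'
#' @param map A [reciprocal_map()].
#' @param path Output TSV path.
#' @return `write_map` returns `path` invisibly; `read_map` a
#'   [reciprocal_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "reciprocal_map"))
  tab <- cbind(omega_deg = map$omega_axis, as.data.frame(map$intensity))
  names(tab)[-1L] <- formatC(map$two_theta_axis, format = "g", digits = 10)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(path, map$metadata)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1L] != "omega_deg") stop("expected first column omega_deg")
  two_theta <- as.numeric(names(tab)[-1L])
  if (anyNA(two_theta)) stop("2-theta header values are not numeric")
  reciprocal_map(tab$omega_deg, two_theta,
                 as.matrix(tab[, -1L, drop = FALSE]),
                 metadata = read_sidecar(path))
}

#' Write / read an NSLD profile
#'
#' Two-column TSV (`z_angstrom`, `rho`) plus a JSON sidecar carrying d,
#' order count, signs, contrast and flags.
#'
#' @param profile An [nsld_profile()].
#' @param path Output TSV path.
#' @return `write_profile` returns `path` invisibly; `read_profile` an
#'   [nsld_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nsld_profile"))
  utils::write.table(data.frame(z_angstrom = profile$z_grid,
                                rho = profile$rho),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(path, c(list(d_spacing = profile$d_spacing,
                             n_orders = profile$n_orders,
                             contrast_d2o = profile$contrast_d2o),
                        profile$metadata))
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.delim(path)
  meta <- read_sidecar(path)
  n <- length(tab$z_angstrom)
  d_fallback <- (max(tab$z_angstrom) - min(tab$z_angstrom)) * n / (n - 1L)
  nsld_profile(tab$z_angstrom, tab$rho,
               d_spacing = meta$d_spacing %||% d_fallback,
               n_orders = meta$n_orders %||% NA_integer_,
               contrast_d2o = meta$contrast_d2o %||% NA_real_,
               metadata = meta)
}

#' Write a metrics table
#'
#' TSV plus JSON twin, rows sorted by (label, temperature, relative
#' humidity).
#'
#' @param metrics Data frame from [analyze_condition_grid()] (or a single
#'   `metrics` row).
#' @param path Output TSV path (a `.json` twin is written alongside).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  metrics <- metrics[order(metrics$label, metrics$temperature,
                           metrics$relative_humidity), , drop = FALSE]
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(metrics, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' All tunable options of the pipeline with documented defaults; round
#' trips losslessly through YAML.
#'
#' @param instrument An [instrument_config()].
#' @param min_prominence Peak-detection prominence fraction.
#' @param max_orders Maximum Bragg orders retained.
#' @param d_b_window Polar-head window for the sign search.
#' @param n_grid Profile grid size.
#' @param seed Default RNG seed for stochastic operations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(instrument = instrument_config(),
                       min_prominence = 2e-4, max_orders = 8L,
                       d_b_window = c(0.5, 0.95), n_grid = 512L,
                       seed = 0L) {
  structure(list(instrument = unclass(instrument),
                 min_prominence = min_prominence,
                 max_orders = as.integer(max_orders),
                 d_b_window = as.numeric(d_b_window),
                 n_grid = as.integer(n_grid), seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [run_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  inst <- do.call(instrument_config, raw$instrument[
    setdiff(names(raw$instrument), character())])
  run_config(instrument = inst,
             min_prominence = raw$min_prominence %||% 2e-4,
             max_orders = raw$max_orders %||% 8L,
             d_b_window = raw$d_b_window %||% c(0.5, 0.95),
             n_grid = raw$n_grid %||% 512L,
             seed = raw$seed %||% 0L)
}

#' Serialize a membrane profile specification to / from YAML
#'
#' @param spec A [membrane_profile_spec()].
#' @param path YAML file path.
#' @return `write_profile_spec` returns `path` invisibly;
#'   `read_profile_spec` a [membrane_profile_spec()].
#' @export
write_profile_spec <- function(spec, path) {
  stopifnot(inherits(spec, "membrane_profile_spec"))
  yaml::write_yaml(list(
    period_d = spec$period_d, n_orders = spec$n_orders, label = spec$label,
    condition = unclass(spec$condition),
    components = lapply(spec$components, unclass)), path)
  invisible(path)
}

#' @rdname write_profile_spec
#' @export
read_profile_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  membrane_profile_spec(
    period_d = raw$period_d,
    components = lapply(raw$components, function(cmp) {
      gaussian_component(cmp$moiety, cmp$center_z, cmp$width_sigma,
                         cmp$amplitude)
    }),
    n_orders = raw$n_orders, label = raw$label,
    condition = sample_condition(raw$condition$temperature,
                                 raw$condition$relative_humidity,
                                 raw$condition$d2o_fraction))
}
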