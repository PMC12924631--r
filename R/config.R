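# Herd-level run configuration: construction, validation, JSON loading.

.config_defaults <- function() list(
  n_barns            = 5L,
  n_pigs_per_sex     = 10L,
  sexes              = c("gilt", "barrow", "boar"),
  run_days           = 140L,
  bw_initial_mean    = 20,
  bw_initial_sd      = 1.0,
  bw_final           = 130,
  me_content         = 3300,
  feed_wastage       = 0.05,
  fdm                = 0.88,
  temperature        = 20,
  noise_cv           = 0.05,
  me_adj             = 0,
  ractopamine_level  = 0,
  ractopamine_start_bw = 78,
  seed               = 42L,
  n_replications     = 500L,
  lipid_protein_ratio = 0.84,
  gut_fill_current_bw = FALSE,
  sttd_p_multiply    = FALSE,
  boar_fi_coeffs     = NULL,
  bwg_coeffs         = c(485.17, 8.8503, -0.0477),
  mixed_pens         = FALSE
)

.check_positive <- function(cfg, keys) {
  for (k in keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config key '", k, "' must be a single positive number, got ",
           deparse(v), call. = FALSE)
  }
}

#' Herd run configuration
#'
#' Builds and validates the full configuration of a simulation run:
#' herd structure, growth horizon, feed energy, thermal environment,
#' stochasticity and RNG settings. Every argument has the model's default;
#' pass only what you want to change.
#'
#' @param ... Configuration keys (lower_snake_case). Supported keys and
#'   defaults: `n_barns` (5), `n_pigs_per_sex` (10), `sexes`
#'   (gilt/barrow/boar), `run_days` (140 d), `bw_initial_mean` (20 kg),
#'   `bw_initial_sd` (1 kg), `bw_final` (130 kg), `me_content`
#'   (3300 kcal/kg feed), `feed_wastage` (0.05), `fdm` (0.88 dry-matter
#'   fraction), `temperature` (20 C), `noise_cv` (0.05, CV of daily gain),
#'   `me_adj` (0 kcal/d activity/genotype adjustment), `ractopamine_level`
#'   (0 mg/kg; inert hook), `ractopamine_start_bw` (78 kg; inert hook),
#'   `seed` (42), `n_replications` (500), `lipid_protein_ratio` (0.84
#'   initial BL:BP), `gut_fill_current_bw` (FALSE: gut fill frozen at the
#'   stocking weight), `sttd_p_multiply` (FALSE: the 0.77 in the STTD-P
#'   equation divides as a retention efficiency), `boar_fi_coeffs`
#'   (NULL: boars use energy-consistent intake), `bwg_coeffs` (published
#'   gain polynomial), `mixed_pens` (FALSE; bookkeeping only).
#'   Unknown keys are an error.
#' @return A validated list of class `herd_config`.
#' @examples
#' cfg <- herd_config(n_pigs_per_sex = 2, n_replications = 5)
#' @export
herd_config <- function(...) {
  supplied <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(supplied) && (is.null(names(supplied)) || any(names(supplied) == "")))
    stop("all config entries must be named", call. = FALSE)
  cfg <- utils::modifyList(defaults, supplied, keep.null = TRUE)

  .check_positive(cfg, c("n_barns", "n_pigs_per_sex", "run_days",
                         "bw_initial_mean", "bw_final", "me_content",
                         "fdm", "lipid_protein_ratio", "n_replications",
                         "ractopamine_start_bw"))
  for (k in c("n_barns", "n_pigs_per_sex", "run_days", "n_replications",
              "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  if (!is.numeric(cfg$temperature) || !is.finite(cfg$temperature))
    stop("config key 'temperature' must be a finite number", call. = FALSE)
  if (cfg$temperature < -273.15)
    stop("config key 'temperature' is below absolute zero", call. = FALSE)
  if (cfg$feed_wastage < 0 || cfg$feed_wastage >= 1)
    stop("config key 'feed_wastage' must lie in [0, 1)", call. = FALSE)
  if (cfg$fdm > 1)
    stop("config key 'fdm' must lie in (0, 1]", call. = FALSE)
  if (cfg$bw_initial_mean >= cfg$bw_final)
    stop("config key 'bw_initial_mean' must be below 'bw_final'",
         call. = FALSE)
  if (cfg$bw_initial_sd < 0)
    stop("config key 'bw_initial_sd' must be >= 0", call. = FALSE)
  if (cfg$noise_cv < 0)
    stop("config key 'noise_cv' must be >= 0", call. = FALSE)
  if (cfg$me_adj < 0 && is.finite(cfg$me_adj)) {
    # negative genotype adjustments are allowed; only non-finite is rejected
  }
  if (!is.finite(cfg$me_adj))
    stop("config key 'me_adj' must be finite", call. = FALSE)
  if (cfg$ractopamine_level < 0)
    stop("config key 'ractopamine_level' must be >= 0", call. = FALSE)
  cfg$sexes <- match.arg(cfg$sexes, list_sexes(), several.ok = TRUE)
  if (anyDuplicated(cfg$sexes))
    stop("config key 'sexes' contains duplicates", call. = FALSE)
  if (!is.null(cfg$boar_fi_coeffs) && length(cfg$boar_fi_coeffs) != 3)
    stop("config key 'boar_fi_coeffs' must have 3 elements (x, y, z)",
         call. = FALSE)
  if (length(cfg$bwg_coeffs) != 3 || !is.numeric(cfg$bwg_coeffs))
    stop("config key 'bwg_coeffs' must be numeric of length 3",
         call. = FALSE)
  class(cfg) <- "herd_config"
  cfg
}

#' @export
print.herd_config <- function(x, ...) {
  cat("<herd_config>\n")
  cat(sprintf("  herd: %d pigs/sex x %s in %d barns, %d replications\n",
              x$n_pigs_per_sex, paste(x$sexes, collapse = "/"), x$n_barns,
              x$n_replications))
  cat(sprintf("  growth: %g -> %g kg over <= %d d, noise_cv = %g, seed = %d\n",
              x$bw_initial_mean, x$bw_final, x$run_days, x$noise_cv, x$seed))
  cat(sprintf("  feed: ME %g kcal/kg, wastage %g, FDM %g, T = %g C\n",
              x$me_content, x$feed_wastage, x$fdm, x$temperature))
  invisible(x)
}

#' Load a run configuration from a JSON file
#'
#' The file is a flat JSON object whose keys are [herd_config()] arguments;
#' absent keys take their defaults, unknown keys are an error (fail loud).
#'
#' @param path Path to the JSON file.
#' @return A validated `herd_config`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"temperature": 18, "n_replications": 10}', f)
#' load_config(f)$temperature
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(herd_config())
  raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (length(raw) == 0) return(herd_config())
  if (is.null(names(raw)) || any(names(raw) == ""))
    stop("config file must be a JSON object with named keys")
  do.call(herd_config, raw)
}
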