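# Replication statistics, the r^2 verification harness, and file output.

.as_records <- function(x) {
  if (inherits(x, "sns_run")) return(x$records)
  if (data.table::is.data.table(x)) return(x)
  if (is.data.frame(x)) return(data.table::as.data.table(x))
  stop("expected an sns_run or a records data.frame")
}

#' Per-day replication statistics
#'
#' Pools all pigs and replications and computes, per sex, variable and day:
#' the mean, the standard deviation, and the 95% confidence interval of the
#' mean (`mean +/- 1.96 * sd / sqrt(n)`, normal approximation; `n` counts
#' the pig-days contributing to that day). Days with a single observation
#' get `sd = 0` and a degenerate interval.
#'
#' @param x An `sns_run` or its records table.
#' @param variables Record columns to summarize.
#' @return A `data.table` with columns `sex`, `variable`, `day`, `n`,
#'   `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
summarize_replications <- function(x, variables = c("bwg", "bw", "pd", "ld",
                                                    "mei", "fi")) {
  records <- .as_records(x)
  if (nrow(records) == 0) stop("empty record set")
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars))
    stop("unknown record variable(s): ", paste(missing_vars, collapse = ", "))
  long <- data.table::melt(
    records[, c("sex", "day", variables), with = FALSE],
    id.vars = c("sex", "day"), variable.name = "variable",
    variable.factor = FALSE)
  value <- NULL # appease R CMD check
  out <- long[, {
    m <- mean(value)
    s <- if (.N > 1) stats::sd(value) else 0
    hw <- 1.96 * s / sqrt(.N)
    list(n = .N, mean = m, sd = s, ci_low = m - hw, ci_high = m + hw)
  }, by = c("sex", "variable", "day")]
  data.table::setorder(out, sex, variable, day)
  out[]
}

#' Linear-regression agreement between two series
#'
#' Ordinary least squares of the simulated series on the reference series;
#' the coefficient of determination is the squared Pearson correlation.
#'
#' @param sim Simulated values.
#' @param reference Reference values (same length, >= 3).
#' @return A list of class `sns_verification`: `r_squared`, `slope`,
#'   `intercept`, `n`.
#' @export
r_squared <- function(sim, reference) {
  stopifnot(length(sim) == length(reference))
  if (length(sim) < 3) stop("need at least 3 paired points")
  if (stats::var(sim) == 0 || stats::var(reference) == 0)
    stop("zero variance in one of the series; r^2 is undefined")
  fit <- stats::lm(sim ~ reference)
  structure(list(r_squared = stats::cor(sim, reference)^2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(sim)),
            class = "sns_verification")
}

#' @export
print.sns_verification <- function(x, ...) {
  cat(sprintf("<sns_verification> r^2 = %.4f, y = %.3f x + %.3f (n = %d)\n",
              x$r_squared, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Verify stochastic output against the deterministic reference
#'
#' For each sex and variable, pairs every simulated pig-day with the
#' deterministic reference trajectory value of the same day (pooling all
#' pigs, days and replications, as in the published scatter comparisons)
#' and fits the regression of simulation on reference.
#'
#' @param run An `sns_run`.
#' @param variables Record columns to verify.
#' @param reference Optional external reference: a data.frame with columns
#'   `sex`, `variable`, `day`, `value`. Defaults to the noise-free
#'   trajectory of the run's own configuration (the deterministic
#'   equations are the reference model's transcription).
#' @param min_day First day to include (day 0 is the stocking snapshot
#'   with zero gain and is excluded by default).
#' @param by_replication If `TRUE`, returns one row per replication
#'   instead of pooling.
#' @return A `data.table` with columns `sex`, `variable` (and
#'   `replication` if requested), `r_squared`, `slope`, `intercept`, `n`.
#' @export
verify_run <- function(run, variables = c("bwg", "bw", "pd", "ld", "mei",
                                          "fi"),
                       reference = NULL, min_day = 1L,
                       by_replication = FALSE) {
  stopifnot(inherits(run, "sns_run"))
  records <- run$records[run$records$day >= min_day]
  if (is.null(reference)) {
    reference <- data.table::rbindlist(lapply(run$config$sexes, function(s) {
      det <- deterministic_trajectory(run$config, s)
      data.table::melt(det[, c("sex", "day", variables), with = FALSE],
                       id.vars = c("sex", "day"), variable.name = "variable",
                       variable.factor = FALSE)
    }))
  } else {
    reference <- data.table::as.data.table(reference)
  }
  data.table::setnames(reference, "value", "ref")
  long <- data.table::melt(
    records[, c("sex", "replication", "day", variables), with = FALSE],
    id.vars = c("sex", "replication", "day"), variable.name = "variable",
    variable.factor = FALSE)
  paired <- merge(long, reference, by = c("sex", "variable", "day"))
  grp <- if (by_replication) c("sex", "variable", "replication")
         else c("sex", "variable")
  value <- ref <- NULL # appease R CMD check
  out <- paired[, {
    v <- r_squared(value, ref)
    list(r_squared = v$r_squared, slope = v$slope,
         intercept = v$intercept, n = v$n)
  }, by = grp]
  data.table::setorderv(out, grp)
  out[]
}

#' Day-130-style requirement snapshot
#'
#' Reduces the records of one day to the published report layout: mean
#' body weight, total SID lysine with its amino-acid expansion, STTD
#' phosphorus and total calcium per sex, followed by the mineral and
#' vitamin requirements evaluated at each sex's mean body weight.
#'
#' @param run An `sns_run`.
#' @param day Snapshot day (default 130).
#' @return A data.frame with columns `section`, `quantity`, `units`, and
#'   one column per sex present in the run.
#' @export
requirements_snapshot <- function(run, day = 130) {
  records <- .as_records(run)
  keep_row <- records[["day"]] == day
  snap <- records[which(keep_row), ]
  if (nrow(snap) == 0) stop("no records on day ", day)
  sexes <- intersect(list_sexes(), unique(snap$sex))
  ratios <- amino_acid_ratios()
  cols <- lapply(sexes, function(s) {
    r <- snap[which(snap[["sex"]] == s), ]
    bw <- mean(r$bw); lys <- mean(r$sid_lysine); sttd <- mean(r$sttd_p)
    micro <- micronutrient_requirements(bw)
    c(bw, lys, unname(expand_amino_acids(lys, ratios)), sttd,
      total_calcium(sttd), micro$value)
  })
  micro <- micronutrient_requirements(100) # template for names/units
  out <- data.frame(
    section = c("growth", "amino_acids", rep("amino_acids", length(ratios)),
                "phosphorus_calcium", "phosphorus_calcium", micro$class),
    quantity = c("bw", "sid_lysine", names(ratios), "sttd_p", "total_ca",
                 micro$nutrient),
    units = c("kg", "g/d", rep("g/d", length(ratios)), "g/d", "g/d",
              micro$units),
    stringsAsFactors = FALSE)
  for (i in seq_along(sexes)) out[[sexes[i]]] <- cols[[i]]
  out
}

#' Export a run to CSV/JSON files
#'
#' Writes `records.csv` (one row per pig-day, ordered by replication, pig,
#' day), `summary.csv` (replication statistics), `verification.csv`
#' (regression against the deterministic reference), a requirement
#' snapshot, and `run_meta.json` (config echo, seed, package version,
#' confidence-interval convention). Re-exporting the same run yields
#' byte-identical files.
#'
#' @param run An `sns_run`.
#' @param out_dir Output directory (created if absent).
#' @param snapshot_day Day for the requirement snapshot; `NULL` to skip.
#' @param write_records If `FALSE`, the (large) per-day record table is
#'   skipped.
#' @return Invisible character vector of the files written.
#' @export
export_results <- function(run, out_dir, snapshot_day = 130,
                           write_records = TRUE) {
  stopifnot(inherits(run, "sns_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if (write_records) {
    f <- file.path(out_dir, "records.csv")
    data.table::fwrite(run$records, f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "summary.csv")
  data.table::fwrite(summarize_replications(run), f)
  files <- c(files, f)
  f <- file.path(out_dir, "verification.csv")
  data.table::fwrite(verify_run(run), f)
  files <- c(files, f)
  if (!is.null(snapshot_day) && any(run$records$day == snapshot_day)) {
    f <- file.path(out_dir, sprintf("requirements_day%d.csv", snapshot_day))
    data.table::fwrite(requirements_snapshot(run, snapshot_day), f)
    files <- c(files, f)
  }
  meta <- list(
    package = "swinesim",
    version = as.character(utils::packageVersion("swinesim")),
    config = unclass(run$config),
    n_replications = run$n_replications,
    days_run = run$days_run,
    ci_convention = "mean +/- 1.96*sd/sqrt(n), n = pig-days pooled across replications")
  f <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Pen-space adequacy check
#'
#' Compares each barn-day's summed minimum space requirement against the
#' available barn area. The model publishes the threshold only; breaches
#' are flagged, not penalized.
#'
#' @param run An `sns_run`.
#' @param barn_area Usable area per barn, m2.
#' @return A `data.table` with columns `replication`, `barn`, `day`,
#'   `n_pigs`, `space_needed`, `crowded`.
#' @export
space_check <- function(run, barn_area) {
  stopifnot(barn_area > 0)
  records <- .as_records(run)
  bw <- NULL # appease R CMD check
  out <- records[, list(n_pigs = .N, space_needed = sum(min_space(bw))),
                 by = c("replication", "barn", "day")]
  out$crowded <- out$space_needed > barn_area
  data.table::setorder(out, replication, barn, day)
  out[]
}

#' Plot a mean trajectory with SD and CI bands
#'
#' Mirrors the published trajectory figures: mean line, a band of +/- one
#' standard deviation, and the 95% confidence band of the mean.
#'
#' @param summary_dt Output of [summarize_replications()].
#' @param variable,sex Which series to draw.
#' @param file Optional PNG path; if given the plot is written there.
#' @return Invisibly, the plotted subset.
#' @export
plot_trajectory <- function(summary_dt, variable = "bw", sex = "gilt",
                            file = NULL) {
  keep_row <- summary_dt[["variable"]] == variable & summary_dt[["sex"]] == sex
  d <- summary_dt[which(keep_row), ]
  if (nrow(d) == 0) stop("no rows for that sex/variable")
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ylim <- range(d$mean - d$sd, d$mean + d$sd)
  graphics::plot(d$day, d$mean, type = "n", xlab = "day on feed",
                 ylab = variable, main = paste(sex, variable), ylim = ylim)
  graphics::polygon(c(d$day, rev(d$day)), c(d$mean - d$sd, rev(d$mean + d$sd)),
                    col = "#cde8cd", border = NA)
  graphics::polygon(c(d$day, rev(d$day)), c(d$ci_low, rev(d$ci_high)),
                    col = "#f3c9c9", border = NA)
  graphics::lines(d$day, d$mean, col = "blue", lwd = 2)
  invisible(d)
}
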