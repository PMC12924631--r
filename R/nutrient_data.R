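# Published day-130 reference values and the log-linear micronutrient
# coefficients reconstructed from them.

.pkg_env <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "swinesim")
  if (!nzchar(path)) {
    # devtools::load_all() layout
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("cannot locate extdata file ", file)
  path
}

#' Published day-130 reference requirement estimates
#'
#' Day-130 body weight, SID lysine, amino-acid, STTD phosphorus and calcium
#' reference estimates for gilts, barrows and boars from the published
#' NRC-based reference run. Used by the verification tests and by the
#' acceptance report; they are *not* consumed by the simulator itself.
#'
#' @return A data.frame with columns `quantity`, `units`, `gilt`, `barrow`,
#'   `boar`.
#' @export
day130_reference <- function() {
  if (is.null(.pkg_env$day130)) {
    .pkg_env$day130 <- utils::read.csv(.extdata("day130_reference.csv"),
                                       stringsAsFactors = FALSE)
  }
  .pkg_env$day130
}

#' Published day-130 mineral and vitamin reference points
#'
#' Per-nutrient reference daily requirements at the three published day-130
#' body weights (one per sex). These three `(BW, value)` points per nutrient
#' are the calibration data from which [nutrient_coefficients()] fits the
#' log-linear requirement curves, the published coefficient table itself
#' being unavailable.
#'
#' @return A data.frame with columns `nutrient`, `class` (mineral/vitamin),
#'   `units`, `bw` (kg) and `value`, three rows per nutrient.
#' @export
micronutrient_points <- function() {
  if (is.null(.pkg_env$micropoints)) {
    wide <- utils::read.csv(.extdata("micronutrient_reference.csv"),
                            stringsAsFactors = FALSE)
    ref <- day130_reference()
    bw <- as.numeric(ref[ref$quantity == "bw", c("gilt", "barrow", "boar")])
    long <- do.call(rbind, lapply(c("gilt", "barrow", "boar"), function(s) {
      data.frame(nutrient = wide$nutrient, class = wide$class,
                 units = wide$units, sex = s,
                 bw = bw[match(s, c("gilt", "barrow", "boar"))],
                 value = wide[[s]], stringsAsFactors = FALSE)
    }))
    .pkg_env$micropoints <- long[order(long$nutrient), ]
  }
  .pkg_env$micropoints
}

#' Log-linear mineral and vitamin requirement coefficients
#'
#' Coefficients of `requirement = intercept + slope * ln(BW)` for every
#' mineral and vitamin, obtained by least squares
#' ([fit_loglinear_coefficients()]) on the three published reference points
#' per nutrient. Fitted once per session and cached.
#'
#' @param points Calibration points as returned by [micronutrient_points()].
#' @return A data.frame with columns `nutrient`, `class`, `units`,
#'   `intercept`, `slope`.
#' @export
nutrient_coefficients <- function(points = micronutrient_points()) {
  key <- "nutrient_coefs"
  if (!is.null(.pkg_env[[key]]) && missing(points)) return(.pkg_env[[key]])
  out <- do.call(rbind, lapply(split(points, points$nutrient), function(p) {
    cf <- fit_loglinear_coefficients(p$bw, p$value)
    data.frame(nutrient = p$nutrient[1], class = p$class[1],
               units = p$units[1],
               intercept = as.numeric(cf["intercept"]),
               slope = as.numeric(cf["slope"]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (missing(points)) .pkg_env[[key]] <- out
  out
}

#' Write the fitted nutrient coefficient table to CSV
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_nutrient_coefficients <- function(path) {
  utils::write.csv(nutrient_coefficients(), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
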