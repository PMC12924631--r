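# Sex-specific coefficient sets (2012 Swine NRC growing-finishing equations).
#
# pd:  protein deposition cubic, Pd(BW) = a * (b + c*BW + d*BW^2 + e*BW^3), g/d
# mei: metabolizable energy intake, MEI(BW) = a * (1 - exp(-exp(b) * BW^c)), kcal/d
# fi:  ad-libitum feed intake, FI(BW) = x * (1 - exp(-exp(y) * BW^z)), kg/d
#      (no published x/y/z exist for boars; see `feed_intake()` for the
#      energy-consistent fallback)
.sex_coefficients <- list(
  gilt = list(
    pd  = c(a = 137, b = 0.7066, c = 0.013289, d = -1.3120e-4, e = 2.8627e-7),
    mei = c(a = 10967, b = -3.803, c = 0.9072),
    fi  = c(x = 2.755, y = -4.755, z = 1.214)
  ),
  barrow = list(
    pd  = c(a = 133, b = 0.7078, c = 0.013764, d = -1.4211e-4, e = 3.2698e-7),
    mei = c(a = 10447, b = -4.283, c = 1.0843),
    fi  = c(x = 2.88, y = -5.921, z = 1.512)
  ),
  boar = list(
    pd  = c(a = 151, b = 0.6558, c = 0.012740, d = -1.0390e-4, e = 1.64001e-7),
    mei = c(a = 10638, b = -3.803, c = 0.9072),
    fi  = NULL
  )
)

# Body-weight-gain polynomial fitted to the NRC phased ad-libitum gain data;
# shared by all sexes unless overridden (only one polynomial is published).
.default_bwg_coeffs <- c(c0 = 485.17, c1 = 8.8503, c2 = -0.0477)

#' Sexes known to the model
#' @return Character vector `c("gilt", "barrow", "boar")`.
#' @export
list_sexes <- function() names(.sex_coefficients)

#' Sex-specific parameter set
#'
#' Bundles the published coefficients driving one sex's growth and intake
#' curves: the protein-deposition cubic, the saturating metabolizable-energy
#' and feed-intake curves, and the body-weight-gain polynomial. The maximum
#' of the Pd cubic over the growing-finishing range (`pd_max`, g/d) is
#' derived analytically at construction and cached; it enters the SID-lysine
#' efficiency denominator and the whole-body water allometry.
#'
#' @param sex One of `"gilt"`, `"barrow"`, `"boar"`.
#' @param bwg_coeffs Optional length-3 override `(c0, c1, c2)` of the BWG
#'   polynomial, g/d (the default is the published fit, identical for the
#'   three sexes).
#' @param fi_coeffs Optional length-3 override `(x, y, z)` of the feed-intake
#'   curve; mainly useful for boars, whose coefficients are unpublished and
#'   which otherwise fall back to energy-consistent intake.
#' @param bw_range Body-weight interval (kg) over which `pd_max` is sought.
#' @return An object of class `sex_params`: a list with elements `sex`,
#'   `pd`, `mei`, `fi` (possibly `NULL`), `bwg`, `pd_max` and
#'   `pd_max_bw` (the maximizing body weight, kg).
#' @examples
#' p <- sex_params("gilt")
#' p$pd_max # ~ 150 g/d near 64 kg
#' @export
sex_params <- function(sex = c("gilt", "barrow", "boar"),
                       bwg_coeffs = NULL, fi_coeffs = NULL,
                       bw_range = c(20, 130)) {
  sex <- match.arg(sex)
  base <- .sex_coefficients[[sex]]
  if (is.null(bwg_coeffs)) bwg_coeffs <- .default_bwg_coeffs
  stopifnot(length(bwg_coeffs) == 3, is.numeric(bwg_coeffs))
  names(bwg_coeffs) <- c("c0", "c1", "c2")
  fi <- base$fi
  if (!is.null(fi_coeffs)) {
    stopifnot(length(fi_coeffs) == 3, is.numeric(fi_coeffs))
    fi <- stats::setNames(as.numeric(fi_coeffs), c("x", "y", "z"))
  }
  if (base$mei[["a"]] <= 0) stop("mei_a must be positive")
  if (!is.null(fi) && fi[["x"]] <= 0) stop("fi_x must be positive")
  obj <- structure(
    list(sex = sex, pd = base$pd, mei = base$mei, fi = fi,
         bwg = bwg_coeffs),
    class = "sex_params"
  )
  pm <- compute_pd_max(obj, lower = bw_range[1], upper = bw_range[2])
  obj$pd_max <- as.numeric(pm)
  obj$pd_max_bw <- attr(pm, "bw_at_max")
  obj
}

#' @export
print.sex_params <- function(x, ...) {
  cat("<sex_params> ", x$sex, "\n", sep = "")
  cat("  Pd cubic   a=", x$pd[["a"]], " b=", x$pd[["b"]], " c=", x$pd[["c"]],
      " d=", x$pd[["d"]], " e=", x$pd[["e"]], "\n", sep = "")
  cat("  MEI curve  a=", x$mei[["a"]], " b=", x$mei[["b"]],
      " c=", x$mei[["c"]], "\n", sep = "")
  if (is.null(x$fi)) {
    cat("  FI curve   (none; energy-consistent fallback)\n")
  } else {
    cat("  FI curve   x=", x$fi[["x"]], " y=", x$fi[["y"]],
        " z=", x$fi[["z"]], "\n", sep = "")
  }
  cat(sprintf("  Pd max     %.2f g/d at %.2f kg\n", x$pd_max, x$pd_max_bw))
  invisible(x)
}

#' Maximum protein deposition over a body-weight interval
#'
#' Maximizes the sex-specific Pd cubic `a*(b + c*BW + d*BW^2 + e*BW^3)` on
#' a closed interval by solving the quadratic stationarity condition
#' `c + 2d*BW + 3e*BW^2 = 0` analytically and comparing interior roots with
#' the endpoints. The cubic is bounded on a closed interval, so a maximum
#' always exists.
#'
#' @param params A [sex_params()] object (only the `pd` coefficients are
#'   used).
#' @param lower,upper Interval bounds, kg.
#' @return Maximum Pd in g/d, with the maximizing body weight attached as
#'   attribute `"bw_at_max"`.
#' @export
compute_pd_max <- function(params, lower = 20, upper = 130) {
  k <- params$pd
  candidates <- c(lower, upper)
  # stationary points of b + c*x + d*x^2 + e*x^3
  e3 <- 3 * k[["e"]]; d2 <- 2 * k[["d"]]; c1 <- k[["c"]]
  if (e3 != 0) {
    disc <- d2^2 - 4 * e3 * c1
    if (disc >= 0) {
      r <- (-d2 + c(-1, 1) * sqrt(disc)) / (2 * e3)
      candidates <- c(candidates, r[r > lower & r < upper])
    }
  } else if (d2 != 0) {
    r <- -c1 / d2
    if (r > lower && r < upper) candidates <- c(candidates, r)
  }
  vals <- protein_deposition(candidates, params)
  i <- which.max(vals)
  structure(vals[i], bw_at_max = as.numeric(candidates[i]))
}

#' Fit the body-weight-gain polynomial
#'
#' Ordinary least squares of daily gain (g/d) on powers of body weight (kg),
#' used to condense phased reference gain data into a single smooth
#' polynomial suitable for daily Euler updates.
#'
#' @param bw Body weights, kg.
#' @param bwg Body-weight gains, g/d.
#' @param degree Polynomial degree (default 2).
#' @return Named coefficient vector `c0..c<degree>` (g/d, g/d per kg, ...).
#' @examples
#' bw <- seq(20, 110, length.out = 10)
#' fit_bwg_polynomial(bw, 485.17 + 8.8503 * bw - 0.0477 * bw^2)
#' @export
fit_bwg_polynomial <- function(bw, bwg, degree = 2) {
  stopifnot(length(bw) == length(bwg), is.numeric(bw), is.numeric(bwg))
  if (length(bw) < degree + 1)
    stop("need at least degree+1 = ", degree + 1, " points, got ", length(bw))
  X <- outer(bw, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1)
    stop("collinear body-weight values: polynomial design matrix is singular")
  coefs <- qr.coef(qrX, bwg)
  stats::setNames(as.numeric(coefs), paste0("c", 0:degree))
}

#' Fit log-linear nutrient coefficients
#'
#' Least squares of a requirement on `ln(BW)`, the functional form the model
#' uses for every mineral (`p + q*ln(BW)`) and vitamin (`m + n*ln(BW)`)
#' requirement.
#'
#' @param bw Body weights, kg (at least two distinct values).
#' @param value Requirement values in the nutrient's own units.
#' @return Named vector `c(intercept, slope)`.
#' @export
fit_loglinear_coefficients <- function(bw, value) {
  stopifnot(length(bw) == length(value), all(bw > 0))
  if (length(unique(bw)) < 2) {
    # degenerate but well-defined when all values agree: a constant fit
    if (length(unique(value)) == 1)
      return(c(intercept = value[1], slope = 0))
    stop("identical body weights: log-linear fit is singular")
  }
  x <- log(bw)
  sl <- stats::cov(x, value) / stats::var(x)
  ic <- mean(value) - sl * mean(x)
  c(intercept = ic, slope = sl)
}

#' Amino-acid requirements as ratios to SID lysine
#'
#' The essential amino acids (and nitrogen) are expressed as fixed
#' proportions of the total SID lysine requirement; these are the published
#' percentage ratios divided by 100.
#'
#' @return Named numeric vector of ratio-to-lysine fractions.
#' @export
amino_acid_ratios <- function() {
  c(arginine                 = 0.457,
    histidine                = 0.344,
    isoleucine               = 0.522,
    leucine                  = 1.007,
    methionine               = 0.289,
    methionine_cysteine      = 0.564,
    phenylalanine            = 0.597,
    phenylalanine_tyrosine   = 0.938,
    threonine                = 0.603,
    tryptophan               = 0.171,
    valine                   = 0.649,
    nitrogen                 = 2.148)
}
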