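#' Linear thickness-concentration calibration
#'
#' Ordinary least squares fit of film thickness (nm) against protein
#' concentration (uM): `thickness = intercept + slope * concentration`.
#' 95% confidence intervals come from the t distribution with `n - 2`
#' degrees of freedom. Nominal concentrations are used as given; stated
#' concentration uncertainties are carried along but not propagated
#' (errors-in-variables fitting is out of scope). The intercept is free by
#' default; set `through_origin = TRUE` to force it to zero.
#'
#' @param points data frame with numeric columns `concentration_uM` (> 0)
#'   and `thickness_nm` (>= 0); at least 3 rows and 2 distinct
#'   concentrations.
#' @param through_origin force a zero intercept.
#' @return An object of class `calibration_fit`: `slope`, `slope_ci_half`,
#'   `intercept`, `intercept_ci_half` (nm and nm/uM, 95% half-widths),
#'   `r_squared`, `n`, and the underlying `lm` model.
#' @examples
#' pts <- data.frame(concentration_uM = c(100, 200, 400, 800),
#'                   thickness_nm = c(5, 11, 21, 42))
#' fit_linear(pts)
#' @export
fit_linear <- function(points, through_origin = FALSE) {
  need <- c("concentration_uM", "thickness_nm")
  if (!all(need %in% names(points))) {
    stop("points must have columns concentration_uM and thickness_nm",
         call. = FALSE)
  }
  pts <- points[stats::complete.cases(points[, need]), ]
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 calibration points, got ", n, call. = FALSE)
  if (any(pts$concentration_uM <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (length(unique(pts$concentration_uM)) < 2L) {
    stop("singular design: all concentrations identical", call. = FALSE)
  }
  model <- if (through_origin) {
    lm(thickness_nm ~ 0 + concentration_uM, data = pts)
  } else {
    lm(thickness_nm ~ concentration_uM, data = pts)
  }
  ci <- suppressWarnings(confint(model, level = 0.95))
  co <- coef(model)
  slope <- unname(co["concentration_uM"])
  intercept <- if (through_origin) 0 else unname(co["(Intercept)"])
  slope_half <- unname((ci["concentration_uM", 2] - ci["concentration_uM", 1]) / 2)
  intercept_half <- if (through_origin) 0 else
    unname((ci["(Intercept)", 2] - ci["(Intercept)", 1]) / 2)
  structure(list(slope = slope,
                 slope_ci_half = slope_half,
                 intercept = intercept,
                 intercept_ci_half = intercept_half,
                 r_squared = suppressWarnings(summary(model)$r.squared),
                 n = n,
                 model = model,
                 through_origin = through_origin),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration: thickness = %.4g (+/- %.2g) + %.4g (+/- %.2g) x conc, R2 = %.4f, n = %d\n",
    x$intercept, x$intercept_ci_half, x$slope, x$slope_ci_half,
    x$r_squared, x$n))
  invisible(x)
}

#' Predict film thickness at a concentration
#'
#' Point prediction `intercept + slope * concentration` with the 95%
#' confidence band of the fitted mean.
#'
#' @param object a [fit_linear()] result.
#' @param concentration_uM concentrations in uM (> 0).
#' @param ... unused.
#' @return Data frame with `concentration_uM`, `thickness_nm`, `ci_lo`,
#'   `ci_hi`.
#' @export
predict.calibration_fit <- function(object, concentration_uM, ...) {
  stopifnot(all(concentration_uM > 0))
  nd <- data.frame(concentration_uM = concentration_uM)
  p <- suppressWarnings(predict(object$model, newdata = nd, interval = "confidence",
               level = 0.95))
  data.frame(concentration_uM = concentration_uM,
             thickness_nm = unname(p[, "fit"]),
             ci_lo = unname(p[, "lwr"]),
             ci_hi = unname(p[, "upr"]))
}

#' Plan the concentration needed for a target thickness
#'
#' Inverse prediction `(target - intercept) / slope`, with a first-order
#' (delta-method) 95% confidence half-width propagated from the slope and
#' intercept covariance.
#'
#' @param fit a [fit_linear()] result with nonzero slope.
#' @param target_thickness_nm desired film thickness in nm.
#' @return A list with `concentration_uM` and `ci_half_uM`.
#' @examples
#' pts <- data.frame(concentration_uM = c(5, 10, 20, 50),
#'                   thickness_nm = 3 * c(5, 10, 20, 50))
#' plan_concentration(fit_linear(pts), 30)
#' @export
plan_concentration <- function(fit, target_thickness_nm) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("slope is zero; target unreachable", call. = FALSE)
  conc <- (target_thickness_nm - fit$intercept) / fit$slope
  if (conc <= 0) {
    stop(sprintf(
      "infeasible target: %g nm is at or below the fitted intercept (%g nm)",
      target_thickness_nm, fit$intercept), call. = FALSE)
  }
  V <- suppressWarnings(vcov(fit$model))
  # c = (T - a)/b ; gradient wrt (a, b) = (-1/b, -(T - a)/b^2)
  g <- if (fit$through_origin) {
    matrix(-(target_thickness_nm) / fit$slope^2)
  } else {
    c(-1 / fit$slope, -(target_thickness_nm - fit$intercept) / fit$slope^2)
  }
  se <- sqrt(as.numeric(t(g) %*% V %*% g))
  tcrit <- qt(0.975, df = fit$model$df.residual)
  list(concentration_uM = conc, ci_half_uM = tcrit * se)
}

#' Built-in calibration and segmentation reference tables
#'
#' Loads the packaged reference tables used throughout the examples and
#' tests: `"table1"` — thickness of spin-coated 4-repeat protein films at
#' eight concentrations measured by microreflectance, ellipsometry and
#' AFM; `"table2"` — thickness-concentration slopes for 4-, 8- and
#' 16-repeat proteins prepared by spin-coating and drop-casting;
#' `"table3"` — areas, thicknesses and volumes of the three segmented
#' regions of a drop-cast film.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return A data frame (read-only transcription; values as printed,
#'   including stated uncertainties).
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_spin_ctpr4.csv",
    table2 = "table2_slopes.csv",
    table3 = "table3_segmentation.csv"
  )
  read.csv(.extdata(file), stringsAsFactors = FALSE)
}

#' Read and write calibration point tables
#'
#' CSV layout: `repeats, method, technique, concentration_uM, thickness_nm,
#' thickness_err_nm` (extra columns preserved).
#'
#' @param path CSV file path.
#' @return A data frame of calibration points.
#' @export
read_calibration_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration_uM", "thickness_nm") %in% names(d))) {
    stop("calibration CSV must have concentration_uM and thickness_nm columns",
         call. = FALSE)
  }
  d
}
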