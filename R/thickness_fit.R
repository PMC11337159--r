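#' Configuration for contrast-spectrum thickness fitting
#'
#' @param t_bounds thickness search bounds in nm, `0 <= t_lo < t_hi`.
#' @param step coarse-grid step in nm (> 0); 1 nm resolves every
#'   interference order in the visible for films below ~1 um.
#' @param window wavelength fit window in nm.
#' @param oxide_thickness fixed oxide thickness in nm (known from the
#'   wafer specification; it is not fitted).
#' @param materials stack materials, see [default_materials()].
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(t_bounds = c(0, 500), step = 1,
                       window = c(450, 750), oxide_thickness = 295,
                       materials = default_materials()) {
  stopifnot(length(t_bounds) == 2L, t_bounds[1] >= 0,
            t_bounds[1] < t_bounds[2], step > 0, length(window) == 2L,
            window[1] < window[2], oxide_thickness >= 0)
  structure(list(t_bounds = t_bounds, step = step, window = window,
                 oxide_thickness = oxide_thickness, materials = materials),
            class = "fit_config")
}

# Sum-of-squares objective factory: precomputes the bare-substrate
# reflectance (independent of film thickness) so each evaluation only
# propagates the film stack.
contrast_objective <- function(spectrum, config) {
  wl <- spectrum$wavelength
  c_meas <- spectrum$contrast
  m <- config$materials
  r_bare <- reflectance(film_stack(0, config$oxide_thickness, m), wl)
  function(t) {
    if (t <= 0) {
      c_mod <- rep(0, length(wl))
    } else {
      r_film <- reflectance(film_stack(t, config$oxide_thickness, m), wl)
      c_mod <- (r_film - r_bare) / (r_film + r_bare)
    }
    sum((c_mod - c_meas)^2)
  }
}

# Newton polish on the 1-D objective using central differences; tightens
# the minimiser well past optimize()'s golden-section tolerance.
newton_polish <- function(f, t, lo, hi, h = 1e-3, iters = 3L) {
  for (i in seq_len(iters)) {
    g <- (f(t + h) - f(t - h)) / (2 * h)
    H <- (f(t + h) - 2 * f(t) + f(t - h)) / h^2
    if (!is.finite(g) || !is.finite(H) || H <= 0) break
    t_new <- min(max(t - g / H, lo), hi)
    if (abs(t_new - t) < 1e-10) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Fit film thickness to a measured contrast spectrum
#'
#' Inverts an optical-contrast spectrum to film thickness by least squares
#' against the transfer-matrix model. Because contrast is periodic-like in
#' thickness (interference orders), the objective is multimodal: a coarse
#' grid scan over the thickness bounds locates every local minimum, each is
#' refined by bounded scalar minimisation plus a Newton polish, and the
#' global minimum is returned together with the ranked alternatives. The
#' thickness uncertainty is a curvature (inverse-Hessian) estimate scaled
#' by the residual variance.
#'
#' When the best and runner-up residuals differ by less than 1% the fit is
#' flagged `ambiguous` and the smaller thickness is preferred; a global
#' minimum sitting on a search boundary is flagged `boundary`.
#'
#' @param spectrum a [contrast_spectrum()]; at least 10 points must fall
#'   inside the fit window.
#' @param config a [fit_config()].
#' @return An object of class `thickness_fit`: list with `thickness_nm`,
#'   `uncertainty_nm`, `rms_residual`, `sse`, `n_points`, `alternatives`
#'   (data frame of refined local minima), `ambiguous`, `boundary`.
#' @examples
#' cs <- simulate_contrast(115)
#' fit <- fit_thickness(cs, fit_config(t_bounds = c(0, 300)))
#' fit$thickness_nm
#' @export
fit_thickness <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "contrast_spectrum"),
            inherits(config, "fit_config"))
  spectrum <- restrict(spectrum, config$window)
  n <- nrow(spectrum)
  if (n < 10L) {
    stop("need at least 10 spectral points in the fit window, got ", n,
         call. = FALSE)
  }
  f <- contrast_objective(spectrum, config)
  grid <- seq(config$t_bounds[1], config$t_bounds[2], by = config$step)
  if (grid[length(grid)] < config$t_bounds[2]) {
    grid <- c(grid, config$t_bounds[2])
  }
  obj <- vapply(grid, f, numeric(1))
  m <- length(grid)

  # local minima on the coarse grid (boundaries included as candidates)
  cand_idx <- which(
    (c(Inf, obj[-m]) >= obj) & (c(obj[-1], Inf) >= obj)
  )
  refined <- lapply(cand_idx, function(i) {
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, m)]
    if (i > 1L && i < m) {
      opt <- optimize(f, lower = lo, upper = hi, tol = 1e-8)
      t_hat <- newton_polish(f, opt$minimum, lo, hi)
    } else {
      opt <- optimize(f, lower = lo, upper = hi, tol = 1e-8)
      t_hat <- opt$minimum
      # keep an exact boundary solution if it beats the interior refinement
      t_bnd <- grid[i]
      if (f(t_bnd) <= f(t_hat)) t_hat <- t_bnd
    }
    c(thickness = t_hat, sse = f(t_hat), boundary = as.numeric(i == 1L || i == m))
  })
  alt <- as.data.frame(do.call(rbind, refined))
  alt <- alt[order(alt$sse, alt$thickness), , drop = FALSE]
  rownames(alt) <- NULL

  best <- alt[1, ]
  ambiguous <- FALSE
  if (nrow(alt) >= 2L) {
    # interference orders are indistinguishable when their RMS residuals
    # differ by less than a 1e-3 contrast-unit noise floor (well below any
    # realistic measurement noise) or by less than 1% of the best SSE
    rms_all <- sqrt(alt$sse / n)
    tied <- (rms_all - rms_all[1]) < 1e-3 |
      (alt$sse - alt$sse[1]) < 0.01 * alt$sse[1]
    if (sum(tied) > 1L) {
      ambiguous <- TRUE
      near <- alt[tied, ]
      best <- near[which.min(near$thickness), ]
    }
  }
  t_hat <- best$thickness
  sse <- best$sse
  boundary <- best$boundary == 1

  # curvature-based uncertainty: Var(t) = 2 s^2 / (d2 SSE / dt2)
  h <- max(config$step / 10, 1e-2)
  H <- (f(min(t_hat + h, config$t_bounds[2] + h)) - 2 * f(t_hat) +
          f(max(t_hat - h, 0))) / h^2
  s2 <- sse / max(n - 1L, 1L)
  unc <- if (is.finite(H) && H > 0) sqrt(2 * s2 / H) else NA_real_

  structure(list(
    thickness_nm = t_hat,
    uncertainty_nm = unc,
    rms_residual = sqrt(sse / n),
    sse = sse,
    n_points = n,
    alternatives = alt,
    ambiguous = ambiguous,
    boundary = boundary
  ), class = "thickness_fit")
}

#' @export
print.thickness_fit <- function(x, ...) {
  cat(sprintf("Film thickness: %.2f nm (+/- %.2f nm), RMS residual %.3g (n = %d)\n",
              x$thickness_nm,
              ifelse(is.na(x$uncertainty_nm), NaN, x$uncertainty_nm),
              x$rms_residual, x$n_points))
  if (x$ambiguous) cat("  note: near-degenerate interference orders; smallest thickness reported\n")
  if (x$boundary) cat("  note: solution on a search boundary\n")
  invisible(x)
}

#' Thickness-residual profile of a contrast spectrum
#'
#' Evaluates the least-squares objective on the coarse thickness grid,
#' exposing the interference-order degeneracy that makes the fit
#' multimodal. Useful for plotting and for choosing sensible bounds.
#'
#' @inheritParams fit_thickness
#' @return A data frame with columns `thickness_nm` and `sse`.
#' @export
residual_profile <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "contrast_spectrum"),
            inherits(config, "fit_config"))
  spectrum <- restrict(spectrum, config$window)
  if (nrow(spectrum) < 1L) stop("no points in window", call. = FALSE)
  f <- contrast_objective(spectrum, config)
  grid <- seq(config$t_bounds[1], config$t_bounds[2], by = config$step)
  data.frame(thickness_nm = grid, sse = vapply(grid, f, numeric(1)))
}
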