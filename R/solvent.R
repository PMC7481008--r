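# Finite-size-aware solvent observables: MSD diffusion with the Yeh-Hummer
# hydrodynamic correction, bulk-water extrapolation for protein boxes, and
# radial distribution functions with spherical / excluded-volume
# normalization.

# cubic-lattice self-interaction constant of the hydrodynamic correction
.xi_cubic <- 2.837297

#' Diffusion coefficient from mean squared displacement
#'
#' Ensemble- and time-origin-averaged MSD of unwrapped particle
#' trajectories, with D from the least-squares slope of MSD = 6 D t over
#' the fit window (3-D). The trajectory is additionally split into
#' contiguous chunks and D re-estimated per chunk; the chunk spread is the
#' uncertainty measure. Wrapped input is refused: if any single-step
#' displacement exceeds half the box edge the coordinates were almost
#' certainly wrapped, and unwrapping heuristics are deliberately not
#' applied.
#'
#' @param positions Tibble with columns `frame`, `particle` and unwrapped
#'   coordinates `xu`, `yu`, `zu` (as produced by [gen_brownian_box()]);
#'   plain `x`, `y`, `z` columns are used if the unwrapped ones are absent,
#'   in which case the caller attests they are unwrapped.
#' @param dt Time per frame; defaults to the `dt` attribute of `positions`.
#' @param fit_range Fractions of the trajectory over which to fit the MSD
#'   slope, default `c(0.1, 0.5)` to avoid the poorly averaged long lags.
#' @param n_chunks Number of contiguous chunks for the spread estimate.
#' @param l_box Box edge for the wrapped-coordinate heuristic; defaults to
#'   the `l_box` attribute, `NULL` skips the check.
#' @return A `diffusion_estimate`: `d_pbc`, `d_chunks`, `d_chunk_sd`,
#'   `msd` tibble (`time`, `msd`), `dt`, `fit_range`.
#' @export
#' @examples
#' pos <- gen_brownian_box(0.2, 5, 20, 200, 1, seed = 1)
#' msd_diffusion(pos)$d_pbc
msd_diffusion <- function(positions, dt = NULL, fit_range = c(0.1, 0.5),
                          n_chunks = 5, l_box = NULL) {
  stopifnot(is.data.frame(positions),
            all(c("frame", "particle") %in% names(positions)))
  dt <- dt %||% attr(positions, "dt")
  if (is.null(dt)) abort("`dt` must be given (or carried as an attribute).",
                         class = "mdinfer_input_error")
  check_positive_scalar(dt, "dt")
  l_box <- l_box %||% attr(positions, "l_box")
  cols <- if (all(c("xu", "yu", "zu") %in% names(positions))) {
    c("xu", "yu", "zu")
  } else c("x", "y", "z")
  if (!all(cols %in% names(positions))) {
    abort("positions need coordinate columns xu/yu/zu or x/y/z.",
          class = "mdinfer_input_error")
  }
  frames <- sort(unique(positions$frame))
  nt <- length(frames)
  if (nt < 100L) {
    abort("at least 100 frames are required for an MSD fit.",
          class = "mdinfer_input_error")
  }
  pos <- positions[order(positions$particle, positions$frame), ]
  np <- length(unique(pos$particle))
  mats <- purrr::map(cols, function(cc)
    matrix(pos[[cc]], nrow = nt, ncol = np))

  if (!is.null(l_box)) {
    max_step <- max(purrr::map_dbl(mats, function(m)
      max(abs(diff(m)))))
    if (max_step > l_box / 2) {
      abort(paste(
        "single-step displacement exceeds half the box edge: the",
        "coordinates look wrapped. Diffusion requires unwrapped",
        "trajectories; no unwrapping heuristic is applied here."),
        class = "mdinfer_wrapped_error")
    }
  }

  msd_of <- function(rows) {
    t0 <- rows[1]; t1 <- rows[length(rows)]
    len <- t1 - t0 + 1L
    lags <- unique(round(seq(1, max(2, floor(fit_range[2] * (len - 1L))),
                             length.out = min(80L, len - 1L))))
    msd <- purrr::map_dbl(lags, function(L) {
      s <- 0
      for (m in mats) {
        d <- m[(t0 + L):t1, , drop = FALSE] -
          m[t0:(t1 - L), , drop = FALSE]
        s <- s + mean(d^2)
      }
      s
    })
    tibble(lag = lags, time = lags * dt, msd = msd)
  }
  fit_d <- function(tab, len) {
    lo <- fit_range[1] * (len - 1L); hi <- fit_range[2] * (len - 1L)
    sel <- tab$lag >= lo & tab$lag <= hi
    if (sum(sel) < 2L) sel <- rep(TRUE, nrow(tab))
    unname(coef(lm(msd ~ time, data = tab[sel, ]))[2] / 6)
  }
  full <- msd_of(c(1L, nt))
  d_pbc <- fit_d(full, nt)
  bounds <- floor(seq(1L, nt, length.out = n_chunks + 1L))
  d_chunks <- purrr::map_dbl(seq_len(n_chunks), function(i) {
    rows <- c(bounds[i], bounds[i + 1L])
    len <- rows[2] - rows[1] + 1L
    fit_d(msd_of(rows), len)
  })
  structure(
    list(d_pbc = d_pbc, d_chunks = d_chunks,
         d_chunk_sd = sd(d_chunks),
         msd = full[, c("time", "msd")], dt = dt, fit_range = fit_range),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D_pbc = %.4g (chunk spread %.3g, %d chunks)\n",
              x$d_pbc, x$d_chunk_sd, length(x$d_chunks)))
  invisible(x)
}

#' Hydrodynamic finite-size correction term
#'
#' The additive correction removing the periodic-boundary suppression of
#' self-diffusion in a cubic box,
#' \eqn{\Delta D = \xi k_B T / (6 \pi \eta L)} with
#' \eqn{\xi = 2.837297}. Vectorised over `l_box`.
#'
#' @param l_box Cubic box edge in nm.
#' @param temperature Kelvin.
#' @param viscosity Shear viscosity in kg m^-1 s^-1 (3.08e-4 for the water
#'   model used here).
#' @return Correction in nm^2/ps.
#' @export
#' @examples
#' yeh_hummer_term(9, 298, 3.08e-4) # ~ 2.234e-4 nm^2/ps = 0.223e-5 cm^2/s
yeh_hummer_term <- function(l_box, temperature, viscosity) {
  stopifnot(is.numeric(l_box), all(l_box > 0))
  check_positive_scalar(temperature, "temperature")
  check_positive_scalar(viscosity, "viscosity")
  # SI: m^2/s, then to nm^2/ps (1 m^2/s = 1e6 nm^2/ps)
  .xi_cubic * .kB * temperature / (6 * pi * viscosity * l_box * 1e-9) * 1e6
}

#' Apply the Yeh-Hummer correction to a PBC diffusion coefficient
#'
#' @param d_pbc Diffusion coefficient measured under periodic boundaries,
#'   nm^2/ps; vectorised together with `l_box`.
#' @inheritParams yeh_hummer_term
#' @return Tibble: `d_pbc`, `l_box`, `correction`, `d_corrected`
#'   (all nm^2/ps) and `d_corrected_cm2_s` in 1e-5 cm^2/s.
#' @export
yeh_hummer_correct <- function(d_pbc, l_box, temperature = 298,
                               viscosity = 3.08e-4) {
  stopifnot(is.numeric(d_pbc), all(d_pbc >= 0))
  corr <- yeh_hummer_term(l_box, temperature, viscosity)
  tibble(
    d_pbc = d_pbc, l_box = l_box, correction = corr,
    d_corrected = d_pbc + corr,
    d_corrected_cm2_s = (d_pbc + corr) * 1e3 # in 1e-5 cm^2/s
  )
}

#' Extrapolate protein-box water diffusion to a larger box
#'
#' Weighted average of the measured diffusion coefficient in a smaller
#' protein box with the bulk-water coefficient, weighted by the number of
#' water molecules present and added:
#' `(n_small * d_small + n_added * d_bulk) / (n_small + n_added)`. This is
#' deliberately the simple average of uncorrected coefficients; it is an
#' approximate renormalization of the protein-to-water ratio, not a
#' hydrodynamic theory.
#'
#' @param d_small Diffusion coefficient in the smaller box.
#' @param n_small Number of waters in the smaller box.
#' @param d_bulk Bulk-water diffusion coefficient.
#' @param n_added Number of bulk-like waters added to reach the target box.
#' @return Extrapolated diffusion coefficient (same units as inputs).
#' @export
#' @examples
#' extrapolate_diffusion(2, 100, 4, 100) # 3
extrapolate_diffusion <- function(d_small, n_small, d_bulk, n_added) {
  if (any(c(d_small, d_bulk) < 0) || any(c(n_small, n_added) < 0) ||
      n_small + n_added <= 0) {
    abort("diffusion coefficients and counts must be non-negative, with a positive total count.",
          class = "mdinfer_input_error")
  }
  (n_small * d_small + n_added * d_bulk) / (n_small + n_added)
}

#' Radial distribution function with configurable normalization
#'
#' Distance-resolved pair density around a reference point (default: the
#' box center), normalised by the reference density computed over a chosen
#' volume: the full box (`"box"`) or a sphere of given radius
#' (`"sphere"`), in either case minus an excluded volume `v_excluded`
#' (e.g. the volume occupied by a protein, inaccessible to solvent).
#' Getting `v_excluded` wrong inflates or deflates g(r) by exactly
#' `(V_norm - v_true) / (V_norm - v_set)`.
#'
#' @param points Tibble `frame, x, y, z` (as from [gen_excluded_config()]);
#'   attributes `l_box` and `n_frames` are used if present.
#' @param r_max Largest distance; must not exceed `l_box/2` (box mode) or
#'   `radius` (sphere mode).
#' @param bin_width Shell width.
#' @param normalization `"box"` or `"sphere"`.
#' @param radius Normalization sphere radius (default 4.25 nm, the
#'   protein-box convention used throughout).
#' @param v_excluded Volume inaccessible to the particles, subtracted from
#'   the normalization volume (default 0).
#' @param center Reference point, numeric length-3; default box center.
#' @param l_box Box edge; defaults to the attribute.
#' @return An `rdf_result` tibble: `r` (shell centers), `g`, `count`;
#'   attributes `normalization`, `v_norm`, `v_excluded`, `density`.
#' @export
rdf_spherical <- function(points, r_max, bin_width,
                          normalization = c("box", "sphere"),
                          radius = 4.25, v_excluded = 0,
                          center = NULL, l_box = NULL) {
  normalization <- rlang::arg_match(normalization)
  stopifnot(is.data.frame(points),
            all(c("frame", "x", "y", "z") %in% names(points)))
  l_box <- l_box %||% attr(points, "l_box")
  if (is.null(l_box)) abort("`l_box` must be given (or carried as attribute).",
                            class = "mdinfer_input_error")
  check_positive_scalar(r_max, "r_max")
  check_positive_scalar(bin_width, "bin_width")
  if (v_excluded < 0) abort("`v_excluded` must be non-negative.",
                            class = "mdinfer_input_error")
  if (normalization == "box" && r_max > l_box / 2 + 1e-12) {
    abort("box normalization requires r_max <= l_box / 2.",
          class = "mdinfer_input_error")
  }
  if (normalization == "sphere") {
    check_positive_scalar(radius, "radius")
    if (r_max > radius + 1e-12) {
      abort("sphere normalization requires r_max <= radius.",
            class = "mdinfer_input_error")
    }
  }
  center <- center %||% rep(l_box / 2, 3)
  stopifnot(length(center) == 3L)
  n_frames <- attr(points, "n_frames") %||% length(unique(points$frame))

  r <- sqrt((points$x - center[1])^2 + (points$y - center[2])^2 +
            (points$z - center[3])^2)
  breaks <- seq(0, r_max, by = bin_width)
  if (tail(breaks, 1) < r_max) breaks <- c(breaks, r_max)
  counts <- graphics::hist(r[r <= r_max], breaks = breaks,
                           plot = FALSE)$counts
  shell_vol <- 4 / 3 * pi * diff(breaks^3)

  v_norm <- if (normalization == "box") l_box^3 else 4 / 3 * pi * radius^3
  if (v_excluded >= v_norm) {
    abort("`v_excluded` must be smaller than the normalization volume.",
          class = "mdinfer_input_error")
  }
  n_ref <- if (normalization == "box") length(r) else sum(r <= radius)
  density <- n_ref / n_frames / (v_norm - v_excluded)
  g <- counts / (n_frames * shell_vol * density)

  out <- tibble(r = (head(breaks, -1) + tail(breaks, -1)) / 2,
                g = g, count = counts)
  structure(out,
            normalization = normalization, v_norm = v_norm,
            v_excluded = v_excluded, density = density,
            radius = if (normalization == "sphere") radius else NA_real_,
            class = c("rdf_result", class(out)))
}
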