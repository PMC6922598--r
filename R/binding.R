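# Quantitative binding characterization: two-state (free/bound) chemical
# exchange lineshape simulation and titration fitting, fraction-bound KD
# bounds, kinetic bookkeeping, and thermofluor melt-curve processing.
#
# The exchange model is the standard two-site Bloch-McConnell treatment of
# a protein observable: state F (apo) and state B (ligand-bound) exchange
# with pseudo-first-order forward rate kon * L_free and reverse rate koff,
# where kon = koff / KD. Spectra are steady-state solutions of the 2x2
# evolution matrix evaluated on a frequency grid.

#' Equilibrium free-ligand and complex concentrations
#'
#' Solves the single-site binding quadratic for protein (binding-site)
#' concentration `p_tot`, total ligand `l_tot` and dissociation constant
#' `kd`: `complex = ((P+L+K) - sqrt((P+L+K)^2 - 4PL)) / 2`.
#'
#' @param p_tot,l_tot,kd Concentrations and KD in the same units (M).
#' @return Named vector `c(l_free, complex)`; mass is conserved exactly.
#' @export
free_ligand <- function(p_tot, l_tot, kd) {
  if (any(c(p_tot, l_tot) < 0) || kd <= 0) stop("concentrations must be >= 0 and kd > 0")
  s <- p_tot + l_tot + kd
  cplx <- (s - sqrt(s^2 - 4 * p_tot * l_tot)) / 2
  cplx <- min(max(cplx, 0), p_tot, l_tot)
  c(l_free = l_tot - cplx, complex = cplx)
}

#' On-rate constant from KD and off-rate
#'
#' @param kd Dissociation constant, M.
#' @param koff Off-rate constant, 1/s.
#' @return kon = koff / kd, in 1/(M s).
#' @export
kon_from <- function(kd, koff) {
  if (kd <= 0) stop("kd must be positive")
  koff / kd
}

#' Two-state exchange parameters
#'
#' Parameters of the two-state lineshape model for one or more observed
#' peaks in (up to) two spectral dimensions.
#'
#' @param kd Dissociation constant, M.
#' @param koff Off-rate constant, 1/s.
#' @param delta_free,delta_bound Matrices (n_peaks x n_dims) of chemical
#'   shifts, ppm.
#' @param r2_free,r2_bound Transverse relaxation rates, 1/s (recycled to
#'   n_peaks x n_dims).
#' @param scale Global intensity scale.
#' @param field_mhz Per-dimension spectrometer frequencies, MHz (defaults:
#'   800 for 1H, 201 for 13C at an 800 MHz 1H field).
#' @return A `two_state_params` object.
#' @export
two_state_params <- function(kd, koff, delta_free, delta_bound,
                             r2_free = 20, r2_bound = 20, scale = 1,
                             field_mhz = c(800, 201.2)) {
  stopifnot(kd > 0, koff > 0)
  delta_free <- rbind(delta_free)
  delta_bound <- rbind(delta_bound)
  stopifnot(all(dim(delta_free) == dim(delta_bound)))
  nd <- ncol(delta_free)
  np <- nrow(delta_free)
  expand <- function(x) matrix(x, np, nd, byrow = length(x) == nd)
  structure(list(kd = kd, koff = koff, delta_free = delta_free,
                 delta_bound = delta_bound, r2_free = expand(r2_free),
                 r2_bound = expand(r2_bound), scale = scale,
                 field_mhz = field_mhz[seq_len(nd)]),
            class = "two_state_params")
}

# steady-state two-site exchange lineshape on an angular-frequency grid
# (rad/s). Returns the real absorption-mode intensity at each grid point.
bloch_mcconnell_1d <- function(omega_grid, omega_f, omega_b, r2f, r2b,
                               kfb, kbf, pf, pb) {
  # A = i*Omega - R + K;  S(w) = Re[ 1' (i w I - A)^-1 p0 ]
  a11 <- 1i * omega_f - r2f - kfb
  a12 <- kbf
  a21 <- kfb
  a22 <- 1i * omega_b - r2b - kbf
  m11 <- 1i * omega_grid - a11
  m22 <- 1i * omega_grid - a22
  det <- m11 * m22 - a12 * a21
  # inverse of [[m11, -a12], [-a21, m22]] applied to (pf, pb)
  v1 <- (m22 * pf + a12 * pb) / det
  v2 <- (a21 * pf + m11 * pb) / det
  Re(v1 + v2)
}

#' Simulate a two-state exchange spectrum
#'
#' Computes the steady-state two-site exchange lineshape for every peak and
#' dimension at the populations implied by `p_tot`, `l_tot` and the model's
#' KD. Pseudo-first-order rates are `k_FB = kon * l_free` (with
#' `kon = koff/kd`) and `k_BF = koff`, which satisfy detailed balance with
#' the equilibrium populations. For two dimensions the 2D peak is the outer
#' product of the per-dimension lineshapes.
#'
#' @param params A [two_state_params()].
#' @param p_tot,l_tot Total protein-site and ligand concentrations, M.
#' @param ppm_grids List (per dimension) of ppm grids, or a single numeric
#'   grid for 1D.
#' @param peaks Which peaks to simulate (default all).
#' @param outer_2d Return full 2D rasters (`TRUE`) or the list of
#'   per-dimension 1D lineshapes (default).
#' @return A list per peak: either `dims` (list of data frames `ppm`,
#'   `amp`) or a 2D `raster` matrix.
#' @export
simulate_lineshape <- function(params, p_tot, l_tot, ppm_grids,
                               peaks = NULL, outer_2d = FALSE) {
  stopifnot(inherits(params, "two_state_params"))
  if (is.numeric(ppm_grids)) ppm_grids <- list(ppm_grids)
  nd <- length(params$field_mhz)
  stopifnot(length(ppm_grids) == nd)
  eq <- free_ligand(p_tot, l_tot, params$kd)
  pb <- if (p_tot > 0) eq[["complex"]] / p_tot else 0
  pf <- 1 - pb
  kon <- params$koff / params$kd
  kfb <- kon * eq[["l_free"]]
  kbf <- params$koff
  np <- nrow(params$delta_free)
  sel <- peaks %||% seq_len(np)
  out <- lapply(sel, function(pk) {
    dims <- lapply(seq_len(nd), function(dm) {
      w <- 2 * pi * params$field_mhz[dm] * ppm_grids[[dm]]
      amp <- bloch_mcconnell_1d(
        w,
        2 * pi * params$field_mhz[dm] * params$delta_free[pk, dm],
        2 * pi * params$field_mhz[dm] * params$delta_bound[pk, dm],
        params$r2_free[pk, dm], params$r2_bound[pk, dm], kfb, kbf, pf, pb)
      data.frame(ppm = ppm_grids[[dm]], amp = params$scale * amp)
    })
    if (outer_2d && nd == 2)
      list(raster = outer(dims[[1]]$amp, dims[[2]]$amp) / params$scale,
           dims = dims)
    else list(dims = dims)
  })
  names(out) <- paste0("peak", sel)
  out
}

#' Build a titration series of simulated spectra
#'
#' Convenience constructor for the titration data model: a list of points,
#' each carrying `p_tot`, `l_tot`, `ratio` and per-peak spectra on shared
#' ppm grids, optionally with added Gaussian amplitude noise.
#'
#' @param params Generating [two_state_params()].
#' @param p_tot Protein concentration, M.
#' @param ratios Ligand:protein molar ratios.
#' @param ppm_grids Per-dimension ppm grids (list).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   maximum apo amplitude (0 for noiseless).
#' @param seed RNG seed used when noise is added.
#' @return A `titration_series` list.
#' @export
make_titration_series <- function(params, p_tot = 118e-6,
                                  ratios = c(0, 0.58, 1.35, 2.47),
                                  ppm_grids = NULL, noise_sd = 0, seed = 1) {
  if (is.null(ppm_grids)) ppm_grids <- default_ppm_grids(params)
  ref <- simulate_lineshape(params, p_tot, 0, ppm_grids)
  ref_max <- max(vapply(ref, function(pk)
    max(vapply(pk$dims, function(d) max(abs(d$amp)), 1)), 1))
  if (noise_sd > 0) set.seed(seed)
  pts <- lapply(ratios, function(rt) {
    sim <- simulate_lineshape(params, p_tot, rt * p_tot, ppm_grids)
    if (noise_sd > 0)
      sim <- lapply(sim, function(pk) {
        pk$dims <- lapply(pk$dims, function(d) {
          d$amp <- d$amp + rnorm(nrow(d), 0, noise_sd * ref_max)
          d
        })
        pk
      })
    list(p_tot = p_tot, l_tot = rt * p_tot, ratio = rt, spectra = sim)
  })
  structure(list(points = pts, ppm_grids = ppm_grids,
                 field_mhz = params$field_mhz), class = "titration_series")
}

# per-dimension ppm grids spanning free..bound shifts with margin
default_ppm_grids <- function(params, n = 96, margin = 3) {
  lapply(seq_along(params$field_mhz), function(dm) {
    lo <- min(params$delta_free[, dm], params$delta_bound[, dm])
    hi <- max(params$delta_free[, dm], params$delta_bound[, dm])
    # margin in units of the largest linewidth (Hz -> ppm)
    wid <- max(params$r2_free[, dm], params$r2_bound[, dm]) / pi /
      params$field_mhz[dm]
    seq(lo - margin * wid, hi + margin * wid, length.out = n)
  })
}

# flatten a titration series into plain numeric blocks so the fitting loop
# avoids repeated data-frame construction; block order is point -> peak ->
# dimension, matching series_residuals
series_compile <- function(series) {
  blocks <- list()
  obs <- list()
  for (ip in seq_along(series$points)) {
    pt <- series$points[[ip]]
    for (pk in seq_along(pt$spectra)) {
      for (dm in seq_along(pt$spectra[[pk]]$dims)) {
        d <- pt$spectra[[pk]]$dims[[dm]]
        blocks[[length(blocks) + 1L]] <- list(
          omega = 2 * pi * series$field_mhz[dm] * d$ppm,
          p_tot = pt$p_tot, l_tot = pt$l_tot, peak = pk, dim = dm)
        obs[[length(obs) + 1L]] <- d$amp
      }
    }
  }
  list(blocks = blocks, obs = unlist(obs),
       lengths = vapply(obs, length, 1L))
}

compiled_model <- function(compiled, params, field_mhz) {
  kon <- params$koff / params$kd
  cache_key <- -1
  pf <- pb <- kfb <- NA_real_
  out <- vector("list", length(compiled$blocks))
  for (k in seq_along(compiled$blocks)) {
    bl <- compiled$blocks[[k]]
    if (bl$l_tot != cache_key) {
      eq <- free_ligand(bl$p_tot, bl$l_tot, params$kd)
      pb <- if (bl$p_tot > 0) eq[["complex"]] / bl$p_tot else 0
      pf <- 1 - pb
      kfb <- kon * eq[["l_free"]]
      cache_key <- bl$l_tot
    }
    f <- field_mhz[bl$dim]
    out[[k]] <- params$scale * bloch_mcconnell_1d(
      bl$omega, 2 * pi * f * params$delta_free[bl$peak, bl$dim],
      2 * pi * f * params$delta_bound[bl$peak, bl$dim],
      params$r2_free[bl$peak, bl$dim], params$r2_bound[bl$peak, bl$dim],
      kfb, params$koff, pf, pb)
  }
  unlist(out)
}

series_residuals <- function(series, params, compiled = NULL) {
  if (is.null(compiled)) compiled <- series_compile(series)
  compiled$obs - compiled_model(compiled, params, series$field_mhz)
}

params_to_vector <- function(p) {
  c(log10(p$kd), log10(p$koff), as.numeric(p$delta_bound),
    log10(as.numeric(p$r2_bound[, 1])), log10(p$scale))
}

vector_to_params <- function(v, template, fix_kd = NULL) {
  np <- nrow(template$delta_free)
  nd <- ncol(template$delta_free)
  i <- 0
  kd <- if (is.null(fix_kd)) 10^v[i <- i + 1] else fix_kd
  if (!is.null(fix_kd)) i <- i + 1
  koff <- 10^v[i <- i + 1]
  db <- matrix(v[i + seq_len(np * nd)], np, nd)
  i <- i + np * nd
  r2b <- 10^v[i + seq_len(np)]
  i <- i + np
  scale <- 10^v[i + 1]
  two_state_params(kd, koff, template$delta_free, db,
                   r2_free = template$r2_free, r2_bound = r2b,
                   scale = scale, field_mhz = template$field_mhz)
}

#' Fit a two-state exchange model to a titration series
#'
#' Joint nonlinear least squares of (KD, koff, bound-state shifts per peak
#' and dimension, bound-state R2 per peak, intensity scale) against all
#' spectra of the series, followed by residual-resampling bootstrap for
#' parameter standard errors. Free-state shifts and R2 are taken from the
#' initial guess (estimate them from the apo point). Deterministic for a
#' given seed.
#'
#' @param series A `titration_series` (>= 3 points spanning sub- and
#'   super-stoichiometric ligand).
#' @param init Initial [two_state_params()].
#' @param seed RNG seed for the bootstrap.
#' @param n_boot Number of bootstrap replicas (default 100).
#' @param fix_kd Optionally fix KD at a value (constrained fit for
#'   chi-square comparisons).
#' @return List with `params` (fitted `two_state_params`), `chisq`,
#'   `se` (named: kd, koff), `ci` (95% bootstrap intervals), `boot`
#'   (replica estimates), `convergence` info.
#' @export
fit_titration <- function(series, init, seed = 1, n_boot = 100,
                          fix_kd = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$points) < 3)
    stop("need at least 3 titration points")
  has_sub <- any(vapply(series$points, function(p) p$l_tot > 0 &&
                          p$l_tot < p$p_tot, TRUE))
  has_super <- any(vapply(series$points, function(p) p$l_tot > p$p_tot, TRUE))
  if (!has_sub || !has_super)
    warning("titration does not span sub- and super-stoichiometric ligand")
  v0 <- params_to_vector(init)
  if (!is.null(fix_kd)) v0[1] <- log10(fix_kd)
  active <- if (is.null(fix_kd)) seq_along(v0) else seq_along(v0)[-1]
  compiled <- series_compile(series)
  resid_for <- function(va, base_v, obs) {
    v <- base_v
    v[active] <- va
    p <- vector_to_params(v, init, fix_kd = fix_kd)
    obs - compiled_model(compiled, p, series$field_mhz)
  }
  fit <- minpack.lm::nls.lm(par = v0[active],
                            fn = resid_for, base_v = v0, obs = compiled$obs,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-10))
  v_fit <- v0
  v_fit[active] <- fit$par
  p_fit <- vector_to_params(v_fit, init, fix_kd = fix_kd)
  res <- compiled$obs - compiled_model(compiled, p_fit, series$field_mhz)
  chisq <- sum(res^2)
  # residual-resampling bootstrap
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("kd", "koff")))
  if (n_boot > 0) {
    set.seed(seed)
    fitted_vals <- compiled$obs - res
    for (b in seq_len(n_boot)) {
      new_obs <- fitted_vals + sample(res, length(res), replace = TRUE)
      fb <- try(suppressWarnings(
        minpack.lm::nls.lm(par = v_fit[active],
                           fn = resid_for, base_v = v_fit, obs = new_obs,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 30))), silent = TRUE)
      if (!inherits(fb, "try-error")) {
        vb <- v_fit
        vb[active] <- fb$par
        pb <- vector_to_params(vb, init, fix_kd = fix_kd)
        boot[b, ] <- c(pb$kd, pb$koff)
      }
    }
  }
  ok <- stats::complete.cases(boot)
  se <- apply(boot[ok, , drop = FALSE], 2, stats::sd)
  ci <- apply(boot[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  list(params = p_fit, chisq = chisq, se = se, ci = ci, boot = boot,
       convergence = list(info = fit$info, message = fit$message,
                          niter = fit$niter))
}

#' KD bounds from fraction-bound chemical-shift analysis
#'
#' Classical chemical-shift-perturbation analysis: the bound fraction at
#' each titration point is `f_i = delta_i / delta_max`, modeled as
#' `complex/P` from the binding quadratic. Two bracketing assumptions about
#' the saturated perturbation give the bounds: taking the last point as
#' fully saturated (`delta_max = delta_last`) overestimates f and yields
#' the lower KD bound; jointly fitting the asymptote yields the upper
#' bound. The point estimate is the joint fit's KD.
#'
#' @param shifts Observed peak positions per titration point: numeric
#'   vector, or a matrix (points x dimensions) whose Euclidean displacement
#'   from the first point is used.
#' @param p_tot Protein concentration, M.
#' @param l_tot Total ligand per point, M (same length as points).
#' @param weights Optional per-dimension weights for the matrix form
#'   (e.g. 1 and 1/4 for 1H and 13C ppm).
#' @return List `kd_lower`, `kd_upper`, `kd_point` (M), `fraction_bound`,
#'   and `wide_bounds` flag for degenerate (2-point) series.
#' @export
fraction_bound_kd <- function(shifts, p_tot, l_tot, weights = NULL) {
  npt <- length(l_tot)
  shifts <- rbind(shifts)
  if (nrow(shifts) == 1 && npt > 1) shifts <- t(shifts)
  stopifnot(nrow(shifts) == npt)
  if (sum(l_tot > 0) < 2) stop("need >= 2 points with nonzero ligand")
  w <- weights %||% rep(1, ncol(shifts))
  dd <- sqrt(colSums((t(shifts) - as.numeric(shifts[1, ]))^2 * w^2))
  if (max(dd) <= 0) stop("no binding signal: all shifts identical")
  cplx <- function(kd) vapply(l_tot, function(L)
    free_ligand(p_tot, L, kd)[["complex"]] / p_tot, 1)
  # lower bound: last point assumed saturated
  f_sat <- dd / dd[npt]
  sse_low <- function(lkd) sum((f_sat - cplx(10^lkd))^2)
  kd_lower <- 10^stats::optimize(sse_low, c(-9, 0))$minimum
  # upper bound / point estimate: delta_max fitted as free asymptote
  sse_joint <- function(par) {
    dmax <- exp(par[2])
    sum((dd / dmax - cplx(10^par[1]))^2)
  }
  op <- stats::optim(c(log10(kd_lower), log(max(dd))), sse_joint,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  kd_fit <- 10^op$par[1]
  lo <- min(kd_lower, kd_fit)
  hi <- max(kd_lower, kd_fit)
  list(kd_lower = lo, kd_upper = hi, kd_point = kd_fit,
       fraction_bound = dd / exp(op$par[2]),
       wide_bounds = sum(l_tot > 0) <= 2)
}

#' Process thermofluor (differential scanning fluorimetry) replicates
#'
#' Averages sample and background replicate curves on a shared temperature
#' grid, subtracts the background mean, and reports the initial
#' fluorescence, the temperature of maximum dF/dT (central differences)
#' and whether the curve decreases monotonically.
#'
#' @param sample_reps,background_reps Data frames whose first column is
#'   temperature (degrees C, strictly increasing) and remaining columns are
#'   replicate fluorescence readings.
#' @return A `melt_curve` list: `temperature`, `fluorescence`, `metrics`
#'   (`initial_fluorescence`, `tm_dfdt`, `monotonic_decrease`,
#'   `n_points`), `replicates` (sample replicate count).
#' @export
process_thermofluor <- function(sample_reps, background_reps) {
  ts <- sample_reps[[1]]
  tb <- background_reps[[1]]
  if (length(ts) != length(tb) || any(abs(ts - tb) > 1e-9))
    stop("sample and background temperature grids differ")
  if (any(diff(ts) <= 0)) stop("temperatures must be strictly increasing")
  sm <- rowMeans(as.matrix(sample_reps[, -1, drop = FALSE]))
  bm <- rowMeans(as.matrix(background_reps[, -1, drop = FALSE]))
  f <- sm - bm
  n <- length(ts)
  dfdt <- rep(NA_real_, n)
  if (n >= 3) {
    dfdt[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (ts[3:n] - ts[1:(n - 2)])
    dfdt[1] <- (f[2] - f[1]) / (ts[2] - ts[1])
    dfdt[n] <- (f[n] - f[n - 1]) / (ts[n] - ts[n - 1])
  }
  tm <- if (all(is.na(dfdt))) NA_real_ else ts[which.max(dfdt)]
  structure(list(
    temperature = ts, fluorescence = f,
    metrics = list(initial_fluorescence = f[1], tm_dfdt = tm,
                   monotonic_decrease = all(diff(f) <= 0),
                   n_points = n),
    replicates = ncol(sample_reps) - 1L), class = "melt_curve")
}
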