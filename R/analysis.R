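# Verification analytics: traveling-wave measurement against the analytic
# Fisher-KPP profile, L2 convergence scoring, and linear stability analysis
# of the Schnakenberg system (steady state, Hopf locus, Turing band).

#' Analytic Fisher-KPP traveling-wave profile
#'
#' The asymptotic series expansion of the pulled-front profile in powers of
#' `1/c^2`, in the traveling-wave coordinate `z = x - c*t`:
#' order 0 is the logistic front `1 / (1 + exp(z/c))`, order 1 adds the
#' correction `c^-2 * s / (1+s)^2 * log(4 s / (1+s)^2)` with `s = exp(z/c)`.
#'
#' @param z Traveling-wave coordinate (vectorized).
#' @param c Wave speed (> 0).
#' @param order 0 or 1.
#' @return Profile values `U(z)`.
#' @export
fisher_analytic_profile <- function(z, c = 2, order = 1) {
  stopifnot(c > 0, order %in% c(0, 1))
  s <- exp(z / c)
  u <- 1 / (1 + s)
  if (order == 1) {
    # the prefactor s/(1+s)^2 decays to 0 in both tails faster than the log
    # diverges; guard the underflow/overflow limits explicitly
    ok <- is.finite(s) & s > 0
    corr <- numeric(length(s))
    corr[ok] <- (s[ok] / (1 + s[ok])^2) *
      log(4 * s[ok] / (1 + s[ok])^2) / c^2
    u <- u + corr
  }
  u
}

# mid-domain 1D slice of a trajectory: x coordinates and a samples x nx
# matrix of one species' values along the row nearest to height/2
.mid_slice <- function(traj, species = traj$species[1]) {
  mesh <- traj$mesh
  iy <- round(mesh$ny / 2)
  row_nodes <- iy * (mesh$nx + 1L) + seq_len(mesh$nx + 1L)
  s <- match(species, traj$species)
  v <- traj$values[row_nodes, s, , drop = FALSE]
  list(x = mesh$coords[row_nodes, 1],
       values = t(matrix(v, nrow = length(row_nodes))))
}

# first downward level crossing along x, by linear interpolation
.front_position <- function(x, u, level) {
  above <- u >= level
  idx <- which(above[-length(above)] & !above[-1])
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  x[i] + (level - u[i]) * (x[i + 1] - x[i]) / (u[i + 1] - u[i])
}

#' Measure the speed of a traveling wave front
#'
#' Extracts, at each sample, the mid-height front position on the
#' mid-domain slice (linear interpolation of the first downward crossing of
#' `level`), then fits the speed by least squares over the late-time
#' window: the last `window` fraction of samples whose front lies strictly
#' inside the domain (at least two grid cells from either end), skipping
#' the accelerating transient and any boundary-contaminated tail.
#'
#' @param traj An `rd_trajectory`.
#' @param level Front level (the Fisher-KPP front is tracked at `kappa/2`).
#' @param window Fraction of valid samples, counted from the end, used for
#'   the linear fit (default 0.5).
#' @param species Species to track (defaults to the first).
#' @return An `rd_wave_measurement`: list with `times`, `front`, `speed`,
#'   and the fitted window indices.
#' @export
measure_wave_speed <- function(traj, level = 0.5, window = 0.5,
                               species = traj$species[1]) {
  sl <- .mid_slice(traj, species)
  front <- vapply(seq_along(traj$times), function(k)
    .front_position(sl$x, sl$values[k, ], level), 0)
  h <- traj$mesh$spacing
  lo <- min(sl$x) + 2 * h
  hi <- max(sl$x) - 2 * h
  valid <- which(is.finite(front) & front > lo & front < hi)
  if (length(valid) < 3L)
    stop("measure_wave_speed: fewer than 3 samples with a front crossing",
         call. = FALSE)
  n_fit <- max(3L, ceiling(window * length(valid)))
  fit_idx <- valid[seq(length(valid) - n_fit + 1L, length(valid))]
  fit <- stats::lm.fit(cbind(1, traj$times[fit_idx]), front[fit_idx])
  structure(list(times = traj$times, front = front,
                 speed = unname(fit$coefficients[2]),
                 fit_window = fit_idx, level = level),
            class = "rd_wave_measurement")
}

#' @exportS3Method base::print
print.rd_wave_measurement <- function(x, ...) {
  cat(sprintf(
    "rd_wave_measurement: speed %.4f (level %.3g, fitted over t = [%g, %g])\n",
    x$speed, x$level, min(x$times[x$fit_window]), max(x$times[x$fit_window])))
  invisible(x)
}

#' L2 convergence score between a simulated and a reference profile
#'
#' Root-mean-square difference over a common grid, with scores above 0.5
#' capped at 0.5 and failed (diverged) runs reported as 1.0 — the
#' convention used for convergence heat maps.
#'
#' @param sim,ref Numeric profiles on the same grid.
#' @param failed Set `TRUE` to mark a diverged / unsolvable run.
#' @return Score in `[0, 0.5]`, or 1.0 for failures.
#' @export
l2_convergence_score <- function(sim, ref, failed = FALSE) {
  if (failed) return(1.0)
  if (length(sim) != length(ref))
    stop("l2_convergence_score: profile lengths differ", call. = FALSE)
  min(sqrt(mean((sim - ref)^2)), 0.5)
}

#' Score a Fisher-KPP run against the analytic front profile
#'
#' Takes the final sampled mid-domain slice, shifts the order-`order`
#' analytic profile so the mid-heights align, and returns the
#' [l2_convergence_score()] between the two.
#'
#' @param traj An `rd_trajectory` of a Fisher-KPP run.
#' @param c Wave speed of the analytic profile (the minimum speed 2 for
#'   unit parameters).
#' @param order Expansion order passed to [fisher_analytic_profile()].
#' @param level Mid-height level used for the alignment shift.
#' @return The capped RMS score.
#' @export
fisher_profile_score <- function(traj, c = 2, order = 1, level = 0.5) {
  sl <- .mid_slice(traj)
  h <- traj$mesh$spacing
  lo <- min(sl$x) + 2 * h
  hi <- max(sl$x) - 2 * h
  # last sample whose front is still inside the domain
  for (k in rev(seq_len(nrow(sl$values)))) {
    u <- sl$values[k, ]
    x0 <- .front_position(sl$x, u, level)
    if (is.finite(x0) && x0 > lo && x0 < hi) {
      ref <- fisher_analytic_profile(sl$x - x0, c = c, order = order)
      return(l2_convergence_score(u, ref))
    }
  }
  1.0
}

#' Schnakenberg parameter set
#' @param k1,k_minus1,k2,k3 Mass-action rate constants (> 0).
#' @param D_U,D_V Diffusion coefficients (>= 0).
#' @return A validated parameter list of class `rd_schnakenberg_params`.
#' @export
schnakenberg_params <- function(k1, k_minus1, k2, k3, D_U = 0, D_V = 0) {
  stopifnot(k1 > 0, k_minus1 > 0, k2 > 0, k3 > 0, D_U >= 0, D_V >= 0)
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k3 = k3,
                 D_U = D_U, D_V = D_V), class = "rd_schnakenberg_params")
}

#' The Schnakenberg reaction system as a parsed two-species network
#'
#' Builds the three-reaction network (reversible production/removal of `U`,
#' constant production of `V`, and the autocatalytic step `2U + V -> 3U`)
#' under mass-action kinetics, giving
#' `dU/dt = k1 - k_minus1 * U + k3 * V * U^2` and
#' `dV/dt = k2 - k3 * V * U^2`.
#'
#' @param p An [schnakenberg_params()] object.
#' @return An `rd_reaction_system` over species `U`, `V`.
#' @export
schnakenberg_system <- function(p) {
  reaction_system(c("U", "V"), list(
    parse_reaction_line(sprintf(
      "ZerothOrderReversibleReaction: <-> U ; k_f = %.17g, k_r = %.17g",
      p$k1, p$k_minus1)),
    parse_reaction_line(sprintf(
      "ZerothOrderReaction: -> V ; k = %.17g", p$k2)),
    parse_reaction_line(sprintf(
      "MassActionReaction: 2 U + V -> 3 U ; k = %.17g", p$k3))
  ))
}

#' Homogeneous steady state of the Schnakenberg system
#'
#' Closed form from setting both reaction rates to zero:
#' `U* = (k1 + k2) / k_minus1`, `V* = k2 / (k3 * U*^2)`.
#'
#' @param p An [schnakenberg_params()] object.
#' @return Named vector `c(U, V)`.
#' @export
schnakenberg_steady_state <- function(p) {
  U <- (p$k1 + p$k2) / p$k_minus1
  V <- p$k2 / (p$k3 * U^2)
  c(U = U, V = V)
}

# Jacobian of the reaction ODEs at the homogeneous steady state
.schnakenberg_jacobian <- function(p) {
  ss <- schnakenberg_steady_state(p)
  U <- ss[["U"]]; V <- ss[["V"]]
  matrix(c(-p$k_minus1 + 2 * p$k3 * U * V, p$k3 * U^2,
           -2 * p$k3 * U * V, -p$k3 * U^2),
         2, 2, byrow = TRUE)
}

#' Locate the Hopf bifurcation of the Schnakenberg ODE system
#'
#' With `k1` as the bifurcation parameter, the steady state loses stability
#' to a limit cycle where the Jacobian trace vanishes with positive
#' determinant.  At the steady state the trace is
#' `-k_minus1 + 2 k2 / U - k3 U^2`, which is strictly decreasing in `U`, so
#' the Hopf locus is the unique positive root, found by bisection
#' (tolerance 1e-10); `k1 = k_minus1 * U - k2` then recovers the parameter
#' value.
#'
#' @param k_minus1,k2,k3 The remaining rate constants (> 0).
#' @return List with `k1`, `U`, and `hopf` (`FALSE` if the root implies a
#'   non-positive `k1` or non-positive determinant, i.e. no genuine Hopf).
#' @export
hopf_point <- function(k_minus1, k2, k3) {
  stopifnot(k_minus1 > 0, k2 > 0, k3 > 0)
  tr <- function(U) -k_minus1 + 2 * k2 / U - k3 * U^2
  lo <- 1e-6
  hi <- 2 * k2 / k_minus1 + 1
  while (tr(hi) > 0) hi <- hi * 2
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (tr(mid) > 0) lo <- mid else hi <- mid
  }
  U <- (lo + hi) / 2
  k1 <- k_minus1 * U - k2
  det_ok <- k_minus1 * k3 * U^2 > 0
  list(k1 = k1, U = U, hopf = det_ok && k1 > 0)
}

#' Turing (diffusion-driven) instability band
#'
#' For a steady state that is stable without diffusion (trace < 0,
#' det > 0), returns the wavenumber-squared interval on which the
#' dispersion relation
#' `D_U D_V q^4 - (D_V f_U + D_U g_V) q^2 + det(J) = 0`
#' admits growing modes.  An empty band (or a failed precondition) means no
#' diffusion-driven instability.
#'
#' @param p An [schnakenberg_params()] with diffusivities set.
#' @return List with `band` (`c(q2_minus, q2_plus)` or `numeric(0)`),
#'   `trace`, `det` and `turing` (logical).
#' @export
turing_band <- function(p) {
  J <- .schnakenberg_jacobian(p)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  out <- list(band = numeric(0), trace = tr, det = dt, turing = FALSE)
  if (tr >= 0 || dt <= 0) return(out)     # not stable without diffusion
  a <- p$D_U * p$D_V
  b <- p$D_V * J[1, 1] + p$D_U * J[2, 2]
  if (a == 0 || b <= 0) return(out)
  disc <- b^2 - 4 * a * dt
  if (disc <= 0) return(out)
  roots <- sort((b + c(-1, 1) * sqrt(disc)) / (2 * a))
  out$band <- roots
  out$turing <- TRUE
  out
}

# growth rate of the fastest mode at wavenumber-squared q2 (dispersion
# relation of the linearized reaction-diffusion system)
.dispersion_growth <- function(p, q2) {
  J <- .schnakenberg_jacobian(p)
  A <- J - diag(c(p$D_U, p$D_V)) * q2
  tr <- A[1, 1] + A[2, 2]
  dt <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr^2 - 4 * dt
  if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
}

#' Per-sample spatial summary statistics of a trajectory
#'
#' @param traj An `rd_trajectory`.
#' @return Data frame with one row per (sample, species): `time`,
#'   `species`, `mean`, `min`, `q25`, `median`, `q75`, `max`, `sd`.
#' @export
spatial_summary <- function(traj) {
  stopifnot(length(traj$times) > 0)
  out <- vector("list", length(traj$times) * length(traj$species))
  k <- 1L
  for (i in seq_along(traj$times)) {
    for (s in seq_along(traj$species)) {
      v <- traj$values[, s, i]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out[[k]] <- data.frame(
        time = traj$times[i], species = traj$species[s],
        mean = mean(v), min = min(v), q25 = q[1], median = q[2],
        q75 = q[3], max = max(v), sd = stats::sd(v),
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

#' Fisher-KPP convergence sweep
#'
#' Runs the Fisher-KPP exemplar over a grid of spatial and temporal step
#' sizes and scores each run's final front against the analytic order-1
#' profile, reproducing the structure of an L2 convergence heat map.
#' Diverged runs score 1.0.
#'
#' @param hs,dts Vectors of spatial / temporal step sizes.
#' @param width,height Domain extent (travel direction is x).
#' @param t_end End time of each run.
#' @param c Analytic wave speed used for the reference profile.
#' @return Matrix of scores with rows `hs` and columns `dts`.
#' @export
fisher_convergence_grid <- function(hs = c(4, 2, 0.5),
                                    dts = c(0.2, 0.05, 0.01),
                                    width = 60, height = 10, t_end = 20,
                                    c = 2) {
  scores <- matrix(NA_real_, length(hs), length(dts),
                   dimnames = list(paste0("h=", hs), paste0("dt=", dts)))
  for (i in seq_along(hs)) {
    for (j in seq_along(dts)) {
      scores[i, j] <- tryCatch({
        model <- fisher_kpp_model(width = width, height = height,
                                  h = hs[i], dt = dts[j], t_end = t_end,
                                  sampling_interval = t_end)
        traj <- run_simulation(model)
        fisher_profile_score(traj, c = c)
      }, error = function(e) 1.0)
    }
  }
  scores
}
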