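# Model-free 15N relaxation: spectral densities, forward R1/R2/NOE
# computation, simple and extended model-free fitting, and the two-site
# jump order parameter.

#' Physical and spectrometer constants for an amide 15N spin pair
#'
#' Collects the gyromagnetic ratios, bond length, CSA and field into the
#' derived quantities used by the relaxation expressions.  The 15N
#' gyromagnetic ratio is negative; transition frequencies are formed from
#' the signed Larmor frequencies, so the zero-quantum spectral density is
#' evaluated at \eqn{\omega_H + |\omega_N|} and the double-quantum at
#' \eqn{\omega_H - |\omega_N|}.
#'
#' @param field_mhz Spectrometer 1H frequency, MHz (default 600; 14.1 T).
#' @param r_nh N-H bond length, Angstrom (default 1.02).
#' @param csa_ppm 15N chemical shift anisotropy, ppm (default -126, the
#'   tryptophan indole Ne1 value; backbone amides commonly use -160 to -170).
#' @param gamma_h,gamma_n Gyromagnetic ratios, rad s^-1 T^-1.
#' @return A `nucleus_constants` list with the inputs plus `omega_h`,
#'   `omega_n` (signed, rad/s), `d2` (squared dipolar coupling constant,
#'   s^-2) and `c2` (squared CSA coupling constant, s^-2).
#' @export
nucleus_constants <- function(field_mhz = 600, r_nh = 1.02, csa_ppm = -126,
                              gamma_h = 2.6752218744e8, gamma_n = -2.7126e7) {
  if (field_mhz <= 0) stopf("field must be positive")
  if (r_nh < 0.95 || r_nh > 1.10)
    stopf("N-H bond length %.3f A outside [0.95, 1.10] A", r_nh)
  hbar <- 1.054571817e-34
  mu0_4pi <- 1e-7
  omega_h <- 2 * pi * field_mhz * 1e6
  b0 <- omega_h / gamma_h
  omega_n <- gamma_n * b0                 # negative
  d <- mu0_4pi * hbar * gamma_h * gamma_n / (r_nh * 1e-10)^3
  cc <- omega_n * csa_ppm * 1e-6 / sqrt(3)
  structure(list(field_mhz = field_mhz, r_nh = r_nh, csa_ppm = csa_ppm,
                 gamma_h = gamma_h, gamma_n = gamma_n,
                 omega_h = omega_h, omega_n = omega_n,
                 d2 = d^2, c2 = cc^2),
            class = "nucleus_constants")
}

.check_mf <- function(s_f2, s_s2, tau_e) {
  if (s_f2 < 0 || s_f2 > 1 || s_s2 < 0 || s_s2 > 1)
    stopf("order parameters must lie in [0, 1]")
  if (tau_e < 0) stopf("tau_e must be non-negative")
}

#' Extended model-free spectral density
#'
#' Two-timescale internal motion: a fast component in the extreme-narrowing
#' limit (amplitude \eqn{1 - S_f^2}, contributing no dispersive term) and a
#' slow component with time constant \eqn{\tau_e},
#' \deqn{J(\omega) = \tfrac{2}{5}\left[\frac{S^2\,\tau_c}{1+(\omega\tau_c)^2}
#'   + \frac{(S_f^2 - S^2)\,\tau'}{1+(\omega\tau')^2}\right],\quad
#'   \frac{1}{\tau'} = \frac{1}{\tau_c} + \frac{1}{\tau_e},}
#' with total order parameter \eqn{S^2 = S_f^2 S_s^2}.
#'
#' @param omega Angular frequency, rad/s (vectorized; the absolute value is
#'   used, J is even).
#' @param tau_c Global tumbling time, s.
#' @param s_f2 Fast-limit order parameter.
#' @param s_s2 Slow-component order parameter.
#' @param tau_e Slow internal correlation time, s.
#' @return J(omega), s/rad.
#' @export
extended_spectral_density <- function(omega, tau_c, s_f2, s_s2, tau_e) {
  if (tau_c <= 0) stopf("tau_c must be positive")
  .check_mf(s_f2, s_s2, tau_e)
  w <- abs(omega)
  s2 <- s_f2 * s_s2
  tp <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else 0
  (2 / 5) * (s2 * tau_c / (1 + (w * tau_c)^2) +
             (s_f2 - s2) * tp / (1 + (w * tp)^2))
}

#' Forward 15N relaxation observables from model-free parameters
#'
#' Standard dipolar + axially-symmetric CSA expressions for amide 15N:
#' \deqn{R_1 = \tfrac{d^2}{4}[J(\omega_H{-}\omega_N) + 3J(\omega_N)
#'   + 6J(\omega_H{+}\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \tfrac{d^2}{8}[4J(0) + J(\omega_H{-}\omega_N) + 3J(\omega_N)
#'   + 6J(\omega_H) + 6J(\omega_H{+}\omega_N)]
#'   + \tfrac{c^2}{6}[4J(0) + 3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \tfrac{d^2}{4}\,\frac{\gamma_H}{\gamma_N}\,
#'   [6J(\omega_H{+}\omega_N) - J(\omega_H{-}\omega_N)]\,/\,R_1}
#' with signed \eqn{\omega_N} (see [nucleus_constants()]).
#'
#' @param s_f2,s_s2,tau_e Extended model-free parameters (use `s_f2 = 1` for
#'   the simple model).
#' @param tau_c Global tumbling time, s.
#' @param constants A `nucleus_constants`.
#' @param r_ex Exchange contribution to R2, s^-1 (default 0).
#' @return List with `R1`, `R2` (s^-1), `NOE` (dimensionless), `S2`.
#' @export
forward_relaxation <- function(s_f2, s_s2, tau_e, tau_c,
                               constants = nucleus_constants(), r_ex = 0) {
  .check_mf(s_f2, s_s2, tau_e)
  k <- constants
  J <- function(w) extended_spectral_density(w, tau_c, s_f2, s_s2, tau_e)
  jmhn <- J(k$omega_h - k$omega_n)  # zero-quantum: omega_h + |omega_n|
  jphn <- J(k$omega_h + k$omega_n)  # double-quantum: omega_h - |omega_n|
  jn <- J(k$omega_n); jh <- J(k$omega_h); j0 <- J(0)
  r1 <- k$d2 / 4 * (jmhn + 3 * jn + 6 * jphn) + k$c2 * jn
  r2 <- k$d2 / 8 * (4 * j0 + jmhn + 3 * jn + 6 * jh + 6 * jphn) +
        k$c2 / 6 * (4 * j0 + 3 * jn) + r_ex
  noe <- 1 + k$d2 / 4 * (k$gamma_h / k$gamma_n) * (6 * jphn - jmhn) / r1
  list(R1 = r1, R2 = r2, NOE = noe, S2 = s_f2 * s_s2)
}

#' Fit model-free parameters to 15N relaxation observables
#'
#' Unweighted least squares of the simple (S2, tau_e) or extended
#' (Sf2, Ss2, tau_e) model-free parameters to one residue's R1, R2 and
#' heteronuclear NOE, with the global tumbling time held fixed.  Multi-start
#' derivative-free (Nelder-Mead) refinement over a grid of total-S2 and
#' tau_e starting values; ties between converged minima are broken by lowest
#' chi-squared, then largest total S2.
#'
#' @param r1,r2 Relaxation rates, s^-1.
#' @param noe Heteronuclear NOE (dimensionless).
#' @param tau_c Global tumbling time, s (fixed).
#' @param constants A `nucleus_constants`.
#' @param model `"extended"` or `"simple"`.
#' @param r_ex Fixed exchange contribution to R2, s^-1.
#' @param weights Optional vector of standard errors of (R1, R2, NOE); when
#'   supplied the fit minimizes the weighted chi-squared.
#' @return A `modelfree_fit` list: `s_f2`, `s_s2`, `s2`, `tau_e` (s),
#'   `chi2`, fitted observables, `tau_e_indeterminate` flag, and the
#'   multi-start `trace`.
#' @export
fit_modelfree <- function(r1, r2, noe, tau_c,
                          constants = nucleus_constants(),
                          model = c("extended", "simple"),
                          r_ex = 0, weights = NULL) {
  model <- match.arg(model)
  if (r1 <= 0 || r2 <= 0) stopf("R1 and R2 must be positive")
  obs <- c(r1, r2, noe)
  w <- if (is.null(weights)) c(1, 1, 1) else 1 / weights^2
  fwd3 <- function(sf2, ss2, te) {
    f <- forward_relaxation(sf2, ss2, te, tau_c, constants, r_ex)
    c(f$R1, f$R2, f$NOE)
  }
  chi2 <- function(th) {
    sf2 <- if (model == "extended") stats::plogis(th[1]) else 1
    ss2 <- stats::plogis(th[2])
    te <- exp(th[3])
    sum(w * (fwd3(sf2, ss2, te) - obs)^2)
  }
  starts <- expand.grid(s2 = seq(0.1, 0.9, by = 0.1),
                        te = c(0.05, 0.5, 1.5, 3) * 1e-9)
  trace <- list(); best <- NULL
  for (i in seq_len(nrow(starts))) {
    s2_0 <- starts$s2[i]
    th0 <- c(stats::qlogis(0.9),
             stats::qlogis(min(if (model == "extended") s2_0 / 0.9 else s2_0, 0.95)),
             log(starts$te[i]))
    o <- tryCatch(
      stats::optim(th0, chi2, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(o)) next
    trace[[length(trace) + 1]] <- c(start_s2 = s2_0, start_te = starts$te[i],
                                    chi2 = o$value)
    s2_fit <- (if (model == "extended") stats::plogis(o$par[1]) else 1) *
              stats::plogis(o$par[2])
    if (is.null(best) || o$value < best$value - 1e-18 ||
        (abs(o$value - best$value) <= 1e-18 && s2_fit > best$s2)) {
      best <- o; best$s2 <- s2_fit
    }
  }
  if (is.null(best))
    stopf("fit failure: no start converged (tried %d)", nrow(starts))
  sf2 <- if (model == "extended") stats::plogis(best$par[1]) else 1
  ss2 <- stats::plogis(best$par[2])
  te <- exp(best$par[3])
  s2 <- sf2 * ss2
  fitted <- fwd3(sf2, ss2, te)
  # tau_e carries no information when the slow-component amplitude vanishes
  indet <- (sf2 - s2) < 1e-3
  structure(list(model = model, s_f2 = sf2, s_s2 = ss2, s2 = s2, tau_e = te,
                 chi2 = best$value,
                 fitted = list(R1 = fitted[1], R2 = fitted[2], NOE = fitted[3]),
                 observed = list(R1 = r1, R2 = r2, NOE = noe),
                 tau_c = tau_c, r_ex = r_ex, constants = constants,
                 tau_e_indeterminate = indet,
                 trace = do.call(rbind, trace)),
            class = "modelfree_fit")
}

#' @export
print.modelfree_fit <- function(x, ...) {
  cat(sprintf("%s model-free fit (tau_c = %.3g ns)\n",
              x$model, x$tau_c * 1e9))
  cat(sprintf("  S2 = %.3f (Sf2 = %.3f, Ss2 = %.3f), tau_e = %.3f ns%s\n",
              x$s2, x$s_f2, x$s_s2, x$tau_e * 1e9,
              if (x$tau_e_indeterminate) " [indeterminate]" else ""))
  cat(sprintf("  chi2 = %.3g; fitted R1 = %.3f, R2 = %.3f, NOE = %.3f\n",
              x$chi2, x$fitted$R1, x$fitted$R2, x$fitted$NOE))
  invisible(x)
}

#' Two-site jump generalized order parameter
#'
#' For an interaction vector jumping between two orientations separated by
#' angle \eqn{\theta_{ab}} with state populations \eqn{p_a}, \eqn{p_b}:
#' \deqn{S^2 = 1 - 3 p_a p_b \sin^2\theta_{ab}.}
#'
#' @param p_b Population of state b (state a has `1 - p_b`).
#' @param theta_ab Inter-state angle between bond-vector orientations,
#'   degrees.
#' @return S2, in `[1 - 3 p_a p_b, 1]`.
#' @export
jump_order_parameter <- function(p_b, theta_ab) {
  if (p_b < 0 || p_b > 1) stopf("population must lie in [0, 1]")
  if (theta_ab < 0 || theta_ab > 180) stopf("theta must lie in [0, 180] degrees")
  p_a <- 1 - p_b
  1 - 3 * p_a * p_b * sin(deg2rad(theta_ab))^2
}

#' Read a batch relaxation TSV (residue, R1, R2, NOE, field_MHz)
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_relaxation_table <- function(path) {
  if (!file.exists(path)) stopf("relaxation table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("residue", "R1", "R2", "NOE", "field_MHz")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("relaxation table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  df
}

#' Write a model-free fit (with the constants used) as JSON
#'
#' @param fit A `modelfree_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modelfree_fit <- function(fit, path) {
  k <- fit$constants
  jsonlite::write_json(
    list(model = fit$model, S2 = fit$s2, Sf2 = fit$s_f2, Ss2 = fit$s_s2,
         tau_e_ns = fit$tau_e * 1e9, tau_c_ns = fit$tau_c * 1e9,
         chi2 = fit$chi2, tau_e_indeterminate = fit$tau_e_indeterminate,
         fitted = fit$fitted, observed = fit$observed, r_ex = fit$r_ex,
         constants = list(field_mhz = k$field_mhz, r_nh_A = k$r_nh,
                          csa_ppm = k$csa_ppm, gamma_h = k$gamma_h,
                          gamma_n = k$gamma_n)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
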