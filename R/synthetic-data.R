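# Synthetic two-conformer scenes, NOE volume simulation with controlled
# noise, relaxation-observable simulation, and correlated shift/broadening
# pairs.  All generators are pure functions of (config, seed): the global
# RNG state is saved and restored.

#' Generate a synthetic two-conformer methyl/probe scene
#'
#' Builds a valine-like scaffold of methyl groups (CA-CB-CG fragments, so
#' degeneracy-merge code paths can be exercised) at controlled distances
#' around a central probe N-H (a tryptophan indole-like Ne1-He1 pair), then
#' derives conformer B by rotating the probe bond vector by a configured
#' angle about an axis through the nitrogen and rigidly displacing a subset
#' of the methyl residues.
#'
#' @param n_methyl Number of methyl groups (>= 6 recommended), default 8.
#' @param dist_range Range of methyl-carbon to probe-proton distances,
#'   Angstrom, default `c(3, 8)`.
#' @param flip_angle Probe bond-vector reorientation between conformers,
#'   degrees, default 83.
#' @param n_displace Number of methyl residues rigidly displaced in
#'   conformer B, default 3.
#' @param displace_mag Displacement magnitude, Angstrom, default 1.5.
#' @param min_sep Minimum allowed distance between any two atoms of
#'   different residues, Angstrom, default 1.5; infeasible configurations
#'   raise a generation error.
#' @param seed Integer seed; the scene is a deterministic function of the
#'   configuration and seed.
#' @return A `synthetic_scene`: list with `structure_a`, `structure_b`
#'   (`noemix_structure`), `probe_sel`, `flip_angle`, `displaced` (residue
#'   numbers), `config`, `seed`.
#' @export
make_scene <- function(n_methyl = 8, dist_range = c(3, 8), flip_angle = 83,
                       n_displace = 3, displace_mag = 1.5, min_sep = 1.5,
                       seed = 1) {
  if (n_methyl < 1) stopf("need at least one methyl group")
  if (dist_range[1] <= min_sep || diff(dist_range) < 0)
    stopf("infeasible distance range")
  if (flip_angle < 0 || flip_angle > 180) stopf("flip angle outside [0, 180]")
  with_seed(seed, {
    probe_h <- c(0, 0, 0)
    probe_n <- c(0, 0, -1.01)
    rows <- list(
      data.frame(chain = "A", resno = 59L, resid = "TRP",
                 elety = c("NE1", "HE1"),
                 x = c(probe_n[1], probe_h[1]), y = c(probe_n[2], probe_h[2]),
                 z = c(probe_n[3], probe_h[3]), stringsAsFactors = FALSE))
    placed <- rbind(probe_h, probe_n)
    rand_dir <- function() {
      repeat {
        v <- stats::rnorm(3)
        if (vnorm(v) > 1e-3) return(unitv(v))
      }
    }
    for (k in seq_len(n_methyl)) {
      ok <- FALSE
      for (try in 1:200) {
        d <- stats::runif(1, dist_range[1], dist_range[2])
        cg <- probe_h + d * rand_dir()
        cb <- cg + 1.54 * rand_dir()
        axis <- unitv(cb - cg)
        ca <- cb + 1.54 * unitv(axis * cos(deg2rad(70.5)) +
                                perpv(axis) * sin(deg2rad(70.5)))
        cand <- rbind(cg, cb, ca)
        dmin <- min(apply(cand, 1, function(p)
          min(sqrt(rowSums(sweep(placed, 2, p)^2)))))
        if (dmin >= min_sep) { ok <- TRUE; break }
      }
      if (!ok) stopf("generation error: cannot place methyl %d without a clash (< %.1f A)",
                     k, min_sep)
      placed <- rbind(placed, cand)
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resno = 10L + k, resid = "VAL",
        elety = c("CG1", "CB", "CA"),
        x = cand[, 1], y = cand[, 2], z = cand[, 3], stringsAsFactors = FALSE)
    }
    atoms_a <- do.call(rbind, rows)
    rownames(atoms_a) <- NULL
    struct_a <- new_structure(atoms_a, label = "conformer_A")

    atoms_b <- atoms_a
    if (flip_angle > 0) {
      bond <- probe_h - probe_n
      Rm <- rotmat(perpv(bond), deg2rad(flip_angle))
      h_new <- probe_n + as.numeric(Rm %*% bond)
      ih <- which(atoms_b$elety == "HE1")
      atoms_b[ih, c("x", "y", "z")] <- h_new
    }
    displaced <- integer()
    if (n_displace > 0) {
      displaced <- sort(sample(10L + seq_len(n_methyl), min(n_displace, n_methyl)))
      for (rn in displaced) {
        shift <- displace_mag * rand_dir()
        i <- atoms_b$resno == rn
        atoms_b$x[i] <- atoms_b$x[i] + shift[1]
        atoms_b$y[i] <- atoms_b$y[i] + shift[2]
        atoms_b$z[i] <- atoms_b$z[i] + shift[3]
      }
    }
    struct_b <- new_structure(atoms_b, label = "conformer_B")
    structure(list(structure_a = struct_a, structure_b = struct_b,
                   probe_sel = "A:59:HE1", flip_angle = flip_angle,
                   displaced = displaced,
                   config = list(n_methyl = n_methyl, dist_range = dist_range,
                                 flip_angle = flip_angle,
                                 n_displace = n_displace,
                                 displace_mag = displace_mag,
                                 min_sep = min_sep),
                   seed = seed),
              class = "synthetic_scene")
  })
}

#' Write a scene's conformers (PDB) and ground truth (JSON) to a directory
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory.
#' @return Invisible character vector of files written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "conformer_A.pdb")
  fb <- file.path(dir, "conformer_B.pdb")
  ft <- file.path(dir, "scene_truth.json")
  write_structure_pdb(scene$structure_a, fa)
  write_structure_pdb(scene$structure_b, fb)
  jsonlite::write_json(
    list(probe_sel = scene$probe_sel, flip_angle = scene$flip_angle,
         displaced = scene$displaced, config = scene$config,
         seed = scene$seed),
    ft, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fa, fb, ft))
}

#' Simulate experimental NOE volumes from a scene
#'
#' Predicts per-conformer NOE tables under the chosen interaction model,
#' mixes them at the true population `p_star`, applies multiplicative
#' log-normal noise to the volumes, and renormalizes to the maximum.
#'
#' @param scene A `synthetic_scene`.
#' @param p_star True population of conformer A.
#' @param model Interaction model for the generating predictions.
#' @param sigma Log-normal noise level (standard deviation of log volume),
#'   default 0.05; `0` gives noise-free volumes.
#' @param cutoff Gating cutoff, Angstrom.
#' @param seed Integer seed for the noise draw.
#' @return An `experimental_noe_table` data frame (`chain`, `resnum`,
#'   `resname`, `methyl_atom`, `volume`); attributes `p_star`, `scale`,
#'   `truth` (noise-free volumes).
#' @export
simulate_noe_volumes <- function(scene, p_star = 0.2, model = "jump",
                                 sigma = 0.05, cutoff = 7, seed = 1) {
  if (p_star < 0 || p_star > 1) stopf("p_star must lie in [0, 1]")
  ta <- predict_noe_table(scene$structure_a, scene$probe_sel, model = model,
                          cutoff = cutoff)
  tb <- predict_noe_table(scene$structure_b, scene$probe_sel, model = model,
                          cutoff = cutoff)
  s <- cross_structure_scale(ta, tb)
  truth <- mixture_predict(ta, tb, s, p_star)
  v <- with_seed(seed, truth * exp(stats::rnorm(length(truth), 0, sigma)))
  v <- v / max(v)
  parts <- strsplit(names(truth), ":", fixed = TRUE)
  df <- data.frame(chain = vapply(parts, `[`, "", 1),
                   resnum = as.integer(vapply(parts, `[`, "", 2)),
                   resname = "VAL",
                   methyl_atom = vapply(parts, `[`, "", 3),
                   volume = unname(v), stringsAsFactors = FALSE)
  attr(df, "p_star") <- p_star
  attr(df, "scale") <- s
  attr(df, "truth") <- truth
  class(df) <- c("experimental_noe_table", "data.frame")
  df
}

#' Simulate 15N relaxation observables from known model-free parameters
#'
#' @param params Data frame with columns `residue`, `s_f2`, `s_s2`,
#'   `tau_e` (s).
#' @param tau_c Global tumbling time, s.
#' @param constants A `nucleus_constants`.
#' @param sigma Named vector of Gaussian noise s.d. for `R1`, `R2`, `NOE`
#'   (absolute units); default all zero (noise-free mode is exact).
#' @param seed Integer seed.
#' @return Data frame with `residue`, `R1`, `R2`, `NOE`, `field_MHz` plus
#'   the true parameters.
#' @export
simulate_relaxation <- function(params, tau_c,
                                constants = nucleus_constants(),
                                sigma = c(R1 = 0, R2 = 0, NOE = 0),
                                seed = 1) {
  base <- c(R1 = 0, R2 = 0, NOE = 0)
  if (is.null(names(sigma))) names(sigma) <- names(base)[seq_along(sigma)]
  base[names(sigma)] <- sigma
  sigma <- base
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      f <- forward_relaxation(params$s_f2[i], params$s_s2[i], params$tau_e[i],
                              tau_c, constants)
      data.frame(residue = params$residue[i],
                 R1 = f$R1 + stats::rnorm(1, 0, sigma[["R1"]]),
                 R2 = f$R2 + stats::rnorm(1, 0, sigma[["R2"]]),
                 NOE = f$NOE + stats::rnorm(1, 0, sigma[["NOE"]]),
                 field_MHz = constants$field_mhz,
                 true_s2 = f$S2, true_tau_e = params$tau_e[i])
    })
    do.call(rbind, rows)
  })
}

#' Simulate correlated shift-difference / linebroadening pairs
#'
#' Draws bivariate-normal pairs with a specified population correlation,
#' shifted well away from zero so both margins stay positive (as |delta
#' shift| and exchange broadening are), for exercising
#' [correlate_broadening()].
#'
#' @param n Number of residues.
#' @param r Population Pearson correlation.
#' @param seed Integer seed.
#' @param mean_dex,sd_dex,mean_dshift,sd_dshift Marginal location/scale
#'   (Hz and ppm).
#' @return Data frame with `resid`, `dex_hz`, `dshift`.
#' @export
simulate_broadening_pairs <- function(n, r, seed = 1,
                                      mean_dex = 3, sd_dex = 0.5,
                                      mean_dshift = 2, sd_dshift = 0.4) {
  if (abs(r) > 1) stopf("correlation must lie in [-1, 1]")
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    data.frame(resid = seq_len(n),
               dex_hz = mean_dex + sd_dex * z1,
               dshift = mean_dshift + sd_dshift * z2)
  })
}
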