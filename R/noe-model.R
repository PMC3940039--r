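# Relative methyl -> probe NOE volume prediction from structures under three
# interaction models: three-site methyl-jump generalized order parameter,
# methyl-carbon centroid, and mean-proton centroid.

#' Rigid isotropic Lorentzian spectral density
#'
#' \eqn{J(\omega) = (2/5)\,\tau_c / (1 + (\omega\tau_c)^2)}.
#'
#' @param omega Angular frequency, rad/s (vectorized).
#' @param tau_c Global rotational correlation time, s.
#' @return J(omega), s/rad.
#' @export
spectral_density_rigid <- function(omega, tau_c) {
  if (tau_c <= 0) stopf("tau_c must be positive")
  (2 / 5) * tau_c / (1 + (omega * tau_c)^2)
}

#' Initial NOE build-up rate factor
#'
#' The cross-relaxation frequency factor \eqn{6J(2\omega) - J(0)} that sets
#' the sign and initial slope of homonuclear NOE build-up for an isolated
#' proton pair.  Positive in the extreme-narrowing limit, negative for slow
#' tumbling; the zero crossing lies at \eqn{\omega\tau_c = \sqrt{5}/2}.
#'
#' @param tau_c Correlation time, s.
#' @param omega 1H Larmor angular frequency, rad/s.
#' @return Signed factor, s/rad.
#' @export
buildup_rate_factor <- function(tau_c, omega) {
  if (tau_c <= 0) stopf("tau_c must be positive")
  6 * spectral_density_rigid(2 * omega, tau_c) - spectral_density_rigid(0, tau_c)
}

#' Three-site methyl-jump effective cross-relaxation rate
#'
#' Angular-radial average of the dipolar interaction between a distal proton
#' and the three jump sites of a rotating methyl group,
#' \deqn{(1/18) \sum_{i=1}^{3}\sum_{j=1}^{3} [3\cos^2\theta_{ij} - 1] /
#'       (r_i^3 r_j^3),}
#' where \eqn{r_i} is the probe-to-proton-i distance and \eqn{\theta_{ij}}
#' the angle at the probe between protons i and j.  (The symmetric
#' \eqn{r_i^3 r_j^3} denominator is the pairwise dipolar contraction; a
#' single-distance \eqn{r_j^3} shorthand sometimes seen in print is
#' dimensionally inconsistent and does not recover the far-field
#' \eqn{1/r^6} limit.)  Units are Angstrom^-6; all physical prefactors cancel
#' in the normalized volume ratios used downstream.
#'
#' @param geometry Output of [methyl_probe_geometry()].
#' @return Raw rate, Angstrom^-6.
#' @export
jump_effective_rate <- function(geometry) {
  r <- geometry$r
  if (any(r <= 0)) stopf("domain error: non-positive probe-proton distance")
  cth <- cos(deg2rad(geometry$theta))
  P <- (3 * cth^2 - 1)
  w <- 1 / r^3
  sum(P * (w %o% w)) / 18
}

#' Centroid approximation to the methyl cross-relaxation rate
#'
#' Models the whole methyl group as a point at either the methyl carbon or
#' the mean methyl-proton position, with the familiar \eqn{1/r^6} distance
#' dependence.
#'
#' @param methyl A `methyl_group`.
#' @param probe A `probe_site` or position vector.
#' @param centroid `"carbon"` or `"mean-proton"`.
#' @return Raw rate, Angstrom^-6.
#' @export
centroid_rate <- function(methyl, probe, centroid = c("carbon", "mean-proton")) {
  centroid <- match.arg(centroid)
  p <- if (inherits(probe, "probe_site")) probe$position else as.numeric(probe)
  ctr <- if (centroid == "carbon") methyl$carbon else colMeans(methyl$protons)
  r <- vnorm(p - ctr)
  if (r < 1e-6) stopf("domain error: probe coincides with the methyl centroid")
  r^-6
}

#' Predict a relative NOE volume table for one structure
#'
#' Computes per-methyl raw cross-relaxation rates toward a single distal
#' probe proton under the chosen interaction model, gates methyls by the
#' methyl-carbon-to-probe distance, merges chemically-shift-degenerate methyl
#' pairs, and normalizes to the maximum entry.
#'
#' @param struct A `noemix_structure`.
#' @param probe_sel `"chain:resno:atom"` selection of the probe proton.
#' @param methyl_sel Optional selection restricting the methyl carbons.
#' @param model `"jump"`, `"carbon"`, or `"mean-proton"`.
#' @param cutoff Gating distance cutoff in Angstrom (methyl carbon to probe
#'   proton), default 7.
#' @param merge Optional degeneracy merge map: data frame with columns
#'   `from_resno`, `from_atom`, `to_resno`, `to_atom` (and optionally
#'   `from_chain`, `to_chain`); the raw rate of each `from` methyl is summed
#'   into its `to` entry before normalization.
#' @param exclude Optional character vector of `"chain:resno:atom"` methyl
#'   carbons to drop from the prediction even if within the cutoff.
#' @param use_explicit_protons Passed to [build_methyl_protons()].
#' @return A `noe_table`: data frame with columns `chain`, `resno`, `resname`,
#'   `methyl_atom`, `gating_distance_A`, `raw_rate`, `normalized_volume`,
#'   `merged_from`; attributes `label`, `model`, `cutoff`, `max_raw`.
#' @export
predict_noe_table <- function(struct, probe_sel, methyl_sel = NULL,
                              model = c("jump", "carbon", "mean-proton"),
                              cutoff = 7, merge = NULL, exclude = NULL,
                              use_explicit_protons = FALSE) {
  model <- match.arg(model)
  if (cutoff <= 0) stopf("cutoff must be positive")
  probe <- probe_site(struct, probe_sel)
  methyls <- build_methyl_protons(struct, selection = methyl_sel,
                                  use_explicit = use_explicit_protons)
  rows <- list()
  for (m in methyls) {
    key <- sprintf("%s:%d:%s", m$chain, m$resno, m$carbon_name)
    if (key %in% (exclude %||% character())) next
    gate <- vnorm(m$carbon - probe$position)
    if (gate > cutoff) next
    rate <- switch(model,
      "jump" = jump_effective_rate(methyl_probe_geometry(m, probe)),
      "carbon" = centroid_rate(m, probe, "carbon"),
      "mean-proton" = centroid_rate(m, probe, "mean-proton"))
    rows[[length(rows) + 1]] <- data.frame(
      chain = m$chain, resno = m$resno, resname = m$resid,
      methyl_atom = m$carbon_name, gating_distance_A = gate,
      raw_rate = rate, merged_from = "", stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning(sprintf("no methyl group within %.1f A of probe %s in '%s'",
                    cutoff, probe_sel, struct$label))
    tab <- data.frame(chain = character(), resno = integer(),
                      resname = character(), methyl_atom = character(),
                      gating_distance_A = numeric(), raw_rate = numeric(),
                      merged_from = character(), normalized_volume = numeric())
    return(.as_noe_table(tab, struct$label, model, cutoff, NA_real_))
  }
  tab <- do.call(rbind, rows)
  if (!is.null(merge)) tab <- .apply_merge_map(tab, merge)
  max_raw <- max(tab$raw_rate)
  tab$normalized_volume <- tab$raw_rate / max_raw
  tab <- tab[order(tab$chain, tab$resno, tab$methyl_atom), , drop = FALSE]
  rownames(tab) <- NULL
  .as_noe_table(tab, struct$label, model, cutoff, max_raw)
}

.as_noe_table <- function(tab, label, model, cutoff, max_raw) {
  attr(tab, "label") <- label
  attr(tab, "model") <- model
  attr(tab, "cutoff") <- cutoff
  attr(tab, "max_raw") <- max_raw
  class(tab) <- c("noe_table", "data.frame")
  tab
}

.apply_merge_map <- function(tab, merge) {
  for (i in seq_len(nrow(merge))) {
    fc <- merge$from_chain[i] %||% tab$chain[1]
    tc <- merge$to_chain[i] %||% tab$chain[1]
    fi <- which(tab$chain == fc & tab$resno == merge$from_resno[i] &
                tab$methyl_atom == merge$from_atom[i])
    ti <- which(tab$chain == tc & tab$resno == merge$to_resno[i] &
                tab$methyl_atom == merge$to_atom[i])
    if (!length(fi) || !length(ti)) next  # partner outside cutoff: nothing to merge
    tab$raw_rate[ti] <- tab$raw_rate[ti] + tab$raw_rate[fi]
    tab$merged_from[ti] <- paste0(tab$merged_from[ti],
                                  sprintf("%d:%s", merge$from_resno[i],
                                          merge$from_atom[i]))
    tab <- tab[-fi, , drop = FALSE]
  }
  tab
}

#' Inter-structure volume scale
#'
#' Ratio of the absolute maximum raw rates of two predicted tables,
#' `a / b`.  This is the factor that places two per-structure normalized
#' tables on a common absolute scale in a conformer mixture.
#'
#' @param a,b `noe_table` objects computed under the same interaction model.
#' @return Positive scalar.
#' @export
cross_structure_scale <- function(a, b) {
  if (!identical(attr(a, "model"), attr(b, "model")))
    stopf("configuration error: tables computed under different models (%s vs %s)",
          attr(a, "model"), attr(b, "model"))
  if (!nrow(a) || !nrow(b)) stopf("cross_structure_scale needs two non-empty tables")
  attr(a, "max_raw") / attr(b, "max_raw")
}

#' Write a predicted NOE table as TSV
#'
#' @param tab A `noe_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noe_table <- function(tab, path) {
  out <- cbind(structure_label = attr(tab, "label"), as.data.frame(tab))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a predicted NOE table (including its absolute scale) to JSON
#'
#' @param tab A `noe_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noe_table_json <- function(tab, path) {
  jsonlite::write_json(
    list(structure_label = attr(tab, "label"), model = attr(tab, "model"),
         cutoff_A = attr(tab, "cutoff"), max_raw_rate = attr(tab, "max_raw"),
         entries = as.data.frame(tab)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
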