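# Reference dataset: methyl -> Trp59 indole H(Ne1) NOESY volumes for
# wild-type FKBP12 together with the per-structure order-parameter
# predictions for the wild-type (2PPN) and G89P (4N19) crystal conformers.

#' FKBP12 methyl-indole NOE reference table
#'
#' Normalized experimental NOESY volumes for the nine methyl to Trp59 indole
#' H(Ne1) cross-peaks of wild-type FKBP12, with the published per-structure
#' generalized-order-parameter predictions (`pred_wt`, `pred_g89p`) and the
#' methyl-carbon to indole-proton gating distances (`dist_wt_A`,
#' `dist_g89p_A`) in the wild-type and G89P crystal conformers.  Methyls
#' beyond the 7 A cutoff in a given structure carry a zero prediction and an
#' `NA` distance for that structure; the Val101 CG1 entry is excluded from
#' the wild-type prediction although its gating distance (6.82 A) is inside
#' the cutoff.  The Val101 CG2 predictions include the chemical-shift
#' degenerate Val63 CG1 contribution.
#'
#' @return Data frame with columns `chain`, `resnum`, `resname`,
#'   `methyl_atom`, `volume`, `dist_wt_A`, `pred_wt`, `dist_g89p_A`,
#'   `pred_g89p`.
#' @seealso [fkbp12_volume_scale()], [fkbp12_merge_map()]
#' @export
fkbp12_noe_table <- function() {
  df <- data.frame(
    chain = "A",
    resnum = c(56L, 76L, 55L, 24L, 101L, 24L, 101L, 63L, 97L),
    resname = c("ILE", "ILE", "VAL", "VAL", "VAL", "VAL", "VAL", "VAL", "LEU"),
    methyl_atom = c("CD1", "CD1", "CG2", "CG2", "CG1", "CG1", "CG2", "CG2", "CD1"),
    volume = c(0.795, 0.828, 0.048, 0.460, 0.650, 0.308, 1.000, 0.651, 0.050),
    dist_wt_A  = c(4.38, 4.14, NA, NA, 6.82, NA, 4.98, 6.88, 6.27),
    pred_wt    = c(0.903, 1.000, 0, 0, 0, 0, 0.348, 0.054, 0.092),
    dist_g89p_A = c(NA, NA, 6.59, 3.89, 3.37, 4.54, 3.32, 3.60, NA),
    pred_g89p  = c(0, 0, 0.018, 0.661, 0.858, 0.173, 1.000, 0.613, 0),
    stringsAsFactors = FALSE
  )
  # guard against transcription drift of the reference values
  sums <- round(c(sum(df$volume), sum(df$pred_wt), sum(df$pred_g89p),
                  sum(df$dist_wt_A, na.rm = TRUE),
                  sum(df$dist_g89p_A, na.rm = TRUE)), 3)
  stopifnot(identical(sums, c(4.790, 2.397, 3.323, 33.470, 25.310)))
  class(df) <- c("experimental_noe_table", "data.frame")
  df
}

#' Inter-structure volume scale for the FKBP12 reference pair
#'
#' Ratio of the normalized-NOE volume scales between the wild-type and G89P
#' conformer predictions, as used in the reference mixture analysis.
#'
#' @return 0.28.
#' @export
fkbp12_volume_scale <- function() 0.28

#' Default degeneracy merge map for the FKBP12 reference analysis
#'
#' The Val63 CG1 resonance is chemically-shift degenerate with Val101 CG2;
#' its predicted rate is summed into the Val101 CG2 entry before
#' normalization (it contributes only ~4% of that predicted volume).
#'
#' @return Data frame usable as the `merge` argument of
#'   [predict_noe_table()].
#' @export
fkbp12_merge_map <- function() {
  data.frame(from_resno = 63L, from_atom = "CG1",
             to_resno = 101L, to_atom = "CG2", stringsAsFactors = FALSE)
}

# predicted per-structure tables from the reference data frame, as named
# volume vectors suitable for mixture_predict / fit_population
.fkbp12_pred <- function(which = c("wt", "g89p")) {
  which <- match.arg(which)
  df <- fkbp12_noe_table()
  v <- if (which == "wt") df$pred_wt else df$pred_g89p
  stats::setNames(v, sprintf("%s:%d:%s", df$chain, df$resnum, df$methyl_atom))
}

#' Run the FKBP12 two-conformer reference mixture fit
#'
#' Fits the wild-type-conformer population against the packaged experimental
#' methyl-indole NOE volumes using the packaged per-structure predictions
#' and volume scale.
#'
#' @param scale Inter-structure scale; default [fkbp12_volume_scale()].
#' @param grid_step Scan step, default 0.01.
#' @return A `mixture_fit` (see [fit_population()]).
#' @export
fkbp12_mixture_fit <- function(scale = fkbp12_volume_scale(), grid_step = 0.01) {
  df <- fkbp12_noe_table()
  fit_population(df, .fkbp12_pred("wt"), .fkbp12_pred("g89p"),
                 scale = scale, grid_step = grid_step)
}

#' FKBP12 carbon-centroid mixture fit from gating distances
#'
#' Rebuilds the per-structure predictions under the methyl-carbon centroid
#' approximation directly from the packaged carbon-to-probe distances
#' (raw rate r^-6, normalized per structure, scale = ratio of maximum raw
#' rates) and fits the population.
#'
#' @param grid_step Scan step, default 0.01.
#' @return A `mixture_fit`; the scale used is in `$scale`.
#' @export
fkbp12_carbon_mixture_fit <- function(grid_step = 0.01) {
  df <- fkbp12_noe_table()
  raw_wt <- ifelse(is.na(df$dist_wt_A) | df$pred_wt == 0, 0, df$dist_wt_A^-6)
  raw_gp <- ifelse(is.na(df$dist_g89p_A), 0, df$dist_g89p_A^-6)
  keys <- sprintf("%s:%d:%s", df$chain, df$resnum, df$methyl_atom)
  s <- max(raw_wt) / max(raw_gp)
  fit_population(df, stats::setNames(raw_wt / max(raw_wt), keys),
                 stats::setNames(raw_gp / max(raw_gp), keys),
                 scale = s, grid_step = grid_step)
}
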