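# Two-conformer population fitting of predicted against experimental
# normalized methyl-NOE volume tables.

# normalized-volume named vector keyed "chain:resno:atom" from a noe_table or
# a plain data frame with (chain?, resno|resnum, methyl_atom, volume-like col)
.volume_vector <- function(tab) {
  if (is.numeric(tab)) {
    if (is.null(names(tab))) stopf("a bare volume vector must be named by key")
    return(tab)
  }
  if (is.null(tab) || !nrow(tab)) return(numeric())
  df <- as.data.frame(tab)
  resno <- df$resno %||% df$resnum
  chain <- df$chain %||% rep("A", nrow(df))
  vol <- df$normalized_volume %||% df$volume
  if (is.null(resno) || is.null(df$methyl_atom) || is.null(vol))
    stopf("NOE table needs resno/resnum, methyl_atom and a volume column")
  stats::setNames(vol, sprintf("%s:%d:%s", chain, as.integer(resno), df$methyl_atom))
}

#' Predict mixture NOE volumes from two conformer tables
#'
#' Combines the per-structure normalized volumes of conformers A and B with
#' population `p` of A and the inter-structure volume scale,
#' \eqn{u(k) = p\,s\,A(k) + (1-p)\,B(k)}, over the union of entry keys
#' (a key absent from one table contributes zero from that conformer), then
#' renormalizes the result to its own maximum.
#'
#' @param table_a,table_b `noe_table` objects or data frames of normalized
#'   volumes for conformers A and B.
#' @param scale Inter-structure volume scale A/B (see
#'   [cross_structure_scale()]).
#' @param p Population of conformer A, in `[0, 1]`.
#' @return Named numeric vector of mixture volumes, maximum exactly 1.
#' @export
mixture_predict <- function(table_a, table_b, scale, p) {
  if (scale <= 0) stopf("scale must be positive")
  if (p < 0 || p > 1) stopf("population p must lie in [0, 1]")
  a <- .volume_vector(table_a); b <- .volume_vector(table_b)
  keys <- union(names(a), names(b))
  if (!length(keys)) stopf("empty union of NOE table keys")
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  u <- p * scale * av + (1 - p) * bv
  stats::setNames(u / max(u), keys)
}

.mixture_rmsd <- function(p, av, bv, scale, ev) {
  u <- p * scale * av + (1 - p) * bv
  sqrt(mean((u / max(u) - ev)^2))
}

#' Fit the conformer-A population to an experimental NOE table
#'
#' Scans the population of conformer A over a grid, computing the RMSD
#' between mixture-predicted and experimental normalized volumes over all
#' common entries (the self-normalizing maximum entry included), then refines
#' the grid argmin by golden-section search.  Grid ties are broken toward
#' larger `p`.
#'
#' @param experimental Experimental table (data frame with `resnum`/`resno`,
#'   `methyl_atom`, `volume`; see [read_noe_volumes()]) or a named volume
#'   vector.
#' @param table_a,table_b Predicted per-structure tables (as in
#'   [mixture_predict()]).
#' @param scale Inter-structure volume scale A/B.
#' @param grid_step Scan step for p, default 0.01.
#' @param refine_tol Golden-section refinement tolerance on p, default 1e-4.
#' @return A `mixture_fit` object: list with `p_opt`, `p_grid` (grid argmin),
#'   `rmsd`, `pearson_r`, `residuals` (data frame), `scan` (p, rmsd),
#'   `degenerate` flag, `n`.
#' @export
fit_population <- function(experimental, table_a, table_b, scale,
                           grid_step = 0.01, refine_tol = 1e-4) {
  ev_all <- if (is.numeric(experimental)) experimental
            else .volume_vector(experimental)
  a <- .volume_vector(table_a); b <- .volume_vector(table_b)
  keys <- union(union(names(a), names(b)), names(ev_all))
  common <- intersect(names(ev_all), keys)
  if (length(common) < 3)
    stopf("insufficient data: %d common entries, need >= 3", length(common))
  av <- stats::setNames(ifelse(keys %in% names(a), a[keys], 0), keys)
  bv <- stats::setNames(ifelse(keys %in% names(b), b[keys], 0), keys)
  # residuals are evaluated on the experimental keys; normalization is over
  # the full key union so the mixture maximum is self-consistent
  idx <- match(common, keys)
  f <- function(p) {
    u <- p * scale * av + (1 - p) * bv
    sqrt(mean((u[idx] / max(u) - ev_all[common])^2))
  }
  ps <- seq(0, 1, by = grid_step)
  rs <- vapply(ps, f, numeric(1))
  degenerate <- (max(rs) - min(rs)) < 1e-12
  if (degenerate) {
    p_grid <- 0.5
    p_opt <- 0.5
  } else {
    p_grid <- ps[max(which(rs == min(rs)))]  # ties toward larger p
    lo <- max(0, p_grid - grid_step); hi <- min(1, p_grid + grid_step)
    p_opt <- stats::optimize(f, c(lo, hi), tol = refine_tol)$minimum
    if (f(p_grid) <= f(p_opt)) p_opt <- p_grid
  }
  u <- p_opt * scale * av + (1 - p_opt) * bv
  pred <- (u / max(u))[idx]
  obs <- ev_all[common]
  r <- if (stats::sd(pred) < 1e-14 || stats::sd(obs) < 1e-14) NA_real_
       else stats::cor(pred, obs)
  res <- data.frame(key = common, observed = unname(obs),
                    predicted = unname(pred),
                    residual = unname(pred - obs), stringsAsFactors = FALSE)
  structure(list(p_opt = p_opt, p_grid = p_grid, rmsd = f(p_opt),
                 pearson_r = r, residuals = res,
                 scan = data.frame(p = ps, rmsd = rs),
                 degenerate = degenerate, n = length(common),
                 scale = scale, grid_step = grid_step),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Two-conformer mixture fit (N = %d entries)\n", x$n))
  if (x$degenerate)
    cat("  degenerate: RMSD independent of p; optimum reported at 0.5\n")
  cat(sprintf("  optimum p(A) = %.4f (grid argmin %.2f)\n", x$p_opt, x$p_grid))
  cat(sprintf("  RMSD = %.4f, Pearson r = %.4f, scale A/B = %.4g\n",
              x$rmsd, x$pearson_r, x$scale))
  invisible(x)
}

#' Evaluate the fit statistics at a fixed population
#'
#' @param fit A `mixture_fit`.
#' @param table_a,table_b,scale As in [fit_population()] (needed to
#'   recompute); alternatively pass the same arguments to [fit_population()]
#'   and read the scan.
#' @param experimental Experimental table.
#' @param p Population at which to report RMSD and r.
#' @return List with `p`, `rmsd`, `pearson_r`.
#' @export
mixture_stats_at <- function(experimental, table_a, table_b, scale, p) {
  ev <- if (is.numeric(experimental)) experimental else .volume_vector(experimental)
  pred_all <- mixture_predict(table_a, table_b, scale, p)
  common <- intersect(names(ev), names(pred_all))
  pred <- pred_all[common]; obs <- ev[common]
  list(p = p, rmsd = sqrt(mean((pred - obs)^2)),
       pearson_r = stats::cor(pred, obs))
}

#' Compare interaction models in the mixture fit
#'
#' Runs [predict_noe_table()] under each requested interaction model for both
#' structures, recomputes the inter-structure scale per model, fits the
#' population, and tabulates the results (jump model first).
#'
#' @param experimental Experimental NOE table.
#' @param struct_a,struct_b `noemix_structure` objects for the two conformers.
#' @param probe_sel Probe proton selection.
#' @param models Character vector of models to compare.
#' @param cutoff,merge,exclude_a,exclude_b Passed to [predict_noe_table()]
#'   (exclusions per structure).
#' @param scale Optional fixed scale; default recomputed per model.
#' @param grid_step Passed to [fit_population()].
#' @return Data frame with columns `model`, `p_opt`, `rmsd`, `pearson_r`;
#'   attribute `fits` holds the full `mixture_fit` objects.
#' @export
compare_models <- function(experimental, struct_a, struct_b, probe_sel,
                           models = c("jump", "carbon", "mean-proton"),
                           cutoff = 7, merge = NULL,
                           exclude_a = NULL, exclude_b = NULL,
                           scale = NULL, grid_step = 0.01) {
  models <- unique(c(intersect("jump", models), setdiff(models, "jump")))
  fits <- list()
  rows <- lapply(models, function(mo) {
    ta <- predict_noe_table(struct_a, probe_sel, model = mo, cutoff = cutoff,
                            merge = merge, exclude = exclude_a)
    tb <- predict_noe_table(struct_b, probe_sel, model = mo, cutoff = cutoff,
                            merge = merge, exclude = exclude_b)
    s <- scale %||% cross_structure_scale(ta, tb)
    ft <- fit_population(experimental, ta, tb, s, grid_step = grid_step)
    fits[[mo]] <<- ft
    data.frame(model = mo, p_opt = ft$p_opt, rmsd = ft$rmsd,
               pearson_r = ft$pearson_r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Read an experimental NOE volume table
#'
#' Tab- or comma-separated with a header containing at least
#' `resnum` (or `resno`), `methyl_atom` and `volume`; optional `chain`,
#' `resname`.
#'
#' @param path Input file.
#' @return Data frame of class `experimental_noe_table`.
#' @export
read_noe_volumes <- function(path) {
  if (!file.exists(path)) stopf("NOE volume table not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  v <- .volume_vector(df)  # validates columns
  if (abs(max(v) - 1) > 1e-9)
    warning("experimental volumes are not normalized to a maximum of 1")
  class(df) <- c("experimental_noe_table", "data.frame")
  df
}

#' Write a mixture fit result as JSON plus TSV side tables
#'
#' @param fit A `mixture_fit`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default `"mixture_fit"`.
#' @return Invisible character vector of the files written.
#' @export
write_mixture_fit <- function(fit, dir, stem = "mixture_fit") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fj <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(p_opt = fit$p_opt, p_grid = fit$p_grid, rmsd = fit$rmsd,
         pearson_r = fit$pearson_r, n = fit$n, scale = fit$scale,
         degenerate = fit$degenerate, residuals = fit$residuals,
         scan = fit$scan),
    fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fr <- file.path(dir, paste0(stem, "_residuals.tsv"))
  utils::write.table(fit$residuals, fr, sep = "\t", quote = FALSE, row.names = FALSE)
  fs <- file.path(dir, paste0(stem, "_scan.tsv"))
  utils::write.table(fit$scan, fs, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fj, fr, fs))
}
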