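# Differential chemical-shift aggregation between conformational models and
# correlation with measured conformational-exchange linebroadening.

#' Read a per-residue chemical-shift prediction table
#'
#' Parses the whitespace-delimited tabular output of structure-based
#' chemical-shift predictors (SPARTA+-style `pred.tab` dialect): optional
#' `REMARK`/`DATA` lines, a `VARS` line naming the columns, a `FORMAT` line
#' (ignored), then one row per residue/nucleus.  Without a `VARS` line the
#' default column order `RESID RESNAME ATOMNAME SS_SHIFT SHIFT RC_SHIFT
#' HM_SHIFT EF_SHIFT SIGMA` is assumed.
#'
#' @param path Input file.
#' @param label Source-structure label; default the file base name.
#' @param shift_col Which column carries the predicted shift, default
#'   `"SHIFT"`.
#' @return A `shift_prediction_table`: data frame with `resid`, `resname`,
#'   `atom`, `shift` (all nuclei retained); attribute `label`.
#' @export
read_shift_predictions <- function(path, label = NULL, shift_col = "SHIFT") {
  if (!file.exists(path)) stopf("prediction table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vars <- c("RESID", "RESNAME", "ATOMNAME", "SS_SHIFT", "SHIFT",
            "RC_SHIFT", "HM_SHIFT", "EF_SHIFT", "SIGMA")
  body <- character()
  for (ln in lines) {
    tok1 <- sub("^\\s*(\\S+).*$", "\\1", ln)
    if (tok1 %in% c("REMARK", "DATA", "FORMAT")) next
    if (tok1 == "VARS") {
      vars <- strsplit(trimws(sub("^\\s*VARS", "", ln)), "\\s+")[[1]]
      next
    }
    body <- c(body, ln)
  }
  if (!length(body)) stopf("parse error: %s contains no data rows", path)
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != length(vars))
      stopf("parse error at data row %d of %s: %d fields, expected %d",
            i, path, length(f), length(vars))
    f
  })
  m <- do.call(rbind, rows)
  colnames(m) <- vars
  if (!all(c("RESID", "ATOMNAME", shift_col) %in% vars))
    stopf("prediction table lacks RESID/ATOMNAME/%s columns", shift_col)
  df <- data.frame(resid = as.integer(m[, "RESID"]),
                   resname = if ("RESNAME" %in% vars) m[, "RESNAME"] else NA,
                   atom = m[, "ATOMNAME"],
                   shift = as.numeric(m[, shift_col]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$resid) || anyNA(df$shift))
    stopf("parse error in %s: non-numeric RESID or %s field", path, shift_col)
  dup <- duplicated(df[, c("resid", "atom")])
  if (any(dup))
    stopf("parse error in %s: duplicated residue/atom row(s): %s", path,
          paste(unique(sprintf("%d:%s", df$resid[dup], df$atom[dup])), collapse = ", "))
  attr(df, "label") <- label %||% sub("\\.[^.]*$", "", basename(path))
  class(df) <- c("shift_prediction_table", "data.frame")
  df
}

# 15N shift per residue as a named vector; residues with no N row are absent
.n15_shifts <- function(tab, nucleus = "N") {
  x <- tab[tab$atom == nucleus, , drop = FALSE]
  stats::setNames(x$shift, x$resid)
}

#' Differential chemical shifts between conformational models
#'
#' Computes per-residue absolute 15N shift differences between a reference
#' structure's predictions and one or more comparison structures',
#' either per comparison structure or against the mean over the comparison
#' structures.  Residue numbering differences are bridged by an explicit
#' mapping.  Residues not covered by the mapping, or missing a 15N
#' prediction in any table, are reported in the `skipped` attribute rather
#' than silently dropped.
#'
#' @param reference A `shift_prediction_table`.
#' @param comparisons A list of `shift_prediction_table`s.
#' @param mapping Optional data frame `(ref, comp)` of residue numbers
#'   pairing reference to comparison numbering (one-to-one); default
#'   identity on the shared residue numbers.
#' @param aggregate `"mean"` (|ref - mean over comparisons|) or
#'   `"per-structure"` (one column of |ref - comp| per comparison).
#' @param nucleus Atom name of the nucleus, default `"N"`.
#' @return Data frame with `resid` (reference numbering) and `dshift`
#'   column(s) in ppm; attribute `skipped` lists unmapped/missing residues.
#' @export
differential_shift <- function(reference, comparisons, mapping = NULL,
                               aggregate = c("mean", "per-structure"),
                               nucleus = "N") {
  aggregate <- match.arg(aggregate)
  if (inherits(comparisons, "shift_prediction_table"))
    comparisons <- list(comparisons)
  ref <- .n15_shifts(reference, nucleus)
  comp <- lapply(comparisons, .n15_shifts, nucleus = nucleus)
  if (is.null(mapping)) {
    shared <- Reduce(intersect, c(list(names(ref)), lapply(comp, names)))
    mapping <- data.frame(ref = as.integer(shared), comp = as.integer(shared))
  }
  if (anyDuplicated(mapping$ref) || anyDuplicated(mapping$comp))
    stopf("residue mapping must be one-to-one")
  ok <- as.character(mapping$ref) %in% names(ref) &
    Reduce(`&`, lapply(comp, function(cv) as.character(mapping$comp) %in% names(cv)))
  skipped <- mapping[!ok, , drop = FALSE]
  mp <- mapping[ok, , drop = FALSE]
  if (!nrow(mp)) stopf("no mapped residue has predictions in every table")
  rv <- ref[as.character(mp$ref)]
  cm <- vapply(comp, function(cv) cv[as.character(mp$comp)], numeric(nrow(mp)))
  cm <- matrix(cm, nrow = nrow(mp))
  out <- if (aggregate == "mean") {
    data.frame(resid = mp$ref, dshift = abs(rv - rowMeans(cm)))
  } else {
    d <- abs(rv - cm)
    colnames(d) <- paste0("dshift_", seq_len(ncol(d)))
    cbind(data.frame(resid = mp$ref), as.data.frame(d))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Correlate differential shifts with exchange linebroadening
#'
#' Pearson correlation between predicted per-residue |delta-shift| values
#' and measured conformational-exchange linebroadening, over residues whose
#' broadening passes the significance threshold and which are not explicitly
#' excluded (e.g. resonances made unreliable by rapid hydrogen exchange).
#'
#' @param dshift Data frame with `resid` and `dshift` (ppm), as from
#'   [differential_shift()] in mean mode.
#' @param dex Data frame with `resid` and `dex_hz` (Hz); optional logical
#'   `reliable` column.
#' @param threshold Significance threshold on `dex_hz`, Hz (default 0.4).
#' @param exclude Integer vector of residue numbers to exclude.
#' @return List with `r` (Pearson), `pairs` (the paired table used),
#'   and `bookkeeping` (counts of used / excluded-by-flag / below-threshold /
#'   unpaired residues, summing to the input residue count).
#' @export
correlate_broadening <- function(dshift, dex, threshold = 0.4, exclude = NULL) {
  if (is.null(dex$resid) || is.null(dex$dex_hz))
    stopf("dex table needs 'resid' and 'dex_hz' columns")
  n_in <- nrow(dex)
  flagged <- dex$resid %in% (exclude %||% integer()) |
    (!is.null(dex$reliable) & !(dex$reliable %||% TRUE))
  paired <- !flagged & dex$resid %in% dshift$resid
  below <- paired & dex$dex_hz < threshold
  use <- paired & !below
  pairs <- data.frame(resid = dex$resid[use],
                      dex_hz = dex$dex_hz[use],
                      dshift = dshift$dshift[match(dex$resid[use], dshift$resid)])
  if (nrow(pairs) < 3)
    stopf("insufficient data: %d pairs pass the threshold, need >= 3", nrow(pairs))
  list(r = stats::cor(pairs$dshift, pairs$dex_hz),
       pairs = pairs,
       bookkeeping = c(used = sum(use), excluded = sum(flagged),
                       below_threshold = sum(below),
                       unpaired = n_in - sum(use) - sum(flagged) - sum(below)))
}

#' Write correlation scatter pairs as TSV
#'
#' @param corr Output of [correlate_broadening()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_broadening_pairs <- function(corr, path) {
  utils::write.table(corr$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
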