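# Command-line pipeline: subcommand dispatcher chaining the analysis modules,
# with provenance output.  A thin executable wrapper ships in inst/cli/.

# parse "--key value" pairs (and bare "--flag") into a named list
.parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stopf("unexpected argument '%s' (expected --key value)", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      out[[key]] <- args[i + 1]; i <- i + 2
    } else {
      out[[key]] <- TRUE; i <- i + 1
    }
  }
  out
}

.cli_num <- function(opt, key, default = NULL) {
  v <- opt[[key]] %||% default
  if (is.null(v)) stopf("missing required option --%s", key)
  as.numeric(v)
}

.write_provenance <- function(dir, command, opt, seed = NULL) {
  cfg <- opt[order(names(opt))]
  jsonlite::write_json(
    list(command = command, config = cfg,
         config_hash = sum(utf8ToInt(paste(names(cfg), unlist(cfg), collapse = ";"))),
         package = "noemix",
         version = as.character(utils::packageVersion("noemix")),
         seed = seed),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `predict`, `fit`, `relax`, `jump`, `ddg`,
#' `shiftcorr` and `simulate` over the package's analysis functions.  Run
#' `noemix_cli("help")` for usage.  The installed script
#' `system.file("cli", "noemix", package = "noemix")` wraps this function
#' for shell use.
#'
#' @param args Character vector of arguments (subcommand first), as from
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly: 0 success, 2 validation error,
#'   3 computation failure.
#' @export
noemix_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: noemix <command> [--key value ...]",
    "commands:",
    "  predict   --structure FILE --probe CH:RES:ATOM [--model jump|carbon|mean-proton]",
    "            [--cutoff 7] [--out DIR]",
    "  fit       (--table1 | --exp TSV --pred-a TSV --pred-b TSV --scale S)",
    "            [--grid-step 0.01] [--out DIR]",
    "  relax     --r1 X --r2 X --noe X --tauc-ns X [--field-mhz 600]",
    "            [--csa-ppm -126] [--rnh-a 1.02] [--model extended|simple] [--out DIR]",
    "  jump      --pb X --theta X",
    "  ddg       --p1 X --p2 X [--temp 298.15]",
    "  shiftcorr --ref TAB --comp TAB[,TAB...] --dex TSV [--threshold 0.4] [--out DIR]",
    "  simulate  [--seed 1] [--p-star 0.2] [--sigma 0.05] --out DIR",
    sep = "\n")
  if (!length(args) || args[1] %in% c("help", "--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  status <- tryCatch({
    opt <- .parse_cli_args(args[-1])
    switch(cmd,
      predict = .cmd_predict(opt),
      fit = .cmd_fit(opt),
      relax = .cmd_relax(opt),
      jump = {
        s2 <- jump_order_parameter(.cli_num(opt, "pb"), .cli_num(opt, "theta"))
        cat(jsonlite::toJSON(list(S2 = s2), auto_unbox = TRUE, digits = NA), "\n")
        0L
      },
      ddg = {
        tt <- .cli_num(opt, "temp", 298.15)
        dd <- delta_delta_g(population_pair(.cli_num(opt, "p1"), tt),
                            population_pair(.cli_num(opt, "p2"), tt))
        cat(jsonlite::toJSON(list(ddG_kJ_mol = dd, temperature_K = tt),
                             auto_unbox = TRUE, digits = NA), "\n")
        0L
      },
      shiftcorr = .cmd_shiftcorr(opt),
      simulate = .cmd_simulate(opt),
      { message("unknown command: ", cmd, "\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing required|not found|matched|unknown|outside|lacks|must lie|unexpected",
              conditionMessage(e))) 2L else 3L
  })
  invisible(as.integer(status))
}

.cmd_predict <- function(opt) {
  if (is.null(opt$structure) || is.null(opt$probe))
    stopf("missing required option --structure/--probe")
  st <- read_structure(opt$structure)
  tab <- predict_noe_table(st, opt$probe,
                           model = opt$model %||% "jump",
                           cutoff = .cli_num(opt, "cutoff", 7))
  out <- opt$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_noe_table(tab, file.path(out, paste0(st$label, "_noe.tsv")))
  write_noe_table_json(tab, file.path(out, paste0(st$label, "_noe.json")))
  .write_provenance(out, "predict", opt)
  message(sprintf("predicted %d methyl entries (cutoff %.1f A, max raw rate %.4g)",
                  nrow(tab), attr(tab, "cutoff"), attr(tab, "max_raw")))
  0L
}

.cmd_fit <- function(opt) {
  fit <- if (isTRUE(opt$table1) || isTRUE(opt$reference)) {
    fkbp12_mixture_fit(scale = .cli_num(opt, "scale", fkbp12_volume_scale()),
                       grid_step = .cli_num(opt, "grid-step", 0.01))
  } else {
    if (is.null(opt$exp) || is.null(opt[["pred-a"]]) || is.null(opt[["pred-b"]]))
      stopf("missing required option --exp/--pred-a/--pred-b (or use --table1)")
    fit_population(read_noe_volumes(opt$exp),
                   utils::read.table(opt[["pred-a"]], header = TRUE, sep = "\t"),
                   utils::read.table(opt[["pred-b"]], header = TRUE, sep = "\t"),
                   scale = .cli_num(opt, "scale"),
                   grid_step = .cli_num(opt, "grid-step", 0.01))
  }
  out <- opt$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_mixture_fit(fit, out)
  .write_provenance(out, "fit", opt)
  print(fit)
  0L
}

.cmd_relax <- function(opt) {
  k <- nucleus_constants(field_mhz = .cli_num(opt, "field-mhz", 600),
                         r_nh = .cli_num(opt, "rnh-a", 1.02),
                         csa_ppm = .cli_num(opt, "csa-ppm", -126))
  fit <- fit_modelfree(.cli_num(opt, "r1"), .cli_num(opt, "r2"),
                       .cli_num(opt, "noe"),
                       tau_c = .cli_num(opt, "tauc-ns") * 1e-9,
                       constants = k, model = opt$model %||% "extended")
  if (!is.null(opt$out)) {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_modelfree_fit(fit, file.path(opt$out, "modelfree_fit.json"))
    .write_provenance(opt$out, "relax", opt)
  }
  print(fit)
  0L
}

.cmd_shiftcorr <- function(opt) {
  if (is.null(opt$ref) || is.null(opt$comp) || is.null(opt$dex))
    stopf("missing required option --ref/--comp/--dex")
  ref <- read_shift_predictions(opt$ref)
  comps <- lapply(strsplit(opt$comp, ",")[[1]], read_shift_predictions)
  ds <- differential_shift(ref, comps, aggregate = "mean")
  dex <- utils::read.table(opt$dex, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  corr <- correlate_broadening(ds, dex,
                               threshold = .cli_num(opt, "threshold", 0.4))
  if (!is.null(opt$out)) {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_broadening_pairs(corr, file.path(opt$out, "shiftcorr_pairs.tsv"))
    .write_provenance(opt$out, "shiftcorr", opt)
  }
  cat(jsonlite::toJSON(list(r = corr$r, bookkeeping = as.list(corr$bookkeeping)),
                       auto_unbox = TRUE, digits = NA), "\n")
  0L
}

.cmd_simulate <- function(opt) {
  if (is.null(opt$out)) stopf("missing required option --out")
  seed <- as.integer(.cli_num(opt, "seed", 1))
  scene <- make_scene(seed = seed)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  write_scene(scene, opt$out)
  vols <- simulate_noe_volumes(scene, p_star = .cli_num(opt, "p-star", 0.2),
                               sigma = .cli_num(opt, "sigma", 0.05),
                               seed = seed)
  utils::write.table(vols, file.path(opt$out, "noe_volumes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_provenance(opt$out, "simulate", opt, seed = seed)
  message("scene written to ", opt$out)
  0L
}
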