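# Orchestration: phantom cohort -> morphometry -> detectors -> fusion ->
# vertebra-wise evaluation, with all artifacts written to an output directory.

#' Run a full screening experiment on a phantom cohort
#'
#' Generates (or loads) a cohort of spines, measures every vertebra, derives
#' height-based (HLR/Genant) calls, runs the contour-irregularity detector
#' and any configured emulated detectors, fuses the height-based calls with
#' each detector under the configured fusion modes, and evaluates everything
#' vertebra-wise (confusion matrices, metric tables with Wilson CIs, ROC).
#'
#' The configuration is a named list (see \code{\link{readRunConfig}}):
#' \describe{
#'   \item{seed}{integer; every random draw is derived from it.}
#'   \item{cohort}{list: \code{n_spines}, \code{acute_rate},
#'     \code{chronic_rate}, \code{level_range}. Alternatively give
#'     \code{masks} (character vector of mask paths) plus \code{truth}
#'     (truth CSV paths) instead of \code{cohort}.}
#'   \item{measurement}{list: \code{sampling_fractions}, \code{axis_method},
#'     \code{hlr_variant}.}
#'   \item{contour_detector}{list: \code{threshold}, \code{jump_threshold},
#'     \code{r0}, \code{d0}; set to NULL to skip.}
#'   \item{emulated_detectors}{named list of \code{list(sens=, spec=)}.}
#'   \item{fusion_modes}{character subset of complement_negative,
#'     confirm_positive.}
#'   \item{out_dir}{output directory (created).}
#' }
#'
#' @param config named list (or path to a YAML file).
#' @return invisibly, a list with the vertebra table, per-method confusion
#'   matrices and metric tables, and ROC curves.
#' @export
runExperiment <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  margs <- list()
  if (!is.null(config$measurement$sampling_fractions))
    margs$samplingFractions <- as.numeric(config$measurement$sampling_fractions)
  if (!is.null(config$measurement$axis_method))
    margs$axisMethod <- config$measurement$axis_method
  if (!is.null(config$measurement$hlr_variant))
    margs$hlrVariant <- config$measurement$hlr_variant
  mcfg <- do.call(measurementConfig, margs)

  # --- inputs: phantom cohort or user-supplied masks -------------------
  if (!is.null(config$cohort) && !is.null(config$masks))
    stop("config error: give exactly one of cohort or masks")
  if (!is.null(config$cohort)) {
    cc <- config$cohort
    specs <- sampleCohortSpecs(
      nSpines = cc$n_spines %||% 40L,
      acuteRate = cc$acute_rate %||% (148 / 1030),
      chronicRate = cc$chronic_rate %||% 0.08,
      levelRange = as.integer(cc$level_range %||% c(5L, 8L)),
      seed = seed)
    phantoms <- lapply(specs, buildPhantom)
    masks <- lapply(phantoms, rasterizePhantom)
    truth <- unlist(lapply(phantoms, truthAcute))
  } else if (!is.null(config$masks)) {
    masks <- lapply(config$masks, readMask)
    truthTabs <- lapply(config$truth, utils::read.csv)
    truth <- unlist(lapply(truthTabs, function(t) as.logical(t$acute)))
    phantoms <- NULL
  } else stop("config error: give one of cohort or masks")

  # --- per-vertebra measurement and detector scores --------------------
  perSpine <- lapply(seq_along(masks), function(i) {
    tab <- measureSpine(masks[[i]], mcfg)
    tab$spine <- i
    tab
  })
  vert <- do.call(rbind, perSpine)
  vert$truth_acute <- truth
  nVert <- nrow(vert)
  vert$vertebra <- seq_len(nVert)

  callSets <- list()
  callSets$hlr <- data.frame(level = vert$vertebra, positive = vert$vcf_flag,
                             score = pmin(pmax(vert$hlr / 100, 0), 1))

  if (!identical(config$contour_detector, FALSE)) {
    cd <- config$contour_detector %||% list()
    sc <- do.call(rbind, lapply(masks, function(m)
      scoreSpine(m, jumpThreshold = cd$jump_threshold %||% 2,
                 r0 = cd$r0 %||% IRREG_R0, d0 = cd$d0 %||% IRREG_D0)))
    callSets$contour <- callFromScores(sc$score, cd$threshold %||% 0.5,
                                       levels = vert$vertebra)
    vert$contour_score <- sc$score
    vert$contour_positive <- callSets$contour$positive
  }

  for (nm in names(config$emulated_detectors)) {
    ed <- config$emulated_detectors[[nm]]
    calls <- emulateDetector(truth, sens = ed$sens, spec = ed$spec,
                             seed = seed + match(nm, names(config$emulated_detectors)))
    calls$level <- vert$vertebra
    callSets[[nm]] <- calls
    vert[[paste0(nm, "_positive")]] <- calls$positive
    vert[[paste0(nm, "_score")]] <- calls$score
  }

  # --- fusion -----------------------------------------------------------
  modes <- config$fusion_modes %||% c("complement_negative", "confirm_positive")
  fused <- list()
  for (nm in setdiff(names(callSets), "hlr")) {
    for (mode in modes) {
      fname <- paste0("hlr_", if (mode == "complement_negative") "neg" else "pos",
                      "_", nm)
      fused[[fname]] <- fuseCalls(callSets$hlr, callSets[[nm]], mode)
      vert[[paste0(fname, "_positive")]] <- fused[[fname]]$positive
    }
  }
  allSets <- c(callSets, fused)

  # --- evaluation -------------------------------------------------------
  confusions <- lapply(allSets, function(cs) confusionMatrix(truth, cs))
  metrics <- lapply(names(confusions), function(nm) {
    mt <- metricTable(confusions[[nm]], digits = 2)
    mt$method <- nm
    mt[c("method", setdiff(names(mt), "method"))]
  })
  metricTab <- do.call(rbind, metrics)

  rocs <- lapply(allSets, function(cs) {
    if (!is.null(cs$score) && length(unique(truth)) == 2)
      rocCurve(truth, cs$score) else NULL
  })

  # --- artifacts --------------------------------------------------------
  writeVertebraTable(vert, file.path(outDir, "vertebra_table.csv"))
  utils::write.csv(metricTab, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  cmJson <- lapply(confusions, function(cm) as.list(counts(cm)))
  jsonlite::write_json(cmJson, file.path(outDir, "confusion_matrices.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(rocs)) {
    if (is.null(rocs[[nm]])) next
    utils::write.csv(rocPoints(rocs[[nm]]),
                     file.path(outDir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  logLines <- c(
    sprintf("seed: %d", seed),
    sprintf("vertebrae: %d (acute %d, normal %d)", nVert, sum(truth),
            sum(!truth)),
    sprintf("methods: %s", paste(names(allSets), collapse = ", ")),
    sprintf("config: %s", jsonlite::toJSON(config, auto_unbox = TRUE)))
  writeLines(logLines, file.path(outDir, "run_log.txt"))

  invisible(list(vertebra_table = vert, confusions = confusions,
                 metrics = metricTab, rocs = rocs, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
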