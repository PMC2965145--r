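#' Run the full multimodel-inference analysis
#'
#' For each of the four response/guild combinations (specialist and
#' generalist x abundance and richness) fits the eight candidate models to
#' the fragmented-landscape sites and builds an AICc selection table; also
#' computes the diversity report (accumulation curves, richness estimates,
#' Bray-Curtis similarity, representation against paired controls) for both
#' guilds. Reports are written as tab-separated text when \code{outdir} is
#' given, together with a run log recording the seed and configuration.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   elements: either \code{input_dir} (study tables readable by
#'   \code{\link{readStudy}}) or \code{scenario} (a preset name from
#'   \code{\link{presetScenarios}}, a scenario JSON path, or a
#'   \linkS4class{Scenario}) optionally paired with
#'   \code{generalist_scenario}; \code{seed} (default 1); \code{link}
#'   ("log"); \code{n_starts} (5); \code{outdir} (optional)
#' @return invisibly, list(study, selection, fits, diversity, log)
#' @export
runAnalysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config)
  cfg <- utils::modifyList(list(seed = 1L, link = "log", n_starts = 5L,
                                outdir = NULL), config)
  log_lines <- c(sprintf("INFO seed=%d link=%s n_starts=%d", cfg$seed,
                         cfg$link, cfg$n_starts))
  withCallingHandlers({
    study <- .resolveStudy(cfg)
  }, warning = function(w) {
    log_lines <<- c(log_lines, paste("WARNING", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  log_lines <- c(log_lines, sprintf("INFO study: %d species, %d sites",
                                    nrow(study), ncol(study)))
  L <- landscapeOrder(study)
  combos <- expand.grid(guild = c("specialist", "generalist"),
                        response = c("abundance", "richness"),
                        stringsAsFactors = FALSE)
  fits <- list()
  selection <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$guild[i]; r <- combos$response[i]
    key <- paste(g, r, sep = "_")
    resp <- aggregateResponses(study, g, fragmented_only = TRUE)
    models <- enumerateCandidates(L, r)
    ff <- list()
    for (m in models) {
      f <- withCallingHandlers(
        tryCatch(fitModel(m, resp, link = cfg$link,
                          n_starts = cfg$n_starts),
                 error = function(e) {
                   log_lines <<- c(log_lines, sprintf(
                     "WARNING %s model %s failed: %s", key, m@model_id,
                     conditionMessage(e)))
                   NULL
                 }),
        warning = function(w) {
          log_lines <<- c(log_lines, sprintf("WARNING %s model %s: %s", key,
                                             m@model_id, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      if (!is.null(f)) ff[[m@model_id]] <- f
    }
    fits[[key]] <- ff
    selection[[key]] <- withCallingHandlers(
      buildSelectionTable(ff),
      warning = function(w) {
        log_lines <<- c(log_lines, sprintf("WARNING %s: %s", key,
                                           conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    log_lines <- c(log_lines, sprintf("INFO %s: best model %s (w = %.3f)",
                                      key, selection[[key]]$model_id[1],
                                      selection[[key]]$weight[1]))
  }
  diversity <- list(specialist = diversityReport(study, "specialist"),
                    generalist = diversityReport(study, "generalist"))
  out <- list(study = study, selection = selection, fits = fits,
              diversity = diversity, log = log_lines)
  if (!is.null(cfg$outdir)) .writeReports(out, cfg)
  invisible(out)
}

.resolveStudy <- function(cfg) {
  if (!is.null(cfg$input_dir)) return(readStudy(cfg$input_dir))
  if (is.null(cfg$scenario))
    stop("config must name input_dir or scenario")
  sc <- cfg$scenario
  if (is.character(sc))
    sc <- if (file.exists(sc)) readScenario(sc) else
      presetScenarios(seed = cfg$seed)[[sc]]
  if (is.null(sc)) stop("unknown scenario in config")
  gsc <- cfg$generalist_scenario
  if (is.null(gsc))
    gsc <- presetScenarios(seed = cfg$seed)[["generalist_release"]]
  else if (is.character(gsc))
    gsc <- if (file.exists(gsc)) readScenario(gsc) else
      presetScenarios(seed = cfg$seed)[[gsc]]
  generateStudy(sc, gsc, seed = cfg$seed)
}

.writeReports <- function(res, cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(res$selection)) {
    writeSelectionTable(res$selection[[key]],
                        file.path(cfg$outdir,
                                  sprintf("selection_%s.tsv", key)))
    co <- do.call(rbind, lapply(res$fits[[key]], function(f)
      data.frame(M = f@model@model_id, coefficient = names(f@params),
                 estimate = sprintf("%.6f", f@params))))
    utils::write.table(co, file.path(cfg$outdir,
                                     sprintf("coefficients_%s.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (g in names(res$diversity)) {
    dv <- res$diversity[[g]]
    curves <- do.call(rbind, lapply(names(dv$curves), function(id) {
      cu <- dv$curves[[id]]
      if (is.null(cu)) return(NULL)
      cbind(landscape_id = id, cu)
    }))
    if (!is.null(curves))
      utils::write.table(
        format(curves, digits = 6),
        file.path(cfg$outdir, sprintf("accumulation_%s.tsv", g)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format(dv$richness, digits = 6),
                       file.path(cfg$outdir, sprintf("richness_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(round(dv$similarity, 3),
                       file.path(cfg$outdir, sprintf("similarity_%s.tsv", g)),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(format(dv$representation, digits = 6),
                       file.path(cfg$outdir,
                                 sprintf("representation_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(res$log, file.path(cfg$outdir, "run_log.txt"))
  invisible(NULL)
}

#' Simulate-and-recover harness
#'
#' Generates replicate studies under one scenario, fits the full candidate
#' set to the scenario's guild/abundance response per replicate, and records
#' which model attains the lowest AICc and the Akaike weight of the
#' generating model. The summary fraction of replicates in which the
#' generating model is best is attached as an attribute and printed by the
#' returned data.frame's summary.
#'
#' @param scenario a \linkS4class{Scenario}
#' @param seeds integer vector, one RNG seed per replicate
#' @param link,n_starts passed to \code{\link{fitModel}}
#' @return data.frame(replicate, seed, best_model, weight_generating,
#'   generating_best, generating_plausible) with attribute
#'   \code{fraction_best}
#' @export
simulateAndRecover <- function(scenario, seeds, link = "log", n_starts = 5L) {
  rows <- lapply(seq_along(seeds), function(i) {
    x <- generateScenario(scenario, seed = seeds[i])
    resp <- aggregateResponses(x, scenario@guild, fragmented_only = TRUE)
    models <- enumerateCandidates(landscapeOrder(x), "abundance")
    fits <- lapply(models, function(m)
      tryCatch(suppressWarnings(fitModel(m, resp, link = link,
                                         n_starts = n_starts)),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    tab <- suppressWarnings(buildSelectionTable(fits))
    gi <- match(scenario@generating_model, tab$model_id)
    data.frame(replicate = i, seed = seeds[i],
               best_model = tab$model_id[1],
               weight_generating = if (is.na(gi)) NA_real_ else tab$weight[gi],
               generating_best = identical(tab$model_id[1],
                                           scenario@generating_model),
               generating_plausible = if (is.na(gi)) FALSE else
                 tab$plausible[gi])
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction_best") <- mean(out$generating_best)
  out
}
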