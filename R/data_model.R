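#' Construct a CaptureExperiment from study tables
#'
#' Assembles the central container from four plain data.frames mirroring the
#' delimited study tables: \code{sites} (site_id, landscape_id, patch_area_ha,
#' is_control), \code{species} (species_id, guild), \code{captures} (site_id,
#' species_id, year in {1,2}, individuals), and \code{landscapes}
#' (landscape_id, forest_cover_percent, is_control, paired_with). Capture
#' entries are cross-validated against the site and species tables;
#' unsurveyed combinations are zero-filled so that every surveyed site is a
#' data point (dropping empty sites would bias constant-model MLEs).
#'
#' @param captures data.frame of capture entries; at most one row per
#'   (site, species, year); individuals must be non-negative integers
#' @param sites data.frame of surveyed sites
#' @param species data.frame of species traits (guild)
#' @param landscapes data.frame of landscape attributes
#' @return a \linkS4class{CaptureExperiment}
#' @examples
#' stud <- generateScenario(presetScenarios()[["regime_shift"]])
#' stud
#' @export
CaptureExperiment <- function(captures, sites, species, landscapes) {
  sites <- as.data.frame(sites)
  species <- as.data.frame(species)
  captures <- as.data.frame(captures)
  landscapes <- as.data.frame(landscapes)
  sites$site_id <- as.character(sites$site_id)
  species$species_id <- as.character(species$species_id)
  landscapes$landscape_id <- as.character(landscapes$landscape_id)
  if (anyDuplicated(sites$site_id))
    stop("duplicated site_id in site table")
  if (anyDuplicated(species$species_id))
    stop("duplicated species_id in species table")

  if (nrow(captures)) {
    captures$site_id <- as.character(captures$site_id)
    captures$species_id <- as.character(captures$species_id)
    bad <- which(!captures$site_id %in% sites$site_id)
    if (length(bad))
      stop("capture row ", bad[1], " references unknown site '",
           captures$site_id[bad[1]], "'")
    bad <- which(!captures$species_id %in% species$species_id)
    if (length(bad))
      stop("capture row ", bad[1], " references unknown species '",
           captures$species_id[bad[1]], "'")
    bad <- which(!captures$year %in% c(1L, 2L))
    if (length(bad))
      stop("capture row ", bad[1], ": year must be 1 or 2")
    bad <- which(is.na(captures$individuals) | captures$individuals < 0 |
                 captures$individuals != round(captures$individuals))
    if (length(bad))
      stop("capture row ", bad[1],
           ": individuals must be a non-negative integer (got ",
           captures$individuals[bad[1]], ")")
    key <- paste(captures$site_id, captures$species_id, captures$year)
    if (anyDuplicated(key))
      stop("duplicate capture entry for (site, species, year): ",
           key[anyDuplicated(key)])
  }

  mk <- function(yr) {
    m <- matrix(0L, nrow = nrow(species), ncol = nrow(sites),
                dimnames = list(species$species_id, sites$site_id))
    cc <- captures[captures$year == yr, , drop = FALSE]
    if (nrow(cc))
      m[cbind(cc$species_id, cc$site_id)] <- as.integer(cc$individuals)
    m
  }
  cd <- DataFrame(
    site_id = sites$site_id,
    landscape_id = as.character(sites$landscape_id),
    patch_area_ha = as.numeric(sites$patch_area_ha),
    log10_area = ifelse(is.na(sites$patch_area_ha), NA_real_,
                        log10(as.numeric(sites$patch_area_ha))),
    is_control = as.logical(sites$is_control),
    row.names = sites$site_id)
  rd <- DataFrame(species_id = species$species_id,
                  guild = as.character(species$guild),
                  row.names = species$species_id)
  se <- SummarizedExperiment(
    assays = SimpleList(year1 = mk(1L), year2 = mk(2L)),
    rowData = rd, colData = cd,
    metadata = list(landscapes = landscapes))
  new("CaptureExperiment", se)
}

#' @describeIn CaptureExperiment compact display
#' @param object a CaptureExperiment
#' @export
setMethod("show", "CaptureExperiment", function(object) {
  cd <- colData(object)
  ls <- metadata(object)$landscapes
  cat("CaptureExperiment:", nrow(object), "species x", ncol(object), "sites\n")
  cat("  guilds:", paste(sprintf("%s (%d)", names(table(rowData(object)$guild)),
                                 table(rowData(object)$guild)), collapse = ", "), "\n")
  cat("  fragmented sites:", sum(!cd$is_control),
      " control sites:", sum(cd$is_control), "\n")
  fragl <- ls[!ls$is_control, , drop = FALSE]
  fragl <- fragl[order(-fragl$forest_cover_percent), , drop = FALSE]
  cat("  fragmented landscapes (by cover):",
      paste(sprintf("%s (%g%%)", fragl$landscape_id,
                    fragl$forest_cover_percent), collapse = ", "), "\n")
  cat("  total individuals:",
      sum(assay(object, "year1")) + sum(assay(object, "year2")), "\n")
  invisible(NULL)
})

#' Landscape table of a study
#'
#' @param x a CaptureExperiment
#' @return data.frame(landscape_id, forest_cover_percent, is_control,
#'   paired_with)
#' @export
landscapeInfo <- function(x) metadata(x)$landscapes

#' Fragmented landscape ids ordered from most to least forested
#'
#' The total order induced by percent forest cover ("most forested",
#' "intermediate", "most deforested") that the candidate-model catalogue is
#' defined over.
#' @param x a CaptureExperiment
#' @return character vector of length >= 1
#' @export
landscapeOrder <- function(x) {
  ls <- landscapeInfo(x)
  fragl <- ls[!ls$is_control, , drop = FALSE]
  fragl$landscape_id[order(-fragl$forest_cover_percent)]
}

#' Site table of a study
#'
#' @param x a CaptureExperiment
#' @param fragmented_only drop control (continuous forest) sites?
#' @return data.frame of site covariates
#' @export
siteInfo <- function(x, fragmented_only = FALSE) {
  cd <- as.data.frame(colData(x))
  if (fragmented_only) cd <- cd[!cd$is_control, , drop = FALSE]
  cd
}

#' Species guild assignments
#'
#' @param x a CaptureExperiment
#' @return named character vector, species_id -> guild
#' @export
speciesGuild <- function(x) {
  stats::setNames(as.character(rowData(x)$guild), rownames(x))
}

#' Read a study from delimited text tables
#'
#' Reads the four comma-separated UTF-8 tables (header row) written by
#' \code{\link{writeStudy}}: \code{sites.csv}, \code{species.csv},
#' \code{captures.csv}, \code{landscapes.csv}.
#'
#' @param dir directory containing the tables, or
#' @param site_path,species_path,capture_path,landscape_path explicit paths
#'   (override \code{dir})
#' @return a \linkS4class{CaptureExperiment}
#' @export
readStudy <- function(dir = NULL, site_path = file.path(dir, "sites.csv"),
                      species_path = file.path(dir, "species.csv"),
                      capture_path = file.path(dir, "captures.csv"),
                      landscape_path = file.path(dir, "landscapes.csv")) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  CaptureExperiment(captures = rd(capture_path), sites = rd(site_path),
                    species = rd(species_path), landscapes = rd(landscape_path))
}

#' Write a study to delimited text tables
#'
#' Emits the same dialect \code{\link{readStudy}} consumes (comma-separated,
#' UTF-8, header row). Zero-count capture entries are not written; the
#' reader restores them, so a writer-to-reader round trip preserves the study.
#'
#' @param x a CaptureExperiment
#' @param dir output directory (created if needed)
#' @return invisibly, the four file paths
#' @export
writeStudy <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cd <- siteInfo(x)
  sites <- data.frame(site_id = cd$site_id, landscape_id = cd$landscape_id,
                      patch_area_ha = cd$patch_area_ha,
                      is_control = cd$is_control)
  species <- data.frame(species_id = rownames(x),
                        guild = as.character(rowData(x)$guild))
  caps <- do.call(rbind, lapply(c(1L, 2L), function(yr) {
    m <- assay(x, paste0("year", yr))
    idx <- which(m > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(site_id = colnames(m)[idx[, 2]],
               species_id = rownames(m)[idx[, 1]],
               year = yr, individuals = m[idx])
  }))
  if (is.null(caps))
    caps <- data.frame(site_id = character(), species_id = character(),
                       year = integer(), individuals = integer())
  caps <- caps[order(caps$site_id, caps$species_id, caps$year), , drop = FALSE]
  paths <- file.path(dir, c("sites.csv", "species.csv", "captures.csv",
                            "landscapes.csv"))
  wr <- function(d, p) utils::write.csv(d, p, row.names = FALSE, quote = FALSE,
                                        fileEncoding = "UTF-8")
  wr(sites, paths[1]); wr(species, paths[2]); wr(caps, paths[3])
  wr(landscapeInfo(x), paths[4])
  invisible(paths)
}

#' Per-site abundance and richness responses for one guild
#'
#' Abundance is the total number of individuals of the guild captured at the
#' site over both years. The richness response is the per-year species counts
#' summed over the two years — i.e. twice the mean yearly richness, always an
#' integer — to be modelled with a multiplicative offset of 2 so that fitted
#' means are expressed per sampling year. Sites with no captures of the guild
#' appear as explicit zero rows.
#'
#' @param x a CaptureExperiment
#' @param guild "specialist" or "generalist"
#' @param fragmented_only keep only fragmented-landscape sites (the model
#'   fitting default); control sites are used for diversity statistics only
#' @return data.frame(site_id, landscape_id, log10_area, abundance,
#'   richness_response, offset) with one row per retained site
#' @export
aggregateResponses <- function(x, guild = c("specialist", "generalist"),
                               fragmented_only = TRUE) {
  guild <- match.arg(guild)
  g <- as.character(rowData(x)$guild)
  if (!any(g == guild))
    stop("no species of guild '", guild, "' in the trait table")
  keep <- g == guild
  y1 <- assay(x, "year1")[keep, , drop = FALSE]
  y2 <- assay(x, "year2")[keep, , drop = FALSE]
  cd <- siteInfo(x)
  out <- data.frame(
    site_id = cd$site_id,
    landscape_id = cd$landscape_id,
    log10_area = cd$log10_area,
    abundance = as.integer(colSums(y1) + colSums(y2)),
    richness_response = as.integer(colSums(y1 > 0) + colSums(y2 > 0)),
    offset = 2L,
    row.names = NULL)
  if (fragmented_only) out <- out[!cd$is_control, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trapping-effort arithmetic of the even-effort design
#'
#' @param n_traps_per_site pitfall traps per site
#' @param n_sessions capture sessions per site
#' @param nights_per_session nights per session
#' @param n_sites surveyed sites
#' @return list(nights_per_site, trapnights_per_site, trapnights_total)
#' @examples
#' samplingEffort(11, 4, 8, 68)  # 32 nights, 352 and 23936 trap-nights
#' @export
samplingEffort <- function(n_traps_per_site, n_sessions, nights_per_session,
                           n_sites) {
  a <- c(n_traps_per_site, n_sessions, nights_per_session, n_sites)
  if (any(a <= 0) || any(a != round(a)))
    stop("all effort arguments must be positive integers")
  nights <- n_sessions * nights_per_session
  tn_site <- n_traps_per_site * nights
  list(nights_per_site = nights, trapnights_per_site = tn_site,
       trapnights_total = tn_site * n_sites)
}
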