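#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

#' CaptureExperiment: site x species x year capture counts
#'
#' A \linkS4class{SummarizedExperiment} holding the raw observational unit of
#' an even-effort patch survey: integer counts of individuals per species
#' (rows) and site (columns), with one assay per sampling year (\code{"year1"},
#' \code{"year2"}). \code{rowData} carries the species guild (forest
#' \code{specialist} or \code{generalist}); \code{colData} carries
#' \code{site_id}, \code{landscape_id}, \code{patch_area_ha} (NA for sites in
#' continuous-forest control landscapes), the derived \code{log10_area}, and
#' \code{is_control}. The landscape table (id, percent forest cover, control
#' flag, pairing) lives in \code{metadata(x)$landscapes}.
#'
#' @section Validity:
#' Counts must be non-negative integers; every guild must be
#' \code{"specialist"} or \code{"generalist"}; fragmented sites must have
#' strictly positive patch areas with \code{log10_area == log10(patch_area_ha)};
#' fragmented landscapes must have distinct forest cover (this induces the
#' most-forested / intermediate / most-deforested ordering); each control
#' landscape must be paired to exactly one fragmented landscape.
#'
#' @aliases CaptureExperiment-class
#' @exportClass CaptureExperiment
setClass("CaptureExperiment", contains = "SummarizedExperiment")

.validCaptureExperiment <- function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("year1", "year2") %in% an))
    msg <- c(msg, "assays must include 'year1' and 'year2'")
  for (a in an) {
    m <- assay(object, a)
    if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
      msg <- c(msg, sprintf("assay '%s' must contain non-negative integers", a))
  }
  rd <- rowData(object)
  if (!"guild" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain a 'guild' column")
  } else if (!all(as.character(rd$guild) %in% c("specialist", "generalist"))) {
    msg <- c(msg, "guild must be 'specialist' or 'generalist'")
  }
  cd <- colData(object)
  need <- c("site_id", "landscape_id", "patch_area_ha", "log10_area", "is_control")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  } else {
    frag <- !cd$is_control
    if (any(frag) && (any(is.na(cd$patch_area_ha[frag])) ||
                      any(cd$patch_area_ha[frag] <= 0)))
      msg <- c(msg, "fragmented sites must have patch_area_ha > 0")
    ok <- frag & !is.na(cd$patch_area_ha)
    if (any(ok) && max(abs(cd$log10_area[ok] - log10(cd$patch_area_ha[ok]))) > 1e-10)
      msg <- c(msg, "log10_area must equal log10(patch_area_ha)")
  }
  ls <- metadata(object)$landscapes
  if (is.null(ls)) {
    msg <- c(msg, "metadata(x)$landscapes is missing")
  } else {
    fragl <- ls[!ls$is_control, , drop = FALSE]
    if (anyDuplicated(fragl$forest_cover_percent))
      msg <- c(msg, "fragmented landscapes must have distinct forest cover")
    ctl <- ls[ls$is_control, , drop = FALSE]
    if (nrow(ctl) && (any(is.na(ctl$paired_with)) ||
                      !all(ctl$paired_with %in% fragl$landscape_id)))
      msg <- c(msg, "each control landscape must be paired with one fragmented landscape")
    if (!all(cd$landscape_id %in% ls$landscape_id))
      msg <- c(msg, "every site must reference a known landscape")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CaptureExperiment", .validCaptureExperiment)

#' CandidateModel: one structured patch-area hypothesis
#'
#' A candidate model is a set of per-landscape component functions — each
#' either constant or linear in log10 patch area — together with an error
#' distribution policy (Poisson, or Negative Binomial for abundance models
#' with no patch-area effect) and a free-parameter count K. Components may
#' share intercepts and/or slopes across the landscapes they cover.
#'
#' @slot model_id one of "A","B","C","D","D2","E","E2","F"
#' @slot response "abundance" or "richness"
#' @slot components list of component descriptors (landscapes, form, sharing)
#' @slot distribution "poisson" or "negbin"
#' @slot K integer count of free parameters (incl. NB dispersion)
#' @slot landscapes character: fragmented landscape ids ordered from most to
#'   least forested
#' @aliases CandidateModel-class
#' @exportClass CandidateModel
setClass("CandidateModel",
  representation(model_id = "character", response = "character",
                 components = "list", distribution = "character",
                 K = "integer", landscapes = "character"))

setValidity("CandidateModel", function(object) {
  msg <- character()
  if (!object@distribution %in% c("poisson", "negbin"))
    msg <- c(msg, "distribution must be 'poisson' or 'negbin'")
  if (!object@response %in% c("abundance", "richness"))
    msg <- c(msg, "response must be 'abundance' or 'richness'")
  if (object@response == "richness" && object@distribution != "poisson")
    msg <- c(msg, "richness models must be Poisson")
  covered <- unlist(lapply(object@components, `[[`, "landscapes"))
  if (anyDuplicated(covered) || !setequal(covered, object@landscapes))
    msg <- c(msg, "every landscape must be covered by exactly one component")
  has_linear <- any(vapply(object@components, function(cc) cc$form == "linear",
                           logical(1)))
  if (object@distribution == "negbin" && has_linear)
    msg <- c(msg, "negbin is reserved for models without patch-area effects")
  if (length(msg)) msg else TRUE
})

#' FittedModel: maximum-likelihood fit of a CandidateModel
#'
#' @slot model the \linkS4class{CandidateModel}
#' @slot params named numeric vector of ML coefficients on the link scale
#'   (log-dispersion last when Negative Binomial)
#' @slot logL maximized log-likelihood (a sum of log-pmfs, hence <= 0)
#' @slot K integer number of free parameters
#' @slot n integer number of sites entering the fit
#' @slot converged logical convergence flag
#' @aliases FittedModel-class
#' @exportClass FittedModel
setClass("FittedModel",
  representation(model = "CandidateModel", params = "numeric", logL = "numeric",
                 K = "integer", n = "integer", converged = "logical"))

#' Scenario: a stated generating world for synthetic capture tables
#'
#' Describes three fragmented landscapes (percent cover, number of surveyed
#' patches), the generating candidate model and its true coefficients on the
#' link scale, the count distribution (Poisson when \code{dispersion_k} is
#' infinite), the guild, the species pool, and a seed.
#'
#' @slot name scenario label
#' @slot landscapes data.frame(forest_cover_percent, n_patches)
#' @slot area_range_ha length-2 numeric, log-uniform patch-area range
#' @slot generating_model model id in A, B, C, D, D2, E, E2, F
#' @slot coefficients named numeric, one per design column of the generating
#'   model (link scale)
#' @slot dispersion_k positive real or Inf (Poisson)
#' @slot guild "specialist" or "generalist"
#' @slot n_years integer, 2
#' @slot n_species species pool size for the guild
#' @slot abundance_profile relative-abundance decay of the geometric species
#'   profile, in (0,1)
#' @slot n_control_sites sites per paired control landscape (0 disables)
#' @slot seed integer RNG seed
#' @aliases Scenario-class
#' @exportClass Scenario
setClass("Scenario",
  representation(name = "character", landscapes = "data.frame",
                 area_range_ha = "numeric", generating_model = "character",
                 coefficients = "numeric", dispersion_k = "numeric",
                 guild = "character", n_years = "integer",
                 n_species = "integer", abundance_profile = "numeric",
                 n_control_sites = "integer", seed = "integer"))

setValidity("Scenario", function(object) {
  msg <- character()
  if (nrow(object@landscapes) != 3L)
    msg <- c(msg, "a scenario describes exactly three fragmented landscapes")
  if (any(object@landscapes$n_patches < 1L))
    msg <- c(msg, "n_patches must be positive")
  if (length(object@area_range_ha) != 2L || any(object@area_range_ha <= 0) ||
      diff(object@area_range_ha) <= 0)
    msg <- c(msg, "area_range_ha must be an increasing positive pair")
  if (!object@generating_model %in% c("A", "B", "C", "D", "D2", "E", "E2", "F"))
    msg <- c(msg, "unknown generating model")
  if (object@dispersion_k <= 0)
    msg <- c(msg, "dispersion_k must be positive (Inf for Poisson)")
  if (!object@guild %in% c("specialist", "generalist"))
    msg <- c(msg, "guild must be specialist or generalist")
  if (object@n_years != 2L)
    msg <- c(msg, "the sampling design has two years")
  if (object@abundance_profile <= 0 || object@abundance_profile >= 1)
    msg <- c(msg, "abundance_profile must be in (0,1)")
  if (length(msg)) msg else TRUE
})
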