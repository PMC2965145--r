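## Candidate catalogue: eight structured hypotheses over three fragmented
## landscapes ordered most -> least forested (L1, L2, L3):
##   A  single constant everywhere (null)
##   B  one shared linear (intercept + slope) in log10 area everywhere
##   C  one constant per landscape (landscape context only)
##   D  per-landscape intercepts, one shared slope
##   D2 per-landscape intercepts and slopes
##   E  constant in L1; linear in {L2, L3} with per-landscape intercepts and
##      a shared slope (patch-area effect below a cover threshold)
##   E2 as E with landscape-specific slopes
##   F  constants in L1 and L3, linear in L2 only (patch-area effect only at
##      intermediate cover — the regime-shift structure)
## Abundance models with no linear component (A, C) use a Negative Binomial
## error with one shared dispersion; all others, and all richness models,
## are Poisson.

.component <- function(landscapes, form,
                       intercepts = c("by_landscape", "shared"),
                       slopes = c("shared", "by_landscape")) {
  list(landscapes = landscapes, form = form,
       intercepts = match.arg(intercepts), slopes = match.arg(slopes))
}

.modelComponents <- function(model_id, L, shared_constant_F = FALSE) {
  switch(model_id,
    A = list(.component(L, "constant", intercepts = "shared")),
    B = list(.component(L, "linear", intercepts = "shared", slopes = "shared")),
    C = lapply(L, .component, form = "constant", intercepts = "shared"),
    D = list(.component(L, "linear", intercepts = "by_landscape",
                        slopes = "shared")),
    D2 = list(.component(L, "linear", intercepts = "by_landscape",
                         slopes = "by_landscape")),
    E = list(.component(L[1], "constant", intercepts = "shared"),
             .component(L[2:3], "linear", intercepts = "by_landscape",
                        slopes = "shared")),
    E2 = list(.component(L[1], "constant", intercepts = "shared"),
              .component(L[2:3], "linear", intercepts = "by_landscape",
                         slopes = "by_landscape")),
    F = if (shared_constant_F)
          list(.component(L[c(1, 3)], "constant", intercepts = "shared"),
               .component(L[2], "linear"))
        else
          list(.component(L[1], "constant", intercepts = "shared"),
               .component(L[2], "linear"),
               .component(L[3], "constant", intercepts = "shared")),
    stop("unknown model id '", model_id, "'"))
}

.designColumns <- function(components) {
  cols <- list()
  for (cc in components) {
    grp <- paste(cc$landscapes, collapse = "+")
    if (cc$form == "constant") {
      cols[[length(cols) + 1L]] <- list(name = sprintf("const[%s]", grp),
                                        landscapes = cc$landscapes,
                                        kind = "intercept")
    } else {
      ints <- if (cc$intercepts == "shared") list(cc$landscapes) else
        as.list(cc$landscapes)
      for (li in ints)
        cols[[length(cols) + 1L]] <- list(
          name = sprintf("int[%s]", paste(li, collapse = "+")),
          landscapes = li, kind = "intercept")
      slps <- if (cc$slopes == "shared") list(cc$landscapes) else
        as.list(cc$landscapes)
      for (li in slps)
        cols[[length(cols) + 1L]] <- list(
          name = sprintf("slope[%s]", paste(li, collapse = "+")),
          landscapes = li, kind = "slope")
    }
  }
  cols
}

#' Enumerate the eight candidate patch-area models
#'
#' Builds the full candidate set for a three-landscape design. Requires the
#' fragmented landscape ids ordered from most to least forested (see
#' \code{\link{landscapeOrder}}); the ordering determines which landscape the
#' threshold (E, E2) and regime-shift (F) structures treat as most forested,
#' intermediate and most deforested.
#'
#' @param landscapes character(3): fragmented landscape ids, most -> least
#'   forested
#' @param response "abundance" (Negative Binomial for the no-area models
#'   A and C) or "richness" (Poisson throughout)
#' @param shared_constant_F if TRUE, model F uses a single constant shared by
#'   the most-forested and most-deforested landscapes instead of two separate
#'   constants (non-default variant)
#' @return named list of 8 \linkS4class{CandidateModel} objects
#' @examples
#' mods <- enumerateCandidates(c("L50", "L30", "L10"), "abundance")
#' vapply(mods, paramCount, integer(1))
#' @export
enumerateCandidates <- function(landscapes,
                                response = c("abundance", "richness"),
                                shared_constant_F = FALSE) {
  response <- match.arg(response)
  if (length(landscapes) != 3L || anyDuplicated(landscapes))
    stop("the candidate catalogue is defined for exactly three distinct ",
         "fragmented landscapes")
  ids <- c("A", "B", "C", "D", "D2", "E", "E2", "F")
  out <- lapply(ids, function(id) {
    comps <- .modelComponents(id, landscapes, shared_constant_F)
    has_linear <- any(vapply(comps, function(cc) cc$form == "linear",
                             logical(1)))
    dist <- if (!has_linear && response == "abundance") "negbin" else "poisson"
    K <- length(.designColumns(comps)) + (dist == "negbin")
    new("CandidateModel", model_id = id, response = response,
        components = comps, distribution = dist, K = as.integer(K),
        landscapes = landscapes)
  })
  names(out) <- ids
  out
}

#' Number of free parameters of a candidate model
#'
#' Counts every free coefficient (constants, intercepts and slopes,
#' respecting sharing) plus one for the Negative Binomial dispersion when the
#' model's distribution is negbin — information criteria must count all
#' estimated parameters.
#'
#' @param model a \linkS4class{CandidateModel}
#' @return integer K
#' @export
paramCount <- function(model) model@K

#' Names of the free coefficients of a candidate model
#'
#' Column labels of the model's design matrix (\code{const[...]},
#' \code{int[...]}, \code{slope[...]}), followed by \code{log_k} for the
#' log-dispersion when the distribution is Negative Binomial.
#'
#' @param model a \linkS4class{CandidateModel}
#' @return character vector of length \code{paramCount(model)}
#' @export
paramNames <- function(model) {
  nm <- vapply(.designColumns(model@components), `[[`, character(1), "name")
  if (model@distribution == "negbin") nm <- c(nm, "log_k")
  nm
}

#' Design matrix of a candidate model on a set of sites
#'
#' One row per site, one column per free mean coefficient; intercept columns
#' are landscape-membership indicators and slope columns carry log10 patch
#' area on the member sites. The dispersion parameter (negbin) is not a
#' column.
#'
#' @param model a \linkS4class{CandidateModel}
#' @param sites data.frame with landscape_id and log10_area (e.g. from
#'   \code{\link{aggregateResponses}})
#' @return numeric matrix, nrow(sites) x (K - negbin)
#' @export
designMatrix <- function(model, sites) {
  unknown <- setdiff(unique(sites$landscape_id), model@landscapes)
  if (length(unknown))
    stop("site landscape(s) not covered by any component: ",
         paste(unknown, collapse = ", "))
  cols <- .designColumns(model@components)
  X <- matrix(0, nrow = nrow(sites), ncol = length(cols),
              dimnames = list(NULL, vapply(cols, `[[`, character(1), "name")))
  for (j in seq_along(cols)) {
    member <- sites$landscape_id %in% cols[[j]]$landscapes
    X[, j] <- if (cols[[j]]$kind == "slope")
      member * sites$log10_area else as.numeric(member)
  }
  X
}

#' Serialize a candidate catalogue to a human-readable description
#'
#' @param models list of \linkS4class{CandidateModel} (from
#'   \code{\link{enumerateCandidates}})
#' @param path optional file; when given, JSON is written there
#' @return JSON string (invisibly when \code{path} is given)
#' @export
describeCatalogue <- function(models, path = NULL) {
  desc <- lapply(models, function(m) list(
    model_id = m@model_id, response = m@response,
    distribution = m@distribution, K = m@K,
    components = lapply(m@components, function(cc) list(
      landscapes = cc$landscapes, form = cc$form,
      intercepts = cc$intercepts, slopes = cc$slopes)),
    coefficients = paramNames(m)))
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @describeIn enumerateCandidates display a candidate model
#' @param object a CandidateModel
#' @export
setMethod("show", "CandidateModel", function(object) {
  cat(sprintf("CandidateModel %s (%s, %s), K = %d\n", object@model_id,
              object@response, object@distribution, object@K))
  for (cc in object@components)
    cat(sprintf("  %s on {%s}%s\n", cc$form,
                paste(cc$landscapes, collapse = ", "),
                if (cc$form == "linear")
                  sprintf(" [intercepts %s, slopes %s]", cc$intercepts,
                          cc$slopes) else ""))
  invisible(NULL)
})
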