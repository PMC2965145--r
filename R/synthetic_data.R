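## Synthetic studies: three fragmented landscapes (50/30/10% cover, 15-20
## patches each), log-uniform patch areas, guild totals drawn from a chosen
## generating candidate model, partitioned multinomially over a geometric
## species-abundance profile and split binomially over the two years.

.landscapeId <- function(cover) sprintf("L%g", cover)

#' Construct a synthetic-data Scenario
#'
#' @param name scenario label
#' @param generating_model candidate id in A, B, C, D, D2, E, E2, F
#' @param coefficients named numeric vector of true mean coefficients on the
#'   log-link scale; names must match the generating model's design columns
#'   (see \code{\link{paramNames}}), e.g. \code{const[L50]}, \code{int[L30]},
#'   \code{slope[L30]}
#' @param landscapes data.frame(forest_cover_percent, n_patches); default
#'   three landscapes at 50/30/10 percent cover with 17 patches each
#' @param area_range_ha log-uniform patch-area range, default (2, 300) ha
#' @param dispersion_k Negative Binomial dispersion of the site totals;
#'   \code{Inf} (default) draws Poisson counts
#' @param guild "specialist" or "generalist"
#' @param n_species guild species-pool size (defaults: 27 specialists,
#'   12 generalists)
#' @param abundance_profile geometric decay of relative species abundances
#' @param n_control_sites sites per paired continuous-forest control
#'   landscape (default 6; 0 disables controls)
#' @param seed integer RNG seed governing one generation call
#' @return a \linkS4class{Scenario}
#' @export
Scenario <- function(name, generating_model, coefficients,
                     landscapes = data.frame(
                       forest_cover_percent = c(50, 30, 10),
                       n_patches = c(17L, 17L, 17L)),
                     area_range_ha = c(2, 300), dispersion_k = Inf,
                     guild = c("specialist", "generalist"),
                     n_species = NULL,
                     abundance_profile = 0.75, n_control_sites = 6L,
                     seed = 1L) {
  guild <- match.arg(guild)
  if (is.null(n_species))
    n_species <- if (guild == "specialist") 27L else 12L
  landscapes <- as.data.frame(landscapes)
  landscapes <- landscapes[order(-landscapes$forest_cover_percent), ,
                           drop = FALSE]
  rownames(landscapes) <- NULL
  landscapes$n_patches <- as.integer(landscapes$n_patches)
  sc <- new("Scenario", name = name, landscapes = landscapes,
            area_range_ha = as.numeric(area_range_ha),
            generating_model = generating_model,
            coefficients = coefficients, dispersion_k = dispersion_k,
            guild = guild, n_years = 2L, n_species = as.integer(n_species),
            abundance_profile = abundance_profile,
            n_control_sites = as.integer(n_control_sites),
            seed = as.integer(seed))
  .checkScenarioCoefficients(sc)
  sc
}

.scenarioModel <- function(scenario) {
  ids <- .landscapeId(scenario@landscapes$forest_cover_percent)
  enumerateCandidates(ids, "abundance")[[scenario@generating_model]]
}

.checkScenarioCoefficients <- function(scenario) {
  model <- .scenarioModel(scenario)
  expect <- setdiff(paramNames(model), "log_k")
  got <- names(scenario@coefficients)
  if (length(scenario@coefficients) != length(expect) ||
      !identical(sort(got), sort(expect)))
    stop("coefficients inconsistent with model ", scenario@generating_model,
         " structure: expected {", paste(expect, collapse = ", "),
         "}, got {", paste(got, collapse = ", "), "}")
  invisible(TRUE)
}

#' @describeIn Scenario display a scenario
#' @param object a Scenario
#' @export
setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s': model %s, guild %s, %s counts\n", object@name,
              object@generating_model, object@guild,
              if (is.finite(object@dispersion_k))
                sprintf("NB(k = %g)", object@dispersion_k) else "Poisson"))
  cat("  landscapes:", paste(sprintf("%g%% (%d patches)",
                                     object@landscapes$forest_cover_percent,
                                     object@landscapes$n_patches),
                             collapse = ", "), "\n")
  cat("  areas: log-uniform on (", object@area_range_ha[1], ",",
      object@area_range_ha[2], ") ha;",
      object@n_species, "species; seed", object@seed, "\n")
  cat("  coefficients:", paste(sprintf("%s = %.3f",
                                       names(object@coefficients),
                                       object@coefficients),
                               collapse = ", "), "\n")
  invisible(NULL)
})

#' Preset generating scenarios
#'
#' The stated worlds used throughout the test suite, one per postulated
#' biodiversity pattern:
#' \describe{
#'   \item{null}{model A — one Poisson mean (5 individuals per site) in all
#'     landscapes.}
#'   \item{patch_area}{model B — a single positive patch-area slope in every
#'     landscape.}
#'   \item{landscape}{model C — constant means falling with deforestation
#'     (30, 15, 3), Negative Binomial (k = 5).}
#'   \item{andren_threshold}{model E — constant in the most-forested
#'     landscape, a shared positive slope below the cover threshold.}
#'   \item{regime_shift}{model F — high constant at 50\% cover, positive
#'     patch-area slope only at 30\%, low constant at 10\% (means run ~3 at
#'     2 ha to ~30 at 300 ha in the intermediate landscape).}
#'   \item{generalist_release}{model C for the generalist guild with means
#'     rising as cover falls (8, 26, 55), Negative Binomial (k = 3).}
#' }
#' Coefficients are illustrative magnitudes on the scale of the observed
#' per-patch abundances, not field estimates.
#'
#' @param seed seed stored in every preset (default 1)
#' @return named list of \linkS4class{Scenario} objects
#' @export
presetScenarios <- function(seed = 1L) {
  list(
    null = Scenario("null", "A",
      c("const[L50+L30+L10]" = log(5)), seed = seed),
    patch_area = Scenario("patch_area", "B",
      c("int[L50+L30+L10]" = 0.91, "slope[L50+L30+L10]" = 1.0), seed = seed),
    landscape = Scenario("landscape", "C",
      c("const[L50]" = log(30), "const[L30]" = log(15), "const[L10]" = log(3)),
      dispersion_k = 5, seed = seed),
    andren_threshold = Scenario("andren_threshold", "E",
      c("const[L50]" = log(30), "int[L30]" = 0.91, "int[L10]" = 0.30,
        "slope[L30+L10]" = 1.0), seed = seed),
    regime_shift = Scenario("regime_shift", "F",
      c("const[L50]" = log(30), "int[L30]" = 0.78, "slope[L30]" = 1.056,
        "const[L10]" = log(3)), seed = seed),
    generalist_release = Scenario("generalist_release", "C",
      c("const[L50]" = log(8), "const[L30]" = log(26), "const[L10]" = log(55)),
      dispersion_k = 3, guild = "generalist", seed = seed))
}

## patch geometry + landscape table of a scenario (consumes RNG)
.scenarioSites <- function(scenario) {
  lt <- scenario@landscapes
  ids <- .landscapeId(lt$forest_cover_percent)
  site_rows <- do.call(rbind, lapply(seq_len(nrow(lt)), function(i) {
    n <- lt$n_patches[i]
    areas <- 10^stats::runif(n, log10(scenario@area_range_ha[1]),
                             log10(scenario@area_range_ha[2]))
    data.frame(site_id = sprintf("%s_s%02d", ids[i], seq_len(n)),
               landscape_id = ids[i], patch_area_ha = areas,
               is_control = FALSE)
  }))
  landscapes <- data.frame(landscape_id = ids,
                           forest_cover_percent = lt$forest_cover_percent,
                           is_control = FALSE, paired_with = NA_character_)
  if (scenario@n_control_sites > 0) {
    ctl_ids <- sub("^L", "C", ids)
    site_rows <- rbind(site_rows, do.call(rbind, lapply(seq_along(ids),
      function(i) data.frame(
        site_id = sprintf("%s_s%02d", ctl_ids[i],
                          seq_len(scenario@n_control_sites)),
        landscape_id = ctl_ids[i], patch_area_ha = NA_real_,
        is_control = TRUE))))
    landscapes <- rbind(landscapes,
      data.frame(landscape_id = ctl_ids, forest_cover_percent = 100,
                 is_control = TRUE, paired_with = ids))
  }
  list(sites = site_rows, landscapes = landscapes)
}

## guild capture rows for a fixed site table (consumes RNG)
.scenarioCaptures <- function(scenario, sites) {
  model <- .scenarioModel(scenario)
  frag <- sites[!sites$is_control, , drop = FALSE]
  X <- designMatrix(model, data.frame(landscape_id = frag$landscape_id,
                                      log10_area = log10(frag$patch_area_ha)))
  mu <- .muFromDesign(X, scenario@coefficients[colnames(X)],
                      rep(1, nrow(frag)), "log")
  mu_all <- c(mu, rep(0, sum(sites$is_control)))
  if (scenario@n_control_sites > 0) {
    ## controls (continuous forest) draw at the most-forested landscape's
    ## mean site total
    top <- .landscapeId(scenario@landscapes$forest_cover_percent[1])
    mu_ctl <- mean(mu[frag$landscape_id == top])
    mu_all[sites$is_control] <- mu_ctl
  }
  totals <- if (is.finite(scenario@dispersion_k))
    stats::rnbinom(length(mu_all), mu = mu_all, size = scenario@dispersion_k)
  else stats::rpois(length(mu_all), mu_all)
  sp_ids <- sprintf("%s_sp%02d", substr(scenario@guild, 1, 4),
                    seq_len(scenario@n_species))
  p <- scenario@abundance_profile^(seq_len(scenario@n_species) - 1)
  p <- p / sum(p)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    if (totals[i] == 0) return(NULL)
    per_sp <- drop(stats::rmultinom(1, totals[i], p))
    nz <- which(per_sp > 0)
    if (!length(nz)) return(NULL)
    y1 <- stats::rbinom(length(nz), per_sp[nz], 0.5)
    y2 <- per_sp[nz] - y1
    out <- data.frame(site_id = sites$site_id[i], species_id = sp_ids[nz],
                      year = 1L, individuals = y1)
    out2 <- out; out2$year <- 2L; out2$individuals <- y2
    rbind(out[out$individuals > 0, ], out2[out2$individuals > 0, ])
  })
  captures <- do.call(rbind, rows)
  if (is.null(captures))
    captures <- data.frame(site_id = character(), species_id = character(),
                           year = integer(), individuals = integer())
  list(captures = captures,
       species = data.frame(species_id = sp_ids, guild = scenario@guild))
}

#' Generate a synthetic study from a scenario
#'
#' Draws patch areas log-uniformly, site guild totals from the scenario's
#' generating model (Poisson, or Negative Binomial when \code{dispersion_k}
#' is finite), partitions each total multinomially across the guild's
#' geometric species-abundance profile, and splits each species count
#' across the two sampling years binomially (p = 0.5). Paired
#' continuous-forest control sites (no patch area) draw at the most-forested
#' landscape's mean. The same seed yields bit-identical output.
#'
#' @param scenario a \linkS4class{Scenario}
#' @param seed overrides \code{scenario@seed} when given
#' @return a \linkS4class{CaptureExperiment}
#' @examples
#' x <- generateScenario(presetScenarios()[["regime_shift"]])
#' aggregateResponses(x, "specialist")[1:3, ]
#' @export
generateScenario <- function(scenario, seed = scenario@seed) {
  .checkScenarioCoefficients(scenario)
  set.seed(seed)
  geom <- .scenarioSites(scenario)
  gen <- .scenarioCaptures(scenario, geom$sites)
  CaptureExperiment(captures = gen$captures, sites = geom$sites,
                    species = gen$species, landscapes = geom$landscapes)
}

#' Generate a two-guild synthetic study on shared sites
#'
#' Draws one patch geometry (from the specialist scenario) and then both
#' guilds' counts on those same sites, mirroring a real survey where the two
#' guilds are trapped together.
#'
#' @param specialist,generalist \linkS4class{Scenario} objects for the two
#'   guilds (their landscape geometries must match)
#' @param seed RNG seed (default: the specialist scenario's)
#' @return a \linkS4class{CaptureExperiment} with both guilds
#' @export
generateStudy <- function(specialist, generalist, seed = specialist@seed) {
  if (specialist@guild != "specialist" || generalist@guild != "generalist")
    stop("scenarios must be a specialist and a generalist world")
  if (!isTRUE(all.equal(specialist@landscapes, generalist@landscapes)))
    stop("the two scenarios must share the landscape geometry")
  .checkScenarioCoefficients(specialist)
  .checkScenarioCoefficients(generalist)
  set.seed(seed)
  geom <- .scenarioSites(specialist)
  g1 <- .scenarioCaptures(specialist, geom$sites)
  g2 <- .scenarioCaptures(generalist, geom$sites)
  CaptureExperiment(captures = rbind(g1$captures, g2$captures),
                    sites = geom$sites,
                    species = rbind(g1$species, g2$species),
                    landscapes = geom$landscapes)
}

#' Write a scenario to a key-value text file (JSON)
#'
#' @param scenario a \linkS4class{Scenario}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeScenario <- function(scenario, path) {
  obj <- list(
    name = scenario@name,
    landscapes = scenario@landscapes,
    area_range_ha = scenario@area_range_ha,
    generating_model = scenario@generating_model,
    coefficients = as.list(scenario@coefficients),
    dispersion_k = if (is.finite(scenario@dispersion_k))
      scenario@dispersion_k else "Inf",
    guild = scenario@guild,
    n_years = scenario@n_years,
    n_species = scenario@n_species,
    abundance_profile = scenario@abundance_profile,
    n_control_sites = scenario@n_control_sites,
    seed = scenario@seed)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Read a scenario from a key-value text file (JSON)
#'
#' @param path file written by \code{\link{writeScenario}}
#' @return a \linkS4class{Scenario}
#' @export
readScenario <- function(path) {
  obj <- jsonlite::fromJSON(path)
  Scenario(name = obj$name, generating_model = obj$generating_model,
           coefficients = unlist(obj$coefficients),
           landscapes = obj$landscapes,
           area_range_ha = obj$area_range_ha,
           dispersion_k = if (identical(obj$dispersion_k, "Inf")) Inf else
             as.numeric(obj$dispersion_k),
           guild = obj$guild, n_species = obj$n_species,
           abundance_profile = obj$abundance_profile,
           n_control_sites = obj$n_control_sites, seed = obj$seed)
}
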