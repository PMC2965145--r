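#' Species-by-sample incidence matrix
#'
#' Binary species x site presence/absence for one guild, pooling both
#' sampling years (a species is present in a sample if captured there in
#' either year). One sample = one site. Species never observed in the
#' retained samples are dropped, so every retained row has incidence >= 1.
#'
#' @param x a \linkS4class{CaptureExperiment}
#' @param guild "specialist" or "generalist"
#' @param landscape_ids optional subset of landscapes to keep (default: all
#'   sites, fragmented and control)
#' @return binary integer matrix, species x samples
#' @export
incidenceMatrix <- function(x, guild = c("specialist", "generalist"),
                            landscape_ids = NULL) {
  guild <- match.arg(guild)
  keep <- as.character(rowData(x)$guild) == guild
  cols <- if (is.null(landscape_ids)) rep(TRUE, ncol(x)) else
    colData(x)$landscape_id %in% landscape_ids
  if (!any(cols)) stop("no sites in the requested landscapes")
  m <- (assay(x, "year1")[keep, cols, drop = FALSE] +
        assay(x, "year2")[keep, cols, drop = FALSE]) > 0
  m <- m[rowSums(m) >= 1, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

## C(H - u, h) / C(H, h) via lchoose; 0 when H - u < h
.absProb <- function(u, H, h) {
  num <- lchoose(H - u, h)
  p <- exp(num - lchoose(H, h))
  p[H - u < h] <- 0
  p
}

#' Sample-based rarefaction (species accumulation) curve
#'
#' Analytic expectation of the number of species in a random subset of h of
#' the H samples: tau(h) = S_obs - sum_i C(H - H_i, h) / C(H, h), with the
#' exact conditional variance obtained from the pairwise joint-absence
#' probabilities (hypergeometric covariances), so sd(H) = 0 and
#' tau(H) = S_obs. The 95% CI is the normal approximation tau +/- 1.96 sd.
#'
#' @param inc binary incidence matrix (species x samples), e.g. from
#'   \code{\link{incidenceMatrix}}
#' @param conf_z normal quantile for the CI (default 1.96)
#' @return data.frame(h, tau, sd, lo95, hi95) for h = 1..H
#' @export
accumulationCurve <- function(inc, conf_z = 1.96) {
  if (is.null(dim(inc)) || nrow(inc) == 0 || ncol(inc) == 0)
    stop("empty incidence matrix")
  inc <- (inc > 0) * 1L
  H <- ncol(inc)
  S <- nrow(inc)
  Hc <- rowSums(inc)
  co <- tcrossprod(inc)                  # samples containing both i and j
  U <- outer(Hc, Hc, "+") - co           # samples containing i or j
  out <- lapply(seq_len(H), function(h) {
    alpha <- .absProb(Hc, H, h)
    tau <- S - sum(alpha)
    A2 <- .absProb(U, H, h)              # joint absence; diag = alpha
    v <- sum(A2) - sum(alpha)^2
    sd <- sqrt(max(v, 0))
    data.frame(h = h, tau = tau, sd = sd,
               lo95 = tau - conf_z * sd, hi95 = tau + conf_z * sd)
  })
  do.call(rbind, out)
}

#' Monte-Carlo species accumulation (check/fallback for the analytic curve)
#'
#' Mean and sd of observed richness over random h-subsets of samples.
#'
#' @param inc binary incidence matrix
#' @param h subset size
#' @param n_draws number of random subsets
#' @return list(mean, sd, se) of richness across draws
#' @export
accumulationMC <- function(inc, h, n_draws = 1000L) {
  inc <- (inc > 0) * 1L
  H <- ncol(inc)
  rich <- vapply(seq_len(n_draws), function(i) {
    s <- sample.int(H, h)
    sum(rowSums(inc[, s, drop = FALSE]) > 0)
  }, numeric(1))
  list(mean = mean(rich), sd = stats::sd(rich),
       se = stats::sd(rich) / sqrt(n_draws))
}

#' Chao2 incidence-based richness estimator
#'
#' Classic form S_obs + q1^2 / (2 q2) when q2 > 0; bias-corrected
#' S_obs + q1 (q1 - 1) / (2 (q2 + 1)) when q2 = 0 (q1 = species found in
#' exactly one sample, q2 in exactly two).
#'
#' @param inc binary incidence matrix
#' @return estimated richness (>= S_obs)
#' @export
chao2 <- function(inc) {
  inc <- (inc > 0) * 1L
  Hc <- rowSums(inc)
  S <- sum(Hc >= 1)
  q1 <- sum(Hc == 1)
  q2 <- sum(Hc == 2)
  if (q2 > 0) S + q1^2 / (2 * q2) else S + q1 * (q1 - 1) / (2 * (q2 + 1))
}

#' First-order jackknife incidence-based richness estimator
#'
#' S_obs + q1 (H - 1) / H.
#'
#' @param inc binary incidence matrix with H >= 2 samples
#' @return estimated richness (>= S_obs)
#' @export
jackknife1 <- function(inc) {
  inc <- (inc > 0) * 1L
  H <- ncol(inc)
  if (H < 2) stop("jackknife1 needs >= 2 samples")
  Hc <- rowSums(inc)
  sum(Hc >= 1) + sum(Hc == 1) * (H - 1) / H
}

#' Presence set of a guild in a set of landscapes
#'
#' @param x a \linkS4class{CaptureExperiment}
#' @param guild "specialist" or "generalist"
#' @param landscape_ids landscapes to pool
#' @return character vector of species ids observed at least once
#' @export
presenceSet <- function(x, guild = c("specialist", "generalist"),
                        landscape_ids) {
  guild <- match.arg(guild)
  keep <- as.character(rowData(x)$guild) == guild
  cols <- colData(x)$landscape_id %in% landscape_ids
  m <- assay(x, "year1")[keep, cols, drop = FALSE] +
    assay(x, "year2")[keep, cols, drop = FALSE]
  rownames(m)[rowSums(m) > 0]
}

#' Bray-Curtis similarity on presence/absence data
#'
#' 100 * 2a / (2a + b + c) with a = shared species, b and c the species
#' found only in one of the two sets; on binary data this equals the
#' Sorensen index, expressed in percent.
#'
#' @param x,y character vectors (presence sets over a common species
#'   universe)
#' @return percent similarity in [0, 100]
#' @export
brayCurtisPresence <- function(x, y) {
  x <- unique(as.character(x)); y <- unique(as.character(y))
  if (!length(x) && !length(y))
    stop("similarity undefined for two empty presence sets")
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  cc <- length(setdiff(y, x))
  100 * 2 * a / (2 * a + b + cc)
}

#' Representation of a control species pool in a fragmented landscape
#'
#' Percentage of the species found in the control (continuous forest)
#' landscape that were also found in the fragmented landscape.
#'
#' @param fragment_species,control_species character presence sets
#' @return 100 * |fragment intersect control| / |control|
#' @export
representationPercent <- function(fragment_species, control_species) {
  control_species <- unique(as.character(control_species))
  if (!length(control_species))
    stop("representation undefined for an empty control species pool")
  100 * length(intersect(unique(as.character(fragment_species)),
                         control_species)) / length(control_species)
}

#' Landscape-scale diversity report
#'
#' Computes, for one guild: per-landscape accumulation curves (fragmented
#' landscapes and their paired controls), observed richness with Chao2 and
#' first-order jackknife estimates, the Bray-Curtis presence/absence
#' similarity matrix among fragmented landscapes, and representation
#' percentages of each fragmented landscape against its paired control.
#'
#' @param x a \linkS4class{CaptureExperiment}
#' @param guild "specialist" (default) or "generalist"
#' @return list(curves, richness, similarity, representation)
#' @export
diversityReport <- function(x, guild = c("specialist", "generalist")) {
  guild <- match.arg(guild)
  ls <- landscapeInfo(x)
  frag <- landscapeOrder(x)
  all_ids <- ls$landscape_id
  curves <- lapply(stats::setNames(all_ids, all_ids), function(id) {
    inc <- tryCatch(incidenceMatrix(x, guild, id), error = function(e) NULL)
    if (is.null(inc) || nrow(inc) == 0) return(NULL)
    accumulationCurve(inc)
  })
  richness <- do.call(rbind, lapply(all_ids, function(id) {
    inc <- tryCatch(incidenceMatrix(x, guild, id), error = function(e) NULL)
    if (is.null(inc) || nrow(inc) == 0)
      return(data.frame(landscape_id = id, S_obs = 0, chao2 = NA_real_,
                        jackknife1 = NA_real_))
    data.frame(landscape_id = id, S_obs = nrow(inc), chao2 = chao2(inc),
               jackknife1 = if (ncol(inc) >= 2) jackknife1(inc) else NA_real_)
  }))
  sim <- matrix(NA_real_, length(frag), length(frag),
                dimnames = list(frag, frag))
  sets <- lapply(stats::setNames(frag, frag),
                 function(id) presenceSet(x, guild, id))
  for (i in seq_along(frag)) for (j in seq_along(frag))
    sim[i, j] <- if (length(sets[[i]]) || length(sets[[j]]))
      brayCurtisPresence(sets[[i]], sets[[j]]) else NA_real_
  ctl <- ls[ls$is_control, , drop = FALSE]
  rep_pct <- do.call(rbind, lapply(seq_len(nrow(ctl)), function(i) {
    ctl_set <- presenceSet(x, guild, ctl$landscape_id[i])
    frag_set <- presenceSet(x, guild, ctl$paired_with[i])
    data.frame(fragmented = ctl$paired_with[i],
               control = ctl$landscape_id[i],
               percent = if (length(ctl_set))
                 representationPercent(frag_set, ctl_set) else NA_real_)
  }))
  list(curves = curves, richness = richness, similarity = sim,
       representation = rep_pct)
}
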