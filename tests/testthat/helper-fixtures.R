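# Fixtures are built in code; nothing is read from disk.

# hand-built three-landscape study tables (2 sites per landscape + controls)
tiny_tables <- function() {
  list(
    landscapes = data.frame(
      landscape_id = c("L50", "L30", "L10", "C50"),
      forest_cover_percent = c(50, 30, 10, 100),
      is_control = c(FALSE, FALSE, FALSE, TRUE),
      paired_with = c(NA, NA, NA, "L50")),
    sites = data.frame(
      site_id = c("s1", "s2", "s3", "s4", "s5", "s6", "c1"),
      landscape_id = c("L50", "L50", "L30", "L30", "L10", "L10", "C50"),
      patch_area_ha = c(10, 100, 5, 250, 2, 80, NA),
      is_control = c(rep(FALSE, 6), TRUE)),
    species = data.frame(
      species_id = c("spA", "spB", "spC"),
      guild = c("specialist", "specialist", "generalist")),
    captures = data.frame(
      site_id = c("s1", "s1", "s1", "s2", "s3", "c1"),
      species_id = c("spA", "spA", "spB", "spC", "spA", "spB"),
      year = c(1L, 2L, 2L, 1L, 1L, 2L),
      individuals = c(2L, 1L, 3L, 4L, 5L, 1L)))
}

tiny_study <- function() {
  tt <- tiny_tables()
  CaptureExperiment(tt$captures, tt$sites, tt$species, tt$landscapes)
}

# small synthetic study for fitting tests
small_study <- function(seed = 42, n_patches = 10L) {
  sc <- presetScenarios()[["regime_shift"]]
  sc@landscapes$n_patches <- rep(as.integer(n_patches), 3)
  generateScenario(sc, seed = seed)
}

# ---- independent NLL oracle ---------------------------------------------
# Means are hand-coded per model id (never through designMatrix), and the
# likelihood goes through stats::dpois / stats::dnbinom.
oracle_mu <- function(model_id, par, landscape_id, x) {
  par <- unname(par)
  eta <- switch(model_id,
    A = rep(par[1], length(x)),
    B = par[1] + par[2] * x,
    C = c(L50 = par[1], L30 = par[2], L10 = par[3])[landscape_id],
    D = c(L50 = par[1], L30 = par[2], L10 = par[3])[landscape_id] +
      par[4] * x,
    D2 = c(L50 = par[1], L30 = par[2], L10 = par[3])[landscape_id] +
      c(L50 = par[4], L30 = par[5], L10 = par[6])[landscape_id] * x,
    E = ifelse(landscape_id == "L50", par[1],
               c(L30 = par[2], L10 = par[3])[landscape_id] + par[4] * x),
    E2 = ifelse(landscape_id == "L50", par[1],
                c(L30 = par[2], L10 = par[3])[landscape_id] +
                  c(L30 = par[4], L10 = par[5])[landscape_id] * x),
    F = ifelse(landscape_id == "L50", par[1],
               ifelse(landscape_id == "L10", par[4], par[2] + par[3] * x)),
    stop("oracle: unknown model ", model_id))
  unname(exp(eta))
}

oracle_nll <- function(model_id, dist, par, resp) {
  y <- resp$abundance
  mu <- oracle_mu(model_id, par, resp$landscape_id, resp$log10_area)
  if (dist == "negbin")
    -sum(stats::dnbinom(y, size = exp(par[length(par)]), mu = mu, log = TRUE))
  else
    -sum(stats::dpois(y, mu, log = TRUE))
}

# coarse grid search: n points per dimension in a +/- half box around center
oracle_grid_min <- function(model_id, dist, center, resp, half = 0.5, n = 5) {
  axes <- lapply(center, function(c0) seq(c0 - half, c0 + half, length.out = n))
  grid <- as.matrix(expand.grid(axes))
  min(apply(grid, 1, function(p) oracle_nll(model_id, dist, p, resp)))
}
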