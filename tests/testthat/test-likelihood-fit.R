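test_that("component mean functions evaluate on both links", {
  expect_equal(meanFunction("constant", log(5)), 5)
  expect_equal(meanFunction("linear", c(0, 1), log10_area = 2), exp(2),
               tolerance = 1e-7)
  # offset 2 doubles the mean for any component
  expect_equal(meanFunction("constant", 1.3, offset = 2),
               2 * meanFunction("constant", 1.3))
  expect_equal(meanFunction("linear", c(0.2, 0.7), log10_area = 1.4, offset = 2),
               2 * meanFunction("linear", c(0.2, 0.7), log10_area = 1.4))
  # identity link floors the linear predictor at a small epsilon
  expect_equal(meanFunction("linear", c(-5, 0), log10_area = 1,
                            link = "identity"), 1e-9)
  expect_error(meanFunction("constant", 1e10), "non-finite")
  expect_error(meanFunction("constant", 1, offset = 3), "offset")
})

test_that("Poisson and Negative Binomial NLLs match closed forms and dpois/dnbinom", {
  expect_identical(nllPoisson(integer(0), numeric(0)), 0)
  expect_equal(nllPoisson(0, 1), 1)
  expect_equal(nllPoisson(2, 2), 2 - log(2), tolerance = 1e-9)   # 1.3068528
  expect_error(nllPoisson(1, 0), "positive")
  expect_error(nllPoisson(c(1, 2), 1), "length")

  expect_equal(nllNegbin(0, 1, 1), log(2), tolerance = 1e-9)
  # geometric pmf (1/3)(2/3)^3 = 8/81
  expect_equal(nllNegbin(3, 2, 1), log(81 / 8), tolerance = 1e-9)
  expect_error(nllNegbin(1, 1, 0), "positive")

  set.seed(5)
  y <- rpois(40, 6); mu <- runif(40, 1, 12); k <- 2.7
  expect_equal(nllPoisson(y, mu), -sum(dpois(y, mu, log = TRUE)),
               tolerance = 1e-10)
  expect_equal(nllNegbin(y, mu, k),
               -sum(dnbinom(y, size = k, mu = mu, log = TRUE)),
               tolerance = 1e-10)
  # Poisson limit of the NB at k = 1e8
  expect_equal(nllNegbin(c(0, 1, 2, 3), rep(2, 4), 1e8),
               nllPoisson(c(0, 1, 2, 3), rep(2, 4)), tolerance = 1e-4)
})

test_that("the whole-model NLL composes component likelihoods additively", {
  x <- small_study(seed = 3, n_patches = 5L)
  resp <- aggregateResponses(x, "specialist")
  mods <- enumerateCandidates(landscapeOrder(x), "abundance")
  # single-component Poisson model reproduces nllPoisson exactly
  p <- c(1.1, 0.6)
  mu <- exp(p[1] + p[2] * resp$log10_area)
  expect_equal(modelNLL(mods$B, p, resp), nllPoisson(resp$abundance, mu),
               tolerance = 1e-12)
  # permuting site order changes nothing
  set.seed(1)
  perm <- sample(nrow(resp))
  pF <- c(3.0, 0.8, 1.0, 1.2)
  expect_equal(modelNLL(mods$F, pF, resp), modelNLL(mods$F, pF, resp[perm, ]),
               tolerance = 1e-12)
  # model F NLL = sum of its three single-component evaluations
  byls <- split(resp, resp$landscape_id)
  parts <- nllPoisson(byls$L50$abundance,
                      rep(exp(pF[1]), nrow(byls$L50))) +
    nllPoisson(byls$L30$abundance, exp(pF[2] + pF[3] * byls$L30$log10_area)) +
    nllPoisson(byls$L10$abundance, rep(exp(pF[4]), nrow(byls$L10)))
  expect_equal(modelNLL(mods$F, pF, resp), parts, tolerance = 1e-12)
  expect_error(modelNLL(mods$F, pF[1:3], resp), "parameters")
})

test_that("closed-form MLEs are recovered exactly", {
  resp <- data.frame(site_id = paste0("s", 1:3), landscape_id = "L50",
                     log10_area = c(0.5, 1, 2), abundance = c(1L, 2L, 3L),
                     richness_response = c(2L, 4L, 6L), offset = 2L)
  one <- new("CandidateModel", model_id = "A", response = "abundance",
             components = list(fragRegime:::.component("L50", "constant",
                                                       intercepts = "shared")),
             distribution = "poisson", K = 1L, landscapes = "L50")
  # constant-Poisson MLE is the sample mean
  f <- fitModel(one, resp)
  expect_equal(exp(coef(f)[[1]]), 2, tolerance = 1e-8)
  expect_true(f@converged)
  expect_lte(f@logL, 0)

  # per-group means for a two-landscape constant model
  resp2 <- data.frame(site_id = paste0("s", 1:4),
                      landscape_id = c("Lx", "Lx", "Ly", "Ly"),
                      log10_area = 1, abundance = c(4L, 4L, 9L, 9L),
                      richness_response = 0L, offset = 2L)
  two <- new("CandidateModel", model_id = "C", response = "abundance",
             components = lapply(c("Lx", "Ly"), fragRegime:::.component,
                                 form = "constant", intercepts = "shared"),
             distribution = "poisson", K = 2L, landscapes = c("Lx", "Ly"))
  f2 <- fitModel(two, resp2)
  expect_equal(unname(exp(coef(f2))), c(4, 9), tolerance = 1e-6)

  # NB constant: fitted mean equals the sample mean (profile property)
  x <- small_study(seed = 9, n_patches = 8L)
  resp3 <- aggregateResponses(x, "specialist")
  A <- enumerateCandidates(landscapeOrder(x), "abundance")$A
  fA <- suppressWarnings(fitModel(A, resp3))
  expect_equal(exp(coef(fA)[[1]]), mean(resp3$abundance), tolerance = 1e-6)
})

test_that("optimized fits agree with glm/glm.nb and beat a local grid search", {
  x <- small_study(seed = 21, n_patches = 10L)
  resp <- aggregateResponses(x, "specialist")
  mods <- enumerateCandidates(landscapeOrder(x), "abundance")

  # D2 (Poisson, per-landscape intercepts+slopes) == glm(y ~ ls * x)
  fD2 <- fitModel(mods$D2, resp)
  g <- glm(abundance ~ 0 + landscape_id + landscape_id:log10_area,
           family = poisson, data = resp)
  expect_equal(fD2@logL, as.numeric(logLik(g)), tolerance = 1e-5)

  # A (negbin constant) == MASS::glm.nb intercept-only fit
  skip_if_not_installed("MASS")
  fA <- suppressWarnings(fitModel(mods$A, resp))
  gnb <- MASS::glm.nb(abundance ~ 1, data = resp)
  expect_equal(fA@logL, as.numeric(logLik(gnb)), tolerance = 1e-4)
  expect_equal(exp(coef(fA)[["log_k"]]), gnb$theta, tolerance = 1e-2)

  # F on a 30-site dataset: fitted NLL <= 5^4 grid optimum around the truth
  truth <- presetScenarios()$regime_shift@coefficients
  fF <- fitModel(mods$F, resp)
  grid_best <- oracle_grid_min("F", "poisson", unname(truth), resp)
  expect_lte(-fF@logL, grid_best + 1e-6)

  # richness response uses the offset of two: fitted mean is per-year
  ri <- enumerateCandidates(landscapeOrder(x), "richness")
  fR <- fitModel(ri$A, resp)
  expect_equal(exp(coef(fR)[[1]]), mean(resp$richness_response) / 2,
               tolerance = 1e-6)
})

test_that("degenerate and non-identifiable inputs are surfaced honestly", {
  # all-zero counts in one component: capped coefficient plus a warning
  resp <- data.frame(site_id = paste0("s", 1:6),
                     landscape_id = rep(c("L50", "L30", "L10"), each = 2),
                     log10_area = rep(c(0.5, 1.5), 3),
                     abundance = c(5L, 7L, 6L, 9L, 0L, 0L),
                     richness_response = 1L, offset = 2L)
  mods <- enumerateCandidates(c("L50", "L30", "L10"), "abundance")
  expect_warning(fF <- fitModel(mods$F, resp), "all-zero")
  expect_equal(unname(coef(fF)["const[L10]"]), log(1e-9))
  # a linear component needs two distinct areas
  resp$log10_area <- 1
  expect_error(fitModel(mods$F, resp), "distinct patch areas")
  # a component with no sites
  expect_error(fitModel(mods$F, resp[resp$landscape_id != "L30", ]),
               "no sites")
})
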