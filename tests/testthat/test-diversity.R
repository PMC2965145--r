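random_incidence <- function(seed, S = 10L, H = 8L, p = 0.35) {
  set.seed(seed)
  m <- matrix(rbinom(S * H, 1, p), S, H,
              dimnames = list(paste0("sp", seq_len(S)), NULL))
  m[rowSums(m) >= 1, , drop = FALSE]
}

test_that("the rarefaction expectation matches enumeration and end points", {
  # 2 species x 2 samples: the two 1-sample subsets see 2 and 1 species
  m <- matrix(c(1, 1, 0, 1), 2, 2)
  cur <- accumulationCurve(m)
  expect_equal(cur$tau[1], 1.5)
  expect_equal(cur$tau[2], 2)          # tau(H) = S_obs
  expect_equal(cur$sd[2], 0)           # conditional variance vanishes at H
  expect_equal(cur$sd[1], 0.5)         # subsets see 2 or 1 species, sd = 1/2
  expect_error(accumulationCurve(matrix(0, 0, 3)), "empty")

  for (seed in 1:3) {
    inc <- random_incidence(seed)
    cur <- accumulationCurve(inc)
    # monotone non-decreasing, ends at S_obs with zero sd
    expect_true(all(diff(cur$tau) >= -1e-12))
    expect_equal(cur$tau[ncol(inc)], nrow(inc))
    expect_equal(cur$sd[ncol(inc)], 0, tolerance = 1e-8)
    expect_equal(cur$lo95, cur$tau - 1.96 * cur$sd)
  }
})

test_that("rarefaction agrees with vegan and with Monte-Carlo subsampling", {
  skip_if_not_installed("vegan")
  inc <- random_incidence(7)
  cur <- accumulationCurve(inc)
  sp <- vegan::specaccum(t(inc), method = "exact")
  expect_equal(cur$tau, as.numeric(sp$richness), tolerance = 1e-8)

  # exact conditional variance vs Monte-Carlo draws at a mid curve point
  set.seed(99)
  h <- 4L
  mc <- accumulationMC(inc, h, n_draws = 4000L)
  expect_lt(abs(cur$tau[h] - mc$mean), 3 * mc$se)
  expect_equal(cur$sd[h], mc$sd, tolerance = 0.08)
})

test_that("incidence-based richness estimators follow their formulas", {
  # S_obs = 5, q1 = 2, q2 = 1 -> chao2 = 7; H = 4 -> jackknife1 = 6.5
  m <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0),
             c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(chao2(m), 7)
  expect_equal(jackknife1(m), 6.5)
  # no uniques: chao2 = S_obs
  m0 <- rbind(c(1, 1, 0), c(0, 1, 1))
  expect_equal(chao2(m0), 2)
  # q2 = 0 switches to the bias-corrected form
  m1 <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))
  expect_equal(chao2(m1), 3 + 2 * 1 / 2)
  expect_error(jackknife1(matrix(1, 2, 1)), ">= 2 samples")
  for (seed in 1:5) {
    inc <- random_incidence(seed + 20)
    expect_gte(chao2(inc), nrow(inc))
    expect_gte(jackknife1(inc), nrow(inc))
  }
  skip_if_not_installed("vegan")
  inc <- random_incidence(31)
  pool <- vegan::specpool(t(inc))
  expect_equal(jackknife1(inc), pool$jack1)
})

test_that("presence/absence similarity and representation behave as set formulas", {
  expect_equal(brayCurtisPresence(c("a", "b"), c("a", "b")), 100)
  expect_equal(brayCurtisPresence(c("a", "b"), c("c", "d")), 0)
  # a = 3 shared, b = 1, c = 2 -> 600/9
  x <- c("s1", "s2", "s3", "x1")
  y <- c("s1", "s2", "s3", "y1", "y2")
  expect_equal(brayCurtisPresence(x, y), 200 / 3, tolerance = 1e-10)
  expect_equal(brayCurtisPresence(x, y), brayCurtisPresence(y, x))
  expect_error(brayCurtisPresence(character(0), character(0)), "empty")
  # == 100 iff identical sets
  expect_lt(brayCurtisPresence(c("a", "b"), c("a", "b", "c")), 100)
  skip_if_not_installed("vegan")
  u <- union(x, y)
  bin <- rbind(as.integer(u %in% x), as.integer(u %in% y))
  expect_equal(brayCurtisPresence(x, y),
               100 * (1 - as.numeric(vegan::vegdist(bin, "bray"))),
               tolerance = 1e-10)

  expect_equal(representationPercent(c("a", "b", "c"), c("a", "b")), 100)
  expect_equal(representationPercent(c("x"), c("a", "b")), 0)
  expect_equal(representationPercent(paste0("s", 1:3), paste0("s", 1:16)),
               18.75)
  expect_error(representationPercent("a", character(0)), "empty")
})

test_that("incidence matrices and the diversity report are assembled per guild", {
  x <- tiny_study()
  inc <- incidenceMatrix(x, "specialist", c("L50", "L30"))
  # spA present at s1 (both years) and s3; spB at s1 only
  expect_identical(dim(inc), c(2L, 4L))
  expect_true(all(rowSums(inc) >= 1))
  expect_identical(unname(inc["spA", ]), c(1L, 0L, 1L, 0L))

  xg <- generateStudy(presetScenarios(4)$regime_shift,
                      presetScenarios(4)$generalist_release, seed = 4)
  rep_ <- diversityReport(xg, "specialist")
  expect_setequal(rownames(rep_$similarity), c("L50", "L30", "L10"))
  expect_equal(diag(rep_$similarity), c(L50 = 100, L30 = 100, L10 = 100))
  expect_identical(rep_$representation$fragmented, c("L50", "L30", "L10"))
  expect_true(all(rep_$representation$percent >= 0 &
                    rep_$representation$percent <= 100))
  expect_true(all(rep_$richness$chao2 >= rep_$richness$S_obs, na.rm = TRUE))
  # gamma diversity collapses in the most deforested landscape under the
  # regime-shift world
  S <- setNames(rep_$richness$S_obs, rep_$richness$landscape_id)
  expect_lt(S[["L10"]], S[["L30"]])
  expect_lt(S[["L10"]], S[["L50"]])
})
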