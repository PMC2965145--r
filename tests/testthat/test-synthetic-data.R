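test_that("presets encode the postulated worlds and round-trip through JSON", {
  pre <- presetScenarios()
  expect_setequal(names(pre), c("null", "patch_area", "landscape",
                                "andren_threshold", "regime_shift",
                                "generalist_release"))
  # regime shift: model F with a positive slope only in the 30% landscape
  rs <- pre$regime_shift
  expect_identical(rs@generating_model, "F")
  expect_gt(rs@coefficients[["slope[L30]"]], 0)
  expect_false(any(grepl("slope\\[L50|slope\\[L10", names(rs@coefficients))))
  # null: a single mean for all landscapes
  expect_identical(pre$null@generating_model, "A")
  expect_length(pre$null@coefficients, 1L)
  # generalist release: constants increasing with deforestation
  gr <- pre$generalist_release@coefficients
  expect_true(gr[["const[L10]"]] > gr[["const[L30]"]] &&
                gr[["const[L30]"]] > gr[["const[L50]"]])
  # serialization round trip preserves every preset
  for (nm in names(pre)) {
    path <- withr::local_tempfile(fileext = ".json")
    writeScenario(pre[[nm]], path)
    expect_equal(readScenario(path), pre[[nm]], info = nm)
  }
})

test_that("coefficients inconsistent with the generating model are rejected", {
  expect_error(Scenario("bad", "F", c("const[L50]" = 1)), "inconsistent")
  expect_error(Scenario("bad", "F",
                        c("const[L50]" = 1, "int[L30]" = 1,
                          "slope[L10]" = 1, "const[L10]" = 1)),
               "inconsistent")
  expect_error(Scenario("bad", "Z", c("const[L50]" = 1)), "unknown")
})

test_that("generation is seed-deterministic and passes study validation", {
  sc <- presetScenarios()[["regime_shift"]]
  a <- generateScenario(sc, seed = 123)
  b <- generateScenario(sc, seed = 123)
  expect_identical(assay(a, "year1"), assay(b, "year1"))
  expect_identical(assay(a, "year2"), assay(b, "year2"))
  expect_equal(as.data.frame(colData(a)), as.data.frame(colData(b)))
  d <- generateScenario(sc, seed = 124)
  expect_false(identical(assay(a, "year1"), assay(d, "year1")))
  # 15-20 patches per landscape by default (17) plus 6-site paired controls
  expect_identical(sum(!colData(a)$is_control), 51L)
  expect_identical(sum(colData(a)$is_control), 18L)
  expect_true(validObject(a))
  # generated tables survive the writer -> reader validation path
  dir <- withr::local_tempdir()
  writeStudy(a, dir)
  expect_s4_class(readStudy(dir), "CaptureExperiment")
})

test_that("generated counts follow the stated generating process", {
  # null world, many sites: site-total mean within the CLT bound of mu = 5
  sc <- presetScenarios()[["null"]]
  sc@landscapes$n_patches <- c(334L, 333L, 333L)
  x <- generateScenario(sc, seed = 2)
  ab <- aggregateResponses(x, "specialist")$abundance
  expect_lt(abs(mean(ab) - 5), 3 * sqrt(5 / 1000))
  # regime-shift world: site totals rise with patch area in the 30% landscape
  rs <- presetScenarios()[["regime_shift"]]
  rs@landscapes$n_patches <- c(17L, 200L, 17L)
  y <- generateScenario(rs, seed = 3)
  resp <- aggregateResponses(y, "specialist")
  l30 <- resp[resp$landscape_id == "L30", ]
  expect_gt(cor(l30$abundance, l30$log10_area, method = "spearman"), 0)
  # ... and are flat in the extreme landscapes (generating constants)
  l50 <- resp[resp$landscape_id == "L50", ]
  expect_lt(abs(mean(l50$abundance) - 30), 3 * sqrt(30 / nrow(l50)))
})

test_that("fitting the generating model to its own output recovers the truth", {
  sc <- presetScenarios()[["regime_shift"]]
  sc@landscapes$n_patches <- rep(60L, 3)
  est <- t(vapply(1:10, function(s) {
    x <- generateScenario(sc, seed = 100 + s)
    resp <- aggregateResponses(x, "specialist")
    f <- fitModel(enumerateCandidates(landscapeOrder(x), "abundance")$F, resp)
    coef(f)
  }, numeric(4)))
  truth <- sc@coefficients[colnames(est)]
  # replicate-mean estimate within 3 standard errors of the truth, per
  # coefficient
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth) <= 3 * se),
              info = paste(round(colMeans(est) - truth, 3), collapse = ", "))
})

test_that("two-guild studies share sites and split guild pools correctly", {
  pre <- presetScenarios(9)
  x <- generateStudy(pre$regime_shift, pre$generalist_release, seed = 9)
  expect_identical(sum(rowData(x)$guild == "specialist"), 27L)
  expect_identical(sum(rowData(x)$guild == "generalist"), 12L)
  expect_identical(ncol(x), 69L)
  # generalist release shows up as higher generalist abundance at 10% cover
  rg <- aggregateResponses(x, "generalist")
  m <- tapply(rg$abundance, rg$landscape_id, mean)
  expect_gt(m[["L10"]], m[["L50"]])
  expect_error(generateStudy(pre$regime_shift, pre$regime_shift),
               "generalist")
})
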