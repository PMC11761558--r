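test_that("wedge deformity yields exact generative heights and HLR", {
  ph <- buildPhantom(phantomSpec(
    nLevels = 1, baseHeight = 21, baseWidth = 60,
    deformities = list(deformitySpec(1, "wedge", heightLoss = 5,
                                     acute = FALSE))))
  expect_equal(unname(trueHeights(ph)[1, ]), c(16, 18.5, 21))
  expect_equal(computeHLR(trueHeights(ph)[1, ]), (1 - 16 / 21) * 100,
               tolerance = 1e-12)
  expect_false(truthAcute(ph))
})

test_that("deformity kinds subtract height loss from the intended heights", {
  for (kind in c("wedge", "biconcave", "crush")) {
    for (L in c(3, 8, 14)) {
      ph <- buildPhantom(phantomSpec(
        nLevels = 1, baseHeight = 36, baseWidth = 60,
        deformities = list(deformitySpec(1, kind, heightLoss = L,
                                         acute = FALSE))))
      h <- trueHeights(ph)[1, ]
      expected <- switch(kind,
        wedge = c(36 - L, 36 - L / 2, 36),
        biconcave = c(36, 36 - L, 36),
        crush = c(36 - L, 36 - L, 36 - L))
      expect_equal(unname(h), expected, tolerance = 1e-12,
                   label = sprintf("%s loss %g", kind, L))
    }
  }
})

test_that("undeformed phantoms have baseline HLR and no acute flags", {
  ph <- buildPhantom(phantomSpec(nLevels = 5))
  expect_false(any(truthAcute(ph)))
  hlrs <- apply(trueHeights(ph), 1, computeHLR)
  expect_equal(hlrs, rep(0, 5), tolerance = 1e-12)

  wed <- c(0, 0, 0, -0.04, -0.08)
  ph2 <- buildPhantom(phantomSpec(nLevels = 5, wedgingProfile = wed))
  hlrs2 <- apply(trueHeights(ph2), 1, computeHLR)
  # printed-variant baseline implied by the wedging profile alone
  expected <- vapply(seq_len(5), function(k) {
    hp <- 36 * 1.06^(k - 1); ha <- hp * (1 - wed[k])
    computeHLR(c(ha + 0.1 * (hp - ha), (ha + hp) / 2, hp - 0.1 * (hp - ha)))
  }, 1)
  expect_equal(hlrs2, expected, tolerance = 1e-9)
})

test_that("step-off and cortical break leave generative heights intact", {
  base <- buildPhantom(phantomSpec(nLevels = 1))
  for (d in list(deformitySpec(1, "step_off", offset = 5),
                 deformitySpec(1, "cortical_break", gapLen = 6))) {
    ph <- buildPhantom(phantomSpec(nLevels = 1, deformities = list(d)))
    expect_equal(trueHeights(ph), trueHeights(base), tolerance = 1e-12)
    expect_true(truthAcute(ph))
  }
})

test_that("fixed absolute loss on scaled copies gives strictly decreasing HLR", {
  # five scaled copies of one body, 5-unit loss each: brute-force HLR over
  # the generated geometries must fall as scale grows
  hlrs <- vapply(seq(1, 1.8, length.out = 5), function(s) {
    ph <- buildPhantom(phantomSpec(
      nLevels = 1, baseHeight = 21 * s, baseWidth = 60 * s,
      deformities = list(deformitySpec(1, "wedge", heightLoss = 5,
                                       acute = FALSE))))
    computeHLR(trueHeights(ph)[1, ])
  }, 1)
  expect_true(all(diff(hlrs) < 0))
})

test_that("scaling a phantom scales heights and preserves generative HLR", {
  defs <- list(deformitySpec(2, "wedge", heightLoss = 0.2 * 36, acute = FALSE))
  ph1 <- buildPhantom(phantomSpec(nLevels = 3, deformities = defs))
  s <- 2.5
  defs2 <- list(deformitySpec(2, "wedge", heightLoss = 0.2 * 36 * s,
                              acute = FALSE))
  ph2 <- buildPhantom(phantomSpec(nLevels = 3, baseWidth = 60 * s,
                                  baseHeight = 36 * s, deformities = defs2))
  expect_equal(trueHeights(ph2), trueHeights(ph1) * s, tolerance = 1e-12)
  expect_equal(apply(trueHeights(ph2), 1, computeHLR),
               apply(trueHeights(ph1), 1, computeHLR), tolerance = 1e-12)
  # fixed absolute loss breaks the invariance
  ph3 <- buildPhantom(phantomSpec(nLevels = 3, baseWidth = 60 * s,
                                  baseHeight = 36 * s, deformities = defs))
  expect_true(computeHLR(trueHeights(ph3)[2, ]) <
                computeHLR(trueHeights(ph1)[2, ]))
})

test_that("deformity level out of range is a named error", {
  expect_error(
    buildPhantom(phantomSpec(nLevels = 2, deformities = list(
      deformitySpec(5, "wedge", heightLoss = 3, acute = FALSE)))),
    "level 5")
})

test_that("acute-marker kinds require acute = TRUE", {
  expect_error(deformitySpec(1, "step_off", offset = 3, acute = FALSE),
               "acute")
  expect_s4_class(deformitySpec(1, "step_off", offset = 3), "DeformitySpec")
})

test_that("rasterization labels pixels by polygon membership", {
  rect <- cbind(x = c(2, 22, 22, 2), y = c(3, 3, 13, 13))
  m <- rasterizeMask(list(rect), dim = c(20, 30))
  expect_identical(sum(m == 1L), 200L)

  two <- list(rect, cbind(x = c(30, 40, 40, 30), y = c(3, 3, 13, 13)))
  m2 <- rasterizeMask(two, dim = c(20, 50))
  expect_setequal(setdiff(unique(as.vector(m2)), 0L), c(1L, 2L))

  overlapping <- list(rect, rect + 1)
  expect_error(rasterizeMask(overlapping, dim = c(20, 30)), "overlap")
})

test_that("rasterized wedge column profile tracks the analytic linear profile", {
  # pure trapezoid: linear top edge from ha to hp
  ph <- buildPhantom(phantomSpec(nLevels = 1, baseHeight = 40, baseWidth = 80,
                                 wedgingProfile = 0.25))
  m <- rasterizePhantom(ph)
  x0 <- 8; w <- 80; hp <- 40; ha <- 30
  cols <- which(colSums(m == 1L) > 0)
  for (j in cols) {
    t <- ((j - 0.5) - x0) / w
    analytic <- ha + t * (hp - ha)
    expect_lt(abs(sum(m[, j] == 1L) - analytic), 1 + 1e-9)
  }
})

test_that("rasterized area matches analytic polygon area within 2%", {
  for (ss in c(1, 2)) {
    ph <- buildPhantom(phantomSpec(nLevels = 2, wedgingProfile = c(0, 0.1)))
    m <- rasterizePhantom(ph, supersample = ss)
    for (k in 1:2) {
      p <- polygons(ph)[[k]]
      # shoelace
      xs <- p[, 1]; ys <- p[, 2]
      area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
      expect_lt(abs(sum(m == k) / ss^2 - area) / area, 0.02)
    }
  }
})

test_that("perfect and null emulated detectors match truth exactly", {
  truth <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  perfect <- emulateDetector(truth, sens = 1, spec = 1, seed = 3)
  expect_identical(perfect$positive, truth)
  none <- emulateDetector(truth, sens = 0, spec = 1, seed = 3)
  expect_false(any(none$positive))
})

test_that("emulated detector hits its operating point within binomial bounds", {
  truth <- rep(TRUE, 10000)
  calls <- emulateDetector(truth, sens = 0.8445, spec = 0.9, seed = 11)
  obs <- mean(calls$positive)
  half <- qnorm(0.995) * sqrt(0.8445 * (1 - 0.8445) / 10000)
  expect_lt(abs(obs - 0.8445), half)
})

test_that("emulator calibration converges at large n (3 sigma)", {
  n <- 1e5
  truth <- rep(c(TRUE, FALSE), length.out = n)
  calls <- emulateDetector(truth, sens = 0.6757, spec = 0.9921, seed = 5)
  sens <- mean(calls$positive[truth])
  spec <- mean(!calls$positive[!truth])
  expect_lt(abs(sens - 0.6757), 3 * sqrt(0.6757 * (1 - 0.6757) / sum(truth)))
  expect_lt(abs(spec - 0.9921), 3 * sqrt(0.9921 * (1 - 0.9921) / sum(!truth)))
  # reproducible under the same seed
  again <- emulateDetector(truth, sens = 0.6757, spec = 0.9921, seed = 5)
  expect_identical(calls, again)
})

test_that("phantom polygons are pairwise disjoint in the raster", {
  specs <- sampleCohortSpecs(4, seed = 21)
  for (sp in specs) {
    ph <- buildPhantom(sp)
    m <- rasterizePhantom(ph)   # would error on overlap
    expect_identical(sort(setdiff(unique(as.vector(m)), 0L)),
                     seq_len(sp@nLevels))
  }
})
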