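test_that("coupling degree is the balance of the two subsystem scores", {
  expect_equal(coupling_degree(0.64, 0.64), 1)
  expect_equal(coupling_degree(0, 0.8), 0)
  expect_equal(coupling_degree(0.2, 0.8), 2 * sqrt(0.16) / 1.0)  # 0.8
  expect_warning(c0 <- coupling_degree(0, 0), "convention")
  expect_equal(c0, 0)
  expect_error(coupling_degree(-0.1, 0.5), "non-negative")
})

test_that("comprehensive index is the weighted subsystem level", {
  expect_equal(comprehensive_index(0.2, 0.8), 0.5)
  expect_equal(comprehensive_index(0.3, 0.9, alpha = 1, beta = 0), 0.3)
  expect_equal(comprehensive_index(0.4, 0.4, alpha = 0.7, beta = 0.3), 0.4)
  expect_error(comprehensive_index(0.2, 0.8, alpha = 0.7, beta = 0.5),
               "sum to 1")
})

test_that("coordination degree supports both the radical and product forms", {
  expect_equal(coordination_degree(1, 1), 1)
  expect_equal(coordination_degree(0, 0.7), 0)
  expect_equal(coordination_degree(0.8, 0.5), sqrt(0.4))  # ~0.63246
  expect_equal(coordination_degree(0.8, 0.5, form = "product"), 0.4)
  expect_error(coordination_degree(1.2, 0.5), "0, 1")
})

test_that("every boundary of the nine-rung ladder maps to its own rung", {
  expect_equal(classify_ccd(0.45)$type, "Borderline disorder")
  expect_equal(classify_ccd(0.45)$stage, "Run-in")
  expect_equal(classify_ccd(0.75)$type, "Intermediate coordinate")
  expect_equal(classify_ccd(0.75)$stage, "Coordination")
  expect_equal(classify_ccd(0)$type, "Severe disorder")
  # half-open convention: each lower bound belongs to its own rung
  lad <- ccd_ladder()
  at_lower <- classify_ccd(lad$lower)
  expect_equal(at_lower$type, lad$type)
  expect_equal(classify_ccd(0.2)$type, "Moderate disorder")
  expect_equal(classify_ccd(1)$type, "Excellent coordinate")
  just_below <- classify_ccd(lad$upper - 1e-9)
  expect_equal(just_below$type, lad$type)
  expect_error(classify_ccd(1.5), "0, 1")
})

test_that("ESV normalisation rescales pooled or per-city", {
  df <- data.frame(city = "a", year = 1:3, esv_total = c(100, 200, 300))
  expect_equal(normalize_esv(df)$g, c(0, 0.5, 1))
  neg <- data.frame(city = "a", year = 1:3, esv_total = c(-10, 0, 10))
  expect_equal(normalize_esv(neg)$g, c(0, 0.5, 1))
  expect_error(normalize_esv(data.frame(city = "a", year = 1:3,
                                        esv_total = c(5, 5, 5))),
               "distinct")
  # per-city extremes differ: pooled and per-city disagree
  two <- data.frame(city = rep(c("a", "b"), each = 2), year = rep(1:2, 2),
                    esv_total = c(0, 10, 0, 20))
  pooled <- normalize_esv(two, "pooled")$g
  percity <- normalize_esv(two, "per_city")$g
  expect_equal(percity, c(0, 1, 0, 1))
  expect_equal(pooled, c(0, 0.5, 0, 1))
})

test_that("the pipeline aligns keys, classifies every row and summarises years", {
  f <- data.frame(city = "a", year = 2011, score = 1)
  g <- data.frame(city = "a", year = 2011, g = 1)
  one <- ccd_pipeline(f, g)
  expect_equal(one$D, 1)
  expect_equal(one$type, "Excellent coordinate")
  # symmetry: swapping (f, g) across cities leaves D unchanged at alpha = beta
  f2 <- data.frame(city = c("a", "b"), year = 2011, score = c(0.2, 0.8))
  g2 <- data.frame(city = c("a", "b"), year = 2011, g = c(0.8, 0.2))
  out <- ccd_pipeline(f2, g2)
  expect_equal(out$D[1], out$D[2])
  # three-row fixture: per-year gap equals the hand-computed max - min
  f3 <- data.frame(city = c("a", "b", "c"), year = 2011,
                   score = c(0.2, 0.5, 0.9))
  g3 <- data.frame(city = c("a", "b", "c"), year = 2011,
                   g = c(0.4, 0.5, 0.3))
  out3 <- ccd_pipeline(f3, g3)
  ys <- attr(out3, "year_summary")
  expect_equal(ys$gap_D, max(out3$D) - min(out3$D))
  expect_equal(ys$mean_D, mean(out3$D))
  # misaligned keys name the offenders
  gbad <- data.frame(city = c("a", "z"), year = 2011, g = c(0.1, 0.2))
  expect_error(ccd_pipeline(f2, gbad), "z 2011")
})

test_that("C and D stay in the unit interval over a randomised sweep", {
  set.seed(37)
  f <- runif(2000, 1e-6, 1)
  g <- runif(2000, 1e-6, 1)
  C <- coupling_degree(f, g)
  D <- coordination_degree(C, comprehensive_index(f, g))
  expect_true(all(C >= 0 & C <= 1))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(C[abs(f - g) > 1e-8] < 1))
  expect_equal(coupling_degree(f, f), rep(1, length(f)))
  # on the diagonal f = g: C = 1, T = f, so D = sqrt(f) (radical form)
  # or D = f (product form); strictly increasing either way
  fs <- sort(runif(50))
  C1 <- coupling_degree(fs, fs)
  expect_equal(coordination_degree(C1, comprehensive_index(fs, fs)), sqrt(fs))
  expect_equal(coordination_degree(C1, comprehensive_index(fs, fs),
                                   form = "product"), fs)
})
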