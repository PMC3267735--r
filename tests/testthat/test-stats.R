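make_design <- function(n) {
  expand.grid(subject = seq_len(n),
              session = c("anodal", "cathodal", "sham"),
              time = c("before", "after"),
              stringsAsFactors = FALSE)
}

test_that("global paired tests handle identical and degenerate data", {
  tbl <- data.frame(subject = rep(1:5, 2),
                    session = "cathodal",
                    time = rep(c("before", "after"), each = 5),
                    threshold = 0.3,
                    value = rep(c(1, 2, 3, 4, 5), 2))
  res <- global_metric_tests(tbl)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  tbl2 <- tbl
  tbl2$value[6:10] <- tbl2$value[1:5] + 0.7  # constant shift, zero variance
  expect_warning(res2 <- global_metric_tests(tbl2), "zero-variance")
  expect_true(is.nan(res2$p))
})

test_that("paired t maps match the textbook formula", {
  set.seed(1)
  des <- make_design(8)
  vals <- matrix(rnorm(nrow(des) * 12), nrow(des), 12)
  pm <- posthoc_paired_map(vals, des, c("cathodal", "after"),
                           c("cathodal", "before"))
  ia <- which(des$session == "cathodal" & des$time == "after")
  ib <- which(des$session == "cathodal" & des$time == "before")
  for (v in sample(12, 5)) {
    tt <- t.test(vals[ia, v], vals[ib, v], paired = TRUE)
    expect_equal(unname(pm$stat[v]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pm$p[v], tt$p.value, tolerance = 1e-10)
  }
  # a contrast of a map with itself is identically zero
  pm0 <- posthoc_paired_map(rbind(vals, vals[ia, ]),
                            rbind(des, transform(des[ia, ], time = "after2")),
                            c("cathodal", "after2"), c("cathodal", "after"))
  expect_true(all(pm0$stat == 0))
})

test_that("the interaction F map equals the repeated-measures ANOVA oracle", {
  set.seed(2)
  des <- make_design(7)
  vals <- matrix(rnorm(nrow(des) * 10), nrow(des), 10)
  sm <- interaction_map(vals, des)
  expect_equal(sm$df, c(2, 12))
  for (v in sample(10, 5)) {
    d <- data.frame(y = vals[, v],
                    subject = factor(des$subject),
                    session = factor(des$session),
                    time = factor(des$time))
    fit <- summary(aov(y ~ session * time + Error(subject / (session * time)),
                       data = d))
    f_oracle <- fit[["Error: subject:session:time"]][[1]]["session:time", "F value"]
    expect_equal(unname(sm$stat[v]), f_oracle, tolerance = 1e-8)
  }
})

test_that("the interaction is invariant to per-subject constants and flat under equal cells", {
  set.seed(3)
  des <- make_design(6)
  vals <- matrix(rnorm(nrow(des) * 6), nrow(des), 6)
  shifted <- vals + rnorm(6)[des$subject]
  f1 <- interaction_map(vals, des)$stat
  f2 <- interaction_map(shifted, des)$stat
  expect_equal(f1, f2, tolerance = 1e-10)

  flat <- matrix(rep(rnorm(6)[des$subject], 4), nrow(des), 4)
  sm <- interaction_map(flat + 1e-9 * matrix(rnorm(nrow(des) * 4), nrow(des)), des)
  expect_true(all(stats::pf(sm$stat, 2, 10, lower.tail = FALSE) > 1e-6))
})

test_that("a planted interaction effect elevates F only in the subregion", {
  set.seed(4)
  des <- make_design(10)
  vals <- matrix(rnorm(nrow(des) * 30), nrow(des), 30)
  bump <- des$session == "cathodal" & des$time == "after"
  vals[bump, 1:8] <- vals[bump, 1:8] + 2
  sm <- interaction_map(vals, des)
  expect_gt(mean(sm$stat[1:8]), 5 * mean(sm$stat[9:30]))
})

test_that("cluster correction returns nothing without supra-threshold voxels", {
  roi <- make_roi(30, "slab", seed = 1)
  set.seed(5)
  des <- data.frame(subject = rep(1:8, 2), session = "cathodal",
                    time = rep(c("before", "after"), each = 8))
  vals <- matrix(rnorm(16 * 30, sd = 1e-2), 16, 30)
  vals <- vals - ave(vals, des$subject)  # kill any paired effect
  pm <- posthoc_paired_map(vals * 0 + matrix(rnorm(16 * 30, sd = 1e-6), 16), des,
                           c("cathodal", "after"), c("cathodal", "before"), roi)
  pm$p[] <- 1
  cc <- cluster_correct(pm, roi, n_permutations = 120, seed = 1)
  expect_equal(nrow(cc$clusters), 0)
})

test_that("a uniform strong effect yields one cluster spanning the ROI", {
  roi <- make_roi(30, "slab", seed = 1)
  set.seed(6)
  n <- 10
  des <- data.frame(subject = rep(1:n, 2), session = "cathodal",
                    time = rep(c("before", "after"), each = n))
  base <- matrix(rnorm(n * 30), n, 30)
  vals <- rbind(base, base + 5 + 0.1 * matrix(rnorm(n * 30), n, 30))
  pm <- posthoc_paired_map(vals, des, c("cathodal", "after"),
                           c("cathodal", "before"), roi)
  cc <- cluster_correct(pm, roi, n_permutations = 200, seed = 2)
  expect_equal(nrow(cc$clusters), 1)
  expect_equal(cc$clusters$n_voxels, 30)
  expect_equal(cc$clusters$mm3, 30 * 27)
  expect_lt(cc$clusters$p_corrected, 0.05)
})

test_that("exhaustive sign-flipping equals the enumeration oracle", {
  # single-voxel ROI: cluster inference reduces to a sign test
  roi <- structure(list(coords = matrix(c(0L, 0L, 0L), 1),
                        voxel_size_mm = 3, n_voxels = 1L),
                   class = "roi_mask")
  set.seed(7)
  for (rep in 1:3) {
    d <- rnorm(9, mean = 0.8)
    des <- data.frame(subject = rep(1:9, 2), session = "cathodal",
                      time = rep(c("before", "after"), each = 9))
    vals <- rbind(matrix(0, 9, 1), matrix(d, 9, 1))
    pm <- posthoc_paired_map(vals, des, c("cathodal", "after"),
                             c("cathodal", "before"), roi)
    cc <- cluster_correct(pm, roi, exhaustive = TRUE)
    if (nrow(cc$clusters)) {
      expect_equal(cc$clusters$p_corrected, oracle_signflip_p(d),
                   tolerance = 1e-12)
    } else {
      expect_gt(pm$p[1], 0.05)
    }
  }
})

test_that("corrected p is stable under subject relabelling", {
  roi <- make_roi(40, "slab", seed = 2)
  set.seed(8)
  n <- 12
  des <- data.frame(subject = rep(1:n, 2), session = "cathodal",
                    time = rep(c("before", "after"), each = n))
  base <- matrix(rnorm(n * 40), n, 40)
  eff <- matrix(0, n, 40)
  eff[, 1:10] <- 1.2
  vals <- rbind(base, base + eff + 0.8 * matrix(rnorm(n * 40), n, 40))
  pm <- posthoc_paired_map(vals, des, c("cathodal", "after"),
                           c("cathodal", "before"), roi)
  cc1 <- cluster_correct(pm, roi, n_permutations = 600, seed = 3)
  perm <- sample(n)
  reorder <- c(perm, n + perm)
  cc2 <- cluster_correct(posthoc_paired_map(vals[reorder, ], des,
                                            c("cathodal", "after"),
                                            c("cathodal", "before"), roi),
                         roi, n_permutations = 600, seed = 4)
  p1 <- cc1$clusters$p_corrected[1]
  p2 <- cc2$clusters$p_corrected[1]
  se <- sqrt(max(p1, 1 / 601) * (1 - max(p1, 1 / 601)) / 600)
  expect_lt(abs(p1 - p2), 2 * se + 2 / 601)
})

test_that("baseline dependence recovers exact and planted relations", {
  before <- matrix(rep(seq(1, 2, length.out = 6), 10), 6, 10)
  after <- before * 1.5  # effect strictly proportional to baseline
  # lm warns about the perfect fit; the exact R^2 is the point here
  bd <- suppressWarnings(baseline_dependence(1:10, before, after))
  expect_equal(bd$r_squared, 1, tolerance = 1e-12)
  expect_equal(bd$slope, 0.5, tolerance = 1e-12)

  # formula oracle against lm on the aggregated scalars
  set.seed(9)
  b2 <- matrix(rnorm(8 * 10), 8, 10)
  a2 <- matrix(rnorm(8 * 10), 8, 10)
  bd2 <- baseline_dependence(2:6, b2, a2)
  x <- rowMeans(b2[, 2:6])
  y <- rowMeans(a2[, 2:6] - b2[, 2:6])
  fit <- lm(y ~ x)
  expect_equal(bd2$slope, unname(coef(fit)[2]))
  expect_equal(bd2$r_squared, summary(fit)$r.squared)
  expect_equal(bd2$p, unname(summary(fit)$coefficients[2, 4]))
  expect_error(baseline_dependence(1:3, b2[1:2, ], a2[1:2, ]), "3 subjects")
})

test_that("dice overlap behaves at the boundaries", {
  expect_equal(dice_overlap(1:10, 1:10), 1)
  expect_equal(dice_overlap(1:10, 11:20), 0)
  expect_equal(dice_overlap(1:10, 6:15), 0.5)
})
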