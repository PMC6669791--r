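make_sset <- function(masks, spacing = c(2, 2, 3)) {
  structure_set(masks, spacing = spacing)
}

test_that("perfect predictions score Dice 1 and zero distances", {
  set.seed(60)
  truth <- list()
  for (id in sprintf("case%03d", 1:3)) {
    m <- array(0, c(10, 10, 6)); m[3:6, 3:6, 2:4] <- 1
    h <- array(0, c(10, 10, 6)); h[7:9, 7:9, 3:5] <- 1
    truth[[id]] <- make_sset(list(left_breast = m, heart = h))
  }
  rep <- evaluate_cohort(truth, truth)
  expect_true(all(rep$dice == 1))
  expect_true(all(rep$rms_surface_mm == 0))
  expect_true(all(rep$hausdorff_mm == 0))
  expect_false(any(rep$excluded))
})

test_that("empty predictions are excluded per organ with a reason", {
  set.seed(61)
  truth <- list(); preds <- list()
  for (i in 1:5) {
    id <- sprintf("case%03d", i)
    m <- array(0, c(8, 8, 4)); m[2:5, 2:5, 2:3] <- 1
    truth[[id]] <- make_sset(list(heart = m))
    pm <- if (i == 3) array(0, c(8, 8, 4)) else {
      shifted <- array(0, c(8, 8, 4)); shifted[3:6, 2:5, 2:3] <- 1; shifted
    }
    preds[[id]] <- make_sset(list(heart = pm))
  }
  rep <- evaluate_cohort(preds, truth)
  expect_identical(sum(rep$excluded), 1L)
  expect_identical(rep$reason[rep$excluded], "empty prediction")
  sm <- summary(rep)
  expect_identical(sm$n, 4L)
  # median equals brute-force sort-and-middle of the scored values
  scored <- rep$dice[!rep$excluded]
  expect_equal(sm$median_dice, sort(scored)[ceiling(length(scored) / 2)])
  expect_error(evaluate_cohort(preds[1:2], truth), "ids")
})

test_that("median reporting is robust to one corrupted case", {
  set.seed(62)
  truth <- list(); predA <- list(); predB <- list()
  for (i in 1:6) {
    id <- sprintf("case%03d", i)
    m <- array(0, c(10, 10, 6)); m[3:7, 3:7, 2:5] <- 1
    truth[[id]] <- make_sset(list(heart = m))
    p <- array(0, c(10, 10, 6)); p[3:7, 3:7, 2:5] <- 1
    p[sample(600, 4)] <- 1                # small perturbation
    predA[[id]] <- make_sset(list(heart = p))
    # one catastrophic failure in cohort B
    q <- if (i == 4) {
      bad <- array(0, c(10, 10, 6)); bad[1, 1, 1] <- 1; bad
    } else p
    predB[[id]] <- make_sset(list(heart = q))
  }
  ra <- summary(evaluate_cohort(predA, truth))
  rb <- summary(evaluate_cohort(predB, truth))
  expect_equal(rb$median_dice, ra$median_dice, tolerance = 0.05)
  expect_lt(rb$mean_dice, ra$mean_dice - 0.05)
})

test_that("paired t test matches the closed formula and handles degeneracy", {
  a <- c(5, 7, 9, 11); b <- a - c(1, 2, 3, 4)
  tt <- paired_t_test(a, b)
  d <- c(1, 2, 3, 4)
  t_ref <- mean(d) / (sd(d) / sqrt(4))
  p_ref <- 2 * (1 - pt(abs(t_ref), df = 3))
  expect_equal(tt$t, t_ref, tolerance = 1e-12)
  expect_equal(tt$p, p_ref, tolerance = 1e-12)
  expect_identical(tt$df, 3)
  # antisymmetry
  rev <- paired_t_test(b, a)
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$p, tt$p)
  # identical inputs: degenerate, flagged
  dg <- paired_t_test(a, a)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p))
  expect_error(paired_t_test(1, 1:2), "equal-length")
})

test_that("type-I error of the paired t test is near nominal under the null", {
  set.seed(63)
  n_sim <- 500
  rejections <- 0
  for (s in seq_len(n_sim)) {
    a <- rnorm(20); b <- rnorm(20)
    if (paired_t_test(a, b)$p < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Bonferroni adjustment divides the level by the comparisons", {
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3)
  expect_equal(round(bonferroni_alpha(0.05, 3), 4), 0.0167)
  expect_equal(bonferroni_alpha(0.07, 1), 0.07)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
  expect_error(bonferroni_alpha(1.2, 2), "in \\(0, 1\\)")
})

test_that("model comparison reports both metrics with the adjusted level", {
  set.seed(64)
  truth <- list(); predA <- list(); predB <- list()
  for (i in 1:6) {
    id <- sprintf("case%03d", i)
    m <- array(0, c(10, 10, 6)); m[3:7, 3:7, 2:5] <- 1
    truth[[id]] <- make_sset(list(heart = m))
    pa <- m
    predA[[id]] <- make_sset(list(heart = pa))
    pb <- array(0, c(10, 10, 6)); pb[4:8, 3:7, 2:5] <- 1
    predB[[id]] <- make_sset(list(heart = pb))
  }
  ra <- evaluate_cohort(predA, truth)
  rb <- evaluate_cohort(predB, truth)
  cmp <- compare_models(ra, rb, alpha = 0.05, m = 3)
  expect_identical(nrow(cmp), 2L)
  expect_setequal(cmp$metric, c("dice", "rms_surface_mm"))
  expect_equal(unique(cmp$alpha_adjusted), 0.05 / 3)
})
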