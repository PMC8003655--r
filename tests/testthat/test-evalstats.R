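test_that("dice follows the overlap formula and its edge rules", {
  a <- voi_mask(array(c(rep(1, 4), rep(0, 23)), c(3, 3, 3)))
  b <- voi_mask(array(c(rep(1, 3), 0, rep(1, 3), rep(0, 20)), c(3, 3, 3)))
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))   # |a|=4, |b|=6, overlap 3 -> 0.6
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(a, a), 1)
  disjoint <- voi_mask(array(c(rep(0, 4), 1, rep(0, 22)), c(3, 3, 3)))
  expect_equal(dice(a, disjoint), 0)
  empty <- voi_mask(array(0, c(3, 3, 3)))
  expect_error(dice(empty, empty), "empty")
  expect_error(dice(a, voi_mask(array(0, c(2, 2, 2)))), "shapes")
})

test_that("dice agrees with a brute-force counting oracle on random masks", {
  for (seed in 1:20) {
    a <- random_mask(c(8, 8, 8), p = 0.3, seed = seed)
    b <- random_mask(c(8, 8, 8), p = 0.4, seed = seed + 100)
    expect_identical(dice(a, b), dice_oracle(a, b))
  }
})

test_that("tumor volume converts voxel counts through spacing metadata", {
  expect_equal(tumor_volume_ml(voi_mask(array(0, c(4, 4, 4)))), 0)
  m <- voi_mask(array(1, c(10, 10, 10)))
  expect_equal(tumor_volume_ml(m), 1)    # 1000 voxels at 1 mm^3 = 1 mL
  aniso <- random_mask(c(6, 6, 6), p = 0.5, seed = 3)
  aniso$spacing <- c(1, 1, 5)
  expect_equal(tumor_volume_ml(aniso), sum(aniso$data) * 5 / 1000)
})

test_that("Welch ANOVA matches its closed forms and oracles", {
  # three identical groups: no between-group variance
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- welch_anova(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # two groups: F = t^2 of the Welch t-test, identical p
  withr::with_seed(10, {
    for (i in 1:10) {
      x <- rnorm(5 + i %% 3); y <- rnorm(7, 0.5, 2)
      res <- welch_anova(list(x, y))
      tt <- t.test(x, y, var.equal = FALSE)
      expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    }
  })

  # fixed arrays: frozen values from an independent implementation
  res <- welch_anova(list(c(1, 2, 3, 4), c(2, 3, 4, 5), c(5, 6, 7, 9)))
  expect_equal(res$F, 7.279889, tolerance = 1e-6)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 5.917808, tolerance = 1e-6)
  expect_equal(res$p, 0.025398, tolerance = 1e-5)

  # k = 2 with exactly equal sample variances and sizes reduces to the
  # classical equal-variance ANOVA
  x <- c(1, 2, 3, 6); y <- x + 2.5
  w <- welch_anova(list(x, y))
  cl <- stats::oneway.test(c(x, y) ~ factor(rep(1:2, each = 4)), var.equal = TRUE)
  expect_equal(w$F, unname(cl$statistic), tolerance = 1e-6)
  expect_equal(w$p, cl$p.value, tolerance = 1e-6)

  expect_error(welch_anova(list(c(1, 1, 1), c(1, 2, 3))), "zero variance")
  expect_error(welch_anova(list(c(1, 2))), "two groups")
})

test_that("Games-Howell matches an independent implementation and its edge rules", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(5, 6, 7, 9))
  gh <- games_howell(g)
  expect_equal(nrow(gh), 3)   # k(k-1)/2
  # frozen from an independent implementation of the Games-Howell formulas
  expect_equal(gh$diff, c(1, 4.25, 3.25))
  expect_equal(gh$se, c(0.912871, 1.070436, 1.070436), tolerance = 1e-6)
  expect_equal(gh$df, c(6.0, 5.584615, 5.584615), tolerance = 1e-6)
  expect_equal(gh$p_adj, c(0.550798, 0.019707, 0.056185), tolerance = 1e-4)

  # two identical groups: adjusted p of 1
  gh2 <- games_howell(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(abs(gh2$p_adj - 1), 1e-6)

  # pair count for k = 4
  g4 <- lapply(1:4, function(i) c(1, 2, 3) + i)
  expect_equal(nrow(games_howell(g4)), 6)
})

test_that("multiplicity never makes a pair more significant", {
  withr::with_seed(21, {
    for (rep in 1:15) {
      k <- sample(3:4, 1)
      g <- lapply(1:k, function(i) rnorm(sample(4:8, 1), mean = i * 0.3))
      gh <- games_howell(g)
      for (r in seq_len(nrow(gh))) {
        i <- as.integer(sub("g", "", gh$group1[r]))
        j <- as.integer(sub("g", "", gh$group2[r]))
        p_welch <- t.test(g[[i]], g[[j]], var.equal = FALSE)$p.value
        expect_gte(gh$p_adj[r], p_welch - 1e-10)
      }
    }
  })
})

test_that("pearson_r matches the covariance definition", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  withr::with_seed(8, { a <- rnorm(20); b <- 0.3 * a + rnorm(20) })
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), direct, tolerance = 1e-12)
  expect_error(pearson_r(1:5, 1:4), "lengths")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_r(1:2, 1:2), "3 observations")
})

test_that("histogram profiles conserve counts and expose the easy-case pattern", {
  ph <- tiny_phantom(seed = 12, shape = c(24L, 24L, 24L), radii = c(6, 6, 6))
  vol <- zscore_normalize(ph$volume)
  voi <- merge_voi(ph$labels)
  hp <- histogram_profile(vol, voi, channel = 2)
  supp_n <- sum(apply(vol$data != 0, 1:3, any))
  for (ch in 1:4) expect_equal(sum(hp$counts[, ch]), supp_n)
  expect_equal(sum(hp$voi_counts), sum(voi$data))
  expect_equal(hp$voi_fraction, sum(voi$data) / supp_n)
  # bright tumor sits to the right of the support-wide median
  z_all <- vol$data[, , , 2][apply(vol$data != 0, 1:3, any)]
  expect_gt(hp$voi_median_z, median(z_all))

  # full-support VOI and empty VOI edges
  full <- voi_mask(array(as.numeric(apply(vol$data != 0, 1:3, any)), c(24, 24, 24)))
  expect_equal(histogram_profile(vol, full)$voi_fraction, 1)
  none <- voi_mask(array(0, c(24, 24, 24)))
  hp0 <- histogram_profile(vol, none)
  expect_equal(hp0$voi_fraction, 0)
  expect_true(is.na(hp0$voi_median_z))
})

test_that("record aggregation reports mean, SD and conserved counts", {
  one <- eval_record("c1", "A", "source", 0.8, 10)
  agg1 <- aggregate_records(one)
  expect_equal(agg1$mean_dice, 0.8)
  expect_equal(agg1$sd_dice, 0)
  expect_equal(agg1$n, 1)

  recs <- rbind(
    eval_record("c1", "A", "source", 0.6, 10),
    eval_record("c2", "A", "source", 0.8, 12),
    eval_record("c3", "B", "target", 0.9, 8),
    eval_record("c4", "B", "target", 0.7, 9),
    eval_record("c5", "B", "target", 0.8, 11))
  agg <- aggregate_records(recs, "model_type")
  expect_equal(agg$mean_dice[agg$model_type == "source"], 0.7)
  expect_equal(agg$mean_dice[agg$model_type == "target"], 0.8)
  expect_equal(agg$sd_dice[agg$model_type == "target"], sd(c(0.9, 0.7, 0.8)))
  expect_equal(sum(agg$n), nrow(recs))
  expect_error(eval_record("c", "A", "nonsense", 0.5, 1))
  expect_error(eval_record("c", "A", "source", 1.5, 1))
})
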