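# Saliency stack: SmoothGrad contracts (reduction, determinism,
# finite-difference oracle lives in test-model), intensity mapping,
# denoising, regional scores with a hand-computed example, group averaging,
# Dice against direct voxel counting, and the per-region group comparison.

test_that("smoothgrad reduces to the plain gradient and is deterministic", {
  mm <- micro_model(c(12, 12, 12))
  set.seed(3)
  vol <- array(rnorm(12^3), c(12, 12, 12))
  plain <- cnn_infer(matrix(as.numeric(vol)), c(12L, 12L, 12L),
                     mm$params, TRUE)
  sg <- smoothgrad(mm, vol, n_samples = 1, noise_fraction = 0, seed = 1)
  expect_equal(as.numeric(sg$data), abs(plain$input_grad[, 1]),
               tolerance = 1e-12)
  expect_true(all(sg$data >= 0))

  a <- smoothgrad(mm, vol, n_samples = 5, noise_fraction = 0.1, seed = 9)
  b <- smoothgrad(mm, vol, n_samples = 5, noise_fraction = 0.1, seed = 9)
  expect_identical(a$data, b$data)
  c <- smoothgrad(mm, vol, n_samples = 5, noise_fraction = 0.1, seed = 10)
  expect_false(identical(a$data, c$data))
  expect_error(smoothgrad(mm, vol, n_samples = 0), "n_samples")
})

test_that("[0,255] mapping: endpoints, affine invariance, degenerate case", {
  x <- array(c(0.2, 0.7), c(2, 1, 1))
  expect_equal(as.numeric(rescale_0_255(x)), c(0, 255))
  set.seed(4)
  y <- array(runif(64), c(4, 4, 4))
  expect_equal(rescale_0_255(3 * y + 11), rescale_0_255(y),
               tolerance = 1e-10)
  expect_true(all(rescale_0_255(array(5, c(3, 3, 3))) == 0))
})

test_that("denoise threshold: both readings of 'bottom 5%'", {
  set.seed(5)
  vals <- sample(1:100)  # 100 distinct positive values
  x <- array(c(vals, rep(0, 25)), c(5, 5, 5))
  per <- denoise_threshold(x, pct = 5, mode = "percentile")
  expect_identical(sum(per == 0), 25L + 5L)  # exactly the 5 smallest zeroed
  expect_true(all(sort(per[per > 0]) == 6:100))

  rng <- denoise_threshold(x, pct = 5, mode = "range")
  expect_true(all(rng[x < 5] == 0))
  expect_true(all(rng[x >= 5] == x[x >= 5]))

  for (mode in c("percentile", "range")) {
    expect_identical(denoise_threshold(x, pct = 0, mode = mode), x)
    expect_true(all(denoise_threshold(x, pct = 100, mode = mode) == 0))
  }
  expect_error(denoise_threshold(x, pct = 101), "pct")
})

test_that("region scores match the hand-computed example", {
  lab <- array(0L, c(2, 2, 1))
  lab[1:2, 1, 1] <- 1L  # region A: two voxels
  lab[1:2, 2, 1] <- 2L  # region B: two voxels
  parc <- parcellation(lab, data.frame(region_id = 1:2, name = c("A", "B"),
                                       hemisphere = c("L", "R")))
  m <- array(0, c(2, 2, 1))
  m[1:2, 1, 1] <- c(20, 20)
  m[1:2, 2, 1] <- c(0, 10)
  tb <- region_scores(m, parc)
  expect_equal(tb$coverage_pct, c(100, 50))
  expect_equal(tb$mean_intensity, c(20, 5))
  expect_equal(tb$weight, c(1, 0))
  expect_equal(tb$weighted_score, c(100, 0))

  expect_equal(region_scores(array(0, c(2, 2, 1)), parc)$weighted_score,
               c(0, 0))
  # invariance to positive rescaling
  expect_equal(region_scores(7 * m, parc)[c("coverage_pct", "weight",
                                            "weighted_score")],
               tb[c("coverage_pct", "weight", "weighted_score")],
               tolerance = 1e-12)
  # all-equal means -> all weights 1 (degenerate min-max rule)
  eq <- array(3, c(2, 2, 1))
  expect_equal(region_scores(eq, parc)$weight, c(1, 1))
  # a region with no voxels in the grid is an error
  parc_bad <- parcellation(lab, data.frame(region_id = c(1:2, 9L),
                                           name = c("A", "B", "ghost"),
                                           hemisphere = c("L", "R", "L")))
  expect_error(region_scores(m, parc_bad), "ghost")
})

test_that("group averaging is sex-balanced, seeded, and binarizes", {
  d <- c(4, 4, 4)
  man <- data.frame(subject_id = sprintf("s%02d", 1:30),
                    age = rep(c(25, 35), 15),
                    sex = rep(c("M", "F"), each = 15), cohort = "healthy")
  set.seed(6)
  maps <- lapply(1:30, function(i) array(runif(64) * (runif(64) > 0.5), d))
  names(maps) <- man$subject_id

  g <- group_average_map(maps, man, "healthy", "<30", seed = 2)
  expect_identical(sort(unname(g$sex_composition)), c(5L, 5L))
  expect_identical(length(g$member_ids), 10L)
  expect_true(all(g$data %in% c(0L, 1L)))
  expect_true(all(man$age[match(g$member_ids, man$subject_id)] < 30))
  g2 <- group_average_map(maps, man, "healthy", "<30", seed = 2)
  expect_identical(g$member_ids, g2$member_ids)

  # identical input maps -> average equals any member (binarized)
  same <- lapply(1:30, function(i) maps[[1]])
  names(same) <- man$subject_id
  gs <- group_average_map(same, man, "healthy", "30-39", seed = 1,
                          n_per_sex = 5)
  expect_identical(gs$data, array(as.integer(maps[[1]] > 0), d))

  expect_error(group_average_map(maps, man, "healthy", "50-59", seed = 1),
               "insufficient")
  expect_error(group_average_map(maps, man, "healthy", "20ish"), "band")
})

test_that("dice equals direct voxel counting", {
  d <- c(5, 5, 5)
  a <- array(0, d); a[1:2, 1, 1] <- 1
  b <- array(0, d); b[2:3, 1, 1] <- 1
  expect_equal(dice(a, b), 0.5)  # |A|=|B|=2, one shared voxel
  expect_equal(dice(a, a), 1)
  c0 <- array(0, d); c0[5, 5, 5] <- 1
  expect_equal(dice(a, c0), 0)
  expect_error(dice(array(0, d), array(0, d)), "empty")

  set.seed(8)
  for (i in 1:10) {
    x <- array(rbinom(125, 1, 0.3), d)
    y <- array(rbinom(125, 1, 0.3), d)
    if (sum(x) + sum(y) == 0) next
    oracle <- 2 * sum(x == 1 & y == 1) / (sum(x) + sum(y))
    expect_equal(dice(x, y), oracle, tolerance = 1e-12)
    expect_equal(dice(x, y), dice(y, x))
  }
})

test_that("per-region comparison: identity, threshold, localization power", {
  mk_tables <- function(score_matrix) {
    lapply(seq_len(ncol(score_matrix)), function(j)
      data.frame(region_id = seq_len(nrow(score_matrix)),
                 name = paste0("r", seq_len(nrow(score_matrix))),
                 weighted_score = score_matrix[, j]))
  }
  set.seed(9)
  base <- matrix(runif(10 * 6, 20, 60), 10, 6)
  res <- compare_region_scores(mk_tables(base), mk_tables(base))
  expect_false(any(res$significant))
  expect_equal(res$p_value, rep(1, 10), tolerance = 1e-9)

  # 102 regions -> the reference Bonferroni threshold
  big <- matrix(runif(102 * 4), 102, 4)
  res102 <- compare_region_scores(mk_tables(big), mk_tables(big))
  expect_equal(unique(res102$corrected_alpha), 0.05 / 102)

  # only region 1 ("ventricle") shifted by 2 pooled SDs, n = 30 per group:
  # that region is flagged with power > 0.9, others stay quiet
  set.seed(10)
  hits <- 0; false_hits <- 0; reps <- 60
  for (r in 1:reps) {
    H <- matrix(rnorm(10 * 30, 50, 5), 10, 30)
    M <- matrix(rnorm(10 * 30, 50, 5), 10, 30)
    M[1, ] <- M[1, ] + 2 * 5
    cmp <- compare_region_scores(mk_tables(H), mk_tables(M))
    hits <- hits + cmp$significant[cmp$region_id == 1]
    false_hits <- false_hits + sum(cmp$significant[cmp$region_id != 1])
  }
  expect_gt(hits / reps, 0.9)
  expect_lt(false_hits / (9 * reps), 0.02)

  # mismatched region sets are refused
  other <- mk_tables(base)
  other[[1]]$region_id <- other[[1]]$region_id + 1L
  expect_error(compare_region_scores(other, mk_tables(base)), "region sets")
})

test_that("trained model localizes the injected aging signal", {
  fx <- trained_micro()
  parc <- build_parcellation(c(20, 20, 20))
  sal <- saliency_pipeline(fx$model, fx$vols[29:36],
                           data.frame(subject_id = sprintf("v%d", 1:8)),
                           parc, n_samples = 8, seed = 5)
  ranks <- vapply(sal$scores, function(tb) {
    ord <- order(-tb$weighted_score)
    min(match(c(1L, 2L), tb$region_id[ord]))
  }, 0)
  # ventricular signal should dominate for most held-out phantoms even in
  # this micro model
  expect_gte(mean(ranks <= 3), 0.5)
})
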