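test_that("nearest-neighbor distances follow the stated exclusion rules", {
  g <- mea_geometry()
  # two singletons two pitches apart: cross distances from both sides,
  # no same-pair distances (singletons are skipped for that list)
  nn <- nearest_neighbor_analysis(channel_set(1), channel_set(3, pair = "3:4"), g)
  expect_equal(nn$cross_pair_distances, c(800, 800))
  expect_length(nn$same_pair_distances, 0)
  expect_true(any(grepl("singleton", nn$excluded$reason)))
  # adjacent same-pair channels
  nn2 <- nearest_neighbor_analysis(channel_set(1:2), channel_set(5, pair = "3:4"), g)
  expect_equal(sort(nn2$same_pair_distances), c(400, 400))
  # a channel responding to both pairs is excluded as a cross-pair source
  # but kept in the same-pair lists
  nn3 <- nearest_neighbor_analysis(channel_set(c(1, 2)),
                                   channel_set(c(2, 8), pair = "3:4"), g)
  expect_equal(sort(nn3$cross_pair_distances),
               sort(c(channel_distance(g, 1, 2), channel_distance(g, 8, 2))))
  expect_length(nn3$same_pair_distances, 4)
  expect_true(2 %in% nn3$excluded$channel)
  expect_error(nearest_neighbor_analysis(channel_set(integer(0)),
                                         channel_set(1, pair = "3:4"), g),
               "no responses")
})

test_that("activation centroids are grid means inside the bounding box", {
  g <- mea_geometry()
  expect_equal(activation_centroid(channel_set(1), g), c(x = 0, y = 0))
  expect_equal(activation_centroid(channel_set(c(1, 3)), g), c(x = 400, y = 0))
  expect_equal(activation_centroid(channel_set(1:32), g), c(x = 1400, y = 600))
  # invariance under channel relabeling (order of events)
  expect_equal(activation_centroid(channel_set(c(7, 2, 30)), g),
               activation_centroid(channel_set(c(30, 7, 2)), g))
  set.seed(3)
  for (i in 1:5) {
    ch <- sample(32, 6)
    cen <- activation_centroid(channel_set(ch), g)
    pos <- channel_position(g, ch)
    expect_true(cen["x"] >= min(pos[, 1]) && cen["x"] <= max(pos[, 1]))
    expect_true(cen["y"] >= min(pos[, 2]) && cen["y"] <= max(pos[, 2]))
  }
  # scalar corner-distance variant stays available behind the switch
  expect_equal(activation_centroid(channel_set(1), g, method = "corner"), 0)
  expect_type(centroid_separation(channel_set(1:4),
                                  channel_set(9:12, pair = "3:4"), g,
                                  method = "corner"), "double")
  expect_error(activation_centroid(channel_set(integer(0)), g), "empty")
})

test_that("exact Wilcoxon signed-rank matches enumeration and known minima", {
  expect_equal(wilcoxon_signed_rank_exact(c(1, 2, 3))$p_value, 0.25)
  expect_equal(wilcoxon_signed_rank_exact(c(1, 2, 3, 4))$p_value, 0.125)
  expect_equal(wilcoxon_signed_rank_exact(c(1, 2, 3, 4, 5))$p_value, 0.0625)
  expect_equal(wilcoxon_signed_rank_exact(c(1, -1))$p_value, 1.0)  # tie symmetry
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank_exact(c(0, 1, 2, 3))$n_used, 3)
  expect_equal(wilcoxon_signed_rank_exact(c(0, 1, 2, 3))$p_value, 0.25)
  expect_error(wilcoxon_signed_rank_exact(c(0, 0)), "zero")
  # agreement with the reference implementation on tie-free samples
  set.seed(8)
  for (n in c(4, 6, 8, 10)) {
    d <- rnorm(n)
    expect_equal(wilcoxon_signed_rank_exact(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("exact Wilcoxon equals brute-force enumeration over all sign patterns", {
  brute <- function(d) {                      # independent oracle
    r <- rank(abs(d)); n <- length(d)
    w <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    min(1, 2 * min(mean(ws >= w - 1e-9), mean(ws <= w + 1e-9)))
  }
  set.seed(5)
  for (n in c(3, 5, 7)) {
    mags <- c(abs(rnorm(n - 2)), 1.5, 1.5)    # include a tie
    for (pat in seq_len(2^n)) {
      sgn <- ifelse(bitwAnd(pat - 1, 2^(0:(n - 1))) > 0, 1, -1)
      d <- mags * sgn
      expect_equal(wilcoxon_signed_rank_exact(d)$p_value, brute(d))
    }
  }
})

test_that("centroid-shift comparison reproduces the analytic minima", {
  a <- c(900, 850, 700, 1000); b <- c(400, 420, 300, 500)
  res <- centroid_shift_analysis(a, b)        # 4 pairs, all positive
  expect_equal(res$p_value, 0.125)
  res3 <- centroid_shift_analysis(a[1:3], b[1:3])
  expect_equal(res3$p_value, 0.25)
  expect_error(centroid_shift_analysis(a[1], b[1]), "at least 2")
  expect_error(centroid_shift_analysis(a, b[1:3]), "same number")
})

test_that("uniform response assignment yields no spatial structure; blocks do", {
  g <- mea_geometry()
  nulls <- c(); hits <- 0
  for (s in 1:6) {
    for (cl in c(0, 1)) {
      pop <- make_population(40, 8, clustering = cl, seed = 500 + s,
                             overlap = 0, rheobase_uA = c(150, 250),
                             nonpref_factor = c(4, 6))
      r12 <- ground_truth_responses(pop, stim_pulse(800, 0.5), "1:2")
      r34 <- ground_truth_responses(pop, stim_pulse(800, 0.5), "3:4")
      nn <- nearest_neighbor_analysis(r12, r34, g)
      if (cl == 1) {
        p <- stats::wilcox.test(nn$cross_pair_distances,
                                nn$same_pair_distances,
                                alternative = "greater", exact = FALSE)$p.value
        hits <- hits + (p < 0.01)
      } else {
        nulls <- c(nulls, nn$same_pair_distances - mean(nn$cross_pair_distances))
      }
    }
  }
  expect_gte(hits, 5)                          # segregation is detected
  expect_lt(abs(mean(nulls)), 200)             # no systematic same/cross gap
})
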