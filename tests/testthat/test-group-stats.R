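test_that("running t-tests match the textbook closed forms", {
  # 3-vs-3 hand check at a single bin, constant elsewhere
  a_vals <- c(1.2, 0.7, 1.0)
  b_vals <- c(0.1, -0.2, 0.4)
  maps_a <- lapply(a_vals, function(v) matrix(c(v, 0, 0, 0), 2, 2))
  maps_b <- lapply(b_vals, function(v) matrix(c(v, 0, 0, 0), 2, 2))
  suppressWarnings(tt <- running_ttest(maps_a, maps_b))
  ref <- stats::t.test(a_vals, b_vals, var.equal = TRUE)
  expect_equal(tt$t_map[1, 1], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$p_map[1, 1], ref$p.value, tolerance = 1e-10)
  # identical groups: t = 0 everywhere (to numerical precision)
  suppressWarnings(t0 <- running_ttest(maps_a, maps_a))
  expect_lt(max(abs(t0$t_map)), 1e-10)
  expect_gt(min(t0$p_map), 1 - 1e-10)
  # one-sample mode against zero
  suppressWarnings(t1 <- running_ttest(maps_a))
  ref1 <- stats::t.test(a_vals)
  expect_equal(t1$t_map[1, 1], unname(ref1$statistic), tolerance = 1e-10)
  # degenerate zero-variance bins warn and fall back to t = 0, p = 1
  const <- lapply(1:3, function(i) matrix(1, 2, 2))
  expect_warning(tc <- running_ttest(const), "zero variance")
  expect_true(all(tc$t_map == 0))
  expect_true(all(tc$p_map == 1))
  expect_error(running_ttest(maps_a[1]), "at least 2")
})

test_that("cluster finding respects 4-connectivity, sign and min size", {
  p <- matrix(1, 6, 6)
  t <- matrix(0, 6, 6)
  expect_length(find_clusters(p, t, 0.05), 0)
  # two diagonal-touching significant bins are separate clusters
  p2 <- p
  p2[2, 2] <- p2[3, 3] <- 1e-4
  t2 <- t
  t2[2, 2] <- t2[3, 3] <- 5
  cl2 <- find_clusters(p2, t2, 0.05)
  expect_length(cl2, 2)
  # a planted 3x3 block is one cluster of 9, matching an igraph oracle
  p3 <- matrix(stats::runif(36, 0.2, 1), 6, 6)
  p3[2:4, 3:5] <- 1e-6
  t3 <- matrix(1, 6, 6)
  cl3 <- find_clusters(p3, t3, 0.05)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$size, 9)
  if (requireNamespace("igraph", quietly = TRUE)) {
    mask <- p3 < 0.05
    idx <- which(mask)
    rc <- arrayInd(idx, dim(mask))
    adj <- outer(seq_along(idx), seq_along(idx), function(i, j) {
      abs(rc[i, 1] - rc[j, 1]) + abs(rc[i, 2] - rc[j, 2]) == 1
    })
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)
    expect_setequal(cl3[[1]]$bins, idx)
  }
  # opposite-sign neighbours split into separate clusters
  t4 <- matrix(0, 6, 6)
  p4 <- matrix(1, 6, 6)
  p4[3, 2:5] <- 1e-6
  t4[3, 2:3] <- 4
  t4[3, 4:5] <- -4
  cl4 <- find_clusters(p4, t4, 0.05)
  expect_length(cl4, 2)
  expect_setequal(vapply(cl4, `[[`, numeric(1), "sign"), c(1, -1))
  # min_size filter
  expect_length(find_clusters(p4, t4, 0.05, min_size = 3), 0)
})

test_that("cluster finding is invariant to bin traversal order", {
  withr::with_seed(5, {
    p <- matrix(stats::runif(96), 8, 12)
    t <- matrix(rnorm(96), 8, 12)
  })
  cl <- find_clusters(p, t, 0.3)
  key <- function(cls) {
    sort(vapply(cls, function(c) paste(sort(c$bins), collapse = ","),
                character(1)))
  }
  # transpose-and-back changes internal visit order but not the clusters
  clt <- find_clusters(t(p), t(t), 0.3)
  remap <- lapply(clt, function(c) {
    rc <- arrayInd(c$bins, c(12, 8))
    c$bins <- (rc[, 1] - 1) * 8 + rc[, 2]
    c
  })
  expect_equal(key(cl), key(remap))
})

test_that("3-vs-3 permutation p values equal brute-force enumeration", {
  maps_a <- make_maps(3, nr = 5, nc = 6, effect = 1.2, seed = 41)
  maps_b <- make_maps(3, nr = 5, nc = 6, seed = 42)
  res <- cluster_permutation_test(maps_a, maps_b, n_perm = 5000,
                                  alpha = 0.1, seed = 1)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(6, 3))
  # independent brute force: all 20 label splits, test-side t and clusters
  all_maps <- c(maps_a, maps_b)
  stat_of_split <- function(ix) {
    ga <- all_maps[ix]
    gb <- all_maps[-ix]
    tm <- matrix(0, 5, 6)
    pm <- matrix(1, 5, 6)
    for (r in 1:5) {
      for (c in 1:6) {
        va <- vapply(ga, function(m) m[r, c], numeric(1))
        vb <- vapply(gb, function(m) m[r, c], numeric(1))
        ht <- stats::t.test(va, vb, var.equal = TRUE)
        tm[r, c] <- ht$statistic
        pm[r, c] <- ht$p.value
      }
    }
    cl <- find_clusters(pm, tm, 0.1)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1),
                                               "stat")))
  }
  splits <- combn(6, 3)
  null <- apply(splits, 2, stat_of_split)
  for (i in seq_len(nrow(res$clusters))) {
    expect_equal(res$clusters$p[i],
                 mean(null >= abs(res$clusters$stat[i]) - 1e-12))
  }
})

test_that("a planted localized group difference is detected", {
  effect <- matrix(0, 12, 15)
  effect[4:8, 6:10] <- 3  # 5x5 block, 3 within-bin SDs
  hits <- vapply(1:25, function(s) {
    maps_a <- make_maps(8, effect = effect, seed = 100 + s)
    maps_b <- make_maps(8, seed = 200 + s)
    res <- cluster_permutation_test(maps_a, maps_b, n_perm = 300,
                                    alpha = 0.05, seed = s)
    cl <- res$clusters
    any(cl$p < 0.05 &
          vapply(cl$bins, function(b) {
            mean(b %in% which(effect > 0)) > 0.5
          }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ROI definition recovers 7+ bin regions and rejects 6-bin ones", {
  base <- matrix(0, 12, 15)
  region7 <- cbind(r = c(3, 3, 3, 4, 4, 4, 5), c = c(4, 5, 6, 4, 5, 6, 5))
  for (i in seq_len(nrow(region7))) base[region7[i, 1], region7[i, 2]] <- 10
  maps <- make_maps(20, effect = base, seed = 51)
  rois <- define_rois(maps, alpha = 1e-10, min_size = 7,
                      frame_times = seq(0, 680, length.out = 15),
                      center_frequencies = seq(100, 8000,
                                               length.out = 12))
  expect_equal(nrow(rois), 1)
  expect_gte(rois$size[1], 7)
  planted <- (region7[, 2] - 1) * 12 + region7[, 1]
  expect_true(all(planted %in% rois$bins[[1]]))
  expect_equal(rois$polarity[1], 1)
  # centroid lies inside the planted region's coordinate range
  expect_gt(rois$centroid_time_ms[1], 680 / 15 * 2)
  expect_lt(rois$centroid_freq_hz[1], 8000 / 12 * 6)

  base6 <- matrix(0, 12, 15)
  base6[3:4, 4:6] <- 10  # exactly 6 adjacent bins
  maps6 <- make_maps(20, effect = base6, seed = 52)
  rois6 <- define_rois(maps6, alpha = 1e-10, min_size = 7)
  expect_equal(nrow(rois6), 0)
  # all-zero maps: degenerate, empty ROI set
  zero <- lapply(1:5, function(i) matrix(0, 4, 4))
  expect_warning(r0 <- define_rois(zero), "zero variance")
  expect_equal(nrow(r0), 0)
})

test_that("ROI group comparison matches a direct t-test", {
  # group effects close enough that between-group heterogeneity does not
  # swamp the pooled one-sample t at the strict ROI threshold
  base <- matrix(0, 12, 15)
  base[4:6, 5:9] <- 10
  maps_a <- make_maps(10, effect = base, seed = 61)
  maps_b <- make_maps(10, effect = 0.7 * base, seed = 62)
  rois <- define_rois(c(maps_a, maps_b), alpha = 1e-10, min_size = 7)
  expect_gte(nrow(rois), 1)
  cmp <- roi_compare(rois, maps_a, maps_b)
  bins <- rois$bins[[1]]
  va <- vapply(maps_a, function(m) mean(m[bins]), numeric(1))
  vb <- vapply(maps_b, function(m) mean(m[bins]), numeric(1))
  ref <- stats::t.test(va, vb, var.equal = TRUE)
  expect_equal(cmp$t[1], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cmp$p[1], ref$p.value, tolerance = 1e-10)
  # identical groups: |t| ~ 0
  cmp0 <- roi_compare(rois, maps_a, maps_a)
  expect_lt(max(abs(cmp0$t)), 1e-12)
  expect_error(roi_compare(rois[0, ], maps_a, maps_b), "empty")
})

test_that("the two-step individual deviance analysis trims then flags", {
  controls <- c(10, 11, 9, 10, 30)
  cases <- c(10, 16, 2)
  # independent two-pass computation
  m1 <- mean(controls)
  s1 <- sd(controls)
  trimmed <- controls[abs(controls - m1) <= 1.65 * s1]
  m2 <- mean(trimmed)
  s2 <- sd(trimmed)
  expect_equal(trimmed, c(10, 11, 9, 10))  # 30 is trimmed in pass 1
  res <- individual_deviance_analysis(controls, cases)
  expect_equal(res$z, (cases - m2) / s2)
  expect_equal(res$deviant, abs((cases - m2) / s2) > 1.65)
  expect_true(res$deviant[2])   # 16 deviates from the trimmed controls
  expect_false(res$deviant[1])  # equal to the control mean: never deviant
  # directional flagging
  lower <- individual_deviance_analysis(controls, cases,
                                        direction = "lower")
  expect_equal(lower$deviant, c(FALSE, FALSE, TRUE))
  # degenerate zero-SD controls error
  expect_error(individual_deviance_analysis(c(0, 0, 0), 1), "zero")
  expect_error(individual_deviance_analysis(c(10, 10, 10, 10, 30), 10),
               "zero")
  expect_error(individual_deviance_analysis(c(1, 2), 1), "at least 3")
})
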