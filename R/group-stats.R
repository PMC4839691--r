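# stack a list of weight maps (matrices or aci_models) into an
# observers x bins matrix (bins in R column-major order of the map)
as_map_matrix <- function(maps) {
  mats <- lapply(maps, function(m) {
    if (inherits(m, "aci_model")) m$beta else m
  })
  dims <- dim(mats[[1]])
  if (any(!vapply(mats, function(m) all(dim(m) == dims), logical(1)))) {
    stop_input("all maps must share the same dimensions")
  }
  out <- t(vapply(mats, as.vector, numeric(prod(dims))))
  attr(out, "map_dim") <- dims
  out
}

# per-bin means and variances of an observers x bins matrix, optionally for
# a subset of rows given as an 0/1 indicator (fast for permutations)
col_stats <- function(m, m2, ind) {
  n <- sum(ind)
  s <- drop(ind %*% m)
  s2 <- drop(ind %*% m2)
  mean <- s / n
  var <- pmax((s2 - n * mean^2) / (n - 1), 0)
  list(mean = mean, var = var, n = n)
}

t_stats <- function(m, m2, ind_a, ind_b = NULL, var_equal = TRUE) {
  a <- col_stats(m, m2, ind_a)
  if (is.null(ind_b)) {
    se <- sqrt(a$var / a$n)
    df <- a$n - 1
    t <- ifelse(se > 0, a$mean / se, 0)
  } else {
    b <- col_stats(m, m2, ind_b)
    if (var_equal) {
      df <- a$n + b$n - 2
      sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
      se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
      t <- ifelse(se > 0, (a$mean - b$mean) / se, 0)
    } else {
      se2 <- a$var / a$n + b$var / b$n
      t <- ifelse(se2 > 0, (a$mean - b$mean) / sqrt(se2), 0)
      df_w <- se2^2 / (((a$var / a$n)^2) / (a$n - 1) +
                         ((b$var / b$n)^2) / (b$n - 1))
      df <- ifelse(se2 > 0, df_w, a$n + b$n - 2)
    }
  }
  list(t = t, df = df, zero_var = if (is.null(ind_b)) a$var == 0 else
    se == 0)
}

#' Per-bin running t-test on weight maps
#'
#' Computes a t statistic and two-tailed p value at every time-frequency
#' bin: a two-sample test between groups A and B (pooled variance by
#' default, Welch with `var_equal = FALSE`), or a one-sample test against
#' zero when `maps_b` is `NULL` (the mode used to define regions of
#' interest on the pooled cohort).
#'
#' @param maps_a,maps_b Lists of weight maps (matrices or `aci_model`s);
#'   `maps_b = NULL` for the one-sample test.
#' @param var_equal Use the pooled-variance two-sample t-test.
#' @return List with `t_map` and `p_map` matrices and the degrees of
#'   freedom `df`. Bins with zero variance get `t = 0`, `p = 1` (with a
#'   warning).
#' @export
running_ttest <- function(maps_a, maps_b = NULL, var_equal = TRUE) {
  if (length(maps_a) < 2) stop_input("need at least 2 maps per group")
  if (!is.null(maps_b) && length(maps_b) < 2) {
    stop_input("need at least 2 maps per group")
  }
  m <- as_map_matrix(c(maps_a, maps_b))
  dims <- attr(m, "map_dim")
  m2 <- m^2
  n_a <- length(maps_a)
  ind_a <- c(rep(1, n_a), rep(0, nrow(m) - n_a))
  ind_b <- if (is.null(maps_b)) NULL else 1 - ind_a
  st <- t_stats(m, m2, ind_a, ind_b, var_equal)
  if (any(st$zero_var)) {
    warn(sprintf("%d bins with zero variance; t set to 0, p to 1",
                 sum(st$zero_var)))
  }
  p <- 2 * pt(-abs(st$t), st$df)
  p[st$zero_var] <- 1
  list(t_map = matrix(st$t, dims[1], dims[2]),
       p_map = matrix(p, dims[1], dims[2]),
       df = if (length(unique(st$df)) == 1) st$df[1] else
         matrix(st$df, dims[1], dims[2]))
}

# connected components of a logical matrix under 4-connectivity, by
# iterative minimum-label propagation; returns a list of linear-index sets
connected_components <- function(mask) {
  if (!any(mask)) return(list())
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  full <- matrix(NA_integer_, nr, nc)
  full[mask] <- lab[mask]
  repeat {
    nb <- full
    up <- rbind(full[-1, , drop = FALSE], NA_integer_)
    dn <- rbind(NA_integer_, full[-nr, , drop = FALSE])
    lf <- cbind(full[, -1, drop = FALSE], NA_integer_)
    rt <- cbind(NA_integer_, full[, -nc, drop = FALSE])
    nb <- pmin(nb, up, dn, lf, rt, na.rm = TRUE)
    nb[!mask] <- NA_integer_
    if (identical(nb, full)) break
    full <- nb
  }
  split(which(mask), full[mask])
}

#' Clusters of significant adjacent bins
#'
#' Thresholds a p-value map at `alpha`, splits the surviving bins by the
#' sign of their t statistic, and returns the maximal 4-connected components
#' (no diagonal adjacency) of at least `min_size` bins.
#'
#' @param p_map,t_map Matrices from [running_ttest()].
#' @param alpha Per-bin cluster-forming threshold in (0, 1).
#' @param min_size Minimum cluster size in bins.
#' @return List of clusters, each a list with `bins` (column-major linear
#'   indices into the map), `size`, `sign`, and `stat` (sum of t over the
#'   cluster's bins).
#' @export
find_clusters <- function(p_map, t_map, alpha = 0.05, min_size = 1) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  out <- list()
  for (s in c(1, -1)) {
    mask <- p_map < alpha & sign(t_map) == s
    for (bins in connected_components(mask)) {
      if (length(bins) >= min_size) {
        out[[length(out) + 1L]] <- list(
          bins = as.integer(bins), size = length(bins), sign = s,
          stat = sum(t_map[bins])
        )
      }
    }
  }
  out[order(vapply(out, function(cl) -abs(cl$stat), numeric(1)))]
}

#' Cluster-based permutation test between two groups of weight maps
#'
#' The observed clusters are formed by thresholding the per-bin two-sample
#' running t-test at `alpha` (two-tailed) and taking 4-connected components
#' split by sign; each cluster's statistic is the sum of its t values. The
#' null distribution is the maximum absolute cluster statistic obtained
#' after randomly permuting the group labels `n_perm` times; each observed
#' cluster's p value is `(1 + #(null >= |stat|)) / (n_perm + 1)`. When the
#' number of distinct label splits does not exceed `n_perm` the test
#' enumerates all splits exhaustively instead (p = fraction of splits with
#' null >= |stat|).
#'
#' @param maps_a,maps_b Lists of weight maps (>= 2 each).
#' @param n_perm Number of random permutations.
#' @param alpha Per-bin cluster-forming threshold (two-tailed).
#' @param seed Seed for the permutations.
#' @param min_size Minimum cluster size.
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @return An `aci_cluster_test`: list with `clusters` (tibble: `cluster`,
#'   `size`, `sign`, `stat`, `p`, `bins` list-column), `t_map`, `p_map`,
#'   `null_max`, `n_perm`, `exhaustive`, `alpha`.
#' @export
cluster_permutation_test <- function(maps_a, maps_b, n_perm = 5000,
                                     alpha = 0.05, seed = 1, min_size = 1,
                                     var_equal = TRUE) {
  n_a <- length(maps_a)
  n_b <- length(maps_b)
  if (n_a < 2 || n_b < 2) stop_input("need at least 2 maps per group")
  m <- as_map_matrix(c(maps_a, maps_b))
  dims <- attr(m, "map_dim")
  m2 <- m^2
  n <- n_a + n_b
  max_stat <- function(ind_a) {
    st <- t_stats(m, m2, ind_a, 1 - ind_a, var_equal)
    p <- 2 * pt(-abs(st$t), st$df)
    p[st$zero_var] <- 1
    cl <- find_clusters(matrix(p, dims[1], dims[2]),
                        matrix(st$t, dims[1], dims[2]), alpha, min_size)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1),
                                               "stat")))
  }
  ind_obs <- c(rep(1, n_a), rep(0, n_b))
  st <- t_stats(m, m2, ind_obs, 1 - ind_obs, var_equal)
  p_obs <- 2 * pt(-abs(st$t), st$df)
  p_obs[st$zero_var] <- 1
  t_map <- matrix(st$t, dims[1], dims[2])
  p_map <- matrix(p_obs, dims[1], dims[2])
  observed <- find_clusters(p_map, t_map, alpha, min_size)
  n_splits <- choose(n, n_a)
  exhaustive <- n_splits <= n_perm
  if (exhaustive) {
    splits <- combn(n, n_a)
    null_max <- apply(splits, 2, function(ix) {
      ind <- numeric(n)
      ind[ix] <- 1
      max_stat(ind)
    })
  } else {
    perms <- withr::with_seed(seed, replicate(n_perm, sample.int(n, n_a)))
    null_max <- apply(perms, 2, function(ix) {
      ind <- numeric(n)
      ind[ix] <- 1
      max_stat(ind)
    })
  }
  p_cluster <- vapply(observed, function(cl) {
    if (exhaustive) {
      mean(null_max >= abs(cl$stat) - 1e-12)
    } else {
      (1 + sum(null_max >= abs(cl$stat) - 1e-12)) / (n_perm + 1)
    }
  }, numeric(1))
  clusters <- tibble(
    cluster = seq_along(observed),
    size = vapply(observed, `[[`, numeric(1), "size"),
    sign = vapply(observed, `[[`, numeric(1), "sign"),
    stat = vapply(observed, `[[`, numeric(1), "stat"),
    p = p_cluster,
    bins = lapply(observed, `[[`, "bins")
  )
  structure(
    list(clusters = clusters, t_map = t_map, p_map = p_map,
         null_max = null_max, n_perm = if (exhaustive) n_splits else n_perm,
         exhaustive = exhaustive, alpha = alpha, min_size = min_size),
    class = "aci_cluster_test"
  )
}

#' @export
print.aci_cluster_test <- function(x, ...) {
  cat(sprintf("<aci_cluster_test> %d cluster(s), %s %d permutations, alpha = %g\n",
              nrow(x$clusters),
              if (x$exhaustive) "exhaustive" else "random", x$n_perm,
              x$alpha))
  print(x$clusters[, c("cluster", "size", "sign", "stat", "p")])
  invisible(x)
}

#' @export
tidy.aci_cluster_test <- function(x, ...) {
  x$clusters
}

#' Regions of interest from the pooled cohort
#'
#' Defines ROIs as clusters of at least `min_size` (default 7) adjacent
#' (4-connected) time-frequency bins whose weights differ consistently from
#' zero across the pooled cohort in a one-sample running t-test at
#' `alpha` (default 1e-10). Each ROI's polarity is the sign of its mean
#' weight and its centroid is the weight-magnitude-weighted mean time and
#' frequency.
#'
#' @param maps Pooled list of weight maps (both groups, >= 3).
#' @param alpha Per-bin significance threshold.
#' @param min_size Minimum number of adjacent bins.
#' @param frame_times,center_frequencies Bin coordinates; defaults are
#'   taken from the first map if it is an `aci_model`.
#' @return An `aci_roi_set` tibble: `roi`, `size`, `polarity` (+1/-1),
#'   `centroid_time_ms`, `centroid_freq_hz`, `stat`, `bins` (list-column of
#'   linear indices). Empty (zero-row) sets are allowed.
#' @export
define_rois <- function(maps, alpha = 1e-10, min_size = 7,
                        frame_times = NULL, center_frequencies = NULL) {
  if (length(maps) < 3) stop_input("need at least 3 maps to define ROIs")
  if (inherits(maps[[1]], "aci_model")) {
    frame_times <- frame_times %||% maps[[1]]$frame_times
    center_frequencies <- center_frequencies %||%
      maps[[1]]$center_frequencies
  }
  tt <- running_ttest(maps, NULL)
  clusters <- find_clusters(tt$p_map, tt$t_map, alpha, min_size)
  m <- as_map_matrix(maps)
  dims <- attr(m, "map_dim")
  mean_map <- matrix(colMeans(m), dims[1], dims[2])
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    w <- abs(mean_map[cl$bins])
    rc <- arrayInd(cl$bins, dims)
    tibble(
      roi = i, size = cl$size, polarity = cl$sign,
      centroid_time_ms = if (!is.null(frame_times))
        sum(w * frame_times[rc[, 2]]) / sum(w) else NA_real_,
      centroid_freq_hz = if (!is.null(center_frequencies))
        sum(w * center_frequencies[rc[, 1]]) / sum(w) else NA_real_,
      stat = cl$stat,
      bins = list(cl$bins)
    )
  })
  out <- if (length(rows) == 0) {
    tibble(roi = integer(), size = numeric(), polarity = numeric(),
           centroid_time_ms = numeric(), centroid_freq_hz = numeric(),
           stat = numeric(), bins = list())
  } else {
    dplyr::bind_rows(rows)
  }
  class(out) <- c("aci_roi_set", class(out))
  attr(out, "map_dim") <- dims
  out
}

#' Compare mean ROI weights between two groups
#'
#' For each ROI, averages each observer's weights over the ROI's bins and
#' compares the two groups with a two-sample t-test (pooled variance by
#' default).
#'
#' @param rois An [define_rois()] result with at least one ROI.
#' @param maps_a,maps_b Weight maps of the two groups.
#' @param var_equal Pooled-variance t-test.
#' @return Tibble with `roi`, `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
roi_compare <- function(rois, maps_a, maps_b, var_equal = TRUE) {
  if (nrow(rois) == 0) stop_input("empty ROI set")
  ma <- as_map_matrix(maps_a)
  mb <- as_map_matrix(maps_b)
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    bins <- rois$bins[[i]]
    va <- rowMeans(ma[, bins, drop = FALSE])
    vb <- rowMeans(mb[, bins, drop = FALSE])
    tst <- stats::t.test(va, vb, var.equal = var_equal)
    tibble(roi = rois$roi[i], mean_a = mean(va), mean_b = mean(vb),
           t = unname(tst$statistic), df = unname(tst$parameter),
           p = tst$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Two-step individual deviance analysis
#'
#' Flags each case whose score deviates by more than `threshold` (default
#' 1.65, the fifth percentile of the normal distribution) standard
#' deviations from the control mean, after first trimming from the control
#' group any control whose own score deviates by more than `threshold` SD
#' and recomputing the mean and SD on the trimmed controls.
#'
#' @param controls Numeric control-group scores (>= 3).
#' @param cases Numeric case scores.
#' @param direction Which deviations count as deviant for the cases:
#'   `"both"`, `"lower"` (lower-is-worse) or `"higher"`.
#' @param threshold SD threshold.
#' @return Tibble with one row per case: `case`, `score`, `z` (relative to
#'   the trimmed control distribution) and `deviant`.
#' @export
individual_deviance_analysis <- function(controls, cases,
                                         direction = c("both", "lower",
                                                       "higher"),
                                         threshold = 1.65) {
  direction <- match.arg(direction)
  if (length(controls) < 3) stop_input("need at least 3 controls")
  m1 <- mean(controls)
  s1 <- sd(controls)
  if (s1 == 0) stop_input("control SD is zero")
  keep <- abs(controls - m1) <= threshold * s1
  trimmed <- controls[keep]
  if (length(trimmed) < 2) stop_input("fewer than 2 controls after trimming")
  m2 <- mean(trimmed)
  s2 <- sd(trimmed)
  if (s2 == 0) stop_input("trimmed control SD is zero")
  z <- (cases - m2) / s2
  deviant <- switch(direction,
    both = abs(z) > threshold,
    lower = z < -threshold,
    higher = z > threshold
  )
  tibble(case = names(cases) %||% seq_along(cases), score = unname(cases),
         z = unname(z), deviant = unname(deviant))
}
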