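# Monte Carlo permutation significance maps with ordinal-fixation
# exchangeability, and nonparametric max-cluster-size correction.
#
# The null hypothesis is that the distribution of fixation locations of each
# ordinal fixation is the same between the contrasted conditions, so
# fixation locations are exchangeable only within (participant x ordinal)
# strata.  Each permutation reassigns the pooled locations in every stratum
# to conditions (preserving per-condition counts), a per-participant density
# contrast is recomputed, and the participant average gives one resampled
# group difference map.  Pixel p-values place the true map within the
# resampled distribution; cluster correction compares observed suprathreshold
# cluster sizes to the null distribution of the maximum cluster size.

#' Permutation test specification
#'
#' @param n_iterations number of resampling iterations (default 10400).
#' @param n_cluster_maps how many of the resampled maps also get their own
#'   statistical map for the max-cluster-size null (default 2600; must not
#'   exceed `n_iterations`).  The first `n_cluster_maps` iterations are used.
#' @param pixel_alpha uncorrected pixel significance threshold (default 0.01).
#' @param cluster_alpha cluster-size threshold (default 0.05).
#' @param connectivity 4 or 8 (default 8-neighbour, the common choice in
#'   spatial cluster inference).
#' @param leave_self_out if `TRUE`, each resampled map's p-values are
#'   computed against the other maps only; the default keeps every map in
#'   its own reference set, which makes the true and resampled maps exactly
#'   exchangeable under the null.
#' @param seed integer seed for the permutation stream.
#' @return an object of class `permutation_spec`.
#' @export
permutation_spec <- function(n_iterations = 10400,
                             n_cluster_maps = 2600,
                             pixel_alpha = 0.01,
                             cluster_alpha = 0.05,
                             connectivity = 8,
                             leave_self_out = FALSE,
                             seed = 1L) {
  stopifnot(n_iterations >= 1, n_cluster_maps >= 0,
            n_cluster_maps <= n_iterations,
            pixel_alpha > 0, pixel_alpha < 1,
            cluster_alpha > 0, cluster_alpha < 1,
            connectivity %in% c(4, 8))
  structure(list(n_iterations = as.integer(n_iterations),
                 n_cluster_maps = as.integer(n_cluster_maps),
                 pixel_alpha = pixel_alpha, cluster_alpha = cluster_alpha,
                 connectivity = connectivity,
                 leave_self_out = leave_self_out,
                 seed = as.integer(seed)),
            class = "permutation_spec")
}

# Sparse basis of per-fixation Gaussian patches: a P x n_fix matrix whose
# column i is fixation i's truncated kernel evaluated at all pixel centers.
# A group difference map is then basis %*% weights.
fixation_basis <- function(x, y, grid, sigma = 0.3, trunc = 4) {
  g <- grid_centers(grid)
  tr <- gaussian_basis_triplets(as.numeric(x), as.numeric(y),
                                g$x, g$y, sigma, trunc)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$v,
                       dims = c(grid$n_x * grid$n_y, length(x)))
}

# Per-fixation signed weights so that basis %*% w equals the group
# difference map (per-participant trial-mean difference, then participant
# mean).  Participants missing either condition are dropped with a warning.
contrast_weights <- function(fx, condition_col, levels, participant_col) {
  cond <- fx[[condition_col]]
  part <- fx[[participant_col]]
  keep_p <- intersect(unique(part[cond == levels[1]]),
                      unique(part[cond == levels[2]]))
  drop_p <- setdiff(unique(part), keep_p)
  if (length(drop_p))
    warning("excluding participant(s) missing a condition: ",
            paste(drop_p, collapse = ", "))
  keep <- part %in% keep_p & cond %in% levels
  fx <- fx[keep, , drop = FALSE]
  cond <- fx[[condition_col]]; part <- fx[[participant_col]]
  n_part <- length(keep_p)
  key <- paste(part, cond, sep = "\r")
  n_trials <- tapply(fx$trial_id, key, function(t) length(unique(t)))
  w <- ifelse(cond == levels[1], 1, -1) / (n_trials[key] * n_part)
  list(fx = fx, weights = as.numeric(w), n_participants = n_part)
}

#' Permute condition labels of fixation locations within strata
#'
#' One draw of the permutation null: within each (participant x ordinal)
#' stratum the pooled fixation locations are randomly reassigned to the two
#' conditions, preserving each condition's fixation count in the stratum.
#' All non-location fields keep their original trial/condition annotations.
#'
#' @param fixations fixation data.frame for the two contrasted conditions.
#' @param condition_col name of the condition column.
#' @param levels the two condition labels being contrasted.
#' @param participant_col name of the participant column.
#' @return the data.frame with `x`, `y` re-assigned.
#' @export
permute_labels <- function(fixations, condition_col = "condition",
                           levels = c("A", "B"),
                           participant_col = "participant_id") {
  stratum <- paste(fixations[[participant_col]], fixations$ordinal,
                   sep = "\r")
  base <- order(stratum)
  p <- order(stratum, stats::runif(nrow(fixations)))
  out <- fixations
  out$x[p] <- fixations$x[base]
  out$y[p] <- fixations$y[base]
  out
}

#' Pixel-wise permutation p-values
#'
#' For pixels where the true value is non-negative,
#' `p = (#\{resampled >= true\} + 1) / (N + 1)`; for negative pixels the
#' lower tail is used.  The add-one convention counts the observed map in
#' its own reference distribution, guaranteeing `p >= 1/(N+1)` and validity
#' under the null; ties count toward the null.
#'
#' @param true_values numeric vector (or matrix) of the observed difference
#'   map.
#' @param resampled matrix of resampled maps, one column per iteration,
#'   rows matching `true_values`.
#' @return list with `p` (same shape as `true_values`) and `sign`
#'   (+1 where condition 1 is greater, -1 where condition 2 is greater,
#'   0 at exact zeros).
#' @export
pixel_pvalues <- function(true_values, resampled) {
  dims <- dim(true_values)
  v <- as.numeric(true_values)
  if (is.null(dim(resampled))) resampled <- matrix(resampled, nrow = length(v))
  N <- ncol(resampled)
  if (N == 0) stop("pixel_pvalues: no resampled maps")
  stopifnot(nrow(resampled) == length(v))
  count_ge <- rowSums(resampled >= v)
  count_le <- rowSums(resampled <= v)
  p <- ifelse(v >= 0, (count_ge + 1) / (N + 1), (count_le + 1) / (N + 1))
  s <- sign(v)
  if (!is.null(dims)) { dim(p) <- dims; dim(s) <- dims }
  list(p = p, sign = s)
}

#' Threshold a p-value map into a signed mask
#'
#' @param pmap list as returned by [pixel_pvalues()] (elements `p`, `sign`).
#' @param alpha pixel significance threshold (default 0.01); pixels with
#'   `p < alpha` keep their sign, all others are 0.
#' @return integer matrix/vector of -1, 0, +1.
#' @export
threshold_map <- function(pmap, alpha = 0.01) {
  out <- ifelse(pmap$p < alpha, pmap$sign, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Label connected clusters of a signed significance mask
#'
#' Connected components are found separately within the positive and the
#' negative suprathreshold pixels (so every cluster is sign-coherent),
#' under 8- or 4-neighbour connectivity.
#'
#' @param mask integer matrix of -1, 0, +1 (pixels indexed `[i, j]` as in
#'   [grid_spec()]).
#' @param connectivity 4 or 8 (default 8).
#' @return data.frame with one row per cluster: `id`, `sign`, `size`, and a
#'   list-column `pixels` of linear pixel indices.
#' @export
label_clusters <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  n_x <- nrow(mask); n_y <- ncol(mask)
  res <- list()
  for (s in c(1L, -1L)) {
    idx <- which(mask == s)
    if (!length(idx)) next
    comp <- connected_components(idx, n_x, n_y, connectivity)
    for (cl in comp)
      res[[length(res) + 1L]] <- list(sign = s, size = length(cl),
                                      pixels = cl)
  }
  if (!length(res))
    return(data.frame(id = integer(0), sign = integer(0), size = integer(0),
                      pixels = I(list())))
  ord <- order(-vapply(res, `[[`, 0L, "size"))
  res <- res[ord]
  data.frame(id = seq_along(res),
             sign = vapply(res, `[[`, 0L, "sign"),
             size = vapply(res, `[[`, 0L, "size"),
             pixels = I(lapply(res, `[[`, "pixels")))
}

# Union-find connected components over a set of linear pixel indices.
connected_components <- function(idx, n_x, n_y, connectivity) {
  k <- length(idx)
  if (k == 1) return(list(idx))
  pos <- match(seq_len(n_x * n_y), idx)   # linear index -> node id (NA out)
  i <- ((idx - 1L) %% n_x) + 1L
  j <- ((idx - 1L) %/% n_x) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  parent <- seq_len(k)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (o in offs) {
    ni <- i + o[1]; nj <- j + o[2]
    ok <- ni >= 1L & ni <= n_x & nj >= 1L & nj <= n_y
    nb <- pos[(nj[ok] - 1L) * n_x + ni[ok]]
    a <- which(ok)[!is.na(nb)]
    b <- nb[!is.na(nb)]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  unname(split(idx, roots))
}

#' Survival threshold and cluster filtering from a max-cluster-size null
#'
#' The survival threshold is the nearest-rank `(1 - cluster_alpha)` quantile
#' of the null maximum-cluster-size distribution; true clusters at least
#' that large survive (clusters smaller than the top `cluster_alpha` of the
#' null are eliminated).
#'
#' @param clusters cluster table from [label_clusters()].
#' @param null_sizes numeric vector of null maximum cluster sizes.
#' @param cluster_alpha cluster threshold (default 0.05).
#' @return the cluster table with a logical `survives` column; the threshold
#'   is attached as attribute `size_threshold`.
#' @export
cluster_correct <- function(clusters, null_sizes, cluster_alpha = 0.05) {
  stopifnot(length(null_sizes) >= 1)
  r <- ceiling((1 - cluster_alpha) * length(null_sizes))
  thr <- sort(null_sizes)[max(r, 1)]
  clusters$survives <- clusters$size >= thr
  attr(clusters, "size_threshold") <- thr
  clusters
}

# Largest count of stack values >= v that still passes `p < alpha` when
# p = count / n_stack.
max_passing_count <- function(alpha, n_stack) {
  a <- alpha * n_stack
  m <- ceiling(a - 1e-9) - 1L
  as.integer(max(m, 0L))
}

# A map value v at pixel p is significant-positive iff v >= 0 and
# v > thr$hi[p] (the (m+1)-th largest stack value at p, ties counting
# toward the null), mirrored for negative pixels.
signed_mask_from_thresholds <- function(v, thr) {
  out <- integer(length(v))
  out[v >= 0 & v > thr$hi] <- 1L
  out[v < 0 & v < thr$lo] <- -1L
  out
}

#' Resampled group difference maps
#'
#' Draws `n` permutations of the fixation-location labels (within
#' participant x ordinal strata) and returns the corresponding group
#' difference maps, one column per iteration.  Memory is bounded by the
#' grid size times the number of retained maps; per-fixation kernels are
#' evaluated once and shared across iterations.
#'
#' @param fixations fixation data.frame (aligned, clamped, filtered).
#' @param grid a [grid_spec()].
#' @param n number of iterations.
#' @param condition_col,levels,participant_col contrast definition.
#' @param sigma kernel sd (deg).
#' @param include_true prepend the observed (unpermuted) map as column 1.
#' @param seed integer seed.
#' @return list with `maps` (P x n [+1] dense matrix), `grid`,
#'   `n_participants`.
#' @export
resampled_difference_maps <- function(fixations, grid, n,
                                      condition_col = "condition",
                                      levels = c("A", "B"),
                                      participant_col = "participant_id",
                                      sigma = 0.3,
                                      include_true = TRUE,
                                      seed = 1L) {
  cw <- contrast_weights(fixations, condition_col, levels, participant_col)
  fx <- cw$fx
  basis <- fixation_basis(fx$x, fx$y, grid, sigma)
  stratum <- paste(fx[[participant_col]], fx$ordinal, sep = "\r")
  si <- match(stratum, unique(stratum))
  base <- order(si)
  w0 <- cw$weights
  set.seed(seed)
  n_fix <- nrow(fx)
  W <- matrix(0, n_fix, n + include_true)
  if (include_true) W[, 1] <- w0
  for (it in seq_len(n)) {
    p <- order(si + stats::runif(n_fix))
    col <- numeric(n_fix)
    col[p] <- w0[base]
    W[, it + include_true] <- col
  }
  maps <- as.matrix(basis %*% W)
  list(maps = maps, grid = grid, n_participants = cw$n_participants)
}

# Row-wise k most extreme values of cbind(buffer, chunk); returns P x k.
update_topk <- function(buffer, chunk, k, decreasing) {
  comb <- if (is.null(buffer)) chunk else cbind(buffer, chunk)
  if (ncol(comb) <= k) return(comb)
  topk_rows(comb, k, decreasing)
}

#' Run a full permutation contrast
#'
#' End-to-end: observed group difference map, pixel-wise Monte Carlo
#' p-values, signed significance mask at `pixel_alpha`, cluster table, and
#' the max-cluster-size null distribution with survival flags.
#'
#' Each map (observed and resampled) is placed within the full stack of
#' `n_iterations + 1` maps, which makes observed and resampled maps
#' exchangeable under the null; for the observed map this reduces to the
#' add-one formula of [pixel_pvalues()].  With `leave_self_out = TRUE` each
#' resampled map is instead compared against the other maps only.
#'
#' Iterations are processed in chunks and only per-pixel tail order
#' statistics, the first `n_cluster_maps` maps, and running counts are kept,
#' so memory stays bounded by the retained subset rather than the full
#' iteration count.
#'
#' @param fixations fixation data.frame (aligned, clamped, filtered to the
#'   ordinal range of interest), containing the condition and participant
#'   columns.
#' @param grid a [grid_spec()].
#' @param spec a [permutation_spec()].
#' @param condition_col,levels,participant_col contrast definition: the
#'   difference is `levels[1] - levels[2]`.
#' @param sigma kernel sd in degrees (default 0.3).
#' @param chunk_size iterations per streaming chunk.
#' @return an object of class `permutation_result`: list with
#'   `true_map` (`difference_map`), `pmap` (p-values + sign), `mask`
#'   (signed matrix), `clusters` (with `survives`), `null_max_sizes`,
#'   `spec`, `contrast`, `n_participants`.
#' @export
run_contrast <- function(fixations, grid, spec = permutation_spec(),
                         condition_col = "condition",
                         levels = c("A", "B"),
                         participant_col = "participant_id",
                         sigma = 0.3,
                         chunk_size = 250L) {
  cw <- contrast_weights(fixations, condition_col, levels, participant_col)
  fx <- cw$fx
  basis <- fixation_basis(fx$x, fx$y, grid, sigma)
  stratum <- paste(fx[[participant_col]], fx$ordinal, sep = "\r")
  si <- match(stratum, unique(stratum))      # integer stratum codes
  base <- order(si)
  w0 <- cw$weights
  n_fix <- nrow(fx)
  N <- spec$n_iterations
  P <- grid$n_x * grid$n_y

  v_true <- as.numeric(basis %*% w0)
  m <- max_passing_count(spec$pixel_alpha, N + 1L)
  k <- m + 1L

  count_ge <- count_le <- numeric(P)
  retained <- matrix(0, P, spec$n_cluster_maps)
  full_stack <- if (spec$leave_self_out) matrix(0, P, N) else NULL
  # the observed map is part of the reference stack
  B_hi <- update_topk(NULL, matrix(v_true, P, 1), k, decreasing = TRUE)
  B_lo <- update_topk(NULL, matrix(v_true, P, 1), k, decreasing = FALSE)

  set.seed(spec$seed)
  done <- 0L
  while (done < N) {
    nc <- min(chunk_size, N - done)
    W <- matrix(0, n_fix, nc)
    for (it in seq_len(nc)) {
      # one numeric key sorts by stratum, random within stratum
      p <- order(si + stats::runif(n_fix))
      col <- numeric(n_fix)
      col[p] <- w0[base]
      W[, it] <- col
    }
    Mc <- as.matrix(basis %*% W)
    cnt <- count_extremes(Mc, v_true)
    count_ge <- count_ge + cnt$ge
    count_le <- count_le + cnt$le
    take <- which(done + seq_len(nc) <= spec$n_cluster_maps)
    if (length(take))
      retained[, done + take] <- Mc[, take]
    if (spec$leave_self_out)
      full_stack[, done + seq_len(nc)] <- Mc
    B_hi <- update_topk(B_hi, Mc, k, decreasing = TRUE)
    B_lo <- update_topk(B_lo, Mc, k, decreasing = FALSE)
    done <- done + nc
  }

  p_true <- ifelse(v_true >= 0, (count_ge + 1) / (N + 1),
                   (count_le + 1) / (N + 1))
  pm <- list(p = matrix(p_true, grid$n_x, grid$n_y),
             sign = matrix(as.integer(sign(v_true)), grid$n_x, grid$n_y))

  thr <- list(hi = B_hi[, k], lo = B_lo[, k])
  mask <- matrix(signed_mask_from_thresholds(v_true, thr),
                 grid$n_x, grid$n_y)
  clusters <- label_clusters(mask, spec$connectivity)

  null_max <- numeric(spec$n_cluster_maps)
  if (spec$n_cluster_maps > 0) {
    for (j in seq_len(spec$n_cluster_maps)) {
      vj <- retained[, j]
      if (spec$leave_self_out) {
        ref <- cbind(v_true, full_stack[, -j, drop = FALSE])
        pj <- pixel_pvalues(vj, ref)
        mj <- matrix(threshold_map(pj, spec$pixel_alpha),
                     grid$n_x, grid$n_y)
      } else {
        mj <- matrix(signed_mask_from_thresholds(vj, thr),
                     grid$n_x, grid$n_y)
      }
      cl <- label_clusters(mj, spec$connectivity)
      null_max[j] <- if (nrow(cl)) max(cl$size) else 0
    }
    clusters <- cluster_correct(clusters, null_max, spec$cluster_alpha)
  } else {
    clusters$survives <- logical(nrow(clusters))
  }

  true_map <- structure(list(grid = grid,
                             values = matrix(v_true, grid$n_x, grid$n_y),
                             n_participants = cw$n_participants),
                        class = "difference_map")
  structure(list(true_map = true_map, pmap = pm, mask = mask,
                 clusters = clusters, null_max_sizes = null_max,
                 spec = spec,
                 contrast = paste(levels, collapse = " vs "),
                 n_participants = cw$n_participants),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result>", x$contrast, "\n")
  cat(sprintf("  %d iterations, %d cluster-null maps, pixel alpha %.3g, cluster alpha %.3g\n",
              x$spec$n_iterations, x$spec$n_cluster_maps,
              x$spec$pixel_alpha, x$spec$cluster_alpha))
  n_sig <- sum(x$mask != 0)
  n_surv <- sum(x$clusters$survives)
  cat(sprintf("  %d suprathreshold pixels in %d cluster(s); %d surviving\n",
              n_sig, nrow(x$clusters), n_surv))
  if (length(x$null_max_sizes))
    cat(sprintf("  cluster-size survival threshold: %s px\n",
                attr(x$clusters, "size_threshold")))
  invisible(x)
}
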