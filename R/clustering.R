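#' Correlation distance between selectivity profiles
#'
#' `pdist[i, j] = 1 - r[i, j]` where `r` is the sample Pearson correlation
#' between the relative-contribution vectors of neurons `i` and `j`.
#'
#' @param profiles neurons x variables matrix (rows need >= 2 variables and
#'   nonzero variance).
#' @return symmetric matrix in `[0, 2]` with zero diagonal.
#' @export
contribution_distance_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2 || ncol(profiles) < 2) {
    stop("need >= 2 profiles with >= 2 variables", call. = FALSE)
  }
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile for neuron(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  D <- 1 - stats::cor(t(profiles))
  diag(D) <- 0
  D
}

#' UPGMA clustering with a height cut
#'
#' Builds an agglomerative tree with unweighted average linkage, cuts it at
#' nodes whose heights are below `thresh_cut`, and discards clusters with
#' fewer than 3 neurons (their members are reported separately).
#'
#' @param distances symmetric dissimilarity matrix (or `dist`).
#' @param thresh_cut cut height.
#' @param min_size minimum retained cluster size.
#' @return list with `assignment` (cluster id per neuron, `NA` for
#'   discarded), `clusters` (list of member indices), `discarded`, and the
#'   `hclust` `tree`.
#' @export
upgma_cut_clusters <- function(distances, thresh_cut, min_size = 3) {
  D <- stats::as.dist(distances)
  tree <- stats::hclust(D, method = "average")
  memb <- stats::cutree(tree, h = thresh_cut)
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  assignment <- ifelse(memb %in% keep, memb, NA_integer_)
  # relabel retained clusters 1..k in order of appearance
  relab <- stats::setNames(seq_along(keep), sort(keep))
  assignment <- ifelse(is.na(assignment), NA_integer_,
                       relab[as.character(assignment)])
  clusters <- split(seq_along(assignment), assignment)
  list(assignment = unname(assignment), clusters = clusters,
       discarded = which(is.na(assignment)), tree = tree)
}

#' Co-membership partition matrix
#'
#' @param assignment cluster id per neuron (`NA` = unclustered).
#' @return binary N x N matrix, `1` where two neurons share a cluster, with
#'   unit diagonal.
#' @export
partition_matrix <- function(assignment) {
  n <- length(assignment)
  P <- matrix(0L, n, n)
  for (cl in unique(assignment[!is.na(assignment)])) {
    idx <- which(!is.na(assignment) & assignment == cl)
    P[idx, idx] <- 1L
  }
  diag(P) <- 1L
  P
}

# correlation between upper triangles of two partition matrices, guarding
# the degenerate zero-variance cases
partition_score <- function(P_test, P_pred) {
  a <- P_test[upper.tri(P_test)]
  b <- P_pred[upper.tri(P_pred)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(if (all(a == b)) 1 else 0)
  }
  stats::cor(a, b)
}

# assign profiles to the closest centroid (same correlation distance as the
# clustering itself)
assign_to_centroids <- function(profiles, centroids) {
  apply(profiles, 1, function(p) {
    d <- apply(centroids, 1, function(cc) {
      if (stats::sd(p) == 0 || stats::sd(cc) == 0) 2
      else 1 - stats::cor(p, cc)
    })
    which.min(d)
  })
}

#' Generalisability of split-half clusterings
#'
#' For one cut threshold: cluster the train-half profiles, assign each
#' test-half profile to the nearest train-cluster centroid, and correlate the
#' upper triangle of the resulting co-membership matrix with that of the
#' clustering computed on the test half directly. Both train/test directions
#' are averaged.
#'
#' @param profiles_a,profiles_b neurons x variables relative-contribution
#'   matrices from two independent halves of the trials.
#' @param thresh_cut cut height.
#' @param min_size minimum retained cluster size.
#' @return the averaged generalisability score (`NA` when either half yields
#'   no retained cluster).
#' @export
cluster_generalisability <- function(profiles_a, profiles_b, thresh_cut,
                                     min_size = 3) {
  mean(c(generalisability_direction(profiles_a, profiles_b, thresh_cut,
                                    min_size)$score,
         generalisability_direction(profiles_b, profiles_a, thresh_cut,
                                    min_size)$score))
}

# one train->test direction; returns the test and predicted partition
# matrices so controls can permute the test partitioning
generalisability_direction <- function(train, test, thresh_cut, min_size = 3) {
  cl_train <- upgma_cut_clusters(contribution_distance_matrix(train),
                                 thresh_cut, min_size)
  cl_test <- upgma_cut_clusters(contribution_distance_matrix(test),
                                thresh_cut, min_size)
  if (!length(cl_train$clusters) || !length(cl_test$clusters)) {
    return(list(score = NA_real_, P_test = NULL, P_pred = NULL))
  }
  centroids <- do.call(rbind, lapply(cl_train$clusters, function(idx) {
    colMeans(train[idx, , drop = FALSE])
  }))
  pred <- assign_to_centroids(test, centroids)
  P_test <- partition_matrix(cl_test$assignment)
  P_pred <- partition_matrix(pred)
  list(score = partition_score(P_test, P_pred), P_test = P_test,
       P_pred = P_pred)
}

#' Cross-validated selection of the tree cut threshold
#'
#' Scans a threshold grid, scoring each by [cluster_generalisability()] of
#' split-half profiles; also reports a label-shuffled control at the selected
#' threshold.
#'
#' @param profiles_a,profiles_b split-half relative-contribution matrices.
#' @param threshold_grid candidate cut heights (default 21 points, 0.5-3.0).
#' @param min_size minimum retained cluster size.
#' @param seed seed for the shuffle control.
#' @return list with `thresh_cut` (argmax), `curve` (threshold,
#'   generalisability), `shuffle_score`.
#' @export
crossval_cut_threshold <- function(profiles_a, profiles_b,
                                   threshold_grid = seq(0.5, 3, length.out = 21),
                                   min_size = 3, seed = 1L) {
  scores <- vapply(threshold_grid, function(th) {
    cluster_generalisability(profiles_a, profiles_b, th, min_size)
  }, numeric(1))
  if (all(is.na(scores))) {
    stop("no threshold produced retained clusters in both halves", call. = FALSE)
  }
  best <- which.max(ifelse(is.na(scores), -Inf, scores))
  # control: score the predicted partition against a label-shuffled test
  # partitioning (permuting the test co-membership matrix, not the profiles)
  shuffle <- with_seed(seed, {
    mean(vapply(list(list(profiles_a, profiles_b),
                     list(profiles_b, profiles_a)), function(pair) {
      dd <- generalisability_direction(pair[[1]], pair[[2]],
                                       threshold_grid[best], min_size)
      if (is.null(dd$P_test)) return(NA_real_)
      perm <- sample(nrow(dd$P_test))
      partition_score(dd$P_test[perm, perm], dd$P_pred)
    }, numeric(1)), na.rm = TRUE)
  })
  list(thresh_cut = threshold_grid[best],
       curve = data.frame(threshold = threshold_grid,
                          generalisability = scores),
       shuffle_score = shuffle)
}

#' Split-half relative-contribution profiles
#'
#' Randomly divides trials into two equal sets, refits each neuron's selected
#' model on each half and recomputes its relative contributions. Neurons
#' whose refit fails on either half are dropped and reported.
#'
#' @param design full-session design matrix.
#' @param counts_matrix bins x units count matrix.
#' @param fits list of selected `glm_fit`s (units with >= 1 variable).
#' @param seed seed for the trial split.
#' @return list with matrices `A` and `B` (rows = retained units) and
#'   `dropped` unit indices.
#' @export
split_half_profiles <- function(design, counts_matrix, fits, seed = 1L) {
  trials <- unique(design$bin_trial)
  halves <- with_seed(seed, {
    perm <- sample(trials)
    list(A = perm[seq_len(floor(length(perm) / 2))],
         B = perm[(floor(length(perm) / 2) + 1L):length(perm)])
  })
  vars_all <- unique(unlist(lapply(fits, function(f) f$variables)))
  profile_half <- function(fit, counts, rows) {
    sub_design <- design
    sub_design$X <- design$X[rows, , drop = FALSE]
    sub_design$bin_trial <- design$bin_trial[rows]
    sub_design$bin_time <- design$bin_time[rows]
    for (v in names(sub_design$variables)) {
      m <- sub_design$variables[[v]]$mask
      sub_design$variables[[v]]$mask <- match(intersect(m, rows), rows)
    }
    full <- fit_map(sub_design, counts[rows], fit$xi, fit$variables,
                    w_init = fit$weights)
    contribution_profile(full, sub_design, counts[rows])
  }
  A <- list(); B <- list(); dropped <- integer(0)
  for (u in seq_along(fits)) {
    res <- tryCatch({
      pa <- profile_half(fits[[u]], counts_matrix[, u],
                         which(design$bin_trial %in% halves$A))
      pb <- profile_half(fits[[u]], counts_matrix[, u],
                         which(design$bin_trial %in% halves$B))
      list(a = pa, b = pb)
    }, error = function(e) NULL)
    if (is.null(res)) {
      dropped <- c(dropped, u)
    } else {
      A[[length(A) + 1L]] <- res$a
      B[[length(B) + 1L]] <- res$b
    }
  }
  list(A = relative_contribution_matrix(A, vars_all),
       B = relative_contribution_matrix(B, vars_all),
       dropped = dropped)
}

#' Non-metric multidimensional scaling of selectivity profiles
#'
#' Kruskal's non-metric MDS (stress-1 criterion) embedding of a
#' dissimilarity matrix into 2 dimensions, initialized from the classical
#' (metric) solution.
#'
#' @param distances symmetric dissimilarity matrix; typically Euclidean
#'   distances between relative-contribution vectors.
#' @param k embedding dimension.
#' @return list with `points` (N x k) and `stress` (Kruskal stress-1, in
#'   `[0, 1]`).
#' @export
mds_projection <- function(distances, k = 2) {
  D <- as.matrix(distances)
  n <- nrow(D)
  eps <- max(D) * 1e-6 + 1e-12
  D[D <= 0] <- eps
  diag(D) <- 0
  res <- tryCatch(
    MASS::isoMDS(stats::as.dist(D), k = k, trace = FALSE, tol = 1e-6),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("non-metric MDS did not converge; returning the classical solution")
    pts <- stats::cmdscale(stats::as.dist(D), k = k)
    return(list(points = pts, stress = NA_real_))
  }
  list(points = res$points, stress = res$stress / 100)
}
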