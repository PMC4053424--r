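#' k-means clustering of granule positions
#'
#' Clusters the (x, y) coordinates of a trajectory (time is excluded from
#' the clustering) with k-means and correlates the cluster affiliation of
#' each coordinate with its observation time. For a granule transported
#' from the mother into the daughter, the two clusters correspond to the
#' two cells and the affiliation series changes once; a granule wandering
#' back and forth changes affiliation many times. Labels are renumbered so
#' cluster 1 is the earlier-occupied one (lower mean membership time).
#'
#' @param traj a [trajectory()].
#' @param k number of clusters (2 for mother/daughter).
#' @param seed RNG seed for the k-means restarts (deterministic result).
#' @param nstart number of random restarts.
#' @return Object of class `pb_clusters`: list with `labels` (per point),
#'   `centers` (k x 2, um), `tau` (number of label changes between
#'   successive time points), `n`, `R_rev`, `J4`, `S_b`, `S_w`,
#'   `degenerate`.
#' @examples
#' tr <- trajectory(t = 0:99, x = c(rep(0, 50), rep(10, 50)),
#'                  y = rep(0, 100))
#' cl <- cluster_positions(tr, seed = 1)
#' cl$tau; cl$R_rev
#' @export
cluster_positions <- function(traj, k = 2, seed = 1, nstart = 10) {
  n <- nrow(traj)
  if (n < k) stop("need at least k points", call. = FALSE)
  xy <- cbind(traj$x, traj$y)
  degenerate <- nrow(unique(xy)) < k
  if (degenerate) {
    labels <- rep(1L, n)
    centers <- rbind(colMeans(xy))
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    km <- kmeans(xy, centers = k, nstart = nstart)
    labels <- km$cluster
    centers <- km$centers
    # cluster 1 = earlier-occupied (lowest mean membership time)
    mt <- tapply(traj$t, labels, mean)
    ord <- order(mt)
    relab <- integer(k); relab[as.integer(names(mt))[ord]] <- seq_len(k)
    labels <- relab[labels]
    centers <- centers[as.integer(names(mt))[ord], , drop = FALSE]
    rownames(centers) <- seq_len(k)
  }
  tau <- sum(diff(labels) != 0)
  J <- if (degenerate) {
    list(J4 = NA_real_, S_b = NULL, S_w = NULL)
  } else {
    cluster_betweenness(xy, labels)
  }
  structure(list(labels = labels, centers = centers, tau = tau, n = n,
                 R_rev = if (n >= 2) tau / (n - 1) else NA_real_,
                 J4 = J$J4, S_b = J$S_b, S_w = J$S_w,
                 degenerate = degenerate),
            class = "pb_clusters")
}

#' @export
print.pb_clusters <- function(x, ...) {
  cat(sprintf("k-means position clustering: n = %d, tau = %d, R_rev = %.3f, J4 = %s\n",
              x$n, x$tau, x$R_rev,
              if (is.finite(x$J4)) sprintf("%.3f", x$J4) else as.character(x$J4)))
  if (x$degenerate) cat("  (degenerate: fewer distinct points than clusters)\n")
  invisible(x)
}

#' Reversibility rate of a cluster-affiliation series
#'
#' `R_rev = tau / (n - 1)` where `tau` is the number of adjacent time
#' points at which the affiliation changes and `n` the number of time
#' points. It equals 0 for a granule transported irreversibly (a single
#' transition contributes `1/(n-1)`, vanishing for long series) and
#' converges to 1 for a granule alternating between the two cells at every
#' step.
#'
#' @param affiliations integer/character vector of cluster labels over
#'   time.
#' @return `R_rev` in `[0, 1]`.
#' @examples
#' reversibility_rate(c(1, 1, 1, 2, 2, 2))  # 1/5
#' reversibility_rate(rep(c(1, 2), 50))     # 1
#' @export
reversibility_rate <- function(affiliations) {
  n <- length(affiliations)
  if (n < 2) stop("need at least 2 time points", call. = FALSE)
  tau <- sum(affiliations[-1] != affiliations[-n])
  tau / (n - 1)
}

#' Cluster betweenness J4
#'
#' Separation of two positional clusters as the ratio of the traces of the
#' between-class and within-class scatter matrices:
#' `J4 = tr(S_b) / tr(S_w)` with
#' `S_w = sum_k sum_{i in k} (x_i - mu_k)(x_i - mu_k)^T / N` and
#' `S_b = sum_k (N_k / N) (mu_k - mu)(mu_k - mu)^T`.
#' Large values mean tight, well-separated clusters, as for a granule
#' moved from the mother into the daughter.
#'
#' @param positions numeric matrix (N x 2) of coordinates, um.
#' @param labels cluster labels, both clusters non-empty.
#' @return List `J4`, `S_b`, `S_w`, `flag` (`"infinite"` when
#'   `tr(S_w) = 0`, i.e. all points sit exactly at their cluster centre).
#' @examples
#' pos <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' cluster_betweenness(pos, c(1, 1, 2, 2))$J4  # 100
#' @export
cluster_betweenness <- function(positions, labels) {
  positions <- as.matrix(positions)
  N <- nrow(positions)
  stopifnot(N == length(labels))
  groups <- split(seq_len(N), labels)
  if (any(lengths(groups) == 0)) stop("empty cluster", call. = FALSE)
  mu <- colMeans(positions)
  d <- ncol(positions)
  S_w <- matrix(0, d, d)
  S_b <- matrix(0, d, d)
  for (g in groups) {
    Xk <- positions[g, , drop = FALSE]
    mk <- colMeans(Xk)
    Xc <- sweep(Xk, 2, mk)
    S_w <- S_w + crossprod(Xc) / N
    dm <- mk - mu
    S_b <- S_b + (length(g) / N) * tcrossprod(dm)
  }
  tw <- sum(diag(S_w))
  J4 <- if (tw > 0) sum(diag(S_b)) / tw else Inf
  list(J4 = J4, S_b = S_b, S_w = S_w,
       flag = if (tw > 0) NULL else "infinite")
}
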