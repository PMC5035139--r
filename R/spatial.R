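#' Spatial statistics: cluster extent, cluster mass, TFCE
#'
#' Cluster-level and threshold-free statistics computed from a statistic
#' map on a regular grid. Connected components use 6, 18, or 26
#' connectivity in 3-D (face, face+edge, or face+edge+corner neighbours;
#' lower-dimensional grids use the corresponding reductions).
#' Out-of-mask voxels are excluded from all spatial operations.
#'
#' @name spatial_statistics
NULL

# Neighbour offsets for a given connectivity on a grid of ndim dims.
conn_offsets <- function(connectivity, ndim) {
  g <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1,
                 "18" = ord >= 1 & ord <= 2,
                 "26" = ord >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Label connected components of suprathreshold voxels. Returns an
# integer array of labels (0 = below threshold / out of mask).
label_clusters <- function(map, threshold, connectivity = 26,
                           mask = NULL) {
  dm <- dim(map) %||% length(map)
  map <- array(map, dm)
  ndim <- length(dm)
  supra <- map > threshold
  if (!is.null(mask)) supra <- supra & array(mask, dm)
  idx <- which(supra)
  labels <- array(0L, dm)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, dm)
  offs <- conn_offsets(connectivity, ndim)
  pos <- array(0L, dm)
  pos[idx] <- seq_along(idx)
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], `+`)
    ok <- rep(TRUE, nrow(nb))
    for (k in seq_len(ndim)) ok <- ok & nb[, k] >= 1 & nb[, k] <= dm[k]
    if (!any(ok)) next
    nb_lin <- nb[ok, , drop = FALSE]
    lin <- as.vector((nb_lin - 1) %*% cumprod(c(1, dm[-ndim]))) + 1
    tgt <- pos[lin]
    src <- which(ok)[tgt > 0]
    if (length(src))
      edges <- rbind(edges, cbind(src, tgt[tgt > 0]))
  }
  if (is.null(edges)) {
    labels[idx] <- seq_along(idx)
    return(labels)
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, length(idx) - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership[seq_along(idx)]
  labels[idx] <- as.integer(comp)
  labels
}

#' @describeIn spatial_statistics Sizes (in voxels) of the connected
#'   suprathreshold components. An empty suprathreshold set yields an
#'   empty cluster list.
#' @param map numeric array (statistic map); a plain vector is treated
#'   as one-dimensional.
#' @param cluster_threshold cluster-forming threshold on the statistic
#'   scale.
#' @param connectivity 6, 18, or 26.
#' @param mask optional logical array of the same shape.
#' @return list with \code{sizes} (or \code{masses}) per cluster and the
#'   integer \code{labels} array.
#' @export
cluster_extent <- function(map, cluster_threshold, connectivity = 26,
                           mask = NULL) {
  labels <- label_clusters(map, cluster_threshold, connectivity, mask)
  sizes <- if (any(labels > 0)) tabulate(labels[labels > 0]) else integer(0)
  list(sizes = sizes, labels = labels)
}

#' @describeIn spatial_statistics Cluster mass: the sum of the statistic
#'   values over each cluster's voxels (the suprathreshold values
#'   themselves, not their excess over the threshold).
#' @export
cluster_mass <- function(map, cluster_threshold, connectivity = 26,
                         mask = NULL) {
  labels <- label_clusters(map, cluster_threshold, connectivity, mask)
  dm <- dim(labels)
  mp <- array(map, dm)
  keep <- labels > 0
  masses <- if (any(keep))
    as.numeric(tapply(mp[keep], labels[keep], sum)) else numeric(0)
  list(masses = masses, labels = labels)
}

#' @describeIn spatial_statistics Threshold-free cluster enhancement:
#'   for each voxel, the integral over cluster-forming thresholds h of
#'   \eqn{e(h)^E h^H dh}, where e(h) is the extent of the cluster
#'   containing the voxel at threshold h. Defaults H = 2, E = 0.5 and
#'   dh = max(map)/100 are the standard volumetric choices. The map must
#'   be non-negative (handle negative contrasts by transforming the
#'   negated map separately); maps that are nowhere positive transform
#'   to all zeros.
#' @param H height exponent.
#' @param E extent exponent.
#' @param dh integration step; must be positive.
#' @return \code{tfce}: numeric array of transformed values.
#' @export
tfce <- function(map, H = 2, E = 0.5, dh = NULL, connectivity = 26,
                 mask = NULL) {
  dm <- dim(map) %||% length(map)
  mp <- array(map, dm)
  if (!is.null(mask)) mp[!array(mask, dm)] <- 0
  mx <- max(mp)
  if (mx <= 0) return(array(0, dm))
  if (is.null(dh)) dh <- mx / 100
  if (dh <= 0) stop("dh must be positive")
  out <- array(0, dm)
  for (h in seq(dh, mx, by = dh)) {
    labels <- label_clusters(mp, h - dh / 2, connectivity)
    keep <- labels > 0
    if (!any(keep)) break
    ext <- tabulate(labels[keep])
    out[keep] <- out[keep] + ext[labels[keep]]^E * h^H * dh
  }
  out
}

#' Permutation inference for spatial statistics
#'
#' Recomputes a spatial statistic on every rearrangement's statistic map
#' and compares each observed cluster (or voxel, for TFCE) against the
#' permutation distribution of the image-wise maximum of that spatial
#' statistic, yielding FWER-corrected p-values.
#'
#' @param dist a \code{\link{run_shuffled_glm}} permutation distribution
#'   whose columns correspond to in-grid voxels.
#' @param grid_dim integer vector, the grid shape.
#' @param type "extent", "mass", or "tfce".
#' @param cluster_threshold cluster-forming threshold (extent/mass).
#' @param H,E,dh TFCE parameters.
#' @param connectivity neighbourhood rule.
#' @return For extent/mass: list with observed cluster statistics,
#'   labels, and corrected p-value per cluster. For TFCE: list with the
#'   observed TFCE map and voxelwise corrected (and uncorrected)
#'   p-values.
#' @export
spatial_perm_test <- function(dist, grid_dim, type = c("extent", "mass",
                                                       "tfce"),
                              cluster_threshold = NULL, H = 2, E = 0.5,
                              dh = NULL, connectivity = 26) {
  type <- match.arg(type)
  J <- nrow(dist$stats)
  if (type %in% c("extent", "mass") && is.null(cluster_threshold))
    stop("extent/mass require a cluster-forming threshold")
  stat_of_map <- function(v) {
    m <- array(v, grid_dim)
    switch(type,
           extent = cluster_extent(m, cluster_threshold, connectivity),
           mass = cluster_mass(m, cluster_threshold, connectivity),
           tfce = tfce(m, H, E, dh, connectivity))
  }
  if (type == "tfce") {
    tfce_obs <- stat_of_map(dist$stats[1, ])
    maxima <- numeric(J)
    exceed <- array(0L, grid_dim)
    for (j in seq_len(J)) {
      tj <- stat_of_map(dist$stats[j, ])
      maxima[j] <- max(tj)
      exceed <- exceed + (tj >= tfce_obs)
    }
    p_fwer <- array(vapply(as.vector(tfce_obs),
                           function(t0) mean(maxima >= t0), numeric(1)),
                    grid_dim)
    list(tfce = tfce_obs, p_fwer = p_fwer, p_uncorrected = exceed / J,
         maxima = maxima)
  } else {
    obs <- stat_of_map(dist$stats[1, ])
    vals <- if (type == "extent") obs$sizes else obs$masses
    maxima <- vapply(seq_len(J), function(j) {
      s <- stat_of_map(dist$stats[j, ])
      v <- if (type == "extent") s$sizes else s$masses
      if (length(v)) max(v) else 0
    }, numeric(1))
    p_fwer <- vapply(vals, function(cv) mean(maxima >= cv), numeric(1))
    list(cluster_stats = vals, labels = obs$labels, p_fwer = p_fwer,
         maxima = maxima)
  }
}
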