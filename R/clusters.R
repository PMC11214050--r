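#' Detect nucleosome clusters from linker lengths
#'
#' A cluster is a maximal run of `min_size` or more consecutive nucleosomes
#' whose internal linkers are all at most `l_c` bp; flanking linkers (when
#' present) exceed `l_c`, so detected runs are disjoint. The array is treated
#' as linear: when a `linker_state` of M periodic linkers is supplied, only
#' the first M - 1 are scanned.
#'
#' @param linkers a `linker_state` or integer vector of linker lengths (bp);
#'   a vector of K linkers describes K + 1 nucleosomes.
#' @param l_c cutoff in bp.
#' @param min_size minimum nucleosomes per cluster.
#' @return list of clusters, each a list with `members` (consecutive
#'   nucleosome indices) and `Ni` (member count); empty list when no run
#'   qualifies.
#' @export
find_clusters <- function(linkers, l_c = 15, min_size = 4) {
  lens <- if (inherits(linkers, "linker_state")) {
    M <- length(linkers$lengths)
    linkers$lengths[seq_len(M - 1)]
  } else as.integer(linkers)
  short <- lens <= l_c
  out <- list()
  run_start <- NA_integer_
  for (j in seq_along(short)) {
    if (short[j] && is.na(run_start)) run_start <- j
    if ((!short[j] || j == length(short)) && !is.na(run_start)) {
      run_end <- if (short[j]) j else j - 1L
      members <- run_start:(run_end + 1L) # K short linkers join K+1 nucleosomes
      if (length(members) >= min_size) {
        out[[length(out) + 1L]] <- list(members = members,
                                        Ni = length(members))
      }
      run_start <- NA_integer_
    }
  }
  out
}

project_cols <- list(XY = c(1, 2), XZ = c(1, 3), YZ = c(2, 3))

#' Projected minor-principal-axis size of a cluster
#'
#' Projects the member positions onto one of the coordinate planes, forms the
#' summed (not count-normalized) outer-product inertia matrix about the 2D
#' centroid, and returns the square root of its smaller eigenvalue -- the
#' minor principal axis, akin to chromatin widths measured on 2D tomography
#' slices. With `normalized = TRUE` the gyration-tensor convention (dividing
#' by the member count) is used instead; the summed form, the default, makes
#' sizes grow with cluster membership.
#'
#' @param positions Ni x 3 matrix of member positions (nm).
#' @param plane one of "XY", "XZ", "YZ".
#' @param normalized divide the inertia matrix by Ni (off by default).
#' @return minor principal axis in nm.
#' @export
cluster_size <- function(positions, plane = c("XY", "XZ", "YZ"),
                         normalized = FALSE) {
  plane <- match.arg(plane)
  X <- as.matrix(positions)[, project_cols[[plane]], drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  I2 <- crossprod(Xc) # sum of outer products about the centroid
  if (normalized) I2 <- I2 / nrow(X)
  ev <- eigen(I2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, min(ev)))
}

#' Cluster table of one configuration
#'
#' @param config a `chain_config`.
#' @param l_c cutoff in bp.
#' @param min_size minimum nucleosomes per cluster.
#' @param normalized see [cluster_size()].
#' @return data.frame with one row per cluster x projection plane: `plane`,
#'   `first`, `Ni`, `minor_axis` (nm).
#' @export
cluster_table <- function(config, l_c = 15, min_size = 4,
                          normalized = FALSE) {
  stopifnot(inherits(config, "chain_config"))
  cl <- find_clusters(config$linkers, l_c = l_c, min_size = min_size)
  if (length(cl) == 0) {
    return(data.frame(plane = character(), first = integer(), Ni = integer(),
                      minor_axis = numeric()))
  }
  do.call(rbind, lapply(names(project_cols), function(pl) {
    data.frame(
      plane = pl,
      first = vapply(cl, function(x) x$members[1], integer(1)),
      Ni = vapply(cl, function(x) x$Ni, integer(1)),
      minor_axis = vapply(cl, function(x) {
        cluster_size(config$nuc_pos[x$members, , drop = FALSE], pl,
                     normalized = normalized)
      }, numeric(1)))
  }))
}

#' Ensemble cluster-size distribution
#'
#' Pools minor-axis sizes over all clusters, configurations, and the XY, XZ,
#' and YZ projection planes, and bins them into a fixed-width histogram.
#' Pooling over the three coordinate planes makes the statistic only weakly
#' sensitive to a global rotation of the ensemble; exact rotation invariance
#' is not claimed.
#'
#' @param configs a list of `chain_config` objects (or a single one).
#' @param l_c cutoff in bp.
#' @param min_size minimum nucleosomes per cluster.
#' @param bin_width histogram bin width in nm.
#' @param normalized see [cluster_size()].
#' @return object of class `cluster_size_distribution`: `sizes` (pooled nm
#'   values), `histogram` (data.frame of bin_left, bin_right, count,
#'   fraction), `mean_size` (NA when no clusters), `n_configs`.
#' @export
ensemble_distribution <- function(configs, l_c = 15, min_size = 4,
                                  bin_width = 5, normalized = FALSE) {
  if (inherits(configs, "chain_config")) configs <- list(configs)
  if (length(configs) < 1) stop("need at least one configuration")
  sizes <- unlist(lapply(configs, function(cfg) {
    cluster_table(cfg, l_c = l_c, min_size = min_size,
                  normalized = normalized)$minor_axis
  }))
  if (length(sizes) == 0) {
    hist_df <- data.frame(bin_left = numeric(), bin_right = numeric(),
                          count = integer(), fraction = numeric())
    mean_size <- NA_real_
  } else {
    edges <- seq(0, bin_width * ceiling(max(sizes) / bin_width + 1e-9),
                 by = bin_width)
    if (length(edges) < 2) edges <- c(0, bin_width)
    counts <- as.integer(table(cut(sizes, edges, right = FALSE,
                                   include.lowest = FALSE)))
    hist_df <- data.frame(bin_left = edges[-length(edges)],
                          bin_right = edges[-1], count = counts,
                          fraction = counts / length(sizes))
    mean_size <- mean(sizes)
  }
  structure(list(sizes = sizes, histogram = hist_df, mean_size = mean_size,
                 n_configs = length(configs)),
            class = "cluster_size_distribution")
}

#' @export
print.cluster_size_distribution <- function(x, ...) {
  cat(sprintf(
    "Cluster-size distribution: %d sizes from %d configurations, mean %s nm\n",
    length(x$sizes), x$n_configs,
    if (is.na(x$mean_size)) "NA" else sprintf("%.2f", x$mean_size)))
  invisible(x)
}

#' Fraction of linkers permitting HP1--HP1 interactions
#'
#' @param linkers a `linker_state` or integer vector of linker lengths (bp).
#' @param l_c cutoff in bp.
#' @return fraction of linkers <= `l_c`, in \[0, 1\]. For a `linker_state`
#'   all M (periodic) linkers count.
#' @export
short_linker_fraction <- function(linkers, l_c = 15) {
  lens <- if (inherits(linkers, "linker_state")) linkers$lengths
          else as.numeric(linkers)
  mean(lens <= l_c)
}

#' Sliding-window moving average of a per-linker profile
#'
#' Centered moving average; near the edges the window truncates to the
#' available span. A constant input is returned unchanged and `window = 1`
#' is the identity.
#'
#' @param values numeric sequence.
#' @param window window width (odd widths give a symmetric window).
#' @return smoothed numeric sequence of the same length.
#' @export
smooth_profile <- function(values, window = 11) {
  n <- length(values)
  stop_if_not_scalar(window, "window", positive = TRUE)
  if (window > n) stop("'window' must not exceed the sequence length")
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(values[lo:hi])
  }, numeric(1))
}

#' Write a cluster-size histogram as CSV
#'
#' @param dist a `cluster_size_distribution`.
#' @param path output CSV path.
#' @export
write_histogram <- function(dist, path) {
  stopifnot(inherits(dist, "cluster_size_distribution"))
  write.csv(dist$histogram, path, row.names = FALSE)
  invisible(path)
}
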