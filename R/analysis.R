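#' Occupancy distribution of the move region
#'
#' Normalized histogram of the number of region members per frame.
#'
#' @param frames Frame list from a \code{campaign_stats} object (or the
#'   object itself).
#' @return Data frame with columns \code{n} and \code{fraction}
#'   (summing to 1).
#' @export
occupancy_histogram <- function(frames) {
  if (inherits(frames, "campaign_stats")) frames <- frames$frames
  if (length(frames) == 0) stop("need at least one frame")
  counts <- vapply(frames, function(f) f$n_region, numeric(1))
  tab <- table(counts)
  data.frame(n = as.integer(names(tab)),
             fraction = as.numeric(tab) / length(counts))
}

#' Pool region primary-site positions over frames
#'
#' Optionally superposes each frame's reference sites onto those of the
#' first frame (least-squares/Kabsch) and applies that rigid motion to the
#' member positions before pooling. Whole-box campaigns carry no reference
#' sites and skip alignment.
#'
#' @param frames Frame list or \code{campaign_stats}.
#' @param align Superpose on the frames' reference sites when available.
#' @return Data frame with columns \code{frame}, \code{x}, \code{y},
#'   \code{z}.
#' @export
pool_region_positions <- function(frames, align = TRUE) {
  if (inherits(frames, "campaign_stats")) frames <- frames$frames
  ref0 <- if (length(frames)) frames[[1]]$ref_xyz else NULL
  do_align <- align && !is.null(ref0) && nrow(ref0) >= 3
  out <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    xyz <- f$region_xyz
    if (nrow(xyz) == 0) return(NULL)
    if (do_align) {
      tr <- kabsch_transform(f$ref_xyz, ref0)
      xyz <- sweep(xyz, 2, tr$center_from) %*% tr$rotation
      xyz <- sweep(xyz, 2, tr$center_to, "+")
    }
    data.frame(frame = i, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(frame = integer(), x = numeric(),
                               y = numeric(), z = numeric()) else out
}

#' Least-squares superposition (Kabsch)
#'
#' Rigid transform mapping point set \code{from} onto \code{to}.
#'
#' @param from,to n x 3 matrices of paired coordinates (n >= 3).
#' @return List: \code{rotation} (to be applied as \code{x \%*\% rotation}),
#'   \code{center_from}, \code{center_to}.
#' @export
kabsch_transform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, center_from = cf, center_to = ct)
}

#' Cluster pooled hydration positions
#'
#' Average-linkage hierarchical clustering of pooled primary-site
#' positions, cut at a fixed distance. For each flat cluster the centroid,
#' the fraction of frames contributing at least one member (the reported
#' occupancy) and the mean member count per frame are returned.
#'
#' @param pooled Data frame from [pool_region_positions()] (columns
#'   \code{frame}, \code{x}, \code{y}, \code{z}).
#' @param cutoff Dendrogram cut height (A); default 2.4.
#' @param n_frames Total number of frames for the occupancy denominator;
#'   defaults to \code{max(pooled$frame)}.
#' @return An object of class \code{cluster_report}: a data frame of
#'   sites (\code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{mean_members}, \code{n_members}) sorted by occupancy.
#' @export
cluster_hydration_sites <- function(pooled, cutoff = 2.4, n_frames = NULL) {
  if (nrow(pooled) == 0) {
    rep <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      occupancy = numeric(), mean_members = numeric(),
                      n_members = integer())
    return(structure(rep, class = c("cluster_report", "data.frame")))
  }
  if (is.null(n_frames)) n_frames <- max(pooled$frame)
  xyz <- as.matrix(pooled[, c("x", "y", "z")])
  if (nrow(xyz) == 1) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(xyz), method = "average")
    cl <- stats::cutree(hc, h = cutoff)
  }
  sites <- lapply(split(seq_len(nrow(xyz)), cl), function(i) {
    data.frame(x = mean(xyz[i, 1]), y = mean(xyz[i, 2]), z = mean(xyz[i, 3]),
               occupancy = length(unique(pooled$frame[i])) / n_frames,
               mean_members = length(i) / n_frames,
               n_members = length(i))
  })
  rep <- do.call(rbind, sites)
  rep <- rep[order(-rep$occupancy, -rep$n_members), , drop = FALSE]
  rownames(rep) <- NULL
  out <- structure(rep, class = c("cluster_report", "data.frame"))
  attr(out, "membership") <- cl   # flat cluster id per pooled position
  out
}

#' Match clusters to reference coordinates
#'
#' One-to-one greedy matching by ascending distance: each cluster is
#' paired with its nearest unmatched reference site if the distance is
#' below the threshold (default 1.4 A, the van der Waals radius of
#' water).
#'
#' @param report A [cluster_hydration_sites()] report.
#' @param reference m x 3 matrix of reference coordinates (A).
#' @param threshold Maximum match distance (A).
#' @return Data frame with columns \code{site}, \code{reference},
#'   \code{distance}.
#' @export
match_to_reference <- function(report, reference, threshold = 1.4) {
  reference <- as.matrix(reference)
  empty <- data.frame(site = integer(), reference = integer(),
                      distance = numeric())
  if (nrow(report) == 0 || nrow(reference) == 0) return(empty)
  sites <- as.matrix(report[, c("x", "y", "z")])
  D <- sqrt(outer(rowSums(sites^2), rep(1, nrow(reference))) +
              outer(rep(1, nrow(sites)), rowSums(reference^2)) -
              2 * sites %*% t(reference))
  pairs <- which(D < threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(empty)
  ord <- order(D[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_s <- logical(nrow(sites)); used_r <- logical(nrow(reference))
  out <- empty
  for (k in seq_len(nrow(pairs))) {
    s <- pairs[k, 1]; r <- pairs[k, 2]
    if (used_s[s] || used_r[r]) next
    used_s[s] <- TRUE; used_r[r] <- TRUE
    out <- rbind(out, data.frame(site = s, reference = r,
                                 distance = D[s, r]))
  }
  out
}

#' Mean bulk density over frames
#'
#' Total movable-species mass over box volume, averaged over frames, in
#' g/cm^3.
#'
#' @param frames Frame list or \code{campaign_stats}.
#' @return Density in g/cm^3.
#' @export
bulk_density <- function(frames) {
  if (inherits(frames, "campaign_stats")) frames <- frames$frames
  if (length(frames) == 0) return(0)
  dens <- vapply(frames, function(f) {
    f$mass_total / prod(f$box) * UNITS$amu_A3_to_g_cm3
  }, numeric(1))
  mean(dens)
}
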