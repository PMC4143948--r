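#' Clustering parameters
#'
#' Parameters of the density-gradient clustering of localization data. The
#' density of a localization is the number of other localizations inside its
#' Eps-environment (a circle of radius `eps`); local density maxima with
#' density strictly greater than `k` seed clusters, which are expanded
#' downhill in density. Clusters whose centres have at least
#' `unit_min_clusters` cluster centres (including themselves) within
#' `unit_radius` seed CAZ-units.
#'
#' @param eps search radius in nm (default 20, about the radius of an
#'   electron-dense CAZ filament with the antibody complex attached).
#' @param k density threshold (default 16 localizations).
#' @param unit_radius CAZ-unit grouping radius in nm (default 200).
#' @param unit_min_clusters minimum clusters within `unit_radius` (default 4).
#' @param count_self logical; if `TRUE` the focal localization is counted in
#'   its own density (default `FALSE`: density counts *other* localizations).
#' @param include_subthreshold logical; attach sub-threshold neighbour
#'   clusters to a seeded unit (default `TRUE`).
#' @param min_cluster_size clusters with fewer members are dropped from
#'   reporting (default 3, the minimum for an ellipse fit).
#' @export
cluster_params <- function(eps = 20, k = 16, unit_radius = 200,
                           unit_min_clusters = 4, count_self = FALSE,
                           include_subthreshold = TRUE, min_cluster_size = 3) {
  stopifnot(eps > 0, k >= 1, unit_radius > 0, unit_min_clusters >= 1)
  structure(list(eps = eps, k = k, unit_radius = unit_radius,
                 unit_min_clusters = unit_min_clusters,
                 count_self = count_self,
                 include_subthreshold = include_subthreshold,
                 min_cluster_size = min_cluster_size),
            class = "cluster_params")
}

loc_xy <- function(table) {
  if (is.matrix(table)) table else cbind(table$x, table$y)
}

# Fixed-radius neighbour lists via cell-grid search. Returns a list of
# integer vectors: for each point, the indices of other points at distance
# <= eps. O(n) cells of size eps; only the 3x3 cell neighbourhood is scanned.
eps_neighbors <- function(xy, eps) {
  n <- nrow(xy)
  out <- vector("list", n)
  if (n == 0) return(out)
  cx <- floor(xy[, 1] / eps); cy <- floor(xy[, 2] / eps)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  coords <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
  cell_of <- match(key, names(cells))
  # index of cell by coordinate for 3x3 lookup
  cell_key <- function(a, b) paste(a, b)
  lookup <- new.env(hash = TRUE, size = length(cells))
  for (i in seq_along(cells)) assign(names(cells)[i], i, envir = lookup)
  eps2 <- eps * eps
  for (ci in seq_along(cells)) {
    pts <- cells[[ci]]
    cand <- pts
    a <- coords[ci, 1]; b <- coords[ci, 2]
    for (da in -1:1) for (db in -1:1) {
      if (da == 0 && db == 0) next
      j <- lookup[[cell_key(a + da, b + db)]]
      if (!is.null(j)) cand <- c(cand, cells[[j]])
    }
    if (length(cand) == 1L) { out[[pts]] <- integer(0); next }
    cxy <- xy[cand, , drop = FALSE]
    for (p in pts) {
      d2 <- (cxy[, 1] - xy[p, 1])^2 + (cxy[, 2] - xy[p, 2])^2
      nb <- cand[d2 <= eps2]
      out[[p]] <- nb[nb != p]
    }
  }
  out
}

#' Local localization density
#'
#' For every localization, the number of localizations within distance `eps`
#' (the Eps-environment). By default the focal localization itself is not
#' counted, matching the reading that a point must *enclose* at least k other
#' localizations; set `count_self = TRUE` in the parameters for the
#' alternative convention.
#'
#' @param table a [loc_table()] or a two-column coordinate matrix.
#' @param eps search radius in nm.
#' @param count_self count the focal localization itself?
#' @param neighbors optional precomputed neighbour lists (internal reuse).
#' @return integer vector of densities.
#' @export
local_density <- function(table, eps = 20, count_self = FALSE,
                          neighbors = NULL) {
  stopifnot(eps > 0)
  xy <- loc_xy(table)
  if (is.null(neighbors)) neighbors <- eps_neighbors(xy, eps)
  d <- lengths(neighbors)
  if (count_self) d <- d + 1L
  as.integer(d)
}

#' Find cluster centres
#'
#' A localization is a cluster centre iff its density is strictly greater
#' than `k` and no localization in its Eps-environment has a strictly higher
#' density. Density plateaus are broken deterministically: among equal-density
#' Eps-neighbours only the point that is smallest in (x, then y, then index)
#' order remains a candidate. Finally candidates are accepted in decreasing
#' density order and any candidate within `eps` of an already accepted centre
#' (necessarily of equal or higher density) is suppressed.
#'
#' @param table a [loc_table()] or coordinate matrix.
#' @param densities densities from [local_density()] at the same `eps`.
#' @param params a [cluster_params()].
#' @param neighbors optional precomputed neighbour lists.
#' @return integer vector of centre indices.
#' @export
find_centres <- function(table, densities, params = cluster_params(),
                         neighbors = NULL) {
  xy <- loc_xy(table)
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  if (is.null(neighbors)) neighbors <- eps_neighbors(xy, params$eps)
  ord_rank <- order(xy[, 1], xy[, 2], seq_len(n)) # position in (x,y,idx) order
  rank_of <- integer(n); rank_of[ord_rank] <- seq_len(n)
  cand <- which(densities > params$k)
  keep <- logical(n)
  for (i in cand) {
    nb <- neighbors[[i]]
    if (length(nb)) {
      dn <- densities[nb]
      if (any(dn > densities[i])) next
      eq <- nb[dn == densities[i]]
      if (length(eq) && any(rank_of[eq] < rank_of[i])) next
    }
    keep[i] <- TRUE
  }
  cand <- which(keep)
  if (length(cand) <= 1L) return(cand)
  # suppression pass: accept in decreasing density, then (x,y,idx) order
  ord <- cand[order(-densities[cand], xy[cand, 1], xy[cand, 2], cand)]
  accepted <- integer(0)
  eps2 <- params$eps^2
  for (i in ord) {
    if (length(accepted)) {
      d2 <- (xy[accepted, 1] - xy[i, 1])^2 + (xy[accepted, 2] - xy[i, 2])^2
      if (any(d2 <= eps2)) next
    }
    accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Expand clusters from centres
#'
#' Breadth-first density-gradient expansion. Starting at each centre (taken in
#' decreasing density order), the Eps-neighbours of a core member join the
#' cluster if their density is strictly lower than the member that discovered
#' them; a joining member with density strictly greater than `k` is itself a
#' core object and keeps expanding, otherwise it is a boundary point where
#' expansion halts. An increase in density along the way ends the cluster at
#' that edge, which separates adjacent clusters at density saddles. Clusters
#' are disjoint: a localization claimed by one cluster is never reassigned.
#' The expansion frontier is processed in decreasing discoverer-density order
#' for determinism.
#'
#' @inheritParams find_centres
#' @param centres centre indices from [find_centres()].
#' @return list with `members` (list of integer vectors, one per centre, each
#'   including its centre) and `assignment` (integer vector, 0 = unclustered).
#' @export
expand_clusters <- function(table, densities, centres,
                            params = cluster_params(), neighbors = NULL) {
  xy <- loc_xy(table)
  n <- nrow(xy)
  if (is.null(neighbors)) neighbors <- eps_neighbors(xy, params$eps)
  assignment <- integer(n)
  members <- vector("list", length(centres))
  if (length(centres) == 0)
    return(list(members = members, assignment = assignment))
  centre_order <- order(-densities[centres], centres)
  for (ci in centre_order) {
    c0 <- centres[ci]
    if (assignment[c0] != 0L) { members[[ci]] <- integer(0); next }
    assignment[c0] <- ci
    mem <- c0
    # frontier of core points to expand, highest density first
    frontier <- c0
    while (length(frontier)) {
      pick <- which.max(densities[frontier])
      i <- frontier[pick]
      frontier <- frontier[-pick]
      di <- densities[i]
      for (j in neighbors[[i]]) {
        if (assignment[j] != 0L) next
        if (densities[j] >= di) next      # density must fall along the path
        assignment[j] <- ci
        mem <- c(mem, j)
        if (densities[j] > params$k) frontier <- c(frontier, j)
      }
    }
    members[[ci]] <- sort(mem)
  }
  list(members = members, assignment = assignment)
}

#' Minimum-area enclosing ellipse of a point set
#'
#' The "tightly fitted" cluster ellipse: the unique minimum-area (Loewner-
#' John) ellipse containing every member, computed with Khachiyan's algorithm.
#'
#' @param xy two-column coordinate matrix (or anything [loc_table()]-like).
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter iteration cap.
#' @return list with `centre`, `radii` (long, short, nm), `orientation`
#'   (radians of the long axis), `shape` (short/long), `area` (pi*a*b, nm^2)
#'   and `degenerate` (TRUE when fewer than 3 points or collinear; no ellipse
#'   fields in that case).
#' @export
fit_ellipse <- function(xy, tol = 1e-6, max_iter = 2000) {
  xy <- loc_xy(xy)
  xy <- unique(xy)
  n <- nrow(xy)
  degen <- function() list(degenerate = TRUE, n = n)
  if (n < 3) return(degen())
  if (abs(stats::cor(xy[, 1], xy[, 2])) > 1 - 1e-12 ||
      stats::sd(xy[, 1]) == 0 || stats::sd(xy[, 2]) == 0) {
    # collinearity check via rank of centred coordinates
    s <- svd(scale(xy, scale = FALSE))$d
    if (s[2] < 1e-9 * max(s[1], 1)) return(degen())
  }
  Q <- t(cbind(xy, 1))              # 3 x n lifted points
  Qt <- t(Q)
  u <- rep(1 / n, n)
  inv3 <- function(X) {             # analytic 3x3 inverse
    d <- X[1, 1] * (X[2, 2] * X[3, 3] - X[2, 3] * X[3, 2]) -
         X[1, 2] * (X[2, 1] * X[3, 3] - X[2, 3] * X[3, 1]) +
         X[1, 3] * (X[2, 1] * X[3, 2] - X[2, 2] * X[3, 1])
    if (!is.finite(d) || abs(d) < 1e-300) return(NULL)
    adj <- matrix(c(
      X[2, 2] * X[3, 3] - X[2, 3] * X[3, 2],
      X[1, 3] * X[3, 2] - X[1, 2] * X[3, 3],
      X[1, 2] * X[2, 3] - X[1, 3] * X[2, 2],
      X[2, 3] * X[3, 1] - X[2, 1] * X[3, 3],
      X[1, 1] * X[3, 3] - X[1, 3] * X[3, 1],
      X[1, 3] * X[2, 1] - X[1, 1] * X[2, 3],
      X[2, 1] * X[3, 2] - X[2, 2] * X[3, 1],
      X[1, 2] * X[3, 1] - X[1, 1] * X[3, 2],
      X[1, 1] * X[2, 2] - X[1, 2] * X[2, 1]), 3, 3)
    adj / d
  }
  for (it in seq_len(max_iter)) {
    X <- crossprod(Qt, u * Qt)      # 3 x 3
    Xi <- inv3(X)
    if (is.null(Xi)) return(degen())
    m <- colSums(Q * (Xi %*% Q))    # Mahalanobis distances
    j <- which.max(m)
    step <- (m[j] - 3) / (3 * (m[j] - 1))
    if (m[j] - 3 < tol * 3) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c0 <- colSums(xy * u)
  P <- t(xy)
  A <- solve(P %*% (u * t(P)) - tcrossprod(c0)) / 2
  # inflate minutely so every member is inside (containment is exact)
  dc <- t(xy) - c0
  dd <- colSums(dc * (A %*% dc))
  if (max(dd) > 1) A <- A / max(dd)
  e <- eigen(A, symmetric = TRUE)
  radii <- 1 / sqrt(e$values)       # descending eigenvalues -> ascending radii
  long <- radii[2]; short <- radii[1]
  v <- e$vectors[, 2]               # eigenvector of the smaller eigenvalue
  if (short > long) { tmp <- long; long <- short; short <- tmp; v <- e$vectors[, 1] }
  list(centre = c0, radii = c(long = long, short = short),
       orientation = atan2(v[2], v[1]) %% pi,
       shape = short / long, area = pi * long * short,
       degenerate = FALSE, n = n)
}

#' Group clusters into CAZ-units
#'
#' Clusters seed a CAZ-unit when at least `unit_min_clusters` cluster centres
#' (including their own) lie within a circle of radius `unit_radius`.
#' Connected components of seeded clusters (linked at centre distance <=
#' `unit_radius`) form the units; sub-threshold clusters adjacent to a seeded
#' cluster are attached when `include_subthreshold` is set. Unclustered
#' localizations are attached to a unit when they fall inside its footprint:
#' the segmentation region containing the unit's clusters when `regions` is
#' supplied, otherwise within `unit_radius` of any member-cluster centre.
#'
#' @param clusters result of [expand_clusters()] (or a `caz_clustering`).
#' @param centres centre indices matching `clusters$members`.
#' @param table the localization table the clusters refer to.
#' @param params a [cluster_params()].
#' @param regions optional output of [segment_caz()] used as unit footprints.
#' @return list of `caz_unit` objects: `clusters` (indices into the cluster
#'   list), `centre_of_mass`, `n_localizations`, `unclustered` (localization
#'   indices inside the footprint that belong to no cluster).
#' @export
group_caz_units <- function(clusters, centres, table,
                            params = cluster_params(), regions = NULL) {
  xy <- loc_xy(table)
  keep <- which(lengths(clusters$members) >= params$min_cluster_size)
  if (length(keep) == 0) return(list())
  cc <- xy[centres[keep], , drop = FALSE]
  m <- length(keep)
  d2 <- as.matrix(stats::dist(cc))^2
  r2 <- params$unit_radius^2
  adj <- d2 <= r2
  seeded <- rowSums(adj) >= params$unit_min_clusters   # diagonal counts self
  if (!any(seeded)) return(list())
  # connected components over seeded clusters
  comp <- integer(m)
  cid <- 0L
  for (s in which(seeded)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & seeded & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  # attach sub-threshold neighbours of each component
  units <- vector("list", cid)
  assignment <- clusters$assignment
  for (u in seq_len(cid)) {
    mem <- which(comp == u)
    if (params$include_subthreshold) {
      extra <- which(!seeded & comp == 0L &
                       apply(adj[, mem, drop = FALSE], 1, any))
      comp[extra] <- u        # a cluster joins at most one unit
      mem <- sort(c(mem, extra))
    }
    cl_ids <- keep[mem]
    loc_idx <- sort(unlist(clusters$members[cl_ids], use.names = FALSE))
    # footprint for unclustered attachment
    if (!is.null(regions) && length(regions)) {
      lab <- attr(regions, "label_matrix")
      bin <- attr(regions, "bin_size")
      cpx <- pmin(floor(xy[centres[cl_ids], 1] / bin) + 1L, ncol(lab))
      cpy <- pmin(floor(xy[centres[cl_ids], 2] / bin) + 1L, nrow(lab))
      labs <- unique(lab[cbind(cpy, cpx)])
      labs <- labs[labs > 0]
      px <- pmin(floor(xy[, 1] / bin) + 1L, ncol(lab))
      py <- pmin(floor(xy[, 2] / bin) + 1L, nrow(lab))
      inside <- lab[cbind(py, px)] %in% labs
    } else {
      inside <- rep(FALSE, nrow(xy))
      for (ci in cl_ids) {
        dd <- (xy[, 1] - xy[centres[ci], 1])^2 + (xy[, 2] - xy[centres[ci], 2])^2
        inside <- inside | dd <= r2
      }
    }
    unc <- which(inside & assignment == 0L)
    all_idx <- c(loc_idx, unc)
    com <- colMeans(xy[all_idx, , drop = FALSE])
    units[[u]] <- structure(
      list(clusters = cl_ids, centre_of_mass = com,
           n_localizations = length(all_idx),
           member_localizations = loc_idx, unclustered = unc),
      class = "caz_unit")
  }
  units
}

#' Density-gradient clustering of a localization table
#'
#' Convenience wrapper running [local_density()], [find_centres()],
#' [expand_clusters()], [fit_ellipse()] per cluster and [group_caz_units()].
#'
#' @param table a [loc_table()].
#' @param params a [cluster_params()].
#' @param regions optional [segment_caz()] regions used as unit footprints.
#' @return a `caz_clustering` object.
#' @export
cluster_localizations <- function(table, params = cluster_params(),
                                  regions = NULL) {
  xy <- loc_xy(table)
  nb <- eps_neighbors(xy, params$eps)
  dens <- local_density(xy, params$eps, params$count_self, neighbors = nb)
  centres <- find_centres(xy, dens, params, neighbors = nb)
  cl <- expand_clusters(xy, dens, centres, params, neighbors = nb)
  sizes <- lengths(cl$members)
  ok <- sizes >= params$min_cluster_size
  ellipses <- lapply(seq_along(cl$members), function(i) {
    if (!ok[i]) return(list(degenerate = TRUE, n = sizes[i]))
    fit_ellipse(xy[cl$members[[i]], , drop = FALSE])
  })
  units <- group_caz_units(cl, centres, xy, params, regions)
  structure(list(table = table, params = params, densities = dens,
                 centres = centres, members = cl$members,
                 assignment = cl$assignment, ellipses = ellipses,
                 units = units),
            class = "caz_clustering")
}

#' @export
print.caz_clustering <- function(x, ...) {
  nc <- sum(lengths(x$members) >= x$params$min_cluster_size)
  cat(sprintf("Density-gradient clustering: %d localizations, %d clusters, %d CAZ-units\n",
              length(x$assignment), nc, length(x$units)))
  cat(sprintf("  eps = %g nm, k = %d, unit rule: >= %d centres in %g nm\n",
              x$params$eps, x$params$k, x$params$unit_min_clusters,
              x$params$unit_radius))
  invisible(x)
}

#' @export
summary.caz_clustering <- function(object, ...) cluster_summary(object)

#' @export
plot.caz_clustering <- function(x, ...) {
  xy <- loc_xy(x$table)
  cols <- ifelse(x$assignment == 0L, "grey70",
                 grDevices::hcl.colors(max(x$assignment), "dynamic")[x$assignment])
  plot(xy[, 1], -xy[, 2], col = cols, pch = 16, cex = 0.4, asp = 1,
       xlab = "x (nm)", ylab = "y (nm)", ...)
  graphics::points(xy[x$centres, 1], -xy[x$centres, 2], pch = 3, col = "black")
  invisible(x)
}

#' Per-unit and per-cluster summary statistics
#'
#' @param clustering a `caz_clustering` (or a list of them, pooled).
#' @return list with `per_unit` data frame (clusters per unit, localizations,
#'   unclustered fraction), `per_cluster` data frame (localizations, long and
#'   short radius, shape, area), and overall means with standard errors.
#'   The mean cluster area is the mean over clusters of pi*a*b, not the
#'   product of mean radii.
#' @export
cluster_summary <- function(clustering) {
  cls <- if (inherits(clustering, "caz_clustering")) list(clustering) else clustering
  pu <- list(); pc <- list()
  for (x in cls) {
    min_sz <- x$params$min_cluster_size
    for (u in x$units) {
      n_in_cl <- length(u$member_localizations)
      pu[[length(pu) + 1L]] <- data.frame(
        n_clusters = length(u$clusters),
        n_localizations = u$n_localizations,
        unclustered_fraction = length(u$unclustered) / max(1L, u$n_localizations))
    }
    for (i in seq_along(x$members)) {
      e <- x$ellipses[[i]]
      if (isTRUE(e$degenerate)) next
      pc[[length(pc) + 1L]] <- data.frame(
        n_localizations = length(x$members[[i]]),
        long_radius = unname(e$radii[1]), short_radius = unname(e$radii[2]),
        shape = e$shape, area = e$area)
    }
  }
  per_unit <- if (length(pu)) do.call(rbind, pu) else
    data.frame(n_clusters = integer(), n_localizations = integer(),
               unclustered_fraction = numeric())
  per_cluster <- if (length(pc)) do.call(rbind, pc) else
    data.frame(n_localizations = integer(), long_radius = numeric(),
               short_radius = numeric(), shape = numeric(), area = numeric())
  mn_sem <- function(v) c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  stats_out <- list()
  if (nrow(per_unit)) {
    stats_out$clusters_per_unit <- mn_sem(per_unit$n_clusters)
    stats_out$unclustered_fraction <- mn_sem(per_unit$unclustered_fraction)
  }
  if (nrow(per_cluster)) {
    stats_out$locs_per_cluster <- mn_sem(per_cluster$n_localizations)
    stats_out$long_radius <- mn_sem(per_cluster$long_radius)
    stats_out$short_radius <- mn_sem(per_cluster$short_radius)
    stats_out$area <- mn_sem(per_cluster$area)
  }
  structure(list(per_unit = per_unit, per_cluster = per_cluster,
                 stats = stats_out),
            class = "caz_cluster_summary")
}

#' @export
print.caz_cluster_summary <- function(x, ...) {
  cat(sprintf("Cluster summary: %d units, %d clusters\n",
              nrow(x$per_unit), nrow(x$per_cluster)))
  for (nm in names(x$stats))
    cat(sprintf("  %-22s %.3g +/- %.2g (s.e.m.)\n", nm,
                x$stats[[nm]]["mean"], x$stats[[nm]]["sem"]))
  invisible(x)
}

#' Radial density profile
#'
#' Pixel intensities are summed into annular bins around the intensity-
#' weighted centre of mass and each bin is normalized by the annulus area,
#' yielding a density per nm^2 as a function of radius.
#'
#' @param image a `rendered_image` (or a plain matrix with `bin_size` given).
#' @param bin_width annulus width in nm (default 10).
#' @param bin_size nm per pixel when `image` is a plain matrix.
#' @param max_radius outermost radius (nm); defaults to the largest pixel
#'   distance present.
#' @return data frame with `radius` (bin centre, nm) and `density`
#'   (intensity per nm^2).
#' @export
radial_profile <- function(image, bin_width = 10, bin_size = NULL,
                           max_radius = NULL) {
  if (inherits(image, "rendered_image")) {
    m <- image$counts; b <- image$bin_size
  } else {
    m <- image
    if (is.null(bin_size)) stop("bin_size required for a plain matrix")
    b <- bin_size
  }
  tot <- sum(m)
  if (tot <= 0) stop("empty region: centre of mass undefined")
  ny <- nrow(m); nx <- ncol(m)
  xs <- (seq_len(nx) - 0.5) * b
  ys <- (seq_len(ny) - 0.5) * b
  wx <- colSums(m); wy <- rowSums(m)
  cx <- sum(xs * wx) / tot; cy <- sum(ys * wy) / tot
  dx <- matrix(xs, ny, nx, byrow = TRUE) - cx
  dy <- matrix(ys, ny, nx) - cy
  r <- sqrt(dx^2 + dy^2)
  if (is.null(max_radius)) max_radius <- max(r)
  bins <- floor(r / bin_width)
  nb <- as.integer(floor(max_radius / bin_width)) + 1L
  sums <- vapply(seq_len(nb) - 1L, function(i) sum(m[bins == i]), numeric(1))
  edges <- (seq_len(nb + 1L) - 1L) * bin_width
  areas <- pi * diff(edges^2)
  data.frame(radius = edges[-length(edges)] + bin_width / 2,
             density = sums / areas)
}

#' Average radial profiles across units
#'
#' @param profiles list of data frames from [radial_profile()].
#' @return data frame with `radius`, `mean` and `sem` of the per-unit
#'   normalized densities (profiles are aligned on their radius bins; shorter
#'   profiles contribute zeros beyond their extent).
#' @export
aggregate_radial_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  nb <- max(vapply(profiles, nrow, integer(1)))
  bw <- profiles[[1]]$radius[2] - profiles[[1]]$radius[1]
  if (nrow(profiles[[1]]) == 1) bw <- 2 * profiles[[1]]$radius[1]
  m <- vapply(profiles, function(p) {
    v <- numeric(nb); v[seq_len(nrow(p))] <- p$density; v
  }, numeric(nb))
  m <- matrix(m, nrow = nb)
  data.frame(radius = (seq_len(nb) - 0.5) * bw,
             mean = rowMeans(m),
             sem = apply(m, 1, stats::sd) / sqrt(ncol(m)))
}
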