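#' Segment CAZ regions from a rendered localization image
#'
#' A mask is built by Gaussian-blurring the rendered counts (1 px s.d. by
#' default) and applying a minimal intensity threshold (0.15 counts);
#' 8-connected components with at least `min_area_px` pixels are kept as CAZ
#' regions. Localization counts per region are taken from the unblurred
#' table: a localization belongs to a region when its pixel does.
#'
#' @param image a `rendered_image` from [render()] (unblurred counts).
#' @param table the [loc_table()] the image was rendered from.
#' @param blur_sigma mask blur s.d. in pixels (default 1).
#' @param threshold minimal blurred intensity, in counts (default 0.15).
#' @param min_area_px minimum component area in pixels (default 300).
#' @param spot_min_px minimum area for a sub-threshold component to count as
#'   an isolated single spot (default 10 px; smaller specks are stray single
#'   localizations or chance coincidences, not antibody-sized spots).
#' @param spot_isolation_nm sub-threshold components closer than this to a
#'   kept region's centroid are satellite fragments of that synapse, not
#'   isolated background spots (default 400 nm).
#' @return list of `caz_region` objects (fields `pixels` — linear indices into
#'   the image matrix —, `area_um2`, `localization_count`, `centroid_nm`,
#'   `loc_idx`), with attributes `label_matrix`, `bin_size`, `small_spots`
#'   (number of sub-threshold antibody-sized components) and `field`.
#' @export
segment_caz <- function(image, table, blur_sigma = 1, threshold = 0.15,
                        min_area_px = 300, spot_min_px = 10,
                        spot_isolation_nm = 400) {
  stopifnot(inherits(image, "rendered_image"))
  f <- field_extent(table)
  if (any(abs(f - image$field) > image$bin_size))
    stop("image and table extents do not match")
  b <- image$bin_size
  blurred <- if (blur_sigma > 0) gaussian_blur(image$counts, blur_sigma) else
    image$counts
  mask <- blurred >= threshold
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= min_area_px)
  small_ids <- which(sizes >= spot_min_px & sizes < min_area_px)
  ny <- nrow(lab); nx <- ncol(lab)
  # per-localization pixel label
  px <- pmin(floor(table$x / b), nx - 1L) + 1L
  py <- pmin(floor(table$y / b), ny - 1L) + 1L
  loc_lab <- lab[cbind(py, px)]
  out <- vector("list", length(keep_ids))
  new_lab <- matrix(0L, ny, nx) # kept labels remapped to 1..K
  for (i in seq_along(keep_ids)) {
    id <- keep_ids[i]
    pix <- which(lab == id)
    new_lab[pix] <- i
    rows <- (pix - 1L) %% ny + 1L
    cols <- (pix - 1L) %/% ny + 1L
    loc_idx <- which(loc_lab == id)
    out[[i]] <- structure(
      list(pixels = pix,
           area_um2 = length(pix) * b^2 / 1e6,
           localization_count = length(loc_idx),
           centroid_nm = c(x = (mean(cols) - 0.5) * b,
                           y = (mean(rows) - 0.5) * b),
           loc_idx = loc_idx),
      class = "caz_region")
  }
  # spots are "isolated" only when away from every kept region
  small_spots <- 0L
  if (length(small_ids)) {
    keep_cent <- if (length(out))
      do.call(rbind, lapply(out, function(r) r$centroid_nm)) else NULL
    for (id in small_ids) {
      pix <- which(lab == id)
      rows <- (pix - 1L) %% ny + 1L
      cols <- (pix - 1L) %/% ny + 1L
      cx <- (mean(cols) - 0.5) * b; cy <- (mean(rows) - 0.5) * b
      iso <- is.null(keep_cent) ||
        all((keep_cent[, 1] - cx)^2 + (keep_cent[, 2] - cy)^2 >
              spot_isolation_nm^2)
      if (iso) small_spots <- small_spots + 1L
    }
  }
  structure(out, label_matrix = new_lab, bin_size = b,
            small_spots = small_spots, field = f,
            class = "caz_regions")
}

#' @export
print.caz_regions <- function(x, ...) {
  cat(sprintf("%d CAZ region(s); %d sub-threshold spot(s)\n",
              length(x), attr(x, "small_spots")))
  for (i in seq_along(x))
    cat(sprintf("  region %d: %.4f um^2, %d localizations\n", i,
                x[[i]]$area_um2, x[[i]]$localization_count))
  invisible(x)
}

#' Background localization and spot density outside CAZ regions
#'
#' @param table a [loc_table()].
#' @param regions output of [segment_caz()].
#' @return list with `loc_density` (localizations per um^2 outside all region
#'   footprints), `spot_density` (sub-threshold connected components per
#'   um^2 of outside area), `outside_area_um2` and `n_outside`.
#' @export
background_density <- function(table, regions) {
  f <- attr(regions, "field")
  b <- attr(regions, "bin_size")
  total_um2 <- f[1] * f[2] / 1e6
  region_um2 <- sum(vapply(regions, function(r) r$area_um2, numeric(1)))
  outside <- total_um2 - region_um2
  if (outside <= 0) stop("no area outside regions: background undefined")
  in_region <- unique(unlist(lapply(regions, function(r) r$loc_idx)))
  n_out <- nrow(table) - length(in_region)
  list(loc_density = n_out / outside,
       spot_density = attr(regions, "small_spots") / outside,
       outside_area_um2 = outside, n_outside = n_out)
}

#' Background quality control
#'
#' Images with more than `max_spot_density` isolated single spots per um^2
#' are excluded from comparative analysis.
#'
#' @param spot_density spots per um^2 (from [background_density()]).
#' @param max_spot_density exclusion threshold (default 2.3).
#' @return `TRUE` (pass) or `FALSE` (fail/exclude).
#' @export
qc_background <- function(spot_density, max_spot_density = 2.3) {
  spot_density <= max_spot_density
}

#' Select isolated single-antibody spots for precision estimation
#'
#' Connected components of the blurred/thresholded image with an area between
#' `size_range` pixels and an ellipticity (second-moment minor/major axis
#' ratio, intensity weighted) of at least `min_ellipticity` are selected; the
#' localizations falling inside each are returned.
#'
#' @param image a `rendered_image` (unblurred counts, 10 nm bins).
#' @param table the matching [loc_table()].
#' @param blur_sigma mask blur s.d. in pixels (default 1).
#' @param threshold minimal blurred intensity (default 0.08 counts).
#' @param size_range allowed component area in pixels (default 16 to 100).
#' @param min_ellipticity minimum axis ratio (default 0.95).
#' @param dilate_px localizations within this Chebyshev pixel distance of an
#'   accepted component are included in its group (default 3): the blurred
#'   mask understates the emitter's support, and clipping the distribution
#'   tails would bias the precision estimate downward.
#' @return list of integer vectors of localization indices, one per accepted
#'   spot.
#' @export
select_precision_spots <- function(image, table, blur_sigma = 1,
                                   threshold = 0.08,
                                   size_range = c(16, 100),
                                   min_ellipticity = 0.95, dilate_px = 3) {
  b <- image$bin_size
  blurred <- if (blur_sigma > 0) gaussian_blur(image$counts, blur_sigma) else
    image$counts
  mask <- blurred >= threshold
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0])
  cand <- which(sizes >= size_range[1] & sizes <= size_range[2])
  ny <- nrow(lab); nx <- ncol(lab)
  px <- pmin(floor(table$x / b), nx - 1L) + 1L
  py <- pmin(floor(table$y / b), ny - 1L) + 1L
  loc_lab <- lab[cbind(py, px)]
  out <- list()
  for (id in cand) {
    pix <- which(lab == id)
    rows <- (pix - 1L) %% ny + 1L
    cols <- (pix - 1L) %/% ny + 1L
    w <- blurred[pix]
    mx <- sum(cols * w) / sum(w); my <- sum(rows * w) / sum(w)
    cxx <- sum(w * (cols - mx)^2) / sum(w)
    cyy <- sum(w * (rows - my)^2) / sum(w)
    cxy <- sum(w * (cols - mx) * (rows - my)) / sum(w)
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE,
                only.values = TRUE)$values
    if (ev[1] <= 0) next
    ratio <- sqrt(max(ev[2], 0) / ev[1])
    if (ratio < min_ellipticity) next
    if (dilate_px > 0) {
      # dilate the component footprint by Chebyshev distance dilate_px
      offs <- expand.grid(dy = (-dilate_px):dilate_px,
                          dx = (-dilate_px):dilate_px)
      drow <- pmin(pmax(rep(rows, nrow(offs)) +
                          rep(offs$dy, each = length(rows)), 1L), ny)
      dcol <- pmin(pmax(rep(cols, nrow(offs)) +
                          rep(offs$dx, each = length(cols)), 1L), nx)
      dpix <- unique((dcol - 1L) * ny + drow)
      loc_pix <- (px - 1L) * ny + py
      idx <- which(loc_pix %in% dpix)
    } else {
      idx <- which(loc_lab == id)
    }
    if (length(idx)) out[[length(out) + 1L]] <- idx
  }
  out
}

#' Localization precision from pooled isolated-emitter histograms
#'
#' Each spot's localizations are aligned to their centre of mass (deviations
#' rescaled by sqrt(k/(k-1)) to undo the centre-of-mass shrinkage of a
#' k-localization group), pooled into a 2D histogram (4 nm bins by default)
#' and fitted with a bin-integrated 2D Gaussian by nonlinear least squares.
#' The reported precision is the mean of the two axis standard deviations.
#'
#' @param groups list of localization index vectors (from
#'   [select_precision_spots()]) or a list of two-column coordinate matrices.
#' @param table the [loc_table()] the indices refer to (omit when `groups`
#'   holds coordinates).
#' @param bin histogram bin width in nm (default 4).
#' @param min_groups minimum number of spots required (default 10).
#' @return a `precision_estimate`: `sigma_x`, `sigma_y`, `sigma`,
#'   `n_localizations`, `n_groups`, `adj_r2`, `degenerate`.
#' @export
estimate_precision <- function(groups, table = NULL, bin = 4,
                               min_groups = 10) {
  if (length(groups) < min_groups)
    stop(sprintf("need at least %d spot groups, got %d", min_groups,
                 length(groups)))
  devs <- lapply(groups, function(g) {
    xy <- if (is.matrix(g)) g else loc_xy(table)[g, , drop = FALSE]
    k <- nrow(xy)
    if (k < 2) return(NULL)
    sweep(xy, 2, colMeans(xy)) * sqrt(k / (k - 1))
  })
  devs <- do.call(rbind, devs[!vapply(devs, is.null, logical(1))])
  n <- nrow(devs)
  if (max(abs(devs)) < .Machine$double.eps^0.5)
    return(structure(list(sigma_x = bin / 2, sigma_y = bin / 2,
                          sigma = bin / 2, n_localizations = n,
                          n_groups = length(groups), adj_r2 = NA_real_,
                          degenerate = TRUE),
                     class = "precision_estimate"))
  lim <- max(5 * stats::sd(devs[, 1]), 5 * stats::sd(devs[, 2]), 4 * bin)
  edges <- seq(-lim, lim, by = bin)
  nb <- length(edges) - 1L
  hx <- cut(devs[, 1], edges, labels = FALSE)
  hy <- cut(devs[, 2], edges, labels = FALSE)
  ok <- !is.na(hx) & !is.na(hy)
  H <- matrix(0, nb, nb)
  tt <- table(hx[ok] + (hy[ok] - 1L) * nb)
  H[as.integer(names(tt))] <- as.integer(tt)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  grid <- expand.grid(x = seq_len(nb), y = seq_len(nb))
  df <- data.frame(z = as.vector(H), x = ctr[grid$x], y = ctr[grid$y])
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  # bin-integrated Gaussian model: amplitude * P(bin_x) * P(bin_y)
  fit <- minpack.lm::nlsLM(
    z ~ A * (stats::pnorm(hi[match(x, ctr)], mx, sx) -
               stats::pnorm(lo[match(x, ctr)], mx, sx)) *
      (stats::pnorm(hi[match(y, ctr)], my, sy) -
         stats::pnorm(lo[match(y, ctr)], my, sy)),
    data = df,
    start = list(A = n, mx = 0, my = 0,
                 sx = stats::sd(devs[, 1]), sy = stats::sd(devs[, 2])),
    lower = c(1e-6, -lim, -lim, bin / 10, bin / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  res <- df$z - stats::fitted(fit)
  r2 <- 1 - sum(res^2) / sum((df$z - mean(df$z))^2)
  adj <- 1 - (1 - r2) * (nrow(df) - 1) / (nrow(df) - length(cf) - 1)
  sx <- abs(cf["sx"]); sy <- abs(cf["sy"])
  structure(list(sigma_x = unname(sx), sigma_y = unname(sy),
                 sigma = unname((sx + sy) / 2), n_localizations = n,
                 n_groups = length(groups), adj_r2 = adj,
                 degenerate = unname((sx + sy) / 2) < bin / 2),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf(
    "Localization precision: %.2f nm (sigma_x %.2f, sigma_y %.2f), %d localizations in %d spots%s\n",
    x$sigma, x$sigma_x, x$sigma_y, x$n_localizations, x$n_groups,
    if (isTRUE(x$degenerate)) " [DEGENERATE: below histogram resolution]" else ""))
  if (!is.na(x$adj_r2)) cat(sprintf("  adjusted R^2 = %.4f\n", x$adj_r2))
  invisible(x)
}

#' Localization precision by nearest-neighbour analysis (NeNA)
#'
#' Distances between each localization and its nearest neighbour in the
#' following camera frame are histogrammed; repeated localizations of the
#' same fluorophore produce a short-range correlation peak whose density is
#' the Rayleigh-type form d/(2 sigma^2) exp(-d^2 / (4 sigma^2)) (the distance
#' between two positions that each carry precision sigma). The histogram is
#' fitted with this peak plus a linear term for uncorrelated neighbours; the
#' correlation sigma is returned.
#'
#' @param table a [loc_table()] with frame indices.
#' @param max_distance histogram range in nm (default 100).
#' @param bin histogram bin width in nm (default 2).
#' @param min_pairs minimum number of frame-adjacent pairs (default 100).
#' @return list with `sigma` (nm, `NA` when no correlation peak is
#'   detectable), `n_pairs`, `fraction_correlated` and `flag`.
#' @export
estimate_precision_nena <- function(table, max_distance = 100, bin = 2,
                                    min_pairs = 100) {
  if (all(is.na(table$frame))) stop("table has no frame indices")
  ord <- order(table$frame)
  fr <- table$frame[ord]
  xy <- loc_xy(table)[ord, , drop = FALSE]
  frames <- sort(unique(fr))
  idx_by_frame <- split(seq_along(fr), fr)
  dists <- numeric(0)
  for (i in seq_len(length(frames) - 1L)) {
    if (frames[i + 1L] != frames[i] + 1L) next
    a <- idx_by_frame[[as.character(frames[i])]]
    b <- idx_by_frame[[as.character(frames[i + 1L])]]
    if (!length(a) || !length(b)) next
    for (p in a) {
      d2 <- (xy[b, 1] - xy[p, 1])^2 + (xy[b, 2] - xy[p, 2])^2
      dists <- c(dists, sqrt(min(d2)))
    }
  }
  dists <- dists[dists <= max_distance]
  if (length(dists) < min_pairs)
    stop(sprintf("too few short-range frame-adjacent pairs (%d < %d)",
                 length(dists), min_pairs))
  edges <- seq(0, max_distance, by = bin)
  h <- graphics::hist(dists, breaks = edges, plot = FALSE)
  df <- data.frame(d = h$mids, y = h$density)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ w * (d / (2 * s^2)) * exp(-d^2 / (4 * s^2)) + b0 * d,
    data = df,
    start = list(w = 0.8, s = max(2 * bin, stats::median(dists) / 1.5),
                 b0 = 1e-4),
    lower = c(0, bin / 10, 0),
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(sigma = NA_real_, n_pairs = length(dists),
                fraction_correlated = 0, flag = "fit_failed"))
  cf <- stats::coef(fit)
  if (cf["w"] < 0.05)
    return(list(sigma = NA_real_, n_pairs = length(dists),
                fraction_correlated = unname(cf["w"]),
                flag = "no_correlation_peak"))
  list(sigma = unname(abs(cf["s"])), n_pairs = length(dists),
       fraction_correlated = unname(cf["w"]), flag = "ok")
}

#' Count spots in a confocal-style intensity image
#'
#' After constant background subtraction and Gaussian blur, a mask is taken
#' at `threshold`; local maxima inside the mask are counted, where maxima
#' closer in intensity than `prominence` to a higher maximum (reachable
#' without descending more than `prominence` below the lower peak) are merged
#' into that maximum, in the spirit of the ImageJ Find Maxima noise
#' tolerance.
#'
#' @param image a `rendered_image` or plain matrix.
#' @param blur_sigma Gaussian blur s.d. in pixels (default 0.9).
#' @param threshold mask threshold on the blurred image.
#' @param prominence minimum drop separating two maxima.
#' @param background constant offset subtracted first (default 0).
#' @return integer spot count.
#' @export
count_spots <- function(image, blur_sigma = 0.9, threshold, prominence,
                        background = 0) {
  m <- if (inherits(image, "rendered_image")) image$counts else image
  m <- pmax(m - background, 0)
  if (blur_sigma > 0) m <- gaussian_blur(m, blur_sigma)
  mask <- m >= threshold
  if (!any(mask)) return(0L)
  ny <- nrow(m); nx <- ncol(m)
  # local maxima (8-neighbourhood, >= neighbours and > at least one, or
  # plateau representative)
  shift <- function(mat, dy, dx) {
    out <- matrix(-Inf, ny, nx)
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[oky, okx] <- mat[ys[oky], xs[okx]]
    out
  }
  is_max <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (m >= shift(m, dy, dx))
  }
  peaks <- which(is_max)
  if (!length(peaks)) return(0L)
  peaks <- peaks[order(-m[peaks], peaks)]
  claimed <- matrix(FALSE, ny, nx)
  count <- 0L
  for (p in peaks) {
    if (claimed[p]) next
    v <- m[p]
    # flood the region reachable from p without dropping below v - prominence
    lvl <- v - prominence
    seen <- new.env(hash = TRUE)
    queue <- p
    assign(as.character(p), TRUE, envir = seen)
    absorbed <- FALSE
    cells <- p
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (claimed[q]) { absorbed <- TRUE; break }
      r <- (q - 1L) %% ny + 1L; cc <- (q - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        rr <- r + dy; ccx <- cc + dx
        if (rr < 1 || rr > ny || ccx < 1 || ccx > nx) next
        q2 <- (ccx - 1L) * ny + rr
        if (m[q2] < lvl) next
        key <- as.character(q2)
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        queue <- c(queue, q2)
        cells <- c(cells, q2)
      }
    }
    claimed[cells] <- TRUE
    if (!absorbed) count <- count + 1L
  }
  count
}

# 8- or 4-connected component labeling by iterative minimum-label
# propagation; converges in O(component diameter) sweeps, all vectorized.
label_components <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  offs <- if (connectivity == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  repeat {
    new <- lab
    for (o in offs) {
      sh <- matrix(.Machine$integer.max, ny, nx)
      ys <- seq_len(ny) + o[1]; xs <- seq_len(nx) + o[2]
      oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
      src <- lab[ys[oky], xs[okx], drop = FALSE]
      src[src == 0L] <- .Machine$integer.max
      sh[oky, okx] <- src
      upd <- mask & sh < new & new > 0L
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels to 1..K
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}
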