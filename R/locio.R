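#' Localization tables
#'
#' A localization table is the universal currency of the pipeline: one row per
#' single-molecule localization with coordinates in nanometres from the
#' top-left corner of the imaged field, the camera frame index in which the
#' emission was detected, and the photon count of the fitted spot.
#'
#' @param x,y numeric, coordinates in nm (0-based, top-left origin).
#' @param frame integer frame indices (optional).
#' @param photons photon counts (optional).
#' @param field numeric length-2, field extent `c(width, height)` in nm.
#'   Defaults to the smallest extent containing all localizations.
#' @param ... further per-localization columns, carried along untouched.
#' @return A `loc_table`: a `data.frame` with columns `x`, `y`, `frame`,
#'   `photons` (plus any extras) and a `field` attribute.
#' @export
loc_table <- function(x, y, frame = NA_integer_, photons = NA_real_,
                      field = NULL, ...) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) == 0) {
    frame <- integer(0)
    photons <- numeric(0)
  }
  df <- data.frame(x = x, y = y, frame = frame, photons = photons, ...)
  if (is.null(field)) {
    field <- if (nrow(df) == 0) c(0, 0) else c(max(x, 0), max(y, 0))
  }
  field <- as.numeric(field)
  if (nrow(df) > 0) {
    if (any(df$x < 0 | df$y < 0 | df$x > field[1] | df$y > field[2]))
      stop("localizations outside the declared field extent")
    if (any(!is.na(df$photons) & df$photons < 0))
      stop("negative photon counts")
  }
  structure(df, field = field, class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  f <- attr(x, "field")
  cat(sprintf("Localization table: %d localizations, field %.0f x %.0f nm\n",
              nrow(x), f[1], f[2]))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Field extent of a localization table
#' @param table a [loc_table()].
#' @return numeric length-2: `c(width, height)` in nm.
#' @export
field_extent <- function(table) attr(table, "field")

# keep loc_table class + field through subsetting
#' @export
`[.loc_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "field") <- attr(x, "field")
    class(out) <- c("loc_table", "data.frame")
  }
  out
}

#' Read a localization table from delimited text
#'
#' The dialect is a single header line naming at least the x/y columns
#' (`x[nm]`, `y[nm]`; plain `x`/`y` are also accepted), tab-, comma- or
#' whitespace-delimited, optionally preceded by a `# field_nm: <w> <h>` comment
#' recording the field extent. Unknown columns are preserved verbatim.
#'
#' @param path file path.
#' @param field optional field extent override, `c(width, height)` nm.
#' @return a [loc_table()].
#' @export
read_localizations <- function(path, field = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("format error: empty localization file")
  skip <- 0L
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("field_nm:\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 3 && is.null(field)) field <- as.numeric(m[2:3])
    skip <- 1L
    lines <- lines[-1]
  }
  if (length(lines) == 0) stop("format error: no header line")
  header <- lines[1]
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = if (skip) "" else "#")
  nm <- names(df)
  find_col <- function(want) {
    hit <- which(tolower(nm) %in% paste0(want, c("", "[nm]", "_nm", " [nm]")))
    if (length(hit)) hit[1] else NA_integer_
  }
  ix <- find_col("x"); iy <- find_col("y")
  if (is.na(ix) || is.na(iy))
    stop("format error: header must name x and y columns (nm)")
  for (i in c(ix, iy)) {
    if (!is.numeric(df[[i]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[i]]))))[1]
      stop(sprintf("parse error: non-numeric value in column '%s', line %d",
                   nm[i], bad + 1L + skip))
    }
  }
  ifr <- find_col("frame"); iph <- find_col("photons")
  extras <- setdiff(seq_along(nm), c(ix, iy, ifr, iph))
  args <- list(x = df[[ix]], y = df[[iy]],
               frame = if (!is.na(ifr)) df[[ifr]] else NA_integer_,
               photons = if (!is.na(iph)) df[[iph]] else NA_real_,
               field = field)
  for (i in extras) args[[nm[i]]] <- df[[i]]
  do.call(loc_table, args)
}

#' Write a localization table as tab-delimited text
#'
#' Emits a `# field_nm:` comment, a header (`x[nm] y[nm] frame photons` plus
#' any extra columns) and one tab-separated row per localization; the round
#' trip through [read_localizations()] is lossless.
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @export
write_localizations <- function(table, path) {
  f <- field_extent(table)
  df <- as.data.frame(table)
  names(df)[names(df) == "x"] <- "x[nm]"
  names(df)[names(df) == "y"] <- "y[nm]"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_nm: %.10g %.10g", f[1], f[2]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter localizations by photon count
#'
#' Keeps localizations with strictly more than `min_photons` photons (the
#' quality filter applied to raw localization exports; spots at or below the
#' threshold are discarded).
#'
#' @param table a [loc_table()].
#' @param min_photons threshold; default 1000.
#' @return filtered `loc_table`.
#' @export
filter_photons <- function(table, min_photons = 1000) {
  stopifnot(min_photons >= 0)
  if (nrow(table) == 0) return(table)
  if (all(is.na(table$photons)))
    stop("localization table has no photon counts; cannot filter")
  table[!is.na(table$photons) & table$photons > min_photons, , drop = FALSE]
}

#' Render a localization table into a pixel image
#'
#' Localizations are binned into square pixels of `bin_size` nm using the
#' half-open convention: a coordinate v falls in pixel `floor(v / bin_size)`,
#' so a point exactly on a bin edge belongs to the higher pixel. Without blur
#' the pixel sum equals the number of binned localizations; with blur a
#' truncated (4 sigma) Gaussian kernel is applied after binning, conserving
#' total intensity up to edge truncation.
#'
#' @param table a [loc_table()].
#' @param bin_size nm per pixel; default 10.
#' @param blur_sigma optional Gaussian blur s.d. in pixels.
#' @return a `rendered_image`: list with `counts` matrix (rows = y), `bin_size`
#'   and `field`.
#' @export
render <- function(table, bin_size = 10, blur_sigma = NULL) {
  stopifnot(bin_size > 0)
  f <- field_extent(table)
  nx <- max(1L, as.integer(ceiling(f[1] / bin_size)))
  ny <- max(1L, as.integer(ceiling(f[2] / bin_size)))
  counts <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(table) > 0) {
    px <- pmin(floor(table$x / bin_size), nx - 1L)
    py <- pmin(floor(table$y / bin_size), ny - 1L)
    tab <- table(py * nx + px)
    idx <- as.integer(names(tab))
    counts[cbind(idx %/% nx + 1L, idx %% nx + 1L)] <- as.integer(tab)
  }
  if (!is.null(blur_sigma) && blur_sigma > 0)
    counts <- gaussian_blur(counts, blur_sigma)
  structure(list(counts = counts, bin_size = bin_size,
                 blur_sigma = blur_sigma, field = f),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("Rendered image: %d x %d px at %.3g nm/px, total intensity %.4g\n",
              ncol(x$counts), nrow(x$counts), x$bin_size, sum(x$counts)))
  invisible(x)
}

#' @export
plot.rendered_image <- function(x, ...) {
  graphics::image(t(x$counts)[, rev(seq_len(nrow(x$counts))), drop = FALSE],
                  useRaster = TRUE, asp = nrow(x$counts) / ncol(x$counts),
                  col = grDevices::hcl.colors(64, "inferno"), axes = FALSE, ...)
  invisible(x)
}

# Separable Gaussian convolution with zero padding; kernel truncated at
# 4 sigma and normalized, so interior mass is conserved and only intensity
# within 4 sigma of the border can leak out.
gaussian_blur <- function(mat, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) { # convolve columns of m with k, zero padded
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in -r:r) {
      src <- seq_len(n) + j
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j + r + 1L] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Write a rendered image as TIFF
#'
#' @param image a `rendered_image`.
#' @param path output path.
#' @param bits 16 or 32 (float).
#' @export
write_rendered_tiff <- function(image, path, bits = 32) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required to write TIFF output")
  m <- image$counts
  if (bits == 16) {
    tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 32L)
  }
  invisible(path)
}
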