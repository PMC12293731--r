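#' Per-slice aortic area signal
#'
#' An `area_signal` holds one patient's ordered sequence of segmented pixel
#' counts, one count per axial CT slice. Slice index 0 is the most cranial
#' (thoracic) slice; indices increase toward the iliac bifurcation, matching
#' the direction in which the upstream tracker follows the aorta. The pixel
#' count of a slice is a unit-less proxy for the aortic cross-sectional area
#' at that level.
#'
#' @param counts integer-like vector of non-negative per-slice pixel counts.
#' @param patient_id character scalar identifying the scan.
#' @return An object of class `area_signal`: a list with elements
#'   `patient_id`, `counts` (integer vector) and `n` (number of slices).
#' @examples
#' s <- area_signal(c(400, 410, 805, 798, 395), "demo")
#' s$n
#' @export
area_signal <- function(counts, patient_id = "patient") {
  if (length(counts) < 1L) {
    stop("an area signal needs at least one slice", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("pixel counts must be finite and non-negative", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  structure(
    list(patient_id = as.character(patient_id), counts = counts,
         n = length(counts)),
    class = "area_signal"
  )
}

#' @export
print.area_signal <- function(x, ...) {
  cat(sprintf("<area_signal> patient %s: %d slices, counts %d..%d\n",
              x$patient_id, x$n, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Aneurysm boundary interval
#'
#' Inclusive start/end slice indices (0-based) of an aneurysm along the axial
#' direction, as annotated by an expert or predicted by a detector.
#'
#' @param start,end integer slice indices with `0 <= start <= end`.
#' @return Object of class `boundary_interval` with fields `start` and `end`.
#' @examples
#' boundary_interval(50, 89)
#' @export
boundary_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start) {
    stop("need 0 <= start <= end", call. = FALSE)
  }
  structure(list(start = start, end = end), class = "boundary_interval")
}

#' @export
print.boundary_interval <- function(x, ...) {
  cat(sprintf("<boundary_interval> [%d, %d] (%d slices)\n",
              x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

# interval length in slices
#' @noRd
interval_length <- function(interval) interval$end - interval$start + 1L

#' @noRd
check_interval <- function(interval, n) {
  if (!inherits(interval, "boundary_interval")) {
    stop("`interval` must be a boundary_interval", call. = FALSE)
  }
  if (interval$end >= n) {
    stop(sprintf("interval [%d, %d] out of range for %d slices",
                 interval$start, interval$end, n), call. = FALSE)
  }
  invisible(interval)
}

#' Binary mask stack
#'
#' An ordered stack of same-sized 2D binary masks (0 = background, 1 =
#' segmented aorta), one per axial slice, ordered cranial to caudal.
#'
#' @param slices list of numeric/integer matrices sharing one dimension;
#'   any non-zero pixel is binarized to 1.
#' @param patient_id character scalar.
#' @return Object of class `mask_stack` with fields `patient_id` and `slices`.
#' @export
mask_stack <- function(slices, patient_id = "patient") {
  if (!is.list(slices) || length(slices) < 1L) {
    stop("`slices` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(slices, function(m) {
    if (!is.matrix(m)) stop("each slice must be a matrix", call. = FALSE)
    dim(m)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent slice dimensions in mask stack", call. = FALSE)
  }
  slices <- lapply(slices, function(m) {
    m2 <- matrix(0L, nrow(m), ncol(m))
    m2[m != 0] <- 1L
    m2
  })
  structure(list(patient_id = as.character(patient_id), slices = slices),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<mask_stack> patient %s: %d slices of %dx%d\n",
              x$patient_id, length(x$slices), d[1], d[2]))
  invisible(x)
}

#' Linear contrast stretching to 8-bit range
#'
#' Linearly rescales an image so that its observed minimum maps to `lo` and
#' its observed maximum to `hi` (defaults 10 and 245), rounding half-up to
#' the nearest integer. This is the normalization applied to grayscale CT
#' slices before any segmentation model sees them. A constant image maps
#' everywhere to `lo`.
#'
#' @param image numeric matrix with non-negative entries.
#' @param lo,hi integer output range, `0 <= lo < hi <= 255`.
#' @return Integer matrix with values in `[lo, hi]`.
#' @examples
#' m <- matrix(c(0, 500, 1000), 1)
#' contrast_stretch(m)  # 10 128 245
#' @export
contrast_stretch <- function(image, lo = 10L, hi = 245L) {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("`image` must be a non-empty matrix", call. = FALSE)
  }
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (!(hi > lo) || lo < 0L || hi > 255L) {
    stop("need 0 <= lo < hi <= 255", call. = FALSE)
  }
  rng <- range(image)
  out <- if (rng[1] == rng[2]) {
    matrix(as.numeric(lo), nrow(image), ncol(image))
  } else {
    lo + (image - rng[1]) * (hi - lo) / (rng[2] - rng[1])
  }
  # round half up (base round() is round-half-even)
  storage.mode(out) <- "double"
  m <- floor(out + 0.5)
  storage.mode(m) <- "integer"
  m
}

#' Load a mask stack from disk
#'
#' Reads either a multi-page TIFF (pages in file order) or a directory of
#' per-slice TIFF/PNG files (lexicographic filename order). Any non-zero
#' pixel is binarized to 1.
#'
#' @param path path to a multi-page TIFF file or a directory of per-slice
#'   `.tif`/`.tiff`/`.png` files.
#' @param patient_id identifier for the resulting stack; defaults to the
#'   file or directory base name.
#' @return A [mask_stack()].
#' @export
load_mask_stack <- function(path, patient_id = NULL) {
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      stop("no TIFF/PNG slices found in ", path, call. = FALSE)
    }
    files <- files[order(basename(files), method = "radix")]
    slices <- lapply(files, read_slice_image)
  } else if (file.exists(path)) {
    slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    slices <- lapply(slices, drop_channels)
  } else {
    stop("cannot read mask stack at ", path, call. = FALSE)
  }
  mask_stack(slices, patient_id = patient_id)
}

#' @noRd
read_slice_image <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file, as.is = TRUE)
  }
  drop_channels(img)
}

# collapse an H x W x C array to a matrix: any non-zero channel counts
#' @noRd
drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img != 0, c(1, 2), any) * 1
  if (!is.matrix(img)) img <- as.matrix(img)
  img
}

#' Write a mask stack as a multi-page TIFF
#'
#' @param stack a [mask_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mask_stack"))
  pages <- lapply(stack$slices, function(m) {
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Extract the per-slice area signal from a mask stack
#'
#' The area signal is simply the number of segmented (value 1) pixels in each
#' slice, in stack order.
#'
#' @param stack a [mask_stack()].
#' @return An [area_signal()] with one count per slice.
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1] <- 1L
#' st <- mask_stack(list(m, m * 0L), "demo")
#' extract_area_signal(st)$counts  # 2 0
#' @export
extract_area_signal <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  counts <- vapply(stack$slices, function(m) sum(m == 1L), integer(1))
  area_signal(counts, patient_id = stack$patient_id)
}

#' Read / write an area signal as a two-column CSV
#'
#' The on-disk format is a CSV with header `slice_index,pixel_count`, where
#' `slice_index` runs consecutively from 0. `read_signal_table()` and
#' `write_signal_table()` are exact inverses.
#'
#' @param path CSV file path.
#' @param patient_id identifier; defaults to the file base name.
#' @return `read_signal_table()` returns an [area_signal()];
#'   `write_signal_table()` returns `path` invisibly.
#' @export
read_signal_table <- function(path, patient_id = NULL) {
  if (is.null(patient_id)) patient_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(tab), c("slice_index", "pixel_count"))) {
    stop("expected header `slice_index,pixel_count` in ", path, call. = FALSE)
  }
  if (nrow(tab) == 0L || !identical(as.numeric(tab$slice_index),
                                    as.numeric(seq_len(nrow(tab)) - 1))) {
    stop("slice_index must run consecutively from 0 in ", path, call. = FALSE)
  }
  if (any(tab$pixel_count < 0)) {
    stop("negative pixel counts in ", path, call. = FALSE)
  }
  area_signal(tab$pixel_count, patient_id = patient_id)
}

#' @rdname read_signal_table
#' @param signal an [area_signal()] to write.
#' @export
write_signal_table <- function(signal, path) {
  stopifnot(inherits(signal, "area_signal"))
  tab <- data.frame(slice_index = seq_len(signal$n) - 1L,
                    pixel_count = signal$counts)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
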