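# Rectangle-mask densitometry of PCR bands on gel images, and the
# two-group band-intensity comparison.  Rectangle coordinates are 0-based
# and half-open: a rectangle (row_start, col_start, height, width) covers
# image rows row_start .. row_start + height - 1 (0-based) and likewise for
# columns.

.check_rects <- function(rects) {
  req <- c("lane_label", "row_start", "col_start", "height", "width")
  miss <- setdiff(req, names(rects))
  if (length(miss))
    stop("rectangle table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(rects$height)) > 1 || length(unique(rects$width)) > 1)
    stop("equal-size violation: all rectangles in one comparison must share ",
         "the same height x width", call. = FALSE)
  rects
}

#' Mean band intensity inside rectangular masks
#'
#' For each rectangle the arithmetic mean of the pixels it covers is
#' reported.  All rectangles must have identical height and width
#' (equal-size masking) and lie fully inside the image.
#'
#' @param image numeric matrix of nonnegative intensities (rows x cols).
#' @param rects data frame with columns \code{lane_label},
#'   \code{row_start}, \code{col_start}, \code{height}, \code{width}
#'   (0-based, half-open) and optionally \code{group}.
#' @return data frame: the rectangle table plus \code{mean_intensity}.
#' @examples
#' img <- matrix(7, 10, 10)
#' quantify_bands(img, data.frame(lane_label = "L1", row_start = 2,
#'                                col_start = 3, height = 4, width = 2))
#' @export
quantify_bands <- function(image, rects) {
  image <- as.matrix(image)
  if (any(image < 0, na.rm = TRUE))
    stop("gel image intensities must be >= 0", call. = FALSE)
  rects <- .check_rects(as.data.frame(rects))
  nr <- nrow(image); nc <- ncol(image)
  rects$mean_intensity <- vapply(seq_len(nrow(rects)), function(i) {
    r0 <- rects$row_start[i]; c0 <- rects$col_start[i]
    h <- rects$height[i]; w <- rects$width[i]
    if (h < 1 || w < 1 || r0 < 0 || c0 < 0 || r0 + h > nr || c0 + w > nc)
      stop(sprintf(
        "rectangle '%s' (row %d, col %d, %dx%d) out of bounds for %dx%d image",
        rects$lane_label[i], r0, c0, h, w, nr, nc), call. = FALSE)
    mean(image[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)])
  }, numeric(1))
  rects
}

#' Compare mean band intensities between two sampler groups
#'
#' Pooled-variance Student's t-test on per-band mean intensities; thin
#' wrapper over [compare_yields()].
#'
#' @param group_a,group_b numeric vectors of band mean intensities.
#' @return a \code{"yield_ttest"} object (see [compare_yields()]).
#' @export
compare_band_groups <- function(group_a, group_b) {
  compare_yields(group_a, group_b, variant = "pooled")
}

#' Read a gel image from CSV or PGM
#'
#' CSV: a headerless numeric matrix.  PGM: plain (P2) or binary (P5)
#' portable graymap.
#'
#' @param path file path; format inferred from the extension
#'   (\code{.csv} vs \code{.pgm}).
#' @return numeric intensity matrix.
#' @export
read_gel_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(.read_pgm(path))
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

.read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, 1)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (expected P2 or P5)",
                                      call. = FALSE)
  hdr <- integer(0)
  while (length(hdr) < 3) {
    ln <- readLines(con, 1)
    ln <- sub("#.*", "", ln)
    hdr <- c(hdr, as.integer(strsplit(trimws(ln), "\\s+")[[1]]))
  }
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    readBin(con, "integer", n = w * h, size = if (maxval > 255) 2 else 1,
            signed = FALSE, endian = "big")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a gel image as plain (P2) PGM
#'
#' @param image numeric matrix; values rounded to integers.
#' @param path output path.
#' @param maxval maximum gray value declared in the header.
#' @export
write_pgm <- function(image, path, maxval = max(1, ceiling(max(image)))) {
  image <- round(as.matrix(image))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  utils::write.table(image, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rectangle table for band quantification
#'
#' @param path CSV with columns \code{lane_label}, \code{row_start},
#'   \code{col_start}, \code{height}, \code{width} and optionally
#'   \code{group}.
#' @return validated data frame.
#' @export
read_rects_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .check_rects(utils::read.csv(path, stringsAsFactors = FALSE))
}
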