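#' Quantification configuration for microscopy operators
#'
#' @param min_particle_px minimum puncta component area, in pixels, for a
#'   cell to count as activated (default 100, i.e. 31.2 um at the default
#'   resolution).
#' @param resolution_um_per_px pixel size in microns (default 0.312).
#' @param intensity_threshold puncta-channel cutoff on the 8-bit scale;
#'   pixels strictly above it are puncta signal (default 0).
#' @return a `QuantConfig` list.
#' @export
quant_config <- function(min_particle_px = 100, resolution_um_per_px = 0.312,
                         intensity_threshold = 0) {
  if (min_particle_px <= 0) stop("min_particle_px must be positive")
  if (resolution_um_per_px <= 0) stop("resolution_um_per_px must be positive")
  if (intensity_threshold < 0) stop("intensity_threshold must be >= 0")
  structure(list(min_particle_px = min_particle_px,
                 resolution_um_per_px = resolution_um_per_px,
                 intensity_threshold = intensity_threshold),
            class = "QuantConfig")
}

#' Connected components of a binary image
#'
#' Labels connected regions of TRUE pixels with 8-neighbor connectivity
#' using an iterative flood fill.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      rr <- r + offs[, 1]; ccn <- cc + offs[, 2]
      ok <- rr >= 1 & rr <= nr & ccn >= 1 & ccn <= nc
      nb <- (ccn[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0) {
        lab[nb] <- nxt
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Percent of cells activated by large puncta
#'
#' The puncta channel is thresholded, its connected components (8-neighbor)
#' are intersected with each cell's mask, and a cell is activated iff some
#' component contributes at least `min_particle_px` pixels *within* that
#' cell (a punctum straddling two cells is counted separately in each).
#' Returns 100 x activated / total cells — the CD68/IBA1 activation score.
#'
#' @param label_mask integer matrix; 0 = background, k > 0 = cell k.
#' @param puncta_image nonnegative intensity matrix, same shape.
#' @param cfg a [quant_config()].
#' @return list with `percent` and `per_cell` (data.frame: `cell`,
#'   `max_puncta_px` largest within-cell component area, `activated`).
#' @export
percent_activated <- function(label_mask, puncta_image, cfg = quant_config()) {
  if (!all(dim(label_mask) == dim(puncta_image)))
    stop("mask and puncta image shapes differ")
  cells <- sort(unique(label_mask[label_mask > 0]))
  if (length(cells) == 0) stop("mask contains no cells")
  comp <- label_components(puncta_image > cfg$intensity_threshold)
  per <- data.frame(cell = cells, max_puncta_px = 0L, activated = FALSE)
  for (ci in seq_along(cells)) {
    inside <- comp[label_mask == cells[ci]]
    inside <- inside[inside > 0]
    if (length(inside) > 0) {
      areas <- table(inside)
      per$max_puncta_px[ci] <- max(areas)
      per$activated[ci] <- any(areas >= cfg$min_particle_px)
    }
  }
  list(percent = 100 * mean(per$activated), per_cell = per)
}

#' Mean channel intensity within each cell mask
#'
#' @param label_mask integer matrix; 0 = background, k > 0 = cell k.
#' @param intensity_image numeric matrix, same shape.
#' @return data.frame with `cell` and `mean_intensity`; labels present in
#'   `1..max(label)` but covering no pixels are excluded and listed in
#'   attribute `empty_labels`.
#' @export
mean_intensity_in_mask <- function(label_mask, intensity_image) {
  if (!all(dim(label_mask) == dim(intensity_image)))
    stop("mask and intensity image shapes differ")
  present <- sort(unique(label_mask[label_mask > 0]))
  mi <- vapply(present, function(k)
    mean(intensity_image[label_mask == k]), numeric(1))
  out <- data.frame(cell = present, mean_intensity = mi)
  mx <- if (length(present) > 0) max(present) else 0L
  attr(out, "empty_labels") <- setdiff(seq_len(mx), present)
  out
}

#' Puncta-intensity-normalized transcript counts per cell
#'
#' Total puncta-channel intensity within each cell's mask divided by the
#' mean intensity of reference single puncta (5-7 individually measured
#' puncta per section in the source protocol). The result estimates the
#' transcript (punctum) count per cell.
#'
#' @param label_mask integer matrix; 0 = background, k > 0 = cell k.
#' @param puncta_image nonnegative intensity matrix, same shape.
#' @param reference_puncta numeric vector of single-punctum total
#'   intensities (>= 1, positive mean).
#' @param cells_to_measure cell labels to report (default: all).
#' @return data.frame with `cell` and `normalized_count`.
#' @export
rnascope_normalized_count <- function(label_mask, puncta_image,
                                      reference_puncta,
                                      cells_to_measure = NULL) {
  if (!all(dim(label_mask) == dim(puncta_image)))
    stop("mask and puncta image shapes differ")
  if (length(reference_puncta) < 1) stop("need at least one reference punctum")
  ref <- mean(reference_puncta)
  if (ref <= 0) stop("mean reference puncta intensity must be positive")
  cells <- sort(unique(label_mask[label_mask > 0]))
  if (!is.null(cells_to_measure)) {
    missing <- setdiff(cells_to_measure, cells)
    if (length(missing) > 0)
      stop("cells absent from mask: ", paste(missing, collapse = ", "))
    cells <- cells_to_measure
  }
  tot <- vapply(cells, function(k)
    sum(puncta_image[label_mask == k]), numeric(1))
  data.frame(cell = cells, normalized_count = tot / ref)
}

#' Convert a pixel measurement to microns
#'
#' Linear conversion `px * resolution_um_per_px`; at the instrument's
#' 0.312 um/pixel, the 100-pixel particle threshold equates to 31.2 um.
#'
#' @param area_px pixel count (or length in pixels).
#' @param resolution_um_per_px microns per pixel (default 0.312).
#' @return the converted value in microns.
#' @export
px_area_to_um <- function(area_px, resolution_um_per_px = 0.312) {
  if (any(area_px < 0)) stop("pixel areas must be nonnegative")
  if (resolution_um_per_px <= 0) stop("resolution must be positive")
  area_px * resolution_um_per_px
}

#' Maximum-intensity projection of a z-stack
#'
#' @param stack 3-d numeric array (rows x cols x z) or list of matrices.
#' @return matrix of per-pixel maxima across z.
#' @export
max_intensity_projection <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3) stop("expected a rows x cols x z stack")
  apply(stack, c(1, 2), max)
}
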