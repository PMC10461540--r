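# Border colour roles -> RGB (0-1). Chosen for contrast on dark palettes.
RENDER_ROLE_RGB <- list(
  green  = c(0.18, 0.80, 0.25),
  blue   = c(0.25, 0.55, 1.00),
  orange = c(1.00, 0.60, 0.10),
  grey   = c(0.65, 0.65, 0.65),
  white  = c(1.00, 1.00, 1.00)
)

#' Rendering options for spectrogram images
#'
#' @param palette Colour-map name passed to [grDevices::hcl.colors()];
#'   default `"viridis"` (perceptually uniform). Other built-ins such as
#'   `"inferno"`, `"mako"` or `"Grays"` also work.
#' @param show_guides Draw dotted time/frequency guide lines through the
#'   selection box edges (default `TRUE`).
#' @param image_width,image_height Output size in pixels (> 0).
#' @param show_bto_codes Label boxes with their BTO display code instead of
#'   the full class name, where a code has been applied (default `FALSE`).
#' @return An object of class `"render_options"`.
#' @export
render_options <- function(palette = "viridis", show_guides = TRUE,
                           image_width = 800, image_height = 400,
                           show_bto_codes = FALSE) {
  if (image_width <= 0 || image_height <= 0) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  structure(list(palette = palette, show_guides = show_guides,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 show_bto_codes = isTRUE(show_bto_codes)),
            class = "render_options")
}

# nearest-neighbour resize of a matrix to h x w
resize_nearest <- function(m, h, w) {
  ri <- pmin(pmax(ceiling(seq_len(h) / h * nrow(m)), 1L), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(w) / w * ncol(m)), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# paint a 1-pixel-thick rectangle border (rows r0..r1, cols c0..c1, clamped)
draw_border <- function(img, r0, r1, c0, c1, rgb, thickness = 2L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r0c <- max(r0, 1L); r1c <- min(r1, h)
  c0c <- max(c0, 1L); c1c <- min(c1, w)
  if (r0c > r1c || c0c > c1c) return(img)
  for (k in seq_len(thickness) - 1L) {
    edges <- list(c(r0 + k, r0 + k, c0c, c1c), c(r1 - k, r1 - k, c0c, c1c),
                  c(r0c, r1c, c0 + k, c0 + k), c(r0c, r1c, c1 - k, c1 - k))
    for (e in edges) {
      rr <- e[1]:e[2]; cc <- e[3]:e[4]
      rr <- rr[rr >= 1 & rr <= h]; cc <- cc[cc >= 1 & cc <= w]
      if (length(rr) && length(cc)) {
        for (ch in 1:3) img[rr, cc, ch] <- rgb[ch]
      }
    }
  }
  img
}

# dotted horizontal + vertical guide lines through a point range
draw_guides <- function(img, rows, cols, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  dot <- function(n) which(seq_len(n) %% 6 < 3)
  for (r in rows) {
    if (r >= 1 && r <= h) for (ch in 1:3) img[r, dot(w), ch] <- rgb[ch]
  }
  for (cl in cols) {
    if (cl >= 1 && cl <= w) for (ch in 1:3) img[dot(h), cl, ch] <- rgb[ch]
  }
  img
}

# render text with the built-in 5x7 font; (r, c) is the top-left pixel
draw_text <- function(img, r, c, text, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  chars <- strsplit(text, "")[[1]]
  for (ch in chars) {
    g <- font_glyph(ch)
    if (!is.null(g)) {
      for (gr in 1:7) for (gc in 1:5) {
        if (g[gr, gc]) {
          rr <- r + gr - 1L; cc <- c + gc - 1L
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
            img[rr, cc, ] <- rgb
          }
        }
      }
    }
    c <- c + 6L
  }
  img
}

#' Render a spectrogram image with annotation overlays
#'
#' Composites the display layers back-to-front, mirroring an annotation
#' session's plot: (1) the dB raster mapped through the colour palette with
#' 0 dB at the palette top, frequency increasing upward; (2) annotation
#' bounding boxes with class labels, border-coloured by category (core
#' green, custom blue, misc orange, unknown grey); (3) the current selection
#' box in white with optional dotted guide lines. Because layers are
#' composited onto the finished raster, adding or removing annotations never
#' changes base-raster pixels outside the boxes.
#'
#' @param dbspec A [to_db()] (possibly [zoom()]ed) spectrogram.
#' @param annotations An [annotation_set()] or `NULL`. Boxes partly outside
#'   the displayed extent are clipped with a warning.
#' @param classes A `"class_list"` (see [build_class_list()]) or `NULL`;
#'   used for border colours and BTO display codes.
#' @param selection A [bounding_box()] or `NULL`.
#' @param options A [render_options()] object.
#' @return A numeric array `image_height x image_width x 3` of RGB values in
#'   \[0, 1\] (class `"render_image"`), suitable for [save_png()].
#' @export
render_spectrogram <- function(dbspec, annotations = NULL, classes = NULL,
                               selection = NULL,
                               options = render_options()) {
  stopifnot(inherits(dbspec, "db_spectrogram"),
            inherits(options, "render_options"))
  if (nrow(dbspec$values) == 0 || ncol(dbspec$values) == 0) {
    stop("cannot render an empty spectrogram", call. = FALSE)
  }
  h <- options$image_height; w <- options$image_width
  dr <- -min(dbspec$values)
  dr <- if (dr <= 0) 1 else dr

  pal <- grDevices::hcl.colors(256, options$palette)
  pal_rgb <- t(grDevices::col2rgb(pal)) / 255
  # row 1 of the image = top = highest frequency
  vals <- dbspec$values[rev(seq_len(nrow(dbspec$values))), , drop = FALSE]
  vals <- resize_nearest(vals, h, w)
  idx <- pmin(pmax(as.integer(round((vals + dr) / dr * 255)) + 1L, 1L), 256L)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal_rgb[idx, ch], h, w)

  t0 <- dbspec$time_extent[1]; t1 <- dbspec$time_extent[2]
  f0 <- dbspec$freq_extent[1]; f1 <- dbspec$freq_extent[2]
  to_col <- function(t) as.integer(round((t - t0) / (t1 - t0) * (w - 1))) + 1L
  to_row <- function(f) as.integer(round((f1 - f) / (f1 - f0) * (h - 1))) + 1L

  if (!is.null(annotations) && length(annotations) > 0) {
    recs <- annotations$records
    clipped <- FALSE
    for (i in seq_len(nrow(recs))) {
      if (recs$end_time[i] < t0 || recs$start_time[i] > t1 ||
          recs$end_freq[i] < f0 || recs$start_freq[i] > f1) {
        clipped <- TRUE
        next
      }
      if (recs$start_time[i] < t0 || recs$end_time[i] > t1 ||
          recs$start_freq[i] < f0 || recs$end_freq[i] > f1) {
        clipped <- TRUE
      }
      role <- if (is.null(classes)) "grey"
              else class_colour(classes, recs$class_label[i])
      rgb <- RENDER_ROLE_RGB[[role]]
      c0 <- to_col(max(recs$start_time[i], t0))
      c1 <- to_col(min(recs$end_time[i], t1))
      r0 <- to_row(min(recs$end_freq[i], f1))
      r1 <- to_row(max(recs$start_freq[i], f0))
      img <- draw_border(img, r0, r1, c0, c1, rgb)
      label <- recs$class_label[i]
      if (options$show_bto_codes && !is.null(classes)) {
        j <- match(label, classes$name)
        if (!is.na(j)) label <- classes$display_code[j]
      }
      img <- draw_text(img, r0 - 9L, c0, label, rgb)
    }
    if (clipped) {
      warning("some annotation box(es) extend outside the displayed extent; rendered clipped",
              call. = FALSE)
    }
  }

  if (!is.null(selection)) {
    stopifnot(inherits(selection, "bounding_box"))
    rgb <- RENDER_ROLE_RGB$white
    c0 <- to_col(max(selection$t_start, t0))
    c1 <- to_col(min(selection$t_end, t1))
    r0 <- to_row(min(selection$f_end, f1))
    r1 <- to_row(max(selection$f_start, f0))
    if (options$show_guides) {
      img <- draw_guides(img, c(r0, r1), c(c0, c1), rgb)
    }
    img <- draw_border(img, r0, r1, c0, c1, rgb)
  }

  structure(img, class = "render_image")
}

#' Write a rendered image to a PNG file
#'
#' @param img A `"render_image"` array from [render_spectrogram()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
save_png <- function(img, path) {
  stopifnot(inherits(img, "render_image"))
  png::writePNG(unclass(img), path)
  invisible(path)
}
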