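#' Render DDQR text as a QR code image
#'
#' Builds a QR symbol (byte mode, version auto-selected as the smallest that
#' fits the payload at the requested error-correction level) and writes it
#' as a black-and-white PNG.
#'
#' @param text Non-empty payload, typically a DDQR Base64 string from
#'   [ddqr_encode()].
#' @param path Output PNG path; when `NULL` no file is written.
#' @param error_correction One of `"L"`, `"M"` (default), `"Q"`, `"H"`.
#' @param module_pixel_size Pixels per module (default 10).
#' @param border_modules Quiet-zone width in modules (default 4, the
#'   standard minimum).
#' @return Invisibly, the pixel matrix (0 = black, 1 = white) with
#'   attributes `version`, `level` and `mask` describing the symbol.
#' @examples
#' img <- render_qr("BvQ")
#' @export
render_qr <- function(text, path = NULL, error_correction = "M",
                      module_pixel_size = 10L, border_modules = 4L) {
  if (!is.character(text) || length(text) != 1L || nchar(text) == 0L) {
    stop_ddqr("ddqr_empty_sequence_error", "QR payload must be a non-empty string")
  }
  stopifnot(module_pixel_size >= 1L, border_modules >= 0L)
  mat <- qr_build_matrix(text, level = error_correction)
  n <- nrow(mat)
  full <- matrix(FALSE, n + 2L * border_modules, n + 2L * border_modules)
  full[border_modules + seq_len(n), border_modules + seq_len(n)] <- mat
  s <- module_pixel_size
  px <- 1 - full[rep(seq_len(nrow(full)), each = s), rep(seq_len(ncol(full)), each = s)]
  storage.mode(px) <- "numeric"
  if (!is.null(path)) {
    png::writePNG(px, target = path)
  }
  invisible(structure(
    px,
    version = attr(mat, "version"), level = attr(mat, "level"),
    mask = attr(mat, "mask")
  ))
}

#' Read the text payload of a QR code image
#'
#' Reads a clean, axis-aligned QR symbol such as those produced by
#' [render_qr()]: the image is binarized, the module grid located from the
#' symbol's bounding box and top-left finder pattern, and the payload
#' recovered through format-information lookup, unmasking, codeword
#' de-interleaving and Reed-Solomon correction.
#'
#' @param image A PNG file path, or a numeric matrix/array of pixel
#'   intensities in `[0, 1]` as returned by [render_qr()] or
#'   [png::readPNG()].
#' @return The decoded text payload.
#' @export
read_qr <- function(image) {
  px <- if (is.character(image)) png::readPNG(image) else image
  if (length(dim(px)) == 3L) px <- px[, , 1L] # grayscale from RGB(A)
  dark <- px < 0.5
  if (!any(dark)) {
    stop_ddqr("ddqr_no_symbol_error", "no QR symbol found (image has no dark pixels)")
  }
  rows <- range(which(rowSums(dark) > 0L))
  cols <- range(which(colSums(dark) > 0L))
  height <- rows[2L] - rows[1L] + 1L
  width <- cols[2L] - cols[1L] + 1L
  if (height != width) {
    stop_ddqr("ddqr_no_symbol_error", "dark region is not square; no single QR symbol found")
  }
  # top-left finder: leading dark run on the first symbol row spans 7 modules
  first_row <- dark[rows[1L], cols[1L]:cols[2L]]
  run <- which(!first_row)[1L]
  if (is.na(run)) run <- width + 1L
  module_px <- (run - 1L) / 7
  n_modules <- round(width / module_px)
  if (n_modules < 21L || n_modules > 177L || (n_modules - 17L) %% 4L != 0L ||
    abs(width / module_px - n_modules) > 0.25) {
    stop_ddqr("ddqr_no_symbol_error", "dark region does not match a QR module grid")
  }
  mid <- floor((seq_len(n_modules) - 0.5) * module_px) + 1L
  centers <- rows[1L] - 1L + mid
  centers_c <- cols[1L] - 1L + mid
  mat <- dark[centers, centers_c]
  if (qr_count_finders(mat) > 3L) {
    stop_ddqr("ddqr_ambiguous_symbol_error", "more than one QR symbol in image")
  }
  qr_read_matrix(mat)
}

# Count 7x7 finder-pattern templates in a module matrix (used to reject
# images that contain several concatenated symbols).
qr_count_finders <- function(mat) {
  template <- matrix(TRUE, 7L, 7L)
  template[2:6, 2:6] <- FALSE
  template[3:5, 3:5] <- TRUE
  n <- nrow(mat)
  hits <- 0L
  for (r in seq_len(n - 6L)) {
    for (c in seq_len(n - 6L)) {
      if (mat[r, c] && mat[r + 6L, c + 6L] && !mat[r + 1L, c + 1L] &&
        identical(unname(mat[r:(r + 6L), c:(c + 6L)]), template)) {
        hits <- hits + 1L
      }
    }
  }
  hits
}
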