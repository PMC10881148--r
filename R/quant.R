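# Intensity-based quantifications: ventral z-fraction, in-mask statistics,
# coating uniformity, densitometry band ratios, adhesion ratios.

#' Ventral fraction of a confocal z-stack
#'
#' Integrates intensity inside the cell outline of each slice and reports the
#' fraction found in the ventral (z = 0, coverslip-proximal) slice relative
#' to the total over all slices. A larger value means more signal at the cell
#' bottom. Slice background, estimated as the median of a cell-free border
#' strip, is subtracted per slice with negative pixels clipped to zero.
#'
#' @param stack Numeric array `[rows, cols, slices]`, ventral slice first.
#' @param masks Per-slice cell outline: a single logical matrix recycled for
#'   all slices, a list of matrices, or `NULL` to integrate whole slices.
#' @param background `"border"` (default) subtracts the per-slice median of
#'   the border strip; `"none"` disables background handling.
#' @param border_px Width of the border strip used for background estimation.
#' @return A list of class `mm_zprofile`: `profile` (per-slice integrated
#'   intensities, ventral first), `fractions` (per-slice shares, summing
#'   to 1), and `ventral_fraction` (`fractions[1]`).
#' @examples
#' st <- simulate_zstack(5, 0.4, 1e5, noise_sd = 0, seed = 1)
#' ventral_fraction(st$stack, st$mask, background = "none")$ventral_fraction
#' @export
ventral_fraction <- function(stack, masks = NULL,
                             background = c("border", "none"),
                             border_px = 4L) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 2L)
  background <- match.arg(background)
  n <- dim(stack)[3]
  get_mask <- function(z) {
    if (is.null(masks)) return(matrix(TRUE, dim(stack)[1], dim(stack)[2]))
    m <- if (is.list(masks)) masks[[z]] else masks
    m > 0
  }
  profile <- numeric(n)
  for (z in seq_len(n)) {
    sl <- stack[, , z]
    if (background == "border") {
      nr <- nrow(sl); nc <- ncol(sl)
      border <- c(sl[seq_len(min(border_px, nr)), ],
                  sl[seq.int(max(1L, nr - border_px + 1L), nr), ],
                  sl[, seq_len(min(border_px, nc))],
                  sl[, seq.int(max(1L, nc - border_px + 1L), nc)])
      sl <- pmax(sl - median(border), 0)
    }
    profile[z] <- sum(sl[get_mask(z)])
  }
  total <- sum(profile)
  if (total <= 0) stop("zero total intensity in the stack", call. = FALSE)
  structure(
    list(profile = profile, fractions = profile / total,
         ventral_fraction = profile[1] / total),
    class = "mm_zprofile"
  )
}

#' Intensity statistics inside a mask
#'
#' Area (pixel count), mean, min and max gray value, and the integrated
#' density (sum = area x mean) of the raw pixel values inside the mask.
#' Display-range settings affect visualization only, never these
#' measurements. A warning is emitted when the maximum equals 1 (the
#' normalized dtype ceiling), which may indicate a saturated exposure.
#'
#' @param image Numeric matrix.
#' @param mask Logical or 0/1 matrix, same dimensions, nonempty.
#' @return A list: `area`, `mean`, `min`, `max`, `integrated`.
#' @export
mean_intensity_in_mask <- function(image, mask) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  m <- mask > 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  v <- image[m]
  if (max(v) >= 1) warning("max pixel at dtype ceiling: exposure may be saturated")
  list(area = sum(m), mean = mean(v), min = min(v), max = max(v),
       integrated = sum(v))
}

#' Coating uniformity at five standard positions
#'
#' Mean gray value of a square of side `square_size` placed at the four
#' corners and the centre of the image, as in a fluorescent-coating
#' uniformity check. Returns the five values with their mean and coefficient
#' of variation.
#'
#' @param image Numeric matrix.
#' @param square_size Side of the measuring square, pixels.
#' @return A list: `values` (named: top_left, top_right, center, bottom_left,
#'   bottom_right), `mean`, `cv`.
#' @export
coating_uniformity <- function(image, square_size) {
  stopifnot(is.matrix(image))
  square_size <- check_count(square_size, "square_size", min = 1L)
  nr <- nrow(image); nc <- ncol(image)
  if (square_size > nr || square_size > nc) {
    stop("square larger than image", call. = FALSE)
  }
  s <- square_size
  ci <- floor((nr - s) / 2) + 1L
  cj <- floor((nc - s) / 2) + 1L
  box <- function(i, j) mean(image[i:(i + s - 1L), j:(j + s - 1L)])
  values <- c(
    top_left = box(1L, 1L),
    top_right = box(1L, nc - s + 1L),
    center = box(ci, cj),
    bottom_left = box(nr - s + 1L, 1L),
    bottom_right = box(nr - s + 1L, nc - s + 1L)
  )
  m <- mean(values)
  list(values = values, mean = m,
       cv = if (m > 0) sd(values) / m else NA_real_)
}

#' Densitometry band ratio
#'
#' Total (integrated) pixel intensity of the target box divided by that of
#' the loading-control box. The two boxes must be identically sized, as in
#' standard blot densitometry.
#'
#' @param target_box Numeric matrix covering the target band.
#' @param control_box Numeric matrix covering the control band (e.g. GAPDH);
#'   same dimensions as `target_box`, positive total.
#' @return Dimensionless normalized intensity.
#' @export
band_ratio <- function(target_box, control_box) {
  stopifnot(is.matrix(target_box), is.matrix(control_box))
  if (!all(dim(target_box) == dim(control_box))) {
    stop("target and control boxes must be identically sized", call. = FALSE)
  }
  ctrl <- sum(control_box)
  if (ctrl <= 0) stop("control intensity must be positive", call. = FALSE)
  sum(target_box) / ctrl
}

#' Adhesion ratio from pre/post-wash fields
#'
#' Ratio of the number of bound cells after washing to the number before
#' (1 = 100% adherence). Inputs may be counts, point matrices, or images (in
#' which case cells are counted with [detect_cells()]). The ratio is not
#' clipped: counting noise can push it above 1, which is flagged.
#'
#' @param pre,post A count, an n x 2 point matrix, or an image matrix.
#' @param config A [tracking_config()] used when images are given.
#' @return A list of class `mm_adhesion`: `pre_count`, `post_count`, `ratio`.
#' @examples
#' adhesion_ratio(100, 50)$ratio
#' @export
adhesion_ratio <- function(pre, post, config = tracking_config()) {
  count_of <- function(obj) {
    if (is.numeric(obj) && length(obj) == 1L) return(check_count(obj, "count"))
    if (is.matrix(obj) && ncol(obj) == 2L) return(nrow(obj))
    if (is.matrix(obj)) return(nrow(detect_cells(obj, config)))
    stop("cannot interpret adhesion input", call. = FALSE)
  }
  pre_count <- count_of(pre)
  post_count <- count_of(post)
  if (pre_count == 0L) stop("pre-wash count is zero; ratio undefined", call. = FALSE)
  ratio <- post_count / pre_count
  if (ratio > 1) message("adhesion ratio > 1 (counting noise)")
  structure(list(pre_count = pre_count, post_count = post_count, ratio = ratio),
            class = "mm_adhesion")
}
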