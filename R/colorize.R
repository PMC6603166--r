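#' Convert an image to gray by channel averaging
#'
#' Every output pixel has `R = G = B = (R + G + B) / 3` of the input pixel —
#' the unweighted channel mean (not luma weighting), matching how the gray
#' presentation group is produced for rating.
#'
#' @param img a [stain_image()].
#' @return A gray [stain_image()] (all three channels equal).
#' @export
to_gray <- function(img) {
  px <- unclass(img)
  g <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  stain_image(array(rep(g, 3L), dim = dim(px)),
              source_id = attr(img, "source_id"))
}

#' Color-code an image in a single channel
#'
#' Converts the image to gray (unweighted channel mean) and places the gray
#' value in the kept channel; the other two channels are exactly zero. Used
#' to present stylized images in green or red so that rating improvements can
#' be separated from mere color resemblance to H&E.
#'
#' @param img a [stain_image()].
#' @param keep channel to keep: `"red"` or `"green"`.
#' @return A [stain_image()] with the two non-kept channels identically zero.
#' @export
color_code <- function(img, keep = c("green", "red")) {
  if (!is.character(keep) || length(keep) != 1L || !keep %in% c("green", "red")) {
    abort("`keep` must be \"green\" or \"red\"", class = "hestain_domain_error")
  }
  px <- unclass(img)
  g <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  out <- array(0, dim = dim(px))
  out[, , if (keep == "red") 1L else 2L] <- g
  stain_image(out, source_id = attr(img, "source_id"))
}

#' Assign images to the four color presentation groups
#'
#' Deterministic seeded shuffle of the image ids followed by a round-robin
#' split into the four groups `gray`, `green`, `red`, `intact`. With 100
#' images each group has exactly 25 members; otherwise group sizes differ by
#' at most one.
#'
#' @param image_ids character vector of image ids.
#' @param seed integer seed making the assignment reproducible.
#' @return A tibble with columns `image_id` and `group` (factor with levels
#'   gray, green, red, intact), one row per id.
#' @export
assign_color_groups <- function(image_ids, seed = 0L) {
  if (length(image_ids) == 0L) {
    abort("`image_ids` must be non-empty", class = "hestain_domain_error")
  }
  if (anyDuplicated(image_ids)) {
    abort("`image_ids` must be unique", class = "hestain_domain_error")
  }
  groups <- c("gray", "green", "red", "intact")
  shuffled <- run_with_preserved_rng(seed, sample(image_ids))
  tab <- tibble::tibble(
    image_id = shuffled,
    group = factor(rep_len(groups, length(shuffled)), levels = groups)
  )
  dplyr::arrange(tab, .data$image_id)
}

#' Apply a color-group presentation to an image
#'
#' @param img a [stain_image()].
#' @param group one of `"gray"`, `"green"`, `"red"`, `"intact"`.
#' @return The recolored [stain_image()] (`intact` returns the input).
#' @export
apply_color_group <- function(img, group) {
  group <- as.character(group)
  switch(group,
         gray = to_gray(img),
         green = color_code(img, "green"),
         red = color_code(img, "red"),
         intact = img,
         abort(sprintf("unknown color group '%s'", group),
               class = "hestain_domain_error"))
}
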