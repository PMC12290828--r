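#' Build the nested stimulus category hierarchy
#'
#' Constructs the three-level image category hierarchy used by the cued-recall
#' experiment: 2 top-level categories (object, scene), each split into 2
#' middle-level categories (animate/inanimate objects, indoor/outdoor scenes),
#' each of which branches into 4 bottom-level categories with 12 specific image
#' instances apiece, for 2 x 2 x 4 x 12 = 192 leaf images.
#'
#' @return A tibble with one row per leaf image and columns `image_id`,
#'   `top`, `middle`, `bottom`, `instance` (1..12). All label columns are
#'   character; `image_id` is unique.
#' @examples
#' h <- build_hierarchy()
#' nrow(h)                      # 192
#' table(h$top)                 # 96 objects, 96 scenes
#' @export
build_hierarchy <- function() {
  bottoms <- list(
    object = list(
      animate   = c("birds", "insects", "mammals", "marine"),
      inanimate = c("tools", "furniture", "vehicles", "instruments")
    ),
    scene = list(
      indoor  = c("kitchen", "office", "bathroom", "bedroom"),
      outdoor = c("forest", "mountain", "beach", "street")
    )
  )
  rows <- purrr::imap(bottoms, function(mids, top) {
    purrr::imap(mids, function(bots, middle) {
      purrr::map(bots, function(bottom) {
        tibble(
          top = top, middle = middle, bottom = bottom,
          instance = 1:12,
          image_id = sprintf("%s_%02d", bottom, 1:12)
        )
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  dplyr::select(out, "image_id", "top", "middle", "bottom", "instance")
}
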