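#' Default geometry of the pictographic face stimuli
#'
#' The four face variants share an identical head outline (an annulus) and a
#' pair of filled square eyes, and differ only in the mouth stroke drawn
#' inside a fixed mouth bounding box. All coordinates are in pixels on the
#' default 100 x 100 canvas and scale linearly with the canvas size.
#'
#' @param height,width Canvas dimensions in pixels.
#' @return A list describing head, eyes and the mouth bounding box, used by
#'   [render_face_variant()]. The `mouth_box` element (`rmin`, `rmax`,
#'   `cmin`, `cmax`) delimits the only region in which variants may differ.
#' @export
face_geometry <- function(height = 100, width = 100) {
  sy <- height / 100
  sx <- width / 100
  list(
    center = c((1 + height) / 2, (1 + width) / 2),
    head_r = c(38 * sy, 42 * sy),
    eye_rows = round(c(35, 42) * sy),
    eye_cols_left = round(c(33, 40) * sx),
    eye_cols_right = round(c(61, 68) * sx),
    mouth_box = list(
      rmin = round(53 * sy), rmax = round(79 * sy),
      cmin = round(33 * sx), cmax = round(68 * sx)
    )
  )
}

#' Default geometry of the barred-square stimuli
#'
#' The four square variants share an identical hollow square outline and
#' differ in a single interior bar: two horizontal bars (top / bottom
#' position) and two vertical bars (left / right position). Bar regions of
#' distinct variants are pairwise disjoint, so each variant carries unique
#' pixel evidence on top of the shared outline.
#'
#' @inheritParams face_geometry
#' @return A list with the outline extent, stroke width and the four bar
#'   rectangles, used by [render_square_variant()].
#' @export
square_geometry <- function(height = 100, width = 100) {
  sy <- height / 100
  sx <- width / 100
  rr <- function(x, s) round(x * s)
  list(
    outline = c(rr(11, sy), rr(90, sy), rr(11, sx), rr(90, sx)),
    stroke = max(1L, rr(4, min(sy, sx))),
    bars = list(
      c(rr(26, sy), rr(29, sy), rr(31, sx), rr(70, sx)), # horizontal, top
      c(rr(77, sy), rr(80, sy), rr(31, sx), rr(70, sx)), # horizontal, bottom
      c(rr(31, sy), rr(70, sy), rr(26, sx), rr(29, sx)), # vertical, left
      c(rr(31, sy), rr(70, sy), rr(72, sx), rr(75, sx))  # vertical, right
    )
  )
}

fill_rect <- function(img, r0, r1, c0, c1) {
  img[r0:r1, c0:c1] <- 1
  img
}

# distance-from-center mask helper for annuli / arcs
dist_grid <- function(height, width, center) {
  dy <- matrix(seq_len(height) - center[1], height, width)
  dx <- matrix(seq_len(width) - center[2], height, width, byrow = TRUE)
  sqrt(dy^2 + dx^2)
}

check_variant_id <- function(variant_id) {
  if (length(variant_id) != 1 || !is.numeric(variant_id) ||
      is.na(variant_id) || variant_id != as.integer(variant_id) ||
      variant_id < 1 || variant_id > 4) {
    stop("`variant_id` must be a single integer in 1..4, got: ",
         deparse(substitute(variant_id)), " = ", format(variant_id))
  }
  as.integer(variant_id)
}

#' Render one face pictogram variant
#'
#' Draws a binary line pictogram of a face: annular head outline, two filled
#' eyes, and one of four mouth shapes (straight, smile, frown, open). The
#' head and eyes are pixel-identical across variants; only pixels inside the
#' mouth bounding box of [face_geometry()] differ.
#'
#' @param variant_id Integer in 1..4 selecting the mouth shape.
#' @param height,width Canvas dimensions in pixels (default 100 x 100).
#' @param geometry Geometry description, see [face_geometry()].
#' @return A `height x width` numeric matrix with values in \{0, 1\}.
#' @examples
#' img <- render_face_variant(2)
#' sum(img > 0)
#' @export
render_face_variant <- function(variant_id, height = 100, width = 100,
                                geometry = face_geometry(height, width)) {
  variant_id <- check_variant_id(variant_id)
  img <- matrix(0, height, width)
  d <- dist_grid(height, width, geometry$center)
  img[d >= geometry$head_r[1] & d <= geometry$head_r[2]] <- 1
  er <- geometry$eye_rows
  img <- fill_rect(img, er[1], er[2], geometry$eye_cols_left[1], geometry$eye_cols_left[2])
  img <- fill_rect(img, er[1], er[2], geometry$eye_cols_right[1], geometry$eye_cols_right[2])
  sy <- height / 100
  sx <- width / 100
  cx <- geometry$center[2]
  # the four mouth strokes occupy (near-)disjoint regions of the mouth box,
  # so each variant carries its own pixel evidence on the shared face
  if (variant_id == 1L) {
    # straight mouth
    img <- fill_rect(img, round(61 * sy), round(65 * sy), round(35 * sx), round(66 * sx))
  } else if (variant_id == 2L) {
    # smile: lower half-annulus, the lowest stroke
    ds <- dist_grid(height, width, c(62 * sy, cx))
    rows <- matrix(seq_len(height), height, width)
    img[ds >= 12 * sy & ds <= 16 * sy &
          rows >= round(67 * sy) & rows <= round(76 * sy)] <- 1
  } else if (variant_id == 3L) {
    # frown: downward arch in the band above the straight mouth
    ds <- dist_grid(height, width, c(74 * sy, cx))
    rows <- matrix(seq_len(height), height, width)
    img[ds >= 15 * sy & ds <= 21 * sy &
          rows >= round(53 * sy) & rows <= round(60 * sy)] <- 1
  } else {
    # open mouth: filled rectangle in the central band
    img <- fill_rect(img, round(66 * sy), round(72 * sy), round(41 * sx), round(60 * sx))
  }
  img
}

#' Render one barred-square pictogram variant
#'
#' Draws a hollow square outline (identical across variants) plus a single
#' interior bar whose orientation and position identify the variant:
#' 1 = horizontal top, 2 = horizontal bottom, 3 = vertical left,
#' 4 = vertical right.
#'
#' @inheritParams render_face_variant
#' @param geometry Geometry description, see [square_geometry()].
#' @return A `height x width` numeric matrix with values in \{0, 1\}.
#' @export
render_square_variant <- function(variant_id, height = 100, width = 100,
                                  geometry = square_geometry(height, width)) {
  variant_id <- check_variant_id(variant_id)
  img <- matrix(0, height, width)
  o <- geometry$outline
  s <- geometry$stroke - 1L
  img <- fill_rect(img, o[1], o[1] + s, o[3], o[4])
  img <- fill_rect(img, o[2] - s, o[2], o[3], o[4])
  img <- fill_rect(img, o[1], o[2], o[3], o[3] + s)
  img <- fill_rect(img, o[1], o[2], o[4] - s, o[4])
  b <- geometry$bars[[variant_id]]
  fill_rect(img, b[1], b[2], b[3], b[4])
}

#' Build a labeled stimulus set for one or both categories
#'
#' Category `"A"` holds the four face pictograms, category `"B"` the four
#' barred squares. Each category contains exactly four variants whose
#' pixelwise intersection (shared structure) is non-empty and strictly
#' contained in their union.
#'
#' @param categories Character vector, subset of `c("A", "B")`.
#' @param height,width Canvas dimensions in pixels.
#' @return A tibble with columns `category`, `variation` and a list-column
#'   `image` of numeric matrices.
#' @examples
#' st <- stimulus_set("B")
#' nrow(st)
#' @export
stimulus_set <- function(categories = c("A", "B"), height = 100, width = 100) {
  categories <- match.arg(categories, c("A", "B"), several.ok = TRUE)
  rows <- purrr::map(categories, function(cat) {
    render <- if (cat == "A") render_face_variant else render_square_variant
    tibble::tibble(
      category = cat,
      variation = 1:4,
      image = purrr::map(1:4, render, height = height, width = width)
    )
  })
  dplyr::bind_rows(rows)
}

#' Add clipped Gaussian pixel noise to an image
#'
#' Adds independent additive Gaussian noise (mean 0, standard deviation
#' `sigma`) to every pixel and clips the result to \[0, 1\]. Noise is drawn
#' from R's current random number stream; seed management is the caller's
#' responsibility (the training loop derives one noise seed per
#' presentation).
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param sigma Noise standard deviation, must be non-negative.
#' @return Matrix of the same shape with all values in \[0, 1\].
#' @export
add_noise <- function(img, sigma = 0.05) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single non-negative number")
  }
  if (sigma == 0) return(img)
  out <- img + stats::rnorm(length(img), mean = 0, sd = sigma)
  dim(out) <- dim(img)
  pmin(pmax(out, 0), 1)
}

#' Build a presentation schedule over a stimulus set
#'
#' Produces the ordered stream of stimulus presentations used for training.
#' Under the `"blocked"` schedule the variants of the set are presented in
#' contiguous runs of `block_size` (cycling over rows of `set` in order);
#' under `"random"` every step draws a variant uniformly at random. Fresh
#' noise is drawn per presentation: each step carries its own noise seed,
#' derived from `seed`, so streams are bit-reproducible.
#'
#' @param set Stimulus set from [stimulus_set()] (one or both categories).
#' @param schedule `"blocked"` or `"random"`.
#' @param block_size Length of each contiguous run under `"blocked"`.
#' @param n_steps Total number of presentations (>= 1).
#' @param seed Integer seed controlling ordering and per-step noise.
#' @param sigma Per-presentation noise standard deviation.
#' @return A tibble (class `corticat_stream`) with columns `step`,
#'   `category`, `variation`, `noise_seed`; the stimulus images and noise
#'   level are stored as attributes. Use [stream_stimulus()] to materialize
#'   the noisy image of a step.
#' @export
build_stream <- function(set, schedule = c("blocked", "random"),
                         block_size = 100, n_steps, seed = 1, sigma = 0.05) {
  schedule <- match.arg(schedule)
  if (!is.data.frame(set) || nrow(set) == 0) {
    stop("`set` must be a non-empty stimulus set")
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    stop("`n_steps` must be >= 1")
  }
  n_steps <- as.integer(n_steps)
  nv <- nrow(set)
  idx <- with_local_seed(seed, {
    ord <- if (schedule == "blocked") {
      # blocks cycle over variants; with several categories the cycle
      # alternates between them (A1, B1, A2, B2, ...) so every category is
      # revisited at the block rhythm
      cycle <- order(set$variation, set$category)
      rep(rep(cycle, each = block_size), length.out = n_steps)
    } else {
      sample.int(nv, n_steps, replace = TRUE)
    }
    list(order = ord,
         noise_seed = sample.int(.Machine$integer.max - 1L, n_steps))
  })
  out <- tibble::tibble(
    step = seq_len(n_steps),
    category = set$category[idx$order],
    variation = set$variation[idx$order],
    noise_seed = idx$noise_seed
  )
  attr(out, "images") <- set
  attr(out, "sigma") <- sigma
  attr(out, "schedule") <- schedule
  attr(out, "block_size") <- as.integer(block_size)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("corticat_stream", class(out))
  out
}

#' Materialize the noisy stimulus image of one stream step
#'
#' @param stream A stream from [build_stream()].
#' @param step Step index (1-based).
#' @return The noisy image matrix presented at that step; deterministic for
#'   a fixed stream.
#' @export
stream_stimulus <- function(stream, step) {
  row <- stream[stream$step == step, ]
  if (nrow(row) != 1) stop("step ", step, " not present in stream")
  set <- attr(stream, "images")
  img <- set$image[[which(set$category == row$category &
                            set$variation == row$variation)]]
  with_local_seed(row$noise_seed, add_noise(img, attr(stream, "sigma")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
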