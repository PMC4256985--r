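test_that("face variants share everything except the mouth region", {
  faces <- lapply(1:4, render_face_variant)
  box <- face_geometry()$mouth_box
  for (i in 1:3) {
    for (j in (i + 1):4) {
      d <- abs(faces[[i]] - faces[[j]])
      d[box$rmin:box$rmax, box$cmin:box$cmax] <- 0
      expect_equal(sum(d), 0)
    }
  }
  # variants are genuinely distinct inside the mouth box
  expect_gt(sum(abs(faces[[1]] - faces[[2]])), 0)
})

test_that("rendering is deterministic and respects the size contract", {
  expect_identical(render_face_variant(3), render_face_variant(3))
  expect_identical(render_square_variant(2), render_square_variant(2))
  img <- render_face_variant(1, height = 50, width = 80)
  expect_identical(dim(img), c(50L, 80L))
  expect_true(all(img %in% c(0, 1)))
})

test_that("foreground pixel counts sit in the calibrated energy band", {
  for (v in 1:4) {
    expect_gte(sum(render_face_variant(v)), 1200)
    expect_lte(sum(render_face_variant(v)), 1600)
    expect_gte(sum(render_square_variant(v)), 1200)
    expect_lte(sum(render_square_variant(v)), 1600)
  }
})

test_that("invalid variant ids are rejected", {
  expect_error(render_face_variant(0), "1..4")
  expect_error(render_face_variant(5), "1..4")
  expect_error(render_square_variant(2.5), "1..4")
})

test_that("square variants intersect in exactly the outline, bars disjoint", {
  sq <- lapply(1:4, render_square_variant)
  inter <- Reduce(pmin, sq)
  geom <- square_geometry()
  outline_only <- sq[[1]]
  b <- geom$bars[[1]]
  outline_only[b[1]:b[2], b[3]:b[4]] <- 0
  expect_identical(inter, outline_only)
  bars <- lapply(sq, function(img) img - inter)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(sum(bars[[i]] * bars[[j]]), 0)
    }
  }
})

test_that("within-category intersection is non-empty and below the union", {
  for (cat in c("A", "B")) {
    imgs <- stimulus_set(cat)$image
    inter <- Reduce(pmin, imgs)
    un <- Reduce(pmax, imgs)
    expect_gt(sum(inter), 0)
    expect_gt(sum(un), sum(inter))
  }
})

test_that("noise injection matches the clipped-Gaussian contract", {
  img <- render_face_variant(1)
  expect_identical(add_noise(img, 0), img)
  expect_error(add_noise(img, -0.1), "non-negative")

  # huge sigma still respects clipping on an all-ones image
  ones <- matrix(1, 20, 20)
  set.seed(7)
  out <- add_noise(ones, 10)
  expect_true(all(out >= 0 & out <= 1))

  # on an all-zero image the surviving positive values follow a half-normal:
  # their mean is sigma * sqrt(2/pi) = 0.0399 for sigma = 0.05
  zeros <- matrix(0, 120, 120)
  set.seed(11)
  noisy <- add_noise(zeros, 0.05)
  expect_true(all(noisy >= 0 & noisy <= 1))
  pos <- noisy[noisy > 0]
  half_normal_mean <- 0.05 * sqrt(2 / pi)
  se <- 0.05 * sqrt(1 - 2 / pi) / sqrt(length(pos))
  expect_lt(abs(mean(pos) - half_normal_mean), 3 * se)
})

test_that("blocked streams emit contiguous runs in variant order", {
  st <- stimulus_set("B")
  stream <- build_stream(st, "blocked", block_size = 100, n_steps = 400,
                         seed = 3)
  expect_equal(nrow(stream), 400)
  expect_equal(stream$variation[1:100], rep(1L, 100))
  expect_equal(stream$variation[101:200], rep(2L, 100))
  expect_equal(stream$variation[301:400], rep(4L, 100))
})

test_that("random streams are seed-reproducible and roughly balanced", {
  st <- stimulus_set("A")
  s1 <- build_stream(st, "random", n_steps = 2000, seed = 5)
  s2 <- build_stream(st, "random", n_steps = 2000, seed = 5)
  s3 <- build_stream(st, "random", n_steps = 2000, seed = 6)
  expect_identical(s1$variation, s2$variation)
  expect_identical(s1$noise_seed, s2$noise_seed)
  expect_false(identical(s1$variation, s3$variation))
  # uniform presentation frequencies (chi-square on counts)
  p <- chisq.test(table(s1$variation))$p.value
  expect_gt(p, 1e-4)
})

test_that("stream stimuli are reproducible, noisy, and stay in [0,1]", {
  st <- stimulus_set("A")
  stream <- build_stream(st, "random", n_steps = 5, seed = 9, sigma = 0.05)
  a <- stream_stimulus(stream, 3)
  b <- stream_stimulus(stream, 3)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  clean <- st$image[[which(st$variation == stream$variation[3] &
                             st$category == stream$category[3])]]
  expect_false(identical(a, clean))
  # distinct steps of the same variant get fresh noise
  same_var <- which(stream$variation == stream$variation[3] &
                      stream$step != 3)
  if (length(same_var) > 0) {
    expect_false(identical(a, stream_stimulus(stream, same_var[1])))
  }
})

test_that("stream construction rejects degenerate inputs", {
  st <- stimulus_set("A")
  expect_error(build_stream(st[0, ], "random", n_steps = 5), "non-empty")
  expect_error(build_stream(st, "random", n_steps = 0), ">= 1")
})

test_that("PGM round-trip preserves images", {
  img <- render_square_variant(1)
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- read_pgm(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 254)
  unlink(path)
})
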