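spec_for <- function(L = 60, ...) {
  m <- contact_map(data.frame(i = 1, j = L), seq_length = L)
  figure_spec(m, ...)
}

const_track <- function(L, label = "x", colour = "red", name = "t") {
  annotation_track(rep(label, L), stats::setNames(colour, label), name = name)
}

test_that("exactly nine slots are addressable, -4..+4 with 0 the diagonal", {
  slots <- track_slots(spec_for())
  expect_equal(nrow(slots), 9)
  expect_equal(slots$slot, -4:4)
  expect_equal(slots$diagonal, slots$slot == 0)
})

test_that("track assignment validates slot, length and occupancy", {
  sp <- spec_for(50)
  tr <- const_track(50)
  expect_error(assign_track(sp, 5, tr), "-4 to \\+4")
  expect_error(assign_track(sp, -5, tr), "-4 to \\+4")
  expect_error(assign_track(sp, 1, const_track(60)), "length 60.*50")

  sp <- assign_track(sp, 1, tr)
  expect_error(assign_track(sp, 1, tr), "occupied")
  expect_silent(assign_track(sp, 1, tr, overwrite = TRUE))

  mirrored <- assign_track(spec_for(50), 2, tr, mirror = TRUE)
  st <- track_slots(mirrored)
  expect_true(st$occupied[st$slot == 2])
  expect_true(st$occupied[st$slot == -2])
  expect_true(st$mirrored[st$slot == -2])
  expect_false(st$mirrored[st$slot == 2])

  diag <- assign_track(spec_for(50), 0, tr, mirror = TRUE)
  expect_equal(sum(track_slots(diag)$occupied), 1)  # 0 is self-mirrored
})

test_that("slot bands sit at offset k*w, are mirror images, and never overlap", {
  g0 <- slot_geometry(0, 100, 2)
  off <- attr(g0, "offsets")
  expect_equal(unname(off), c(-1, 1))
  # centered on the diagonal: vertices symmetric under (x,y) swap
  expect_setequal(round(g0$x, 9), round(g0$y, 9))

  gp <- slot_geometry(1, 100, 2)
  gm <- slot_geometry(-1, 100, 2)
  expect_setequal(paste(round(gp$x, 9), round(gp$y, 9)),
                  paste(round(gm$y, 9), round(gm$x, 9)))

  # rasterization oracle at w = 1 on L = 100: each integer cell claims <= 1 slot
  grid <- expand.grid(i = 1:100, j = 1:100)
  d <- grid$j - grid$i
  claims <- vapply(-4:4, function(k) {
    lohi <- conmapr:::slot_offsets(k, 1)
    d >= lohi[["lo"]] & d < lohi[["hi"]]
  }, logical(nrow(grid)))
  expect_true(all(rowSums(claims) <= 1))
  claimed <- apply(claims, 1, function(r) if (any(r)) (-4:4)[which(r)] else NA_integer_)
  expect_identical(unname(claimed), slot_at_offset(d, 1))
})

test_that("a superposition renders as three point layers in black/red/grey", {
  a <- contact_map(data.frame(i = c(1, 2), j = c(30, 40)), seq_length = 60)
  b <- contact_map(data.frame(i = c(1, 5), j = c(30, 50)), seq_length = 60)
  cls <- superpose_maps(a, b, min_sep = 0)
  scene <- build_figure(figure_spec(cls))
  layers <- unique(scene$points[c("layer", "colour")])
  expect_setequal(layers$layer, c("matched", "model_only", "predicted_only"))
  expect_setequal(layers$colour, c("black", "red", "grey"))
})

test_that("track segments equal the maximal constant runs", {
  topo <- read_topcons("ooMMMiii")
  m <- contact_map(data.frame(i = 1, j = 8), seq_length = 8)
  sp <- assign_track(figure_spec(m, min_sep = 2), 0, topo)
  scene <- build_figure(sp)
  segs <- unique(scene$tracks[c("id", "label")])
  expect_equal(nrow(segs), 3)
  expect_equal(segs$label, c("outside", "membrane", "inside"))

  set.seed(8)
  for (rep in 1:5) {
    L <- 40
    states <- sample(c("A", "B"), L, replace = TRUE)
    tr <- annotation_track(states, c(A = "red", B = "blue"))
    # the inner slots are never clipped: segment count == run count exactly
    sp <- assign_track(spec_for(L, min_sep = 10), sample(-1:1, 1), tr)
    scene <- build_figure(sp)
    expect_equal(length(unique(scene$tracks$id)), length(rle(states)$lengths))

    # outer slots: runs survive iff their band rectangle, parameterized by
    # along-diagonal position s and offset d, overlaps the plot square on
    # every separating axis (x, y; the s and d axes always overlap here)
    k <- sample(c(-4, -3, 3, 4), 1)
    sp2 <- assign_track(spec_for(L, min_sep = 10), k, tr)
    scene2 <- build_figure(sp2)
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    w <- 2
    dlo <- k * w - w / 2
    dhi <- k * w + w / 2
    visible <- (ends + 0.5 - dlo / 2 > 0.5) &
      (starts - 0.5 + dlo / 2 < L + 0.5) &
      (starts - 0.5 - dhi / 2 < L + 0.5) &
      (ends + 0.5 + dhi / 2 > 0.5)
    expect_equal(length(unique(scene2$tracks$id)), sum(visible))
  }
})

test_that("an empty figure refuses to build", {
  sp <- figure_spec(seq_length = 30)
  expect_error(build_figure(sp), "nothing to draw")
})

test_that("a symmetric single-map scene is transposition invariant", {
  set.seed(4)
  m <- random_contact_map(80, 40)
  scene <- build_figure(figure_spec(m, min_sep = 5))
  pts <- paste(scene$points$x, scene$points$y)
  swapped <- paste(scene$points$y, scene$points$x)
  expect_setequal(pts, swapped)
})

test_that("contacts inside the blanking zone are excluded from point layers", {
  m <- contact_map(data.frame(i = c(1, 1), j = c(3, 20)), seq_length = 30)
  scene <- build_figure(figure_spec(m, min_sep = 5))
  expect_true(all(abs(scene$points$x - scene$points$y) >= 5))
  expect_equal(nrow(scene$points), 2)  # (1,20) drawn in both triangles
})

test_that("track layers of distinct slots never claim the same grid cell", {
  L <- 50
  sp <- spec_for(L, min_sep = 10)
  for (k in -4:4) {
    sp <- assign_track(sp, k, const_track(L, name = paste0("t", k)))
  }
  scene <- build_figure(sp)
  grid <- expand.grid(i = 1:L, j = 1:L)
  counts <- integer(nrow(grid))
  for (id in unique(scene$tracks$id)) {
    poly <- scene$tracks[scene$tracks$id == id, ]
    slot <- poly$slot[1]
    lohi <- conmapr:::slot_offsets(slot, 2)
    d <- grid$j - grid$i
    inside <- d >= lohi[["lo"]] & d < lohi[["hi"]]
    counts <- counts + inside
  }
  expect_true(all(counts <= 1))
})

test_that("tracks that would overlap plotted contacts trigger a warning", {
  m <- contact_map(data.frame(i = 1, j = 8), seq_length = 40)
  sp <- assign_track(figure_spec(m, min_sep = 5), 4, const_track(40))
  expect_warning(build_figure(sp), "overlap")
  sp_far <- assign_track(figure_spec(m, min_sep = 10), 4, const_track(40))
  expect_silent(build_figure(sp_far))
})

test_that("heatmap mode colours cells by probability or expected distance", {
  m <- contact_map(data.frame(i = c(1, 2), j = c(20, 30),
                              score = c(0.9, 0.2)), seq_length = 40)
  scene <- build_figure(figure_spec(m, mode = "heatmap"))
  expect_equal(nrow(scene$cells), 4)  # two pairs, both triangles
  expect_setequal(scene$cells$value, c(0.9, 0.2))

  one_hot <- function(bin) { v <- numeric(10); v[bin] <- 1; v }
  d <- distogram(tibble::tibble(i = c(1, 2), j = c(20, 30),
                                probs = list(one_hot(1), one_hot(10))),
                 seq_length = 40)
  sd <- build_figure(figure_spec(d, mode = "heatmap"))
  # expected distance: mid of (0,4] = 2; open bin (20,Inf) counted at 22
  expect_setequal(sd$cells$value, c(2, 22))

  cls <- superpose_maps(m, m, min_sep = 0)
  expect_error(figure_spec(cls, mode = "heatmap"), "heatmap mode requires")
})
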