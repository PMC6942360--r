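test_that("patch counts follow round(side^2 * cover / mean_area)", {
  # the ~1000-ha arena yields 100/200/400 patches at 5/10/20% cover
  expect_equal(n_patches(generate_landscape(cover = 0.05, seed = 1)), 100)
  expect_equal(n_patches(generate_landscape(cover = 0.20, seed = 1)), 400)
  # small arena: 100 ha, 25% cover, 0.5-ha patches -> 50
  expect_equal(n_patches(small_landscape(seed = 2)), 50)
})

test_that("generation is reproducible for a fixed seed and varies otherwise", {
  a <- small_landscape(seed = 7)
  b <- small_landscape(seed = 7)
  expect_identical(a$patches, b$patches)
  c <- small_landscape(seed = 8)
  expect_false(identical(a$patches$x, c$patches$x))
})

test_that("patches respect arena bounds, positivity and edge spacing", {
  L <- small_landscape(seed = 3)
  p <- L$patches
  expect_true(all(p$area > 0))
  expect_true(all(p$age >= 0))
  expect_true(all(p$x >= 0 & p$x <= L$side & p$y >= 0 & p$y <= L$side))
  d <- distance_matrix(L)
  r <- patch_radius(p$area)
  required <- outer(r, r, `+`) + L$min_dist
  diag(required) <- 0
  expect_true(all(d >= required - 1e-9))
})

test_that("initial age modes give uniform or zero ages", {
  Lu <- small_landscape(seed = 4)
  expect_true(all(Lu$patches$age >= 0 & Lu$patches$age <= 100))
  expect_gt(length(unique(Lu$patches$age)), 5)
  Lz <- small_landscape(seed = 4, initial_age_mode = "zero")
  expect_true(all(Lz$patches$age == 0))
})

test_that("sampled patch areas match the truncated-normal target", {
  set.seed(42)
  areas <- spomdyn:::sample_patch_areas(10000, 0.5, 0.2)
  expect_true(all(areas > 0))
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - 0.5), 3 * se)
})

test_that("overcrowded parameterizations fail with a clear diagnostic", {
  expect_error(
    generate_landscape(side = 200, cover = 0.9, mean_area = 0.5,
                       sd_area = 0.05, min_dist = 10, seed = 1,
                       max_tries = 50),
    "too crowded"
  )
})

test_that("distance matrix is symmetric, zero-diagonal, Euclidean", {
  L3 <- triangle_landscape()
  d <- distance_matrix(L3)
  expect_equal(d[1, 2], 300)
  expect_equal(d[1, 3], 400)
  expect_equal(d[2, 3], 500) # 3-4-5 triangle
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))

  L1 <- as_landscape(data.frame(id = 1, x = 5, y = 5, area = 1, age = 0),
                     side = 10)
  expect_equal(distance_matrix(L1), matrix(0, 1, 1, dimnames = list(1, 1)))

  L <- small_landscape(seed = 5)
  d <- distance_matrix(L)
  # triangle inequality on a sample of triples
  set.seed(1)
  for (k in 1:200) {
    ijk <- sample(nrow(d), 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("turnover conserves patch count and retires destroyed ids", {
  L <- generate_landscape(cover = 0.10, seed = 6) # 200 patches
  tv <- apply_turnover(L, 0.10, seed = 7)
  expect_length(tv$destroyed_ids, 20)
  expect_length(tv$created_ids, 20)
  expect_equal(n_patches(tv$landscape), 200)
  expect_true(all(!tv$destroyed_ids %in% tv$landscape$patches$id))
  expect_true(all(tv$created_ids > max(L$patches$id) - 1L))
  expect_true(all(tv$landscape$patches$age[
    tv$landscape$patches$id %in% tv$created_ids] == 0))
  expect_false(anyDuplicated(tv$landscape$patches$id) > 0)

  # count conserved across the whole fraction range
  Ls <- small_landscape(seed = 8)
  for (f in c(0, 0.03, 0.27, 0.5, 1)) {
    expect_equal(n_patches(apply_turnover(Ls, f, seed = 9)$landscape),
                 n_patches(Ls))
  }
})

test_that("full turnover replaces every id and resets every age", {
  L <- small_landscape(seed = 10)
  tv <- apply_turnover(L, 1, seed = 11)
  expect_length(intersect(L$patches$id, tv$landscape$patches$id), 0)
  expect_true(all(tv$landscape$patches$age == 0))
})

test_that("zero turnover is a no-op", {
  L <- small_landscape(seed = 12)
  tv <- apply_turnover(L, 0, seed = 13)
  expect_identical(tv$landscape$patches, L$patches)
  expect_length(tv$destroyed_ids, 0)
})

test_that("new patch areas keep habitat cover approximately constant", {
  L <- generate_landscape(cover = 0.10, seed = 14)
  cov0 <- realized_cover(L)
  tv <- L
  set.seed(15)
  for (t in 1:20) tv <- apply_turnover(tv, 0.2)$landscape
  expect_lt(abs(realized_cover(tv) - cov0), 0.02)
})

test_that("original-patch survival matches (1 - f)^T on average", {
  f <- 0.1
  T_steps <- 5
  n_rep <- 200
  L <- small_landscape(seed = 16) # 50 patches
  ids0 <- L$patches$id
  set.seed(17)
  surv <- replicate(n_rep, {
    Lt <- L
    for (t in seq_len(T_steps)) Lt <- apply_turnover(Lt, f)$landscape
    sum(ids0 %in% Lt$patches$id)
  })
  p_surv <- (1 - f)^T_steps
  expected <- n_patches(L) * p_surv
  se <- sqrt(n_patches(L) * p_surv * (1 - p_surv) / n_rep)
  expect_lt(abs(mean(surv) - expected), 3 * se)
})

test_that("aging increments every age by one and nothing else", {
  L <- triangle_landscape(ages = c(3L, 7L, 0L))
  L2 <- advance_age(L)
  expect_equal(L2$patches$age, c(4L, 8L, 1L))
  expect_identical(L2$patches[, c("id", "x", "y", "area")],
                   L$patches[, c("id", "x", "y", "area")])
  for (i in 1:99) L2 <- advance_age(L2)
  expect_equal(L2$patches$age, c(103L, 107L, 100L))
})

test_that("landscapes round-trip through the delimited table format", {
  L <- small_landscape(seed = 18)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(L, path)
  L2 <- read_landscape(path, side = L$side, cover = L$target_cover,
                       mean_area = L$mean_area, sd_area = L$sd_area,
                       min_dist = L$min_dist)
  expect_equal(L2$patches, L$patches, tolerance = 1e-12)
  expect_error(read_landscape(path, side = 1), "x") # coords out of bounds
})

test_that("GeoJSON export writes one polygon feature per patch", {
  L <- triangle_landscape()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_landscape_geojson(L, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 3)
  expect_equal(gj$features[[2]]$properties$id, 2)
})
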