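test_that("position ranking matches a brute-force somatotopic sort", {
  grid <- dc_fiber_grid()
  rp <- rank_positions(grid)
  expect_length(rp$tiers, 3)
  expect_true(all(vapply(rp$tiers, nrow, 1L) == 20))
  # the origin (most medial, most dorsal) leads tier 1
  expect_equal(rp$tiers[[1]]$X[1], 0)
  expect_equal(rp$tiers[[1]]$Y[1], 0)
  # exhaustive oracle on a 10 x 10 unit lattice
  g10 <- dc_fiber_grid(10, 10)
  z <- g10$X^0.15 + g10$Y^0.45
  ord <- order(z, g10$X, g10$Y)
  rp10 <- rank_positions(g10)
  for (k in 1:3) {
    expect_equal(rp10$tiers[[k]]$index,
                 g10$index[ord[((k - 1) * 20 + 1):(k * 20)]])
  }
  expect_error(rank_positions(rbind(g10, g10)), "duplicate")
  expect_error(rank_positions(g10[1:30, ]), "at least")
})

test_that("map sampling wires tiers to zones per targeting and is seed-deterministic", {
  tiers <- rank_positions(dc_fiber_grid())$tiers
  m_center <- sample_map(tiers, "center", seed = 3)
  m_surr <- sample_map(tiers, "surround", seed = 3)
  m_mix <- sample_map(tiers, "mix", seed = 3)
  for (m in list(m_center, m_surr, m_mix)) {
    expect_equal(as.integer(table(m$fibers$zone)), c(15L, 15L, 15L))
    expect_true(all(m$fibers$diameter_um >= 2.2 & m$fibers$diameter_um <= 8))
    # tier exclusivity: no position in two zones
    expect_false(anyDuplicated(m$fibers$index) > 0)
  }
  expect_true(all(m_center$fibers$zone[m_center$fibers$tier == 1] == 1))
  expect_true(all(m_surr$fibers$zone[m_surr$fibers$tier == 1] == 2))
  expect_true(all(m_surr$fibers$zone[m_surr$fibers$tier == 2] == 1))
  # mix: exactly 8 tier-1 fibers to zone 1 and 7 to zone 2
  t1 <- m_mix$fibers[m_mix$fibers$tier == 1, ]
  expect_equal(sum(t1$zone == 1), 8)
  expect_equal(sum(t1$zone == 2), 7)
  t2 <- m_mix$fibers[m_mix$fibers$tier == 2, ]
  expect_equal(sum(t2$zone == 1), 7)
  expect_equal(sum(t2$zone == 2), 8)
  # determinism and seed sensitivity
  expect_identical(sample_map(tiers, "center", seed = 3)$fibers,
                   m_center$fibers)
  expect_false(identical(sample_map(tiers, "center", seed = 4)$fibers$index,
                         m_center$fibers$index))
  expect_error(sample_map(tiers, "nonsense"), "arg")
  # 25 maps by default
  expect_length(sample_maps(tiers, "center"), 25)
})

test_that("fiber diameters realize the published mean and SD", {
  set.seed(202)
  d <- draw_fiber_diameters(1e5)
  expect_equal(mean(d), 4.4, tolerance = 0.02 / 4.4)
  expect_equal(sd(d), 1.0, tolerance = 0.02)
  expect_true(all(d >= 2.2 & d <= 8))
  # moment-matching oracle: numeric integration of the matched density
  p <- scsdh:::truncnorm_matched(4.4, 1.0, 2.2, 8)
  mm <- scsdh:::truncnorm_moments(p[["mu"]], p[["sigma"]], 2.2, 8)
  expect_equal(unname(mm["mean"]), 4.4, tolerance = 1e-6)
  expect_equal(unname(mm["sd"]), 1.0, tolerance = 1e-6)
})

test_that("maps serialize to JSON and back", {
  tiers <- rank_positions(dc_fiber_grid())$tiers
  m <- sample_map(tiers, "mix", seed = 9)
  path <- tempfile(fileext = ".json")
  write_dc_map(m, path)
  m2 <- read_dc_map(path)
  expect_equal(m2$targeting, "mix")
  expect_equal(m2$fibers$index, m$fibers$index)
  expect_equal(m2$fibers$diameter_um, m$fibers$diameter_um)
})

test_that("map-to-network wiring resolves the library and keeps determinism", {
  grid <- dc_fiber_grid()
  tiers <- rank_positions(grid)$tiers
  map <- sample_map(tiers, "center", seed = 5)
  lib <- fake_library(grid)
  # below-threshold amplitude: all 45 trains empty
  z40 <- map_to_network_inputs(map, lib, 90, 225, 40)
  expect_true(all(vapply(unlist(z40, recursive = FALSE), length, 1L) == 0))
  # suprathreshold amplitude: trains attached to every zone slot
  z80 <- map_to_network_inputs(map, lib, 90, 225, 80)
  expect_length(z80, 3)
  expect_true(all(vapply(z80, length, 1L) == 15))
  expect_true(all(vapply(unlist(z80, recursive = FALSE), length, 1L) == 2))
  expect_identical(z80, map_to_network_inputs(map, lib, 90, 225, 80))
  # empty library rejected
  empty_lib <- fake_library(grid)
  rm(list = ls(empty_lib$entries), envir = empty_lib$entries)
  expect_error(map_to_network_inputs(map, empty_lib, 90, 225, 80), "empty")
})
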