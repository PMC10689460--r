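test_that("grid_row is a bijection of the 440 off-centre cells onto [0, 440)", {
  rows <- integer(0)
  for (y in -10:10) for (x in -10:10) {
    if (x == 0 && y == 0) next
    r <- grid_row(x, y)
    expect_identical(grid_row_inverse(r), c(x, y))
    rows <- c(rows, r)
  }
  expect_length(rows, 440)
  expect_equal(sort(rows), 0:439)
  expect_equal(grid_row(-10, -10), 0L)
  expect_equal(grid_row(10, 10), 439L)
  expect_error(grid_row(0, 0), "centre")
  expect_error(grid_row(11, 0), "range")
})

test_that("the distance-2 neighbourhood has 12 offsets plus centre (Delannoy 13)", {
  offs <- neighbour_offsets()
  expect_equal(nrow(offs), 12)
  # recompute by enumeration: cells with Manhattan distance <= 2 number 13
  cells <- expand.grid(dx = -2:2, dy = -2:2)
  cells <- cells[abs(cells$dx) + abs(cells$dy) <= 2, ]
  expect_equal(nrow(cells), 13)
  cols <- mapply(slot_for_offset, offs$dx, offs$dy)
  expect_equal(sort(cols), 0:11)
  expect_equal(slot_for_offset(0, 0, same_coord = TRUE), 12L)
  expect_error(slot_for_offset(0, 3), "neighbourhood")
  expect_error(slot_for_offset(0, 0), "neighbourhood")
})

test_that("develop/encode round-trip is exact in both directions", {
  set.seed(4)
  b <- decode_body(fixture_cppn("plus"))
  g <- random_brain_genome()
  n <- develop_brain(g, b)
  expect_identical(unclass(encode_brain(n, b, g)), unclass(g))
  n2 <- develop_brain(encode_brain(n, b, g), b)
  expect_identical(n2$w_internal, n$w_internal)
  expect_identical(n2$coupling, n$coupling)
})

test_that("develop reads the documented rows, slots and antisymmetry", {
  b <- decode_body(fixture_cppn("plus"))
  g <- brain_genome(0)
  gm <- unclass(g)
  # joint decode order: (0,1), (0,-1), (-1,0), (1,0)
  gm[grid_row(0, 1) + 1, 14] <- 0.7                          # internal of joint 1
  gm[grid_row(0, 1) + 1, slot_for_offset(0, -2) + 1] <- 0.3  # (0,1) -> (0,-1)
  gm[grid_row(0, 1) + 1, slot_for_offset(-1, -1) + 1] <- -0.2 # (0,1) -> (-1,0)
  n <- develop_brain(brain_genome(gm), b)
  expect_equal(n$w_internal, c(0.7, 0, 0, 0))
  expect_equal(n$coupling[1, 2], 0.3)
  expect_equal(n$coupling[2, 1], -0.3)
  expect_equal(n$coupling[1, 3], -0.2)
  expect_equal(n$coupling[3, 1], 0.2)
})

test_that("all-zero genome develops into an all-zero network", {
  b <- decode_body(fixture_cppn("plus"))
  n <- develop_brain(brain_genome(0), b)
  expect_true(all(n$w_internal == 0))
  expect_true(all(n$coupling == 0))
  # core-only body -> empty network
  n0 <- develop_brain(brain_genome(0), decode_body(fixture_cppn("core_only")))
  expect_equal(n0$n, 0)
})

test_that("write-back touches exactly the expressed entries", {
  b <- decode_body(fixture_cppn("plus"))
  g <- brain_genome(0)
  n <- develop_brain(g, b)
  n <- set_network_weights(n, c(rep(1, 4), rep(2, 6)))
  g2 <- encode_brain(n, b, g)
  # 4 internal entries + one entry per neighbour pair (all 6 pairs neighbours)
  expect_equal(sum(unclass(g2) != 0), 4 + 6)
})

test_that("joints stacked in z share a row and use the same-coordinate slot", {
  b <- stacked_z_body()
  g <- brain_genome(0)
  gm <- unclass(g)
  gm[grid_row(0, 1) + 1, 13] <- 0.9   # same-coordinate slot (column 12)
  n <- develop_brain(brain_genome(gm), b)
  expect_equal(n$n, 2)
  expect_equal(n$coupling[1, 2], 0.9)
  expect_equal(n$coupling[2, 1], -0.9)
})

test_that("uniform crossover picks each entry from either parent with p 1/2", {
  set.seed(8)
  g1 <- brain_genome(1)
  g2 <- brain_genome(2)
  expect_identical(unclass(uniform_crossover_brain(g1, g1)), unclass(g1))
  child <- uniform_crossover_brain(g1, g2)
  expect_true(all(unclass(child) %in% c(1, 2)))
  frac <- mean(unclass(child) == 1)
  # binomial 99.9% CI at n = 6160 around 0.5
  expect_lt(abs(frac - 0.5), 3.3 * sqrt(0.25 / 6160))
  set.seed(99); c1 <- uniform_crossover_brain(g1, g2)
  set.seed(99); c2 <- uniform_crossover_brain(g1, g2)
  expect_identical(c1, c2)
})

test_that("gaussian mutation perturbs ~80% of entries with sd 0.5 noise", {
  set.seed(12)
  g <- brain_genome(0)
  expect_identical(gaussian_mutate_brain(g, p = 0), g)
  m <- unclass(gaussian_mutate_brain(g, p = 0.8, sd = 0.5))
  changed <- m != 0
  n <- length(m)  # 6160 entries
  expect_lt(abs(mean(changed) - 0.8), 3.3 * sqrt(0.8 * 0.2 / n))
  deltas <- m[changed]
  expect_lt(abs(mean(deltas)), 3.3 * 0.5 / sqrt(sum(changed)))
  expect_lt(abs(sd(deltas) - 0.5), 0.03)
})

test_that("variation never changes the table shape and keeps entries finite", {
  set.seed(30)
  g <- random_brain_genome()
  for (i in 1:20) {
    g <- gaussian_mutate_brain(uniform_crossover_brain(g, random_brain_genome()))
    expect_equal(dim(unclass(g)), c(440, 14))
    expect_true(all(is.finite(unclass(g))))
  }
})

test_that("neighbouring joints of decoded bodies are always addressable", {
  # tree distance <= 2 implies 2D Manhattan offset <= 2 or same coordinate
  set.seed(77)
  for (i in 1:100) {
    b <- random_body()
    ue <- lamevo:::.used_entries(b)
    expect_true(all(ue$col >= 0 & ue$col <= 13))
    expect_true(all(ue$row >= 0 & ue$row <= 439))
  }
})

test_that("brain genome CSV and JSON round-trip bit-exactly", {
  set.seed(2)
  g <- random_brain_genome()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_brain_csv(g, path)
  expect_identical(as.numeric(unclass(read_brain_csv(path))),
                   as.numeric(unclass(g)))
  expect_identical(as.numeric(unclass(brain_from_json(brain_to_json(g)))),
                   as.numeric(unclass(g)))
})
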