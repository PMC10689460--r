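test_that("random CPPN generation is deterministic and respects arity", {
  g1 <- random_cppn(seed = 42)
  g2 <- random_cppn(seed = 42)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$conns), 20)  # fully connected: 4 inputs x 5 outputs
  expect_equal(sum(g1$nodes$type == "input"), 4)
  expect_equal(sum(g1$nodes$type == "output"), 5)
})

test_that("random genomes satisfy the genome invariants in bulk", {
  set.seed(11)
  for (i in 1:500) {
    g <- random_cppn()
    expect_silent(validate_cppn(g))
  }
})

test_that("CPPN queries are deterministic and ties break by output order", {
  g <- random_cppn(seed = 3)
  q1 <- query_cppn(g, 1, 2, 0, 2)
  q2 <- query_cppn(g, 1, 2, 0, 2)
  expect_identical(q1, q2)
  # all-zero genome: every output is 0, argmax tie -> first in fixed order
  zero <- cppn_genome(
    data.frame(id = 1:9, type = c(rep("input", 4), rep("output", 5)),
               act = "linear", bias = 0),
    data.frame(src = integer(), dst = integer(), weight = numeric(),
               enabled = logical(), innov = numeric()))
  b <- decode_body(zero)
  # brick wins the type tie everywhere, rotation 0 wins the rotation tie
  expect_true(all(b$modules$kind[-1] == "brick"))
  expect_true(all(b$modules$rotation == 0))
  expect_equal(module_count(b), 10)  # grows until the module cap
})

test_that("fixture genomes decode to their documented bodies", {
  b1 <- decode_body(fixture_cppn("core_only"))
  expect_equal(module_count(b1), 0)
  expect_equal(b1$modules$kind, "core")

  b2 <- decode_body(fixture_cppn("plus"))
  expect_equal(module_count(b2), 4)
  expect_true(all(b2$modules$kind[-1] == "active_hinge"))
  got <- b2$modules[-1, c("x", "y", "z")]
  expect_setequal(paste(got$x, got$y, got$z),
                  c("0 1 0", "0 -1 0", "-1 0 0", "1 0 0"))

  b3 <- decode_body(fixture_cppn("chain10"))
  expect_equal(module_count(b3), 10)
  expect_equal(b3$modules$y, 0:10)
  expect_true(all(b3$modules$x == 0 & b3$modules$z == 0))
})

test_that("a module attached to the front of the core sits at (0,1,0)", {
  b <- decode_body(fixture_cppn("chain10"))
  first <- b$modules[2, ]
  expect_equal(c(first$x, first$y, first$z), c(0, 1, 0))
  expect_equal(first$depth, 1)
})

test_that("decoded bodies satisfy the body invariants under mutation", {
  set.seed(21)
  g <- fixture_cppn("plus")
  for (i in 1:300) {
    g2 <- mutate_body(g, body_mutation_rates(p_mutate = 1))
    b <- decode_body(g2)
    expect_silent(validate_body(b))
    expect_lte(module_count(b), 10)
  }
})

test_that("zero-rate mutation and self-crossover are the identity on the body", {
  g <- random_cppn(seed = 9)
  expect_identical(mutate_body(g, body_mutation_rates(p_mutate = 0)), g)
  set.seed(1)
  child <- crossover_body(g, g, p_cross = 1)
  expect_identical(body_to_json(decode_body(child)),
                   body_to_json(decode_body(g)))
})

test_that("crossover children keep all matching genes and stay valid", {
  set.seed(5)
  g1 <- random_cppn()
  g2 <- random_cppn()
  for (i in 1:200) {
    child <- crossover_body(g1, g2, f1 = 1, f2 = 0, p_cross = 1)
    expect_silent(validate_cppn(child))
    expect_setequal(child$conns$innov, g1$conns$innov)
  }
  # crosses of mutated parents also stay valid
  for (i in 1:100) {
    m1 <- mutate_body(g1, body_mutation_rates(p_mutate = 1))
    m2 <- mutate_body(g2, body_mutation_rates(p_mutate = 1))
    expect_silent(validate_cppn(crossover_body(m1, m2, p_cross = 1)))
  }
})

test_that("add-connection on a saturated minimal genome leaves it unchanged", {
  g <- random_cppn(seed = 2)  # fully connected, no hidden nodes
  set.seed(3)
  g2 <- lamevo:::.add_connection(g)
  expect_identical(g2, g)
})

test_that("2D projection keys joints by (x, y) and preserves z-collisions", {
  plus <- decode_body(fixture_cppn("plus"))
  pj <- project_2d(plus)
  expect_setequal(names(pj), c("0,1", "0,-1", "-1,0", "1,0"))
  expect_true(all(lengths(pj) == 1))

  expect_length(project_2d(decode_body(fixture_cppn("core_only"))), 0)

  stacked <- stacked_z_body()
  ps <- project_2d(stacked)
  expect_equal(names(ps), "0,1")
  expect_length(ps[["0,1"]], 2)
})

test_that("body JSON serialization round-trips", {
  for (f in c("plus", "chain10")) {
    b <- decode_body(fixture_cppn(f))
    b2 <- body_from_json(body_to_json(b))
    expect_equal(b2$modules[, c("kind", "x", "y", "z", "rotation", "depth")],
                 b$modules[, c("kind", "x", "y", "z", "rotation", "depth")])
    expect_identical(body_to_json(b2), body_to_json(b))
  }
})

test_that("shipped fixture files match the constructors", {
  for (f in c("core_only", "plus", "chain10")) {
    path <- system.file("extdata", paste0("fixture_", f, ".json"),
                        package = "lamevo")
    g <- cppn_from_json(paste(readLines(path), collapse = ""))
    expect_identical(body_to_json(decode_body(g)),
                     body_to_json(decode_body(fixture_cppn(f))))
    bpath <- system.file("extdata", paste0("body_", f, ".json"),
                         package = "lamevo")
    expect_identical(paste(readLines(bpath), collapse = ""),
                     as.character(body_to_json(decode_body(g))))
  }
})
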