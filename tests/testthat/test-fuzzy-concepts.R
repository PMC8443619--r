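# Interval type-2 conceptual labels: evaluation, repair, fuzzification.

test_that("membership intervals follow shoulder semantics and interpolate linearly", {
  mf <- it2_mf("left_shoulder", upper = c(0, 1), lower = c(0, 0.5))
  expect_equal(membership_interval(mf, -1), list(lower = 1, upper = 1))
  expect_equal(membership_interval(mf, 2), list(lower = 0, upper = 0))
  # hand interpolation of each bound independently
  expect_equal(membership_interval(mf, 0.25), list(lower = 0.5, upper = 0.75))

  # dense-grid numeric oracle: each bound is the linear interpolant of its
  # own breakpoints
  g <- seq(-0.5, 1.5, by = 0.01)
  mu <- membership_interval(mf, g)
  expect_equal(mu$upper, approx(c(0, 1), c(1, 0), g, rule = 2)$y)
  expect_equal(mu$lower, approx(c(0, 0.5), c(1, 0), g, rule = 2)$y)

  up <- it2_mf("right_shoulder", upper = c(0, 1), lower = c(0.5, 1))
  expect_equal(membership_interval(up, -1), list(lower = 0, upper = 0))
  expect_equal(membership_interval(up, 2), list(lower = 1, upper = 1))
  expect_equal(membership_interval(up, 0.75), list(lower = 0.5, upper = 0.75))

  tz <- it2_mf("trapezium", upper = c(0, 1, 2, 3), lower = c(0.5, 1, 2, 2.5))
  expect_equal(membership_interval(tz, 1.5), list(lower = 1, upper = 1))
  expect_equal(membership_interval(tz, 0.5), list(lower = 0, upper = 0.5))
  expect_equal(membership_interval(tz, 2.75), list(lower = 0, upper = 0.25))
})

test_that("degenerate zero-width edges evaluate as steps, not errors", {
  mf <- it2_mf("left_shoulder", c(1, 1), c(1, 1))
  expect_equal(membership_interval(mf, c(0.999, 1, 1.001)),
               list(lower = c(1, 1, 0), upper = c(1, 1, 0)))
  tz <- it2_mf("trapezium", c(0, 0, 2, 2), c(0, 0, 2, 2))
  expect_equal(membership_interval(tz, c(-0.1, 0, 2, 2.1)),
               list(lower = c(0, 1, 1, 0), upper = c(0, 1, 1, 0)))
})

test_that("constructor rejects malformed parameters", {
  expect_error(it2_mf("left_shoulder", c(0, 1, 2), c(0, 1)), "breakpoints")
  expect_error(it2_mf("trapezium", c(0, 1), c(0, 1)), "breakpoints")
  expect_error(it2_mf("left_shoulder", c(1, 0), c(0, 1)), "non-decreasing")
  expect_error(it2_mf("left_shoulder", c(0, NaN), c(0, 1)), "finite")
  expect_error(it2_mf("left_shoulder", c(0, 1), c(0.5, 1.5)), "nested")
  expect_error(membership_interval(it2_mf("left_shoulder", 0:1, 0:1), NA),
               "NA")
})

test_that("repair sorts, nests, and is idempotent", {
  # already-valid parameters pass through unchanged
  mf <- repair_mf("trapezium", c(0, 1, 2, 3), c(0.5, 1.2, 1.8, 2.5))
  mf2 <- repair_mf("trapezium", mf$upper, mf$lower)
  expect_identical(mf, mf2)
  # reversed pair is sorted
  expect_equal(repair_mf("left_shoulder", c(1, 0), c(0, 0))$upper, c(0, 1))
  # lower support exceeding upper support gets clipped into it
  mf <- repair_mf("left_shoulder", c(0, 1), c(0.5, 2))
  expect_true(nesting_holds(mf))
  expect_true(all(mf$lower <= mf$upper))
})

test_that("repair enforces nesting and idempotence over random draws", {
  set.seed(71)
  for (i in 1:300) {
    shape <- sample(c("left_shoulder", "trapezium", "right_shoulder"), 1)
    np <- if (shape == "trapezium") 4L else 2L
    u <- rnorm(np, 0, 3); l <- rnorm(np, 0, 3)
    mf <- repair_mf(shape, u, l)
    expect_true(nesting_holds(mf))
    expect_identical(repair_mf(shape, mf$upper, mf$lower), mf)
  }
})

test_that("evaluation at a breakpoint equals the limit from both sides", {
  set.seed(8)
  for (i in 1:50) {
    mf <- random_mf()
    for (b in unique(c(mf$upper, mf$lower))) {
      at <- membership_interval(mf, b)
      eps <- 1e-9
      lo <- membership_interval(mf, b - eps)
      hi <- membership_interval(mf, b + eps)
      for (side in c("lower", "upper")) {
        expect_true(min(lo[[side]], hi[[side]]) - 1e-6 <= at[[side]] &&
                    at[[side]] <= max(lo[[side]], hi[[side]]) + 1e-6)
      }
    }
  }
})

test_that("channel concept sets keep the fixed 16-parameter layout", {
  set.seed(5)
  p <- random_params16()
  cs <- repair_concepts(p, channel_id = 3L)
  expect_s3_class(cs, "channel_concept_set")
  expect_length(concepts_to_vector(cs), 16L)
  # round-trip conserves all values once repaired
  v <- concepts_to_vector(cs)
  expect_identical(concepts_to_vector(repair_concepts(v, 3L)), v)
  expect_error(repair_concepts(p[1:15]), "16")
  expect_error(repair_concepts(replace(p, 4, Inf)), "finite")
})

test_that("bank round-trips its full parameter vector", {
  set.seed(9)
  for (n in c(1L, 3L, 10L)) {
    bank <- vector_to_bank(rnorm(16L * n), seq_len(n))
    v <- bank_to_vector(bank)
    expect_length(v, 16L * n)
    expect_identical(bank_to_vector(vector_to_bank(v, seq_len(n))), v)
  }
  expect_error(vector_to_bank(rnorm(20)), "multiple of 16")
})

test_that("fuzzify matches per-entry membership_interval calls", {
  set.seed(13)
  bank <- vector_to_bank(rnorm(32, 0, 2), 1:2)
  vals <- matrix(rnorm(4, 0, 2), 2, 2)
  m <- mv_matrix(vals, c("A", "B"), channel_ids = 1:2)
  fz <- fuzzify(bank, m)
  expect_equal(dim(fz), c(2L, 2L, 3L, 2L))
  for (i in 1:2) for (j in 1:2) for (k in 1:3) {
    mu <- membership_interval(bank$sets[[j]][[col_levels()[k]]], vals[i, j])
    expect_equal(unname(fz[i, j, k, ]), c(mu$lower, mu$upper))
  }
  expect_true(all(fz >= 0 & fz <= 1))
  expect_error(fuzzify(bank, matrix(0, 2, 3)), "channels")
})

test_that("fuzzify hits the flat top and dead zones exactly", {
  bank <- crisp_bank(1L)
  fz <- fuzzify(bank, matrix(1, 1, 1))          # centre of "active" plateau
  expect_equal(unname(fz[1, 1, "active", ]), c(1, 1))
  # value outside every support of a narrow bank
  narrow <- concept_bank(list(channel_concept_set(
    1,
    inactive = repair_mf("left_shoulder", c(-9, -8), c(-9, -8)),
    active = repair_mf("trapezium", c(-1, 0, 0, 1), c(0, 0, 0, 0)),
    very_active = repair_mf("right_shoulder", c(8, 9), c(8, 9)))))
  fz <- fuzzify(narrow, matrix(5, 1, 1))
  expect_equal(unname(fz[1, 1, , ]), matrix(0, 3, 2))
})

test_that("default_bank spans the data and leaves no trial unlabelled", {
  set.seed(21)
  vals <- cbind(runif(50), runif(50) + 10)      # disjoint channel ranges
  m <- mv_matrix(vals, rep_len(c("A", "B"), 50), channel_ids = 1:2)
  bank <- default_bank(m)
  expect_false(identical(concepts_to_vector(bank$sets[[1]]),
                         concepts_to_vector(bank$sets[[2]])))
  # supports lie within the channel range
  expect_true(all(concepts_to_vector(bank$sets[[1]]) >= 0 &
                  concepts_to_vector(bank$sets[[1]]) <= 1))
  # every observed value carries at least one nonzero upper membership
  fz <- fuzzify(bank, m)
  expect_true(all(apply(fz[, , , "upper"], 1:2, max) > 0))
  expect_error(default_bank(mv_matrix(cbind(rep(1, 5)), rep("A", 5))),
               "constant")
})

test_that("concept bank JSON round-trip is bit-stable", {
  set.seed(33)
  bank <- vector_to_bank(rnorm(48, 0, pi), 1:3)
  path <- withr::local_tempfile(fileext = ".json")
  write_concept_bank(bank, path)
  back <- read_concept_bank(path)
  expect_identical(bank_to_vector(back), bank_to_vector(bank))
  expect_equal(back$channel_ids, bank$channel_ids)
})
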