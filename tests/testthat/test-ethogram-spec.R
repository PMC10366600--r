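test_that("state preset has the documented repertoire and transition range", {
  sp <- make_state_preset()
  expect_identical(sort(names(sp$behaviors)), sprintf("b%02d", 1:10))
  expect_identical(sp$transition_label, "b00")
  expect_identical(sp$transition_range, c(2L, 8L))
  expect_identical(sp$n_features, 1L)
  expect_length(validate_spec(sp), 0L)
  # designed pose geometry: sanity pair far apart, alike pair within one
  # spread of each other
  m <- function(b) sp$behaviors[[b]]$constituents[[1L]]$key_pose$mean
  s <- function(b) sp$behaviors[[b]]$constituents[[1L]]$key_pose$spread
  expect_gte(abs(m("b01") - m("b02")) / max(s("b01"), s("b02")), 4)
  expect_lte(abs(m("b03") - m("b04")) / max(s("b03"), s("b04")), 1 + 1e-9)
})

test_that("single-sample Bayes error separates the sanity pair but not the alike pair", {
  o <- bayes_oracle(make_state_preset())
  expect_lt(pair_error(o, "b01", "b02"), 0.01)
  expect_gt(pair_error(o, "b03", "b04"), 0.25)
})

test_that("composite preset encodes the point, unordered and ordered structures", {
  cp <- make_composite_preset()
  expect_length(validate_spec(cp), 0L)
  b11 <- cp$behaviors$b11
  expect_identical(b11$structure_type, "atomic")
  expect_identical(b11$constituents[[1L]]$kind, "point")
  b15 <- cp$behaviors$b15
  expect_identical(b15$structure_type, "ordered")
  expect_identical(vapply(b15$constituents, `[[`, "", "kind"),
                   c("point", "state", "point"))
  # b13's X uses a key pose that b14 also references
  ids13 <- vapply(cp$behaviors$b13$constituents,
                  function(cn) cn$key_pose$id, "")
  ids14 <- vapply(cp$behaviors$b14$constituents,
                  function(cn) cn$key_pose$id, "")
  expect_true(length(intersect(ids13, ids14)) >= 1L)
  # shared stretched pose between b15 and b16
  ids16 <- vapply(cp$behaviors$b16$constituents,
                  function(cn) cn$key_pose$id, "")
  expect_identical(b15$constituents[[2L]]$key_pose$id,
                   intersect(b15$constituents[[2L]]$key_pose$id, ids16))
})

test_that("validate_spec reports violations as diagnostics, not errors", {
  sp <- make_state_preset()
  sp$behaviors[[2L]]$label <- "b03"
  d <- validate_spec(sp)
  expect_true(any(grepl("b03", d)))

  sp2 <- make_state_preset()
  sp2$transition_range <- c(1L, 8L)
  expect_true(any(grepl("transition_range", validate_spec(sp2))))

  sp3 <- make_state_preset()
  sp3$behaviors$b05$mixture_weights <- c(0.9, 0.2)
  expect_true(any(grepl("b05", validate_spec(sp3))))

  sp4 <- make_state_preset()
  sp4$noise_sigma <- -1
  expect_true(any(grepl("noise_sigma", validate_spec(sp4))))
})

test_that("constituent constructors enforce point and state duration rules", {
  kp <- key_pose("p", 0, 0.1)
  expect_error(new_behavior <- state_constituent(kp, dur_fixed(1)),
               "minimum")
  pt <- point_constituent(kp)
  expect_identical(pt$duration$family, "fixed")
  expect_identical(pt$duration$params$n, 1L)
  expect_error(key_pose("bad", 0, -1), "spread")
  expect_error(key_pose("bad", 0, 0.1, held_frac = 1), "held_frac")
  expect_error(fluctuation(period = 6), "period")
})

test_that("specs round-trip through JSON with field-by-field equality", {
  for (sp in list(make_state_preset(), make_composite_preset())) {
    path <- withr::local_tempfile(fileext = ".json")
    write_ethogram(sp, path)
    sp2 <- read_ethogram(path)
    expect_equal(sp2, sp)
  }
})

test_that("duration families sample integers at or above their minimum", {
  set.seed(1)
  for (dd in list(dur_fixed(5), dur_unif(2, 8), dur_gamma(20),
                  dur_gamma(3, shape = 3))) {
    x <- sample_duration(dd, 500L)
    expect_true(is.integer(x))
    expect_gte(min(x), dd$minimum)
  }
  x <- sample_duration(dur_unif(2, 8), 2000L)
  expect_identical(sort(unique(x)), 2:8)
})
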