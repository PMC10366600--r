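test_that("event sequences are uniform with no immediate repeats", {
  sp <- make_state_preset()
  set.seed(42)
  labs <- sample_event_sequence(sp, 10000L)
  expect_false(any(labs[-1L] == labs[-length(labs)]))
  # each label's frequency within 3 standard errors of 1/10
  p <- 1 / 10
  se <- sqrt(p * (1 - p) / 10000)
  freq <- table(factor(labs, levels = names(sp$behaviors))) / 10000
  expect_true(all(abs(freq - p) < 3 * se))
  expect_length(sample_event_sequence(sp, 1L), 1L)
})

test_that("transitions ramp monotonically strictly between the poses", {
  seg <- make_transition(0, 1, 5L, scatter = 0)
  expect_identical(dim(seg), c(5L, 1L))
  expect_true(all(diff(seg[, 1L]) > 0))
  expect_true(all(seg > 0 & seg < 1))
  seg2 <- make_transition(c(2, 2), c(2, 2), 4L, scatter = 0)
  expect_true(all(seg2 == 2))
  expect_error(make_transition(0, 1, 1L), "outside")
  expect_error(make_transition(0, 1, 9L), "outside")
})

test_that("fluctuations have the configured periodicity and smoothness", {
  set.seed(7)
  # identity when switched off
  seg <- matrix(rnorm(50), 50, 1)
  expect_identical(apply_fluctuations(seg, fluctuation()), seg)
  # dominant FFT peak at 1/6 for a period-6 sinusoid
  base <- matrix(0, 600, 1)
  out <- apply_fluctuations(base, fluctuation(period = 6,
                                              period_amplitude = 1))
  spec <- Mod(stats::fft(out[, 1L]))[2:300]
  expect_equal(which.max(spec), 100L)  # 600 / 6
  # lag-1 autocorrelation of the smoothed wander matches the closed form
  # (w - 1) / w for a length-w moving average
  out2 <- apply_fluctuations(matrix(0, 20000, 1),
                             fluctuation(amount = 1, smoothness = 10))
  r1 <- stats::acf(out2[, 1L], lag.max = 1, plot = FALSE)$acf[2L]
  expect_gt(r1, 0.8)
  expect_equal(r1, 9 / 10, tolerance = 0.03)
  expect_equal(stats::sd(out2[, 1L]), 1, tolerance = 0.05)
})

test_that("observation noise has the requested scale and leaves labels alone", {
  set.seed(8)
  x <- matrix(0, 5000, 2)
  expect_identical(add_observation_noise(x, 0), x)
  y <- add_observation_noise(x, 1)
  expect_equal(stats::sd(as.numeric(y)), 1, tolerance = 0.03)
  expect_error(add_observation_noise(x, -0.1), "sigma")
})

test_that("generated series satisfy the label-partition and transition invariants", {
  sp <- make_state_preset()
  s <- generate_dataset(sp, 300L, seed = 11)
  n <- nrow(s$features)
  expect_length(s$behavior, n)
  expect_length(s$subevent, n)
  expect_false(anyNA(s$behavior))
  # transition runs bounded and strictly between events
  r <- rle(s$behavior)
  tr <- r$lengths[r$values == "b00"]
  expect_gte(min(tr), 2L)
  expect_lte(max(tr), 8L)
  expect_false(r$values[1L] == "b00")
  expect_false(r$values[length(r$values)] == "b00")
  # events table matches the label runs; sub-events tile events exactly
  for (i in sample.int(nrow(s$events), 20L)) {
    ev <- s$events[i, ]
    expect_true(all(s$behavior[(ev$start + 1L):ev$end] == ev$label))
    sub <- s$subevents[s$subevents$event == ev$event, ]
    expect_identical(sub$start[1L], ev$start)
    expect_identical(sub$end[nrow(sub)], ev$end)
    if (nrow(sub) > 1L)
      expect_identical(sub$start[-1L], sub$end[-nrow(sub)])
  }
})

test_that("long- and short-duration classes differ by an order of magnitude", {
  sp <- make_state_preset()
  s <- generate_dataset(sp, 1000L, seed = 3)
  durs <- s$events$end - s$events$start
  m <- tapply(durs, s$events$label, mean)
  expect_gte(m[["b06"]] / m[["b07"]], 10)
})

test_that("state samples scatter around the key pose with the configured spread", {
  # no fluctuation wander, no observation noise: marginal deviation from
  # the pose mean is the pose scatter itself
  sp <- ethogram_spec(list(
    behavior_atomic("bA", state_constituent(key_pose("pA", -1, 0.3),
                                            dur_gamma(15))),
    behavior_atomic("bB", state_constituent(key_pose("pB", 1, 0.3),
                                            dur_gamma(15)))),
    noise_sigma = 0, name = "scatter-check")
  s <- generate_dataset(sp, 400L, seed = 5)
  dev <- s$features[s$behavior == "bA", 1L] + 1
  expect_equal(stats::sd(dev), 0.3, tolerance = 0.05)
  expect_equal(mean(dev), 0, tolerance = 0.05)
})

test_that("point behaviors contribute exactly one labeled sample per event", {
  cp <- make_composite_preset()
  s <- generate_dataset(cp, 300L, seed = 21)
  e11 <- s$events[s$events$label == "b11", ]
  expect_gt(nrow(e11), 0L)
  expect_true(all(e11$end - e11$start == 1L))
  expect_identical(sum(s$behavior == "b11"), nrow(e11))
  # ordered triple: point, internal transition, state, transition, point
  s15 <- s$subevents[s$subevents$event ==
                       s$events$event[s$events$label == "b15"][1L], ]
  expect_identical(s15$label, c("b15.takeoff", "b15.t", "b15.X", "b15.t",
                                "b15.landing"))
})

test_that("generation is deterministic and merge_transitions reassigns b00", {
  sp <- make_state_preset()
  a <- generate_dataset(sp, 150L, seed = 9)
  b <- generate_dataset(sp, 150L, seed = 9)
  expect_identical(a$features, b$features)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$events, b$events)
  d <- generate_dataset(sp, 150L, seed = 10)
  expect_false(identical(a$features, d$features))
  m <- generate_dataset(sp, 150L, seed = 9, merge_transitions = TRUE)
  expect_false(any(m$behavior == "b00"))
  expect_identical(m$features, a$features)
})

test_that("series round-trip through CSV + sidecar exactly", {
  s <- generate_dataset(make_composite_preset(), 60L, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  s2 <- read_series(path)
  expect_identical(s2$features, s$features)
  expect_identical(s2$behavior, s$behavior)
  expect_identical(s2$subevent, s$subevent)
  expect_equal(s2$events, s$events)
  expect_equal(s2$spec, s$spec)
  # 1-feature series: time + feature + two label columns
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  expect_identical(header, c("time", "f1", "behavior", "subevent"))
})

test_that("malformed series files raise parse errors naming the problem", {
  s <- generate_dataset(make_state_preset(), 20L, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  df <- utils::read.csv(path)
  bad1 <- paste0(path, "_nocol.csv")
  file.copy(paste0(path, ".meta.json"), paste0(bad1, ".meta.json"))
  utils::write.csv(df[, setdiff(names(df), "subevent")], bad1,
                   row.names = FALSE)
  expect_error(read_series(bad1), "subevent")
  bad2 <- paste0(path, "_badnum.csv")
  file.copy(paste0(path, ".meta.json"), paste0(bad2, ".meta.json"))
  df$f1[5L] <- "not-a-number"
  utils::write.csv(df, bad2, row.names = FALSE)
  expect_error(suppressWarnings(read_series(bad2)), "line 6")
})
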