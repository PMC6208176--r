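make_map <- function(values, class = "Q1", labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_along(values))
  out <- tibble::tibble(class = class, channel = seq_along(values),
                        channel_label = labels, activity = values)
  class(out) <- c("activity_map", class(out))
  out
}

test_that("thresholding is sign-blind and strict", {
  map <- make_map(c(0.9, -0.7, 0.1))
  cs <- select_emotional_channels(map, 0.5)
  expect_equal(cs$indices, c(1L, 2L))
  # value exactly at the threshold is excluded
  cs2 <- select_emotional_channels(make_map(c(0.5, 0.51)), 0.5)
  expect_equal(cs2$indices, 2L)
  expect_warning(select_emotional_channels(map, 0.95), "no channel")
  expect_error(select_emotional_channels(map, 0), "threshold")
  expect_error(select_emotional_channels(map, 1), "threshold")
})

test_that("selection equals a brute-force filter on random maps", {
  set.seed(10)
  for (i in 1:20) {
    v <- runif(12, -1, 1)
    th <- runif(1, 0.05, 0.95)
    cs <- suppressWarnings(select_emotional_channels(make_map(v), th))
    expect_equal(cs$indices, which(abs(v) > th))
  }
})

test_that("raising the threshold never enlarges the channel set", {
  set.seed(11)
  v <- runif(15, -1, 1)
  prev <- seq_len(15)
  for (th in seq(0.1, 0.9, by = 0.1)) {
    cur <- suppressWarnings(select_emotional_channels(make_map(v), th))$indices
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("channel intersection behaves as set intersection", {
  s1 <- channel_set(c(1, 3, 5), c("a", "c", "e"), "Q1")
  s2 <- channel_set(c(3, 5, 7), c("c", "e", "g"), "Q2")
  out <- intersect_channels(list(s1, s2))
  expect_equal(out$indices, c(3L, 5L))
  expect_equal(out$class_label, "intersection")
  # idempotence
  same <- intersect_channels(list(s1, s1, s1, s1))
  expect_equal(same$indices, s1$indices)
  # disjoint sets raise an actionable error
  s3 <- channel_set(c(2, 4), c("b", "d"), "Q3")
  expect_error(intersect_channels(list(s1, s3)), "decrease")
})

test_that("intersecting four overlapping montage subsets keeps common labels", {
  # four per-quarter electrode lists with four channels in common
  q1 <- c("Fp1", "Fz", "F4", "F3", "F8", "Cz", "P4", "Pz", "P3", "O2")
  q2 <- c("Pz", "P4", "P3", "O2", "Cz", "F3")
  q3 <- c("F3", "T4", "C3", "T6", "P3", "T5", "Cz", "O2")
  q4 <- c("P3", "Cz", "Pz", "P4", "O1", "O2", "T6", "T5", "F3")
  space <- unique(c(q1, q2, q3, q4))
  sets <- lapply(list(q1, q2, q3, q4), function(lb)
    channel_set(match(lb, space), lb, "Q"))
  out <- intersect_channels(sets)
  expect_setequal(out$labels, c("Cz", "O2", "F3", "P3"))
})

test_that("threshold tuning maximizes the scorer with ties to the smallest", {
  maps <- dplyr::bind_rows(
    make_map(c(0.95, 0.9, 0.3, -0.6), "Q1"),
    make_map(c(0.9, 0.95, -0.7, 0.2), "Q2"),
    make_map(c(0.85, 0.9, 0.1, 0.3), "Q3"),
    make_map(c(0.9, 0.85, 0.4, -0.1), "Q4")
  )
  class(maps) <- c("activity_map", class(maps))
  # single candidate comes straight back
  expect_equal(as.numeric(tune_threshold(maps, 0.5, function(cs) 1)), 0.5)
  # a scorer preferring more channels picks the smallest threshold
  th <- tune_threshold(maps, c(0.2, 0.5, 0.8), function(cs) length(cs$indices))
  expect_equal(as.numeric(th), 0.2)
  # planted common core {1, 2}: scorer = accuracy surrogate peaking there
  th2 <- tune_threshold(maps, seq(0.1, 0.9, 0.1), function(cs)
    as.numeric(setequal(cs$indices, c(1, 2))))
  expect_setequal(attr(th2, "channels")$indices, c(1, 2))
  # all-empty intersections raise
  lone <- dplyr::bind_rows(
    make_map(c(0.9, 0.1, 0.1, 0.1), "Q1"),
    make_map(c(0.1, 0.9, 0.1, 0.1), "Q2"),
    make_map(c(0.1, 0.1, 0.9, 0.1), "Q3"),
    make_map(c(0.1, 0.1, 0.1, 0.9), "Q4")
  )
  class(lone) <- c("activity_map", class(lone))
  expect_error(tune_threshold(lone, c(0.5, 0.7), function(cs) 1), "empty")
})
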