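frame2 <- c("A", "B")

test_that("mass functions enforce the belief-function conditions", {
  m <- mass_function(c(Q1 = 0.6, "Q2,Q3" = 0.4))
  expect_s3_class(m, "mass_function")
  expect_error(mass_function(c(Q1 = 0.5, Q2 = 0.2)), "sum to 1")
  expect_error(mass_function(c(Q1 = 1.4, Q2 = -0.4)), "negative")
  expect_error(mass_function(c(Q9 = 1)), "outside the frame")
  # member order inside a hypothesis does not matter
  m2 <- mass_function(c("Q3,Q2" = 0.4, Q1 = 0.6))
  expect_equal(unclass(m2), unclass(m))
})

test_that("softmax conversion yields singleton masses satisfying the axioms", {
  m <- softmax_mass(c(0, 0, 0, 0))
  expect_equal(as.numeric(m), rep(0.25, 4))
  m2 <- softmax_mass(c(1, 0, 0, 0))
  expect_equal(unname(unclass(m2)["Q1"]), exp(1) / (exp(1) + 3), tolerance = 1e-12)
  # shift invariance
  r <- c(0.3, -1.2, 2.0, 0.4)
  expect_equal(unclass(softmax_mass(r + 7)), unclass(softmax_mass(r)))
  expect_equal(sum(unclass(m2)), 1)
})

test_that("Dempster combination matches the hand-enumerated example", {
  m1 <- mass_function(c(A = 0.6, B = 0.4), frame2)
  m2 <- mass_function(c(A = 0.7, B = 0.3), frame2)
  out <- dempster_combine(m1, m2)
  expect_equal(out$conflict, 0.46)
  expect_equal(unname(unclass(out$mass)["A"]), 0.42 / 0.54, tolerance = 1e-9)
  expect_equal(unname(unclass(out$mass)["B"]), 0.12 / 0.54, tolerance = 1e-9)
})

test_that("the vacuous mass is the neutral element with zero conflict", {
  m <- mass_function(c(Q1 = 0.5, "Q2,Q4" = 0.3, "Q1,Q2,Q3,Q4" = 0.2))
  out <- dempster_combine(m, vacuous_mass())
  expect_equal(out$conflict, 0)
  expect_equal(as.numeric(unclass(out$mass)[names(m)]), as.numeric(m),
               tolerance = 1e-12)
})

random_mass <- function(frame = quarter_levels()) {
  subsets <- unlist(lapply(seq_along(frame), function(k)
    combn(frame, k, paste, collapse = ",", simplify = FALSE)), use.names = FALSE)
  pick <- sample(subsets, sample(2:5, 1))
  v <- runif(length(pick))
  mass_function(stats::setNames(v / sum(v), pick))
}

test_that("combination is commutative, associative, and axiom-preserving", {
  set.seed(40)
  for (i in 1:15) {
    m1 <- random_mass()
    m2 <- random_mass()
    ab <- dempster_combine(m1, m2)
    ba <- dempster_combine(m2, m1)
    expect_equal(unclass(ab$mass)[sort(names(ab$mass))],
                 unclass(ba$mass)[sort(names(ba$mass))], tolerance = 1e-12)
    expect_equal(ab$conflict, ba$conflict)
    expect_gte(ab$conflict, 0)
    expect_lt(ab$conflict, 1)
    expect_equal(sum(unclass(ab$mass)), 1, tolerance = 1e-9)
    expect_true(all(unclass(ab$mass) >= 0))
    m3 <- random_mass()
    left <- dempster_combine(dempster_combine(m1, m2)$mass, m3)$mass
    right <- dempster_combine(m1, dempster_combine(m2, m3)$mass)$mass
    expect_equal(unclass(left)[sort(names(left))],
                 unclass(right)[sort(names(right))], tolerance = 1e-9)
  }
})

test_that("total conflict is an error", {
  m1 <- mass_function(c(A = 1), frame2)
  m2 <- mass_function(c(B = 1), frame2)
  expect_error(dempster_combine(m1, m2), "total conflict")
})

test_that("decisions maximize singleton belief with low-index ties", {
  expect_equal(decide(mass_function(c(Q3 = 1))), "Q3")
  expect_message(d <- decide(mass_function(
    c(Q1 = 0.25, Q2 = 0.25, Q3 = 0.25, Q4 = 0.25))), "tie")
  expect_equal(d, "Q1")
  set.seed(41)
  for (i in 1:10) {
    m <- random_mass()
    # brute-force belief: sum masses of subsets of each singleton
    bel <- vapply(quarter_levels(), function(q) {
      tot <- 0
      for (h in names(m)) {
        if (all(strsplit(h, ",")[[1]] %in% q)) tot <- tot + unclass(m)[[h]]
      }
      tot
    }, 0)
    expect_equal(suppressMessages(decide(m)),
                 quarter_levels()[which.max(bel)])
  }
})

test_that("class prototypes are per-class means", {
  X <- matrix(c(0, 0, 1, 1, 4, 4, 6, 6), 4, 2, byrow = TRUE)
  y <- c("a", "a", "b", "b")
  p <- class_prototypes(X, y)
  expect_equal(p["a", ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(p["b", ], c(5, 5), ignore_attr = TRUE)
  # one sample per class: prototypes are the samples
  p1 <- class_prototypes(X[c(1, 3), ], c("a", "b"))
  expect_equal(unname(p1), unname(X[c(1, 3), ]))
})

test_that("relabeling thresholds inverse-distance memberships", {
  protos <- rbind(c1 = c(0, 0), c2 = c(4, 0))
  # exactly on a prototype: singleton target
  r0 <- relabel(c(0, 0), protos, 0.4)
  expect_equal(r0$target, "c1")
  expect_equal(unname(r0$membership), c(1, 0))
  # distances 1 and 3: memberships 0.75 / 0.25
  r <- relabel(c(1, 0), protos, 0.3)
  expect_equal(unname(r$membership), c(0.75, 0.25))
  expect_equal(r$target, "c1")
  # equidistant with a low threshold: composite target
  r2 <- relabel(c(2, 0), protos, 0.2)
  expect_equal(unname(r2$membership), c(0.5, 0.5))
  expect_setequal(r2$target, c("c1", "c2"))
  # four equidistant prototypes: membership 0.25 each, all four retained
  protos4 <- rbind(Q1 = c(1, 0), Q2 = c(-1, 0), Q3 = c(0, 1), Q4 = c(0, -1))
  r3 <- relabel(c(0, 0), protos4, 0.2)
  expect_equal(unname(r3$membership), rep(0.25, 4))
  expect_setequal(r3$target, quarter_levels())
})

make_separable_table <- function(n_per_class, seed) {
  set.seed(seed)
  centers <- rbind(Q1 = c(3, 0, 0, 0), Q2 = c(0, 3, 0, 0),
                   Q3 = c(0, 0, 3, 0), Q4 = c(0, 0, 0, 3))
  rows <- lapply(quarter_levels(), function(q) {
    X <- matrix(rnorm(n_per_class * 4, sd = 0.6), n_per_class, 4)
    X <- sweep(X, 2, centers[q, ], "+")
    Y <- matrix(rnorm(n_per_class * 4, sd = 0.6), n_per_class, 4)
    Y <- sweep(Y, 2, centers[q, ], "+")
    tibble::tibble(
      quarter = q,
      arousal = if (q %in% c("Q1", "Q2")) 7 else 3,
      valence = if (q %in% c("Q1", "Q4")) 7 else 3
    ) |>
      dplyr::bind_cols(tibble::as_tibble(X, .name_repair = ~paste0("a", 1:4)),
                       tibble::as_tibble(Y, .name_repair = ~paste0("v", 1:4)))
  })
  dplyr::bind_rows(rows)
}

test_that("fused decisions do not fall behind the single learners", {
  for (seed in 1:5) {
    tbl <- make_separable_table(12, seed)
    subsets <- list(arousal = paste0("a", 1:4), valence = paste0("v", 1:4))
    fit <- fit_dst(tbl, subsets, hidden = 8, maxit = 300, seed = seed)
    pred <- predict(fit, tbl)
    acc_fused <- mean(pred$.pred == tbl$quarter)
    acc_single <- max(mean(pred$.pred_arousal == tbl$quarter),
                      mean(pred$.pred_valence == tbl$quarter))
    expect_gte(acc_fused, acc_single - 0.02)
    expect_true(all(pred$conflict >= 0 & pred$conflict < 1))
  }
})

test_that("tidy and glance summarize a fitted fusion model", {
  tbl <- make_separable_table(8, 7)
  fit <- fit_dst(tbl, list(arousal = paste0("a", 1:4),
                           valence = paste0("v", 1:4)),
                 hidden = 4, maxit = 150, seed = 7)
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$learner), c("arousal", "valence"))
  gl <- glance(fit)
  expect_equal(gl$n_features_arousal, 4)
  expect_equal(gl$hidden, 4)
})

test_that("saved model bundles reproduce predictions exactly", {
  tbl <- make_separable_table(8, 8)
  fit <- fit_dst(tbl, list(arousal = paste0("a", 1:4),
                           valence = paste0("v", 1:4)),
                 hidden = 5, maxit = 200, seed = 8)
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  p1 <- predict(fit, tbl)
  p2 <- predict(back, tbl)
  expect_equal(p2$.pred, p1$.pred)
  expect_equal(p2$conflict, p1$conflict, tolerance = 1e-9)
  expect_equal(p2$mass_Q1, p1$mass_Q1, tolerance = 1e-9)
})
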