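lab_seq <- function(...) {
  spec <- list(...)
  unlist(lapply(spec, function(s) rep(s[[1]], s[[2]])))
}

test_that("total courtship time counts the four elements and excludes copulation", {
  e <- ethogram(rep("none", 50), fps = 24)
  expect_equal(total_courtship_time(e), 0)
  e2 <- ethogram(rep("singing", 240), fps = 24)
  expect_equal(total_courtship_time(e2), 10)
  e3 <- ethogram(lab_seq(list("orientation", 100), list("tapping", 50), list("none", 30)),
                 fps = 24)
  expect_equal(total_courtship_time(e3), 150 / 24)  # 6.25 s
  e4 <- ethogram(lab_seq(list("singing", 100), list("copulation", 100)), fps = 24)
  expect_equal(total_courtship_time(e4), 100 / 24)
})

test_that("element proportions divide by the observation window", {
  e <- ethogram(rep("singing", 80), fps = 24)
  p <- element_proportions(e)
  expect_equal(p$proportion[p$element == "singing"], 1)
  expect_equal(sum(p$proportion), 1)
  e2 <- ethogram(lab_seq(list("singing", 25), list("none", 75)), fps = 24)
  p2 <- element_proportions(e2)
  expect_equal(p2$proportion[p2$element == "singing"], 0.25)
  # to-copulation window truncates at onset
  e3 <- ethogram(lab_seq(list("singing", 30), list("none", 10), list("copulation", 60)),
                 fps = 24, window = "to_copulation")
  p3 <- element_proportions(e3)
  expect_equal(p3$proportion[p3$element == "singing"], 30 / 40)
  expect_equal(p3$proportion[p3$element == "copulation"], 0)
  expect_error(ethogram(rep("copulation", 10), fps = 24, window = "to_copulation"),
               "window is empty")
})

test_that("the worked transition example counts and normalizes as expected", {
  e <- ethogram(c("orientation", "orientation", "singing", "singing",
                  "orientation", "tapping"), fps = 24)
  tm <- transition_matrix(e)
  expect_equal(tm$counts["orientation", "singing"], 1L)
  expect_equal(tm$counts["singing", "orientation"], 1L)
  expect_equal(tm$counts["orientation", "tapping"], 1L)
  expect_equal(tm$probabilities["orientation", "singing"], 0.5)
  expect_equal(tm$probabilities["orientation", "tapping"], 0.5)
  expect_equal(tm$probabilities["singing", "orientation"], 1)
  # a constant sequence has no changes
  tm0 <- transition_matrix(ethogram(rep("singing", 20), fps = 24))
  expect_equal(sum(tm0$counts), 0)
  expect_true("singing" %in% tm0$undefined_rows)
})

test_that("transition counting equals a brute-force pairwise scan on random sequences", {
  set.seed(99)
  states <- c("orientation", "tapping", "singing", "attempted_copulation")
  for (rep_i in 1:5) {
    n <- sample(50:1000, 1)
    lab <- sample(c(states, "none"), n, replace = TRUE,
                  prob = c(0.25, 0.2, 0.25, 0.1, 0.2))
    e <- ethogram(lab, fps = 24)
    tm <- transition_matrix(e, include_copulation = FALSE)
    # oracle: literal scan over consecutive certified labels; none breaks it
    want <- matrix(0L, 4, 4, dimnames = list(states, states))
    prev <- NA
    for (x in lab) {
      if (x == "none") { prev <- NA; next }
      if (!is.na(prev) && prev != x) want[prev, x] <- want[prev, x] + 1L
      prev <- x
    }
    expect_identical(unname(tm$counts), unname(want))
    # rows with outgoing changes sum to 1
    rs <- rowSums(tm$probabilities, na.rm = TRUE)
    expect_true(all(abs(rs[rowSums(tm$counts) > 0] - 1) < 1e-12))
  }
})

test_that("bridging none joins A,none,B into A->B", {
  lab <- c("singing", "none", "none", "tapping")
  e <- ethogram(lab, fps = 24)
  expect_equal(sum(transition_matrix(e)$counts), 0)
  expect_equal(transition_matrix(e, bridge_none = TRUE)$counts["singing", "tapping"], 1L)
})

test_that("time is conserved across proportions, none, and copulation", {
  set.seed(7)
  lab <- sample(c("orientation", "singing", "none", "copulation"), 500, replace = TRUE)
  e <- ethogram(lab, fps = 24)
  p <- element_proportions(e)
  win_s <- 500 / 24
  total <- sum(p$proportion[p$element %in% c("orientation", "tapping", "singing",
                                             "attempted_copulation")]) * win_s
  none_s <- p$proportion[p$element == "none"] * win_s
  cop_s <- p$proportion[p$element == "copulation"] * win_s
  expect_equal(total + none_s + cop_s, win_s, tolerance = 1e-9)
  expect_equal(total, total_courtship_time(e), tolerance = 1e-9)
})

test_that("the courtship summary round-trips through JSON and plots", {
  e <- ethogram(lab_seq(list("orientation", 30), list("singing", 30),
                        list("orientation", 10), list("tapping", 10)), fps = 24)
  summ <- courtship_pattern_summary(element_proportions(e), transition_matrix(e))
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(summ, path)
  back <- read_summary_json(path)
  expect_equal(as.numeric(back$proportions$orientation),
               as.numeric(summ$proportions$orientation))
  expect_equal(as.numeric(back$transition_probabilities$orientation$singing),
               as.numeric(summ$transition_probabilities$orientation$singing))
  expect_s3_class(autoplot(summ), "ggplot")
  expect_s3_class(autoplot(e), "ggplot")
  expect_s3_class(autoplot(transition_matrix(e)), "ggplot")
})

test_that("tidy and glance summarize the ethogram", {
  lab <- lab_seq(list("none", 10), list("singing", 50),
                 list("attempted_copulation", 20), list("copulation", 20))
  e <- ethogram(lab, fps = 24)
  td <- tidy(e)
  expect_equal(nrow(td), 100)
  expect_equal(td$label[11], "singing")
  g <- glance(e)
  expect_true(g$copulated)
  expect_equal(g$total_courtship_s, 70 / 24)
  expect_equal(g$copulation_onset_s, 80 / 24)
})
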