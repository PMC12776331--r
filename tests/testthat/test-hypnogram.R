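test_that("REM rescoring rules handle the canonical cases", {
  run <- function(x) apply_scoring_rules(hypnogram(x))$states
  # singleton REM flanked by NREM takes the previous state
  expect_equal(run(c("N", "R", "N", "N")), c("N", "N", "N", "N"))
  # whole REM run directly after Wake becomes Wake (sleep-onset REM excluded)
  expect_equal(run(c("W", "R", "R", "R", "N")), c("W", "W", "W", "W", "N"))
  # >= 2 consecutive REM after NREM is a valid bout: unchanged
  expect_equal(run(c("N", "R", "R", "W")), c("N", "R", "R", "W"))
  # identity on REM-free input
  expect_equal(run(rep("W", 50)), rep("W", 50))
  # cascade: rescoring a REM run can create a new singleton REM downstream
  expect_equal(run(c("N", "N", "W", "R", "R", "R", "N", "N")),
               c("N", "N", "W", "W", "W", "W", "N", "N"))
})

test_that("leading REM run is rescored to Wake with a warning", {
  h <- hypnogram(c("R", "R", "N", "N"))
  expect_warning(out <- apply_scoring_rules(h), "begins with REM")
  expect_equal(out$states, c("W", "W", "N", "N"))
})

test_that("rescoring is idempotent, safe and epoch-conserving on random input", {
  set.seed(101)
  for (i in 1:300) {
    labs <- random_labels(sample(5:200, 1))
    h <- hypnogram(labs)
    out <- suppressWarnings(apply_scoring_rules(h))
    s <- out$states
    expect_length(s, length(labs))
    r <- rle(s)
    # no singleton REM runs
    expect_false(any(r$values == "R" & r$lengths == 1L))
    # no REM run directly after Wake
    prev <- c("", r$values[-length(r$values)])
    expect_false(any(r$values == "R" & prev == "W"))
    # idempotence
    expect_identical(suppressWarnings(apply_scoring_rules(out))$states, s)
    # only REM epochs may change
    expect_true(all(s[labs != "R"] == labs[labs != "R"]))
  }
})

test_that("detect_bouts matches the run-length-encoding oracle", {
  h <- hypnogram(c("W", "W", "N", "N", "N", "W"))
  b <- detect_bouts(h)
  expect_equal(b$state, c("W", "N"))
  expect_equal(b$onset_epoch, c(0L, 2L))
  expect_equal(b$n_epochs, c(2L, 3L))
  expect_equal(b$duration_s, c(20, 30))
  # homogeneous sequence -> a single bout
  b2 <- detect_bouts(hypnogram(rep("N", 17)))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$n_epochs, 17L)
  # random sequences vs oracle
  set.seed(202)
  for (i in 1:100) {
    labs <- random_labels(sample(c(3, 10, 500, 2000), 1))
    got <- detect_bouts(hypnogram(labs))
    want <- oracle_bouts(labs)
    expect_equal(got$state, want$state)
    expect_equal(got$onset_epoch, want$onset_epoch)
    expect_equal(got$n_epochs, want$n_epochs)
  }
})

test_that("time_in_state counts every epoch once and conserves 100%", {
  h <- hypnogram(rep("W", 8640))
  tis <- time_in_state(h)
  expect_equal(tis$time_pct, c(100, 0, 0))
  h2 <- hypnogram(c("W", "W", "N", "N", "N", "N", "R", "R"))
  tis2 <- time_in_state(h2)
  expect_equal(tis2$time_pct, c(25, 50, 25))
  expect_equal(tis2$time_min, c(2, 4, 2) * 10 / 60)
  # singleton epochs count toward time even though they form no bout
  h3 <- hypnogram(c("W", "N", "W", "N", "W", "N"))
  expect_equal(time_in_state(h3)$time_pct, c(50, 50, 0))
  expect_equal(nrow(detect_bouts(h3)), 0L)
  # conservation on random windows
  set.seed(303)
  for (i in 1:50) {
    h4 <- hypnogram(random_labels(8640))
    w <- sample(list("H24", "LIGHT", "DARK", c(3, 7), c(22, 4)), 1)[[1]]
    expect_lt(abs(sum(time_in_state(h4, w)$time_pct) - 100), 1e-9)
  }
  expect_error(time_in_state(hypnogram(rep("W", 360)), c(5, 6)),
               "no epochs")
})

test_that("adding epochs of a state never decreases its share", {
  set.seed(404)
  for (i in 1:50) {
    labs <- random_labels(200)
    h <- hypnogram(labs)
    p0 <- time_in_state(h)$time_pct[1]  # W share
    h2 <- hypnogram(c(labs, rep("W", 20)))
    expect_gte(time_in_state(h2)$time_pct[1], p0)
  }
})

test_that("hourly profile bins by ZT hour and averages across days", {
  h <- hypnogram(rep("N", 8640))
  hp <- hourly_profile(h)
  expect_equal(nrow(hp), 24L)
  expect_equal(hp$pct_N, rep(100, 24))
  expect_true(all(hp$complete))
  expect_equal(hp$n_epochs, rep(360L, 24))
  # alternating 1-h blocks
  h2 <- hypnogram(rep(rep(c("W", "N"), each = 360), 12))
  hp2 <- hourly_profile(h2)
  expect_equal(hp2$pct_W, rep(c(100, 0), 12))
  # multi-day pooling equals mean of single-day values (complete days)
  set.seed(505)
  labs <- random_labels(8640 * 3)
  hp3 <- hourly_profile(hypnogram(labs))
  daily <- sapply(0:2, function(d) {
    hourly_profile(hypnogram(labs[(d * 8640 + 1):((d + 1) * 8640)]))$pct_W
  })
  expect_equal(hp3$pct_W, rowMeans(daily))
  # partial trailing hour flagged
  hp4 <- hourly_profile(hypnogram(random_labels(360 + 100)))
  expect_true(hp4$complete[1])
  expect_false(hp4$complete[2])
})

test_that("bout_stats counts by onset phase and reports missing means as NA", {
  h <- hypnogram(c(rep("W", 2), rep("N", 3), rep("W", 4), "N"))
  bs <- bout_stats(detect_bouts(h))
  expect_equal(bs$bout_count, c(2L, 1L, 0L))
  expect_equal(bs$mean_bout_duration_s[1], 30)  # (20 + 40) / 2
  expect_true(is.na(bs$mean_bout_duration_s[3]))
  # a bout spanning the light/dark boundary belongs to its onset phase
  labs <- c(rep("N", 4318), rep("W", 10), rep("N", 8640 - 4328))
  h2 <- hypnogram(labs)  # W bout starts at epoch 4318 (ZT 11.99), ends in dark
  b2 <- detect_bouts(h2)
  expect_equal(b2$phase[b2$state == "W"], "LIGHT")
  expect_equal(bout_stats(b2, "LIGHT")$bout_count[1], 1L)
  expect_equal(bout_stats(b2, "DARK")$bout_count[1], 0L)
})

test_that("bout histogram uses half-open bins and conserves totals", {
  mk <- function(durs) {
    # build a hypnogram containing W bouts of the given durations
    labs <- unlist(lapply(durs / 10, function(k) c(rep("W", k), "N", "N")))
    detect_bouts(hypnogram(labs))
  }
  hist <- bout_histogram(mk(c(50, 60, 100, 300)))
  expect_equal(hist$count, c(1L, 1L, 1L, 0L, 0L, 0L, 1L))
  expect_equal(hist$bin, c("<60", "60-100", "100-140", "140-180",
                           "180-220", "220-260", ">260"))
  # empty bout list
  empty <- detect_bouts(hypnogram(c("W", "N", "W", "N")))
  expect_equal(bout_histogram(empty)$count, rep(0L, 7))
  # random bouts vs counting oracle
  set.seed(606)
  for (i in 1:20) {
    durs <- sample(seq(20, 400, by = 10), 300, replace = TRUE)
    b <- mk(durs)
    expect_equal(bout_histogram(b)$count,
                 oracle_histogram(b$duration_s[b$state == "W"],
                                  c(60, 100, 140, 180, 220, 260)))
    expect_equal(sum(bout_histogram(b)$count), sum(b$state == "W"))
  }
  expect_error(bout_histogram(empty, edges_s = c(100, 60)), "increasing")
})

test_that("architecture summary is additive across light and dark phases", {
  set.seed(707)
  for (i in 1:25) {
    h <- hypnogram(random_labels(sample(c(8640, 12960, 17280), 1)))
    s <- summarize_architecture(h)
    for (st in c("W", "N", "R")) {
      g <- function(w, col) s[[col]][s$window == w & s$state == st]
      expect_equal(g("H24", "time_min"), g("LIGHT", "time_min") + g("DARK", "time_min"))
      expect_equal(g("H24", "bout_count"), g("LIGHT", "bout_count") + g("DARK", "bout_count"))
    }
    # recount from scratch
    b <- oracle_bouts(h$states)
    expect_equal(sum(s$bout_count[s$window == "H24"]), nrow(b))
    expect_equal(sum(s$n_epochs[s$window == "H24"]), n_epochs(h))
  }
})

test_that("state labels are validated at parse time", {
  expect_error(hypnogram(c("W", "X")), "unknown state label")
  expect_equal(hypnogram(c("Wake", "nrem", "REM"))$states, c("W", "N", "R"))
  expect_error(hypnogram(character(0)), "at least one epoch")
  expect_error(hypnogram("W", epoch_s = 0), "positive")
})
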