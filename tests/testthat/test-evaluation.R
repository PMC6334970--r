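test_that("identification rate follows (a - b - c)/a", {
  expect_equal(identificationRate(total = 100, falseNegatives = 0,
                                  falsePositives = 0), 100)
  expect_equal(identificationRate(total = 100, falseNegatives = 10,
                                  falsePositives = 5), 85)
  expect_equal(identificationRate(list(total = 8, falseNegatives = 1,
                                       falsePositives = 1)), 75)
  expect_error(identificationRate(total = 0, falseNegatives = 0,
                                  falsePositives = 0), "total")
  expect_error(identificationRate(total = 5, falseNegatives = 4,
                                  falsePositives = 2), "<=")
})

test_that("file-level confusion counts match a brute-force tally", {
  files <- sprintf("f%02d.wav", 1:40)
  set.seed(71)
  for (rep in 1:5) {
    autoCount <- rpois(40, 0.8)
    truthInt <- sample(0:3, 40, replace = TRUE)
    auto <- data.frame(sourceFile = files, black_drum = autoCount)
    truth <- data.frame(sourceFile = files, species = "black_drum",
                        intensity = truthInt)
    cc <- filePresenceConfusion(auto, truth, "black_drum")
    expect_equal(cc$total, 40)
    expect_equal(cc$falseNegatives, sum(truthInt >= 1 & autoCount == 0))
    expect_equal(cc$falsePositives, sum(truthInt == 0 & autoCount >= 1))
    expect_lte(cc$falseNegatives + cc$falsePositives, cc$total)
  }
  # perfect agreement: IR = 100; detector silenced: b = present files
  auto <- data.frame(sourceFile = files, black_drum = 0L)
  truth <- data.frame(sourceFile = files, species = "black_drum",
                      intensity = rep(c(0L, 2L), 20))
  cc <- filePresenceConfusion(auto, truth, "black_drum")
  expect_equal(cc$falseNegatives, 20)
  expect_equal(cc$falsePositives, 0)
  expect_equal(identificationRate(cc), 50)
  # mismatched universes are an explicit error
  expect_error(filePresenceConfusion(auto[-1, ], truth, "black_drum"),
               "universes differ")
})

test_that("intensity categories follow the 0/1/2/3 coding", {
  mk <- function(onsets, durs) data.frame(onsetS = onsets, durationS = durs)
  expect_equal(intensityFromManifest(mk(numeric(0), numeric(0))), 0L)
  expect_equal(intensityFromManifest(mk(1, 0.5)), 1L)
  expect_equal(intensityFromManifest(mk(c(1, 3), c(0.5, 0.5))), 2L)
  expect_equal(intensityFromManifest(mk(c(1, 1.2), c(0.5, 0.5))), 3L)
  # randomized sets against the O(n^2) pairwise-overlap oracle
  set.seed(72)
  for (i in 1:40) {
    n <- sample(0:6, 1)
    ev <- mk(runif(n, 0, 10), runif(n, 0.1, 2))
    got <- intensityFromManifest(ev)
    overlap <- FALSE
    if (n >= 2)
      for (a in 1:(n - 1)) for (b in (a + 1):n)
        if (ev$onsetS[b] < ev$onsetS[a] + ev$durationS[a] &&
            ev$onsetS[a] < ev$onsetS[b] + ev$durationS[b]) overlap <- TRUE
    want <- if (n == 0) 0L else if (n == 1) 1L else if (overlap) 3L else 2L
    expect_equal(got, want)
  }
})

test_that("nightly sums group files into noon-to-noon windows", {
  tz <- "UTC"
  ts <- as.POSIXct(c("2014-03-01 12:00", "2014-03-01 23:40",
                     "2014-03-02 11:40", "2014-03-02 12:00",
                     "2014-03-04 03:00"), tz = tz)
  v <- c(1, 3, 2, 5, 7)
  ns <- nightlySums(v, ts)
  expect_equal(ns$nightStart, as.Date(c("2014-03-01", "2014-03-02",
                                        "2014-03-03")))
  # a file at 23:40 on day d and at 11:40 next day belong to night d
  expect_equal(ns$value, c(1 + 3 + 2, 5, 7))
  # conservation: no file lost or double-counted
  expect_equal(sum(ns$value, na.rm = TRUE), sum(v))
  # zero-file nights inside the range are missing, not zero
  ts2 <- as.POSIXct(c("2014-03-01 13:00", "2014-03-03 13:00"), tz = tz)
  ns2 <- nightlySums(c(1, 1), ts2)
  expect_true(is.na(ns2$value[2]))
  expect_equal(ns2$nFiles, c(1L, 0L, 1L))
  expect_error(nightlySums(c(1, 2), rep(ts[1], 2)), "duplicate")
  # random assignment equals a brute-force grouping oracle
  set.seed(73)
  ts3 <- as.POSIXct("2014-05-01", tz = tz) +
    sort(sample(0:(20 * 86400), 300)) + 0.5
  v3 <- rpois(300, 2)
  ns3 <- nightlySums(v3, ts3)
  night <- as.Date(format(ts3 - 12 * 3600, "%Y-%m-%d"))
  for (i in seq_len(nrow(ns3))) {
    inNight <- night == ns3$nightStart[i]
    if (any(inNight)) expect_equal(ns3$value[i], sum(v3[inNight]))
    else expect_true(is.na(ns3$value[i]))
  }
  expect_equal(sum(ns3$value, na.rm = TRUE), sum(v3))
})

test_that("nightly correlation matches the textbook formula", {
  expect_equal(correlateNightly(1:10, 2 * (1:10))$r, 1)
  expect_equal(correlateNightly(1:10, -(1:10) + 7)$r, -1)
  set.seed(74)
  x <- rnorm(30, 10, 3)
  y <- 0.6 * x + rnorm(30)
  res <- correlateNightly(x, y)
  mx <- mean(x); my <- mean(y)
  rOracle <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tOracle <- rOracle * sqrt(28 / (1 - rOracle^2))
  pOracle <- 2 * pt(-abs(tOracle), 28)
  expect_equal(res$r, rOracle, tolerance = 1e-12)
  expect_equal(res$p, pOracle, tolerance = 1e-12)
  expect_equal(res$n, 30)
  expect_warning(res0 <- correlateNightly(rep(1, 5), rnorm(5)),
                 "zero-variance")
  expect_true(is.na(res0$r))
  expect_error(correlateNightly(1:2, 1:2), "at least 3")
  # data.frame interface aligns on nightStart
  a <- data.frame(nightStart = as.Date("2014-01-01") + 0:9, value = x[1:10])
  b <- data.frame(nightStart = as.Date("2014-01-01") + 0:9,
                  value = 2 * x[1:10])
  expect_equal(correlateNightly(a, b)$r, 1)
})

test_that("temperature anomaly subtracts a 30-day moving average", {
  # constant series: anomaly identically zero where defined
  x <- rep(17.5, 24 * 90)
  an <- temperatureAnomaly(x)
  expect_true(all(an[!is.na(an)] == 0))
  expect_true(any(is.na(an)))  # incomplete edge windows flagged
  # linear ramp: centered window gives zero anomaly in the interior
  ramp <- seq(10, 25, length.out = 24 * 90)
  anr <- temperatureAnomaly(ramp)
  interior <- anr[!is.na(anr)]
  expect_lt(max(abs(interior)), 1e-9)
  # seeded sinusoid + trend against a brute-force windowed-mean oracle
  set.seed(75)
  n <- 24 * 75
  y <- 15 + 5 * sin(2 * pi * seq_len(n) / (24 * 30)) +
    seq_len(n) / 2000 + rnorm(n, 0, 0.3)
  any_ <- temperatureAnomaly(y)
  k <- 24 * 30 + 1
  half <- (k - 1) / 2
  for (i in c(half + 1, 1000, n - half)) {
    oracle <- y[i] - mean(y[(i - half):(i + half)])
    expect_equal(any_[i], oracle, tolerance = 1e-10)
  }
  expect_true(all(is.na(any_[1:half])))
  # trailing alignment uses only the past
  tr <- temperatureAnomaly(y, align = "trailing")
  i <- 2000
  expect_equal(tr[i], y[i] - mean(y[(i - 24 * 30 + 1):i]),
               tolerance = 1e-10)
  # gaps flag their windows unless tolerated
  yg <- y; yg[1200] <- NA
  ang <- temperatureAnomaly(yg)
  expect_true(is.na(ang[1200 - half]))
  angTol <- temperatureAnomaly(yg, maxGapFrac = 0.01)
  expect_false(is.na(angTol[1200 - half]))
})

test_that("lunar categories partition the 30-day cycle", {
  expect_equal(as.character(lunarCategory(1)), "new_moon")
  expect_equal(as.character(lunarCategory(28)), "new_moon")
  expect_equal(as.character(lunarCategory(15)), "full_moon")
  expect_equal(as.character(lunarCategory(5)), "first_quarter")
  expect_equal(as.character(lunarCategory(20)), "third_quarter")
  all30 <- lunarCategory(1:30)
  expect_false(any(is.na(all30)))
  expect_equal(as.integer(table(all30)),
               c(8L, 7L, 8L, 7L))  # 27-4, 5-11, 12-19, 20-26
  expect_error(lunarCategory(0), "1..30")
  expect_error(lunarCategory(31), "1..30")
})

test_that("schedule arithmetic matches the deployment logs", {
  expect_equal(expectedFileCount(86, 4), 24768)
  expect_equal(expectedFileCount(242, 4), 69696)
  expect_equal(expectedFileCount(1, 1), 72)
  expect_error(expectedFileCount(0, 4), "positive")
})

test_that("covariate helpers behave sensibly", {
  ts <- as.POSIXct("2014-06-01", tz = "UTC") + seq(0, 86400 * 2 - 1, 600)
  lev <- 1.5 + 1.4 * sin(2 * pi * as.numeric(ts) / (12.42 * 3600))
  tr <- tidalRange(ts, lev)
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$tidalRange > 2 & tr$tidalRange <= 2.8))
  dl <- dayLength(as.Date(c("2014-06-21", "2014-12-21")), 32.2)
  expect_gt(dl[1], 13)
  expect_lt(dl[2], 11)
})
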