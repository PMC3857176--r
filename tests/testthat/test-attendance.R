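test_that("seasonal cycles run from 1 April to 31 March", {
  expect_equal(seasonal_cycle(as.Date("2002-04-01")), "2002/03")
  expect_equal(seasonal_cycle(as.Date("2003-03-31")), "2002/03")
  expect_equal(seasonal_cycle(as.Date("1999-12-25")), "1999/00")
  # every date maps to exactly one cycle: consecutive days never skip
  days <- as.Date("2001-01-01") + 0:1500
  cyc <- seasonal_cycle(days)
  expect_true(all(nchar(cyc) == 7))
  expect_true(all(table(cyc)[unique(cyc)] <= 366))
})

test_that("occurrence counts days and occupancy spans first to last day", {
  s <- make_store(list("a", "a", "b"),
                  dates = c("2002-10-01", "2002-10-08", "2002-10-03"))
  rec <- occurrence_occupancy(s)
  a <- rec[rec$individual_id == "a", ]
  expect_equal(a$occurrence, 2)
  expect_equal(a$occupancy, 7)
  b <- rec[rec$individual_id == "b", ]
  expect_equal(b$occurrence, 1)
  expect_true(is.na(b$occupancy))
  # consecutive days -> occupancy 1; same-day duplicates are one day
  s2 <- make_store(list("a", "a", "a"),
                   dates = c("2002-10-01", "2002-10-01", "2002-10-02"))
  rec2 <- occurrence_occupancy(s2)
  expect_equal(rec2$occurrence, 2)
  expect_equal(rec2$occupancy, 1)
})

test_that("occurrence and occupancy are translation invariant", {
  set.seed(7)
  n_enc <- 15
  ids <- sprintf("I%02d", 1:6)
  groups <- lapply(1:n_enc, function(e) sample(ids, sample(1:3, 1)))
  dates <- as.Date("2001-05-01") + sort(sample.int(200, n_enc, TRUE))
  s <- make_store(groups, dates = dates)
  shift <- 37L  # keeps every date inside the same seasonal cycle
  enc <- s$encounters
  enc$date <- enc$date + shift
  s2 <- encounter_store(s$individuals, enc, s$memberships)
  r1 <- occurrence_occupancy(s)
  r2 <- occurrence_occupancy(s2)
  # cycles relabel but per-individual occurrence/occupancy multisets persist
  expect_equal(sort(r1$occurrence), sort(r2$occurrence))
  expect_equal(sort(r1$occupancy, na.last = TRUE),
               sort(r2$occupancy, na.last = TRUE))
})

test_that("attendance equals a day-recount oracle on random stores", {
  set.seed(42)
  for (rep in 1:25) {
    s <- random_store()
    got <- occurrence_occupancy(s)
    want <- oracle_attendance(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("mean occurrence is the frequency-weighted mean", {
  expect_equal(mean_occurrence(c(`1` = 10)), 1)
  expect_equal(mean_occurrence(c(`2` = 5, `4` = 5)), 3)
  expect_error(mean_occurrence(numeric()), "empty")
  v <- 4
  expect_equal(mean_occurrence(stats::setNames(100, v)), v)
})

test_that("sex ratio chi-square against parity matches the closed form", {
  expect_equal(sex_ratio_test(20, 20)$chi2, 0)
  t2 <- sex_ratio_test(40, 18)
  expect_equal(round(t2$chi2, 2), 8.34)
  expect_lt(t2$p, 0.005)
  expect_equal(sex_ratio_test(30, 0)$chi2, 30)
  # Yates shrinks the statistic
  expect_lt(sex_ratio_test(40, 18, yates = TRUE)$chi2, t2$chi2)
  expect_error(sex_ratio_test(0, 0), "zero")
})

test_that("OSR pools individual-day identification events per grouping", {
  # one female seen 3 days in October, one male seen 1 day
  s <- make_store(list("f", "f", "f", "m"),
                  dates = c("2002-10-02", "2002-10-09", "2002-10-20",
                            "2002-10-05"),
                  sexes = c(f = "female", m = "male"))
  o <- osr_table(s)
  row <- o[o$grouping == "mid_spring" & o$class == "all", ]
  expect_equal(row$females, 3)
  expect_equal(row$males, 1)
  expect_equal(round(row$ratio_m_per_f, 2), 0.33)
  # same month in different years pools; same day twice counts once
  s2 <- make_store(list("f", "f", "f", "m"),
                   dates = c("2002-10-02", "2002-10-02", "2003-10-09",
                             "2002-10-05"),
                   sexes = c(f = "female", m = "male"))
  o2 <- osr_table(s2)
  row2 <- o2[o2$grouping == "mid_spring" & o2$class == "all", ]
  expect_equal(row2$females, 2)
  # March/April events are excluded but counted
  s3 <- make_store(list("f", "m"), dates = c("2002-03-10", "2002-10-05"),
                   sexes = c(f = "female", m = "male"))
  expect_equal(attr(osr_table(s3), "n_unassigned"), 1)
  # calves excluded by default, included on request
  s4 <- make_store(list(c("mom", "kid")),
                   sexes = c(mom = "female", kid = "male"),
                   ages = c(kid = "calf_of_year"),
                   mothers = c(kid = "mom"))
  o4 <- osr_table(s4)
  expect_equal(sum(o4$males), 0)
  o5 <- osr_table(s4, exclude_calves = FALSE)
  expect_equal(sum(o5[o5$class == "all", "males"]), 1)
})

test_that("OSR counts are additive over disjoint date ranges", {
  sexes <- c(f = "female", m = "male", g = "female")
  early <- list("f", "m", "g")
  late <- list("f", "f", "m")
  s_all <- make_store(c(early, late),
                      dates = c("2002-10-01", "2002-10-02", "2002-10-03",
                                "2002-10-20", "2002-10-21", "2002-10-22"),
                      sexes = sexes)
  s_early <- make_store(early,
                        dates = c("2002-10-01", "2002-10-02", "2002-10-03"),
                        sexes = sexes)
  s_late <- make_store(late,
                       dates = c("2002-10-20", "2002-10-21", "2002-10-22"),
                       sexes = sexes)
  pick <- function(s) {
    o <- osr_table(s)
    o[o$grouping == "mid_spring" & o$class == "all", c("females", "males")]
  }
  expect_equal(pick(s_all)$females, pick(s_early)$females + pick(s_late)$females)
  expect_equal(pick(s_all)$males, pick(s_early)$males + pick(s_late)$males)
})

test_that("group size statistics and t-tests match direct computation", {
  # familiar {1,2,3} (via resighted r), unfamiliar {1,1,1}
  s <- make_store(list(c("r"), c("r", "x"), c("r", "y", "z"),
                       "u1", "u2", "u3"))
  g <- suppressWarnings(group_size_stats(s))
  fam <- g[g$variant == "all" & g$class == "familiar", ]
  unf <- g[g$variant == "all" & g$class == "unfamiliar", ]
  expect_equal(fam$mean, 2)
  expect_equal(unf$mean, 1)
  expect_equal(fam$n, 3)
  expect_equal(unf$prop_singles, 1)
  # identical distributions give t = 0
  s2 <- make_store(list(c("r", "p"), c("r", "q"), c("a", "b"), c("c", "d"),
                        c("p", "x")))
  g2 <- suppressWarnings(group_size_stats(s2))
  expect_equal(g2$t[g2$variant == "all"][1], 0)
  # oracle recount on a random store
  set.seed(12)
  s3 <- random_store()
  g3 <- suppressWarnings(group_size_stats(s3))
  cls <- classify_groups(s3)
  for (cl in c("familiar", "unfamiliar")) {
    x <- s3$encounters$group_size_estimate[cls == cl]
    row <- g3[g3$variant == "all" & g3$class == cl, ]
    expect_equal(row$n, length(x))
    if (length(x)) expect_equal(row$mean, mean(x))
  }
})

test_that("pair composition expectation follows the binomial expansion", {
  expect_equal(unname(expected_pair_composition(4, 1)), c(2, 1, 1))
  expect_equal(unname(expected_pair_composition(5, 0)), c(0, 5, 0))
  e <- expected_pair_composition(20, 0.89)
  expect_equal(unname(round(e * 2) / 2), c(10, 5.5, 4.5))
})

test_that("observed pair composition counts sexed dyads once per day", {
  sexes <- c(f1 = "female", f2 = "female", m1 = "male", m2 = "male")
  s <- make_store(list(c("f1", "m1"), c("f1", "m1"),  # same pair, two days
                       c("f1", "f2"), c("m1", "m2"),
                       c("f1", "m1")),                # third day, same pair
                  dates = c("2002-10-01", "2002-10-02", "2002-10-03",
                            "2002-10-04", "2002-10-02"),
                  sexes = sexes)
  pc <- pair_sex_composition(s, sex_ratio = 1)
  tot <- colSums(pc$observed[c("mixed", "female_female", "male_male")])
  expect_equal(unname(tot), c(2, 1, 1))  # same-day duplicate dropped
})
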