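#' Seasonal cycle of a date
#'
#' Attendance is analysed over a 12-month window running from 1 April of one
#' year to 31 March of the next, so that animals over-summering on the
#' feeding ground are not split across calendar years. A date in or after
#' April belongs to the cycle starting that year; January-March dates belong
#' to the cycle that started the previous April.
#'
#' @param dates Date vector (or ISO 8601 strings).
#' @return Character vector of cycle labels, `"1993/94"` style.
#' @export
seasonal_cycle <- function(dates) {
  dates <- parse_iso_dates(dates)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  start <- ifelse(m >= 4, y, y - 1L)
  sprintf("%d/%02d", start, (start + 1L) %% 100L)
}

# first day of the cycle labelled "YYYY/.."
cycle_start_year <- function(label) as.integer(sub("/.*$", "", label))

#' Seasonal grouping of a month
#'
#' Months are pooled into the seasonal groupings used for the operational
#' sex ratio: May-July = late autumn to mid-winter, August = late winter,
#' September = early spring, October = mid-spring, November = late spring,
#' December = early summer, January-February = mid-to-late summer. March and
#' April belong to no grouping and map to `NA`.
#'
#' @param month integer month 1-12, or a Date vector.
#' @return Factor of grouping names (ordered through the season), `NA` for
#'   March and April.
#' @export
season_grouping <- function(month) {
  if (inherits(month, "Date") ||
      (is.character(month) && all(grepl("-", month[!is.na(month)]))))
    month <- as.integer(format(parse_iso_dates(month), "%m"))
  levs <- c("late_autumn_to_mid_winter", "late_winter", "early_spring",
            "mid_spring", "late_spring", "early_summer", "mid_late_summer")
  map <- c(`1` = "mid_late_summer", `2` = "mid_late_summer",
           `3` = NA, `4` = NA,
           `5` = "late_autumn_to_mid_winter", `6` = "late_autumn_to_mid_winter",
           `7` = "late_autumn_to_mid_winter", `8` = "late_winter",
           `9` = "early_spring", `10` = "mid_spring", `11` = "late_spring",
           `12` = "early_summer")
  factor(map[as.character(month)], levels = levs)
}

#' Occurrence and occupancy per individual and seasonal cycle
#'
#' *Occurrence* is the number of separate days an individual was sighted
#' within one seasonal cycle. *Occupancy* is the number of days between its
#' first and last sighting dates in that cycle, counted from the day after
#' the first sighting (so sightings on consecutive days give an occupancy of
#' 1); it is defined only for individuals sighted on at least two separate
#' days and is `NA` otherwise.
#'
#' @param store an [encounter_store].
#' @param cycles optional character vector of cycle labels to restrict to.
#' @return data.frame with columns `individual_id`, `cycle`, `occurrence`,
#'   `occupancy`; one row per individual per cycle in which it was sighted.
#' @export
occurrence_occupancy <- function(store, cycles = NULL) {
  stopifnot(inherits(store, "encounter_store"))
  mem <- store$memberships
  date <- store$encounters$date[match(mem$encounter_id,
                                      store$encounters$encounter_id)]
  cyc <- seasonal_cycle(date)
  keep <- if (is.null(cycles)) rep(TRUE, length(cyc)) else cyc %in% cycles
  if (!any(keep))
    return(data.frame(individual_id = character(), cycle = character(),
                      occurrence = integer(), occupancy = integer()))
  df <- data.frame(individual_id = mem$individual_id[keep],
                   cycle = cyc[keep], date = date[keep])
  df <- df[!duplicated(df), ]  # distinct sighting days
  sp <- split(df$date, paste(df$individual_id, df$cycle, sep = "\r"))
  key <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(
    individual_id = vapply(key, `[`, "", 1L),
    cycle = vapply(key, `[`, "", 2L),
    occurrence = vapply(sp, length, 0L),
    occupancy = vapply(sp, function(d)
      if (length(d) >= 2) as.integer(max(d) - min(d)) else NA_integer_, 0L),
    row.names = NULL)
  out[order(out$cycle, out$individual_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Mean occurrence
#'
#' Frequency-weighted mean of occurrence values, either from the records
#' returned by [occurrence_occupancy()] or from a printed frequency table
#' (a named numeric vector mapping occurrence value to count).
#'
#' @param x data.frame with an `occurrence` column, or a named numeric
#'   vector of counts per occurrence value.
#' @return The mean occurrence (numeric scalar).
#' @examples
#' mean_occurrence(c(`1` = 255, `2` = 27, `3` = 8, `4` = 3, `5` = 1))
#' @export
mean_occurrence <- function(x) {
  if (is.data.frame(x)) {
    if (!nrow(x)) stop_ws("no attendance records")
    return(mean(x$occurrence))
  }
  if (!length(x) || sum(x) == 0) stop_ws("empty occurrence table")
  vals <- as.numeric(names(x))
  if (anyNA(vals)) stop_ws("occurrence table must have numeric names")
  sum(vals * x) / sum(x)
}

#' One-degree-of-freedom sex-ratio test against parity
#'
#' Goodness-of-fit chi-square of observed female and male counts against a
#' 1:1 expectation, optionally with Yates' continuity correction.
#'
#' @param f_count,m_count nonnegative counts.
#' @param yates apply the continuity correction (default `FALSE`).
#' @return List with `chi2`, `df` (1) and `p`.
#' @export
sex_ratio_test <- function(f_count, m_count, yates = FALSE) {
  if (f_count < 0 || m_count < 0) stop_ws("counts must be nonnegative")
  n <- f_count + m_count
  if (n == 0) stop_ws("both counts are zero")
  dev <- abs(f_count - m_count)
  if (yates) dev <- max(0, dev - 1)
  chi2 <- dev^2 / n
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Compare two sex ratios (2x2 contingency test)
#'
#' Chi-square comparison of the female:male split between two classes of
#' individuals (e.g. resighted vs non-resighted), with Yates' correction by
#' default as is conventional for 2x2 tables.
#'
#' @param f1,m1 counts in the first class.
#' @param f2,m2 counts in the second class.
#' @param yates apply continuity correction (default `TRUE`).
#' @return The `htest` object from [stats::chisq.test()].
#' @export
sex_ratio_comparison <- function(f1, m1, f2, m2, yates = TRUE) {
  stats::chisq.test(matrix(c(f1, m1, f2, m2), nrow = 2), correct = yates)
}

#' Operational sex ratio table
#'
#' Counts (individual, day) identification events of known-sex individuals
#' per seasonal grouping, pooling the same month across years, separately for
#' resighted and non-resighted individuals and combined. Calves of the year
#' are excluded by default (their presence tracks their mother's); unknown-sex
#' individuals are always excluded; March and April sightings fall outside
#' every grouping and are dropped (their number is reported as an attribute).
#'
#' @param store an [encounter_store].
#' @param exclude_calves drop `calf_of_year` individuals (default `TRUE`).
#' @return data.frame with columns `grouping`, `class` (`resighted`,
#'   `non_resighted`, `all`), `females`, `males`, `ratio_m_per_f` (males per
#'   female, `NA` when no females), `chi2`, `p` (parity test). Attribute
#'   `n_unassigned` counts the March/April events excluded.
#' @export
osr_table <- function(store, exclude_calves = TRUE) {
  stopifnot(inherits(store, "encounter_store"))
  mem <- store$memberships
  date <- store$encounters$date[match(mem$encounter_id,
                                      store$encounters$encounter_id)]
  ind <- store$individuals[match(mem$individual_id,
                                 store$individuals$individual_id), ]
  keep <- ind$sex %in% c("female", "male")
  if (exclude_calves) keep <- keep & ind$age_class != "calf_of_year"
  df <- data.frame(individual_id = mem$individual_id[keep],
                   date = date[keep], sex = ind$sex[keep])
  df <- df[!duplicated(df), ]  # one identification event per individual-day
  df$grouping <- season_grouping(df$date)
  n_unassigned <- sum(is.na(df$grouping))
  df <- df[!is.na(df$grouping), ]
  status <- resighting_status(store)
  df$class <- status[df$individual_id]

  levs <- levels(season_grouping(10))
  rows <- list()
  for (g in levs) {
    for (cl in c("resighted", "non_resighted", "all")) {
      sel <- df$grouping == g & (cl == "all" | df$class == cl)
      f <- sum(df$sex[sel] == "female")
      m <- sum(df$sex[sel] == "male")
      tst <- if (f + m > 0) sex_ratio_test(f, m) else list(chi2 = NA, p = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        grouping = g, class = cl, females = f, males = m,
        ratio_m_per_f = if (f > 0) m / f else NA_real_,
        chi2 = tst$chi2, p = tst$p)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Group-size statistics for familiar and unfamiliar groups
#'
#' Summarises encounter group sizes (the estimated total group size, which
#' includes unidentified animals) for familiar vs unfamiliar groups, with an
#' unpaired pooled-variance t-test, in four variants: all groups; groups
#' larger than one; all groups with the single largest group per class
#' removed; and groups larger than one with the largest removed.
#'
#' @param store an [encounter_store].
#' @return data.frame with one row per (variant x class): `variant`, `class`,
#'   `n`, `mean`, `se`, `min`, `max`, `prop_singles`, and the shared t-test
#'   columns `t`, `df`, `p` repeated across the two class rows (`NA` with a
#'   warning when a class has fewer than two groups).
#' @export
group_size_stats <- function(store) {
  cls <- classify_groups(store)
  sizes <- store$encounters$group_size_estimate
  names(sizes) <- store$encounters$encounter_id
  fam <- sizes[cls == "familiar"]
  unf <- sizes[cls == "unfamiliar"]

  drop_largest <- function(x) if (length(x)) x[-which.max(x)] else x
  variants <- list(
    all = list(fam, unf),
    size_gt1 = list(fam[fam > 1], unf[unf > 1]),
    no_outlier = list(drop_largest(fam), drop_largest(unf)),
    size_gt1_no_outlier = list(drop_largest(fam)[drop_largest(fam) > 1],
                               drop_largest(unf)[drop_largest(unf) > 1]))

  rows <- list()
  for (v in names(variants)) {
    xs <- variants[[v]]
    tt <- if (length(xs[[1]]) >= 2 && length(xs[[2]]) >= 2) {
      n1 <- length(xs[[1]]); n2 <- length(xs[[2]])
      pooled <- ((n1 - 1) * stats::var(xs[[1]]) +
                   (n2 - 1) * stats::var(xs[[2]])) / (n1 + n2 - 2)
      if (pooled == 0) {
        # degenerate zero-variance classes: report 0 when the means agree
        d <- mean(xs[[1]]) - mean(xs[[2]])
        list(t = if (d == 0) 0 else sign(d) * Inf, df = n1 + n2 - 2,
             p = if (d == 0) 1 else 0)
      } else {
        t <- stats::t.test(xs[[1]], xs[[2]], var.equal = TRUE)
        list(t = unname(t$statistic), df = unname(t$parameter),
             p = t$p.value)
      }
    } else {
      warning("variant '", v, "': a class has fewer than 2 groups; ",
              "t-test omitted", call. = FALSE)
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    }
    for (i in 1:2) {
      x <- xs[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, class = c("familiar", "unfamiliar")[i],
        n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        se = if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_,
        prop_singles = if (length(x)) mean(x == 1) else NA_real_,
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sex composition of pairs, observed and expected under random association
#'
#' Tabulates the sex composition (mixed, female-female, male-male) of dyads:
#' encounters with exactly two identified members, both of known sex, with
#' calves of the year excluded and repeated sightings of the same pair on the
#' same day counted once. Expected counts under random association follow the
#' binomial expansion `n * (2p(1-p), p^2, (1-p)^2)` where `p` is the female
#' proportion implied by the supplied sex ratio.
#'
#' @param store an [encounter_store].
#' @param sex_ratio males per female used for the expectation (e.g. `0.89`
#'   for a 1F:0.89M ratio). Default `NULL` uses the known-sex, non-calf
#'   individuals in the store.
#' @return List with `observed` (data.frame of counts per familiar/unfamiliar
#'   class), `expected` (data.frame, same shape), `p_female`, and
#'   `composition_test` (chi-square comparing the familiar vs unfamiliar
#'   distributions, `NULL` when a margin is empty).
#' @export
pair_sex_composition <- function(store, sex_ratio = NULL) {
  stopifnot(inherits(store, "encounter_store"))
  ind <- store$individuals
  if (is.null(sex_ratio)) {
    sexed <- ind$sex[ind$sex %in% c("female", "male") &
                       ind$age_class != "calf_of_year"]
    nf <- sum(sexed == "female")
    if (nf == 0) stop_ws("no sexed females; supply sex_ratio explicitly")
    sex_ratio <- sum(sexed == "male") / nf
  }
  p <- 1 / (1 + sex_ratio)

  mem <- store$memberships
  n_members <- table(mem$encounter_id)
  pair_enc <- names(n_members)[n_members == 2]
  cls <- classify_groups(store)

  comp <- data.frame(class = character(), composition = character(),
                     date = as.Date(character()), a = character(),
                     b = character())
  for (e in pair_enc) {
    ids <- sort(mem$individual_id[mem$encounter_id == e])
    rec <- ind[match(ids, ind$individual_id), ]
    if (any(rec$age_class == "calf_of_year")) next
    if (!all(rec$sex %in% c("female", "male"))) next
    composition <- if (rec$sex[1] != rec$sex[2]) "mixed"
      else if (rec$sex[1] == "female") "female_female" else "male_male"
    comp <- rbind(comp, data.frame(
      class = unname(cls[e]), composition = composition,
      date = store$encounters$date[store$encounters$encounter_id == e],
      a = ids[1], b = ids[2]))
  }
  # same pair on the same day counted once
  comp <- comp[!duplicated(comp[c("date", "a", "b")]), ]

  comps <- c("mixed", "female_female", "male_male")
  observed <- expected <- data.frame(class = c("familiar", "unfamiliar"))
  for (cc in comps) {
    observed[[cc]] <- vapply(observed$class, function(cl)
      sum(comp$class == cl & comp$composition == cc), 0)
  }
  n_cl <- vapply(observed$class, function(cl) sum(comp$class == cl), 0)
  probs <- c(mixed = 2 * p * (1 - p), female_female = p^2,
             male_male = (1 - p)^2)
  for (cc in comps) expected[[cc]] <- n_cl * probs[[cc]]

  tab <- as.matrix(observed[comps])
  test <- if (all(rowSums(tab) > 0))
    suppressWarnings(stats::chisq.test(tab)) else NULL
  list(observed = observed, expected = expected, p_female = p,
       composition_test = test)
}

#' Binomial expectation for pair sex composition
#'
#' Expected numbers of mixed, all-female and all-male dyads among `n_pairs`
#' random pairings at female proportion `p = 1/(1 + sex_ratio)`.
#'
#' @param n_pairs number of dyads.
#' @param sex_ratio males per female.
#' @return Named numeric vector `(mixed, female_female, male_male)`.
#' @export
expected_pair_composition <- function(n_pairs, sex_ratio) {
  p <- 1 / (1 + sex_ratio)
  c(mixed = n_pairs * 2 * p * (1 - p),
    female_female = n_pairs * p^2,
    male_male = n_pairs * (1 - p)^2)
}
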