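test_that("scenario configuration validates fields", {
  cfg <- scenario_wsa_default(1)
  expect_s3_class(cfg, "scenario_config")
  expect_error(scenario_config(1, detection_prob = 1.5), "\\[0, 1\\]")
  expect_error(scenario_config(1, nonsense = 2), "unknown")
  bad <- cfg
  bad$arrival_month_probs$female <- rep(0.5, 12)
  expect_error(validate_scenario(bad), "summing to 1")
})

test_that("the same seed reproduces the scenario exactly", {
  s1 <- simulate_scenario(scenario_wsa_default(31))
  s2 <- simulate_scenario(scenario_wsa_default(31))
  expect_identical(s1$store$encounters, s2$store$encounters)
  expect_identical(s1$store$memberships, s2$store$memberships)
  expect_identical(s1$panel$alleles, s2$panel$alleles)
  expect_identical(s1$truth$pedigree, s2$truth$pedigree)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(s1, d1); write_scenario(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  s3 <- simulate_scenario(scenario_wsa_default(32))
  expect_false(identical(s1$store$encounters, s3$store$encounters))
})

test_that("offspring genotypes are Mendelian and mtDNA is maternal", {
  gen <- simulate_genotypes(scenario_wsa_default(5))
  ped <- gen$truth$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  expect_gt(nrow(kids), 0)
  ids <- ped$individual_id
  hap <- gen$truth$haplotypes
  for (i in seq_len(nrow(kids))) {
    kid <- kids$individual_id[i]
    mom <- kids$mother_id[i]
    expect_identical(unname(hap[kid]), unname(hap[mom]))
    if (all(c(kid, mom) %in% gen$panel$ids)) {
      pr <- panel_pair(gen$panel, kid, mom)
      for (l in seq_len(10)) {
        k <- pr$g1[c(2 * l - 1, 2 * l)]
        m <- pr$g2[c(2 * l - 1, 2 * l)]
        expect_true(any(k %in% m))  # one allele from the mother
      }
      # sampled fathers contribute the other allele
      dad <- kids$father_id[i]
      if (!is.na(dad) && dad %in% gen$panel$ids) {
        prd <- panel_pair(gen$panel, kid, dad)
        for (l in seq_len(10)) {
          k <- prd$g1[c(2 * l - 1, 2 * l)]
          d <- prd$g2[c(2 * l - 1, 2 * l)]
          expect_true(any(k %in% d))
        }
      }
    }
  }
})

test_that("founder panels recover the configured allele frequencies", {
  cfg <- scenario_config(9, n_individuals = 1000L, freq_law = "equifrequent",
                         n_mother_calf_pairs = 0L, n_fs_pairs = 0L)
  gen <- simulate_genotypes(cfg)
  f <- estimate_allele_frequencies(gen$panel)
  for (l in seq_along(f))
    expect_true(all(abs(f[[l]] - 1 / 8) < 0.03))
})

test_that("true relationships derive from the pedigree", {
  gen <- simulate_genotypes(scenario_wsa_default(13))
  ped <- gen$truth$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  k1 <- kids$individual_id[1]
  expect_equal(true_relationship(gen$truth, k1, kids$mother_id[1]), "PO")
  # siblings by the same mother
  sib <- split(kids$individual_id, kids$mother_id)
  sib <- sib[lengths(sib) >= 2]
  expect_gt(length(sib), 0)
  found_fs <- FALSE
  for (s in sib) {
    rel <- true_relationship(gen$truth, s[1], s[2])
    expect_true(rel %in% c("FS", "HS"))
    if (rel == "FS") found_fs <- TRUE
  }
  # unrelated founders
  f12 <- ped$individual_id[is.na(ped$mother_id)][1:2]
  expect_equal(true_relationship(gen$truth, f12[1], f12[2]), "U")
})

test_that("perfect detection turns presence into daily occurrence", {
  cfg <- scenario_config(3, n_individuals = 6L, n_mother_calf_pairs = 0L,
                         n_fs_pairs = 0L, detection_prob = 1,
                         years = 2001L,
                         return_prob = c(female = 1, male = 1, unknown = 1),
                         same_day_repeat_prob = 0,
                         effort_days_per_month = stats::setNames(
                           rep(15, 12), month.abb))
  sim <- simulate_encounters(cfg, simulate_genotypes(cfg))
  rec <- occurrence_occupancy(sim$store)
  pres <- sim$presence
  for (i in seq_len(nrow(pres))) {
    eff_days <- unique(
      sim$store$encounters$date[sim$store$encounters$date >= pres$start[i] &
                                  sim$store$encounters$date <= pres$end[i]])
    r <- rec[rec$individual_id == pres$individual_id[i] &
               rec$cycle == pres$cycle[i], ]
    if (length(eff_days)) {
      expect_equal(r$occurrence, length(eff_days))
    } else {
      expect_equal(nrow(r), 0)
    }
  }
})

test_that("attendance brackets the true presence intervals", {
  s <- simulate_scenario(scenario_wsa_default(19))
  rec <- occurrence_occupancy(s$store)
  pres <- s$truth$presence
  key <- paste(pres$individual_id, pres$cycle)
  for (i in seq_len(nrow(rec))) {
    j <- match(paste(rec$individual_id[i], rec$cycle[i]), key)
    if (is.na(j)) next  # same-cycle sightings of post-natal calves etc.
    h <- sighting_history(s$store, rec$individual_id[i])
    d <- h$sighting_days[seasonal_cycle(h$sighting_days) == rec$cycle[i]]
    expect_true(all(d >= pres$start[j] & d <= pres$end[j]))
    if (!is.na(rec$occupancy[i]))
      expect_lte(rec$occupancy[i],
                 as.integer(pres$end[j] - pres$start[j]))
  }
})

test_that("cow and natal calf always travel together", {
  s <- simulate_scenario(scenario_wsa_default(27))
  ped <- s$truth$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  mem <- s$store$memberships
  checked <- 0L
  for (i in seq_len(nrow(kids))) {
    kid <- kids$individual_id[i]
    if (!kid %in% mem$individual_id) next
    # encounters of the calf in its natal cycle must include the mother
    encs <- mem$encounter_id[mem$individual_id == kid]
    dates <- s$store$encounters$date[match(encs,
                                           s$store$encounters$encounter_id)]
    natal <- encs[seasonal_cycle(dates) == kids$natal_cycle[i]]
    for (e in natal) {
      expect_true(kids$mother_id[i] %in%
                    mem$individual_id[mem$encounter_id == e])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("the default scenario lands in the study's observable envelope", {
  s <- simulate_scenario(scenario_wsa_default(42))
  n_ident <- length(unique(s$store$memberships$individual_id))
  expect_gte(n_ident, 150)
  expect_lte(n_ident, 400)
  # multi-year site fidelity: some individuals resighted across >= 2 cycles
  rec <- occurrence_occupancy(s$store)
  per_id <- table(rec$individual_id)
  expect_gt(sum(per_id >= 2), 0)
  # group sizes: small mean with occasional larger feeding aggregations
  expect_lt(mean(s$store$encounters$group_size_estimate), 4)
  # the configured female bias in mid-spring shows up in the OSR
  o <- osr_table(s$store)
  row <- o[o$grouping == "mid_spring" & o$class == "all", ]
  expect_gt(row$females, row$males)
})
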