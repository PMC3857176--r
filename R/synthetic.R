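#' Scenario configuration for the synthetic sighting and pedigree generator
#'
#' Bundles every tunable of the generator: panel size, marker structure,
#' pedigree shape, seasonal presence by sex and class, residency, detection,
#' survey effort and group formation. `scenario_wsa_default()` returns the
#' packaged default emulating a small mid-latitude coastal feeding ground
#' surveyed over many years.
#'
#' @param seed mandatory integer seed; the whole scenario is reproducible
#'   from it.
#' @param ... overrides for any default field, see [scenario_wsa_default()]
#'   for the field list.
#' @return Object of class `scenario_config` (a validated named list).
#' @export
scenario_config <- function(seed, ...) {
  cfg <- scenario_wsa_default(seed)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop_ws("unknown scenario field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_scenario(cfg)
}

#' Packaged default scenario
#'
#' Emulates the study system at desk scale: a regional pool of ~300
#' identifiable whales surveyed over 14 April-March seasonal cycles with
#' uneven monthly boat effort (spring-heavy), 10 microsatellite loci,
#' maternally inherited mtDNA haplotypes, a pedigree of mother-calf pairs
#' with mostly unsampled fathers, days-to-months residencies, small groups
#' with rare large feeding aggregations, and sex-specific seasonality:
#' non-nursing females peaking in mid-spring (October), males in late winter
#' to spring, and cow-calf pairs arriving in mid-to-late summer.
#'
#' @param seed integer seed (default 42).
#' @return A `scenario_config`.
#' @export
scenario_wsa_default <- function(seed = 42L) {
  mon <- function(...) {
    v <- numeric(12)
    names(v) <- month.abb
    inp <- c(...)
    v[names(inp)] <- inp
    v
  }
  cfg <- list(
    seed = as.integer(seed),
    # population and markers
    n_individuals = 300L,          # non-calf pool
    prop_female = 0.5,
    n_loci = 10L,
    alleles_per_locus = 8L,
    freq_law = "dirichlet",        # or "equifrequent"
    dirichlet_conc = 1.5,
    n_mtdna_haplotypes = 12L,
    # pedigree
    n_mother_calf_pairs = 12L,
    max_calves_per_mother = 3L,    # calving intervals of 1-3 years
    father_sampled_prob = 0.3,
    n_fs_pairs = 3L,               # mothers whose first two calves share a father
    # survey frame
    years = 1993:2006,             # seasonal-cycle start years
    effort_days_per_month = mon(Apr = 1, May = 1, Jun = 1, Jul = 1, Aug = 2,
                                Sep = 4, Oct = 7, Nov = 6, Dec = 4, Jan = 3,
                                Feb = 4, Mar = 4),
    # presence
    return_prob = c(female = 0.40, male = 0.30, unknown = 0.30),
    residency_mean_days = 30,
    arrival_month_probs = list(
      female = mon(May = 0.02, Jun = 0.02, Jul = 0.03, Aug = 0.06,
                   Sep = 0.12, Oct = 0.32, Nov = 0.20, Dec = 0.12,
                   Jan = 0.06, Feb = 0.05),
      male = mon(May = 0.04, Jun = 0.04, Jul = 0.08, Aug = 0.18, Sep = 0.20,
                 Oct = 0.18, Nov = 0.12, Dec = 0.08, Jan = 0.04, Feb = 0.04),
      unknown = mon(May = 0.03, Jun = 0.03, Jul = 0.05, Aug = 0.12,
                    Sep = 0.16, Oct = 0.25, Nov = 0.16, Dec = 0.10,
                    Jan = 0.05, Feb = 0.05),
      cow_calf = mon(Dec = 0.15, Jan = 0.45, Feb = 0.40)),
    # detection and grouping
    detection_prob = 0.04,
    group_lambda = 1.2,            # group size = 1 + Poisson(lambda)
    aggregation_prob = 0.03,       # per effort day with enough whales around
    aggregation_max = 20L,
    same_day_repeat_prob = 0.04,
    unidentified_extra_lambda = 1.0,
    feature_probs = c(fluke = 0.6, dorsal = 0.7, genotype = 0.55),
    locations = c("Saldanha Bay", "St Helena Bay", "Cape Columbine"))
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  probs <- c(cfg$prop_female, cfg$father_sampled_prob, cfg$detection_prob,
             cfg$aggregation_prob, cfg$same_day_repeat_prob,
             cfg$return_prob, cfg$feature_probs)
  if (any(probs < 0 | probs > 1))
    stop_ws("scenario probabilities must lie in [0, 1]")
  if (cfg$n_loci < 1 || cfg$alleles_per_locus < 2)
    stop_ws("need at least 1 locus with 2 alleles")
  if (!cfg$freq_law %in% c("dirichlet", "equifrequent"))
    stop_ws("freq_law must be 'dirichlet' or 'equifrequent'")
  for (nm in names(cfg$arrival_month_probs)) {
    p <- cfg$arrival_month_probs[[nm]]
    if (length(p) != 12 || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop_ws("arrival_month_probs$", nm,
              " must be 12 nonnegative values summing to 1")
  }
  if (cfg$residency_mean_days <= 0) stop_ws("residency_mean_days must be > 0")
  if (length(cfg$effort_days_per_month) != 12)
    stop_ws("effort_days_per_month must have 12 entries")
  structure(cfg, class = "scenario_config")
}

# symmetric Dirichlet draw via gammas (no extra dependency needed)
rdirichlet1 <- function(n_cat, conc) {
  g <- stats::rgamma(n_cat, shape = conc)
  g / sum(g)
}

#' Simulate a pedigreed genotype panel
#'
#' Creates the individual pool (founders plus calves), assigns sexes,
#' identification features and mtDNA haplotypes, builds the pedigree
#' (mothers with 1-3 calves at 1-3 year calving intervals, fathers sampled
#' into the panel with configured probability, optional full-sibling pairs),
#' and draws genotypes: founders from Hardy-Weinberg at the scenario's
#' allele frequencies, offspring by Mendelian inheritance of one uniformly
#' chosen allele per parent per locus, mtDNA copied from the mother.
#'
#' @param config a `scenario_config`.
#' @return List with `individuals` (store-schema attribute table),
#'   `panel` (a [genotype_panel()] of the genotyped individuals), and
#'   `truth` (list: `pedigree` data.frame with `individual_id`, `mother_id`,
#'   `father_id`, `natal_cycle`, `sex_true`; `freqs_true`; `haplotypes`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(cfg$seed, {
    # true allele frequencies
    freqs_true <- lapply(seq_len(cfg$n_loci), function(l) {
      f <- if (cfg$freq_law == "equifrequent")
        rep(1 / cfg$alleles_per_locus, cfg$alleles_per_locus)
      else rdirichlet1(cfg$alleles_per_locus, cfg$dirichlet_conc)
      names(f) <- seq_len(cfg$alleles_per_locus)
      attr(f, "null") <- 0
      f
    })
    names(freqs_true) <- paste0("L", seq_len(cfg$n_loci))
    class(freqs_true) <- "allele_freqs"

    n <- cfg$n_individuals
    founder_ids <- sprintf("W%03d", seq_len(n))
    sex_true <- ifelse(stats::runif(n) < cfg$prop_female, "female", "male")
    hap_probs <- rdirichlet1(cfg$n_mtdna_haplotypes, 2)
    haplo <- paste0("H", sample.int(cfg$n_mtdna_haplotypes, n, replace = TRUE,
                                    prob = hap_probs))
    draw_hw <- function(m) {
      A <- matrix(0L, m, 2 * cfg$n_loci)
      for (l in seq_len(cfg$n_loci)) {
        f <- freqs_true[[l]]
        A[, 2 * l - 1] <- sample.int(length(f), m, TRUE, prob = f)
        A[, 2 * l] <- sample.int(length(f), m, TRUE, prob = f)
      }
      A
    }
    alleles <- draw_hw(n)

    # pedigree: mothers with calves at 1-3 year intervals
    mothers <- sample(founder_ids[sex_true == "female"],
                      cfg$n_mother_calf_pairs)
    males <- founder_ids[sex_true == "male"]
    ped <- data.frame(individual_id = founder_ids,
                      mother_id = NA_character_, father_id = NA_character_,
                      natal_cycle = NA_character_, sex_true = sex_true)
    calf_rows <- list()
    calf_alleles <- list()
    calf_haplo <- character()
    calf_sex <- character()
    unsampled_fathers <- list()   # genotypes of fathers outside the panel
    ci <- 0L
    for (mi in seq_along(mothers)) {
      mom <- mothers[mi]
      n_calves <- sample.int(cfg$max_calves_per_mother, 1)
      first_year <- sample(cfg$years[-length(cfg$years)], 1)
      year <- first_year
      shared_father <- NULL
      if (mi <= cfg$n_fs_pairs && n_calves < 2) n_calves <- 2L
      for (k in seq_len(n_calves)) {
        if (year > max(cfg$years)) break
        # father: reuse for designated full-sibling families, else fresh
        if (mi <= cfg$n_fs_pairs && k <= 2) {
          if (is.null(shared_father)) {
            shared_father <- if (stats::runif(1) < cfg$father_sampled_prob)
              sample(males, 1) else list(genotype = draw_hw(1))
          }
          father <- shared_father
        } else {
          father <- if (stats::runif(1) < cfg$father_sampled_prob)
            sample(males, 1) else list(genotype = draw_hw(1))
        }
        ci <- ci + 1L
        calf_id <- sprintf("C%03d", ci)
        mom_g <- alleles[match(mom, founder_ids), ]
        dad_g <- if (is.character(father))
          alleles[match(father, founder_ids), ] else father$genotype[1, ]
        g <- integer(2 * cfg$n_loci)
        for (l in seq_len(cfg$n_loci)) {
          g[2 * l - 1] <- mom_g[2 * l - 1 + (stats::runif(1) < 0.5)]
          g[2 * l] <- dad_g[2 * l - 1 + (stats::runif(1) < 0.5)]
        }
        calf_alleles[[ci]] <- g
        calf_haplo[ci] <- haplo[match(mom, founder_ids)]
        calf_sex[ci] <- ifelse(stats::runif(1) < 0.5, "female", "male")
        calf_rows[[ci]] <- data.frame(
          individual_id = calf_id, mother_id = mom,
          father_id = if (is.character(father)) father else NA_character_,
          natal_cycle = sprintf("%d/%02d", year, (year + 1L) %% 100L),
          sex_true = calf_sex[ci])
        year <- year + sample.int(3, 1)  # calving interval 1-3 years
      }
    }
    n_calves <- ci
    if (n_calves) {
      ped <- rbind(ped, do.call(rbind, calf_rows))
      alleles <- rbind(alleles, do.call(rbind, calf_alleles))
      haplo <- c(haplo, calf_haplo)
      sex_true <- c(sex_true, calf_sex)
    }
    all_ids <- ped$individual_id

    # identification features; anyone in the study must carry at least one
    fp <- cfg$feature_probs
    m <- length(all_ids)
    has_genotype <- stats::runif(m) < fp["genotype"]
    has_fluke <- stats::runif(m) < fp["fluke"]
    has_dorsal <- stats::runif(m) < fp["dorsal"]
    none <- !(has_genotype | has_fluke | has_dorsal)
    has_fluke[none] <- TRUE
    # mothers and their calves are genotyped so the pedigree is testable
    fam <- all_ids %in% c(mothers, ped$individual_id[!is.na(ped$mother_id)])
    has_genotype[fam] <- TRUE

    sex_obs <- ifelse(has_genotype, sex_true, "unknown")
    individuals <- data.frame(
      individual_id = all_ids,
      sex = sex_obs,
      age_class = ifelse(is.na(ped$mother_id), "adult_or_juvenile",
                         "calf_of_year"),
      has_fluke_photo = has_fluke,
      has_dorsal_photo = has_dorsal,
      has_genotype = has_genotype,
      mother_id = ped$mother_id)

    panel <- genotype_panel(all_ids[has_genotype],
                            alleles[has_genotype, , drop = FALSE],
                            loci = names(freqs_true),
                            mtdna = haplo[has_genotype])
    list(individuals = individuals, panel = panel,
         truth = list(pedigree = ped, freqs_true = freqs_true,
                      haplotypes = stats::setNames(haplo, all_ids)))
  })
}

#' True pedigree relationship of a pair
#'
#' Derives U / HS / FS / PO from the ground-truth pedigree: PO for a direct
#' parent link, FS for a shared mother and father, HS for exactly one shared
#' (known) parent, U otherwise. Unknown (unsampled) fathers are treated as
#' distinct.
#'
#' @param truth the `truth` element returned by [simulate_genotypes()].
#' @param id1,id2 individual ids.
#' @return One of `"PO"`, `"FS"`, `"HS"`, `"U"`.
#' @export
true_relationship <- function(truth, id1, id2) {
  ped <- truth$pedigree
  r1 <- ped[ped$individual_id == id1, ]
  r2 <- ped[ped$individual_id == id2, ]
  if (!nrow(r1) || !nrow(r2)) stop_ws("unknown individual in pedigree")
  parents <- function(r) c(r$mother_id, r$father_id)
  if (id1 %in% parents(r2) || id2 %in% parents(r1)) return("PO")
  shared_m <- !is.na(r1$mother_id) && !is.na(r2$mother_id) &&
    r1$mother_id == r2$mother_id
  shared_f <- !is.na(r1$father_id) && !is.na(r2$father_id) &&
    r1$father_id == r2$father_id
  if (shared_m && shared_f) return("FS")
  if (shared_m || shared_f) return("HS")
  "U"
}

#' Simulate seasonally structured encounter histories
#'
#' Draws, per seasonal cycle, which individuals visit the feeding ground
#' (sex-specific return probabilities; mothers always visit in their calf's
#' natal cycle, with the calf co-travelling), their arrival date (sex- and
#' class-specific month distributions) and residency (exponential, mean as
#' configured). Survey effort days are drawn per month; on each effort day
#' the individuals present are detected independently, detected whales are
#' partitioned into groups around a small mean size with rare large feeding
#' aggregations, cow-calf pairs are never split, and occasionally an
#' individual is recorded in a second group on the same day. The estimated
#' group size adds unidentified animals on top of the identified members.
#'
#' @param config a `scenario_config`.
#' @param gen output of [simulate_genotypes()] for the same config.
#' @return List with `store` (an [encounter_store]) and `presence`
#'   (data.frame of true presence intervals: `individual_id`, `cycle`,
#'   `start`, `end`).
#' @export
simulate_encounters <- function(config, gen) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  ind <- gen$individuals
  ped <- gen$truth$pedigree
  with_seed(cfg$seed + 1L, {
    ids <- ind$individual_id
    n <- length(ids)
    is_calf <- !is.na(ped$mother_id)
    natal <- ped$natal_cycle
    sex_t <- ped$sex_true

    presence <- list()
    enc_rows <- list()
    mem_rows <- list()
    enc_i <- 0L

    for (y in cfg$years) {
      cyc <- sprintf("%d/%02d", y, (y + 1L) %% 100L)
      cyc_start <- as.Date(sprintf("%d-04-01", y))
      cyc_end <- as.Date(sprintf("%d-03-31", y + 1))
      # calves of this cycle and their mothers
      natal_calves <- ids[is_calf & natal == cyc]
      natal_mothers <- ped$mother_id[match(natal_calves, ids)]

      start <- end <- rep(as.Date(NA), n)
      for (i in seq_len(n)) {
        id <- ids[i]
        if (is_calf[i]) {
          # calves exist only from their natal cycle on; in the natal cycle
          # presence is the mother's (assigned below)
          if (natal[i] >= cyc || id %in% natal_calves) next
        }
        cls <- if (id %in% natal_mothers) "cow_calf" else sex_t[i]
        ret <- if (id %in% natal_mothers) 1.0
          else cfg$return_prob[[if (sex_t[i] %in% names(cfg$return_prob))
            sex_t[i] else "unknown"]]
        if (stats::runif(1) >= ret) next
        mp <- cfg$arrival_month_probs[[
          if (cls %in% names(cfg$arrival_month_probs)) cls else "unknown"]]
        mth <- sample.int(12, 1, prob = mp)
        yy <- if (mth >= 4) y else y + 1L
        first <- as.Date(sprintf("%d-%02d-01", yy, mth))
        ndays <- as.integer(seq(first, by = "month", length.out = 2)[2] -
                              first)
        arr <- first + sample.int(ndays, 1) - 1L
        res <- max(1, round(stats::rexp(1, 1 / cfg$residency_mean_days)))
        start[i] <- arr
        end[i] <- min(arr + res, cyc_end)
      }
      # co-travel: natal calves share their mother's interval
      for (k in seq_along(natal_calves)) {
        ci <- match(natal_calves[k], ids)
        mi <- match(natal_mothers[k], ids)
        start[ci] <- start[mi]; end[ci] <- end[mi]
      }
      here <- which(!is.na(start))
      if (!length(here)) next
      presence[[length(presence) + 1L]] <- data.frame(
        individual_id = ids[here], cycle = cyc,
        start = start[here], end = end[here])

      # effort calendar for this cycle
      effort_days <- as.Date(character())
      for (mth in 1:12) {
        lam <- cfg$effort_days_per_month[[month.abb[mth]]]
        if (lam <= 0) next
        nd <- stats::rpois(1, lam)
        if (nd == 0) next
        yy <- if (mth >= 4) y else y + 1L
        first <- as.Date(sprintf("%d-%02d-01", yy, mth))
        mdays <- as.integer(seq(first, by = "month", length.out = 2)[2] -
                              first)
        effort_days <- c(effort_days,
                         first + sample.int(mdays, min(nd, mdays)) - 1L)
      }
      effort_days <- sort(unique(effort_days))

      for (d in effort_days) {
        d <- as.Date(d, origin = "1970-01-01")
        avail <- here[start[here] <= d & end[here] >= d]
        if (!length(avail)) next
        # detection: calves follow their mothers in the natal cycle
        avail_ids <- ids[avail]
        calf_here <- avail_ids[avail_ids %in% natal_calves]
        adult_here <- setdiff(avail_ids, calf_here)
        det <- adult_here[stats::runif(length(adult_here)) <
                            cfg$detection_prob]
        det_calves <- calf_here[natal_mothers[match(calf_here, natal_calves)]
                                %in% det]
        if (!length(det)) next
        # group the detections, cow-calf pairs as indivisible units
        units <- lapply(det, function(x) {
          kid <- det_calves[natal_mothers[match(det_calves, natal_calves)]
                            == x]
          c(x, kid)
        })
        units <- units[sample.int(length(units))]
        groups <- list()
        if (length(units) >= 3 && stats::runif(1) < cfg$aggregation_prob) {
          take <- min(length(units), cfg$aggregation_max)
          groups[[1]] <- unlist(units[seq_len(take)])
          units <- units[-seq_len(take)]
        }
        while (length(units)) {
          s <- 1 + stats::rpois(1, cfg$group_lambda)
          take <- min(s, length(units))
          groups[[length(groups) + 1L]] <- unlist(units[seq_len(take)])
          units <- units[-seq_len(take)]
        }
        # occasional second sighting of an individual on the same day
        extra <- det[stats::runif(length(det)) < cfg$same_day_repeat_prob]
        for (x in extra) {
          home <- which(vapply(groups, function(g) x %in% g, TRUE))
          others <- setdiff(seq_along(groups), home)
          if (length(others)) {
            tgt <- others[sample.int(length(others), 1)]
            groups[[tgt]] <- c(groups[[tgt]], x)
          } else {
            groups[[length(groups) + 1L]] <- x
          }
        }
        loc <- sample(cfg$locations, 1)
        for (gi in seq_along(groups)) {
          g <- unique(groups[[gi]])
          enc_i <- enc_i + 1L
          enc_rows[[enc_i]] <- data.frame(
            encounter_id = sprintf("E%05d", enc_i),
            date = d, sighting_no = gi, location_name = loc,
            latitude = -33 + stats::runif(1, -0.5, 0.5),
            longitude = 18 + stats::runif(1, -0.5, 0.5),
            group_size_estimate = length(g) +
              stats::rpois(1, cfg$unidentified_extra_lambda))
          mem_rows[[enc_i]] <- data.frame(
            encounter_id = sprintf("E%05d", enc_i), individual_id = g)
        }
      }
    }
    if (!enc_i) stop_ws("scenario produced no encounters")
    encounters <- do.call(rbind, enc_rows)
    memberships <- do.call(rbind, mem_rows)
    seen <- unique(memberships$individual_id)
    # keep referenced mothers in the table even when never encountered
    moms <- stats::na.omit(ind$mother_id[ind$individual_id %in% seen])
    store <- encounter_store(ind[ind$individual_id %in% c(seen, moms), ],
                             encounters, memberships)
    list(store = store, presence = do.call(rbind, presence))
  })
}

#' Run a full synthetic scenario
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_encounters()],
#' returning everything the pipeline consumes together with the ground
#' truth. The genotype panel is restricted to genotyped individuals that
#' were actually encountered (plus stranded-style extras are not modelled).
#'
#' @param config a `scenario_config` (default [scenario_wsa_default()]).
#' @return List with `store`, `panel`, `truth` (pedigree, true frequencies,
#'   haplotypes, presence), and `config`.
#' @export
simulate_scenario <- function(config = scenario_wsa_default()) {
  gen <- simulate_genotypes(config)
  encs <- simulate_encounters(config, gen)
  truth <- gen$truth
  truth$presence <- encs$presence
  # biopsies come from encounters: only encountered whales carry genotypes
  keep <- gen$panel$ids %in% encs$store$individuals$individual_id
  panel <- genotype_panel(gen$panel$ids[keep],
                          gen$panel$alleles[keep, , drop = FALSE],
                          loci = gen$panel$loci,
                          mtdna = gen$panel$mtdna[keep])
  list(store = encs$store, panel = panel, truth = truth, config = config)
}

#' Write a simulated scenario to CSV files
#'
#' Emits the encounter CSV and genotype CSV consumed by [load_encounters()]
#' and [read_genotypes()], plus the ground truth as a pedigree CSV and a
#' presence CSV.
#'
#' @param scenario output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(encounters = file.path(dir, "encounters.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             pedigree = file.path(dir, "truth_pedigree.csv"),
             presence = file.path(dir, "truth_presence.csv"))
  write_encounters(scenario$store, paths["encounters"])
  write_genotypes(scenario$panel, paths["genotypes"])
  utils::write.csv(scenario$truth$pedigree, paths["pedigree"],
                   row.names = FALSE, na = "")
  pres <- scenario$truth$presence
  pres$start <- format(pres$start, "%Y-%m-%d")
  pres$end <- format(pres$end, "%Y-%m-%d")
  utils::write.csv(pres, paths["presence"], row.names = FALSE)
  invisible(paths)
}
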