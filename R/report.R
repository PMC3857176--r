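#' Per-cycle attendance report
#'
#' One row per seasonal cycle in which anything was sighted: number of
#' identified individuals, mean and maximum occurrence, and for individuals
#' seen on two or more days the occupancy sample size, mean, standard error
#' and range. The standard error is `NA` when fewer than two individuals
#' contribute an occupancy.
#'
#' @param store an [encounter_store].
#' @param path optional CSV output path.
#' @return data.frame with columns `cycle`, `n_identified`, `mean_occurrence`,
#'   `max_occurrence`, `n_occupancy`, `mean_occupancy`, `se_occupancy`,
#'   `min_occupancy`, `max_occupancy`.
#' @export
report_attendance <- function(store, path = NULL) {
  rec <- occurrence_occupancy(store)
  if (!nrow(rec)) stop_ws("store contains no sightings")
  sp <- split(rec, rec$cycle)
  out <- do.call(rbind, lapply(sp, function(r) {
    occ <- r$occupancy[!is.na(r$occupancy)]
    data.frame(cycle = r$cycle[1],
               n_identified = nrow(r),
               mean_occurrence = mean(r$occurrence),
               max_occurrence = max(r$occurrence),
               n_occupancy = length(occ),
               mean_occupancy = if (length(occ)) mean(occ) else NA_real_,
               se_occupancy = if (length(occ) >= 2)
                 stats::sd(occ) / sqrt(length(occ)) else NA_real_,
               min_occupancy = if (length(occ)) min(occ) else NA_real_,
               max_occupancy = if (length(occ)) max(occ) else NA_real_)
  }))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, na = "n/a")
  out
}

#' Occupancy by sex, with a Kruskal-Wallis comparison
#'
#' Convenience summary of within-cycle occupancy separated by sex (calves
#' excluded): per-sex n, mean and standard error, plus the Kruskal-Wallis
#' rank test across sexes.
#'
#' @param store an [encounter_store].
#' @return List with `summary` (data.frame) and `test` (`htest` or `NULL`
#'   when fewer than two sexes contribute).
#' @export
occupancy_by_sex <- function(store) {
  rec <- occurrence_occupancy(store)
  rec <- rec[!is.na(rec$occupancy), ]
  ind <- store$individuals
  rec$sex <- ind$sex[match(rec$individual_id, ind$individual_id)]
  calf <- ind$age_class[match(rec$individual_id, ind$individual_id)] ==
    "calf_of_year"
  rec <- rec[!calf, ]
  sp <- split(rec$occupancy, rec$sex)
  summary <- do.call(rbind, lapply(names(sp), function(s) data.frame(
    sex = s, n = length(sp[[s]]), mean = mean(sp[[s]]),
    se = if (length(sp[[s]]) >= 2)
      stats::sd(sp[[s]]) / sqrt(length(sp[[s]])) else NA_real_)))
  test <- if (length(sp) >= 2) stats::kruskal.test(rec$occupancy,
                                                   factor(rec$sex)) else NULL
  list(summary = summary, test = test)
}

#' Per-individual association report and network export
#'
#' The per-individual table (first and last sighting dates, number of
#' encounters, associates, maximum and mean HWI) sorted by decreasing mean
#' HWI, plus the network edge list. With no eligible individuals an empty
#' report is returned with a warning.
#'
#' @param store an [encounter_store].
#' @param threshold display threshold for network edges (default 0.3).
#' @param out_dir optional directory; writes `associations.csv`,
#'   `network_edges.csv`, `network_edges_nodes.csv` and `network.graphml`.
#' @return List with `individuals` (data.frame), `matrix`
#'   (the [association_matrix()] or `NULL`), `network` (edge/node list) and
#'   `summaries`.
#' @export
report_associations <- function(store, threshold = 0.3, out_dir = NULL) {
  ids <- eligible_individuals(store)
  if (!length(ids)) {
    warning("no individuals eligible for association analysis", call. = FALSE)
    empty <- data.frame(individual_id = character(), sex = character(),
                        first_seen = as.Date(character()),
                        last_seen = as.Date(character()),
                        n_encounters = integer(), n_associates = integer(),
                        max_hwi = numeric(), mean_hwi = numeric())
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      utils::write.csv(empty, file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
    }
    return(list(individuals = empty, matrix = NULL, network = NULL,
                summaries = NULL))
  }
  am <- association_matrix(store, ids)
  s <- am$summary
  firsts <- lapply(ids, function(id) sighting_history(store, id))
  s$sex <- store$individuals$sex[match(ids, store$individuals$individual_id)]
  s$first_seen <- as.Date(vapply(firsts, function(h)
    format(min(h$sighting_days)), ""))
  s$last_seen <- as.Date(vapply(firsts, function(h)
    format(max(h$sighting_days)), ""))
  s <- s[order(-s$mean_hwi, s$individual_id),
         c("individual_id", "sex", "first_seen", "last_seen", "n_encounters",
           "n_associates", "max_hwi", "mean_hwi")]
  rownames(s) <- NULL
  net <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(s, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)
    net <- export_network(am, threshold = threshold,
                          path = file.path(out_dir, "network_edges.csv"),
                          store = store,
                          graphml = file.path(out_dir, "network.graphml"))
  } else {
    net <- export_network(am, threshold = threshold, store = store)
  }
  list(individuals = s, matrix = am, network = net,
       summaries = association_summaries(am))
}

#' Operational sex ratio report
#'
#' @param store an [encounter_store].
#' @param exclude_calves drop calves of the year (default `TRUE`).
#' @param path optional CSV output path.
#' @return The [osr_table()] data.frame.
#' @export
report_osr <- function(store, exclude_calves = TRUE, path = NULL) {
  out <- osr_table(store, exclude_calves = exclude_calves)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Parent-offspring census report
#'
#' Runs the PO census over a genotype panel, attaches resighting classes
#' from the store when given, and cross-tabulates the detected PO pairs by
#' class pair.
#'
#' @param panel a [genotype_panel()] with at least two members.
#' @param store optional [encounter_store] supplying resighted /
#'   non-resighted classes (individuals absent from the store are labelled
#'   `unsighted`).
#' @param n_sim simulated pairs for the PO-vs-FS test per detected pair
#'   (0 = skip).
#' @param seed seed for the simulation test.
#' @param min_loci minimum shared typed loci.
#' @param out_dir optional directory; writes `po_census.csv` and
#'   `po_class_crosstab.csv`.
#' @return List with `census` (data.frame) and `crosstab` (table or `NULL`).
#' @export
report_kinship <- function(panel, store = NULL, n_sim = 0, seed = NULL,
                           min_loci = 6, out_dir = NULL) {
  if (length(panel$ids) < 2) stop_ws("need at least two genotyped individuals")
  classes <- NULL
  if (!is.null(store)) {
    status <- resighting_status(store)
    classes <- stats::setNames(rep("unsighted", length(panel$ids)),
                               panel$ids)
    known <- intersect(panel$ids, names(status))
    classes[known] <- status[known]
  }
  census <- po_census(panel, classes = classes, n_sim = n_sim, seed = seed,
                      min_loci = min_loci)
  crosstab <- NULL
  if (!is.null(classes) && nrow(census)) {
    pair_class <- apply(census[c("class1", "class2")], 1, function(x)
      paste(sort(x), collapse = " x "))
    crosstab <- table(pair_class)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(census, file.path(out_dir, "po_census.csv"),
                     row.names = FALSE)
    if (!is.null(crosstab))
      utils::write.csv(as.data.frame(crosstab),
                       file.path(out_dir, "po_class_crosstab.csv"),
                       row.names = FALSE)
  }
  list(census = census, crosstab = crosstab)
}

#' Full analysis report
#'
#' Orchestrates every analysis over a store (and optionally a genotype
#' panel): group-size statistics, pair sex composition, OSR with parity
#' tests, per-cycle attendance, occupancy by sex, association report with
#' network export, and the PO census. All tables are written as CSV files
#' under `out_dir` together with a plain-text metadata sidecar (input
#' checksums, package version, seed).
#'
#' @param store an [encounter_store].
#' @param panel optional [genotype_panel()].
#' @param out_dir output directory (created if needed).
#' @param seed seed for the kinship simulation test.
#' @param n_sim simulated pairs per PO pair for the PO-vs-FS test (0 = skip).
#' @param hwi_threshold network display threshold.
#' @param exclude_calves exclude calves from OSR and pair composition.
#' @param min_loci minimum shared typed loci for relatedness.
#' @return List with all component results, invisibly.
#' @export
whale_report <- function(store, panel = NULL, out_dir, seed = 1,
                         n_sim = 0, hwi_threshold = 0.3,
                         exclude_calves = TRUE, min_loci = 6) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  res$group_sizes <- group_size_stats(store)
  utils::write.csv(res$group_sizes, file.path(out_dir, "group_sizes.csv"),
                   row.names = FALSE)
  res$pair_composition <- pair_sex_composition(store)
  utils::write.csv(cbind(res$pair_composition$observed,
                         stats::setNames(res$pair_composition$expected[-1],
                                  paste0("exp_", names(
                                    res$pair_composition$expected)[-1]))),
                   file.path(out_dir, "pair_composition.csv"),
                   row.names = FALSE)
  res$osr <- report_osr(store, exclude_calves = exclude_calves,
                        path = file.path(out_dir, "osr.csv"))
  res$attendance <- report_attendance(store,
                                      path = file.path(out_dir,
                                                       "attendance.csv"))
  res$occupancy_by_sex <- occupancy_by_sex(store)
  res$associations <- report_associations(store, threshold = hwi_threshold,
                                          out_dir = out_dir)
  if (!is.null(panel) && length(panel$ids) >= 2)
    res$kinship <- report_kinship(panel, store = store, n_sim = n_sim,
                                  seed = seed, min_loci = min_loci,
                                  out_dir = out_dir)
  meta <- c(
    sprintf("whalesight version: %s",
            as.character(utils::packageVersion("whalesight"))),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %s", seed),
    sprintf("n_sim: %s", n_sim),
    sprintf("hwi_threshold: %s", hwi_threshold),
    sprintf("min_loci: %s", min_loci),
    sprintf("store: %d individuals, %d encounters, %d memberships",
            nrow(store$individuals), nrow(store$encounters),
            nrow(store$memberships)),
    if (!is.null(panel)) sprintf("panel: %d genotyped individuals, %d loci",
                                 length(panel$ids), length(panel$loci)),
    output_checksums(out_dir))
  writeLines(meta, file.path(out_dir, "run_metadata.txt"))
  invisible(res)
}

output_checksums <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) return(character())
  sums <- tools::md5sum(files)
  sprintf("md5 %s %s", sums, basename(names(sums)))
}
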