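#' Half-weight association index
#'
#' The half-weight index between individuals a and b is
#' `HWI = X / (X + 0.5 * (Ya + Yb))`, where `X` is the number of encounters
#' in which a and b were seen together, `Ya` the number in which a was seen
#' without b, and `Yb` the number in which b was seen without a. With the
#' encounter as sampling unit there is no "seen in the same sampling period
#' but not together" term. The index lies in [0, 1]; 1 means the pair
#' co-occurred in every encounter of either member.
#'
#' @param X,Ya,Yb nonnegative dyad counts (vectorised).
#' @return HWI value(s) in [0, 1].
#' @examples
#' hwi(3, 0, 0)   # always together -> 1
#' hwi(1, 3, 3)   # 0.25
#' @export
hwi <- function(X, Ya, Yb) {
  if (any(X < 0 | Ya < 0 | Yb < 0)) stop_ws("dyad counts must be nonnegative")
  denom <- X + 0.5 * (Ya + Yb)
  if (any(denom == 0))
    stop_ws("HWI undefined: all dyad counts are zero")
  X / denom
}

#' Individuals eligible for association analysis
#'
#' The social-structure analysis is restricted to resighted individuals that
#' were encountered at least once together with another resighted individual.
#' Resighted animals only ever seen alone or with non-resighted whales carry
#' no dyadic information among the resighted pool and are excluded.
#'
#' @param store an [encounter_store].
#' @return Character vector of eligible individual ids (sorted).
#' @export
eligible_individuals <- function(store) {
  status <- resighting_status(store)
  res <- names(status)[status == "resighted"]
  if (!length(res)) return(character())
  mem <- store$memberships[store$memberships$individual_id %in% res, ]
  n_res <- table(mem$encounter_id)
  social_enc <- names(n_res)[n_res >= 2]
  sort(unique(mem$individual_id[mem$encounter_id %in% social_enc]))
}

#' Encounter-level association matrix of half-weight indices
#'
#' Tallies dyad counts over all encounters in the store (multiple encounters
#' on the same day count separately) for the given individuals and returns
#' the symmetric matrix of half-weight indices together with per-individual
#' summaries. An individual's encounter total includes encounters with
#' animals outside `ids`, so solo sightings and sightings with non-eligible
#' whales still dilute its indices.
#'
#' @param store an [encounter_store].
#' @param ids individuals to include; defaults to [eligible_individuals()].
#' @return Object of class `association_matrix`: list with `ids`, `hwi`
#'   (symmetric matrix, diagonal `NA`), `X` (joint-encounter counts),
#'   `n_encounters` (per-individual totals), and a `summary` data.frame with
#'   per-individual `n_encounters`, `n_associates` (partners with `X >= 1`),
#'   `mean_hwi` (average over all other included ids, zeros included) and
#'   `max_hwi`.
#' @export
association_matrix <- function(store, ids = eligible_individuals(store)) {
  stopifnot(inherits(store, "encounter_store"))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_ws("ids must be unique")
  bad <- setdiff(ids, store$individuals$individual_id)
  if (length(bad)) stop_ws("unknown individual(s): ", paste(bad, collapse = ", "))
  n <- length(ids)
  enc_ids <- store$encounters$encounter_id
  # incidence matrix: encounters x individuals
  mem <- store$memberships[store$memberships$individual_id %in% ids, ]
  M <- matrix(0L, nrow = length(enc_ids), ncol = n,
              dimnames = list(enc_ids, ids))
  if (nrow(mem)) M[cbind(match(mem$encounter_id, enc_ids),
                         match(mem$individual_id, ids))] <- 1L
  X <- crossprod(M)
  tot <- encounter_counts(store)[ids]
  H <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    denom <- 0.5 * outer(tot, tot, `+`)  # X + 0.5(Ya + Yb) = (na + nb)/2
    H <- X / denom
    diag(H) <- NA_real_
  }
  off <- function(f, default) {
    if (n < 2) return(rep(default, n))
    vapply(seq_len(n), function(i) f(H[i, -i], X[i, -i]), 0)
  }
  summary <- data.frame(
    individual_id = ids,
    n_encounters = as.integer(tot),
    n_associates = as.integer(off(function(h, x) sum(x >= 1), 0)),
    mean_hwi = off(function(h, x) mean(h), NA_real_),
    max_hwi = off(function(h, x) max(h), NA_real_),
    row.names = NULL)
  structure(list(ids = ids, hwi = H, X = X, n_encounters = tot,
                 summary = summary),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("<association_matrix>", length(x$ids), "individuals\n")
  if (length(x$ids) >= 2) {
    v <- x$hwi[upper.tri(x$hwi)]
    cat("  nonzero dyads:", sum(v > 0), "of", length(v), "\n")
    if (any(v > 0)) cat("  HWI range (nonzero):",
                        format(min(v[v > 0]), digits = 3), "-",
                        format(max(v), digits = 3), "\n")
  }
  invisible(x)
}

#' Frequency distributions of association parameters
#'
#' Histogram tables of the three per-individual association parameters:
#' number of associates (integer counts), mean HWI (binned to 0.01) and
#' maximum HWI (rounded to the nearest 0.1, half up).
#'
#' @param am an [association_matrix()].
#' @return List of three tables: `associates`, `mean_hwi`, `max_hwi`.
#' @export
association_summaries <- function(am) {
  stopifnot(inherits(am, "association_matrix"))
  s <- am$summary
  list(
    associates = table(s$n_associates),
    mean_hwi = table(round_half_up(s$mean_hwi, 2)),
    max_hwi = table(round_half_up(s$max_hwi, 1)))
}

#' Export the association network as an edge list (and optionally GraphML)
#'
#' Writes one edge per dyad with a positive HWI, carrying the exact index,
#' the index rounded to the nearest 0.1 (the conventional display precision
#' for social network diagrams) and a `displayable` flag marking edges at or
#' above the display threshold. A node table carries sex, cow and calf
#' attributes when a store is supplied.
#'
#' @param am an [association_matrix()].
#' @param threshold display threshold on the exact HWI (default 0.3).
#' @param path optional path for the edge-list CSV; a node table is written
#'   alongside with suffix `_nodes.csv`.
#' @param store optional [encounter_store] for node attributes (`sex`,
#'   `is_cow` = listed as somebody's mother, `is_calf` = calf of the year).
#' @param graphml optional path for a GraphML file with the same attributes.
#' @return List with `edges` and `nodes` data.frames, invisibly.
#' @export
export_network <- function(am, threshold = 0.3, path = NULL, store = NULL,
                           graphml = NULL) {
  stopifnot(inherits(am, "association_matrix"))
  ids <- am$ids
  n <- length(ids)
  edges <- data.frame(source = character(), target = character(),
                      hwi = numeric(), hwi_rounded = numeric(),
                      displayable = logical())
  if (n >= 2) {
    ut <- which(upper.tri(am$hwi), arr.ind = TRUE)
    h <- am$hwi[ut]
    keep <- h > 0
    edges <- data.frame(source = ids[ut[keep, 1]], target = ids[ut[keep, 2]],
                        hwi = h[keep],
                        hwi_rounded = round_half_up(h[keep], 1),
                        displayable = h[keep] >= threshold)
    edges <- edges[order(-edges$hwi, edges$source, edges$target), ]
    rownames(edges) <- NULL
  }
  nodes <- data.frame(id = ids, sex = NA_character_, is_cow = NA,
                      is_calf = NA)
  if (!is.null(store)) {
    ind <- store$individuals[match(ids, store$individuals$individual_id), ]
    nodes$sex <- ind$sex
    nodes$is_cow <- ids %in% stats::na.omit(store$individuals$mother_id)
    nodes$is_calf <- ind$age_class == "calf_of_year"
  }
  if (!is.null(path)) {
    utils::write.csv(edges, path, row.names = FALSE)
    utils::write.csv(nodes, sub("\\.csv$", "_nodes.csv", path),
                     row.names = FALSE)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(list(edges = edges, nodes = nodes))
}

#' Correlation between sighting frequency and number of associates
#'
#' Pearson correlation between the number of encounters of each included
#' individual and its number of associates; animals seen more often have
#' more opportunities to accumulate associates.
#'
#' @param am an [association_matrix()].
#' @return List with `r`, `n` and `p` (from [stats::cor.test()]).
#' @export
sightings_vs_associates <- function(am) {
  stopifnot(inherits(am, "association_matrix"))
  s <- am$summary
  if (nrow(s) < 3) stop_ws("need at least 3 individuals")
  if (stats::sd(s$n_encounters) == 0 || stats::sd(s$n_associates) == 0)
    stop_ws("correlation undefined: constant vector")
  ct <- stats::cor.test(s$n_encounters, s$n_associates, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(s), p = ct$p.value)
}
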