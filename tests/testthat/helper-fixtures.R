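# Compact store builder: `groups` is a list of character vectors of member
# ids; one encounter per element. Optional named vectors set per-individual
# attributes; dates default to consecutive days.
make_store <- function(groups, dates = NULL, sexes = NULL, ages = NULL,
                       mothers = NULL, gse = NULL) {
  ids <- unique(unlist(groups))
  pick <- function(v, default) {
    out <- rep(default, length(ids))
    names(out) <- ids
    if (!is.null(v)) {
      nm <- intersect(names(v), ids)
      out[nm] <- v[nm]
    }
    unname(out)
  }
  individuals <- data.frame(
    individual_id = ids,
    sex = pick(sexes, "unknown"),
    age_class = pick(ages, "adult_or_juvenile"),
    has_fluke_photo = TRUE, has_dorsal_photo = FALSE, has_genotype = FALSE,
    mother_id = pick(mothers, NA_character_))
  if (is.null(dates)) dates <- as.Date("2002-10-01") + seq_along(groups) - 1
  dates <- as.Date(dates)
  encounters <- data.frame(
    encounter_id = sprintf("E%03d", seq_along(groups)),
    date = dates,
    sighting_no = stats::ave(seq_along(groups), as.character(dates),
                             FUN = seq_along),
    location_name = "Bay", latitude = NA_real_, longitude = NA_real_,
    group_size_estimate = if (is.null(gse)) lengths(groups) else gse)
  memberships <- data.frame(
    encounter_id = rep(encounters$encounter_id, lengths(groups)),
    individual_id = unlist(groups))
  encounter_store(individuals, encounters, memberships)
}

# store realising exact dyad counts for individuals "a" and "b":
# X joint encounters, Ya solo sightings of a, Yb of b
dyad_store <- function(X, Ya, Yb, extra = list()) {
  groups <- c(rep(list(c("a", "b")), X),
              rep(list("a"), Ya), rep(list("b"), Yb), extra)
  make_store(groups)
}

# randomized small store for oracle-equivalence checks
random_store <- function(n_ind_max = 10, n_enc_max = 20) {
  n_ind <- sample(2:n_ind_max, 1)
  n_enc <- sample(1:n_enc_max, 1)
  ids <- sprintf("I%02d", seq_len(n_ind))
  groups <- lapply(seq_len(n_enc), function(e)
    sample(ids, min(n_ind, 1 + stats::rpois(1, 1.2))))
  dates <- as.Date("2001-04-01") +
    sort(sample.int(700, n_enc, replace = TRUE))
  make_store(groups, dates = dates)
}

# brute-force triple-loop half-weight association oracle
oracle_assoc <- function(store, ids) {
  members <- lapply(store$encounters$encounter_id, function(e)
    store$memberships$individual_id[store$memberships$encounter_id == e])
  n <- length(ids)
  H <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- ids[i]; b <- ids[j]
      X <- Ya <- Yb <- 0
      for (m in members) {
        ina <- a %in% m; inb <- b %in% m
        if (ina && inb) X <- X + 1
        else if (ina) Ya <- Ya + 1
        else if (inb) Yb <- Yb + 1
      }
      H[i, j] <- X / (X + 0.5 * (Ya + Yb))
    }
  }
  H
}

# day-recount oracle for occurrence and occupancy
oracle_attendance <- function(store) {
  mem <- store$memberships
  date <- store$encounters$date[match(mem$encounter_id,
                                      store$encounters$encounter_id)]
  cyc <- seasonal_cycle(date)
  key <- unique(data.frame(id = mem$individual_id, cycle = cyc, date = date))
  out <- list()
  for (id in unique(key$id)) {
    for (cy in unique(key$cycle[key$id == id])) {
      d <- key$date[key$id == id & key$cycle == cy]
      out[[length(out) + 1L]] <- data.frame(
        individual_id = id, cycle = cy, occurrence = length(d),
        occupancy = if (length(d) >= 2) as.integer(max(d) - min(d))
          else NA_integer_)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$cycle, df$individual_id), ]
}

# equifrequent allele frequency panel
uniform_freqs <- function(n_loci = 10, n_alleles = 8) {
  out <- lapply(seq_len(n_loci), function(l) {
    f <- rep(1 / n_alleles, n_alleles)
    names(f) <- seq_len(n_alleles)
    attr(f, "null") <- 0
    f
  })
  names(out) <- paste0("L", seq_len(n_loci))
  class(out) <- "allele_freqs"
  out
}

# interleave per-locus allele matrices (from simulate_genotype_pairs) into
# the flat genotype vectors the pair-level API consumes
flat_genotypes <- function(sim) {
  L <- ncol(sim$a1)
  n <- nrow(sim$a1)
  g1 <- matrix(0L, n, 2 * L); g2 <- matrix(0L, n, 2 * L)
  for (l in seq_len(L)) {
    g1[, 2 * l - 1] <- sim$a1[, l]; g1[, 2 * l] <- sim$a2[, l]
    g2[, 2 * l - 1] <- sim$b1[, l]; g2[, 2 * l] <- sim$b2[, l]
  }
  list(g1 = g1, g2 = g2)
}

# a tiny three-member pedigree panel: mother, father, child
trio_panel <- function(seed = 11, n_loci = 10, n_alleles = 8) {
  set.seed(seed)
  draw <- function() sample.int(n_alleles, 2 * n_loci, replace = TRUE)
  mom <- draw(); dad <- draw()
  child <- integer(2 * n_loci)
  for (l in seq_len(n_loci)) {
    child[2 * l - 1] <- mom[2 * l - 1 + (runif(1) < 0.5)]
    child[2 * l] <- dad[2 * l - 1 + (runif(1) < 0.5)]
  }
  genotype_panel(c("mom", "dad", "child"), rbind(mom, dad, child),
                 mtdna = c("H1", "H2", "H1"))
}
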