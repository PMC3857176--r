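#' Build a validated encounter store
#'
#' An encounter store is the central container for a photo-identification
#' study: a table of individually identified animals, a table of encounters
#' (discrete data-collection events with one group of animals), and the
#' membership relation between them. All downstream analyses (attendance,
#' association indices, relatedness censuses) operate on a store.
#'
#' @param individuals data.frame with columns `individual_id`, `sex`
#'   (`"female"`, `"male"` or `"unknown"`), `age_class`
#'   (`"adult_or_juvenile"`, `"calf_of_year"` or `"yearling"`),
#'   `has_fluke_photo`, `has_dorsal_photo`, `has_genotype` (logical) and
#'   `mother_id` (NA when unknown).
#' @param encounters data.frame with columns `encounter_id`, `date` (Date or
#'   ISO 8601 string), `sighting_no` (integer order within a day),
#'   `location_name`, `latitude`, `longitude`, `group_size_estimate`.
#' @param memberships data.frame with columns `encounter_id`, `individual_id`;
#'   one row per identified group member.
#' @return An object of class `encounter_store`: a list with the three
#'   validated data.frames, encounters sorted by `(date, sighting_no)`.
#' @details Validation enforces: unique individual and encounter ids; every
#'   membership refers to a known encounter; each encounter has at least one
#'   member, no duplicated member, and a `group_size_estimate` at least the
#'   number of identified members (groups may contain unidentified animals,
#'   never fewer animals than were identified); calves of the year that occur
#'   in an encounter carry at least one identification feature; `mother_id`,
#'   when set, refers to a female or unknown-sex individual.
#' @seealso [load_encounters()], [resighting_status()], [classify_groups()]
#' @export
encounter_store <- function(individuals, encounters, memberships) {
  individuals <- as.data.frame(individuals)
  encounters <- as.data.frame(encounters)
  memberships <- as.data.frame(memberships)

  need_ind <- c("individual_id", "sex", "age_class", "has_fluke_photo",
                "has_dorsal_photo", "has_genotype", "mother_id")
  need_enc <- c("encounter_id", "date", "sighting_no", "location_name",
                "latitude", "longitude", "group_size_estimate")
  miss <- setdiff(need_ind, names(individuals))
  if (length(miss))
    stop_ws("individuals is missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(need_enc, names(encounters))
  if (length(miss))
    stop_ws("encounters is missing columns: ", paste(miss, collapse = ", "))

  individuals$individual_id <- as.character(individuals$individual_id)
  encounters$encounter_id <- as.character(encounters$encounter_id)
  memberships$encounter_id <- as.character(memberships$encounter_id)
  memberships$individual_id <- as.character(memberships$individual_id)
  encounters$date <- parse_iso_dates(encounters$date)

  if (anyDuplicated(individuals$individual_id))
    stop_ws("duplicated individual_id in individuals table")
  if (anyDuplicated(encounters$encounter_id))
    stop_ws("duplicated encounter_id in encounters table")

  bad_sex <- setdiff(unique(individuals$sex), c("female", "male", "unknown"))
  if (length(bad_sex))
    stop_ws("invalid sex value(s): ", paste(bad_sex, collapse = ", "))
  bad_age <- setdiff(unique(individuals$age_class),
                     c("adult_or_juvenile", "calf_of_year", "yearling"))
  if (length(bad_age))
    stop_ws("invalid age_class value(s): ", paste(bad_age, collapse = ", "))

  unknown_enc <- setdiff(memberships$encounter_id, encounters$encounter_id)
  if (length(unknown_enc))
    stop_ws("memberships refer to unknown encounter(s): ",
            paste(utils::head(unknown_enc, 5), collapse = ", "))
  unknown_ind <- setdiff(memberships$individual_id, individuals$individual_id)
  if (length(unknown_ind))
    stop_ws("memberships refer to unknown individual(s): ",
            paste(utils::head(unknown_ind, 5), collapse = ", "))

  dup <- duplicated(memberships[c("encounter_id", "individual_id")])
  if (any(dup))
    stop_ws("individual listed twice in one encounter: ",
            paste(unique(memberships$individual_id[dup]), collapse = ", "))

  n_members <- table(factor(memberships$encounter_id,
                            levels = encounters$encounter_id))
  if (any(n_members == 0))
    stop_ws("encounter(s) without any identified member: ",
            paste(names(n_members)[n_members == 0][1:min(5, sum(n_members == 0))],
                  collapse = ", "))
  too_small <- encounters$group_size_estimate < as.integer(n_members)
  if (any(too_small))
    stop_ws("group_size_estimate smaller than number of identified members ",
            "in encounter(s): ",
            paste(encounters$encounter_id[too_small], collapse = ", "))
  if (any(encounters$group_size_estimate < 1))
    stop_ws("group_size_estimate must be a positive integer")

  # calves of the year appearing in any encounter need >= 1 identification
  # feature, otherwise they could never have been linked across encounters
  seen <- unique(memberships$individual_id)
  calves <- individuals$age_class == "calf_of_year" &
    individuals$individual_id %in% seen
  no_feature <- calves & !(individuals$has_fluke_photo |
                             individuals$has_dorsal_photo |
                             individuals$has_genotype)
  if (any(no_feature))
    stop_ws("encountered calf_of_year without any identification feature: ",
            paste(individuals$individual_id[no_feature], collapse = ", "))

  mom <- individuals$mother_id
  has_mom <- !is.na(mom) & mom != ""
  if (any(has_mom)) {
    mom_sex <- individuals$sex[match(mom[has_mom], individuals$individual_id)]
    bad <- !is.na(mom_sex) & mom_sex == "male"
    if (any(bad))
      stop_ws("mother_id refers to a male individual for: ",
              paste(individuals$individual_id[has_mom][bad], collapse = ", "))
  }
  individuals$mother_id[!has_mom] <- NA_character_

  ord <- order(encounters$date, encounters$sighting_no)
  encounters <- encounters[ord, , drop = FALSE]
  rownames(encounters) <- NULL
  rownames(individuals) <- NULL
  rownames(memberships) <- NULL

  structure(list(individuals = individuals, encounters = encounters,
                 memberships = memberships),
            class = "encounter_store")
}

# Strict ISO 8601 (YYYY-MM-DD) day parser: rejects impossible calendar days
# such as 1999-02-30 and names the offending rows.
parse_iso_dates <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  ok_format <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  d[ok_format] <- as.Date(x[ok_format], format = "%Y-%m-%d")
  # as.Date silently rolls nothing but returns NA for invalid days
  bad <- is.na(d)
  if (any(bad))
    stop_ws("unparseable ", what, " value(s) at row(s) ",
            paste(utils::head(which(bad), 5), collapse = ", "), ": ",
            paste(utils::head(x[bad], 5), collapse = ", "))
  d
}

#' @export
print.encounter_store <- function(x, ...) {
  cat("<encounter_store>\n")
  cat("  individuals:", nrow(x$individuals), "\n")
  cat("  encounters: ", nrow(x$encounters), "\n")
  cat("  memberships:", nrow(x$memberships), "\n")
  if (nrow(x$encounters))
    cat("  dates:      ", format(min(x$encounters$date)), "to",
        format(max(x$encounters$date)), "\n")
  invisible(x)
}

#' Read an encounter table from CSV
#'
#' Reads the long-format encounter CSV (one row per individual per encounter)
#' and assembles a validated [encounter_store]. Columns: `encounter_id`,
#' `date`, `sighting_no`, `location_name`, `latitude`, `longitude`,
#' `group_size_estimate`, `individual_id`, `sex`, `age_class`,
#' `has_fluke_photo`, `has_dorsal_photo`, `has_genotype`, `mother_id`.
#' Every input row becomes exactly one encounter membership.
#'
#' @param path CSV file path.
#' @return An [encounter_store].
#' @export
load_encounters <- function(path) {
  if (!file.exists(path)) stop_ws("file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("encounter_id", "date", "sighting_no", "location_name",
            "latitude", "longitude", "group_size_estimate", "individual_id",
            "sex", "age_class", "has_fluke_photo", "has_dorsal_photo",
            "has_genotype", "mother_id")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_ws("encounter CSV is missing columns: ", paste(miss, collapse = ", "))

  raw$date <- parse_iso_dates(raw$date)
  to_log <- function(v) as.logical(v) | v %in% c("1", "true", "TRUE", "True")
  to_num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))

  ind <- raw[!duplicated(raw$individual_id),
             c("individual_id", "sex", "age_class", "has_fluke_photo",
               "has_dorsal_photo", "has_genotype", "mother_id")]
  for (cc in c("has_fluke_photo", "has_dorsal_photo", "has_genotype"))
    ind[[cc]] <- to_log(ind[[cc]])
  ind$mother_id[ind$mother_id == ""] <- NA_character_

  enc <- raw[!duplicated(raw$encounter_id),
             c("encounter_id", "date", "sighting_no", "location_name",
               "latitude", "longitude", "group_size_estimate")]
  enc$sighting_no <- as.integer(enc$sighting_no)
  enc$latitude <- to_num(enc$latitude)
  enc$longitude <- to_num(enc$longitude)
  enc$group_size_estimate <- as.integer(enc$group_size_estimate)

  mem <- raw[c("encounter_id", "individual_id")]
  encounter_store(ind, enc, mem)
}

#' Write an encounter store back to the long CSV schema
#'
#' Inverse of [load_encounters()]: one row per (encounter, individual), with
#' individual attributes repeated. Reloading the file reproduces the logical
#' content of the store.
#'
#' @param store an [encounter_store].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(store, path) {
  stopifnot(inherits(store, "encounter_store"))
  mem <- store$memberships
  enc <- store$encounters[match(mem$encounter_id,
                                store$encounters$encounter_id), ]
  ind <- store$individuals[match(mem$individual_id,
                                 store$individuals$individual_id), ]
  out <- cbind(enc, ind)
  out <- out[order(out$date, out$sighting_no, out$individual_id), ]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Resighting status of every individual
#'
#' An individual is *resighted* when it was identified in at least two
#' encounters; encounters on the same day count separately, so two groups on
#' one day already make a resighting. Individuals identified exactly once
#' (or declared but never encountered) are *non_resighted*.
#'
#' @param store an [encounter_store].
#' @return Named character vector (`"resighted"` / `"non_resighted"`) over
#'   all individuals in the store.
#' @export
resighting_status <- function(store) {
  stopifnot(inherits(store, "encounter_store"))
  n <- table(factor(store$memberships$individual_id,
                    levels = store$individuals$individual_id))
  out <- ifelse(as.integer(n) >= 2, "resighted", "non_resighted")
  names(out) <- store$individuals$individual_id
  out
}

#' Classify encounters as familiar or unfamiliar groups
#'
#' A group (encounter) is *familiar* when it contains at least one resighted
#' individual, and *unfamiliar* when it contains none.
#'
#' @param store an [encounter_store].
#' @return Named character vector (`"familiar"` / `"unfamiliar"`) over all
#'   encounters.
#' @export
classify_groups <- function(store) {
  status <- resighting_status(store)
  mem <- store$memberships
  fam_ids <- unique(mem$encounter_id[status[mem$individual_id] == "resighted"])
  out <- ifelse(store$encounters$encounter_id %in% fam_ids,
                "familiar", "unfamiliar")
  names(out) <- store$encounters$encounter_id
  out
}

#' Sighting history of one individual
#'
#' @param store an [encounter_store].
#' @param individual_id id of an individual that occurs in at least one
#'   encounter.
#' @return List with `individual_id`, `encounters` (the encounter rows sorted
#'   by date then sighting number) and `sighting_days` (distinct dates,
#'   ascending). Several encounters on one day yield one sighting day.
#' @export
sighting_history <- function(store, individual_id) {
  stopifnot(inherits(store, "encounter_store"))
  if (!individual_id %in% store$individuals$individual_id)
    stop_ws("unknown individual: ", individual_id)
  eids <- store$memberships$encounter_id[
    store$memberships$individual_id == individual_id]
  if (!length(eids))
    stop_ws("individual was never encountered: ", individual_id)
  enc <- store$encounters[store$encounters$encounter_id %in% eids, ]
  enc <- enc[order(enc$date, enc$sighting_no), ]
  rownames(enc) <- NULL
  list(individual_id = individual_id,
       encounters = enc,
       sighting_days = sort(unique(enc$date)))
}

# encounter counts per individual, as a named integer vector over all ids
encounter_counts <- function(store) {
  n <- table(factor(store$memberships$individual_id,
                    levels = store$individuals$individual_id))
  out <- as.integer(n)
  names(out) <- store$individuals$individual_id
  out
}
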