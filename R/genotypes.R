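#' Construct a genotype panel
#'
#' A genotype panel holds unordered diploid microsatellite genotypes for a
#' set of individuals at a fixed, ordered list of loci, with an optional
#' maternally inherited mtDNA haplotype per individual. Allele labels are
#' positive integers; 0 encodes a missing allele (a locus is treated as
#' missing when either allele is 0).
#'
#' @param ids character vector of individual ids (unique).
#' @param alleles integer matrix, one row per individual and two columns per
#'   locus (`locus1_a, locus1_b, locus2_a, ...`); 0 = missing.
#' @param loci locus names; default `L1..Ln`.
#' @param mtdna optional character vector of haplotypes (`NA` = unknown).
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(ids, alleles, loci = NULL, mtdna = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_ws("duplicated individual ids")
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != length(ids))
    stop_ws("alleles must have one row per individual")
  if (ncol(alleles) %% 2 != 0)
    stop_ws("alleles must have two columns per locus")
  storage.mode(alleles) <- "integer"
  if (any(alleles < 0, na.rm = TRUE)) stop_ws("allele labels must be >= 0")
  alleles[is.na(alleles)] <- 0L
  # a half-missing genotype is treated as fully missing
  n_loci <- ncol(alleles) / 2
  for (l in seq_len(n_loci)) {
    cols <- c(2 * l - 1, 2 * l)
    half <- xor(alleles[, cols[1]] == 0L, alleles[, cols[2]] == 0L)
    alleles[half, cols] <- 0L
  }
  loci <- loci %||% paste0("L", seq_len(n_loci))
  if (length(loci) != n_loci) stop_ws("length(loci) must match allele columns")
  if (is.null(mtdna)) mtdna <- rep(NA_character_, length(ids))
  mtdna <- as.character(mtdna)
  if (length(mtdna) != length(ids))
    stop_ws("mtdna must have one entry per individual")
  dimnames(alleles) <- list(ids, NULL)
  structure(list(ids = ids, loci = loci, alleles = alleles, mtdna = mtdna),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel>", length(x$ids), "individuals,",
      length(x$loci), "loci\n")
  typed <- colSums(x$alleles[, seq(1, ncol(x$alleles), by = 2), drop = FALSE]
                   != 0)
  cat("  typed per locus:", paste(typed, collapse = " "), "\n")
  cat("  mtDNA known:", sum(!is.na(x$mtdna)), "\n")
  invisible(x)
}

# genotype of one individual at one locus, c(a, b) or NULL when missing
panel_genotype <- function(panel, id, locus) {
  i <- match(id, panel$ids)
  if (is.na(i)) stop_ws("unknown individual: ", id)
  l <- if (is.character(locus)) match(locus, panel$loci) else locus
  g <- panel$alleles[i, c(2 * l - 1, 2 * l)]
  if (any(g == 0L)) NULL else unname(g)
}

#' Read a genotype table from CSV
#'
#' Expected columns: `individual_id`, `mtdna_haplotype` (may be empty), then
#' two columns per locus named `<locus>_a`, `<locus>_b`, with 0 for missing
#' alleles.
#'
#' @param path CSV file path.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_ws("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df))
    stop_ws("genotype CSV must have an individual_id column")
  mtdna <- if ("mtdna_haplotype" %in% names(df)) {
    h <- as.character(df$mtdna_haplotype)
    h[h == ""] <- NA_character_
    h
  } else NULL
  acols <- grep("_(a|b)$", names(df), value = TRUE)
  loci <- unique(sub("_(a|b)$", "", acols))
  ordered <- as.vector(rbind(paste0(loci, "_a"), paste0(loci, "_b")))
  miss <- setdiff(ordered, names(df))
  if (length(miss))
    stop_ws("genotype CSV missing allele columns: ",
            paste(miss, collapse = ", "))
  genotype_panel(df$individual_id, as.matrix(df[ordered]), loci = loci,
                 mtdna = mtdna)
}

#' Write a genotype panel to CSV
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(individual_id = panel$ids,
                   mtdna_haplotype = ifelse(is.na(panel$mtdna), "",
                                            panel$mtdna))
  a <- as.data.frame(panel$alleles)
  names(a) <- as.vector(rbind(paste0(panel$loci, "_a"),
                              paste0(panel$loci, "_b")))
  utils::write.csv(cbind(df, a), path, row.names = FALSE)
  invisible(path)
}

#' Read a GenePop genotype file
#'
#' Minimal reader for the classic GenePop format: a title line, one locus
#' name per line (or a single comma-separated line), then `Pop` sections with
#' `id , g1 g2 ...` rows where each genotype is 4 or 6 digits (two equal-width
#' allele codes; 00/000 = missing). Populations are pooled.
#'
#' @param path GenePop file path.
#' @return A [genotype_panel()] (no mtDNA).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop_ws("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop_ws("not a GenePop file: too short")
  body <- lines[-1]
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_at)) stop_ws("not a GenePop file: no Pop line")
  locus_lines <- body[seq_len(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  sample_lines <- body[-seq_len(pop_at[1] - 1)]
  sample_lines <- sample_lines[!grepl("^\\s*pop\\s*$", sample_lines,
                                      ignore.case = TRUE)]
  ids <- character(); rows <- list()
  for (ln in sample_lines) {
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop_ws("malformed GenePop sample line: ", ln)
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gts) != length(loci))
      stop_ws("sample ", id, " has ", length(gts), " genotypes for ",
              length(loci), " loci")
    w <- nchar(gts[1]) / 2
    if (!w %in% c(2, 3)) stop_ws("genotype codes must be 4 or 6 digits")
    a <- as.integer(substr(gts, 1, w))
    b <- as.integer(substr(gts, w + 1, 2 * w))
    ids <- c(ids, id)
    rows[[length(rows) + 1L]] <- as.vector(rbind(a, b))
  }
  genotype_panel(ids, do.call(rbind, rows), loci = loci)
}

#' Estimate allele frequencies from a genotype panel
#'
#' Frequencies are estimated by direct allele counting over all typed
#' individuals at each locus. When `null_alleles = TRUE`, a per-locus null
#' allele frequency is additionally estimated from the homozygote excess
#' (`(He - Ho) / (He + Ho)`, truncated at 0, where `He` is the expected and
#' `Ho` the observed heterozygosity) and the visible-allele frequencies are
#' rescaled to sum to `1 - null`.
#'
#' @param panel a [genotype_panel()].
#' @param null_alleles estimate null allele frequencies (default `FALSE`).
#' @param exclude optional ids to leave out of the counting (e.g. the focal
#'   pair of a relatedness estimate).
#' @return Object of class `allele_freqs`: a list with one named numeric
#'   vector of frequencies per locus; each carries a `null` attribute (0 when
#'   disabled).
#' @export
estimate_allele_frequencies <- function(panel, null_alleles = FALSE,
                                        exclude = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- !(panel$ids %in% exclude)
  A <- panel$alleles[keep, , drop = FALSE]
  out <- vector("list", length(panel$loci))
  names(out) <- panel$loci
  for (l in seq_along(panel$loci)) {
    a1 <- A[, 2 * l - 1]; a2 <- A[, 2 * l]
    typed <- a1 != 0L
    if (!any(typed))
      stop_ws("no typed individuals at locus ", panel$loci[l])
    alle <- c(a1[typed], a2[typed])
    tab <- table(alle)
    f <- as.numeric(tab) / length(alle)
    names(f) <- names(tab)
    nullf <- 0
    if (null_alleles) {
      ho <- mean(a1[typed] != a2[typed])
      he <- 1 - sum(f^2)
      nullf <- max(0, (he - ho) / (he + ho))
      f <- f * (1 - nullf)
    }
    attr(f, "null") <- nullf
    out[[l]] <- f
  }
  structure(out, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("<allele_freqs>", length(x), "loci;",
      paste(vapply(x, length, 0L), collapse = " "), "alleles per locus\n")
  nulls <- vapply(x, function(f) attr(f, "null"), 0)
  if (any(nulls > 0))
    cat("  null allele frequencies:",
        paste(format(nulls, digits = 2), collapse = " "), "\n")
  invisible(x)
}
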