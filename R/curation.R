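#' Age-range midpoint
#'
#' Numeric ages pass through; a range string `"A-B"` becomes `(A+B)/2`;
#' anything unparseable becomes `NA` (never an error), so downstream
#' missing-data exclusion handles it.
#'
#' @param age_field numeric or character vector.
#' @return numeric vector of ages in years, `NA` where unparseable.
#' @export
age_midpoint <- function(age_field) {
  if (is.numeric(age_field)) return(as.numeric(age_field))
  vapply(as.character(age_field), function(a) {
    if (is.na(a)) return(NA_real_)
    a <- trimws(a)
    if (grepl("^[0-9]+(\\.[0-9]+)?$", a)) return(as.numeric(a))
    m <- regmatches(a, regexec("^([0-9]+)\\s*[-–]\\s*([0-9]+)$", a))[[1]]
    if (length(m) == 3L) return((as.numeric(m[2]) + as.numeric(m[3])) / 2)
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

.STRAT_FIELDS <- c("manufacturer", "deviation_index", "sex", "age", "ethnicity")

#' Exclude rows with missing stratification data
#'
#' Rows missing any of the stratification fields (manufacturer, deviation
#' index, sex, age, ethnicity) are excluded; the log records each excluded
#' image with the first missing field. Ages are parsed with [age_midpoint]
#' first, so an unparseable age counts as missing.
#'
#' @param table data frame with `image_id`, `patient_id` and the
#'   stratification fields.
#' @return list with `retained` (data frame, with a numeric `age_years`
#'   column added) and `exclusions` (data frame `image_id`, `reason`).
#' @export
apply_inclusion_filters <- function(table) {
  stopifnot(all(c("image_id", .STRAT_FIELDS) %in% names(table)))
  table$age_years <- age_midpoint(table$age)
  first_missing <- rep(NA_character_, nrow(table))
  for (f in rev(.STRAT_FIELDS)) {
    col <- if (f == "age") table$age_years else table[[f]]
    miss <- is.na(col) | (is.character(col) & !nzchar(trimws(as.character(col))))
    miss[is.na(miss)] <- TRUE
    first_missing[miss] <- f
  }
  keep <- is.na(first_missing)
  exclusions <- data.frame(image_id = table$image_id[!keep],
                           reason = first_missing[!keep],
                           stringsAsFactors = FALSE)
  list(retained = table[keep, , drop = FALSE], exclusions = exclusions)
}

#' Keep one image per patient
#'
#' Selects exactly one row per `patient_id`, uniformly at random with the
#' seeded generator, to avoid patient-level leakage across partitions.
#' Deterministic given the seed.
#'
#' @param table data frame with `patient_id` and `image_id`.
#' @param seed integer seed.
#' @return the deduplicated data frame, ordered by `image_id`.
#' @export
select_one_per_patient <- function(table, seed = 1L) {
  set.seed(seed)
  table <- table[order(table$image_id), , drop = FALSE]
  groups <- split(seq_len(nrow(table)), table$patient_id)
  pick <- vapply(groups, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  out <- table[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Largest-remainder (Hamilton) allocation of n into parts proportional to
# fractions; ties broken by part order.
#' @keywords internal
largest_remainder <- function(n, fractions) {
  target <- n * fractions
  base <- floor(target)
  rem <- target - base
  short <- n - sum(base)
  if (short > 0L) {
    order_ix <- order(-rem, seq_along(rem))
    base[order_ix[seq_len(short)]] <- base[order_ix[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Stratified train/tune/test partition
#'
#' Groups rows into strata by the joint key of the stratification fields
#' (age binned into decades, deviation index into observed terciles), then
#' within each stratum shuffles with the seeded generator and allocates by
#' largest-remainder rounding of the target fractions. A final adjustment
#' pass moves single rows between splits (within the strata where the
#' allocation is most over target) so that the global split sizes equal the
#' largest-remainder allocation of the full table — exact whenever
#' `n * fraction` is an integer. Strata with fewer than 3 rows fall back to
#' a coarser key (dropping the deviation-index bin, then the age bin).
#'
#' @param table deduplicated data frame (one row per patient) containing
#'   the stratification fields; `age_years` is computed if absent.
#' @param fractions numeric vector of length 3 summing to 1 (default the
#'   64/16/20 train/tune/test split).
#' @param strata character vector of stratification fields.
#' @param seed integer seed.
#' @return data frame `image_id`, `split` (`train`/`tune`/`test`).
#' @export
stratified_partition <- function(table,
                                 fractions = c(train = 0.64, tune = 0.16, test = 0.20),
                                 strata = .STRAT_FIELDS,
                                 seed = 1L) {
  stopifnot(length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  splits <- names(fractions) %||% c("train", "tune", "test")
  if (is.null(names(fractions))) names(fractions) <- splits
  if (anyDuplicated(table$image_id)) stop("image ids must be unique")

  if (!"age_years" %in% names(table)) table$age_years <- age_midpoint(table$age)
  n <- nrow(table)

  age_bin <- floor(table$age_years / 10)
  di <- table$deviation_index
  di_cuts <- stats::quantile(di, probs = c(1 / 3, 2 / 3), na.rm = TRUE,
                             names = FALSE, type = 7)
  di_bin <- findInterval(di, di_cuts)  # 0/1/2 terciles

  key_full <- paste(table$manufacturer, table$sex, table$ethnicity,
                    age_bin, di_bin, sep = "|")
  key_nodi <- paste(table$manufacturer, table$sex, table$ethnicity,
                    age_bin, sep = "|")
  key_noage <- paste(table$manufacturer, table$sex, table$ethnicity, sep = "|")

  key <- key_full
  small <- names(which(table(key) < 3L))
  key[key %in% small] <- paste0("~", key_nodi[key %in% small])
  small <- names(which(table(key) < 3L))
  key[key %in% small] <- paste0("~~", key_noage[key %in% small])
  small <- names(which(table(key) < 3L))
  key[key %in% small] <- "~~~rest"

  set.seed(seed)
  assignment <- rep(NA_character_, n)
  counts <- matrix(0L, nrow = 0L, ncol = 3L)
  stratum_ids <- sort(unique(key))
  alloc <- list()
  for (s in stratum_ids) {
    ix <- which(key == s)
    ix <- ix[sample.int(length(ix))]
    k <- largest_remainder(length(ix), fractions)
    assignment[ix] <- rep(splits, times = k)
    alloc[[s]] <- list(ix = ix, k = k)
  }

  # global correction toward the exact largest-remainder totals
  target <- largest_remainder(n, fractions)
  names(target) <- splits
  for (pass in seq_len(2L * n)) {
    have <- vapply(splits, function(sp) sum(assignment == sp), integer(1))
    over <- splits[have > target]
    under <- splits[have < target]
    if (!length(over)) break
    o <- over[1]; u <- under[1]
    # move one row from o to u in the stratum where o is most above its target
    excess <- vapply(stratum_ids, function(s) {
      ix <- alloc[[s]]$ix
      sum(assignment[ix] == o) - length(ix) * fractions[[o]]
    }, numeric(1))
    cand <- stratum_ids[order(-excess)]
    moved <- FALSE
    for (s in cand) {
      ix <- alloc[[s]]$ix
      pool <- ix[assignment[ix] == o]
      if (length(pool)) {
        assignment[pool[length(pool)]] <- u
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }

  data.frame(image_id = table$image_id, split = assignment,
             stringsAsFactors = FALSE)
}
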