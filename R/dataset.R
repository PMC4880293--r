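# Observation datasets: per-day, per-treatment hairpin read-pair counts
# plus the conversion profiles needed to interpret them.

#' Observation dataset of hairpin BS/oxBS dyad counts
#'
#' @param counts Data frame with columns `day` (nonnegative integer),
#'   `treatment` (`"bs"` or `"ox"`) and the four read-pair counts `TT`,
#'   `TC`, `CT`, `CC` (nonnegative integers).  At most one row per
#'   (day, treatment).
#' @param profiles Conversion profiles: either `NULL` (ideal conversion,
#'   all probabilities 1), a list `list(bs = , ox = )` of
#'   [conversion_profile()]s applied to every day, or a data frame with
#'   columns `day`, `treatment`, `c`, `d`, `e_or_f` (a row with `day = NA`
#'   is the fallback for days without their own row).
#' @param locus Locus label.
#' @param cpg_position CpG position within the locus, or `"aggregate"`
#'   for counts pooled over positions.
#' @param divisions_per_day Number of cell divisions per observation day;
#'   the default 1 encodes one division every 24 hours, so the division
#'   index of day `d` is `d`.
#' @return An object of class `"observation_dataset"`.
#' @export
observation_dataset <- function(counts, profiles = NULL, locus = "locus",
                                cpg_position = "aggregate",
                                divisions_per_day = 1L) {
  need <- c("day", "treatment", OBS_STATES)
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stop("`counts` must have columns day, treatment, TT, TC, CT, CC")
  }
  counts <- counts[need]
  if (any(!counts$treatment %in% c("bs", "ox"))) {
    stop("treatment must be 'bs' or 'ox'")
  }
  if (any(counts$day < 0 | counts$day != round(counts$day))) {
    stop("days must be nonnegative integers")
  }
  cnt <- as.matrix(counts[OBS_STATES])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be nonnegative integers")
  }
  key <- paste(counts$day, counts$treatment)
  if (anyDuplicated(key)) {
    stop("duplicate (day, treatment) rows: ", paste(key[duplicated(key)], collapse = ", "))
  }
  counts <- counts[order(counts$day, counts$treatment), , drop = FALSE]
  rownames(counts) <- NULL
  if (divisions_per_day < 1 || divisions_per_day != round(divisions_per_day)) {
    stop("`divisions_per_day` must be a positive integer")
  }
  profiles <- .normalize_profiles(profiles)
  structure(
    list(
      locus = locus, cpg_position = as.character(cpg_position),
      counts = counts, profiles = profiles,
      days = sort(unique(counts$day)),
      divisions_per_day = as.integer(divisions_per_day)
    ),
    class = "observation_dataset"
  )
}

.normalize_profiles <- function(profiles) {
  if (is.null(profiles)) {
    return(NULL)
  }
  if (is.data.frame(profiles)) {
    need <- c("day", "treatment", "c", "d", "e_or_f")
    if (!all(need %in% names(profiles))) {
      stop("profile table must have columns day, treatment, c, d, e_or_f")
    }
    return(profiles[need])
  }
  if (is.list(profiles) && all(c("bs", "ox") %in% names(profiles)) &&
    inherits(profiles$bs, "conversion_profile") &&
    inherits(profiles$ox, "conversion_profile")) {
    return(data.frame(
      day = NA_integer_, treatment = c("bs", "ox"),
      c = c(profiles$bs$c, profiles$ox$c),
      d = c(profiles$bs$d, profiles$ox$d),
      e_or_f = c(profiles$bs$e, profiles$ox$f)
    ))
  }
  stop("`profiles` must be NULL, list(bs =, ox =) of conversion profiles, or a data frame")
}

#' Conversion profile in effect for one day and treatment
#'
#' Looks up the dataset's profile table: an exact (day, treatment) row
#' wins, otherwise the treatment's `day = NA` fallback row; a dataset
#' without profiles uses ideal conversion (all probabilities 1).
#'
#' @param data An [observation_dataset()].
#' @param day Observation day.
#' @param treatment `"bs"` or `"ox"`.
#' @return A [conversion_profile()].
#' @export
get_profile <- function(data, day, treatment) {
  stopifnot(inherits(data, "observation_dataset"))
  treatment <- match.arg(treatment, c("bs", "ox"))
  tab <- data$profiles
  if (is.null(tab)) {
    return(if (treatment == "bs") {
      conversion_profile("bs", 1, 1, e = 1, day = day)
    } else {
      conversion_profile("ox", 1, 1, f = 1, day = day)
    })
  }
  hit <- tab[!is.na(tab$day) & tab$day == day & tab$treatment == treatment, , drop = FALSE]
  if (nrow(hit) == 0L) {
    hit <- tab[is.na(tab$day) & tab$treatment == treatment, , drop = FALSE]
  }
  if (nrow(hit) == 0L) {
    stop("no conversion profile for treatment '", treatment, "' at day ", day)
  }
  hit <- hit[1L, ]
  if (treatment == "bs") {
    conversion_profile("bs", c = hit$c, d = hit$d, e = hit$e_or_f, day = day)
  } else {
    conversion_profile("ox", c = hit$c, d = hit$d, f = hit$e_or_f, day = day)
  }
}

#' Read-pair counts for one day and treatment
#'
#' @inheritParams get_profile
#' @return Named integer vector over `TT, TC, CT, CC`, or `NULL` if the
#'   dataset has no row for this (day, treatment).
#' @export
counts_for <- function(data, day, treatment) {
  stopifnot(inherits(data, "observation_dataset"))
  row <- data$counts[data$counts$day == day & data$counts$treatment == treatment, , drop = FALSE]
  if (nrow(row) == 0L) {
    return(NULL)
  }
  out <- as.numeric(row[1L, OBS_STATES])
  names(out) <- OBS_STATES
  out
}

#' @export
print.observation_dataset <- function(x, ...) {
  cat(
    "Hairpin BS/oxBS dyad counts for locus '", x$locus, "' (",
    x$cpg_position, ")\n",
    sep = ""
  )
  cat(
    "days:", paste(x$days, collapse = ", "),
    "| divisions per day:", x$divisions_per_day, "\n"
  )
  print(x$counts)
  if (is.null(x$profiles)) {
    cat("conversion: ideal (no profile table attached)\n")
  } else {
    cat("conversion profiles:\n")
    print(x$profiles)
  }
  invisible(x)
}

# ---- TSV input/output -------------------------------------------------

.COUNT_COLS <- c(
  "locus", "cpg_position", "day", "treatment",
  "count_TT", "count_TC", "count_CT", "count_CC"
)

#' Read a dyad count table
#'
#' Reads a tab-separated count table with header columns `locus`,
#' `cpg_position`, `day`, `treatment`, `count_TT`, `count_TC`,
#' `count_CT`, `count_CC` and returns one [observation_dataset()] per
#' locus (aggregating CpG positions) or per (locus, position).
#' Malformed rows are reported with their line number in the file.
#'
#' @param path Path to the counts TSV.
#' @param errors_path Optional path to a conversion-error TSV with columns
#'   `locus`, `day`, `treatment`, `c`, `d`, `e_or_f`; matching rows are
#'   attached to each dataset.
#' @param aggregate If `TRUE` (default), counts are summed over CpG
#'   positions within a locus; otherwise one dataset per position.
#' @param divisions_per_day Passed to [observation_dataset()].
#' @return Named list of [observation_dataset()]s.
#' @export
read_counts <- function(path, errors_path = NULL, aggregate = TRUE,
                        divisions_per_day = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.COUNT_COLS, names(tab))
  if (length(missing)) {
    stop("count table ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  line <- seq_len(nrow(tab)) + 1L # header is line 1
  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop("count table ", path, ": ", what, " at line ",
        paste(line[cond], collapse = ", "),
        call. = FALSE
      )
    }
  }
  cnt <- as.matrix(tab[paste0("count_", OBS_STATES)])
  bad_row(!tab$treatment %in% c("bs", "ox"), "unknown treatment")
  bad_row(apply(cnt, 1, function(r) any(!is.finite(r) | r < 0 | r != round(r))),
    "negative or non-integer count")
  bad_row(!is.finite(tab$day) | tab$day < 0 | tab$day != round(tab$day),
    "invalid day")
  key <- paste(tab$locus, tab$cpg_position, tab$day, tab$treatment)
  bad_row(duplicated(key), "duplicate (locus, position, day, treatment)")

  errors <- if (!is.null(errors_path)) read_conversion_errors(errors_path) else NULL
  groups <- if (aggregate) tab$locus else paste(tab$locus, tab$cpg_position, sep = ":")
  out <- list()
  for (g in unique(groups)) {
    sub <- tab[groups == g, , drop = FALSE]
    counts <- stats::aggregate(
      sub[paste0("count_", OBS_STATES)],
      by = list(day = sub$day, treatment = sub$treatment), FUN = sum
    )
    names(counts)[3:6] <- OBS_STATES
    prof <- NULL
    if (!is.null(errors)) {
      prof <- errors[errors$locus == sub$locus[1L], c("day", "treatment", "c", "d", "e_or_f")]
      if (nrow(prof) == 0L) prof <- NULL
    }
    out[[g]] <- observation_dataset(counts,
      profiles = prof, locus = sub$locus[1L],
      cpg_position = if (aggregate) "aggregate" else sub$cpg_position[1L],
      divisions_per_day = divisions_per_day
    )
  }
  out
}

#' Write dyad count tables
#'
#' @param datasets An [observation_dataset()] or a list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(datasets, path) {
  if (inherits(datasets, "observation_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    data.frame(
      locus = d$locus, cpg_position = d$cpg_position,
      day = d$counts$day, treatment = d$counts$treatment,
      count_TT = d$counts$TT, count_TC = d$counts$TC,
      count_CT = d$counts$CT, count_CC = d$counts$CC
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a conversion-error table
#'
#' Tab-separated with header `locus`, `day`, `treatment`, `c`, `d`,
#' `e_or_f` (the last column holds `e` for BS rows and `f` for oxBS
#' rows).
#'
#' @param path TSV path.
#' @return Data frame of conversion probabilities.
#' @export
read_conversion_errors <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "day", "treatment", "c", "d", "e_or_f")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("conversion table ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(!tab$treatment %in% c("bs", "ox"))) stop("unknown treatment in ", path)
  probs <- as.matrix(tab[c("c", "d", "e_or_f")])
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    stop("conversion probabilities in ", path, " must lie in [0, 1]")
  }
  tab[need]
}

#' @rdname read_conversion_errors
#' @param profiles Data frame as returned by [read_conversion_errors()].
#' @export
write_conversion_errors <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
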