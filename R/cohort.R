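#' @keywords internal
"_PACKAGE"

# Canonical column set for a cohort table. HVPG is optional (screening use);
# cholesterol and GGT are optional labs (only Forns needs them).
.cohort_numeric_cols <- c("age", "ast", "alt", "ggt", "albumin",
                          "bilirubin_total", "cholesterol", "plt", "inr",
                          "hvpg")
.cohort_required_cols <- c("id", "age", "sex", "ast", "alt", "albumin",
                           "plt", "inr")
.cohort_all_cols <- c("id", "age", "sex", "etiology", "child_pugh",
                      "ascites", "ast", "alt", "ggt", "albumin",
                      "bilirubin_total", "cholesterol", "plt", "inr", "hvpg")

.etiology_levels <- c("HBV", "HCV", "alcohol", "PBC", "autoimmune",
                      "cryptogenic")
.viral_etiologies <- c("HBV", "HCV")
.ascites_levels <- c("none", "mild", "moderate_severe")

#' Classify an HVPG measurement into portal-hypertension grades
#'
#' The hepatic venous pressure gradient (HVPG, mmHg) is graded with
#' inclusive lower bounds: clinically significant portal hypertension
#' (CSPH) at HVPG >= 10 mmHg, severe portal hypertension (SPH) at
#' HVPG >= 12 mmHg. Grade 1 is HVPG < 10, grade 2 is 10 <= HVPG < 12,
#' grade 3 is HVPG >= 12.
#'
#' @param hvpg numeric vector of HVPG values in mmHg; finite, >= 0.
#' @return data frame with logical columns \code{csph}, \code{sph} and
#'   integer \code{grade} (1, 2 or 3), one row per input value.
#' @examples
#' classify_hvpg(c(9.9, 10, 12))
#' @export
classify_hvpg <- function(hvpg) {
  if (length(hvpg) == 0L) stop("hvpg must be non-empty")
  if (!is.numeric(hvpg) || any(!is.finite(hvpg)) || any(hvpg < 0))
    stop("hvpg must be finite and >= 0 (mmHg)")
  csph <- hvpg >= 10
  sph <- hvpg >= 12
  data.frame(csph = csph, sph = sph, grade = 1L + csph + sph)
}

# Normalise one categorical column to canonical labels; unknown values
# become NA (reported by the caller's validator).
.canon_factor <- function(x, levels, aliases = list()) {
  x <- trimws(as.character(x))
  low <- tolower(x)
  out <- rep(NA_character_, length(x))
  for (lev in levels) out[low == tolower(lev)] <- lev
  for (alias in names(aliases)) out[low == alias] <- aliases[[alias]]
  out
}

#' Read and validate a patient cohort from a delimited text file
#'
#' Reads a CSV/TSV with a header row, maps columns to the canonical schema,
#' normalises categorical labels, and validates every row. Rows failing
#' validation are collected into an error report (attribute
#' \code{"validation"}), never silently dropped. Albumin values are expected
#' on the ~20--55 numeric scale used by every printed cutoff; if the column
#' looks like the g/dL scale (values < 10) a warning is emitted and
#' \code{albumin_gdl_to_gl = TRUE} rescales by 10.
#'
#' @param path path to a delimited text file.
#' @param col_map optional named character vector mapping canonical names
#'   (names) to file column names (values), or a path to a YAML/JSON file
#'   with such a mapping.
#' @param sep field separator; inferred from the extension (".tsv" uses tab)
#'   when NULL.
#' @param albumin_gdl_to_gl multiply albumin by 10 when it appears to be on
#'   the g/dL scale.
#' @param provenance free-text label stored on the cohort.
#' @return object of class \code{ph_cohort}: a data frame of validated
#'   records with the canonical columns.
#' @export
read_cohort <- function(path, col_map = NULL, sep = NULL,
                        albumin_gdl_to_gl = FALSE, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (is.character(col_map) && length(col_map) == 1L && file.exists(col_map))
    col_map <- unlist(read_cohort_config(col_map))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw))
        stop("mapped column '", src, "' (for '", canon, "') not in file")
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.cohort_required_cols, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  as_cohort(raw, albumin_gdl_to_gl = albumin_gdl_to_gl,
            provenance = provenance)
}

#' Read a column-mapping / analysis configuration file (YAML or JSON)
#' @param path file path ending in .yaml/.yml or .json.
#' @return named list.
#' @export
read_cohort_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Build a validated cohort from a data frame
#'
#' @param df data frame with the canonical columns (see
#'   \code{\link{read_cohort}}); extra columns are dropped.
#' @param albumin_gdl_to_gl rescale albumin by 10 (g/dL to the working
#'   scale).
#' @param provenance free-text label.
#' @return \code{ph_cohort} object. Row-level validation failures are
#'   reported in the \code{"validation"} attribute as a data frame with
#'   \code{row}, \code{field} and \code{reason}; offending rows are excluded
#'   from the cohort. An error is thrown only if no valid row remains.
#' @export
as_cohort <- function(df, albumin_gdl_to_gl = FALSE, provenance = "data") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(.cohort_all_cols, names(df)))
    df[[col]] <- rep(NA, nrow(df))
  problems <- data.frame(row = integer(), field = character(),
                         reason = character(), stringsAsFactors = FALSE)
  note <- function(rows, field, reason) {
    if (length(rows))
      problems <<- rbind(problems, data.frame(row = rows, field = field,
                                              reason = reason,
                                              stringsAsFactors = FALSE))
  }

  for (col in .cohort_numeric_cols) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    note(bad, col, "unparseable numeric")
    df[[col]] <- num
  }

  df$id <- as.character(df$id)
  df$sex <- .canon_factor(df$sex, c("male", "female"),
                          list(m = "male", f = "female"))
  df$etiology <- .canon_factor(df$etiology, .etiology_levels,
                               list(pbc = "PBC", hbv = "HBV", hcv = "HCV"))
  df$child_pugh <- .canon_factor(df$child_pugh, c("A", "B", "C"))
  df$ascites <- .canon_factor(df$ascites, .ascites_levels,
                              list(no = "none",
                                   "moderate-severe" = "moderate_severe"))

  # unit heuristic on the column, not single outliers: a g/dL-scale column
  # sits around 3-5, the working scale around 20-55
  alb <- df$albumin
  if (sum(!is.na(alb)) > 0 && stats::median(alb, na.rm = TRUE) < 10) {
    if (albumin_gdl_to_gl) {
      df$albumin <- alb * 10
    } else {
      warning("albumin column looks like the g/dL scale (median < 10); ",
              "printed index cutoffs assume the ~20-55 numeric scale. ",
              "Use albumin_gdl_to_gl = TRUE to convert.")
    }
  }

  # strictly-positive labs; age > 0; hvpg >= 0 when present
  for (col in c("age", "ast", "alt", "ggt", "albumin", "cholesterol",
                "plt", "inr", "bilirubin_total"))
    note(which(!is.na(df[[col]]) & df[[col]] <= 0), col, "must be > 0")
  note(which(!is.na(df$hvpg) & (df$hvpg < 0 | !is.finite(df$hvpg))),
       "hvpg", "must be finite and >= 0")
  for (col in setdiff(.cohort_required_cols, "id")) {
    already <- problems$row[problems$field == col]
    note(setdiff(which(is.na(df[[col]])), already), col,
         "missing required value")
  }

  bad_rows <- sort(unique(problems$row))
  keep <- df[setdiff(seq_len(nrow(df)), bad_rows), .cohort_all_cols,
             drop = FALSE]
  if (anyDuplicated(keep$id)) stop("duplicate patient ids in cohort")
  if (nrow(keep) == 0L && nrow(df) > 0L)
    stop("no valid rows; first problem: row ", problems$row[1], ", field ",
         problems$field[1], " (", problems$reason[1], ")")
  rownames(keep) <- NULL
  structure(keep, class = c("ph_cohort", "data.frame"),
            provenance = provenance, validation = problems)
}

#' Write a cohort to CSV in canonical column order
#' @param cohort \code{ph_cohort} or data frame.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, .cohort_all_cols],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.ph_cohort <- function(x, ...) {
  cat(sprintf("<ph_cohort> %d patients (%s)\n", nrow(x),
              attr(x, "provenance")))
  v <- attr(x, "validation")
  if (!is.null(v) && nrow(v))
    cat(sprintf("  %d row(s) excluded by validation\n",
                length(unique(v$row))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Split a cohort into the study's subgroups
#'
#' Partitions along one of the subgroup axes used in the subgroup analysis:
#' Child-Pugh A vs B/C, viral (HBV/HCV) vs non-viral etiology, or sex.
#' The partition is exhaustive and disjoint; an empty subgroup is returned
#' with zero rows and a warning so downstream analyses can skip it.
#'
#' @param cohort \code{ph_cohort} object.
#' @param axis one of \code{"child_pugh_AB_C"}, \code{"etiology_viral_nonviral"},
#'   \code{"sex"}.
#' @return named list of \code{ph_cohort} objects.
#' @export
split_subgroups <- function(cohort,
                            axis = c("child_pugh_AB_C",
                                     "etiology_viral_nonviral", "sex")) {
  axis <- match.arg(axis)
  df <- as.data.frame(cohort)
  key <- switch(axis,
    child_pugh_AB_C = {
      if (any(is.na(df$child_pugh))) stop("child_pugh missing for some records")
      ifelse(df$child_pugh == "A", "child_pugh_A", "child_pugh_BC")
    },
    etiology_viral_nonviral = {
      if (any(is.na(df$etiology))) stop("etiology missing for some records")
      ifelse(df$etiology %in% .viral_etiologies, "viral", "nonviral")
    },
    sex = {
      if (any(is.na(df$sex))) stop("sex missing for some records")
      df$sex
    })
  groups <- switch(axis,
    child_pugh_AB_C = c("child_pugh_A", "child_pugh_BC"),
    etiology_viral_nonviral = c("viral", "nonviral"),
    sex = c("male", "female"))
  out <- lapply(groups, function(g) {
    sub <- df[key == g, , drop = FALSE]
    rownames(sub) <- NULL
    structure(sub, class = c("ph_cohort", "data.frame"),
              provenance = paste0(attr(cohort, "provenance"), ":", g))
  })
  names(out) <- groups
  empty <- groups[vapply(out, nrow, 0L) == 0L]
  if (length(empty))
    warning("empty subgroup(s): ", paste(empty, collapse = ", "),
            "; downstream analyses will be skipped for them")
  out
}
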