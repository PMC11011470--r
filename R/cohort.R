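#' Canonical abnormality entities
#'
#' The seven pathological entities evaluated by the pipeline, in the fixed
#' (alphabetical) order used for every per-entity output.
#'
#' @return Character vector of the seven entity identifiers.
#' @export
#' @examples
#' chest_entities()
chest_entities <- function() {
  c("adenopathy", "atelectasis", "fracture", "pleural_effusion",
    "pneumonia", "pneumothorax", "tumor")
}

#' Canonical cohort CSV column order
#' @keywords internal
cohort_columns <- function() {
  ent <- chest_entities()
  c("patient_id", "age", "sex", "foreign_material",
    as.vector(rbind(paste0("gold_", ent), paste0("score_", ent))))
}

#' Construct a cohort object
#'
#' A cohort is a per-patient table: identifier, covariates (age in years,
#' sex coded 0 = male / 1 = female, foreign-material flag) and, for each of
#' the seven entities, a binary gold-standard label (`gold_<entity>`) and a
#' continuous AI probability score in \[0, 1\] (`score_<entity>`).
#'
#' @param df data.frame with the canonical cohort columns (see
#'   [cohort_columns()]); extra columns are dropped.
#' @param provenance free-text origin (file path, or generator seed/config
#'   digest).
#' @return A `cohort` object (a data.frame subclass).
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing cohort column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, cols, drop = FALSE]
  df$patient_id <- as.character(df$patient_id)
  # accept M/F sidecar coding for sex on the way in
  if (is.character(df$sex) || is.factor(df$sex)) {
    s <- toupper(as.character(df$sex))
    s[s == "M"] <- "0"
    s[s == "F"] <- "1"
    df$sex <- suppressWarnings(as.integer(s))
  }
  for (col in setdiff(cols, "patient_id")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  int_cols <- c("age", "sex", "foreign_material", paste0("gold_", chest_entities()))
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  rownames(df) <- NULL
  structure(df, class = c("cohort", "data.frame"), provenance = provenance)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d gold-positive findings (provenance: %s)\n",
              nrow(x), sum(gold_matrix(x)), attr(x, "provenance")))
  invisible(x)
}

#' Extract the gold-label or score matrix of a cohort
#'
#' @param cohort a `cohort`.
#' @return Numeric matrix, patients x 7 entities, in canonical entity order.
#' @export
gold_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[, paste0("gold_", chest_entities())])
  colnames(m) <- chest_entities()
  m
}

#' @rdname gold_matrix
#' @export
score_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[, paste0("score_", chest_entities())])
  colnames(m) <- chest_entities()
  m
}

#' Per-patient multimorbidity
#'
#' Count of gold-standard-positive findings among the seven entities.
#'
#' @param cohort a `cohort`.
#' @return Integer vector, one value in 0..7 per patient.
#' @export
multimorbidity <- function(cohort) {
  as.integer(rowSums(gold_matrix(cohort)))
}

#' Validate a cohort against its type invariants
#'
#' Checks uniqueness of patient ids, age >= 18, binary coding of sex,
#' foreign-material and gold labels, scores within \[0, 1\], and absence of
#' missing values. Reporting operation: violations are returned, not raised.
#'
#' @param cohort a `cohort` (or plain data.frame with cohort columns).
#' @return data.frame with columns `patient_id`, `field`, `message`;
#'   zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  viol <- list()
  add <- function(pid, field, msg) {
    viol[[length(viol) + 1L]] <<- data.frame(
      patient_id = pid, field = field, message = msg,
      stringsAsFactors = FALSE)
  }
  df <- as.data.frame(cohort)
  missing_cols <- setdiff(cohort_columns(), names(df))
  for (col in missing_cols) {
    ent <- sub("^(gold|score)_", "", col)
    add("<cohort>", col,
        if (col %in% names(df)) "" else
          if (grepl("^(gold|score)_", col)) paste0("missing entity column for ", ent)
          else "missing column")
  }
  if (length(missing_cols) > 0) return(do.call(rbind, viol))
  if (nrow(df) == 0) {
    add("<cohort>", "records", "cohort is empty")
    return(do.call(rbind, viol))
  }
  dup <- df$patient_id[duplicated(df$patient_id)]
  for (id in unique(dup)) add(id, "patient_id", "duplicate id")
  chk <- function(idx, field, msg) {
    for (i in which(idx)) add(df$patient_id[i], field, msg)
  }
  chk(is.na(df$age) | df$age < 18, "age", "age must be an integer >= 18")
  chk(!df$sex %in% c(0L, 1L), "sex", "sex must be 0 (male) or 1 (female)")
  chk(!df$foreign_material %in% c(0L, 1L), "foreign_material",
      "foreign_material must be 0 or 1")
  for (ent in chest_entities()) {
    g <- df[[paste0("gold_", ent)]]
    s <- df[[paste0("score_", ent)]]
    chk(!g %in% c(0L, 1L), paste0("gold_", ent), "gold label must be 0 or 1")
    chk(is.na(s) | s < 0 | s > 1, paste0("score_", ent),
        "score must lie in [0, 1]")
  }
  if (length(viol) == 0) {
    data.frame(patient_id = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
}

#' Read a cohort from its canonical CSV
#'
#' @param path CSV file path. Header must match the canonical schema; row
#'   order is preserved. Sex may be coded 0/1 or M/F.
#' @return A validated `cohort` with `provenance = path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cohort <- as_cohort(df, provenance = path)
  rep <- validate_cohort(cohort)
  if (nrow(rep) > 0) {
    rows <- match(rep$patient_id, cohort$patient_id)
    stop("invalid cohort in ", path, ": ",
         paste(sprintf("row %s, %s: %s", ifelse(is.na(rows), "?", rows),
                       rep$field, rep$message), collapse = "; "))
  }
  cohort
}

#' Write a cohort to its canonical CSV
#'
#' Columns in canonical order; scores serialized with 6 decimal places so
#' that write/read round-trips are byte-stable.
#'
#' @param cohort a valid `cohort` (may have zero rows: header-only file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns(), drop = FALSE]
  for (col in paste0("score_", chest_entities())) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
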