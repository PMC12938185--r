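# Per-subject microstate feature vectors and the cohort feature table.
#
# Naming grammar:
#   [Band]_TP_X-Y            transition probability from MsX to MsY
#   [Band]_[Metric]_[State]  state-wise metric, Metric in {MD, COV, MO, GEV}
# e.g. Delta_TP_C-B, Delta_MO_D, Alpha_COV_A.

metric_codes <- c(MD = "mean_duration", COV = "coverage",
                  MO = "occurrence", GEV = "gev")

#' Compute all microstate features for one recording in one band
#'
#' Back-fits the templates, enforces the minimum duration, and returns the
#' 28 named features of one band: 4 classes x 4 metrics (mean duration MD,
#' coverage COV, occurrence MO, explained variance GEV) plus the 12
#' off-diagonal transition probabilities.
#'
#' @param recording a band-filtered `eeg_recording`.
#' @param template_set the band's `template_set` (canonical labels A-D).
#' @param band_name band name used as feature prefix (e.g. `"delta"`).
#' @param min_ms minimum microstate duration in ms.
#' @return named numeric vector of length 28.
#' @export
subject_features <- function(recording, template_set, band_name,
                             min_ms = 30) {
  seg <- smooth_min_duration(backfit(recording, template_set), min_ms)
  tm <- temporal_metrics(seg)
  gev <- gev_per_class(recording, seg, template_set)
  tp <- transition_probabilities(seg)
  pre <- band_prefix(band_name)
  cls <- seg$class_names
  out <- c()
  for (code in names(metric_codes)) {
    vals <- if (code == "GEV") gev else tm[[metric_codes[[code]]]]
    names(vals) <- paste0(pre, "_", code, "_", cls)
    out <- c(out, vals)
  }
  tpv <- c()
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (i == j) next
    tpv[paste0(pre, "_TP_", cls[i], "-", cls[j])] <- tp[i, j]
  }
  c(out, tpv)
}

#' Parse a feature name back to its components
#'
#' @param name a feature column name.
#' @return list with `band`, `kind` (`"TP"` or a metric code), and `states`
#'   (length 1 for metrics, 2 = from/to for transitions); errors on names
#'   outside the grammar.
#' @export
parse_feature_name <- function(name) {
  m <- regmatches(name, regexec("^(Delta|Theta|Alpha|Beta)_TP_([A-Z])-([A-Z])$", name))[[1]]
  if (length(m)) return(list(band = tolower(m[2]), kind = "TP", states = m[3:4]))
  m <- regmatches(name, regexec("^(Delta|Theta|Alpha|Beta)_(MD|COV|MO|GEV)_([A-Z])$", name))[[1]]
  if (length(m)) return(list(band = tolower(m[2]), kind = m[3], states = m[4]))
  stop("not a microstate feature name: ", name)
}

is_feature_name <- function(name) {
  grepl("^(Delta|Theta|Alpha|Beta)_(TP_[A-Z]-[A-Z]|(MD|COV|MO|GEV)_[A-Z])$", name)
}

#' Assemble the cohort feature table
#'
#' One row per subject, one column per named microstate feature, joined
#' with the clinical table (group, DHI, VAS, ABC). Subjects missing from
#' the clinical table keep their features with `NA` scores (they are
#' excluded later from the correlation stage).
#'
#' @param features named list: `features[[subject_id]]` is a named feature
#'   vector (concatenated across bands).
#' @param clinical data.frame with `subject_id`, `group` and score columns.
#' @return data.frame of class `feature_table` (`check.names = FALSE`;
#'   transition names contain `-`).
#' @export
build_feature_table <- function(features, clinical = NULL) {
  ids <- names(features)
  cols <- names(features[[1]])
  bad <- cols[!vapply(cols, is_feature_name, logical(1))]
  if (length(bad)) stop("unparseable feature names: ", paste(bad, collapse = ", "))
  mat <- do.call(rbind, lapply(features, function(f) f[cols]))
  ft <- data.frame(subject_id = ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(ft) <- NULL
  if (!is.null(clinical)) {
    ft <- merge(data.frame(subject_id = ids, stringsAsFactors = FALSE),
                clinical, by = "subject_id", all.x = TRUE, sort = FALSE)
    ft <- cbind(ft, mat)
    rownames(ft) <- NULL
  }
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Feature columns of a feature table
#' @param ft a `feature_table`.
#' @return character vector of microstate feature column names.
#' @export
feature_columns <- function(ft) {
  names(ft)[vapply(names(ft), is_feature_name, logical(1))]
}

#' Write / read a feature table as CSV with a JSON metadata sidecar
#'
#' @param ft a `feature_table`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param meta named list stored in the sidecar (bands, seeds, provenance).
#' @export
write_feature_table <- function(ft, path, meta = list()) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(ft) <- c("feature_table", "data.frame")
  ft
}
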