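#' Load a specimen calibration table
#'
#' A calibration table has one row per specimen with its taxon, taxonomic
#' group, total convex-hull volume and body mass. The packaged table is the
#' published 32-specimen dataset (9 birds, 14 non-primate mammals, 9
#' primates) whose hull volumes were measured from LiDAR and CT scans of
#' complete mounted skeletons; it is the canonical calibration input for all
#' the regression machinery in this package.
#'
#' Volumes are cubic metres, masses kilograms. The group label must be one of
#' `"non-primate mammal"`, `"primate"`, `"bird"`. The `accession` and `sex`
#' columns are carried through but never used in computation.
#'
#' @param path path to a CSV file with columns `species, accession, sex,
#'   group, vol_CH_m3, M_b_kg, mass_source`, or the token `"packaged"` for
#'   the bundled published table.
#' @return A `calibration_dataset`: a validated `data.frame` with the seven
#'   columns above.
#' @examples
#' tab <- load_calibration_table("packaged")
#' table(tab$group)
#' @export
load_calibration_table <- function(path = "packaged") {
  if (identical(path, "packaged")) {
    path <- system.file("extdata", "brassey2014_specimens.csv",
                        package = "hullmass", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(vol_CH_m3 = "numeric", M_b_kg = "numeric"))
  as_calibration_dataset(df, strict_groups = TRUE)
}

#' @rdname load_calibration_table
#' @param df a data.frame to validate and class as a calibration dataset.
#' @param label free-text label.
#' @param strict_groups restrict group labels to the three published ones
#'   (CSV ingestion does; programmatic construction, e.g. of synthetic
#'   datasets, may use any label).
#' @export
as_calibration_dataset <- function(df, label = "", strict_groups = FALSE) {
  missing_cols <- setdiff(.table_columns, names(df))
  # mass_source / accession / sex are tolerated absent for synthetic data
  required <- c("species", "group", "vol_CH_m3", "M_b_kg")
  if (length(setdiff(required, names(df))))
    stop("calibration table lacks columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  for (col in setdiff(missing_cols, required)) df[[col]] <- ""
  df <- df[, .table_columns]
  if (nrow(df) < 1L) stop("calibration table is empty")
  if (any(!is.finite(df$vol_CH_m3)) || any(df$vol_CH_m3 <= 0))
    stop("all vol_CH_m3 values must be finite and > 0")
  if (any(!is.finite(df$M_b_kg)) || any(df$M_b_kg <= 0))
    stop("all M_b_kg values must be finite and > 0")
  if (strict_groups) {
    bad <- setdiff(unique(df$group), .groups)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  if (any(!nzchar(df$group))) stop("every record needs a group label")
  df$sex[!df$sex %in% c("M", "F")] <- "unknown"
  attr(df, "label") <- label
  class(df) <- c("calibration_dataset", "data.frame")
  df
}

#' @rdname load_calibration_table
#' @param dataset a `calibration_dataset`.
#' @export
write_calibration_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  write.csv(as.data.frame(dataset)[, .table_columns], path, row.names = FALSE)
  invisible(path)
}

# subset helper retaining the class
.cd_subset <- function(dataset, keep) {
  out <- as.data.frame(dataset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_calibration_dataset(out, label = attr(dataset, "label") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
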