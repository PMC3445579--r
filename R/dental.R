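# Ziphodont dentition morphometrics.
#
# Ziphodont teeth carry carinae formed by a keel plus true denticles.
# Denticle size separates two grades used in generic diagnoses:
# macroziphodonty (all denticle dimensions exceed 300 um) versus
# microziphodonty (no dimension exceeds 300 um). The 300 um boundary itself
# is microziphodont: "do not exceed" is inclusive, "exceed" is strict.

ZIPHODONT_THRESHOLD_UM <- 300

#' Classify ziphodonty from denticle dimensions
#'
#' Classifies each tooth from its three denticle dimensions (apicobasal
#' length, height, transverse width, in micrometres): all three strictly
#' greater than 300 um gives `macroziphodont`; all three at most 300 um
#' gives `microziphodont`; mixed patterns are `indeterminate` (the diagnoses
#' never describe such a case, so no guess is made).
#'
#' @param teeth A data frame with columns `denticle_length_um`,
#'   `denticle_height_um`, `denticle_width_um` (one row per tooth). Other
#'   columns are carried through.
#' @return The input tibble with an added `ziphodonty` factor column.
#' @export
#' @examples
#' classify_ziphodonty(tibble::tibble(
#'   denticle_length_um = 425, denticle_height_um = 330,
#'   denticle_width_um = 675))
classify_ziphodonty <- function(teeth) {
  teeth <- tibble::as_tibble(teeth)
  need <- c("denticle_length_um", "denticle_height_um", "denticle_width_um")
  missing_cols <- setdiff(need, names(teeth))
  if (length(missing_cols)) {
    stop_input(paste0("missing denticle dimension column(s): ",
                      paste(missing_cols, collapse = ", ")), "validation_error")
  }
  dims <- as.matrix(teeth[need])
  if (any(is.na(dims)) || any(dims <= 0)) {
    stop_input("all three denticle dimensions must be present and positive",
               "validation_error")
  }
  cls <- ifelse(
    rowSums(dims > ZIPHODONT_THRESHOLD_UM) == 3L, "macroziphodont",
    ifelse(rowSums(dims <= ZIPHODONT_THRESHOLD_UM) == 3L, "microziphodont",
           "indeterminate")
  )
  teeth$ziphodonty <- factor(cls, levels = c("macroziphodont",
                                             "microziphodont",
                                             "indeterminate"))
  teeth
}

#' Basal crown compression ratio
#'
#' Mesiodistal over labiolingual basal crown width; 1 means a circular
#' cross-section, larger values a mesiodistally elongate (labiolingually
#' compressed) crown. Unrounded; reports use 2 decimals.
#'
#' @param mesiodistal_mm,labiolingual_mm Basal crown widths, mm, positive.
#' @return Dimensionless ratio(s).
#' @export
#' @examples
#' compression_ratio(4.9, 4.2) # ~1.17
compression_ratio <- function(mesiodistal_mm, labiolingual_mm) {
  if (any(!is.finite(mesiodistal_mm)) || any(mesiodistal_mm <= 0) ||
      any(!is.finite(labiolingual_mm)) || any(labiolingual_mm <= 0)) {
    stop_input("crown widths must be positive", "domain_error")
  }
  mesiodistal_mm / labiolingual_mm
}

#' Denticle density along a carina
#'
#' Denticles per millimetre of carina, from a denticle count over a measured
#' span. Unrounded; reports round to the nearest integer, matching how
#' densities are published.
#'
#' @param count Number of denticles counted (>= 1).
#' @param span_mm Carinal span over which they were counted, mm, positive.
#' @return Density in denticles/mm.
#' @export
#' @examples
#' denticle_density(12, 2) # 6
denticle_density <- function(count, span_mm) {
  if (any(!is.finite(count)) || any(count < 1)) {
    stop_input("`count` must be >= 1", "domain_error")
  }
  if (any(!is.finite(span_mm)) || any(span_mm <= 0)) {
    stop_input("`span_mm` must be positive", "domain_error")
  }
  count / span_mm
}

#' Dental classification report
#'
#' Builds the per-tooth report: ziphodonty class, basal compression ratio
#' (2 decimals) and, when count/span columns are present, denticle densities
#' (nearest integer).
#'
#' @param teeth Data frame with denticle dimensions (see
#'   [classify_ziphodonty()]); optionally `crown_mesiodistal_basal_mm` and
#'   `crown_labiolingual_basal_mm`, and paired `*_count` / `*_span_mm`
#'   columns (e.g. `mesial_count`, `mesial_span_mm`).
#' @return A tibble, one row per tooth.
#' @export
dental_report <- function(teeth) {
  out <- classify_ziphodonty(teeth)
  if (all(c("crown_mesiodistal_basal_mm", "crown_labiolingual_basal_mm") %in%
          names(out))) {
    ok <- is.finite(out$crown_mesiodistal_basal_mm) &
      is.finite(out$crown_labiolingual_basal_mm)
    out$compression_ratio <- NA_real_
    if (any(ok)) {
      out$compression_ratio[ok] <- round_half_up(
        compression_ratio(out$crown_mesiodistal_basal_mm[ok],
                          out$crown_labiolingual_basal_mm[ok]), 2)
    }
  }
  count_cols <- grep("_count$", names(out), value = TRUE)
  for (cc in count_cols) {
    span_col <- sub("_count$", "_span_mm", cc)
    if (span_col %in% names(out)) {
      dens_col <- sub("_count$", "_density_per_mm", cc)
      ok <- is.finite(out[[cc]]) & is.finite(out[[span_col]])
      out[[dens_col]] <- NA_real_
      if (any(ok)) {
        out[[dens_col]][ok] <- round_half_up(
          denticle_density(out[[cc]][ok], out[[span_col]][ok]), 0)
      }
    }
  }
  out
}

#' Packaged MUJA-1004 tooth measurements
#'
#' Published measurements of the isolated tooth crown MUJA-1004 (referred to
#' cf. *Plesiosuchus manselii*): crown 10.3 mm apicobasally, basal widths
#' 4.9 mm (mesiodistal) by 4.2 mm (labiolingual), denticle densities of
#' 6/mm on the distal carina and 8-10/mm on the mesial carina near
#' mid-crown. Denticle dimensions for this specimen are microziphodont; the
#' packaged values (150 x 120 x 200 um) are synthetic placeholders consistent
#' with the published microziphodont grade, flagged in the `provenance`
#' column, because exact dimensions were not printed.
#'
#' @return A tibble with one row per measured tooth.
#' @export
muja1004_tooth <- function() {
  path <- system.file("extdata", "muja1004_tooth.csv",
                      package = "metriomorph", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
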