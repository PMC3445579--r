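# Landmark table I/O and validation.
#
# The standard landmark file is a CSV of 2-D points digitized on a mandible in
# lateral view, one row per landmark:
#   specimen_id, taxon, label, x, y
# with labels drawn from a controlled vocabulary: "glenoid" (jaw joint),
# "dentary_tip_anterior", "retroarticular_posterior" and "tooth_tip_NN"
# (dentary tooth apices numbered anterior to posterior).

landmark_label_pattern <- "^(glenoid|dentary_tip_anterior|retroarticular_posterior|tooth_tip_[0-9]{2})$"

#' Read a mandible landmark table
#'
#' Reads the standard landmark CSV (columns `specimen_id`, `taxon`, `label`,
#' `x`, `y`; coordinates in cm, lateral view with anterior +x and dorsal +y)
#' and validates it: labels must belong to the controlled vocabulary, every
#' specimen must provide a `glenoid` landmark and at least two dentary tooth
#' tips (`tooth_tip_01`, `tooth_tip_02`, ...), and coordinates must be finite
#' numbers. Row order within a specimen is preserved.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `specimen_id`, `taxon`, `label`, `x`, `y`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "specimen_id,taxon,label,x,y",
#'   "S1,Metriorhynchus,glenoid,0,0",
#'   "S1,Metriorhynchus,tooth_tip_01,70,7",
#'   "S1,Metriorhynchus,tooth_tip_02,36,7"
#' ), f)
#' read_landmark_table(f)
read_landmark_table <- function(path) {
  if (!file.exists(path)) stop_input(paste0("landmark file not found: ", path), "io_error")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  needed <- c("specimen_id", "taxon", "label", "x", "y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop_input(paste0("landmark file lacks column(s): ",
                      paste(missing_cols, collapse = ", ")), "format_error")
  }
  for (col in c("x", "y")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      stop_input(sprintf("non-numeric %s coordinate at line %d of %s",
                         col, bad[1] + 1L, path), "parse_error")
    }
    raw[[col]] <- num
  }
  df <- tibble::as_tibble(raw[needed])
  validate_landmark_table(df)
  df
}

#' Write a mandible landmark table
#'
#' @param landmarks A landmark tibble as returned by [read_landmark_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(landmarks, path) {
  validate_landmark_table(landmarks)
  df <- as.data.frame(landmarks[, c("specimen_id", "taxon", "label", "x", "y")])
  df$x <- formatC(df$x, format = "g", digits = 15)
  df$y <- formatC(df$y, format = "g", digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_landmark_table <- function(df) {
  bad_label <- !grepl(landmark_label_pattern, df$label)
  if (any(bad_label)) {
    stop_input(paste0("unknown landmark label(s): ",
                      paste(unique(df$label[bad_label]), collapse = ", ")),
               "validation_error")
  }
  for (sp in unique(df$specimen_id)) {
    sub <- df[df$specimen_id == sp, ]
    if (!nzchar(sp)) stop_input("empty specimen_id", "validation_error")
    if (!any(sub$label == "glenoid")) {
      stop_input(paste0("specimen ", sp, " lacks mandatory landmark: glenoid"),
                 "validation_error")
    }
    if (sum(startsWith(sub$label, "tooth_tip_")) < 2) {
      stop_input(paste0("specimen ", sp,
                        " needs at least 2 dentary tooth tips (tooth_tip_NN)"),
                 "validation_error")
    }
    if (anyDuplicated(sub$label)) {
      stop_input(paste0("specimen ", sp, " has duplicated landmark label(s)"),
                 "validation_error")
    }
  }
  invisible(df)
}

# Split a validated landmark table into per-specimen landmark sets:
# list(specimen_id, taxon, tooth_tips [n x 2, anterior->posterior], glenoid,
# dentary_tip_anterior, retroarticular_posterior).
landmark_sets <- function(df) {
  validate_landmark_table(df)
  lapply(split(df, factor(df$specimen_id, levels = unique(df$specimen_id))),
         function(sub) {
    tips <- sub[startsWith(sub$label, "tooth_tip_"), ]
    tips <- tips[order(tips$label), ]
    pt <- function(lab) {
      r <- sub[sub$label == lab, ]
      if (nrow(r) == 0) return(NULL)
      c(r$x[1], r$y[1])
    }
    list(
      specimen_id = sub$specimen_id[1],
      taxon = sub$taxon[1],
      tooth_tips = cbind(x = tips$x, y = tips$y),
      glenoid = pt("glenoid"),
      dentary_tip_anterior = pt("dentary_tip_anterior"),
      retroarticular_posterior = pt("retroarticular_posterior")
    )
  })
}
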