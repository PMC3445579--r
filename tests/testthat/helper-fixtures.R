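# Shared test helpers: tiny in-code fixtures.

toy_landmarks <- function(specimen_id = "S1", taxon = "Metriorhynchus superciliosus") {
  tibble::tibble(
    specimen_id = specimen_id,
    taxon = taxon,
    label = c("glenoid", "tooth_tip_01", "tooth_tip_02"),
    x = c(0, 70, 36.21),
    y = c(0, 7.04, 7.04)
  )
}

# Build a character_matrix from a character vector of state strings,
# e.g. cm_from_strings(c(A = "01?", B = "011")).
cm_from_strings <- function(rows, ordered = FALSE, outgroup = NA_character_) {
  states <- do.call(rbind, lapply(rows, function(r) {
    chars <- strsplit(r, "")[[1]]
    ifelse(chars %in% c("?", "-"), NA_integer_, as.integer(chars))
  }))
  rownames(states) <- names(rows)
  character_matrix(states, ordered = ordered, outgroup = outgroup)
}

write_temp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Non-trivial bipartitions of a phylo as a list of label vectors (the side
# away from the alphabetically first label), via package internals.
tidy_tree_keys <- function(tree) {
  keys <- metriomorph:::utree_bipartitions(metriomorph:::phylo_to_utree(tree))
  strsplit(keys, "\r", fixed = TRUE)
}
tidy_consensus_keys <- tidy_tree_keys

# 2-D rigid motion of a landmark tibble.
transform_landmarks <- function(lm, angle_deg = 0, dx = 0, dy = 0, scale = 1) {
  th <- angle_deg * pi / 180
  x <- lm$x * scale
  y <- lm$y * scale
  lm$x <- cos(th) * x - sin(th) * y + dx
  lm$y <- sin(th) * x + cos(th) * y + dy
  lm
}
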