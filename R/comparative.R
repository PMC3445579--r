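# Comparative gape table and the end-to-end report.

#' Published optimum-gape measurements
#'
#' The seven published (taxon, optimum gape angle, prey-depth fraction,
#' maximum known mandible length) rows of the comparative gape table,
#' shipped as a plain-text fixture. Passing this through
#' [build_comparative_table()] reproduces the table's derived columns
#' (maximum optimum prey depth; depth standardized to a 60 cm mandible).
#'
#' @return A tibble with columns `taxon`, `specimen_id`, `gape_angle_deg`,
#'   `prey_depth_fraction`, `mandible_length_cm`.
#' @export
gape_reference_measurements <- function() {
  path <- system.file("extdata", "gape_reference_measurements.csv",
                      package = "metriomorph", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Build the comparative optimum-gape table
#'
#' Combines printed (angle, fraction, mandible length) records and/or
#' landmark-derived specimens into the standard comparative table: per row
#' the optimum gape angle (degrees), optimum prey depth as a percentage of
#' mandible length, the maximum known mandible length (cm), the maximum
#' known optimum prey depth (fraction x mandible length, cm, 2 decimals) and
#' the prey depth standardized to the reference mandible length (1 decimal).
#' Rounding is half-up at this reporting boundary only; upstream arithmetic
#' is full precision. Rows are labelled by provenance (`"printed"` or
#' `"landmarks"`).
#'
#' @param values Optional data frame of printed records with columns
#'   `taxon`, `specimen_id`, `gape_angle_deg`, `prey_depth_fraction`,
#'   `mandible_length_cm` (e.g. [gape_reference_measurements()]).
#' @param landmarks Optional landmark tibble; converted via [optimum_gape()].
#' @param measurements Optional measured mandible lengths for the landmark
#'   specimens (see [optimum_gape()]).
#' @param cfg A [pipeline_config()] (reference length and rounding).
#' @return A tibble of class `comparative_table`, rows in input order.
#' @export
#' @examples
#' build_comparative_table(values = gape_reference_measurements())
build_comparative_table <- function(values = NULL, landmarks = NULL,
                                    measurements = NULL,
                                    cfg = pipeline_config()) {
  rows <- list()
  if (!is.null(values)) {
    v <- tibble::as_tibble(values)
    need <- c("taxon", "specimen_id", "gape_angle_deg", "prey_depth_fraction",
              "mandible_length_cm")
    if (!all(need %in% names(v))) {
      stop_input(paste0("`values` must have columns: ", paste(need, collapse = ", ")),
                 "validation_error")
    }
    v$provenance <- "printed"
    rows <- c(rows, list(v[c(need, "provenance")]))
  }
  if (!is.null(landmarks)) {
    g <- optimum_gape(landmarks, measurements = measurements,
                      reference_length_cm = cfg$reference_mandible_length_cm)
    g <- g[c("taxon", "specimen_id", "gape_angle_deg", "prey_depth_fraction",
             "mandible_length_cm")]
    g$provenance <- "landmarks"
    rows <- c(rows, list(g))
  }
  if (!length(rows)) {
    stop_input("supply printed `values` and/or `landmarks`", "validation_error")
  }
  df <- dplyr::bind_rows(rows)
  ref <- cfg$reference_mandible_length_cm
  tibble::new_tibble(
    tibble::tibble(
      taxon = df$taxon,
      specimen_id = df$specimen_id,
      gape_angle_deg = round_half_up(df$gape_angle_deg, cfg$angle_digits),
      prey_depth_pct = 100 * round_half_up(df$prey_depth_fraction,
                                           cfg$fraction_digits),
      max_mandible_cm = df$mandible_length_cm,
      max_prey_depth_cm = round_half_up(
        prey_depth_at_length(round_half_up(df$prey_depth_fraction,
                                           cfg$fraction_digits),
                             df$mandible_length_cm), cfg$depth_digits),
      standardized_depth_cm = round_half_up(
        prey_depth_at_length(round_half_up(df$prey_depth_fraction,
                                           cfg$fraction_digits), ref), 1),
      provenance = df$provenance
    ),
    class = "comparative_table"
  )
}

#' @rdname build_comparative_table
#' @param object A `comparative_table`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.comparative_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$taxon <- factor(df$taxon, levels = df$taxon[order(df$standardized_depth_cm)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon,
                                   y = .data$standardized_depth_cm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = "optimum prey depth at reference mandible length (cm)") +
    ggplot2::theme_minimal()
}

#' Run the full analysis and write a report bundle
#'
#' Orchestrates the pipeline stages and writes one reproducible report to
#' `out_dir`: the comparative gape table (TSV), body-size estimates (TSV),
#' the dental classification (TSV), a parsimony run (tree files plus a TSV
#' of length/CI/RI/RC and clade supports), and a JSON manifest echoing the
#' configuration and seed. Stages can be toggled; with all stages at their
#' defaults the run uses only packaged fixtures and simulated data, so it
#' needs no external input. Outputs are byte-identical under a fixed seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector from
#'   `c("gape", "allometry", "dental", "phylo")`.
#' @param values,landmarks,measurements Inputs for the gape stage (defaults
#'   to the packaged printed measurements).
#' @param matrix Optional [character_matrix()] for the phylogenetic stage
#'   (defaults to a seeded simulated matrix).
#' @param mandibles Data frame with `specimen_id` and `mandible_length_cm`
#'   for the allometry stage (defaults to the two large-geosaurine
#'   mandibles, 87.5 and 132.2 cm).
#' @return The manifest as a list, invisibly.
#' @export
run_report <- function(cfg = pipeline_config(), out_dir,
                       stages = c("gape", "allometry", "dental", "phylo"),
                       values = gape_reference_measurements(),
                       landmarks = NULL, measurements = NULL,
                       matrix = NULL,
                       mandibles = data.frame(
                         specimen_id = c("SMNS 82043", "NHMUK PV R1089"),
                         mandible_length_cm = c(87.5, 132.2))) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "metriomorph",
    version = as.character(utils::packageVersion("metriomorph")),
    seed = cfg$rng_seed,
    config = unclass(cfg),
    stages = as.list(setNames(rep("PENDING", length(stages)), stages))
  )
  write_tsv_plain <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  status <- 0L
  for (st in stages) {
    ok <- tryCatch({
      if (st == "gape") {
        tab <- build_comparative_table(values = values, landmarks = landmarks,
                                       measurements = measurements, cfg = cfg)
        write_tsv_plain(tab, "comparative_gape.tsv")
      } else if (st == "allometry") {
        ref <- allometric_reference()
        model <- calibrate_body_length_model(body_length_anchors())
        bas <- estimate_basicranial(mandibles$mandible_length_cm, ref)
        pred <- predict_total_length(model, bas)
        out <- tibble::tibble(
          specimen_id = mandibles$specimen_id,
          mandible_cm = mandibles$mandible_length_cm,
          basicranial_cm = round_half_up(bas, 1),
          total_length_m = round_half_up(pred$total_length_m, 2),
          extrapolated = pred$extrapolated
        )
        write_tsv_plain(out, "allometry.tsv")
      } else if (st == "dental") {
        write_tsv_plain(dental_report(muja1004_tooth()), "dental.tsv")
      } else if (st == "phylo") {
        cm <- matrix %||% sim_character_matrix(seed = cfg$rng_seed)$matrix
        res <- parsimony_search(cm, cfg)
        write_newick(res$mpt_set, file.path(out_dir, "mpts.nwk"))
        write_newick(res$strict_consensus, file.path(out_dir, "strict_consensus.nwk"))
        write_newick(res$majority_consensus, file.path(out_dir, "majority_consensus.nwk"))
        write_tsv_plain(glance(res), "parsimony_summary.tsv")
        if (cfg$n_bootstrap > 0) {
          bs <- bootstrap_support(cm, cfg)
          write_tsv_plain(bs, "bootstrap_support.tsv")
        }
      }
      TRUE
    }, error = function(e) {
      manifest$stages[[st]] <<- paste0("FAILED: ", conditionMessage(e))
      FALSE
    })
    if (ok) manifest$stages[[st]] <- "OK" else status <- 1L
  }
  manifest$status <- if (status == 0L) "OK" else "FAILED"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
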