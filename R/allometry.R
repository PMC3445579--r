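# Body-size estimation.
#
# Two-step procedure used for large geosaurine specimens known only from
# mandibles: (1) estimate basicranial length from mandible length using the
# basicranial:mandibular ratio of a completely preserved reference skull
# ("Metriorhynchus" brachyrhynchus NHMUK PV R3804, mandible 80.9 cm,
# basicranium 76.8 cm), under the stated assumption that the basicranium and
# mandible of the target taxon scale in the same proportions as the
# reference; (2) convert basicranial length to total body length with a
# linear model calibrated on published (basicranial, total length) anchor
# pairs, which are collinear to under a centimetre.

#' Reference skull for the basicranial:mandibular ratio
#'
#' @param ref_mandible_cm Reference mandible length, cm (default 80.9).
#' @param ref_basicranial_cm Reference basicranial length, cm (default 76.8).
#' @param ref_taxon Label for the reference specimen.
#' @return A list of class `allometric_reference`; the `ratio` element is
#'   recomputed from the two lengths, never stored independently.
#' @export
#' @examples
#' allometric_reference()$ratio # 0.949...
allometric_reference <- function(ref_mandible_cm = 80.9,
                                 ref_basicranial_cm = 76.8,
                                 ref_taxon = "\"Metriorhynchus\" brachyrhynchus NHMUK PV R3804") {
  if (ref_mandible_cm <= 0 || ref_basicranial_cm <= 0) {
    stop_input("reference lengths must be positive", "domain_error")
  }
  structure(
    list(ref_taxon = ref_taxon,
         ref_mandible_cm = ref_mandible_cm,
         ref_basicranial_cm = ref_basicranial_cm,
         ratio = ref_basicranial_cm / ref_mandible_cm),
    class = "allometric_reference"
  )
}

#' Estimate basicranial length from mandible length
#'
#' Multiplies the mandible length by the reference basicranial:mandibular
#' ratio. Returns the unrounded estimate; reports round to 1 decimal place.
#'
#' @param mandible_cm Mandible length(s), cm, positive.
#' @param ref An [allometric_reference()].
#' @return Basicranial length estimate(s), cm.
#' @export
#' @examples
#' estimate_basicranial(87.5)  # ~83.1
#' estimate_basicranial(132.2) # ~125.5
estimate_basicranial <- function(mandible_cm, ref = allometric_reference()) {
  if (any(!is.finite(mandible_cm)) || any(mandible_cm <= 0)) {
    stop_input("`mandible_cm` must be positive", "domain_error")
  }
  mandible_cm * ref$ratio
}

#' Calibrate the linear basicranial-to-total-length model
#'
#' Ordinary least squares of total body length (cm) on basicranial length
#' (cm) through the supplied anchor pairs; with exactly two anchors this is
#' exact interpolation. The three published anchor pairs — (83.1 cm, 4.49 m),
#' (100 cm, 5.42 m), (125.5 cm, 6.83 m) — are collinear to well under 1 cm,
#' so a straight line reproduces every published estimate at printed
#' precision.
#'
#' @param anchors A data frame with columns `basicranial_cm` and
#'   `total_length_cm`, at least two rows with distinct basicranial values.
#' @return An object of class `body_length_model` with elements `fit` (the
#'   underlying `lm`), `slope`, `intercept`, `anchors` and `max_residual_cm`.
#' @export
#' @examples
#' m <- calibrate_body_length_model(body_length_anchors())
#' glance(m)
calibrate_body_length_model <- function(anchors) {
  anchors <- tibble::as_tibble(anchors)
  stopifnot(all(c("basicranial_cm", "total_length_cm") %in% names(anchors)))
  if (nrow(anchors) < 2) stop_input("need >= 2 anchor pairs", "validation_error")
  if (anyDuplicated(anchors$basicranial_cm)) {
    stop_input("anchor basicranial lengths must be distinct (singular fit)",
               "singular_fit_error")
  }
  fit <- lm(total_length_cm ~ basicranial_cm, data = anchors)
  res <- anchors$total_length_cm - unname(predict(fit))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop_input("calibrated slope must be positive", "validation_error")
  }
  structure(
    list(fit = fit,
         slope = slope,
         intercept = unname(coef(fit)[1]),
         anchors = anchors,
         max_residual_cm = max(abs(res))),
    class = "body_length_model"
  )
}

#' Predict total body length from basicranial length
#'
#' @param model A [calibrate_body_length_model()] fit.
#' @param basicranial_cm Basicranial length(s), cm, positive.
#' @return A tibble with `basicranial_cm`, `total_length_m` (unrounded;
#'   reports round to 2 decimals) and `extrapolated` (TRUE when the input
#'   lies outside the anchor range).
#' @export
#' @examples
#' m <- calibrate_body_length_model(
#'   data.frame(basicranial_cm = c(100, 125.5), total_length_cm = c(542, 683)))
#' predict_total_length(m, 83.1) # ~4.49 m
predict_total_length <- function(model, basicranial_cm) {
  stopifnot(inherits(model, "body_length_model"))
  if (any(!is.finite(basicranial_cm)) || any(basicranial_cm <= 0)) {
    stop_input("`basicranial_cm` must be positive", "domain_error")
  }
  rng <- range(model$anchors$basicranial_cm)
  cm <- model$slope * basicranial_cm + model$intercept
  tibble::tibble(
    basicranial_cm = basicranial_cm,
    total_length_m = cm / 100,
    extrapolated = basicranial_cm < rng[1] | basicranial_cm > rng[2]
  )
}

#' Published body-length calibration anchors
#'
#' The three published (basicranial length, total body length) pairs used to
#' calibrate the linear body-length model, shipped as a plain-text fixture.
#'
#' @return A tibble with columns `basicranial_cm` and `total_length_cm`.
#' @export
body_length_anchors <- function() {
  path <- system.file("extdata", "body_length_anchors.tsv",
                      package = "metriomorph", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path))
}

#' @export
print.body_length_model <- function(x, ...) {
  cat("<body_length_model>\n")
  cat(sprintf("  total_length_cm = %.4f * basicranial_cm + %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  %d anchors, max |residual| = %.3f cm\n",
              nrow(x$anchors), x$max_residual_cm))
  invisible(x)
}

#' @rdname calibrate_body_length_model
#' @param x,object A `body_length_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.body_length_model <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    unit = c("cm", "cm total length per cm basicranial")
  )
}

#' @rdname calibrate_body_length_model
#' @exportS3Method generics::glance
glance.body_length_model <- function(x, ...) {
  tibble::tibble(
    n_anchors = nrow(x$anchors),
    slope = x$slope,
    intercept = x$intercept,
    max_residual_cm = x$max_residual_cm
  )
}

#' @rdname calibrate_body_length_model
#' @exportS3Method ggplot2::autoplot
autoplot.body_length_model <- function(object, ...) {
  ggplot2::ggplot(object$anchors,
                  ggplot2::aes(x = .data$basicranial_cm,
                               y = .data$total_length_cm)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "basicranial length (cm)", y = "total body length (cm)") +
    ggplot2::theme_minimal()
}
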