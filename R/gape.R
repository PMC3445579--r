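# Optimum-gape geometry.
#
# The optimum gape is the gape angle at which several teeth contact a prey
# item simultaneously; it is a geometric proxy for the biomechanically
# optimal prey depth. It is constructed in lateral view by (1) fitting a
# straight line across the dentary tooth apices, (2) taking the parallel line
# through the jaw joint (glenoid), and (3) measuring the angle subtended at
# the posterior-most dentary tooth tip between the two parallel lines. The
# perpendicular distance h between the lines is the optimum prey depth; with
# d the along-line distance from the glenoid to the posterior-most tooth tip,
# the optimum gape angle is atan(h / d).

#' Fit a straight line across dentary tooth apices
#'
#' Total-least-squares (orthogonal) line fit: the line through the centroid
#' along the principal eigenvector of the scatter of the points, i.e. the
#' line minimizing the sum of squared perpendicular residuals. With exactly
#' two points this is the line through both. The direction is normalized and
#' oriented so that the first-to-last (anterior-to-posterior) tooth sequence
#' projects positively onto it.
#'
#' @param tooth_tips A numeric matrix or data frame with two columns (x, y),
#'   rows ordered anterior to posterior; at least two non-coincident points.
#' @return A list with unit `direction`, `point` (the centroid) and
#'   `rms_residual` (root-mean-square perpendicular residual).
#' @export
#' @examples
#' fit_tooth_line(cbind(c(0, 5, 10), c(2, 2, 2)))
fit_tooth_line <- function(tooth_tips) {
  pts <- as.matrix(tooth_tips)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2 || any(!is.finite(pts))) {
    stop_input("need >= 2 finite tooth-tip points", "validation_error")
  }
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (all(abs(cen) < 1e-12)) {
    stop_input("tooth tips are all coincident: degenerate geometry",
               "geometry_error")
  }
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  # orient anterior -> posterior along the digitized tooth sequence
  chord <- pts[nrow(pts), ] - pts[1, ]
  if (sum(dir * chord) < 0) dir <- -dir
  normal <- c(-dir[2], dir[1])
  res <- as.vector(cen %*% normal)
  list(direction = dir, point = ctr,
       rms_residual = sqrt(mean(res^2)))
}

# Core geometry for one landmark set; returns raw (unrounded) metrics.
gape_metrics_one <- function(lm_set, mandible_length_cm = NULL,
                             reference_length_cm = 60,
                             tooth_line = c("tls", "chord")) {
  tooth_line <- match.arg(tooth_line)
  tips <- lm_set$tooth_tips
  if (is.null(lm_set$glenoid)) {
    stop_input(paste0("specimen ", lm_set$specimen_id, " lacks glenoid"),
               "validation_error")
  }
  if (is.null(mandible_length_cm)) {
    a <- lm_set$dentary_tip_anterior
    p <- lm_set$retroarticular_posterior
    if (is.null(a) || is.null(p)) {
      stop_input(paste0("specimen ", lm_set$specimen_id,
                        ": no measured mandible length and no ",
                        "dentary_tip_anterior/retroarticular_posterior landmarks"),
                 "validation_error")
    }
    mandible_length_cm <- sqrt(sum((a - p)^2))
  }
  if (!is.finite(mandible_length_cm) || mandible_length_cm <= 0) {
    stop_input("mandible length must be a positive number", "validation_error")
  }
  fit <- if (tooth_line == "chord") {
    fit_tooth_line(tips[c(1, nrow(tips)), , drop = FALSE])
  } else {
    fit_tooth_line(tips)
  }
  dir <- fit$direction
  normal <- c(-dir[2], dir[1])
  h <- abs(sum((lm_set$glenoid - fit$point) * normal))
  post <- tips[nrow(tips), ]
  d <- sum((lm_set$glenoid - post) * dir)
  if (d <= 0) {
    stop_input(paste0("specimen ", lm_set$specimen_id,
                      ": posterior-most tooth tip is not anterior to the ",
                      "glenoid along the tooth line (d <= 0)"),
               "geometry_error")
  }
  angle <- atan2(h, d) * 180 / pi
  frac <- h / mandible_length_cm
  tibble::tibble(
    specimen_id = lm_set$specimen_id %||% NA_character_,
    taxon = lm_set$taxon %||% NA_character_,
    gape_angle_deg = angle,
    prey_depth_cm = h,
    mandible_length_cm = mandible_length_cm,
    prey_depth_fraction = frac,
    standardized_depth_cm = frac * reference_length_cm
  )
}

#' Optimum gape angle and optimum prey depth from landmarks
#'
#' Applies the two-parallel-lines construction to each specimen in a landmark
#' table: h is the perpendicular distance from the glenoid to the tooth-apex
#' line (the optimum prey depth, cm), d the along-line distance from the
#' glenoid's projection to the posterior-most tooth tip's projection, and the
#' optimum gape angle is `atan(h/d)` in degrees. The prey-depth fraction is
#' h divided by mandible length, and the standardized depth is that fraction
#' times the reference mandible length (default 60 cm).
#'
#' Mandible length is taken from `measurements` when supplied (measured
#' lengths take precedence, as in published comparative tables); otherwise it
#' is the distance between the `dentary_tip_anterior` and
#' `retroarticular_posterior` landmarks.
#'
#' All returned values are unrounded; rounding to table precision happens in
#' [build_comparative_table()].
#'
#' @param landmarks Landmark tibble (see [read_landmark_table()]).
#' @param measurements Optional data frame with columns `specimen_id` and
#'   `mandible_length_cm`.
#' @param reference_length_cm Reference mandible length for standardized
#'   depths (cm). Default 60.
#' @param tooth_line `"tls"` (total least squares across all tooth tips,
#'   default) or `"chord"` (line through the first and last tip only).
#' @return A tibble with one row per specimen: `specimen_id`, `taxon`,
#'   `gape_angle_deg`, `prey_depth_cm`, `mandible_length_cm`,
#'   `prey_depth_fraction`, `standardized_depth_cm`.
#' @export
#' @examples
#' lm <- tibble::tibble(
#'   specimen_id = "S1", taxon = "Metriorhynchus superciliosus",
#'   label = c("glenoid", "tooth_tip_01", "tooth_tip_02"),
#'   x = c(0, 70, 36.21), y = c(0, 7.04, 7.04)
#' )
#' optimum_gape(lm, measurements = data.frame(specimen_id = "S1",
#'                                            mandible_length_cm = 88))
optimum_gape <- function(landmarks, measurements = NULL,
                         reference_length_cm = 60,
                         tooth_line = c("tls", "chord")) {
  tooth_line <- match.arg(tooth_line)
  sets <- landmark_sets(landmarks)
  rows <- lapply(sets, function(s) {
    len <- NULL
    if (!is.null(measurements)) {
      hit <- measurements$specimen_id == s$specimen_id
      if (any(hit)) len <- measurements$mandible_length_cm[which(hit)[1]]
    }
    gape_metrics_one(s, mandible_length_cm = len,
                     reference_length_cm = reference_length_cm,
                     tooth_line = tooth_line)
  })
  dplyr::bind_rows(rows)
}

#' Optimum prey depth at a given mandible length
#'
#' Rescales an optimum prey-depth fraction (h / mandible length) to an
#' absolute depth at another mandible length. This is how species of very
#' different body size are compared at a common 60 cm mandible.
#'
#' @param fraction Prey-depth fraction(s), in `[0, 1)`.
#' @param length_cm Mandible length(s), cm, positive.
#' @return Depth(s) in cm (unrounded).
#' @export
#' @examples
#' prey_depth_at_length(0.21, 60)   # 12.6
#' prey_depth_at_length(0.15, 87.5) # 13.125 -> printed as 13.13
prey_depth_at_length <- function(fraction, length_cm) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction >= 1)) {
    stop_input("`fraction` must be in [0, 1)", "domain_error")
  }
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop_input("`length_cm` must be positive", "domain_error")
  }
  fraction * length_cm
}

#' Plot a mandible landmark set with its fitted tooth line
#'
#' Displays the digitized landmarks in lateral view together with the fitted
#' tooth-apex line and the parallel line through the glenoid, visualizing the
#' optimum-gape construction.
#'
#' @param landmarks Landmark tibble for a single specimen.
#' @param tooth_line Line-fit method passed to [optimum_gape()].
#' @return A ggplot object.
#' @export
plot_gape_construction <- function(landmarks, tooth_line = "tls") {
  sets <- landmark_sets(landmarks)
  if (length(sets) != 1) {
    stop_input("plot_gape_construction() expects a single specimen", "validation_error")
  }
  s <- sets[[1]]
  fit <- if (tooth_line == "chord") {
    fit_tooth_line(s$tooth_tips[c(1, nrow(s$tooth_tips)), , drop = FALSE])
  } else {
    fit_tooth_line(s$tooth_tips)
  }
  span <- range(c(s$tooth_tips[, 1], s$glenoid[1]))
  tvals <- seq(span[1] - fit$point[1] - 5, span[2] - fit$point[1] + 5, length.out = 2)
  line1 <- data.frame(x = fit$point[1] + tvals * fit$direction[1],
                      y = fit$point[2] + tvals * fit$direction[2])
  line2 <- data.frame(x = s$glenoid[1] + tvals * fit$direction[1],
                      y = s$glenoid[2] + tvals * fit$direction[2])
  df <- data.frame(x = landmarks$x, y = landmarks$y, label = landmarks$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = line1, colour = "steelblue") +
    ggplot2::geom_line(data = line2, colour = "grey50", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = s$specimen_id, x = "anterior → (cm)",
                  y = "dorsal → (cm)") +
    ggplot2::theme_minimal()
}
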