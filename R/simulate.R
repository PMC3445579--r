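# Seeded synthetic-data generators.
#
# These state a known ground truth so every analysis stage has a
# parameter-recovery test: mandible landmark sets constructed so the
# noiseless optimum-gape computation returns the specified angle and
# prey-depth fraction exactly, and character matrices evolved on a known
# tree under a k-state Markov jump process with a controllable fraction of
# ordered characters and missing data.

#' Simulate a mandible landmark set with known gape geometry
#'
#' Constructs a lateral-view landmark set (anterior +x, dorsal +y): glenoid
#' at the origin, dentary tooth apices on a line at perpendicular offset
#' `h = L * (d/L) * tan(angle)` above the glenoid's parallel line, with the
#' posterior-most tooth tip at along-line distance `d = L * (d/L)` from the
#' glenoid. Noiseless generation followed by [optimum_gape()] recovers the
#' specified angle exactly and the prey-depth fraction
#' `(d/L) * tan(angle)`. Isotropic Gaussian noise of sd
#' `landmark_noise_sd * L` is then added to every landmark.
#'
#' Defaults emulate the largest-gape taxon in the published comparative
#' table (mandible 132.2 cm, optimum gape 24 degrees) with a 13-tooth
#' dentary row, the count seen in these taxa.
#'
#' @param true_gape_angle_deg True optimum gape angle, degrees, in (0, 90).
#' @param mandible_length_cm Mandible length L, cm.
#' @param posterior_tooth_offset_fraction d/L, the along-line glenoid to
#'   posterior-tooth distance as a fraction of L, in (0, 1).
#' @param n_teeth Number of dentary tooth apices (>= 2).
#' @param tooth_span_fraction Tooth-row span as a fraction of L.
#' @param landmark_noise_sd Noise sd as a fraction of L (>= 0).
#' @param specimen_id,taxon Labels for the output table.
#' @param seed Integer seed; same seed, same coordinates.
#' @return A list with `landmarks` (standard landmark tibble), and `truth`
#'   (one-row tibble with the generating angle, prey depth, fraction).
#' @export
#' @examples
#' sim <- sim_mandible(true_gape_angle_deg = 24, seed = 1,
#'                     landmark_noise_sd = 0)
#' optimum_gape(sim$landmarks,
#'              measurements = data.frame(specimen_id = "sim",
#'                                        mandible_length_cm = 132.2))
sim_mandible <- function(true_gape_angle_deg = 24,
                         mandible_length_cm = 132.2,
                         posterior_tooth_offset_fraction = 0.45,
                         n_teeth = 13,
                         tooth_span_fraction = 0.5,
                         landmark_noise_sd = 0.005,
                         specimen_id = "sim",
                         taxon = "simulated",
                         seed = 1L) {
  ang <- true_gape_angle_deg
  L <- mandible_length_cm
  dfrac <- posterior_tooth_offset_fraction
  if (ang < 0 || ang >= 90) stop_input("angle must be in [0, 90)", "spec_error")
  if (dfrac <= 0 || dfrac >= 1) stop_input("d/L must be in (0, 1)", "spec_error")
  if (n_teeth < 2) stop_input("need >= 2 teeth", "spec_error")
  if (landmark_noise_sd < 0) stop_input("noise sd must be >= 0", "spec_error")
  d <- dfrac * L
  h <- d * tan(ang * pi / 180)
  if (h >= L) stop_input("infeasible geometry: prey depth >= mandible length", "spec_error")
  span <- tooth_span_fraction * L
  # glenoid at origin; teeth anterior (larger x), on the line y = h;
  # posterior-most tooth at x = d, anterior-most at x = d + span
  xs <- seq(d + span, d, length.out = n_teeth) # anterior -> posterior
  tooth <- cbind(x = xs, y = rep(h, n_teeth))
  retro <- c(-0.05 * L, 0)
  dent <- c(retro[1] + L, 0) # so the landmark chord equals L exactly
  lm <- tibble::tibble(
    specimen_id = specimen_id,
    taxon = taxon,
    label = c("glenoid", "dentary_tip_anterior", "retroarticular_posterior",
              sprintf("tooth_tip_%02d", seq_len(n_teeth))),
    x = c(0, dent[1], retro[1], tooth[, 1]),
    y = c(0, dent[2], retro[2], tooth[, 2])
  )
  if (landmark_noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(2 * nrow(lm), sd = landmark_noise_sd * L),
                                    ncol = 2))
    lm$x <- lm$x + noise[, 1]
    lm$y <- lm$y + noise[, 2]
  }
  truth <- tibble::tibble(
    specimen_id = specimen_id,
    gape_angle_deg = ang,
    prey_depth_cm = h,
    mandible_length_cm = L,
    prey_depth_fraction = h / L
  )
  list(landmarks = lm, truth = truth)
}

# Random unrooted binary topology by sequential random insertion.
random_topology <- function(labels) {
  n <- length(labels)
  ord <- sample.int(n)
  tree <- utree(cbind(rep(n + 1L, 3), ord[1:3]), n, labels)
  nextnode <- n + 2L
  if (n > 3) {
    for (i in 4:n) {
      e <- sample.int(nrow(tree$edge), 1)
      tree <- insert_leaf(tree, e, ord[i], nextnode)
      nextnode <- nextnode + 1L
    }
  }
  tree
}

#' Simulate a character matrix on a known tree
#'
#' Evolves each character along a (random or supplied) unrooted binary tree
#' under a k-state Markov jump process with equal branch lengths: the number
#' of change events per branch is Poisson with mean `rate`; an unordered
#' character jumps to a uniformly random different state, an ordered
#' character takes a +/-1 step (reflected at the ends of the state scale, so
#' every event is a real change and states never leave `0..k-1`). Cells are
#' then masked uniformly at random with probability `missing_fraction`.
#'
#' Defaults state the recovery-experiment world used throughout the tests:
#' 12 taxa, 150 binary characters at a low per-branch rate (low homoplasy),
#' with the ordered fraction of the empirical 240-character matrix
#' (40/240) and no missing data.
#'
#' @param n_taxa Number of taxa (>= 4); ignored when `tree` is supplied.
#' @param n_characters Number of characters.
#' @param n_states States per character, k in 2..6.
#' @param rate Expected change events per branch (> 0).
#' @param fraction_ordered Fraction of characters flagged (and evolved) as
#'   ordered.
#' @param missing_fraction Fraction of cells masked as missing.
#' @param tree Optional `phylo` to simulate on (unrooted binary).
#' @param seed Integer seed.
#' @return A list with `matrix` (a [character_matrix()]), `tree` (`phylo`),
#'   and `n_changes` (total change events drawn, for calibration checks).
#' @export
#' @examples
#' sim <- sim_character_matrix(n_taxa = 6, n_characters = 20, seed = 42)
#' sim$matrix
sim_character_matrix <- function(n_taxa = 12,
                                 n_characters = 150,
                                 n_states = 2,
                                 rate = 0.1,
                                 fraction_ordered = 40 / 240,
                                 missing_fraction = 0,
                                 tree = NULL,
                                 seed = 1L) {
  if (is.null(tree) && n_taxa < 4) stop_input("need >= 4 taxa", "spec_error")
  if (rate <= 0) stop_input("rate must be > 0", "spec_error")
  if (n_states < 2 || n_states > 6) stop_input("n_states must be in 2..6", "spec_error")
  if (fraction_ordered < 0 || fraction_ordered > 1 ||
      missing_fraction < 0 || missing_fraction > 1) {
    stop_input("fractions must be in [0, 1]", "spec_error")
  }
  k <- as.integer(n_states)
  with_seed(seed, {
    ut <- if (is.null(tree)) {
      random_topology(paste0("t", seq_len(n_taxa)))
    } else {
      phylo_to_utree(tree)
    }
    ntip <- ut$ntip
    ori <- orient_utree(ut)
    n_ord <- round(fraction_ordered * n_characters)
    ordered <- seq_len(n_characters) %in% sample.int(n_characters, n_ord)
    states <- matrix(NA_integer_, ntip, n_characters,
                     dimnames = list(ut$labels, NULL))
    par_map <- integer(ori$maxid)
    for (p in seq_len(ori$maxid)) {
      for (ch in ori$children[[p]]) par_map[ch] <- p
    }
    node_state <- integer(ori$maxid)
    total_changes <- 0L
    for (j in seq_len(n_characters)) {
      node_state[ori$root] <- sample.int(k, 1) - 1L
      for (v in rev(ori$postorder)) { # preorder: parents before children
        if (v == ori$root) next
        s <- node_state[par_map[v]]
        nev <- rpois(1, rate)
        total_changes <- total_changes + nev
        if (nev > 0) {
          for (e in seq_len(nev)) {
            if (ordered[j]) {
              s <- if (s == 0L) 1L
                   else if (s == k - 1L) k - 2L
                   else s + sample(c(-1L, 1L), 1)
            } else {
              s <- (s + sample.int(k - 1L, 1)) %% k
            }
          }
        }
        node_state[v] <- s
        if (v <= ntip) states[v, j] <- s
      }
    }
    if (missing_fraction > 0) {
      mask <- runif(length(states)) < missing_fraction
      states[mask] <- NA_integer_
    }
    list(
      matrix = character_matrix(states, ordered = ordered),
      tree = utree_to_phylo(ut),
      n_changes = total_changes
    )
  })
}
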