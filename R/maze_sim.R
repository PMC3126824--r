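#' Strain parameter set for the maze simulator
#'
#' Behavioural phenotypes are encoded as three numbers: the ceiling of the
#' per-junction turn probability, the gain translating stimulus salience
#' into bias, and a stimulus-independent left/right asymmetry.
#'
#' @param name Strain label, e.g. `"wild_type"` or `"dunce1"`.
#' @param p_max Maximum per-choice probability of turning with the stimulus,
#'   in (0.5, 1\].
#' @param salience_gain Non-negative gain mapping salience to bias.
#' @param baseline_asymmetry Stimulus-independent additive bias (default 0).
#' @return A `strain_params` object.
#' @export
strain_params <- function(name, p_max = 0.75, salience_gain = 1,
                          baseline_asymmetry = 0) {
  if (!is.finite(p_max) || p_max <= 0.5 || p_max > 1)
    stop("p_max must lie in (0.5, 1]", call. = FALSE)
  if (!is.finite(salience_gain) || salience_gain < 0)
    stop("salience_gain must be >= 0", call. = FALSE)
  if (!is.finite(baseline_asymmetry))
    stop("baseline_asymmetry must be finite", call. = FALSE)
  structure(
    list(name = as.character(name), p_max = p_max,
         salience_gain = salience_gain,
         baseline_asymmetry = baseline_asymmetry),
    class = "strain_params"
  )
}

#' One maze run's tube counts
#'
#' Nine non-negative integer counts indexed by tube -4..+4, with the
#' stimulus direction flag, strain label, maze identifier and the number of
#' flies loaded (flies lost in the maze are loaded but never counted).
#'
#' @param counts Integer vector of length 9 (tubes -4..+4, in that order).
#' @param stimulus_direction +1 or -1.
#' @param strain Strain label.
#' @param maze_id Identifier.
#' @param n_loaded Flies loaded; must be >= sum(counts).
#' @return A `tube_counts` object.
#' @export
tube_counts <- function(counts, stimulus_direction = 1L, strain = "unknown",
                        maze_id = "maze1", n_loaded = sum(counts)) {
  counts <- as.integer(counts)
  if (length(counts) != 9L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be 9 non-negative integers (tubes -4..+4)",
         call. = FALSE)
  if (!stimulus_direction %in% c(-1L, 1L))
    stop("stimulus_direction must be +1 or -1", call. = FALSE)
  n_loaded <- as.integer(n_loaded)
  if (is.na(n_loaded) || n_loaded < sum(counts))
    stop("n_loaded must be >= sum(counts)", call. = FALSE)
  structure(
    list(counts = stats::setNames(counts, -4:4),
         stimulus_direction = as.integer(stimulus_direction),
         strain = as.character(strain), maze_id = as.character(maze_id),
         n_loaded = n_loaded),
    class = "tube_counts"
  )
}

#' @export
print.tube_counts <- function(x, ...) {
  cat(sprintf("<tube_counts> %s (%s), direction %+d, %d/%d flies counted\n",
              x$maze_id, x$strain, x$stimulus_direction, sum(x$counts),
              x$n_loaded))
  print(x$counts)
  invisible(x)
}

#' Terminal tube reached by a sequence of eight binary choices
#'
#' The maze has 8 sequential T-junctions; each choice moves the fly half a
#' tube index toward +4 (choice +1) or -4 (choice -1), so the exit tube is
#' `(#(+1) - #(-1)) / 2`, an integer in \[-4, +4\].
#'
#' @param choices Vector of exactly 8 values in {+1, -1}.
#' @return Integer tube index in -4..+4.
#' @examples
#' tube_from_choices(rep(1, 8))            # +4
#' tube_from_choices(c(1, 1, 1, 1, 1, 1, -1, -1))  # +2
#' @export
tube_from_choices <- function(choices) {
  if (length(choices) != 8L)
    stop("exactly 8 choices are required", call. = FALSE)
  if (!all(choices %in% c(-1, 1)))
    stop("choices must be +1 or -1", call. = FALSE)
  as.integer(sum(choices) / 2)
}

#' Simulate one maze run
#'
#' Each loaded fly is independently lost with probability `loss_prob`
#' (loaded but never counted); each surviving fly makes 8 independent
#' Bernoulli(`p_turn`) choices toward the stimulus and exits by
#' [tube_from_choices()]. Counts are reported in absolute tube coordinates:
#' when the stimulus moves in the -1 direction the tube sign is mirrored.
#'
#' @param n_flies Flies loaded (> 0).
#' @param p_turn Per-junction probability of turning with the stimulus.
#' @param loss_prob Probability a fly is lost, in \[0, 1).
#' @param stimulus_direction +1 or -1.
#' @param seed Integer seed.
#' @param strain,maze_id Labels carried into the record.
#' @return A `tube_counts` record.
#' @export
simulate_maze <- function(n_flies = 25L, p_turn = 0.5, loss_prob = 0.05,
                          stimulus_direction = 1L, seed,
                          strain = "unknown", maze_id = "maze1") {
  n_flies <- as.integer(n_flies)
  if (is.na(n_flies) || n_flies <= 0L)
    stop("n_flies must be a positive integer", call. = FALSE)
  if (!is.finite(p_turn) || p_turn < 0 || p_turn > 1)
    stop("p_turn must lie in [0, 1]", call. = FALSE)
  if (!is.finite(loss_prob) || loss_prob < 0 || loss_prob >= 1)
    stop("loss_prob must lie in [0, 1)", call. = FALSE)
  if (!stimulus_direction %in% c(-1L, 1L))
    stop("stimulus_direction must be +1 or -1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::with_seed(seed, {
    kept <- stats::runif(n_flies) >= loss_prob
    n_kept <- sum(kept)
    # 8 i.i.d. Bernoulli junction choices collapse to one Binomial(8, p)
    # draw per fly; tube = #toward - 4, identical to tube_from_choices()
    tube_rel <- if (n_kept > 0)
      stats::rbinom(n_kept, 8L, p_turn) - 4L else integer(0)
    tube_abs <- tube_rel * as.integer(stimulus_direction)
    counts <- tabulate(tube_abs + 5L, nbins = 9L)
    tube_counts(counts, stimulus_direction, strain, maze_id,
                n_loaded = n_flies)
  })
}

#' Psychometric link from stimulus salience to turn probability
#'
#' Saturating-exponential bias:
#' `p = 0.5 + (p_max - 0.5) * (1 - exp(-gain * salience)) + asymmetry`,
#' clamped to \[0, 1\]. Salience 0 gives `0.5 + asymmetry`; the probability
#' saturates at `p_max` (+ asymmetry) as salience grows.
#'
#' @param salience Non-negative stimulus salience.
#' @param strain A [strain_params()].
#' @return Per-junction turn probability.
#' @export
psychometric_bias <- function(salience, strain) {
  stopifnot(inherits(strain, "strain_params"))
  if (any(!is.finite(salience)) || any(salience < 0))
    stop("salience must be >= 0", call. = FALSE)
  p <- 0.5 + (strain$p_max - 0.5) * (1 - exp(-strain$salience_gain * salience)) +
    strain$baseline_asymmetry
  pmin(pmax(p, 0), 1)
}

#' Reference strain parameter sets
#'
#' Two calibrated phenotypes for the simulator: a wild-type set and a
#' hyper-responsive mutant-like set (higher ceiling and salience gain,
#' mirroring a learning mutant's stronger response to high-contrast,
#' highly structured motion). The gains are calibrated so the standard
#' green/black grating (salience ~0.17 under the default geometry and
#' salience scale) yields expected VRs near 0.5 and 1.5 respectively, the
#' baseline magnitudes of the paradigm.
#'
#' @return Named list of two [strain_params()].
#' @export
paradigm_strains <- function() {
  list(
    wild_type = strain_params("wild_type", p_max = 0.75,
                              salience_gain = 1.67),
    dunce1 = strain_params("dunce1", p_max = 0.95, salience_gain = 3.13)
  )
}

# per-stage/per-maze seeds derived from a master seed: one documented
# splitting point so any stage can be re-run in isolation
derive_seeds <- function(master_seed, n, stage = "maze") {
  offset <- sum(utf8ToInt(stage))
  withr::with_seed(as.integer(master_seed) + offset,
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a direction-balanced experiment
#'
#' Runs `n_mazes/2` mazes with the stimulus moving in the +1 direction and
#' `n_mazes/2` in the -1 direction (the paradigm's direction balancing),
#' with per-maze seeds derived deterministically from the master seed.
#' The per-junction turn probability is `psychometric_bias(salience, strain)`,
#' with the baseline asymmetry applied in absolute (not stimulus) coordinates
#' so that balancing cancels it.
#'
#' @param strain A [strain_params()].
#' @param salience Stimulus salience (>= 0).
#' @param n_mazes Even number of mazes.
#' @param n_flies_per_maze Flies loaded per maze (default 25).
#' @param loss_prob Per-fly loss probability (default 0.05).
#' @param seed Master seed.
#' @return A list of `tube_counts` records.
#' @export
simulate_experiment <- function(strain, salience, n_mazes = 8L,
                                n_flies_per_maze = 25L, loss_prob = 0.05,
                                seed) {
  stopifnot(inherits(strain, "strain_params"))
  n_mazes <- as.integer(n_mazes)
  if (is.na(n_mazes) || n_mazes < 2L || n_mazes %% 2L != 0L)
    stop("n_mazes must be an even integer >= 2", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dirs <- rep(c(1L, -1L), each = n_mazes / 2L)
  seeds <- derive_seeds(seed, n_mazes, stage = "maze")
  p_stim <- 0.5 + (strain$p_max - 0.5) *
    (1 - exp(-strain$salience_gain * salience))
  lapply(seq_len(n_mazes), function(i) {
    # asymmetry is a bias toward absolute +, independent of stimulus
    # direction: in stimulus coordinates it flips sign with direction
    p <- pmin(pmax(p_stim + dirs[i] * strain$baseline_asymmetry, 0), 1)
    simulate_maze(n_flies_per_maze, p, loss_prob, dirs[i], seeds[i],
                  strain = strain$name,
                  maze_id = sprintf("maze%03d", i))
  })
}

#' Estimate the per-junction turn probability from tube counts
#'
#' Inverts the binomial maze model: the direction-corrected mean tube index
#' m over all counted flies satisfies `m = 4(2p - 1)`, so
#' `p_hat = (m/4 + 1)/2`, with a 95% Wald interval from the binomial over
#' `8 * total flies` junction choices.
#'
#' @param records List of `tube_counts`.
#' @return List with `p_hat` and `ci95` (length-2 numeric).
#' @export
estimate_p <- function(records) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "tube_counts")))
  tot <- 0; n_flies <- 0
  for (r in records) {
    tot <- tot + sum(r$counts * (-4:4)) * r$stimulus_direction
    n_flies <- n_flies + sum(r$counts)
  }
  if (n_flies == 0L) stop("no counted flies in any record", call. = FALSE)
  m <- tot / n_flies
  p_hat <- (m / 4 + 1) / 2
  n_choices <- 8 * n_flies
  se <- sqrt(p_hat * (1 - p_hat) / n_choices)
  list(p_hat = p_hat,
       ci95 = c(max(0, p_hat - 1.96 * se), min(1, p_hat + 1.96 * se)))
}
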