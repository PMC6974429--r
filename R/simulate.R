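#' Generator configuration for synthetic agonistic event logs
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a latent linear dominance hierarchy (random permutation of ranks), dyad
#' fight times from an inhomogeneous Poisson process whose rate declines
#' exponentially with observed time since mixing (fighting is most intense
#' right after regrouping), win probabilities that increase with the rank
#' gap, and an initiator who is usually — not always — the eventual winner.
#'
#' Parameters, with units and defaults:
#' * `lambda0`: base fight rate per dyad per observed hour at mixing.
#' * `kappa` (1/h, default 0.15): exponential decay of the fight rate over
#'   observed time; the rate after t observed hours is
#'   `lambda0 * exp(-kappa * t)`.
#' * `beta` (default 2): hierarchy steepness.  The higher-ranked animal of
#'   a dyad wins with probability `plogis(beta * drank / (N - 1))`, where
#'   `drank` is the rank gap; normalising by `N - 1` gives `beta` the same
#'   meaning in pens of any size.  `beta = 0` is an exchangeable 50/50
#'   null; large `beta` a strict hierarchy.
#' * `gamma` (in \[0, 1\], default 0.8): probability that the eventual
#'   winner is also the initiator; otherwise the initiator is drawn
#'   uniformly from the pair.  Attackers usually win, but the initiator
#'   model is deliberately decoupled from the outcome because the network
#'   edges follow initiator/receiver while significance tests follow
#'   winner/loser.
#' * `n_animals_mean`, `n_animals_sd`: pen size distribution (rounded
#'   normal, minimum 2).
#'
#' @param n_animals_mean,n_animals_sd pen-size distribution.
#' @param schedule an [obs_schedule].
#' @param lambda0 base dyadic fight rate (fights per dyad per observed hour).
#' @param kappa temporal decay rate (>= 0, per observed hour).
#' @param beta hierarchy steepness (>= 0).
#' @param gamma initiator-wins probability in \[0, 1\].
#' @param mean_duration_s mean fight duration in seconds (exponential).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_animals_mean = 8.9, n_animals_sd = 0.6,
                             schedule = schedule_preset("piglets_28h"),
                             lambda0 = 1, kappa = 0.15, beta = 2,
                             gamma = 0.8, mean_duration_s = 20) {
  stopifnot(inherits(schedule, "obs_schedule"))
  if (lambda0 < 0 || kappa < 0 || beta < 0) stop("rates and steepness must be >= 0")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (n_animals_mean < 2) stop("mean pen size must be >= 2")
  structure(list(n_animals_mean = n_animals_mean, n_animals_sd = n_animals_sd,
                 schedule = schedule, lambda0 = lambda0, kappa = kappa,
                 beta = beta, gamma = gamma, mean_duration_s = mean_duration_s),
            class = "generator_config")
}

# Integral of exp(-kappa t) over [0, T]: expected per-dyad fights / lambda0.
decay_integral <- function(kappa, T) if (kappa > 0) (1 - exp(-kappa * T)) / kappa else T

#' Simulate the agonistic event log of one pen
#'
#' Animals receive latent ranks by random permutation.  Each unordered dyad
#' fights at times drawn from an inhomogeneous Poisson process with rate
#' `lambda0 * exp(-kappa * t)` over observed hours; the higher-ranked
#' animal wins each fight with probability
#' `plogis(beta * drank / (N - 1))`; the winner initiates with probability
#' `gamma`, otherwise the initiator is uniform on the pair.  Fight start
#' times are mapped back into the schedule's clock blocks (whole minutes).
#'
#' @param config a [generator_config()].
#' @param pen_id pen identifier for the generated log.
#' @param animals optional explicit animal ids (overrides the pen-size
#'   draw).
#' @param seed optional RNG seed for a reproducible pen.
#' @return An [event_log] with the pen's roster and events; latent ranks
#'   are attached as `attr(, "ranks")` (named, 1 = lowest).
#' @export
simulate_pen <- function(config, pen_id = "pen1", animals = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(animals)) {
    n <- max(2L, as.integer(round(stats::rnorm(1, config$n_animals_mean,
                                               config$n_animals_sd))))
    animals <- sprintf("%s-a%02d", pen_id, seq_len(n))
  }
  animals <- as.character(animals)
  n <- length(animals)
  if (n < 2L) stop("a pen needs at least 2 animals")
  ranks <- sample(n)
  names(ranks) <- animals
  sch <- config$schedule
  T <- total_hours(sch)
  I <- decay_integral(config$kappa, T)

  pairs <- utils::combn(animals, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    m <- stats::rpois(1L, config$lambda0 * I)
    if (m == 0L) next
    u <- stats::runif(m)
    t <- if (config$kappa > 0)
      -log(1 - u * (1 - exp(-config$kappa * T))) / config$kappa
    else u * T
    hi <- if (ranks[a] > ranks[b]) a else b
    lo <- if (hi == a) b else a
    p_hi <- stats::plogis(config$beta * abs(ranks[a] - ranks[b]) / (n - 1))
    hi_wins <- stats::runif(m) < p_hi
    winner <- ifelse(hi_wins, hi, lo)
    loser <- ifelse(hi_wins, lo, hi)
    win_initiates <- stats::runif(m) < config$gamma
    coin <- stats::runif(m) < 0.5
    initiator <- ifelse(win_initiates | coin, winner, loser)
    receiver <- ifelse(initiator == winner, loser, winner)
    clock <- hours_to_clock(sch, t)
    rows[[length(rows) + 1L]] <- data.frame(
      pen_id = pen_id, initiator = initiator, receiver = receiver,
      winner = winner, loser = loser, day = clock$day,
      clock_time = floor(clock$clock_time),
      duration_s = 1 + round(stats::rexp(m, 1 / config$mean_duration_s)))
  }
  events <- if (length(rows)) do.call(rbind, rows)
            else data.frame(pen_id = character(), initiator = character(),
                            receiver = character(), winner = character(),
                            loser = character(), day = integer(),
                            clock_time = numeric(), duration_s = numeric())
  roster <- stats::setNames(list(animals), pen_id)
  log <- event_log(events, roster, schedule = sch, check_schedule = TRUE)
  attr(log, "ranks") <- ranks
  log
}

cohort_presets <- list(
  piglets   = list(size_mean = 8.9,  size_sd = 0.6, schedule = "piglets_28h",
                   fights_per_animal_hour = 12.3),
  fatteners = list(size_mean = 20.9, size_sd = 1.7, schedule = "fatteners_17h",
                   fights_per_animal_hour = 5.9),
  gilts     = list(size_mean = 20.8, size_sd = 3.4, schedule = "fatteners_17h",
                   fights_per_animal_hour = 5.3)
)

#' Simulate a cohort of pens for one age group
#'
#' Presets mirror the three standard mixing events: weaned piglets (pen
#' size 8.9 +/- 0.6, 28 h schedule, 12.3 fights per animal-hour),
#' fattening pigs (20.9 +/- 1.7, 17 h, 5.9) and gilts (20.8 +/- 3.4, 17 h,
#' 5.3).  For each pen the base rate `lambda0` is calibrated so the
#' expected number of fights per animal-hour over the pen's full schedule
#' matches the preset target:
#' `lambda0 = f * N * T / (D * I)` with `D = N(N-1)/2` dyads and `I` the
#' integral of the temporal decay over the `T` observed hours.
#'
#' @param age_group `"piglets"`, `"fatteners"` or `"gilts"`.
#' @param n_pens number of pens to simulate.
#' @param seed optional RNG seed for a reproducible cohort.
#' @param kappa,beta,gamma generator parameters (see [generator_config()]).
#' @return An [event_log] with all pens (`pen01`, `pen02`, ...); per-pen
#'   latent ranks in `attr(, "ranks")`.
#' @export
simulate_cohort <- function(age_group = c("piglets", "fatteners", "gilts"),
                            n_pens = 10L, seed = NULL,
                            kappa = 0.15, beta = 2, gamma = 0.8) {
  age_group <- match.arg(age_group)
  if (n_pens < 1L) stop("need at least one pen")
  if (!is.null(seed)) set.seed(seed)
  preset <- cohort_presets[[age_group]]
  sch <- schedule_preset(preset$schedule)
  T <- total_hours(sch)
  I <- decay_integral(kappa, T)
  logs <- vector("list", n_pens)
  ranks <- list()
  for (i in seq_len(n_pens)) {
    pen <- sprintf("pen%02d", i)
    n <- max(2L, as.integer(round(stats::rnorm(1, preset$size_mean, preset$size_sd))))
    D <- n * (n - 1) / 2
    lambda0 <- preset$fights_per_animal_hour * n * T / (D * I)
    cfg <- generator_config(n_animals_mean = n, n_animals_sd = 0, schedule = sch,
                            lambda0 = lambda0, kappa = kappa, beta = beta,
                            gamma = gamma)
    logs[[i]] <- simulate_pen(cfg, pen_id = pen,
                              animals = sprintf("%s-a%02d", pen, seq_len(n)))
    ranks[[pen]] <- attr(logs[[i]], "ranks")
  }
  events <- do.call(rbind, lapply(logs, function(l) l$events))
  roster <- do.call(c, lapply(logs, function(l) l$roster))
  log <- event_log(events, roster, schedule = sch, check_schedule = TRUE)
  attr(log, "ranks") <- ranks
  log
}

#' Observed fights per animal-hour
#'
#' Event count divided by (number of animals x observed hours), pooled over
#' the pens of a log — the standard rate used to compare fighting activity
#' between age groups.
#'
#' @param log an [event_log].
#' @param hours observed hours the events cover; defaults to the schedule
#'   total.
#' @param per_pen return one rate per pen instead of the pooled rate.
#' @return Numeric rate (or named vector with `per_pen = TRUE`).
#' @export
fights_per_animal_hour <- function(log, hours = NULL, per_pen = FALSE) {
  stopifnot(inherits(log, "event_log"))
  if (is.null(hours)) {
    if (is.null(log$schedule)) stop("no schedule: supply hours")
    hours <- total_hours(log$schedule)
  }
  if (per_pen) {
    counts <- table(factor(log$events$pen_id, levels = names(log$roster)))
    as.numeric(counts) / (lengths(log$roster) * hours)
  } else {
    nrow(log$events) / (sum(lengths(log$roster)) * hours)
  }
}
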