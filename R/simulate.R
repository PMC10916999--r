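# Seeded synthetic-cohort generator. Emulates a community cohort of older
# adults completing the two keyboard tapping tests plus count-valued
# cognitive outcomes linked to the motor features through a log-linear
# (negative-binomial) model. Every downstream stage of the package can be
# exercised on its output.

#' Synthetic cohort configuration
#'
#' Builds the full parameterization of a synthetic cohort. Defaults emulate
#' the published cohort the package is designed around: a community sample of
#' 1359 older adults of whom 105 leave the tapping protocol incomplete and,
#' among the 1254 completers, 74 report cognitive symptoms, 3 Parkinson's
#' disease and 8 multiple sclerosis — leaving 1169 analysable participants.
#' Demographic targets (age 65.8 +/- 7.37 truncated to 51-89 years, 73.1%
#' female, six-level education distribution, HADS anxiety 4.28 +/- 3.55 and
#' depression 2.90 +/- 2.72) and tapping-frequency targets (single-key blocks
#' 5.54/5.62/5.70/5.77 presses per s; alternate-key 2.17 dominant, 2.00
#' non-dominant) are the published cohort descriptives. The truncated /
#' floor-0 distributions are re-located internally so their *realized* means
#' hit the configured targets.
#'
#' Inter-press intervals are lognormal, so the rhythm-variability feature
#' (SD of log intervals) recovers the configured `sigma_log_interval` in
#' expectation. Per-participant lognormal random effects scale rate, rhythm
#' and dwell.
#'
#' The outcome model links each cognitive count to centred covariates and
#' centred motor features through a log-linear negative-binomial (or
#' Poisson) model. The default scenario injects a motor link into episodic
#' memory only (dominant-hand alternate-key frequency and non-dominant
#' variability -> PAL errors) and none into the working-memory outcomes.
#'
#' @param n_participants Cohort size before any exclusion.
#' @param seed Integer seed; fully determines the cohort via independent
#'   per-participant substreams.
#' @param demographics,tapping,outcomes,exclusions Optional lists merged
#'   over the defaults (partial overrides allowed at any depth-1 key).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 1359, seed = 1L,
                       demographics = list(), tapping = list(),
                       outcomes = list(), exclusions = list()) {
  demo_def <- list(
    age_mean = 65.8, age_sd = 7.37, age_min = 51, age_max = 89,
    p_female = 0.731,
    education_probs = c(
      left_before_16 = 49, left_at_16 = 108, left_at_17_18 = 162,
      undergraduate = 577, masters = 202, phd = 71
    ) / 1169,
    hads_anxiety_mean = 4.28, hads_anxiety_sd = 3.55, hads_anxiety_max = 19,
    hads_depression_mean = 2.90, hads_depression_sd = 2.72,
    hads_depression_max = 15
  )
  tap_def <- list(
    # presses per second, per protocol block (published block means)
    single_key_freq = c(5.54, 5.62, 5.70, 5.77),
    alternate_freq = c(dominant = 2.17, non_dominant = 2.00),
    # between-participant coefficient of variation of tapping rate
    single_key_rate_cv = 0.813 / 5.54,
    alternate_rate_cv = c(dominant = 0.365 / 2.17, non_dominant = 0.321 / 2.00),
    # within-block SD of log inter-press interval (the variability feature);
    # alternate-key values are plausible but uncalibrated (not published)
    sigma_log_interval = c(single_key = 0.10, alternate_dominant = 0.18,
                           alternate_non_dominant = 0.20),
    rhythm_cv = 0.30,   # participant-level spread of the rhythm multiplier
    # fraction of log-rate variance shared across tests/hands (one latent
    # "motor ability" factor), so single- and alternate-key speeds correlate
    rate_share = 0.5,
    # dwell time, ms (uncalibrated: typical keyboard dwell range)
    dwell_mean = c(single_key = 95, alternate = 110),
    dwell_sd = c(single_key = 20, alternate = 25),
    dwell_participant_cv = 0.15,
    # probability a press lands on an adjacent / other key
    p_adjacent = c(single_key = 0.010, alternate = 0.030),
    p_other = c(single_key = 0.003, alternate = 0.010)
  )
  out_def <- list(
    paltea6 = list(
      family = "nb", mu0 = 4.40, theta = 1.0, cap = 22,
      age = 0.025, sex_male = 0.05,
      education = c(-0.04, -0.08, -0.12, -0.16, -0.20),
      hads_anxiety = 0.01, hads_depression = 0.02,
      motor = c(sk_freq_b1 = -0.20, ak_freq_dom = -0.30, ak_var_nd = 1.50)
    ),
    swmbe6 = list(
      family = "nb", mu0 = 3.22, theta = 1.4, cap = 13,
      age = 0.020, sex_male = 0.05,
      education = c(-0.04, -0.08, -0.12, -0.16, -0.20),
      hads_anxiety = 0.01, hads_depression = 0.02,
      motor = c()
    ),
    swms = list(
      # published SD < mean: under-dispersed, so Poisson not NB
      family = "poisson", mu0 = 7.75, theta = NA, cap = 13,
      age = 0.010, sex_male = 0.02,
      education = c(-0.02, -0.04, -0.06, -0.08, -0.10),
      hads_anxiety = 0.005, hads_depression = 0.01,
      motor = c()
    )
  )
  exc_def <- list(
    n_symptomatic = 74, n_pd = 3, n_ms = 8, n_incomplete = 105
  )
  cfg <- list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    demographics = utils::modifyList(demo_def, demographics),
    tapping = utils::modifyList(tap_def, tapping),
    outcomes = utils::modifyList(out_def, outcomes),
    exclusions = utils::modifyList(exc_def, exclusions)
  )
  tot_flags <- with(cfg$exclusions, n_symptomatic + n_pd + n_ms + n_incomplete)
  if (tot_flags > cfg$n_participants) {
    stop("exclusion-flag counts exceed the cohort size", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# --- location solvers: hit a target mean after truncation/clipping ---------

.trunc_normal_mean <- function(loc, sd, lo, hi) {
  a <- (lo - loc) / sd
  b <- (hi - loc) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  loc + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

.clip_normal_mean <- function(loc, sd, lo, hi) {
  a <- (lo - loc) / sd
  b <- (hi - loc) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    loc * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

.solve_loc <- function(target, sd, lo, hi, mean_fun) {
  stats::uniroot(
    function(loc) mean_fun(loc, sd, lo, hi) - target,
    interval = c(target - 4 * sd, target + 4 * sd), tol = 1e-9
  )$root
}

.rtnorm <- function(n, loc, sd, lo, hi) {
  # rejection sampling; acceptance is high for the configured ranges
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, loc, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# lognormal multiplier with mean exactly 1 and coefficient of variation cv
.rmult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate participant demographics
#'
#' Draws `n` demographic records from the configured distributions using the
#' current RNG state: truncated-normal age (re-located so the truncated mean
#' equals the configured target), Bernoulli sex, categorical education, and
#' rounded floor-0 normal HADS scores (also re-located to hit their target
#' means after clipping).
#'
#' @param n Number of participants.
#' @param config A [sim_config()].
#' @return Tibble of demographic scalars (no ids).
#' @export
simulate_demographics <- function(n, config = sim_config()) {
  d <- config$demographics
  age_loc <- .solve_loc(d$age_mean, d$age_sd, d$age_min, d$age_max,
    .trunc_normal_mean)
  anx_loc <- .solve_loc(d$hads_anxiety_mean, d$hads_anxiety_sd, 0,
    d$hads_anxiety_max, .clip_normal_mean)
  dep_loc <- .solve_loc(d$hads_depression_mean, d$hads_depression_sd, 0,
    d$hads_depression_max, .clip_normal_mean)
  tibble::tibble(
    age_years = round(.rtnorm(n, age_loc, d$age_sd, d$age_min, d$age_max), 1),
    sex = factor(
      ifelse(rbinom(n, 1, d$p_female) == 1, "female", "male"),
      levels = c("female", "male")
    ),
    education_level = factor(
      sample(names(d$education_probs), n, TRUE, prob = d$education_probs),
      levels = names(d$education_probs)
    ),
    hads_anxiety = as.integer(pmin(pmax(
      round(rnorm(n, anx_loc, d$hads_anxiety_sd)), 0), d$hads_anxiety_max)),
    hads_depression = as.integer(pmin(pmax(
      round(rnorm(n, dep_loc, d$hads_depression_sd)), 0), d$hads_depression_max))
  )
}

#' Draw participant-level tapping latents
#'
#' One draw of the lognormal random effects for a single participant: a rate
#' multiplier per test/hand (sharing a configurable fraction of their
#' log-variance through one latent motor-ability factor), a rhythm
#' multiplier common to all blocks, and a dwell multiplier. All multipliers
#' have mean exactly 1.
#'
#' @param config A [sim_config()].
#' @return Named list of multipliers.
#' @export
participant_latents <- function(config = sim_config()) {
  tp <- config$tapping
  z_shared <- rnorm(1)
  rate_mult <- function(cv) {
    if (cv <= 0) return(1)
    s_tot <- sqrt(log(1 + cv^2))
    s_sh <- sqrt(tp$rate_share) * s_tot
    s_sp <- sqrt(max(s_tot^2 - s_sh^2, 0))
    exp(s_sh * z_shared + rnorm(1, 0, s_sp) - s_tot^2 / 2)
  }
  list(
    rate_single = rate_mult(tp$single_key_rate_cv),
    rate_alt_dom = rate_mult(tp$alternate_rate_cv[["dominant"]]),
    rate_alt_nd = rate_mult(tp$alternate_rate_cv[["non_dominant"]]),
    rhythm = .rmult(1, tp$rhythm_cv),
    dwell = .rmult(1, tp$dwell_participant_cv)
  )
}

# Generate one block's worth of raw key events using the current RNG state.
# Returns a tibble (key_label, down_ms, up_ms) or NULL for zero presses.
.simulate_block_events <- function(rate_per_s, sigma_log, dwell_mean,
                                   dwell_sd, p_adj, p_other, duration_s,
                                   test_type, adjacency) {
  t_ms <- duration_s * 1000
  cv2 <- exp(sigma_log^2) - 1
  # ordinary-renewal correction so E[press count] = rate * duration
  target_count <- rate_per_s * duration_s
  mu_interval <- t_ms / (target_count + 0.5 - cv2 / 2)
  draw <- function(m) {
    if (sigma_log > 0) {
      rlnorm(m, meanlog = log(mu_interval) - sigma_log^2 / 2, sdlog = sigma_log)
    } else {
      rep(mu_interval, m)
    }
  }
  iv <- draw(ceiling(target_count * 1.5) + 20)
  while (sum(iv) < t_ms) iv <- c(iv, draw(20))
  # round each interval to integer ms (>= 1), so constant configured
  # intervals stay exactly constant after discretization
  iv <- pmax(round(iv), 1)
  down <- cumsum(iv)
  down <- down[down < t_ms]
  n <- length(down)
  if (n == 0) return(NULL)

  dwell <- pmax(round(rnorm(n, dwell_mean, dwell_sd)), 5)
  up <- down + dwell
  nxt <- c(down[-1], Inf)
  up <- pmin(up, nxt - 1)          # release before the next press lands
  up <- pmin(up, t_ms)             # truncated at block end (flagged on read)
  up <- pmax(up, down + 1)

  if (test_type == "single_key") {
    expected <- rep("space", n)
  } else {
    anchor <- sample(c("s", "semicolon"), 1)
    other <- setdiff(c("s", "semicolon"), anchor)
    expected <- rep(c(anchor, other), length.out = n)
  }
  u <- stats::runif(n)
  key <- expected
  other_pool <- c("q", "w", "e", "r", "t", "y", "u", "i", "o", "g", "h", "j", "k")
  adj_idx <- which(u < p_adj)
  oth_idx <- which(u >= p_adj & u < p_adj + p_other)
  for (i in adj_idx) {
    adj <- adjacency[[expected[i]]]
    key[i] <- adj[sample.int(length(adj), 1)]
  }
  for (i in oth_idx) {
    key[i] <- other_pool[sample.int(length(other_pool), 1)]
  }
  tibble::tibble(key_label = key, down_ms = down, up_ms = up)
}

#' Simulate one participant's tapping session
#'
#' Generates the raw key events of the full protocol (four 10 s single-key
#' blocks, then one 30 s alternate-key block per hand) for one participant
#' under the given latent multipliers, using the current RNG state.
#' Inter-press intervals are lognormal with a participant/block-specific
#' median and SD; a renewal-theory correction keeps the expected press count
#' at the configured block rate.
#'
#' @param latents From [participant_latents()].
#' @param config A [sim_config()].
#' @param n_blocks_done Number of protocol blocks completed, in protocol
#'   order (single 1-4, alternate dominant, alternate non-dominant); 6 is a
#'   complete session, fewer simulates early drop-out.
#' @param adjacency Adjacency map used for drawing wrong keys.
#' @return Event tibble (`test_type`, `hand`, `block_index`, `key_label`,
#'   `down_ms`, `up_ms`).
#' @export
simulate_tapping_session <- function(latents, config = sim_config(),
                                     n_blocks_done = 6L,
                                     adjacency = default_adjacency()) {
  tp <- config$tapping
  plan <- list()
  for (b in 1:4) {
    plan[[b]] <- list(
      test_type = "single_key", hand = "dominant", block_index = b,
      rate = tp$single_key_freq[b] * latents$rate_single,
      sigma = tp$sigma_log_interval[["single_key"]] * latents$rhythm,
      dwell_mean = tp$dwell_mean[["single_key"]] * latents$dwell,
      dwell_sd = tp$dwell_sd[["single_key"]],
      p_adj = tp$p_adjacent[["single_key"]], p_other = tp$p_other[["single_key"]],
      duration_s = .SINGLE_KEY_DURATION_S
    )
  }
  plan[[5]] <- list(
    test_type = "alternate_key", hand = "dominant", block_index = 1L,
    rate = tp$alternate_freq[["dominant"]] * latents$rate_alt_dom,
    sigma = tp$sigma_log_interval[["alternate_dominant"]] * latents$rhythm,
    dwell_mean = tp$dwell_mean[["alternate"]] * latents$dwell,
    dwell_sd = tp$dwell_sd[["alternate"]],
    p_adj = tp$p_adjacent[["alternate"]], p_other = tp$p_other[["alternate"]],
    duration_s = .ALTERNATE_KEY_DURATION_S
  )
  plan[[6]] <- utils::modifyList(plan[[5]], list(
    hand = "non_dominant",
    rate = tp$alternate_freq[["non_dominant"]] * latents$rate_alt_nd,
    sigma = tp$sigma_log_interval[["alternate_non_dominant"]] * latents$rhythm
  ))
  out <- list()
  for (j in seq_len(min(n_blocks_done, 6L))) {
    p <- plan[[j]]
    ev <- .simulate_block_events(
      p$rate, p$sigma, p$dwell_mean, p$dwell_sd, p$p_adj, p$p_other,
      p$duration_s, p$test_type, adjacency
    )
    if (is.null(ev)) next
    ev$test_type <- p$test_type
    ev$hand <- p$hand
    ev$block_index <- p$block_index
    out[[length(out) + 1]] <- ev
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      test_type = character(0), hand = character(0),
      block_index = integer(0), key_label = character(0),
      down_ms = numeric(0), up_ms = numeric(0)
    ))
  }
  dplyr::bind_rows(out)[, c(
    "test_type", "hand", "block_index", "key_label", "down_ms", "up_ms"
  )]
}

# Reference values used to centre covariates/features in the outcome model.
.feature_centers <- function(config) {
  tp <- config$tapping
  feats <- c("freq", "var", "dwell", "acc")
  centers <- c()
  for (b in 1:4) {
    centers[paste0("sk_", feats, "_b", b)] <- c(
      tp$single_key_freq[b], tp$sigma_log_interval[["single_key"]],
      tp$dwell_mean[["single_key"]],
      1 + tp$p_adjacent[["single_key"]] + 2 * tp$p_other[["single_key"]]
    )
  }
  hands <- c(dom = "dominant", nd = "non_dominant")
  for (suffix in names(hands)) {
    hand <- hands[[suffix]]
    centers[paste0("ak_", feats, "_", suffix)] <- c(
      tp$alternate_freq[[hand]],
      tp$sigma_log_interval[[paste0("alternate_", hand)]],
      tp$dwell_mean[["alternate"]],
      1 + tp$p_adjacent[["alternate"]] + 2 * tp$p_other[["alternate"]]
    )
  }
  centers
}

#' Simulate cognitive count outcomes
#'
#' Draws the three cognitive counts for each participant from the configured
#' log-linear count models, using the current RNG state. The linear
#' predictor centres continuous covariates at their configured population
#' means and motor features at their configured generator targets, so the
#' intercept `log(mu0)` is the expected log count of a reference participant.
#' Counts are capped at the configured task maxima.
#'
#' @param features Feature tibble row(s) as from [build_feature_table()];
#'   missing feature cells contribute zero (centre value).
#' @param demographics Demographic tibble row(s) aligned with `features`.
#' @param config A [sim_config()].
#' @return Tibble with integer columns `paltea6`, `swmbe6`, `swms`.
#' @export
simulate_cognitive_counts <- function(features, demographics,
                                      config = sim_config()) {
  n <- nrow(demographics)
  d <- config$demographics
  centers <- .feature_centers(config)
  edu_idx <- as.integer(demographics$education_level)
  out <- list()
  for (oc in names(config$outcomes)) {
    m <- config$outcomes[[oc]]
    eta <- log(m$mu0) +
      m$age * (demographics$age_years - d$age_mean) +
      m$sex_male * (demographics$sex == "male") +
      c(0, m$education)[edu_idx] +
      m$hads_anxiety * (demographics$hads_anxiety - d$hads_anxiety_mean) +
      m$hads_depression * (demographics$hads_depression - d$hads_depression_mean)
    for (f in names(m$motor)) {
      x <- features[[f]] - centers[[f]]
      x[is.na(x)] <- 0
      eta <- eta + m$motor[[f]] * x
    }
    mu <- exp(eta)
    y <- if (identical(m$family, "poisson")) {
      rpois(n, mu)
    } else {
      rnbinom(n, size = m$theta, mu = mu)
    }
    if (is.finite(m$cap)) y <- pmin(y, m$cap)
    out[[oc]] <- as.integer(y)
  }
  tibble::as_tibble(out)
}

.sub_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 9973) %% 2147483647
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the full generator: demographics, latents, raw tapping event
#' streams, realized motor features, cognitive counts, and exclusion-flag
#' injection. Each participant is drawn from an independent RNG substream
#' derived from the seed and the participant index, so earlier participants
#' are unchanged when `n_participants` grows.
#'
#' Exclusion flags are injected into fixed index ranges at the head of the
#' (exchangeable) cohort: the first `n_symptomatic` participants report
#' cognitive symptoms, the next `n_pd` Parkinson's disease, the next `n_ms`
#' multiple sclerosis, and the following `n_incomplete` stop the tapping
#' protocol early (completing 1-5 of the 6 blocks).
#'
#' @param config A [sim_config()].
#' @return List with class `synthetic_cohort`: `participants` (validated
#'   participant tibble), `events` (validated event tibble), `provenance`
#'   (source string, seed, package version).
#' @export
simulate_cohort <- function(config = sim_config()) {
  n <- config$n_participants
  exc <- config$exclusions
  ids <- sprintf("P%05d", seq_len(n))
  sym <- seq_len(exc$n_symptomatic)
  pd <- exc$n_symptomatic + seq_len(exc$n_pd)
  ms <- exc$n_symptomatic + exc$n_pd + seq_len(exc$n_ms)
  inc <- exc$n_symptomatic + exc$n_pd + exc$n_ms + seq_len(exc$n_incomplete)

  event_list <- vector("list", n)
  demo_list <- vector("list", n)
  count_list <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.sub_seed(config$seed, i))
    demo <- simulate_demographics(1, config)
    lat <- participant_latents(config)
    n_done <- if (i %in% inc) sample(1:5, 1) else 6L
    ev <- simulate_tapping_session(lat, config, n_blocks_done = n_done)
    ev <- dplyr::bind_cols(tibble::tibble(participant_id = ids[i]), ev)
    feats <- build_feature_table(ev, participant_ids = ids[i])
    counts <- simulate_cognitive_counts(feats, demo, config)
    event_list[[i]] <- ev
    demo_list[[i]] <- demo
    count_list[[i]] <- counts
  }
  demo <- dplyr::bind_rows(demo_list)
  counts <- dplyr::bind_rows(count_list)
  participants <- dplyr::bind_cols(
    tibble::tibble(participant_id = ids),
    demo[, c("age_years", "sex", "education_level")],
    tibble::tibble(
      hads_anxiety = demo$hads_anxiety,
      hads_depression = demo$hads_depression,
      memory_change = seq_len(n) %in% sym,
      dementia_dx = FALSE,
      memory_impairment_dx = FALSE,
      pd_dx = seq_len(n) %in% pd,
      ms_dx = seq_len(n) %in% ms
    ),
    counts
  )
  events <- validate_events(dplyr::bind_rows(event_list))
  structure(
    list(
      participants = validate_participants(participants),
      events = events,
      provenance = list(
        source = "tapcog synthetic cohort generator",
        seed = config$seed,
        n_participants = n,
        package_version = as.character(utils::packageVersion("tapcog"))
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants, %d key events (seed %d)\n",
    nrow(x$participants), nrow(x$events), x$provenance$seed
  ))
  invisible(x)
}
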