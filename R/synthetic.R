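# Synthetic inputs for recovery testing: sum-of-Gaussian sigma-profiles with
# role-typical peak placement, screening libraries shaped like the real one,
# exponential decay series with multiplicative noise and occasional >100%
# overshoot, and known descriptor -> rate-constant ground truths. The
# generator emulates the statistical structure the analysis assumes, not the
# chemistry of specific constituents; descriptors of synthetic mixtures are
# always computed through the real integration and mixing code.

#' Parameters of the synthetic-data generator
#'
#' @param seed Master seed; every generator output is reproducible from it.
#' @param n_systems Number of DES systems in a synthetic library.
#' @param water_levels Water contents (wt%) crossed with the systems.
#' @param n_solid Number of (system, level) cells excluded as solids.
#' @param grid_step Sigma-grid spacing (e/A^2) of generated profiles.
#' @param total_area_range Range (A^2) the total profile area is drawn from.
#' @param molar_mass_range Range (g/mol) synthetic molar masses are drawn
#'   from.
#' @param sigma_noise Multiplicative Gaussian noise SD on decay series.
#' @param overshoot_prob Probability a decay series gets early points
#'   inflated above 100% ("overstabilization" signature).
#' @param overshoot_range Multipliers (of 100%) for overshoot points.
#' @param max_days Last sampling day of a decay series.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_systems = 10L,
                           water_levels = c(10, 30, 50), n_solid = 2L,
                           grid_step = 5e-4,
                           total_area_range = c(50, 150),
                           molar_mass_range = c(50, 200),
                           sigma_noise = 0.05, overshoot_prob = 0.3,
                           overshoot_range = c(1.05, 1.4), max_days = 28) {
  stopifnot(grid_step > 0, sigma_noise >= 0,
            overshoot_prob >= 0, overshoot_prob <= 1,
            all(total_area_range > 0), all(molar_mass_range > 0))
  structure(list(seed = as.integer(seed), n_systems = as.integer(n_systems),
                 water_levels = water_levels, n_solid = as.integer(n_solid),
                 grid_step = grid_step, total_area_range = total_area_range,
                 molar_mass_range = molar_mass_range,
                 sigma_noise = sigma_noise, overshoot_prob = overshoot_prob,
                 overshoot_range = overshoot_range, max_days = max_days),
            class = "synthetic_spec")
}

#' Generate a synthetic sigma-profile
#'
#' Sum-of-Gaussians histogram on a uniform grid spanning +/-0.025 e/A^2.
#' Hydrogen-bond acceptors carry most of their surface area at negative
#' sigma, donors at positive sigma, nonpolar molecules near zero, and water
#' is bimodal with mass in both signed tails. Peak centres are jittered per
#' seed; the total area is drawn from the spec's range.
#'
#' @param role `"HBA"`, `"HBD"`, `"water"` or `"nonpolar"`.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for this profile.
#' @param name Profile identifier.
#' @return A [sigma_profile()].
#' @export
synth_sigma_profile <- function(role = c("HBA", "HBD", "water", "nonpolar"),
                                spec = synthetic_spec(), seed = spec$seed,
                                name = paste0(role, "_", seed)) {
  role <- match.arg(role)
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed %% .Machine$integer.max)
  m <- round(0.025 / spec$grid_step)
  sigma <- (-m:m) * spec$grid_step
  peaks <- switch(role,
    HBA = list(mu = c(-0.014, -0.006, 0.003),
               sd = c(0.0030, 0.0025, 0.0020), w = c(0.55, 0.30, 0.15)),
    HBD = list(mu = c(0.014, 0.006, -0.003),
               sd = c(0.0030, 0.0025, 0.0020), w = c(0.55, 0.30, 0.15)),
    water = list(mu = c(-0.015, 0.015, 0),
                 sd = c(0.0025, 0.0025, 0.0020), w = c(0.44, 0.44, 0.12)),
    nonpolar = list(mu = 0, sd = 0.0040, w = 1))
  mu <- peaks$mu + stats::rnorm(length(peaks$mu), 0, 6e-4)
  dens <- rep(0, length(sigma))
  for (j in seq_along(mu))
    dens <- dens + peaks$w[j] * stats::dnorm(sigma, mu[j], peaks$sd[j])
  area <- stats::runif(1, spec$total_area_range[1L], spec$total_area_range[2L])
  p <- area * dens / sum(dens)
  sigma_profile(sigma, p, name = name)
}

#' Generate a synthetic DES screening library
#'
#' Builds `n_systems` DES systems (an HBA plus one or two HBDs, molar parts
#' 1-3, molar masses uniform in the spec's range), flags `n_solid` random
#' (system, water-level) cells as solid, enumerates the liquid
#' formulations, and computes every mixture descriptor through
#' [integrate_descriptors()], [mole_fractions_from_recipe()] and
#' [mix_descriptors()] -- the generator never duplicates that arithmetic.
#' The default spec mirrors the real screen's shape: 10 systems x 3 water
#' levels - 2 solids = 28 formulations.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `systems`, `recipes`, `constituents` (named list including
#'   `"water"`, each with profile and descriptors), `profiles` (named list
#'   of [sigma_profile()]s) and `table` (data frame label,
#'   water_wt_percent, S1..S10, truncated_mass).
#' @export
synth_library <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_sys <- spec$n_systems
  n_hbd <- sample(1:2, n_sys, replace = TRUE)
  s0 <- spec$seed %% 1000000L

  profiles <- list()
  constituents <- list()
  mk <- function(cname, role, seed) {
    prof <- synth_sigma_profile(role, spec, seed = seed, name = cname)
    profiles[[cname]] <<- prof
    set.seed(seed + 1L)
    mass <- if (role == "water") 18.015 else
      stats::runif(1, spec$molar_mass_range[1L], spec$molar_mass_range[2L])
    constituents[[cname]] <<- constituent(
      cname, role = if (role == "nonpolar") "HBD" else role,
      molar_mass = mass, descriptors = integrate_descriptors(prof))
    constituents[[cname]]
  }

  systems <- vector("list", n_sys)
  for (i in seq_len(n_sys)) {
    base <- (s0 * 131L + i * 17L) %% 1000000L
    hba <- mk(sprintf("HBA_%02d", i), "HBA", base + 1L)
    hbds <- lapply(seq_len(n_hbd[i]), function(j)
      mk(sprintf("HBD_%02d_%d", i, j), "HBD", base + 10L * j))
    set.seed(base + 97L)
    parts <- c(sample(1:2, 1L), sample(1:3, n_hbd[i], replace = TRUE))
    systems[[i]] <- des_system(i, c(list(hba), hbds), parts)
  }
  water <- mk("water", "water", (s0 * 131L) %% 1000000L + 7919L)

  if (spec$n_solid > 0L) {
    set.seed(spec$seed + 211L)
    cells <- expand.grid(sys = seq_len(n_sys),
                         lvl = seq_along(spec$water_levels))
    solid <- cells[sample.int(nrow(cells), spec$n_solid), ]
    for (r in seq_len(nrow(solid))) {
      i <- solid$sys[r]
      systems[[i]]$solid_at <- c(systems[[i]]$solid_at,
                                 spec$water_levels[solid$lvl[r]])
    }
  }

  recipes <- enumerate_library(systems, spec$water_levels)
  table <- mixture_descriptor_table(recipes, water)
  list(systems = systems, recipes = recipes, constituents = constituents,
       profiles = profiles, table = table)
}

#' Sampling times of a stability time course
#'
#' The screen's cadence: hourly points on the first day (0, 2, 4, 6, 8 h),
#' daily points through day 7, then weekly, truncated once the true decay
#' curve crosses 50% residual activity (the first sub-50% point is kept) or
#' at `max_days`. At least the first four time points are always retained
#' so a two-parameter fit stays identified.
#'
#' @param k_true True first-order rate constant (day^-1).
#' @param max_days Last sampling day.
#' @return Numeric vector of times in days.
#' @export
decay_sampling_times <- function(k_true, max_days = 28) {
  times <- c(0, c(2, 4, 6, 8) / 24, 1:7, seq(14, max_days, by = 7))
  true <- 100 * exp(-k_true * times)
  below <- which(true < 50)
  keep <- if (length(below)) max(min(below), 4L) else length(times)
  times[seq_len(min(keep, length(times)))]
}

#' Generate a synthetic residual-activity decay series
#'
#' Residuals follow `100 exp(-k_true t) (1 + eps)` with
#' `eps ~ N(0, sigma_noise)`; the time-zero point is exactly 100 by
#' definition. With probability `overshoot_prob` one to three points within
#' the first three days are inflated above 100% to mimic the
#' overstabilization artefact (and exercise censoring). Negative noisy
#' values are clamped at zero.
#'
#' @param k_true True rate constant (day^-1), >= 0.
#' @param spec A [synthetic_spec()] (noise and overshoot parameters).
#' @param seed Integer seed.
#' @param label Series identifier.
#' @return An [activity_series()]; the true rate is attached as attribute
#'   `k_true`.
#' @export
synth_decay_series <- function(k_true, spec = synthetic_spec(),
                               seed = spec$seed, label = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"), k_true >= 0)
  set.seed(seed %% .Machine$integer.max)
  times <- decay_sampling_times(k_true, spec$max_days)
  true <- 100 * exp(-k_true * times)
  eps <- stats::rnorm(length(times), 0, spec$sigma_noise)
  residual <- true * (1 + eps)
  residual[times == 0] <- 100
  if (spec$overshoot_prob > 0 && stats::runif(1) < spec$overshoot_prob) {
    early <- which(times > 0 & times <= 3)
    # leave at least 3 points to survive censoring so the series stays fittable
    max_over <- min(3L, length(early), length(times) - 3L)
    if (max_over >= 1L) {
      n_over <- sample.int(max_over, 1L)
      pick <- sample(early, n_over)
      residual[pick] <- 100 * stats::runif(n_over, spec$overshoot_range[1L],
                                           spec$overshoot_range[2L])
    }
  }
  # nudge any censorable leftovers if fewer than 3 sub-100 points remain
  over <- residual > 100 & times > 0
  if (sum(!over) - 1L < 2L) {
    fix <- which(over)[seq_len(3L - (sum(!over)))]
    residual[fix] <- 99.9
  }
  residual[residual < 0] <- 0
  out <- activity_series(times, residual, label = label)
  attr(out, "k_true") <- k_true
  out
}

#' Generate a standalone descriptor matrix with a correlated signal block
#'
#' Draws an n x 10 descriptor table in which the `planted` columns share a
#' common latent factor (pairwise correlation `r_within`) while the
#' remaining columns are independent. Real mixture-descriptor tables show
#' exactly this structure -- polarity regions that respond to composition
#' together -- and the within-block correlation is what makes every member
#' of an informative block individually detectable by rank correlation.
#'
#' @param n Number of rows.
#' @param planted Column indices forming the correlated block.
#' @param r_within Pairwise correlation inside the block, in \[0, 1).
#' @param seed Integer seed.
#' @param center,spread Location and scale of the descriptor values (A^2).
#' @return Matrix with columns S1..S10, attribute `planted`.
#' @export
synth_descriptor_matrix <- function(n = 84, planted = c(2, 5, 9),
                                    r_within = 0.5, seed = 1L,
                                    center = 60, spread = 12) {
  stopifnot(r_within >= 0, r_within < 1, all(planted %in% 1:10))
  set.seed(seed)
  z <- matrix(stats::rnorm(n * 10L), n, 10L)
  f <- stats::rnorm(n)
  z[, planted] <- sqrt(1 - r_within) * z[, planted] + sqrt(r_within) * f
  S <- center + spread * z
  S[S < 0] <- 0
  colnames(S) <- paste0("S", 1:10)
  attr(S, "planted") <- sort(planted)
  S
}

#' Plant a known descriptor -> rate-constant ground truth
#'
#' Builds a response `log10 k = g(descriptors) + noise` over the rows of a
#' descriptor table, with `g` either linear in a planted subset of
#' descriptors or a shallow tanh MLP over all of them (i.e. inside the
#' model search space). The raw `g` values are affinely mapped onto
#' `log10(k_range)` so generated rate constants stay in a realistic,
#' fittable range. The planted column indices and all parameters are
#' returned for recovery assertions.
#'
#' @param descriptor_table Data frame or matrix holding descriptor columns
#'   S1..S10 (extra columns are ignored).
#' @param family `"linear"` (planted subset) or `"mlp"` (shallow tanh net).
#' @param seed Integer seed.
#' @param n_signal Number of planted descriptors for the linear family.
#' @param planted Optional explicit planted column indices (linear family);
#'   overrides `n_signal`.
#' @param sigma_noise SD of Gaussian noise added to log10 k.
#' @param k_range Range of generated rate constants (unit of the caller's
#'   choosing; default suits per-day decay generation).
#' @return List: `dataset` (a [qspr_dataset()], transform log10), `k`,
#'   `planted` (column indices carrying signal), `params` (the coefficients
#'   or truth-network weights), `family`.
#' @export
synth_qspr_truth <- function(descriptor_table,
                             family = c("linear", "mlp"), seed = 1L,
                             n_signal = 3L, planted = NULL, sigma_noise = 0,
                             k_range = c(0.02, 4)) {
  family <- match.arg(family)
  tab <- as.data.frame(descriptor_table)
  scols <- paste0("S", 1:10)
  if (!all(scols %in% names(tab)))
    stop("descriptor_table must contain columns S1..S10")
  S <- as.matrix(tab[, scols])
  n <- nrow(S)
  set.seed(seed)
  z <- scale(S)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- matrix(as.numeric(z), n, 10L, dimnames = list(NULL, scols))

  if (family == "linear") {
    planted <- if (is.null(planted)) sort(sample.int(10L, n_signal))
               else sort(as.integer(planted))
    # equal-magnitude, block-coherent coefficients: every signal descriptor
    # is equally identifiable, and a correlated block responds as one
    beta <- rep(sample(c(-1, 1), 1L) * 0.6, length(planted))
    g <- as.numeric(z[, planted, drop = FALSE] %*% beta)
    params <- list(beta = beta)
  } else {
    h <- 4L
    W1 <- matrix(stats::runif(h * 10L, -0.7, 0.7), h, 10L)
    b1 <- stats::runif(h, -0.3, 0.3)
    w2 <- stats::runif(h, -1, 1)
    g <- as.numeric(tanh(z %*% t(W1) + matrix(b1, n, h, byrow = TRUE)) %*% w2)
    planted <- 1:10
    params <- list(W1 = W1, b1 = b1, w2 = w2)
  }

  lo <- log10(k_range[1L]); hi <- log10(k_range[2L])
  rg <- range(g)
  y <- if (diff(rg) > 0) lo + (g - rg[1L]) / diff(rg) * (hi - lo)
       else rep((lo + hi) / 2, n)
  y <- y + stats::rnorm(n, 0, sigma_noise)
  k <- 10^y
  list(dataset = qspr_dataset(S, k, enzyme = "synthetic", transform = "log10"),
       k = k, planted = planted, params = params, family = family)
}
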