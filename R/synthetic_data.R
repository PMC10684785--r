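# Synthetic study system: guild-structured gene repertoires and
# serial-dilution community dynamics in which competition strength between
# two MAGs is proportional to their gene-repertoire similarity (1 - D_ij).
# With the default configuration the high-overlap guilds undergo
# competitive exclusion once the community approaches carrying capacity,
# producing an abrupt collapse from a taxon-rich state to an oligopolistic
# state -- the phenomenon the niche-overlap indices are designed to flag.

#' Scenario configuration for the synthetic study system
#'
#' Defaults emulate the structure of a 110-day serial-dilution microcosm
#' sequenced at 13 time points: 32 MAGs in 4 functional guilds, gene
#' repertoires of roughly 1,100 genes built from a small shared housekeeping
#' core, large guild-specific cores (high within-guild, low between-guild
#' Jaccard similarity), and partly-shared accessory genes; daily 20% medium
#' replacement; and strong Lotka-Volterra competition scaling with
#' gene-repertoire similarity, which drives an abrupt competitive-exclusion
#' collapse of the functionally redundant guilds early in the series.
#'
#' @param n_guilds number of functional guilds.
#' @param mags_per_guild MAGs per guild.
#' @param n_housekeeping_genes genes shared by every MAG.
#' @param n_guild_core_genes genes shared by every member of a guild.
#' @param n_accessory_genes accessory gene draws per MAG.
#' @param accessory_share_within_guild probability an accessory draw comes
#'   from the guild's shared accessory pool rather than being private.
#' @param guild_accessory_pool_size size of each guild's accessory pool.
#' @param n_days length of the daily series.
#' @param burn_in_days days simulated and discarded before day 1, so the
#'   reported series starts from an equilibrated community instead of the
#'   growth ramp (default 0; the null scenario uses 30).
#' @param sampling_days sparse sampling grid (default: the 13-point grid
#'   day 1, 10, 20, 24, 30, 40, 50, 60, 70, 80, 90, 100, 110).
#' @param growth_rate_range per-day intrinsic growth rates are drawn
#'   uniformly from this range.
#' @param competition_strength scale \code{s} of interspecific competition:
#'   \code{alpha_ij = s * (1 - D_ij)} for \code{i != j} (and 1 on the
#'   diagonal). Values making \code{alpha_ij > 1} within guilds drive
#'   competitive exclusion of functionally redundant MAGs.
#' @param uniform_competition if TRUE, \code{alpha_ij = competition_strength}
#'   for all pairs, decoupling dynamics from gene content (null scenario).
#' @param dilution_fraction fraction of the culture replaced daily.
#' @param noise_sigma standard deviation of multiplicative lognormal
#'   process noise.
#' @param detection_threshold relative-abundance detection threshold.
#' @return a list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_guilds = 4L,
                            mags_per_guild = 8L,
                            n_housekeeping_genes = 200L,
                            n_guild_core_genes = 800L,
                            n_accessory_genes = 100L,
                            accessory_share_within_guild = 0.7,
                            guild_accessory_pool_size = 400L,
                            n_days = 110L,
                            burn_in_days = 0L,
                            sampling_days = c(1, 10, 20, 24, 30, 40, 50,
                                              60, 70, 80, 90, 100, 110),
                            growth_rate_range = c(2.5, 3.2),
                            competition_strength = 8,
                            uniform_competition = FALSE,
                            dilution_fraction = 0.2,
                            noise_sigma = 0.03,
                            detection_threshold = 0.001) {
  cfg <- list(n_guilds = as.integer(n_guilds),
              mags_per_guild = as.integer(mags_per_guild),
              n_housekeeping_genes = as.integer(n_housekeeping_genes),
              n_guild_core_genes = as.integer(n_guild_core_genes),
              n_accessory_genes = as.integer(n_accessory_genes),
              accessory_share_within_guild = accessory_share_within_guild,
              guild_accessory_pool_size = as.integer(guild_accessory_pool_size),
              n_days = as.integer(n_days),
              burn_in_days = as.integer(burn_in_days),
              sampling_days = as.numeric(sampling_days),
              growth_rate_range = as.numeric(growth_rate_range),
              competition_strength = competition_strength,
              uniform_competition = isTRUE(uniform_competition),
              dilution_fraction = dilution_fraction,
              noise_sigma = noise_sigma,
              detection_threshold = detection_threshold)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

#' Null scenario configuration
#'
#' One functional guild and abundance dynamics decoupled from gene content
#' (uniform sub-critical competition), so any apparent association between
#' niche overlap and subsequent community change is spurious. Used to check
#' that the pipeline does not manufacture the collapse signal.
#'
#' @param ... overrides passed to [scenario_config()].
#' @return a \code{scenario_config}.
#' @export
null_scenario_config <- function(...) {
  scenario_config(n_guilds = 1L, mags_per_guild = 32L,
                  uniform_competition = TRUE, competition_strength = 0.5,
                  burn_in_days = 30L, ...)
}

validate_scenario_config <- function(cfg) {
  counts <- c(cfg$n_guilds, cfg$mags_per_guild, cfg$n_days,
              cfg$guild_accessory_pool_size)
  if (any(counts < 1L)) stop("scenario counts must be positive", call. = FALSE)
  if (cfg$n_housekeeping_genes < 0L || cfg$n_guild_core_genes < 0L ||
      cfg$n_accessory_genes < 0L) {
    stop("gene counts must be nonnegative", call. = FALSE)
  }
  if (cfg$n_housekeeping_genes + cfg$n_guild_core_genes +
      cfg$n_accessory_genes < 1L) {
    stop("configuration implies empty gene repertoires", call. = FALSE)
  }
  p <- c(cfg$accessory_share_within_guild, cfg$dilution_fraction)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sigma < 0) stop("noise_sigma must be nonnegative", call. = FALSE)
  if (cfg$burn_in_days < 0L) stop("burn_in_days must be nonnegative", call. = FALSE)
  if (length(cfg$growth_rate_range) != 2L ||
      any(cfg$growth_rate_range <= 0) || diff(cfg$growth_rate_range) < 0) {
    stop("growth_rate_range must be two positive increasing values", call. = FALSE)
  }
  if (any(cfg$sampling_days < 1) || any(cfg$sampling_days > cfg$n_days)) {
    stop("sampling_days must lie within 1..n_days", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a guild-structured gene-repertoire matrix
#'
#' Each MAG's repertoire is the union of the housekeeping core (shared by
#' all MAGs), its guild's core genes, and an accessory draw in which each
#' gene comes from the guild's shared accessory pool with probability
#' \code{accessory_share_within_guild} and is otherwise private to the MAG.
#' By construction expected within-guild Jaccard similarity exceeds
#' between-guild similarity.
#'
#' @param cfg a \code{scenario_config}.
#' @param seed integer seed; all randomness flows through it.
#' @return binary gene matrix with MAG rownames \code{M01, M02, ...} and a
#'   \code{"guild"} attribute giving each MAG's guild assignment.
#' @export
generate_guild_genomes <- function(cfg = scenario_config(), seed = 1L) {
  validate_scenario_config(cfg)
  set.seed(as.integer(seed))
  n_mags <- cfg$n_guilds * cfg$mags_per_guild
  mag_ids <- sprintf("M%02d", seq_len(n_mags))
  guild <- rep(seq_len(cfg$n_guilds), each = cfg$mags_per_guild)

  hk <- if (cfg$n_housekeeping_genes > 0L) {
    sprintf("hk_%04d", seq_len(cfg$n_housekeeping_genes))
  } else character(0L)
  core <- lapply(seq_len(cfg$n_guilds), function(g) {
    if (cfg$n_guild_core_genes > 0L) {
      sprintf("g%d_core_%04d", g, seq_len(cfg$n_guild_core_genes))
    } else character(0L)
  })
  pool <- lapply(seq_len(cfg$n_guilds), function(g) {
    sprintf("g%d_acc_%04d", g, seq_len(cfg$guild_accessory_pool_size))
  })

  repertoires <- vector("list", n_mags)
  for (i in seq_len(n_mags)) {
    g <- guild[i]
    acc <- character(0L)
    if (cfg$n_accessory_genes > 0L) {
      from_pool <- stats::runif(cfg$n_accessory_genes) <
        cfg$accessory_share_within_guild
      n_pool <- sum(from_pool)
      n_priv <- cfg$n_accessory_genes - n_pool
      pool_genes <- if (n_pool > 0L) {
        unique(sample(pool[[g]], n_pool, replace = TRUE))
      } else character(0L)
      priv_genes <- if (n_priv > 0L) {
        sprintf("%s_priv_%04d", mag_ids[i], seq_len(n_priv))
      } else character(0L)
      acc <- c(pool_genes, priv_genes)
    }
    repertoires[[i]] <- c(hk, core[[g]], acc)
  }
  all_genes <- unique(unlist(repertoires))
  if (length(all_genes) == 0L) stop("configuration implies empty gene repertoires", call. = FALSE)
  m <- matrix(0L, n_mags, length(all_genes), dimnames = list(mag_ids, all_genes))
  for (i in seq_len(n_mags)) m[i, repertoires[[i]]] <- 1L
  m <- validate_gene_matrix(m)
  attr(m, "guild") <- stats::setNames(guild, mag_ids)
  m
}

#' Simulate serial-dilution community dynamics
#'
#' Discrete-time Lotka-Volterra growth with daily serial dilution:
#' \deqn{n_i(t+1) = (1 - f) \, n_i(t) \exp\{r_i (1 - \sum_j \alpha_{ij} n_j / K)\} \, \epsilon_i(t)}
#' where \code{f} is the dilution fraction, \code{K = 1} the shared carrying
#' capacity, \code{alpha_ii = 1}, \code{alpha_ij = s (1 - D_ij)} for
#' \code{i != j} (gene-repertoire similarity drives competition; or a
#' uniform constant under \code{uniform_competition}), and
#' \code{epsilon} is multiplicative lognormal noise with log-sd
#' \code{noise_sigma}. Output rows are closed to relative abundance.
#'
#' @param genomes gene matrix from [generate_guild_genomes()] (used for
#'   \code{D_ij}); its rownames define the community.
#' @param cfg a \code{scenario_config}.
#' @param seed integer seed.
#' @return daily abundance matrix (days \code{1..n_days} as rows).
#' @export
simulate_dynamics <- function(genomes, cfg = scenario_config(), seed = 1L) {
  validate_scenario_config(cfg)
  genomes <- validate_gene_matrix(genomes)
  set.seed(as.integer(seed))
  n <- nrow(genomes)
  if (n < 2L) stop("need at least 2 MAGs", call. = FALSE)

  if (cfg$uniform_competition) {
    A <- matrix(cfg$competition_strength, n, n)
  } else {
    D <- pairwise_jaccard(genomes)
    A <- cfg$competition_strength * (1 - D)
  }
  diag(A) <- 1

  r <- stats::runif(n, cfg$growth_rate_range[1L], cfg$growth_rate_range[2L])
  K <- 1
  # start rare and even: the community grows toward capacity before
  # competitive sorting begins
  x <- rep(0.02 / n, n) * exp(stats::rnorm(n, 0, 0.1))

  total_days <- cfg$burn_in_days + cfg$n_days
  out <- matrix(NA_real_, total_days, n,
                dimnames = list(seq_len(total_days), rownames(genomes)))
  for (t in seq_len(total_days)) {
    growth <- exp(r * (1 - as.vector(A %*% x) / K))
    if (any(!is.finite(growth))) {
      stop("divergent dynamics (overflow); reduce growth rates or competition_strength",
           call. = FALSE)
    }
    eps <- if (cfg$noise_sigma > 0) {
      exp(stats::rnorm(n, -cfg$noise_sigma^2 / 2, cfg$noise_sigma))
    } else rep(1, n)
    x <- (1 - cfg$dilution_fraction) * x * growth * eps
    x <- pmax(x, 1e-12)
    out[t, ] <- x / sum(x)
  }
  if (cfg$burn_in_days > 0L) {
    out <- out[-seq_len(cfg$burn_in_days), , drop = FALSE]
    rownames(out) <- seq_len(cfg$n_days)
  }
  validate_abundance_table(out)
}

#' Subset an abundance table to a sparse sampling grid
#'
#' @param a daily abundance table.
#' @param days days to keep, in order (must all be present).
#' @return the row subset, still a validated abundance table.
#' @export
sample_timepoints <- function(a, days) {
  a <- validate_abundance_table(a)
  if (length(days) == 0L) stop("days must be nonempty", call. = FALSE)
  have <- as.numeric(rownames(a))
  missing <- setdiff(days, have)
  if (length(missing)) {
    stop("day(s) not in table: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_abundance_table(a[match(days, have), , drop = FALSE])
}

#' Generate a complete synthetic collapse scenario
#'
#' Convenience wrapper: genomes, daily dynamics, the sparse sampled table,
#' and truth metadata (guild assignments and the measured collapse day, the
#' day of maximum abruptness of the daily series).
#'
#' @param cfg a \code{scenario_config}.
#' @param seed integer seed.
#' @param window abruptness window used to locate the collapse day.
#' @return list with \code{genomes}, \code{daily}, \code{sampled},
#'   \code{guild}, \code{collapse_day}, \code{max_abruptness}, \code{config}.
#' @export
generate_scenario <- function(cfg = scenario_config(), seed = 1L, window = 5L) {
  genomes <- generate_guild_genomes(cfg, seed)
  daily <- simulate_dynamics(genomes, cfg, seed = as.integer(seed) + 1L)
  sampled <- sample_timepoints(daily, cfg$sampling_days)
  ab <- abruptness_series(daily, w = window)
  peak <- which.max(ab)
  list(genomes = genomes,
       daily = daily,
       sampled = sampled,
       guild = attr(genomes, "guild"),
       collapse_day = as.numeric(rownames(daily))[peak],
       max_abruptness = ab[peak],
       config = cfg)
}
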