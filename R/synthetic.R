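# Seeded generator for complete multi-tree, multi-station dendroband
# datasets with known ground truth.  The generator emulates the everwet
# study conditions: rainfall with embedded multi-week dry spells, a soil
# moisture bucket responding to rain input and evapotranspiration, sensors
# with positive bias / noise / rare extreme spikes, and trees whose daily
# increments respond to lagged SMP and same-day temperature with ARMA(2,2)
# noise, plus diurnal swelling-shrinkage and dry-period shower (bark
# swelling) artefacts.  Truth is emitted separately and never consumed by
# the analysis pipeline.

#' Default tree table for the synthetic stand
#'
#' Eighteen banded trees across four stations (two lower-slope, two
#' ridge), six species, with the stand's girth structure, plus the
#' generator's per-tree true response parameters: size-standardized SMP
#' and TEMP response coefficients (`beta_s_scaled`, `beta_t_scaled`; the
#' working coefficients are back-scaled by `gbh / 50`), diurnal amplitude
#' (x 1e4), bark-swelling quadratic coefficients on `ln(rain)` and which
#' day's rain drives them, and absolute growth rate in mm/yr.  Understorey
#' trees carry larger diurnal amplitudes and mostly positive SMP
#' responses; overstorey trees the reverse, with a few deliberate
#' exceptions so both signs occur within guilds.
#'
#' @return Data frame, one row per band.
#' @export
default_tree_table <- function() {
  t2 <- data.frame(
    band_id = c("g11", "g12", "g14", "g15", "g22", "g23", "g24", "g25",
                "g31", "g32", "g33", "g34", "g35", "g41", "g42", "g43",
                "g44", "g45"),
    station = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L,
                4L, 4L, 4L, 4L, 4L),
    species_code = c("Mw", "Sf", "Lb", "Sf", "Pm", "Dm", "Mw", "Sf",
                     "Mw", "Sp", "Lb", "Dm", "Dm", "Sf", "Dm", "Pm",
                     "Sp", "Pm"),
    gbh = c(31, 97, 31, 27, 74, 30, 34, 33, 34, 78, 39, 39, 48,
            31, 33, 117, 97, 69))
  t2$scl <- ifelse(t2$gbh > 60, 2L, 1L)
  st_xy <- cbind(x = c(25, 75, 25, 75), y = c(25, 25, 75, 75))
  within_station <- seq_len(nrow(t2)) %% 5L
  t2$x <- st_xy[t2$station, "x"] + c(-6, -2, 2, 6, 0)[within_station + 1L]
  t2$y <- st_xy[t2$station, "y"] + c(3, -5, 5, -3, 7)[within_station + 1L]
  t2$CanStat <- pmin(5, pmax(1, round(1.426 + 0.02761 * t2$gbh, 2)))
  t2$beta_s_scaled <- c(0.9, -1.6, -0.8, 1.9, -1.3, 0.7, 1.1, 2.3,
                        0.8, -2.1, -0.7, 0.9, -1.0, 2.5, 0.6, -2.4,
                        -1.8, -1.2)
  t2$beta_t_scaled <- c(1.1, 2.2, 0.8, 2.7, 1.5, 1.8, 1.0, 2.4,
                        1.2, 1.9, -0.6, 1.6, 0.9, 2.5, 1.3, 1.7,
                        2.0, 1.4)
  t2$beta_s <- backscale_coefficient(t2$beta_s_scaled, t2$gbh)
  t2$beta_t <- backscale_coefficient(t2$beta_t_scaled, t2$gbh)
  t2$amplitude <- c(10, 2.5, 9, 14, 3, 8, 11, 13, 9, 2, 8, 7, 6,
                    12, 7, 1.5, 2.2, 2.8)
  t2$bark_b1 <- c(2.4, 1.8, 1.6, -2.0, 2.2, 1.4, 2.8, 2.0, 1.8, 2.6,
                  1.6, 1.2, -1.6, 3.0, 2.0, 1.4, 2.4, 1.8)
  t2$bark_b2 <- c(0.9, 0.6, 0.75, 0.45, 1.05, 0.6, 1.2, 0.75, 0.6, 1.35,
                  0.45, 0.6, 0.45, 1.35, 0.75, 0.45, 0.9, 0.6)
  t2$bark_day <- ifelse(t2$band_id %in% c("g12", "g33"), "previous", "current")
  t2$agr <- c(1.2, 4.5, 0.8, 1.5, 3.5, 0.9, 1.4, 1.8, 1.1, 4.0, 1.0,
              1.3, 1.6, 2.0, 0.9, 5.0, 4.2, 3.0)
  t2
}

#' Synthetic study configuration
#'
#' Bundles the generator's conditions: the calendar (a frame containing an
#' 18-month wet window and a 98-day dry window with three embedded dry
#' spells), the rainfall regimes, the soil-moisture bucket, sensor error
#' structure, the trees, the ARMA(2,2) increment noise and missingness
#' rates.  Defaults reproduce the study dimensions: 18 bands over 4
#' stations with 3-4 sensors each, a 550-day wet period, a 98-day dry
#' period, everwet rainfall around 8.1 mm/day.
#'
#' @param start,end frame endpoints (dates).
#' @param trees tree table, see [default_tree_table()].
#' @param wet_window,dry_window analysis windows.
#' @param dry_spells list of `c(start, end)` date pairs forced dry.
#' @param rain_wet_prob,rain_wet_shape,rain_wet_mean zero-inflated gamma
#'   rainfall in the wet regime (probability of a rain day, gamma shape,
#'   overall mean mm/day).
#' @param rain_dry_prob,rain_dry_shape,rain_dry_mean same for non-spell
#'   dry-period days.
#' @param spell_rain_light_prob,spell_rain_heavy_prob within spells:
#'   probabilities of a light (0.2-7 mm) and a heavy (12-45 mm) shower
#'   (light drizzle stays frequent through the dry period; short showers
#'   do not recharge the dry topsoil).
#' @param bark_decay day-to-day retention of the bark swelling state: a
#'   shower's swelling decays as `bark_decay^days` while the bark re-dries.
#' @param temp_mean,temp_dry_shift,temp_ar,temp_sd 14:00 logger
#'   temperature AR(1) (degrees C).
#' @param smp_input_gain kPa recharge per mm rain; `smp_et0` kPa/day
#'   evapotranspiration drawdown at `temp_mean`; `smp_et_slope` relative
#'   drawdown increase per degree; `smp_drain0`, `smp_drain_scale`
#'   drainage `drain0 * exp(smp / scale)` kPa/day (fast near saturation,
#'   negligible when dry), which sets the everwet equilibrium near
#'   -35 kPa; `smp_nonspell_floor` clamp for non-spell days, kPa
#'   (between-spell rains and subsoil recharge keep measured topsoil
#'   tension above it).
#' @param spell_level,spell_sd,spell_cap forced latent SMP during spells
#'   (mean, SD, upper cap kPa).
#' @param post_spell_level latent SMP resumed the day after a spell ends
#'   (rapid rewetting).
#' @param n_sensors sensors per station; `sensor_bias_range` uniform
#'   positive bias, kPa; `sensor_noise_sd` kPa; `sensor_spike_prob` daily
#'   probability of an unrealistic extreme-low spike on each station's
#'   last sensor (restricted to very dry days, when poor soil contact
#'   makes such readings plausible).
#' @param arma_ar,arma_ma,innov_sd ARMA(2,2) daily increment noise
#'   (cm/1000).
#' @param miss_single_rate,miss_pair_rate half-hourly missingness rates;
#'   `long_gap_start`, `long_gap_days` one multi-day outage per band.
#' @param station4_dry_failure drop station-4 sensors from 2010-01-01
#'   (the station without usable dry-period records).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(start = as.Date("2007-03-01"),
                       end = as.Date("2010-06-30"),
                       trees = default_tree_table(),
                       wet_window = period_window("2007-03-17", "2008-09-16", "wet"),
                       dry_window = period_window("2010-03-18", "2010-06-23", "dry"),
                       dry_spells = list(c("2010-02-18", "2010-03-07"),
                                         c("2010-03-12", "2010-03-28"),
                                         c("2010-04-11", "2010-04-28")),
                       rain_wet_prob = 0.65, rain_wet_shape = 0.9,
                       rain_wet_mean = 8.1,
                       rain_dry_prob = 0.65, rain_dry_shape = 0.8,
                       rain_dry_mean = 2.5,
                       spell_rain_light_prob = 0.45,
                       spell_rain_heavy_prob = 0.07,
                       bark_decay = 0.95,
                       temp_mean = 26.9, temp_dry_shift = 0.9,
                       temp_ar = 0.6, temp_sd = 0.7,
                       smp_input_gain = 0.45, smp_et0 = 1.2,
                       smp_et_slope = 0.15,
                       smp_drain0 = 9, smp_drain_scale = 25,
                       smp_nonspell_floor = -120,
                       spell_level = -300, spell_sd = 15, spell_cap = -180,
                       post_spell_level = -60,
                       n_sensors = c(3L, 4L, 3L, 4L),
                       sensor_bias_range = c(0.5, 6),
                       sensor_noise_sd = 1.5,
                       sensor_spike_prob = 0.01,
                       arma_ar = c(1.2, -0.5), arma_ma = c(-0.6, 0.3),
                       innov_sd = 1.5,
                       miss_single_rate = 0.003, miss_pair_rate = 0.001,
                       long_gap_start = as.Date("2008-12-01"),
                       long_gap_days = 5L,
                       station4_dry_failure = TRUE) {
  cfg <- as.list(environment())
  cfg$start <- as.Date(start); cfg$end <- as.Date(end)
  stopifnot(cfg$end > cfg$start, all(abs(c(arma_ar, arma_ma)) < 2),
            innov_sd >= 0, sensor_noise_sd >= 0, temp_sd >= 0)
  if (any(Mod(polyroot(c(1, -arma_ar))) <= 1) ||
      any(Mod(polyroot(c(1, arma_ma))) <= 1))
    stop("ARMA noise parameters must be stationary and invertible")
  cfg$dry_spells <- lapply(dry_spells, as.Date)
  structure(cfg, class = "sim_config")
}

in_any_spell <- function(dates, spells) {
  out <- rep(FALSE, length(dates))
  for (s in spells) out <- out | (dates >= s[1L] & dates <= s[2L])
  out
}

#' Simulate the climate and soil-moisture environment
#'
#' Daily rainfall (zero-inflated gamma, with spells forced near-dry),
#' 14:00 logger temperature (AR(1)), a latent station-level soil moisture
#' potential following a bucket model
#' `smp[t] = clamp(smp[t-1] + gain * rain[t] - et(temp[t]), floor, 0)`
#' outside spells and a forced low level within them (short showers do not
#' penetrate dry topsoil), and per-sensor readings = latent + positive
#' bias + noise, with rare extreme-low spikes on each station's last
#' sensor.  All randomness flows from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return List: `dates`, `rain`, `temp`, `smp_latent` (the bucket state),
#'   `smp_drive` (the cleaned across-station daily mean the trees respond
#'   to), `sensors` (long data frame `sensor_id`, `station`, `date`,
#'   `smp`), `spells` (the configured truth windows).
#' @export
simulate_climate <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  dates <- seq(config$start, config$end, by = 1)
  n <- length(dates)
  spell <- in_any_spell(dates, config$dry_spells)
  dryish <- spell | (dates >= config$dry_window$start &
                     dates <= config$dry_window$end)

  rain <- numeric(n)
  wet_scale <- config$rain_wet_mean / (config$rain_wet_prob * config$rain_wet_shape)
  dry_scale <- config$rain_dry_mean / (config$rain_dry_prob * config$rain_dry_shape)
  u <- runif(n)
  wet_idx <- !dryish & u < config$rain_wet_prob
  rain[wet_idx] <- rgamma(sum(wet_idx), config$rain_wet_shape, scale = wet_scale)
  ndry_idx <- dryish & !spell & u < config$rain_dry_prob
  rain[ndry_idx] <- rgamma(sum(ndry_idx), config$rain_dry_shape, scale = dry_scale)
  us <- runif(n)
  light <- spell & us < config$spell_rain_light_prob
  heavy <- spell & us >= config$spell_rain_light_prob &
    us < config$spell_rain_light_prob + config$spell_rain_heavy_prob
  rain[light] <- runif(sum(light), 0.2, 7)
  rain[heavy] <- runif(sum(heavy), 12, 45)

  temp_dev <- as.numeric(arima.sim(list(ar = config$temp_ar), n,
                                   sd = config$temp_sd))
  temp <- config$temp_mean + config$temp_dry_shift * dryish + temp_dev

  smp <- numeric(n)
  prev <- 0
  spell_noise <- rnorm(n, 0, config$spell_sd)
  for (i in seq_len(n)) {
    if (spell[i]) {
      smp[i] <- min(config$spell_cap, config$spell_level + spell_noise[i])
      prev <- config$post_spell_level
    } else {
      et <- config$smp_et0 *
        (1 + config$smp_et_slope * (temp[i] - config$temp_mean))
      drain <- config$smp_drain0 * exp(prev / config$smp_drain_scale)
      smp[i] <- min(0, max(config$smp_nonspell_floor,
                           prev + config$smp_input_gain * rain[i] - et - drain))
      prev <- smp[i]
    }
  }

  sensors <- do.call(rbind, lapply(seq_along(config$n_sensors), function(st) {
    do.call(rbind, lapply(seq_len(config$n_sensors[st]), function(j) {
      bias <- runif(1, config$sensor_bias_range[1L], config$sensor_bias_range[2L])
      val <- smp + bias + rnorm(n, 0, config$sensor_noise_sd)
      if (j == config$n_sensors[st]) {
        # very dry soil makes the contact poor: unrealistic extreme lows
        spike <- runif(n) < config$sensor_spike_prob & smp <= -150
        val[spike] <- runif(sum(spike), -2000, -1200)
      }
      if (config$station4_dry_failure && st == 4L)
        val[dates >= as.Date("2010-01-01")] <- NA_real_
      data.frame(sensor_id = sprintf("s%d%d", st, j), station = st,
                 date = dates, smp = val)
    }))
  }))
  # The driving covariate the trees respond to: the soil-water state as
  # characterized at the stations (per-sensor offset cleaning, station
  # averaging, across-station mean).  Using the cleaned series rather
  # than the latent bucket state as the response driver keeps estimator
  # validation free of covariate-measurement mismatch.
  drive <- smp_station_drive(sensors)
  smp_drive <- drive$smp[match(dates, drive$date)]

  list(dates = dates, rain = rain, temp = temp, smp_latent = smp,
       smp_drive = smp_drive, sensors = sensors,
       spells = data.frame(
         start = as.Date(vapply(config$dry_spells, function(s)
           format(s[1L]), character(1))),
         end = as.Date(vapply(config$dry_spells, function(s)
           format(s[2L]), character(1)))))
}

diurnal_shape <- function() {
  h <- (0:(SLOTS_PER_DAY - 1L)) / 2
  s <- exp(-((h - 10) / 2.5)^2) - 0.9 * exp(-((h - 15.5) / 2.8)^2)
  s <- s - s[1L]
  s / max(abs(s))
}

#' Simulate one band's half-hourly girth series
#'
#' Daily mean girth follows a cumulative path
#' `gthm[i+1] = gthm[i] + 1e-3 * gthi[i]` with
#' `gthi[i] = g0 + beta_s * (-sqrt(|SMP[i-1]|) - mean) + beta_t *
#' (TEMP[i] - mean) + e[i]`, `e ~ ARMA(2,2)`; `g0` converts the tree's
#' growth rate (mm/yr) to a mean daily increment.  `SMP` here is the
#' cleaned across-station series (`smp_drive`), the soil-water state the
#' stations characterize.  Half-hourly values add
#' a fixed within-day swelling-shrinkage shape (mid-morning peak,
#' mid-afternoon trough, zero at midnight) scaled by the tree's amplitude,
#' and, on the day after a qualifying dry-period shower, a transient
#' bark-swelling bump `b1 * ln(rain) + b2 * ln(rain)^2` (cm/1000).
#' Missing values are injected as singles, pairs and one long outage.
#'
#' @param climate result of [simulate_climate()].
#' @param tree one row of the tree table (with truth columns).
#' @param config the [sim_config()].
#' @param seed integer RNG seed for this band.
#' @return An [hh_series()] spanning the configured frame.
#' @export
simulate_tree <- function(climate, tree, config, seed) {
  set.seed(seed)
  dates <- climate$dates
  n <- length(dates)
  smp_tr <- smp_regression_transform(climate$smp_drive)
  smp_lag <- c(smp_tr[1L], smp_tr[seq_len(n - 2L)])   # lag 1 for day i -> i+1
  temp0 <- climate$temp[seq_len(n - 1L)]
  eps <- as.numeric(arima.sim(list(ar = config$arma_ar, ma = config$arma_ma),
                              n - 1L, sd = config$innov_sd))
  g0 <- tree$agr * 100 / 365.25
  gthi <- g0 + tree$beta_s * (smp_lag - mean(smp_lag)) +
    tree$beta_t * (temp0 - mean(temp0)) + eps
  gthm <- tree$gbh + cumsum(c(0, gthi)) * 1e-3

  # Bark swelling: a shower on dry-period bark swells it in proportion to
  # how dry the bark is (spells: fully dry), and the swelling then decays
  # slowly as the bark re-dries.  Wet-period bark stays wet: no artefact.
  dryish <- in_any_spell(dates, config$dry_spells) |
    (dates >= config$dry_window$start & dates <= config$dry_window$end)
  dryness <- pmin(1, abs(climate$smp_latent) / abs(config$spell_level))
  arrival <- ifelse(dryish & climate$rain >= 1,
                    (tree$bark_b1 * log(climate$rain) +
                       tree$bark_b2 * log(climate$rain)^2) * dryness, 0)
  shift <- if (tree$bark_day == "previous") 2L else 1L
  bump <- as.numeric(stats::filter(
    c(rep(0, shift), arrival[seq_len(n - shift)]),
    config$bark_decay, method = "recursive"))           # cm/1000, per day

  shape <- diurnal_shape()
  girth <- rep(gthm + bump * 1e-3, each = SLOTS_PER_DAY) +
    tree$gbh * (tree$amplitude / 1e4) * rep(shape, n)

  nslot <- n * SLOTS_PER_DAY
  miss <- runif(nslot) < config$miss_single_rate
  pair_at <- which(runif(nslot - 1L) < config$miss_pair_rate)
  miss[pair_at] <- TRUE; miss[pair_at + 1L] <- TRUE
  if (!is.na(config$long_gap_start) &&
      config$long_gap_start >= config$start &&
      config$long_gap_start + config$long_gap_days - 1L <= config$end) {
    d0 <- as.integer(config$long_gap_start - config$start)
    miss[(d0 * SLOTS_PER_DAY + 1L):((d0 + config$long_gap_days) * SLOTS_PER_DAY)] <- TRUE
  }
  girth[miss] <- NA_real_
  hh_series(tree$band_id,
            window_grid(period_window(config$start, config$end)),
            girth)
}

#' Simulate a complete dataset with ground truth
#'
#' @param config a [sim_config()].
#' @param seed master seed; the climate uses `seed` and band `i` uses
#'   `seed + 1000 + i`, so per-band series are reproducible individually.
#' @return List: `climate`, `bands` (named list of [hh_series()]),
#'   `trees` (analysis-facing metadata only), `truth` (the per-tree true
#'   parameters and spell windows; never consumed by the pipeline).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  climate <- simulate_climate(config, seed)
  bands <- lapply(seq_len(nrow(config$trees)), function(i)
    simulate_tree(climate, config$trees[i, ], config, seed + 1000L + i))
  names(bands) <- config$trees$band_id
  meta_cols <- c("band_id", "station", "species_code", "gbh", "scl",
                 "x", "y", "CanStat")
  truth_cols <- c("band_id", "station", "gbh", "beta_s", "beta_t",
                  "beta_s_scaled", "beta_t_scaled", "amplitude",
                  "bark_b1", "bark_b2", "bark_day", "agr")
  list(climate = climate,
       bands = bands,
       trees = config$trees[, meta_cols],
       truth = list(trees = config$trees[, truth_cols],
                    spells = climate$spells))
}

#' Write a simulated dataset as delimited text tables
#'
#' Emits the analysis-facing tables in the pipeline's input dialects —
#' `bands.tsv` (band_id, timestamp, girth_cm), `sensors.tsv` (sensor_id,
#' station, date, smp_kPa), `climate.tsv` (date, rain_mm, temp14_C),
#' `trees.tsv` (metadata only) — plus the ground truth separately in
#' `truth_trees.tsv` and `truth_spells.tsv`.  Truth never appears in the
#' analysis-facing tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param seed master seed, as in [simulate_dataset()].
#' @return Invisibly, the list of file paths written.
#' @export
emit_dataset <- function(config = sim_config(), dir, seed = 1L) {
  sim <- simulate_dataset(config, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("bands.tsv", "sensors.tsv", "climate.tsv",
                            "trees.tsv", "truth_trees.tsv",
                            "truth_spells.tsv"))
  bands_long <- do.call(rbind, lapply(sim$bands, function(b) {
    keep <- !is.na(b$girth)
    data.frame(band_id = b$band_id,
               timestamp = format(b$time[keep], "%Y-%m-%dT%H:%M:%S"),
               girth_cm = b$girth[keep])
  }))
  wt <- function(d, p) write.table(d, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(bands_long, paths[1L])
  sens <- sim$climate$sensors
  names(sens)[names(sens) == "smp"] <- "smp_kPa"
  wt(sens[!is.na(sens$smp_kPa), ], paths[2L])
  wt(data.frame(date = format(sim$climate$dates), rain_mm = sim$climate$rain,
                temp14_C = sim$climate$temp), paths[3L])
  wt(sim$trees, paths[4L])
  wt(sim$truth$trees, paths[5L])
  wt(sim$truth$spells, paths[6L])
  invisible(setNames(as.list(paths),
                     c("bands", "sensors", "climate", "trees",
                       "truth_trees", "truth_spells")))
}

#' Read the delimited input tables
#'
#' Readers for the pipeline's text dialects (tab- or comma-separated,
#' tolerant of CR/LF line endings and quoted fields).
#' `read_band_series()` returns a named list of [hh_series()];
#' the others return validated data frames.
#'
#' @param path file path.
#' @return See description.
#' @export
read_band_series <- function(path) {
  d <- read.delim(path, sep = "", stringsAsFactors = FALSE)
  stopifnot(all(c("band_id", "timestamp", "girth_cm") %in% names(d)))
  lapply(split(d, d$band_id), function(b)
    hh_series(b$band_id[1L],
              as.POSIXct(b$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
              b$girth_cm))
}

#' @rdname read_band_series
#' @export
read_sensor_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sensor_id", "station", "date", "smp_kPa") %in% names(d)))
  d$date <- as.Date(d$date)
  names(d)[names(d) == "smp_kPa"] <- "smp"
  d
}

#' @rdname read_band_series
#' @export
read_climate_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "rain_mm") %in% names(d)))
  d$date <- as.Date(d$date)
  if (any(d$rain_mm < 0, na.rm = TRUE)) stop("negative rainfall")
  d
}

#' @rdname read_band_series
#' @export
read_tree_table <- function(path) {
  tree_table(read.delim(path, stringsAsFactors = FALSE))
}
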