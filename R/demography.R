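# Inter-generational growth rates (IGR) and Mesoamerican period mapping.
#
# The IGR between consecutive 25-year generations is
#   IGR = 100 * (Nef_n - Nef_{n-1}) / Nef_{n-1},
# with n-1 the OLDER generation, so positive values mean growth toward the
# present.  Extrema and trend inversions of the IGR series are mapped onto
# the Mesoamerican chronological periods.

#' Mesoamerican chronological period table
#'
#' Default boundaries in years before present (ybp, anchor 1950 CE):
#' Lithic 15000-2500, Preclassic 2500-1750, Classic 1750-1050, Postclassic
#' 1050-429, Colonial 429-0.  The Preclassic/Classic boundary of 150-200 CE
#' is taken at its midpoint (~1750 ybp) and the Colonial onset at 1521 CE
#' (429 ybp).  A time `t` belongs to the period with `start_ybp >= t >
#' end_ybp` (half-open on the recent side); `t = 0` maps to the most recent
#' period and times older than the oldest boundary to `"pre-chronology"`.
#'
#' @param periods optional data frame with `name`, `start_ybp`, `end_ybp`
#'   (contiguous, strictly decreasing, ending at 0) to override the default.
#' @return data frame of class `"period_table"`.
#' @export
period_table <- function(periods = NULL) {
  if (is.null(periods)) {
    periods <- data.frame(
      name = c("Lithic", "Preclassic", "Classic", "Postclassic", "Colonial"),
      start_ybp = c(15000, 2500, 1750, 1050, 429),
      end_ybp = c(2500, 1750, 1050, 429, 0))
  }
  stopifnot(all(c("name", "start_ybp", "end_ybp") %in% names(periods)))
  if (any(periods$start_ybp <= periods$end_ybp) ||
      any(periods$end_ybp[-nrow(periods)] != periods$start_ybp[-1]) ||
      utils::tail(periods$end_ybp, 1) != 0) {
    stop("periods must be contiguous, strictly decreasing in ybp and end at 0",
         call. = FALSE)
  }
  structure(periods, class = c("period_table", "data.frame"))
}

#' Read a period table from YAML
#'
#' Expects a sequence of maps with `name`, `start_ybp`, `end_ybp`.
#'
#' @param path YAML file.
#' @return a [period_table()].
#' @export
read_period_table <- function(path) {
  raw <- yaml::read_yaml(path)
  period_table(do.call(rbind, lapply(raw, function(p)
    data.frame(name = p$name, start_ybp = p$start_ybp, end_ybp = p$end_ybp))))
}

#' Map times to chronological periods
#'
#' @param t times in ybp.
#' @param periods a [period_table()].
#' @return character vector of period names (`"pre-chronology"` for times
#'   older than the table's oldest boundary).
#' @export
period_of <- function(t, periods = period_table()) {
  vapply(t, function(tt) {
    if (tt > periods$start_ybp[1]) return("pre-chronology")
    hit <- which(periods$start_ybp >= tt & tt > periods$end_ybp)
    if (!length(hit)) return(periods$name[nrow(periods)])  # t == 0
    periods$name[hit[1]]
  }, "")
}

#' Resample a skyline trajectory onto the generation grid
#'
#' Produces Nef at 25-year steps (or `generation_years` steps) from the
#' oldest covered generation down to the present, by step-function evaluation
#' of the trajectory's posterior median (no interpolation across group
#' boundaries: each gridpoint takes the value of the trajectory point at or
#' immediately below it in ybp).
#'
#' @param traj a `"skyline_trajectory"`, or any data frame with `time_ybp`
#'   and `median` columns.
#' @param generation_years step size in years (default 25).
#' @param window optional maximum age in ybp (defaults to the trajectory's
#'   span).
#' @return data frame with `time_ybp` (oldest first) and `nef`.
#' @export
resample_to_generations <- function(traj, generation_years = 25,
                                    window = NULL) {
  if (!nrow(traj)) stop("empty trajectory", call. = FALSE)
  top <- window %||% max(traj$time_ybp)
  grid <- seq(floor(top / generation_years) * generation_years, 0,
              by = -generation_years)
  nef <- stats::approx(traj$time_ybp, traj$median, xout = grid,
                       method = "constant", f = 0, rule = 2)$y
  data.frame(time_ybp = grid, nef = nef)
}

#' Inter-generational growth rate series
#'
#' `IGR_n = 100 * (Nef_n - Nef_{n-1}) / Nef_{n-1}` with `n-1` the older
#' generation; the oldest gridpoint has no IGR.  The compounding identity
#' holds exactly: the most recent Nef equals the oldest Nef times
#' `prod(1 + IGR/100)`.
#'
#' @param nef_grid data frame from [resample_to_generations()] (`time_ybp`
#'   decreasing toward 0, `nef` positive).
#' @param periods a [period_table()] used to annotate each generation.
#' @return data frame of class `"igr_series"`: `time_ybp`, `nef`, `igr`
#'   (percent; `NA` at the oldest generation), `period`.
#' @export
igr_series <- function(nef_grid, periods = period_table()) {
  stopifnot(nrow(nef_grid) >= 2)
  if (any(nef_grid$nef <= 0)) {
    stop("undefined growth rate: Nef must be positive everywhere",
         call. = FALSE)
  }
  ord <- order(nef_grid$time_ybp, decreasing = TRUE)  # oldest first
  g <- nef_grid[ord, , drop = FALSE]
  igr <- c(NA_real_, 100 * diff(g$nef) / g$nef[-nrow(g)])
  out <- data.frame(time_ybp = g$time_ybp, nef = g$nef, igr = igr,
                    period = period_of(g$time_ybp, periods))
  structure(out, class = c("igr_series", "data.frame"))
}

most_recent_which <- function(x, f) {
  # index of the extremum, ties broken toward the most recent time
  # (series is ordered oldest -> recent)
  cand <- which(x == f(x, na.rm = TRUE))
  cand[length(cand)]
}

#' Locate Nef and IGR extrema and their periods
#'
#' Argmax/argmin of Nef and of the IGR over the generation grid, ties broken
#' toward the most recent generation, each mapped to its chronological
#' period.
#'
#' @param series an [igr_series()].
#' @param periods a [period_table()].
#' @return one-row data frame: `nef_max`, `nef_max_ybp`, `nef_max_period`,
#'   same for `nef_min`, `igr_max` and `igr_min`.
#' @export
locate_extrema <- function(series, periods = period_table()) {
  stopifnot(nrow(series) >= 1)
  lab <- function(t) period_of(t, periods)
  i_nmax <- most_recent_which(series$nef, max)
  i_nmin <- most_recent_which(series$nef, min)
  ig <- series$igr
  i_gmax <- most_recent_which(replace(ig, is.na(ig), -Inf), max)
  i_gmin <- most_recent_which(replace(ig, is.na(ig), Inf), min)
  data.frame(
    nef_max = series$nef[i_nmax], nef_max_ybp = series$time_ybp[i_nmax],
    nef_max_period = lab(series$time_ybp[i_nmax]),
    nef_min = series$nef[i_nmin], nef_min_ybp = series$time_ybp[i_nmin],
    nef_min_period = lab(series$time_ybp[i_nmin]),
    igr_max = series$igr[i_gmax], igr_max_ybp = series$time_ybp[i_gmax],
    igr_max_period = lab(series$time_ybp[i_gmax]),
    igr_min = series$igr[i_gmin], igr_min_ybp = series$time_ybp[i_gmin],
    igr_min_period = lab(series$time_ybp[i_gmin]))
}

#' Detect the IGR trend inversion
#'
#' Raw IGR series fluctuate intensely, so the sign change is located on a
#' centered moving average: an inversion is the most recent time where the
#' smoothed IGR crosses zero with persistent opposite signs on both flanks
#' (at least `window / 2` generations each).  The reported period is the one
#' in which the rates pass through equal (zero) value.  `mode = "raw"` uses
#' the unsmoothed series (window 1, no persistence).
#'
#' @param series an [igr_series()].
#' @param window smoothing window in generations (default 5).
#' @param periods a [period_table()].
#' @param mode `"smoothed"` (default) or `"raw"`.
#' @return data frame with zero rows if no inversion, else one row per
#'   crossing (most recent first): `time_ybp`, `period`, `direction`,
#'   `window`.
#' @export
detect_inversion <- function(series, window = 5, periods = period_table(),
                             mode = c("smoothed", "raw")) {
  mode <- match.arg(mode)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  x <- series$igr[-1]                 # defined from the second-oldest on
  t <- series$time_ybp[-1]
  if (mode == "raw") window <- 1
  if (length(x) < window) {
    stop("series shorter than the smoothing window", call. = FALSE)
  }
  sm <- if (window > 1) {
    as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  } else x
  flank <- max(1L, floor(window / 2))
  sgn <- sign(sm)
  # transitions between consecutive strictly-signed values (zero plateaus in
  # between are where "the rates have equal values"; the crossing is dated at
  # the midpoint of the transition segment)
  nz <- which(!is.na(sgn) & sgn != 0)
  hits <- list()
  if (length(nz) >= 2) {
    for (q in seq_len(length(nz) - 1)) {
      a <- nz[q]; b <- nz[q + 1]
      if (sgn[a] == sgn[b]) next
      before <- sgn[max(1, a - flank + 1):a]
      after <- sgn[b:min(length(sgn), b + flank - 1)]
      before <- before[!is.na(before)]
      after <- after[!is.na(after)]
      # persistence: no opposite-signed value inside either flank
      if (any(before * sgn[a] < 0) || any(after * sgn[b] < 0)) next
      # dated where the new sign first appears: a zero plateau (flat
      # reconstruction) is the tail of the previous regime, so the crossing
      # brackets the first strictly-opposite value
      t_cross <- mean(c(t[b - 1], t[b]))
      hits[[length(hits) + 1]] <- data.frame(
        time_ybp = t_cross, period = period_of(t_cross, periods),
        direction = if (sgn[a] > 0) "positive->negative"
                    else "negative->positive",
        window = window)
    }
  }
  if (!length(hits)) {
    return(data.frame(time_ybp = numeric(0), period = character(0),
                      direction = character(0), window = numeric(0)))
  }
  out <- do.call(rbind, rev(hits))  # most recent first
  out
}

#' Assemble per-population demographic reports
#'
#' One row per population combining Nef/IGR extrema and the detected
#' inversion period, plus long-format scatter data (population, region,
#' metric, time, period) suited to period-distribution plots.
#'
#' @param series_list named list of [igr_series()] per population.
#' @param regions optional named population -> cultural-region vector.
#' @param periods a [period_table()].
#' @param window smoothing window for [detect_inversion()].
#' @return list with `table` (one row per population) and `scatter`
#'   (long format).
#' @export
report_tables <- function(series_list, regions = NULL,
                          periods = period_table(), window = 5) {
  stopifnot(length(series_list) >= 1)
  rows <- lapply(names(series_list), function(p) {
    s <- series_list[[p]]
    ex <- locate_extrema(s, periods)
    inv <- detect_inversion(s, window, periods)
    cbind(population = p,
          region = if (is.null(regions)) NA_character_ else
            unname(regions[p]),
          ex,
          inversion_ybp = if (nrow(inv)) inv$time_ybp[1] else NA_real_,
          inversion_period = if (nrow(inv)) inv$period[1] else NA_character_,
          inversion_direction = if (nrow(inv)) inv$direction[1] else
            NA_character_)
  })
  tab <- do.call(rbind, rows)
  long <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(population = tab$population[i], region = tab$region[i],
               metric = c("nef_max", "nef_min", "igr_max", "igr_min",
                          "inversion"),
               time_ybp = c(tab$nef_max_ybp[i], tab$nef_min_ybp[i],
                            tab$igr_max_ybp[i], tab$igr_min_ybp[i],
                            tab$inversion_ybp[i]),
               period = c(tab$nef_max_period[i], tab$nef_min_period[i],
                          tab$igr_max_period[i], tab$igr_min_period[i],
                          tab$inversion_period[i]))
  }))
  list(table = tab, scatter = long)
}
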