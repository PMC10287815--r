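# Biaxial biomechanics analysis: stress/strain, cycle segmentation,
# steady-cycle selection, mean slope, tangent modulus, anisotropy index.

#' Convert a raw biaxial trace to per-axis stress-strain series
#'
#' Nominal stress per axis is force divided by the initial cross-section
#' `thickness * width` (N/mm^2 = MPa); strain is converted from % to a
#' fraction.
#'
#' @param trace A `mech_trace` (from [simulate_specimen_mech()] or
#'   [read_mech_trace()]).
#' @return Named list of two `stress_strain` tibbles (`x` = longitudinal,
#'   `y` = transverse) with columns `time_s`, `strain` (fraction) and
#'   `stress_MPa`.
#' @export
compute_stress_strain <- function(trace) {
  stop_unless(inherits(trace, "mech_trace"), "`trace` must be a mech_trace")
  g <- trace$geometry
  stop_unless(g$thickness > 0 && g$width_x > 0 && g$width_y > 0,
              "geometry dimensions must be positive")
  mk <- function(axis) {
    width <- if (axis == "x") g$width_x else g$width_y
    out <- tibble::tibble(
      time_s = trace$data$time_s,
      strain = trace$data[[paste0("strain_", axis, "_pct")]] / 100,
      stress_MPa = trace$data[[paste0("force_", axis, "_N")]] / (g$thickness * width)
    )
    attr(out, "axis") <- axis
    class(out) <- c("stress_strain", class(out))
    out
  }
  list(x = mk("x"), y = mk("y"))
}

# Locate cycle boundaries (indices of strain minima between cycles).
# Boundaries are valley minima of runs where the smoothed strain falls below
# half the lowest protocol level. The smoothing window and the minimum
# boundary separation are derived from the protocol (a quarter of the
# threshold-crossing time and half the shortest cycle period, respectively)
# so that strain jitter neither splits a valley nor invents sliver cycles.
find_cycle_boundaries <- function(strain_pct, protocol) {
  n <- length(strain_pct)
  rate_s <- protocol$strain_rate / 60            # % strain per second
  thresh <- min(protocol$strain_levels) / 2
  n_sm <- max(5L, round(0.25 * protocol$sample_rate * thresh / rate_s))
  n_sm <- n_sm + (n_sm + 1L) %% 2L               # odd window
  sm <- as.numeric(stats::filter(strain_pct, rep(1 / n_sm, n_sm), sides = 2))
  sm[is.na(sm)] <- strain_pct[is.na(sm)]
  low <- sm < thresh
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  bounds <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    bounds <- c(bounds, seg[which.min(strain_pct[seg])])
  }
  # merge boundaries closer than half the shortest cycle period, keeping the
  # deeper minimum
  min_sep <- round(protocol$sample_rate * min(protocol$strain_levels) / rate_s)
  if (length(bounds) > 1) {
    kept <- bounds[1]
    for (b in bounds[-1]) {
      last <- kept[length(kept)]
      if (b - last < min_sep) {
        if (strain_pct[b] < strain_pct[last]) kept[length(kept)] <- b
      } else {
        kept <- c(kept, b)
      }
    }
    bounds <- kept
  }
  # ensure the trace endpoints act as boundaries
  if (length(bounds) == 0 || bounds[1] > 1L) bounds <- c(1L, bounds)
  if (bounds[length(bounds)] < n) bounds <- c(bounds, n)
  bounds
}

#' Segment a stress-strain series into loading/unloading cycles
#'
#' Cycles are delimited by strain minima (valleys near zero strain); each
#' cycle is split at its strain maximum into a loading and an unloading limb
#' and assigned to the nearest protocol strain level by peak strain (ties go
#' to the lower level). An error names any level with fewer than 3 detected
#' cycles.
#'
#' @param series A `stress_strain` tibble from [compute_stress_strain()].
#' @param protocol The [mech_protocol()] the series was acquired under.
#' @return A `cycle_set` tibble with one row per cycle: `axis`,
#'   `strain_level_pct`, `cycle` (1-based within level), `peak_strain`
#'   (fraction), and list-columns `loading` / `unloading` each holding paired
#'   `strain` and `stress_MPa` vectors.
#' @export
segment_cycles <- function(series, protocol = mech_protocol()) {
  stop_unless(inherits(series, "stress_strain"),
              "`series` must come from compute_stress_strain()")
  stop_unless(inherits(protocol, "mech_protocol"), "`protocol` must be mech_protocol")
  strain_pct <- series$strain * 100
  bounds <- find_cycle_boundaries(strain_pct, protocol)
  levels <- protocol$strain_levels

  lev_v <- numeric(0); peak_v <- numeric(0)
  load_l <- list(); unload_l <- list()
  strain <- series$strain; stress <- series$stress_MPa
  for (ci in seq_len(length(bounds) - 1L)) {
    idx <- bounds[ci]:bounds[ci + 1L]
    if (length(idx) < 5L) next  # spurious sliver between coincident minima
    peak_rel <- which.max(strain_pct[idx])
    peak_pct <- strain_pct[idx[peak_rel]]
    if (peak_pct < min(levels) / 2) next  # no excursion: not a cycle
    # nearest level; equidistant peaks go to the lower level
    d <- abs(levels - peak_pct)
    lev <- levels[which.min(d + 1e-12 * levels)]
    load_idx <- idx[1:peak_rel]
    unload_idx <- idx[peak_rel:length(idx)]
    k <- length(lev_v) + 1L
    lev_v[k] <- lev; peak_v[k] <- peak_pct / 100
    load_l[[k]] <- list(strain = strain[load_idx], stress_MPa = stress[load_idx])
    unload_l[[k]] <- list(strain = strain[unload_idx], stress_MPa = stress[unload_idx])
  }
  if (length(lev_v) == 0) stop("no cycles detected in series", call. = FALSE)
  cyc <- tibble::tibble(
    axis = attr(series, "axis") %||% "x",
    strain_level_pct = lev_v,
    cycle = stats::ave(seq_along(lev_v), lev_v, FUN = seq_along),
    peak_strain = peak_v,
    loading = load_l,
    unloading = unload_l
  )

  counts <- table(factor(cyc$strain_level_pct, levels = levels))
  bad <- names(counts)[counts < 3]
  if (length(bad) > 0) {
    stop("fewer than 3 cycles detected at strain level(s): ",
         paste0(bad, "%", collapse = ", "), call. = FALSE)
  }
  class(cyc) <- c("cycle_set", class(cyc))
  cyc
}

#' Keep only the last k (steady-state) cycles per strain level
#'
#' Viscoelastic preconditioning settles within ten cycles, so analysis uses
#' the final `k` cycles of each level (default 3: cycles 8-10 of 10).
#'
#' @param cycles A `cycle_set` from [segment_cycles()].
#' @param k Number of trailing cycles to keep per level.
#' @return The filtered `cycle_set`, order preserved.
#' @export
select_steady_cycles <- function(cycles, k = 3) {
  stop_unless(inherits(cycles, "cycle_set"), "`cycles` must be a cycle_set")
  stop_unless(is_scalar_num(k) && k >= 1, "`k` must be >= 1")
  idx_by_level <- split(seq_len(nrow(cycles)), cycles$strain_level_pct)
  short <- names(idx_by_level)[lengths(idx_by_level) < k]
  if (length(short) > 0) {
    stop("fewer than k = ", k, " cycles at strain level(s): ",
         paste0(short, "%", collapse = ", "), call. = FALSE)
  }
  keep <- sort(unlist(lapply(idx_by_level, function(i) utils::tail(i, k)),
               use.names = FALSE))
  out <- cycles[keep, ]
  class(out) <- class(cycles)
  out
}

#' Mean slope (stiffness) of one cycle
#'
#' First-order least-squares fits of stress on strain over the loading limb
#' and over the unloading limb; the arithmetic mean of the two slopes is the
#' cycle's stiffness in MPa.
#'
#' @param cycle One row of a `cycle_set` (or a list with `loading` and
#'   `unloading` data frames holding `strain` and `stress_MPa`).
#' @return Mean slope in MPa.
#' @export
mean_slope <- function(cycle) {
  seg <- function(x) if (!is.null(x$strain)) x else x[[1]]
  ld <- seg(cycle$loading)
  ul <- seg(cycle$unloading)
  (ls_slope(ld$strain, ld$stress_MPa) + ls_slope(ul$strain, ul$stress_MPa)) / 2
}

#' Tangent modulus over the terminal strain window
#'
#' For each supplied (steady-state) cycle, the least-squares slope of the
#' loading limb restricted to the last `window_pct` % strain below that
#' cycle's peak; the estimate at the level is the mean over cycles. The
#' fitted window's mean strain is returned alongside so estimates can be
#' compared against the material tangent at the strain actually probed.
#'
#' @param cycles_at_level A `cycle_set` subset holding the steady cycles of
#'   one axis at one strain level.
#' @param window_pct Window width in % strain (default 1).
#' @return A list with `tangent_MPa`, `peak_strain` (mean observed peak,
#'   fraction), `window_center_strain` (mean strain of the fitted points,
#'   fraction) and `per_cycle` slopes.
#' @export
tangent_modulus <- function(cycles_at_level, window_pct = 1) {
  stop_unless(is_scalar_num(window_pct) && window_pct > 0, "`window_pct` must be > 0")
  w <- window_pct / 100
  slopes <- numeric(nrow(cycles_at_level))
  centers <- numeric(nrow(cycles_at_level))
  peaks <- numeric(nrow(cycles_at_level))
  for (i in seq_len(nrow(cycles_at_level))) {
    ld <- cycles_at_level$loading[[i]]
    peak <- max(ld$strain)
    if (peak - min(ld$strain) < w) {
      stop(sprintf("loading limb spans only %.3g strain, less than the %.3g window",
                   peak - min(ld$strain), w), call. = FALSE)
    }
    inwin <- ld$strain >= peak - w
    if (sum(inwin) < 2) {
      stop("fewer than 2 samples inside the tangent window; raise the sample rate or widen the window",
           call. = FALSE)
    }
    slopes[i] <- ls_slope(ld$strain[inwin], ld$stress_MPa[inwin])
    centers[i] <- mean(ld$strain[inwin])
    peaks[i] <- peak
  }
  list(tangent_MPa = mean(slopes), peak_strain = mean(peaks),
       window_center_strain = mean(centers), per_cycle = slopes)
}

#' Anisotropy index from per-axis tangent moduli
#'
#' AI at a strain level is the longitudinal (x) tangent modulus divided by
#' the transverse (y) tangent modulus of the same specimen.
#'
#' @param tangent_x,tangent_y Tangent moduli (MPa).
#' @return Dimensionless AI (vectorized).
#' @export
anisotropy_index <- function(tangent_x, tangent_y) {
  if (any(!is.finite(tangent_y)) || any(tangent_y <= 0)) {
    stop("transverse tangent modulus must be positive to form an anisotropy index",
         call. = FALSE)
  }
  tangent_x / tangent_y
}

#' Full per-specimen biomechanics analysis
#'
#' Composes [compute_stress_strain()], [segment_cycles()],
#' [select_steady_cycles()], [mean_slope()], [tangent_modulus()] and
#' [anisotropy_index()] over both axes and all protocol strain levels.
#'
#' @param trace A `mech_trace`.
#' @param k_last Steady cycles per level to analyze (default 3).
#' @param window_pct Tangent window width in % strain (default 1).
#' @return A `specimen_mechanics` object: list with `moduli` (tibble:
#'   `specimen_id`, `axis`, `strain_level_pct`, `mean_slope_MPa`,
#'   `tangent_modulus_MPa`, `window_center_strain`) and `ai` (tibble:
#'   `specimen_id`, `strain_level_pct`, `ai`).
#' @export
analyze_specimen <- function(trace, k_last = 3, window_pct = 1) {
  series <- compute_stress_strain(trace)
  axes <- character(0); levs <- numeric(0)
  msl <- numeric(0); tmod <- numeric(0); wc <- numeric(0)
  for (axis in c("x", "y")) {
    cyc <- tryCatch(
      select_steady_cycles(segment_cycles(series[[axis]], trace$protocol), k = k_last),
      error = function(e) stop(sprintf("specimen '%s', axis %s: %s",
                                       trace$specimen_id, axis, conditionMessage(e)),
                               call. = FALSE)
    )
    for (lev in trace$protocol$strain_levels) {
      sel <- which(cyc$strain_level_pct == lev)
      at_level <- cyc[sel, ]
      tm <- tryCatch(
        tangent_modulus(at_level, window_pct = window_pct),
        error = function(e) stop(sprintf("specimen '%s', axis %s, level %g%%: %s",
                                         trace$specimen_id, axis, lev,
                                         conditionMessage(e)), call. = FALSE)
      )
      k <- length(axes) + 1L
      axes[k] <- axis; levs[k] <- lev
      msl[k] <- mean(mapply(function(ld, ul)
        mean_slope(list(loading = ld, unloading = ul)),
        at_level$loading, at_level$unloading))
      tmod[k] <- tm$tangent_MPa
      wc[k] <- tm$window_center_strain
    }
  }
  moduli <- tibble::tibble(specimen_id = trace$specimen_id, axis = axes,
                           strain_level_pct = levs, mean_slope_MPa = msl,
                           tangent_modulus_MPa = tmod,
                           window_center_strain = wc)
  ai <- moduli |>
    dplyr::select("specimen_id", "axis", "strain_level_pct", "tangent_modulus_MPa") |>
    tidyr::pivot_wider(names_from = "axis", values_from = "tangent_modulus_MPa") |>
    dplyr::mutate(ai = anisotropy_index(.data$x, .data$y)) |>
    dplyr::select("specimen_id", "strain_level_pct", "ai")
  structure(list(moduli = moduli, ai = ai, specimen_id = trace$specimen_id),
            class = "specimen_mechanics")
}

#' @export
print.specimen_mechanics <- function(x, ...) {
  cat(sprintf("<specimen_mechanics> '%s'\n", x$specimen_id))
  print(x$moduli, n = Inf)
  invisible(x)
}
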