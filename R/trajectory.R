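#' Multi-agent trajectory tables
#'
#' A `flock_traj` is a tidy tibble of synchronous agent positions with one
#' row per (time, agent) pair, columns `time` (seconds), `agent` (identifier)
#' and Cartesian coordinates `x`, `y` and optionally `z` in metres, sampled
#' on a common, equally spaced time grid. The sampling interval `dt` is
#' carried as an attribute. All agents must be observed at every time step;
#' gaps are an error, never imputed.
#'
#' @param data A data frame with columns `time`, `agent`, `x`, `y` and
#'   optionally `z`.
#' @param dt Optional sampling interval in seconds; inferred from the `time`
#'   column when `NULL`.
#' @return A `flock_traj` tibble ordered by time then agent (agents in order
#'   of first appearance).
#' @examples
#' df <- tidyr::expand_grid(time = 0:4, agent = c("a", "b"))
#' df$x <- seq_len(nrow(df)); df$y <- 0
#' as_flock_traj(df)
#' @export
as_flock_traj <- function(data, dt = NULL) {
  req <- c("time", "agent", "x", "y")
  if (!all(req %in% names(data))) {
    stopf("trajectory data needs columns %s", paste(req, collapse = ", "))
  }
  coords <- intersect(c("x", "y", "z"), names(data))
  data <- tibble::as_tibble(data)[, c("time", "agent", coords)]
  if (anyNA(data)) abort("trajectory contains missing values")
  agents <- unique(as.character(data$agent))
  times <- sort(unique(data$time))
  if (nrow(data) != length(agents) * length(times)) {
    key <- paste(data$time, data$agent)
    if (anyDuplicated(key)) abort("duplicate (time, agent) rows")
    abort("unaligned trajectory: agents do not share one time grid")
  }
  if (anyDuplicated(paste(data$time, data$agent))) {
    abort("duplicate (time, agent) rows")
  }
  if (length(times) < 2) abort("trajectory needs at least 2 time steps")
  steps <- diff(times)
  if (diff(range(steps)) > 1e-9 * max(abs(steps))) {
    abort("unaligned trajectory: time grid is not equally spaced")
  }
  dt <- dt %||% steps[[1]]
  if (dt <= 0) abort("dt must be positive")
  data$agent <- as.character(data$agent)
  data <- dplyr::arrange(data,
                         .data$time,
                         match(.data$agent, agents))
  new_flock_traj(data, dt = dt, agents = agents)
}

new_flock_traj <- function(data, dt, agents) {
  tibble::new_tibble(data,
                     dt = dt,
                     agents = agents,
                     class = "flock_traj")
}

#' @export
print.flock_traj <- function(x, ...) {
  dm <- traj_dims(x)
  cat(sprintf("# flock_traj: %d agents x %d steps, D = %d, dt = %g s\n",
              dm$N, dm$T, dm$D, traj_dt(x)))
  NextMethod()
}

#' Trajectory metadata accessors
#'
#' @param traj A [as_flock_traj()] trajectory.
#' @return `traj_dt()` the sampling interval in seconds; `traj_agents()` the
#'   agent identifiers in column order; `traj_dims()` a list with `T`
#'   (steps), `N` (agents) and `D` (spatial dimension).
#' @export
traj_dt <- function(traj) attr(traj, "dt")

#' @rdname traj_dt
#' @export
traj_agents <- function(traj) attr(traj, "agents")

#' @rdname traj_dt
#' @export
traj_dims <- function(traj) {
  agents <- traj_agents(traj)
  coords <- intersect(c("x", "y", "z"), names(traj))
  list(T = nrow(traj) / length(agents),
       N = length(agents),
       D = length(coords))
}

# dense array view [step, agent, coord]; rows of traj are already ordered
# by time then agent
traj_array <- function(traj) {
  dm <- traj_dims(traj)
  coords <- intersect(c("x", "y", "z"), names(traj))
  arr <- array(NA_real_, dim = c(dm$T, dm$N, dm$D))
  for (d in seq_along(coords)) {
    arr[, , d] <- matrix(traj[[coords[d]]], nrow = dm$T, ncol = dm$N,
                         byrow = TRUE)
  }
  dimnames(arr) <- list(NULL, traj_agents(traj), coords)
  arr
}

# rebuild a flock_traj from an array [T, N, D]
traj_from_array <- function(arr, dt, agents = NULL, t0 = 0) {
  Tn <- dim(arr)[1]; N <- dim(arr)[2]; D <- dim(arr)[3]
  agents <- agents %||% sprintf("a%02d", seq_len(N))
  coords <- c("x", "y", "z")[seq_len(D)]
  df <- tibble::tibble(
    time = rep(t0 + (seq_len(Tn) - 1) * dt, each = N),
    agent = rep(agents, times = Tn)
  )
  for (d in seq_len(D)) {
    df[[coords[d]]] <- as.vector(t(arr[, , d]))
  }
  new_flock_traj(df, dt = dt, agents = agents)
}

#' Read and write trajectory CSV files
#'
#' The on-disk format is a delimited text file with header
#' `time,agent,x,y[,z]`, one row per (time, agent) observation, seconds and
#' metres, `.` decimal separator. All agents must share one equally spaced
#' time grid; ragged grids and duplicate rows are errors.
#'
#' @param path File path.
#' @param dialect Delimiter tag, `"csv"` (default) or `"tsv"`.
#' @return `read_trajectory()` returns a [as_flock_traj()] trajectory;
#'   `write_trajectory()` invisibly returns `path`.
#' @export
read_trajectory <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  as_flock_traj(df)
}

#' @rdname read_trajectory
#' @param traj Trajectory to write.
#' @export
write_trajectory <- function(traj, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(tibble::as_tibble(traj), path, progress = FALSE)
  invisible(path)
}

#' Decimate a trajectory to a coarser sampling interval
#'
#' Keeps every `factor`-th frame starting from the first and multiplies `dt`
#' accordingly. No interpolation is performed: retained frames are carried
#' over exactly.
#'
#' @inheritParams traj_dt
#' @param factor Positive integer decimation factor.
#' @return A `flock_traj` with `ceiling(T / factor)` steps.
#' @export
resample_trajectory <- function(traj, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor)) {
    abort("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(traj)
  dm <- traj_dims(traj)
  if (dm$T <= factor) abort("trajectory too short to resample")
  keep_steps <- seq(1L, dm$T, by = factor)
  arr <- traj_array(traj)[keep_steps, , , drop = FALSE]
  traj_from_array(arr, dt = traj_dt(traj) * factor,
                  agents = traj_agents(traj), t0 = min(traj$time))
}

#' Drop the altitude coordinate of a 3D trajectory
#'
#' @inheritParams traj_dt
#' @return A 2D `flock_traj` with only `x` and `y` columns.
#' @export
project_xy <- function(traj) {
  if (!"z" %in% names(traj)) return(traj)
  df <- tibble::as_tibble(traj)[, c("time", "agent", "x", "y")]
  new_flock_traj(df, dt = traj_dt(traj), agents = traj_agents(traj))
}

#' Curation thresholds for trajectory filtering
#'
#' Bundles the thresholds used by [trim_idle()] and [remove_stranded()].
#' GPS flight data typically needs both: stretches before take-off and after
#' landing where the flock barely moves, and individuals that never join the
#' flock. The defaults make that curation reproducible: a step counts as
#' idle when the flock-mean speed is below 1 m/s, and an agent as stranded
#' when it sits further than three times the typical flock radius from the
#' centroid of the others for more than half of the recording.
#'
#' @param idle_speed_threshold Flock-mean speed below which a step is idle,
#'   m/s.
#' @param idle_min_run Minimum length (steps) of a leading/trailing idle run
#'   before it is trimmed.
#' @param stranded_distance_threshold Distance from the leave-one-out flock
#'   centroid beyond which an agent is far, metres. `NULL` means 3 times the
#'   time-median of the global separation measure, computed per trajectory.
#' @param stranded_min_fraction Fraction of steps an agent must be far to be
#'   dropped, in (0, 1].
#' @return A `filter_config` list.
#' @export
filter_config <- function(idle_speed_threshold = 1,
                          idle_min_run = 5L,
                          stranded_distance_threshold = NULL,
                          stranded_min_fraction = 0.5) {
  if (idle_speed_threshold <= 0 || idle_min_run <= 0) {
    abort("idle thresholds must be positive")
  }
  if (!is.null(stranded_distance_threshold) &&
      stranded_distance_threshold <= 0) {
    abort("stranded_distance_threshold must be positive")
  }
  if (stranded_min_fraction <= 0 || stranded_min_fraction > 1) {
    abort("stranded_min_fraction must be in (0, 1]")
  }
  structure(list(idle_speed_threshold = idle_speed_threshold,
                 idle_min_run = as.integer(idle_min_run),
                 stranded_distance_threshold = stranded_distance_threshold,
                 stranded_min_fraction = stranded_min_fraction),
            class = "filter_config")
}

#' Drop agents persistently far from the flock
#'
#' An agent is stranded when its distance to the centroid of the *other*
#' agents exceeds `stranded_distance_threshold` in more than
#' `stranded_min_fraction` of the time steps. Stranded agents are removed so
#' that downstream model fits see a genuinely interacting population.
#'
#' @inheritParams traj_dt
#' @param cfg A [filter_config()].
#' @return The trajectory with stranded agents removed.
#' @export
remove_stranded <- function(traj, cfg = filter_config()) {
  dm <- traj_dims(traj)
  if (dm$N < 2) abort("need at least 2 agents")
  arr <- traj_array(traj)
  thr <- cfg$stranded_distance_threshold
  if (is.null(thr)) {
    thr <- 3 * median(d_global_frames(arr))
  }
  # a stranded agent drags everyone's leave-one-out centroid toward
  # itself, so offenders are removed greedily, worst first, re-checking
  # the remaining flock after each removal
  keep <- seq_len(dm$N)
  repeat {
    stats <- vapply(seq_along(keep), function(k) {
      sub <- arr[, keep, , drop = FALSE]
      others <- sub[, -k, , drop = FALSE]
      cent <- apply(others, c(1, 3), mean)         # T x D
      d <- sqrt(rowSums((sub[, k, ] - cent)^2))
      c(frac = mean(d > thr), meand = mean(d))
    }, numeric(2))
    bad <- which(stats["frac", ] > cfg$stranded_min_fraction)
    if (!length(bad)) break
    worst <- bad[order(-stats["frac", bad], -stats["meand", bad])][1]
    keep <- keep[-worst]
    if (length(keep) < 2) abort("empty flock: all agents stranded")
  }
  if (length(keep) == dm$N) return(traj)
  traj_from_array(arr[, keep, , drop = FALSE], dt = traj_dt(traj),
                  agents = traj_agents(traj)[keep], t0 = min(traj$time))
}

#' Trim idle stretches at the start and end of a recording
#'
#' Removes leading and trailing maximal runs (of at least `idle_min_run`
#' steps) in which the speed of the flock centroid stays below
#' `idle_speed_threshold`. Interior steps are never removed, so the time
#' grid stays contiguous.
#'
#' @inheritParams remove_stranded
#' @return The trimmed trajectory.
#' @export
trim_idle <- function(traj, cfg = filter_config()) {
  dm <- traj_dims(traj)
  if (dm$T < 3) abort("need at least 3 time steps")
  arr <- traj_array(traj)
  cent <- apply(arr, c(1, 3), mean)                       # T x D
  speed <- sqrt(rowSums(diff(cent)^2)) / traj_dt(traj)    # length T-1
  idle <- speed < cfg$idle_speed_threshold
  lead <- run_length_from(idle)
  trail <- run_length_from(rev(idle))
  drop_head <- if (lead >= cfg$idle_min_run) lead else 0L
  drop_tail <- if (trail >= cfg$idle_min_run) trail else 0L
  keep <- seq_len(dm$T)
  keep <- keep[keep > drop_head & keep <= dm$T - drop_tail]
  if (length(keep) < 3) abort("trajectory entirely idle")
  if (length(keep) == dm$T) return(traj)
  t0 <- min(traj$time) + drop_head * traj_dt(traj)
  traj_from_array(arr[keep, , , drop = FALSE], dt = traj_dt(traj),
                  agents = traj_agents(traj), t0 = t0)
}

# length of the initial TRUE run
run_length_from <- function(flags) {
  if (!length(flags) || !flags[1]) return(0L)
  r <- rle(flags)
  r$lengths[1]
}

# d_global per frame on a [T, N, D] array
d_global_frames <- function(arr) {
  cent <- apply(arr, c(1, 3), mean)
  Tn <- dim(arr)[1]
  vapply(seq_len(Tn), function(t) {
    mean(sqrt(rowSums((arr[t, , , drop = TRUE] -
                         matrix(cent[t, ], dim(arr)[2], dim(arr)[3],
                                byrow = TRUE))^2)))
  }, numeric(1))
}
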