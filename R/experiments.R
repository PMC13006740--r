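#' Run a replicate ensemble
#'
#' The simulation is stochastic, so experiments are reported as the mean and
#' a confidence band of plus/minus one standard deviation over replicate
#' runs with distinct seeds (`seed0`, `seed0 + 1`, ...). A failed replicate
#' is recorded with a warning and the ensemble continues with the
#' survivors.
#'
#' @param config a [sim_config()].
#' @param n number of replicates, `>= 1`.
#' @param seed0 first seed.
#' @return an object of class `replicate_summary`: list with `summary`
#'   (data.frame of per-time mean and sd for each series column), `runs`
#'   (list of trajectories), `seeds`, and `failures`.
#' @export
run_replicates <- function(config, n = 10, seed0 = 1L) {
  stopifnot(n >= 1)
  seeds <- seq.int(seed0, length.out = n)
  runs <- vector("list", n)
  fail <- character(0)
  for (k in seq_len(n)) {
    runs[[k]] <- tryCatch(run_simulation(config, seed = seeds[k]),
                          error = function(e) e)
    if (inherits(runs[[k]], "error")) {
      fail <- c(fail, sprintf("seed %d: %s", seeds[k],
                              conditionMessage(runs[[k]])))
      runs[k] <- list(NULL)
    }
  }
  if (length(fail))
    warning(sprintf("%d replicate(s) failed:\n%s", length(fail),
                    paste(fail, collapse = "\n")))
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all replicates failed", call. = FALSE)
  series <- lapply(runs[ok], `[[`, "series")
  times <- series[[1]]$time
  cols <- setdiff(names(series[[1]]), "time")
  summ <- data.frame(time = times)
  for (cn in cols) {
    mat <- vapply(series, `[[`, numeric(length(times)), cn)
    mat <- matrix(mat, nrow = length(times))
    summ[[paste0(cn, "_mean")]] <- rowMeans(mat)
    summ[[paste0(cn, "_sd")]] <- apply(mat, 1, sd)
    if (ncol(mat) == 1L) summ[[paste0(cn, "_sd")]] <- 0
  }
  structure(list(summary = summ, runs = runs, seeds = seeds,
                 failures = fail),
            class = "replicate_summary")
}

#' Endpoint of a replicate ensemble
#'
#' Mean and sd of the viable cell count at the final recorded time -- the
#' endpoint treatment-efficacy metric of the sweep experiments.
#'
#' @param reps a [run_replicates()] result.
#' @return list with `mean`, `sd`, `time`, and the per-replicate values.
#' @export
endpoint_viable <- function(reps) {
  ok <- !vapply(reps$runs, is.null, logical(1))
  vals <- vapply(reps$runs[ok], function(r) {
    s <- r$series
    s$viable[nrow(s)]
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       time = reps$summary$time[nrow(reps$summary)], values = vals)
}

#' Sweep specification
#'
#' Named parameter axes over a base configuration. Axis names are dotted
#' paths into the config, e.g. `"design.gamma1"` or `"inheritance_x"`.
#'
#' @param axes named list; each element is the vector of values for one
#'   axis.
#' @param replicates replicates per grid point, `>= 1`.
#' @param base a [sim_config()].
#' @param seed0 first replicate seed (the same seeds are reused at every
#'   grid point, so differences between points are paired).
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(axes, replicates = 10, base = sim_config(),
                       seed0 = 1L) {
  if (!length(axes) || is.null(names(axes)) || any(names(axes) == ""))
    stop("axes must be a non-empty named list", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(axes = axes, replicates = replicates, base = base,
                 seed0 = seed0),
            class = "sweep_spec")
}

# set a dotted-path entry of a config, e.g. "design.gamma1"
config_set <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    config[[parts]] <- value
  } else if (length(parts) == 2L) {
    config[[parts[1]]][[parts[2]]] <- value
  } else stop("config paths have at most two components", call. = FALSE)
  config
}

#' Run a Cartesian parameter sweep
#'
#' Executes the full grid of axis values, each with the spec's replicate
#' count, and summarizes each grid point by the viable cell count at the
#' horizon (mean and sd over replicates).
#'
#' @param spec a [sweep_spec()].
#' @return data.frame: one row per grid point with the axis values,
#'   `viable_mean`, `viable_sd`, and `n_runs`.
#' @export
sweep_grid <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(spec$axes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- grid
  out$viable_mean <- NA_real_
  out$viable_sd <- NA_real_
  out$n_runs <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    cfg <- spec$base
    for (ax in names(spec$axes))
      cfg <- config_set(cfg, ax, grid[[ax]][r])
    validate_sim_config(cfg)
    reps <- run_replicates(cfg, n = spec$replicates, seed0 = spec$seed0)
    ep <- endpoint_viable(reps)
    out$viable_mean[r] <- ep$mean
    out$viable_sd[r] <- ep$sd
    out$n_runs[r] <- length(ep$values)
  }
  out
}

#' Release-state histogram matrix
#'
#' Rows are the cells whose centers fall inside the given region, columns
#' the m release-state populations -- the data behind release-state heatmap
#' figures. Row sums equal each cell's total internalized NP count.
#'
#' @param state a [sim_state()] (or a cell population).
#' @param region `c(xmin, xmax, ymin, ymax)` in um; default whole domain.
#' @return numeric matrix (cells x m), rownames = cell ids; zero rows if
#'   the region holds no cells.
#' @export
release_state_histogram <- function(state, region = NULL) {
  cells <- if (inherits(state, "sim_state")) state$cells else state
  if (is.null(region)) {
    keep <- rep(TRUE, n_cells(cells))
  } else {
    stopifnot(length(region) == 4)
    keep <- cells$x >= region[1] & cells$x <= region[2] &
      cells$y >= region[3] & cells$y <= region[4]
  }
  m <- cells$np[keep, , drop = FALSE]
  rownames(m) <- cells$id[keep]
  colnames(m) <- paste0("state_", seq_len(ncol(m)) - 1L)
  m
}
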