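#' Detachment rate of one species
#'
#' Number of detachment events per second, optionally restricted by cause
#' (crowding vs processivity) and to a time window.
#'
#' @param run An `mmls_run`.
#' @param species `"fast"`, `"slow"`, or a species name such as `"Kin3F"`.
#' @param cause `"all"` (default), `"crowding"` or `"processivity"`.
#' @param section Section index (default 1).
#' @param window Optional numeric `c(start_s, end_s)`; default is the whole
#'   run.
#' @return Detachment rate in motors/s.
#' @export
detachment_rate <- function(run, species = "fast",
                            cause = c("all", "crowding", "processivity"),
                            section = 1, window = NULL) {
  cause <- match.arg(cause)
  sp <- match_species(run, species)
  ser <- run$sections[[section]]$detach_series
  if (is.null(window)) {
    iters <- seq_len(run$iters_run)
    dur <- run$iters_run * run$dt_s
  } else {
    stopifnot(length(window) == 2, window[2] > window[1])
    i0 <- max(1L, seconds_to_iterations(window[1], run$dt_s) + 1L)
    i1 <- min(run$iters_run, seconds_to_iterations(window[2], run$dt_s))
    if (i1 < i0) return(0)
    iters <- i0:i1
    dur <- length(iters) * run$dt_s
  }
  counts <- ser[iters, sp, , drop = FALSE]
  if (cause != "all") counts <- counts[, , cause, drop = FALSE]
  if (dur <= 0) return(0)
  sum(counts) / dur
}

match_species <- function(run, species) {
  nm <- c(run$species$fast$name, run$species$slow$name)
  if (species %in% c("fast", "a")) return(nm[1])
  if (species %in% c("slow", "b")) return(nm[2])
  if (species %in% nm) return(species)
  stop("unknown species: ", species)
}

#' Bin a detailed per-iteration series
#'
#' Sums a per-iteration series into consecutive non-overlapping bins
#' (default 25 iterations = 1 s).  A trailing partial bin is retained and
#' flagged via the `"partial_last"` attribute.
#'
#' @param detailed Numeric vector (one value per iteration).
#' @param bin_iters Bin width in iterations (>= 1).
#' @return Numeric vector of bin sums with attribute `"partial_last"`.
#' @examples
#' bin_outflow(rep(1, 25))  # a single bin summing to 25
#' @export
bin_outflow <- function(detailed, bin_iters = 25) {
  bin_iters <- as.integer(bin_iters)
  if (bin_iters < 1) stop("bin_iters must be >= 1")
  n <- length(detailed)
  if (n == 0)
    return(structure(numeric(0), partial_last = FALSE))
  grp <- (seq_len(n) - 1L) %/% bin_iters
  out <- as.numeric(tapply(detailed, grp, sum))
  names(out) <- NULL
  structure(out, partial_last = (n %% bin_iters) != 0)
}

#' Per-iteration delivery counts for one section
#'
#' @param run An `mmls_run`.
#' @param section Section index.
#' @return Data frame with columns `iter`, `time_s`, `lane`, `species`,
#'   `count` (only iterations/lanes present in the run).
#' @export
outflow_detailed <- function(run, section = 1) {
  ofl <- run$sections[[section]]$outflow
  idx <- which(ofl > 0, arr.ind = TRUE)
  data.frame(
    iter = idx[, 1],
    time_s = idx[, 1] * run$dt_s,
    lane = idx[, 2],
    species = dimnames(ofl)[[3]][idx[, 3]],
    count = ofl[idx])
}

#' Binned outflow series for one section
#'
#' @param run An `mmls_run`.
#' @param section Section index.
#' @param bin_iters Bin width in iterations (default 25 = 1 s).
#' @param by `"total"` for a single series or `"lane_species"` for a matrix
#'   of series (bins x lane.species).
#' @return Numeric vector or matrix of per-bin delivery counts.
#' @export
outflow_binned <- function(run, section = 1, bin_iters = 25,
                           by = c("total", "lane_species")) {
  by <- match.arg(by)
  ofl <- run$sections[[section]]$outflow
  if (by == "total")
    return(bin_outflow(rowSums(ofl), bin_iters))
  cols <- expand.grid(lane = seq_len(dim(ofl)[2]),
                      species = dimnames(ofl)[[3]])
  out <- sapply(seq_len(nrow(cols)), function(k)
    bin_outflow(ofl[, cols$lane[k], cols$species[k]], bin_iters))
  colnames(out) <- paste(cols$lane, cols$species, sep = ".")
  out
}

#' Mean outflow rate of a section over a time window
#'
#' @param run An `mmls_run`.
#' @param section Section index.
#' @param window `c(start_s, end_s)`; defaults to the second half of the
#'   run (steady state).
#' @return Outflow in motors/s.
#' @export
outflow_rate <- function(run, section = 1, window = NULL) {
  if (is.null(window)) window <- c(run$horizon_s / 2, run$horizon_s)
  i0 <- max(1L, seconds_to_iterations(window[1], run$dt_s) + 1L)
  i1 <- min(run$n_iters, seconds_to_iterations(window[2], run$dt_s))
  if (i1 < i0) return(0)
  ofl <- run$sections[[section]]$outflow
  sum(ofl[i0:i1, , ]) / ((i1 - i0 + 1) * run$dt_s)
}

#' Dynamicity map and per-site profile
#'
#' Dynamicity counts every detachment and reattachment event, attributed to
#' the reservoir anchor site.  `dynamicity_map()` returns the lane x site
#' event matrix; `dynamicity_profile()` collapses lanes into a per-site
#' curve along the lattice.
#'
#' @param run An `mmls_run`.
#' @param species `"fast"`, `"slow"`, `"both"`, or a species name.
#' @param section Section index.
#' @return A lane x site matrix (`dynamicity_map`) or a length-`n_sites`
#'   vector (`dynamicity_profile`) of event counts.
#' @export
dynamicity_map <- function(run, species = "both", section = 1) {
  s <- run$sections[[section]]
  if (identical(species, "both")) {
    det <- apply(s$detach_counts, c(1, 2), sum)
    rea <- apply(s$reattach_counts, c(1, 2), sum)
  } else {
    sp <- match_species(run, species)
    det <- apply(s$detach_counts[, , sp, , drop = FALSE], c(1, 2), sum)
    rea <- s$reattach_counts[, , sp]
  }
  det + rea
}

#' @rdname dynamicity_map
#' @export
dynamicity_profile <- function(run, species = "both", section = 1) {
  colSums(dynamicity_map(run, species, section))
}

#' End-of-run motor ledger
#'
#' @param run An `mmls_run`.
#' @return Named vector of motor counts by final status plus the created
#'   total; conservation requires `created == sum of the rest`.
#' @export
run_ledger <- function(run) {
  st <- factor(run$motors$status,
               levels = c("queued", "on_lattice", "in_reservoir", "delivered",
                          "leaked", "in_junction", "dropped"))
  c(created = sum(run$created), table(st))
}

#' Write a run's metrics and event tables to a directory
#'
#' Writes `metrics.json` (totals, rates, clearance), `dynamicity.csv`,
#' `outflow_detailed.csv` and `outflow_binned.csv` per section, plus the
#' resolved configuration (`config.json`) for reproducibility.
#'
#' @param run An `mmls_run`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- list(
    chain = run$spec$name,
    horizon_s = run$horizon_s,
    iters_run = run$iters_run,
    created = as.list(run$created),
    dropped = run$dropped,
    clearance_s = run$clearance_s,
    ledger = as.list(run_ledger(run)),
    sections = lapply(seq_along(run$sections), function(si) list(
      totals = as.list(run$sections[[si]]$totals),
      detachment_rate_fast = detachment_rate(run, "fast", section = si),
      detachment_rate_slow = detachment_rate(run, "slow", section = si),
      outflow_rate_second_half = outflow_rate(run, section = si))))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(chain = run$spec$name, influx = unclass(run$influx),
              horizon_s = run$horizon_s, seed = run$seed,
              dt_s = run$dt_s,
              n_lanes = run$spec$geometry$n_lanes,
              n_sites = run$spec$geometry$n_sites,
              species = lapply(run$species, unclass))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (si in seq_along(run$sections)) {
    tag <- sprintf("section%d", si)
    dm <- dynamicity_map(run, "both", si)
    idx <- which(dm >= 0, arr.ind = TRUE)
    write.csv(data.frame(lane = idx[, 1], site = idx[, 2],
                         events = dm[idx]),
              file.path(dir, sprintf("dynamicity_%s.csv", tag)),
              row.names = FALSE)
    write.csv(outflow_detailed(run, si),
              file.path(dir, sprintf("outflow_detailed_%s.csv", tag)),
              row.names = FALSE)
    ob <- outflow_binned(run, si)
    write.csv(data.frame(bin = seq_along(ob), time_s = seq_along(ob) * 25 *
                           run$dt_s, count = as.numeric(ob)),
              file.path(dir, sprintf("outflow_binned_%s.csv", tag)),
              row.names = FALSE)
  }
  invisible(dir)
}
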