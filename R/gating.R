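#' Amplitude-based equal-count respiratory gating
#'
#' Bins are sorted by respiratory amplitude (ties broken by time, earlier bin
#' first) and the cumulative event counts are partitioned at the count
#' quantiles `total/G, 2 total/G, ...`. Gating granularity is the signal bin
#' (all events in a 100-ms bin share a gate), so exactly equal counts are
#' impossible in general; boundaries are placed on the bin edges that
#' minimise the maximum pairwise gate-count difference among the candidate
#' edges nearest each quantile (ties toward the lower edge). Gate 0 is the
#' lowest-amplitude (end-expiration) gate.
#'
#' @param signal conditioned signal tibble from [condition_signal()] (needs
#'   `amplitude`; `counts` used unless given separately).
#' @param counts_per_bin optional integer vector of per-bin event counts.
#' @param n_gates number of gates `G` (default 4).
#' @return an `rmc_gates` object: `$assignment` tibble (`bin`, `time_s`,
#'   `amplitude`, `counts`, `gate` in `0..G-1`), `$thresholds` (G-1 amplitude
#'   boundaries, mm), `$gate_counts`, `$n_gates`.
#' @export
equal_count_gates <- function(signal, counts_per_bin = NULL, n_gates = 4L) {
  amp <- signal$amplitude
  counts <- if (!is.null(counts_per_bin)) as.integer(counts_per_bin)
            else as.integer(signal$counts)
  stopifnot(length(amp) == length(counts))
  G <- as.integer(n_gates)
  if (G < 1) stop("n_gates must be >= 1")
  if (G > sum(counts > 0)) stop("more gates than non-empty bins")
  total <- sum(counts)
  if (total < G) stop("fewer events than gates")
  ord <- order(amp, seq_along(amp))       # amplitude, then time
  csum <- cumsum(counts[ord])
  gate_sorted <- if (G == 1) rep(0L, length(amp)) else {
    edges <- optimal_count_edges(csum, total, G)
    # bin i (sorted order) belongs to gate = number of edges before it
    findInterval(seq_along(csum), edges + 1L)
  }
  gate <- integer(length(amp))
  gate[ord] <- as.integer(gate_sorted)
  gate_counts <- vapply(0:(G - 1), function(g) sum(counts[gate == g]), 0L)
  thresholds <- if (G == 1) numeric(0) else {
    vapply(1:(G - 1), function(g) {
      lo <- max(amp[gate == g - 1L])
      hi <- min(amp[gate == g])
      (lo + hi) / 2
    }, 0)
  }
  assignment <- tibble::tibble(
    bin = seq_along(amp),
    time_s = if ("time_s" %in% names(signal)) signal$time_s else seq_along(amp),
    amplitude = amp, counts = counts, gate = gate)
  structure(list(assignment = assignment, thresholds = thresholds,
                 gate_counts = gate_counts, n_gates = G),
            class = "rmc_gates")
}

# Choose G-1 edges (indices into the sorted cumulative-count vector; edge e
# means "gates split after sorted bin e") minimising the max pairwise
# gate-count difference. Candidates are the few edges nearest each count
# quantile; exhaustive over the small candidate grid for G <= 6, greedy
# nearest-edge otherwise.
optimal_count_edges <- function(csum, total, G) {
  n <- length(csum)
  targets <- total * seq_len(G - 1) / G
  nearest <- vapply(targets, function(b) which.min(abs(csum - b)), 0L)
  cand <- lapply(seq_len(G - 1), function(g) {
    e <- nearest[g] + (-2:2)
    sort(unique(pmin(n - 1L, pmax(1L, e))))
  })
  if (G > 6) return(pmin(n - 1L, pmax(seq_len(G - 1), nearest)))
  grids <- do.call(expand.grid, cand)
  best <- NULL
  best_spread <- Inf
  for (r in seq_len(nrow(grids))) {
    e <- as.integer(grids[r, ])
    if (G > 2 && any(diff(e) < 1)) next
    gc <- diff(c(0, csum[e], total))
    spread <- max(gc) - min(gc)
    # enumeration order makes the first minimum the lowest-edge choice
    if (spread < best_spread) {
      best_spread <- spread
      best <- e
    }
  }
  best
}

#' @export
print.rmc_gates <- function(x, ...) {
  cat(sprintf("<rmc_gates> %d gates, counts: %s (max imbalance %d)\n",
              x$n_gates, paste(x$gate_counts, collapse = ", "),
              max(x$gate_counts) - min(x$gate_counts)))
  invisible(x)
}

#' Split a list-mode set into per-gate sets
#'
#' Every event is assigned the gate of its signal bin; the gate sets
#' partition the input (disjoint and exhaustive). Per-gate headers record the
#' gate index and amplitude range.
#'
#' @param listmode an `rmc_listmode`.
#' @param gates an `rmc_gates` from [equal_count_gates()].
#' @param bin_ms signal bin width used for the assignment, ms.
#' @return list of `rmc_listmode`, one per gate (index `0..G-1`).
#' @export
split_listmode <- function(listmode, gates, bin_ms = NULL) {
  asg <- gates$assignment
  if (is.null(bin_ms)) {
    bin_ms <- if (nrow(asg) > 1) round((asg$time_s[2] - asg$time_s[1]) * 1000)
              else 100
  }
  ev <- listmode$events
  bin <- ev$t_ms %/% bin_ms + 1L
  if (any(bin > nrow(asg)))
    stop("event timestamps extend beyond the gate assignment range")
  gate <- asg$gate[bin]
  lapply(0:(gates$n_gates - 1L), function(g) {
    sel <- gate == g
    h <- listmode$header
    h$gate <- g
    h$n_events <- sum(sel)
    amps <- asg$amplitude[asg$gate == g]
    h$amplitude_range <- if (length(amps)) range(amps) else c(NA_real_, NA_real_)
    new_listmode(ev[sel, , drop = FALSE], h)
  })
}
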