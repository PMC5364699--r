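# Ks distributions per pair class, kernel-density peak location and
# relative ordering of evolutionary events.

#' Gaussian kernel density of a Ks sample
#'
#' Density is evaluated on the fixed grid `0, 0.01, ..., ks_max`. Bandwidth
#' follows Silverman's rule of thumb (`stats::bw.nrd0`) unless a fixed
#' numeric bandwidth is given. Non-finite values and values above `ks_max`
#' are excluded and counted.
#'
#' @param values numeric Ks values.
#' @param pair_class label carried into the result.
#' @param ks_max upper end of the evaluation grid.
#' @param bandwidth `"silverman"` or a positive number.
#' @param step grid step.
#' @return object of class `ks_distribution`: list with `pair_class`,
#'   `values`, `grid`, `density`, `bandwidth`, `n`, `n_excluded`.
#' @export
ks_density <- function(values, pair_class = "ks", ks_max = 3.0,
                       bandwidth = "silverman", step = 0.01) {
  finite <- values[is.finite(values)]
  kept <- finite[finite <= ks_max & finite >= 0]
  n_excluded <- length(values) - length(kept)
  if (length(kept) < 10) {
    stop("insufficient sample: need >= 10 finite Ks values, got ",
         length(kept))
  }
  bw <- if (identical(bandwidth, "silverman")) {
    stats::bw.nrd0(kept)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  grid <- seq(0, ks_max, by = step)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = kept, sd = bw)),
                 numeric(1))
  structure(list(pair_class = pair_class, values = kept, grid = grid,
                 density = dens, bandwidth = bw, n = length(kept),
                 n_excluded = n_excluded),
            class = "ks_distribution")
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat("<ks_distribution> ", x$pair_class, ": n=", x$n, ", bw=",
      sprintf("%.4f", x$bandwidth), ", grid 0..",
      max(x$grid), "\n", sep = "")
  invisible(x)
}

#' Locate density peaks
#'
#' The primary mode is the grid argmax (leftmost grid point on a plateau,
#' flagged). Secondary modes are local maxima by discrete slope sign change,
#' suppressed when below 25% of the primary density.
#'
#' @param dist a `ks_distribution`.
#' @param min_rel_height secondary modes below this fraction of the primary
#'   density are suppressed.
#' @return list of class `ks_peaks`: `pair_class`, `primary_mode`,
#'   `primary_density`, `modes` (data.frame ks, density), `flat`.
#' @export
find_peaks <- function(dist, min_rel_height = 0.25) {
  d <- dist$density
  g <- dist$grid
  flat <- length(unique(d)) == 1
  if (flat) {
    mid <- g[ceiling(length(g) / 2)]
    return(structure(list(pair_class = dist$pair_class, primary_mode = mid,
                          primary_density = d[1],
                          modes = data.frame(ks = mid, density = d[1]),
                          flat = TRUE),
                     class = "ks_peaks"))
  }
  primary_i <- which.max(d)        # leftmost maximum on plateaus
  # local maxima detected on the run-length-compressed profile, so plateaus
  # count once (leftmost grid point of the run)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  max_runs <- vapply(seq_len(k), function(j) {
    left <- if (j == 1) -Inf else r$values[j - 1]
    right <- if (j == k) -Inf else r$values[j + 1]
    r$values[j] > left && r$values[j] > right
  }, logical(1))
  cand_i <- starts[max_runs]       # leftmost grid point of each maximal run
  keep <- d[cand_i] >= min_rel_height * d[primary_i]
  cand_i <- cand_i[keep]
  modes <- data.frame(ks = g[cand_i], density = d[cand_i])
  modes <- modes[order(-modes$density, modes$ks), , drop = FALSE]
  rownames(modes) <- NULL
  structure(list(pair_class = dist$pair_class, primary_mode = g[primary_i],
                 primary_density = d[primary_i], modes = modes,
                 flat = FALSE),
            class = "ks_peaks")
}

#' @export
print.ks_peaks <- function(x, ...) {
  cat("<ks_peaks> ", x$pair_class, ": primary mode at Ks=",
      sprintf("%.2f", x$primary_mode),
      if (x$flat) " [flat]" else "", "; ", nrow(x$modes), " mode(s)\n",
      sep = "")
  invisible(x)
}

#' Order evolutionary events by Ks peak position
#'
#' Classes are sorted by ascending primary mode: the smallest modal Ks is
#' the most recent event. Classes whose modes differ by at most one grid
#' step are reported as unresolved.
#'
#' @param peaks list of `ks_peaks` objects (one per pair class).
#' @param step grid step used to declare ties unresolved.
#' @return list of class `event_ordering`: `table` (class, mode, order; most
#'   recent first), `unresolved` (data.frame of tied class pairs) and a
#'   human-readable `statement`.
#' @export
order_events <- function(peaks, step = 0.01) {
  if (inherits(peaks, "ks_peaks")) peaks <- list(peaks)
  tab <- do.call(rbind, lapply(peaks, function(p) {
    data.frame(pair_class = p$pair_class, mode = p$primary_mode,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$mode, tab$pair_class), , drop = FALSE]
  tab$order <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  unresolved <- list()
  if (nrow(tab) > 1) {
    for (i in seq_len(nrow(tab) - 1)) {
      if (tab$mode[i + 1] - tab$mode[i] <= step + 1e-12) {
        unresolved[[length(unresolved) + 1]] <- data.frame(
          class_a = tab$pair_class[i], class_b = tab$pair_class[i + 1],
          stringsAsFactors = FALSE)
      }
    }
  }
  unresolved <- if (length(unresolved) > 0) {
    do.call(rbind, unresolved)
  } else {
    data.frame(class_a = character(0), class_b = character(0),
               stringsAsFactors = FALSE)
  }
  statement <- paste0(
    "event order, most recent first: ",
    paste(sprintf("%s (mode Ks=%.2f)", tab$pair_class, tab$mode),
          collapse = " < "),
    if (nrow(unresolved) > 0) {
      paste0(" [unresolved: ",
             paste(paste(unresolved$class_a, unresolved$class_b, sep = "~"),
                   collapse = ", "), "]")
    } else "")
  structure(list(table = tab, unresolved = unresolved,
                 statement = statement),
            class = "event_ordering")
}

#' @export
print.event_ordering <- function(x, ...) {
  cat("<event_ordering> ", x$statement, "\n", sep = "")
  invisible(x)
}
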