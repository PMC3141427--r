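# Windowed-identity dot plots: the homology engine behind JH discovery,
# CH-exon mapping seeds and zone-duplication detection.

#' Dot-plot parameters
#'
#' The identity threshold is applied as an integer match count
#' `ceiling(window * min_identity)` (27/30 at 85%, 18/30 at 60%), which
#' removes float-comparison ambiguity.
#'
#' @param window window length in nt.
#' @param min_identity minimum window identity in (0, 1].
#' @return list with `window`, `min_identity`, `min_matches`.
#' @export
dot_params <- function(window = 30L, min_identity = 0.85) {
  stopifnot(window >= 1L, min_identity > 0, min_identity <= 1)
  list(window = as.integer(window), min_identity = min_identity,
       min_matches = as.integer(ceiling(window * min_identity)))
}

#' Windowed-identity dot-plot match cells
#'
#' A cell (i, j) is reported iff the window `a[i, i+w)` vs `b[j, j+w)` has
#' identity at or above the threshold; the enumeration is exhaustive over
#' all window pairs on common diagonals. N never matches. With
#' `orientation = "reverse"` the comparison is against the reverse
#' complement of `b`; reported `j` is then the 0-based start of the window
#' on the *forward* `b` coordinates.
#'
#' @param a,b sequences (character scalars).
#' @param params a [dot_params()] list.
#' @param orientation "forward" or "reverse".
#' @return data.frame with 0-based `i`, `j`, `identity`, `orientation`.
#' @export
dot_matches <- function(a, b, params = dot_params(), orientation = "forward") {
  stopifnot(orientation %in% c("forward", "reverse"))
  a <- normalize_residues(a, "a"); b <- normalize_residues(b, "b")
  w <- params$window
  if (nchar(a) < w || nchar(b) < w) {
    warning("sequence shorter than window; no match cells")
    return(data.frame(i = integer(0), j = integer(0), identity = numeric(0),
                      orientation = character(0)))
  }
  btxt <- if (orientation == "reverse") revcomp(b) else b
  cells <- .dot_matches_cpp(a, btxt, w, params$min_matches)
  cells <- as.data.frame(cells)
  if (orientation == "reverse" && nrow(cells)) {
    cells$j <- nchar(b) - cells$j - w
  }
  data.frame(i = cells$i, j = cells$j, identity = cells$matches / w,
             orientation = rep(orientation, nrow(cells)),
             stringsAsFactors = FALSE)
}

#' Merge dot-plot cells into diagonal runs
#'
#' Cells on the same diagonal (constant i - j in the comparison frame)
#' whose window starts are within `max_gap + 1` of each other are merged
#' into one run. Runs are sorted by length descending; each cell belongs to
#' at most one run. `max_gap = 0` requires strictly contiguous cells.
#'
#' @param matches output of [dot_matches()] (single orientation).
#' @param window window used to produce `matches`.
#' @param max_gap largest tolerated gap (in window starts) within a run.
#' @return data.frame with `a_start`, `b_start`, `length`, `mean_identity`,
#'   `orientation`, `n_cells` (`b_start` is the forward-strand start of the
#'   run's span on b for both orientations).
#' @export
merge_diagonals <- function(matches, window, max_gap = 0L) {
  empty <- data.frame(a_start = integer(0), b_start = integer(0),
                      length = integer(0), mean_identity = numeric(0),
                      orientation = character(0), n_cells = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(empty)
  ori <- unique(matches$orientation)
  stopifnot(length(ori) == 1L)
  # comparison-frame j: reverse-orientation cells advance right-to-left on b
  jc <- if (ori == "reverse") -matches$j else matches$j
  d <- matches$i - jc
  runs <- list()
  for (dd in unique(d)) {
    sub <- matches[d == dd, , drop = FALSE]
    sub <- sub[order(sub$i), , drop = FALSE]
    brk <- c(0L, which(diff(sub$i) > max_gap + 1L), nrow(sub))
    for (k in seq_len(length(brk) - 1L)) {
      blk <- sub[(brk[k] + 1L):brk[k + 1L], , drop = FALSE]
      a0 <- blk$i[1L]; a1 <- blk$i[nrow(blk)]
      b_span_start <- min(blk$j)
      runs[[length(runs) + 1L]] <- data.frame(
        a_start = a0, b_start = b_span_start,
        length = a1 - a0 + window,
        mean_identity = mean(blk$identity),
        orientation = ori, n_cells = nrow(blk),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, runs)
  out <- out[order(-out$length, out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect segmental duplications between two sequences
#'
#' Dot-plot matching at window 30 and 85% identity followed by diagonal-run
#' merging, in both orientations. When `a` and `b` are the same sequence the
#' trivial main diagonal is excluded.
#'
#' @param a,b sequences.
#' @param params a [dot_params()]; defaults to window 30, 85% identity.
#' @param max_gap run-merging gap tolerance.
#' @param min_length discard runs shorter than this many nt.
#' @return data.frame of diagonal runs as from [merge_diagonals()].
#' @export
detect_duplications <- function(a, b = a, params = dot_params(30L, 0.85),
                                max_gap = 0L, min_length = params$window) {
  self <- identical(a, b)
  out <- list()
  for (ori in c("forward", "reverse")) {
    cells <- suppressWarnings(dot_matches(a, b, params, orientation = ori))
    if (self && ori == "forward" && nrow(cells)) {
      cells <- cells[cells$i != cells$j, , drop = FALSE]
    }
    if (nrow(cells)) {
      out[[length(out) + 1L]] <- merge_diagonals(cells, params$window, max_gap)
    }
  }
  if (!length(out)) return(merge_diagonals(
    data.frame(i = integer(0), j = integer(0), identity = numeric(0),
               orientation = character(0)), params$window, max_gap))
  res <- do.call(rbind, out)
  res <- res[res$length >= min_length, , drop = FALSE]
  res <- res[order(-res$length, res$a_start, res$b_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of positions of `a` covered by diagonal runs
#'
#' @param runs data.frame from [merge_diagonals()] / [detect_duplications()].
#' @param interval optional 0-based half-open `c(start, end)` restricting the
#'   span of `a` over which coverage is measured.
#' @param a_len length of `a` (required when `interval` is NULL).
#' @return covered fraction in \[0, 1\].
#' @export
run_coverage <- function(runs, interval = NULL, a_len = NULL) {
  if (is.null(interval)) {
    stopifnot(!is.null(a_len))
    interval <- c(0L, a_len)
  }
  span <- interval[2L] - interval[1L]
  if (span <= 0L || nrow(runs) == 0L) return(0)
  cov <- logical(span)
  for (k in seq_len(nrow(runs))) {
    s <- max(runs$a_start[k], interval[1L]) - interval[1L]
    e <- min(runs$a_start[k] + runs$length[k], interval[2L]) - interval[1L]
    if (e > s) cov[(s + 1L):e] <- TRUE
  }
  mean(cov)
}
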