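# Independent brute-force oracles. Deliberately naive: plain substr loops,
# no sharing with the package's scanning code.

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

oracle_scan_motif <- function(seq, motif, max_mm) {
  n <- nchar(seq); w <- nchar(motif)
  out <- list()
  if (w <= n) {
    for (p in 0:(n - w)) {
      d <- oracle_hamming(substr(seq, p + 1L, p + w), motif)
      if (d <= max_mm) out[[length(out) + 1L]] <- c(p, d)
    }
  }
  if (!length(out)) return(data.frame(pos = integer(0), mismatches = integer(0)))
  m <- do.call(rbind, out)
  data.frame(pos = m[, 1L], mismatches = m[, 2L])
}

oracle_revcomp <- function(x) {
  ch <- rev(strsplit(x, "")[[1L]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch], collapse = "")
}

# enumerate RSS hits on one strand text by explicit double loops
.oracle_rss_one <- function(seq, hept, nona, hmm, nmm, sclass, slack) {
  n <- nchar(seq)
  rows <- list()
  spacers <- (sclass - slack):(sclass + slack)
  # downstream_of_coding: heptamer then nonamer
  for (p in 0:max(-1L, n - 7L)) {
    if (oracle_hamming(substr(seq, p + 1L, p + 7L), hept) > hmm) next
    for (s in spacers) {
      q <- p + 7L + s
      if (q + 9L > n) next
      dn <- oracle_hamming(substr(seq, q + 1L, q + 9L), nona)
      if (dn <= nmm) {
        rows[[length(rows) + 1L]] <- data.frame(
          orientation = "downstream_of_coding", hept_start = p,
          nona_start = q, spacer_len = s, stringsAsFactors = FALSE)
      }
    }
  }
  # upstream_of_coding: revcomp(nonamer) then revcomp(heptamer)
  rcn <- oracle_revcomp(nona); rch <- oracle_revcomp(hept)
  for (p in 0:max(-1L, n - 9L)) {
    if (oracle_hamming(substr(seq, p + 1L, p + 9L), rcn) > nmm) next
    for (s in spacers) {
      q <- p + 9L + s
      if (q + 7L > n) next
      dh <- oracle_hamming(substr(seq, q + 1L, q + 7L), rch)
      if (dh <= hmm) {
        rows[[length(rows) + 1L]] <- data.frame(
          orientation = "upstream_of_coding", hept_start = q,
          nona_start = p, spacer_len = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

oracle_scan_rss <- function(seq, hept = "CACAGTG", nona = "TATTATTGT",
                            hmm = 1L, nmm = 2L, sclass = 23L, slack = 1L,
                            strand = "both") {
  n <- nchar(seq)
  out <- list()
  if (strand %in% c("+", "both")) {
    f <- .oracle_rss_one(seq, hept, nona, hmm, nmm, sclass, slack)
    if (!is.null(f)) { f$strand <- "+"; out[[length(out) + 1L]] <- f }
  }
  if (strand %in% c("-", "both")) {
    r <- .oracle_rss_one(oracle_revcomp(seq), hept, nona, hmm, nmm, sclass, slack)
    if (!is.null(r)) {
      hs <- r$hept_start; ns <- r$nona_start
      r$hept_start <- n - (hs + 7L)
      r$nona_start <- n - (ns + 9L)
      r$strand <- "-"
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out)) {
    return(data.frame(orientation = character(0), hept_start = integer(0),
                      nona_start = integer(0), spacer_len = integer(0),
                      strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$hept_start, res$nona_start, res$strand, res$orientation), ]
}

oracle_dot <- function(a, b, w, min_identity) {
  na <- nchar(a); nb <- nchar(b)
  need <- ceiling(w * min_identity)
  rows <- list()
  for (i in 0:(na - w)) {
    wa <- substr(a, i + 1L, i + w)
    for (j in 0:(nb - w)) {
      mm <- oracle_hamming(wa, substr(b, j + 1L, j + w))
      if (w - mm >= need) rows[[length(rows) + 1L]] <- c(i, j, w - mm)
    }
  }
  if (!length(rows)) {
    return(data.frame(i = integer(0), j = integer(0), matches = integer(0)))
  }
  m <- do.call(rbind, rows)
  data.frame(i = m[, 1L], j = m[, 2L], matches = m[, 3L])
}

# union-find over cells: same diagonal, window starts within max_gap + 1
oracle_merge <- function(cells, w, max_gap = 0L) {
  n <- nrow(cells)
  if (n == 0L) return(data.frame(a_start = integer(0), b_start = integer(0),
                                 length = integer(0), n_cells = integer(0)))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (p < q && (cells$i[p] - cells$j[p]) == (cells$i[q] - cells$j[q]) &&
        abs(cells$i[p] - cells$i[q]) <= max_gap + 1L) {
      parent[find(p)] <- find(q)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    data.frame(a_start = min(cells$i[idx]), b_start = min(cells$j[idx]),
               length = max(cells$i[idx]) - min(cells$i[idx]) + w,
               n_cells = length(idx))
  })
  res <- do.call(rbind, out)
  res[order(res$a_start, res$b_start), ]
}

oracle_amplicon <- function(template, fwd, rev, max_mm = 0L) {
  n <- nchar(template); lf <- nchar(fwd); lr <- nchar(rev)
  rcr <- oracle_revcomp(rev)
  rows <- list()
  for (i in 0:(n - lf)) {
    if (oracle_hamming(substr(template, i + 1L, i + lf), fwd) > max_mm) next
    for (j in 0:(n - lr)) {
      if (j < i + lf) next
      if (oracle_hamming(substr(template, j + 1L, j + lr), rcr) > max_mm) next
      rows[[length(rows) + 1L]] <- c(i, j + lr)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, rows)
  res <- data.frame(start = m[, 1L], end = m[, 2L])
  res[order(res$start, res$end), ]
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
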