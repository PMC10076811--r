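#' CRISPR detection parameters
#'
#' Defaults follow the published defaults of the CRISPR Recognition Tool
#' family of detectors: at least 3 repeat copies, repeat length 19-38 bp,
#' spacer length 19-48 bp, search window (seed word) 8 bp, and at most 2
#' mismatches per repeat copy against the column-majority consensus.
#'
#' @param min_repeats minimum number of repeat copies in an array.
#' @param repeat_len length-2 integer vector: repeat length bounds.
#' @param spacer_len length-2 integer vector: spacer length bounds.
#' @param window seed word length for repeat discovery.
#' @param max_mismatch maximum mismatches of a repeat copy vs consensus.
#' @return a named list of parameters.
#' @export
crispr_params <- function(min_repeats = 3L, repeat_len = c(19L, 38L),
                          spacer_len = c(19L, 48L), window = 8L,
                          max_mismatch = 2L) {
  stopifnot(min_repeats >= 2L, repeat_len[1] <= repeat_len[2],
            spacer_len[1] <= spacer_len[2], window >= 4L)
  list(min_repeats = as.integer(min_repeats),
       repeat_len = as.integer(repeat_len),
       spacer_len = as.integer(spacer_len),
       window = as.integer(window),
       max_mismatch = as.integer(max_mismatch))
}

#' Detect CRISPR arrays in a host genome
#'
#' Seed-scanning detector in the style of the CRISPR Recognition Tool:
#' a repeated seed word at a period compatible with one repeat plus one
#' spacer nominates a candidate array; the chain of repeat copies is
#' grown by re-seeding from the last copy (so each copy may carry its own
#' point mutations), and repeat boundaries are then refined column by
#' column across copies. A boundary column is accepted when all copies
#' agree, or when it bridges an isolated disagreement flanked by two
#' agreeing columns, within the per-copy mismatch budget. Arrays within
#' one genome are non-overlapping; coordinates are 0-based half-open.
#'
#' @param host single genome: a named one-record
#'   \link[Biostrings]{DNAStringSet} or a nucleotide string.
#' @param params see \code{\link{crispr_params}}.
#' @return list of arrays; each is a list with \code{host_id},
#'   \code{start}, \code{end} (0-based half-open span of the array),
#'   \code{repeat_seq} (consensus), \code{repeat_starts} (0-based starts
#'   of each copy), \code{repeat_len}, and \code{spacers} (character
#'   vector, in order). Empty list when nothing qualifies.
#' @export
detect_crispr_arrays <- function(host, params = crispr_params()) {
  if (is(host, "DNAStringSet")) {
    host_id <- names(host)[1]
    s <- as.character(host[[1]])
  } else {
    host_id <- "host"
    s <- toupper(as.character(host))
  }
  p <- params
  v <- seq_ints(s)
  L <- length(v)
  w <- p$window
  dmin <- p$repeat_len[1] + p$spacer_len[1]
  dmax <- p$repeat_len[2] + p$spacer_len[2]
  if (L < p$min_repeats * p$repeat_len[1] +
        (p$min_repeats - 1L) * p$spacer_len[1]) return(list())
  code <- word_codes(v, w)
  n <- length(code)
  # discovery: seed pairs (i, i+d) with the same word, d in [dmin, dmax]
  cand <- NULL
  for (d in dmin:dmax) {
    if (n - d < 1L) break
    i <- which(code[seq_len(n - d)] == code[(1L + d):n])
    i <- i[!is.na(code[i])]
    if (length(i)) cand <- rbind(cand, cbind(i = i, d = d))
  }
  if (is.null(cand)) return(list())
  cand <- cand[order(cand[, "i"], cand[, "d"]), , drop = FALSE]
  arrays <- list()
  scan_from <- 1L
  for (r in seq_len(nrow(cand))) {
    i <- unname(cand[r, "i"])
    if (i < scan_from) next
    arr <- build_array(v, code, i, unname(cand[r, "d"]), p)
    if (is.null(arr)) next
    arr$host_id <- host_id
    arr$repeat_seq <- paste(c("A", "C", "G", "T")[arr$consensus],
                            collapse = "")
    arr$consensus <- NULL
    arrays[[length(arrays) + 1L]] <- arr
    scan_from <- arr$end + 1L   # past the accepted array
  }
  arrays
}

# Next/previous copy of the word neighbourhood around anchor `last`,
# searching distances [dmin, dmax] in the given direction. Re-seeding
# from offsets around the anchor lets the chain survive point mutations
# in any one copy. Returns the aligned anchor position or NA.
#' @keywords internal
chain_step <- function(v, code, last, p, dir) {
  w <- p$window
  dmin <- p$repeat_len[1] + p$spacer_len[1]
  dmax <- p$repeat_len[2] + p$spacer_len[2]
  off_max <- p$repeat_len[2] - w
  n <- length(code)
  L <- length(v)
  # exact-match run through the seed word at (a, b): a true repeat copy
  # extends well beyond the seed, a random word collision does not
  run_len <- function(a, b) {
    l <- 0L
    while (a - l - 1L >= 1L && b - l - 1L >= 1L &&
           v[a - l - 1L] == v[b - l - 1L] && v[a - l - 1L] != 0L)
      l <- l + 1L
    r <- 0L
    while (a + w + r <= L && b + w + r <= L &&
           v[a + w + r] == v[b + w + r] && v[a + w + r] != 0L)
      r <- r + 1L
    w + l + r
  }
  best <- NA_integer_; best_score <- -1L
  for (o in 0:off_max) {
    for (sgn in if (o == 0L) 1L else c(1L, -1L)) {
      pos <- last + sgn * o
      if (pos < 1L || pos > n || is.na(code[pos])) next
      for (d in dmin:dmax) {
        tgt <- pos + dir * d
        if (tgt < 1L || tgt > n || is.na(code[tgt])) next
        if (code[pos] != code[tgt]) next
        sc <- run_len(pos, tgt)
        if (sc > best_score) {
          best_score <- sc
          best <- tgt - sgn * o
        }
      }
    }
  }
  best
}

# Grow and refine one candidate array anchored at seed position i with
# period d. Exact-word chaining both ways, preliminary boundary
# refinement, consensus rescue of copies with no intact seed word, then
# strict refinement. Returns NULL if the candidate does not qualify.
#' @keywords internal
build_array <- function(v, code, i, d, p) {
  anchors <- c(i, i + d)
  repeat {                                      # forward
    nxt <- chain_step(v, code, anchors[length(anchors)], p, 1L)
    if (is.na(nxt) || nxt <= anchors[length(anchors)]) break
    anchors <- c(anchors, nxt)
    if (length(anchors) > 60L) break
  }
  repeat {                                      # backward
    prv <- chain_step(v, code, anchors[1L], p, -1L)
    if (is.na(prv) || prv >= anchors[1L]) break
    anchors <- c(prv, anchors)
    if (length(anchors) > 60L) break
  }
  # anchors at either end can be random collisions; take the longest
  # contiguous anchor window that refines to a qualifying repeat
  n <- length(anchors)
  prelim <- NULL
  for (len in n:2) {
    for (s0 in 1:(n - len + 1L)) {
      prelim <- refine_bounds(v, anchors[s0:(s0 + len - 1L)], p)
      if (!is.null(prelim)) break
    }
    if (!is.null(prelim)) break
  }
  if (is.null(prelim)) return(NULL)
  starts <- rescue_copies(v, prelim, p)
  if (length(starts) < p$min_repeats) return(NULL)
  refine_array(v, starts, p)
}

# Add copies before/after the known ones wherever a stretch at a
# spacing compatible with the bounds matches the consensus within twice
# the per-copy budget (the preliminary consensus may itself carry
# mutated columns). Returns the updated starts.
#' @keywords internal
rescue_copies <- function(v, prelim, p) {
  starts <- prelim$starts
  rl <- prelim$rep_len
  cons <- prelim$cons
  L <- length(v)
  # generous: the preliminary consensus may carry mutated or
  # over-extended columns; strict refinement re-validates every copy
  lim <- 2L * p$max_mismatch + 2L
  probe <- function(q) {
    if (q < 1L || q + rl - 1L > L) return(Inf)
    b <- v[q + 0:(rl - 1L)]
    if (any(b == 0L)) return(Inf)
    sum(b != cons)
  }
  repeat {                                      # before the first copy
    qs <- (starts[1L] - rl - p$spacer_len[2]):
          (starts[1L] - rl - p$spacer_len[1])
    mm <- vapply(qs, probe, numeric(1))
    if (min(mm) > lim) break
    starts <- c(qs[which.min(mm)], starts)
    if (length(starts) > 60L) break
  }
  repeat {                                      # after the last copy
    qs <- (starts[length(starts)] + rl + p$spacer_len[1]):
          (starts[length(starts)] + rl + p$spacer_len[2])
    mm <- vapply(qs, probe, numeric(1))
    if (min(mm) > lim) break
    starts <- c(starts, qs[which.min(mm)])
    if (length(starts) > 60L) break
  }
  starts
}

# Column-wise boundary extension across aligned repeat copies. A column
# is accepted when all copies agree; a run of at most 2 disagreeing
# columns is bridged when the column beyond it is unanimous again,
# within a per-copy mismatch budget. Extension stops at the maximum
# repeat length and never eats a spacer below its minimum. Returns
# starts, rep_len and the column-majority consensus, or NULL when the
# refined repeat is shorter than the minimum.
#' @keywords internal
refine_bounds <- function(v, anchors, p) {
  w <- p$window
  nc <- length(anchors)
  L <- length(v)
  budget <- integer(nc)            # mismatches charged per copy
  gaps <- diff(anchors)
  col_state <- function(t) {
    pos <- anchors + t
    if (any(pos < 1L | pos > L)) return(NULL)
    b <- v[pos]
    if (any(b == 0L)) return(NULL)
    tab <- tabulate(b, 4L)
    list(b = b, tab = tab, ok = max(tab) == nc)
  }
  # charge a disagreeing column: among tied majority bases pick the one
  # that keeps the worst per-copy load smallest (a fixed tie-break would
  # pile all charges of a 2-copy alignment onto one copy)
  charge <- function(st, load) {
    cand <- which(st$tab == max(st$tab))
    best <- NULL
    for (mb in cand) {
      nl <- load + (st$b != mb)
      if (is.null(best) || max(nl) < max(best)) best <- nl
    }
    best
  }
  ext_left <- 0L; ext_right <- 0L
  # extra columns are admissible while the repeat stays within its
  # maximum length and the shortest spacer above its minimum
  room <- function(extra) {
    tl <- w + ext_left + ext_right + extra
    tl <= p$repeat_len[2] &&
      (nc < 2L || min(gaps) - tl >= p$spacer_len[1])
  }
  accept <- function(dir, ncols) {
    if (dir > 0) ext_right <<- ext_right + ncols
    else ext_left <<- ext_left + ncols
  }
  step <- function(dir) {
    t0 <- if (dir > 0) (w - 1L) + ext_right + 1L else -(ext_left + 1L)
    st0 <- col_state(t0)
    if (is.null(st0)) return(FALSE)
    if (st0$ok) {
      if (!room(1L)) return(FALSE)
      accept(dir, 1L)
      return(TRUE)
    }
    for (run in 1:2) {
      cols <- lapply(0:run, function(j) col_state(t0 + dir * j))
      if (any(vapply(cols, is.null, logical(1)))) return(FALSE)
      if (!cols[[run + 1L]]$ok) next      # no unanimous closing column
      nb <- budget
      for (s in cols[seq_len(run)]) nb <- charge(s, nb)
      if (any(nb > p$max_mismatch)) return(FALSE)
      if (!room(run + 1L)) return(FALSE)
      budget <<- nb
      accept(dir, run + 1L)
      return(TRUE)
    }
    FALSE
  }
  while (step(-1L)) {}
  while (step(1L)) {}
  rep_len <- w + ext_left + ext_right
  if (rep_len < p$repeat_len[1]) return(NULL)
  starts <- anchors - ext_left
  if (starts[1] < 1L || starts[nc] + rep_len - 1L > L) return(NULL)
  cons <- vapply(0:(rep_len - 1L), function(t)
    which.max(tabulate(v[starts + t], 4L)), integer(1))
  list(starts = starts, rep_len = rep_len, cons = cons)
}

# Trim copies violating the per-copy mismatch budget (edges first) or
# the spacer bounds. Returns the surviving starts or NULL.
#' @keywords internal
trim_copies <- function(v, starts, rl, p) {
  repeat {
    if (length(starts) < p$min_repeats) return(NULL)
    cons <- vapply(0:(rl - 1L), function(t)
      which.max(tabulate(v[starts + t], 4L)), integer(1))
    mm <- vapply(starts, function(s)
      sum(v[s + 0:(rl - 1L)] != cons), integer(1))
    if (mm[1L] > p$max_mismatch) { starts <- starts[-1L]; next }
    if (mm[length(mm)] > p$max_mismatch) {
      starts <- starts[-length(starts)]; next
    }
    if (any(mm > p$max_mismatch)) return(NULL)
    break
  }
  repeat {
    k <- length(starts)
    if (k < p$min_repeats) return(NULL)
    sp <- diff(starts) - rl
    if (all(sp >= p$spacer_len[1] & sp <= p$spacer_len[2])) break
    if (sp[k - 1L] < p$spacer_len[1] || sp[k - 1L] > p$spacer_len[2])
      starts <- starts[-k]
    else starts <- starts[-1L]
  }
  starts
}

# Strict refinement of a candidate copy set: alternate boundary
# extension and copy trimming until stable (a trimmed spurious copy can
# have capped the extension), then assemble the final array.
#' @keywords internal
refine_array <- function(v, anchors, p) {
  starts <- anchors
  rb <- NULL
  for (iter in 1:6) {
    rb <- refine_bounds(v, starts, p)
    if (is.null(rb)) return(NULL)
    kept <- trim_copies(v, rb$starts, rb$rep_len, p)
    if (is.null(kept)) return(NULL)
    if (identical(kept, rb$starts)) break
    starts <- kept
    rb <- NULL
  }
  if (is.null(rb)) return(NULL)
  starts <- rb$starts
  rl <- rb$rep_len
  k <- length(starts)
  cons <- vapply(0:(rl - 1L), function(t)
    which.max(tabulate(v[starts + t], 4L)), integer(1))
  ends <- starts + rl - 1L
  spacers <- vapply(seq_len(k - 1L), function(j) {
    paste(c("A", "C", "G", "T")[v[(ends[j] + 1L):(starts[j + 1L] - 1L)]],
          collapse = "")
  }, character(1))
  list(start = starts[1L] - 1L, end = ends[k],
       repeat_starts = starts - 1L, repeat_len = rl,
       consensus = cons, spacers = spacers)
}

#' Build the pooled spacer database for a bundle
#'
#' Runs array detection on every reference host genome and pools all
#' spacers with their provenance. Duplicate spacer sequences from
#' different hosts are kept as separate entries.
#'
#' @param bundle a \code{"ref_bundle"}.
#' @param params see \code{\link{crispr_params}}.
#' @return object of class \code{"spacer_db"}: data.frame with columns
#'   spacer_id, host_id, spacer_seq.
#' @export
build_spacer_db <- function(bundle, params = crispr_params()) {
  rows <- list()
  for (h in names(bundle$hosts)) {
    arrays <- detect_crispr_arrays(bundle$hosts[h], params)
    for (ai in seq_along(arrays)) {
      sp <- arrays[[ai]]$spacers
      if (!length(sp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_id = sprintf("%s_arr%d_sp%d", h, ai, seq_along(sp)),
        host_id = h, spacer_seq = sp, stringsAsFactors = FALSE)
    }
  }
  db <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spacer_id = character(), host_id = character(),
               spacer_seq = character(), stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("spacer_db", "data.frame")
  db
}

#' Persist / load a spacer database
#'
#' FASTA with record IDs \code{spacer_id|host_id}, plus a TSV index.
#'
#' @param db a \code{"spacer_db"}.
#' @param fasta,tsv output paths.
#' @return invisibly, the paths (write) or the \code{"spacer_db"} (read).
#' @export
write_spacer_db <- function(db, fasta, tsv) {
  seqs <- Biostrings::DNAStringSet(db$spacer_seq)
  names(seqs) <- paste(db$spacer_id, db$host_id, sep = "|")
  Biostrings::writeXStringSet(seqs, fasta)
  write.table(as.data.frame(db), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_spacer_db
#' @export
read_spacer_db <- function(tsv) {
  db <- read.table(tsv, header = TRUE, sep = "\t",
                   colClasses = "character")
  class(db) <- c("spacer_db", "data.frame")
  db
}

#' Predict a host from CRISPR spacer evidence
#'
#' The phage genome is searched against the pooled spacers in
#' short-query mode (spacers are 19-48 bp). A spacer hit means the host
#' has archived a fragment of this (or a close) phage: the host of the
#' top spacer hit is assigned when the e-value passes the cutoff. Ties
#' on bit score break by e-value, then by the lexicographically smaller
#' host ID.
#'
#' @param phage single-record named \link[Biostrings]{DNAStringSet}.
#' @param spacers a \code{"spacer_db"}.
#' @param e_cutoff e-value threshold (cascade default 1e-2).
#' @param backend see \code{\link{ph_search}}.
#' @return an \code{"alignment_prediction"} with method \code{"crispr"}.
#' @export
crispr_predict <- function(phage, spacers, e_cutoff = 1e-2,
                           backend = "auto") {
  stopifnot(length(phage) == 1L)
  if (nrow(spacers) == 0L)
    return(alignment_prediction(names(phage), NA_character_, NA_real_,
                                "crispr"))
  tg <- Biostrings::DNAStringSet(spacers$spacer_seq)
  names(tg) <- spacers$spacer_id
  hits <- ph_search(phage, tg, "short_query", e_cutoff, backend)
  if (nrow(hits) == 0L)
    return(alignment_prediction(names(phage), NA_character_, NA_real_,
                                "crispr"))
  hits$host_id <- spacers$host_id[match(hits$target_id,
                                        spacers$spacer_id)]
  ord <- order(-hits$bit_score, hits$e_value, hits$host_id,
               hits$target_id)
  th <- hits[ord[1L], ]
  alignment_prediction(names(phage), th$host_id, th$e_value, "crispr")
}
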