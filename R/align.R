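#' Pairwise nucleotide similarity search
#'
#' Searches every query genome against a target database and returns hits
#' as (query_id, target_id, bit_score, e_value) rows, the currency of all
#' alignment-based predictors. Two interchangeable backends satisfy the
#' same contract:
#' \describe{
#'   \item{\code{"blast"}}{the external BLAST+ \code{blastn} binary
#'     (tabular outfmt 6); \code{mode = "short_query"} maps to the
#'     \code{blastn-short} task used for spacer-sized targets.}
#'   \item{\code{"internal"}}{a built-in exact-seed aligner: shared words
#'     (word size 11 standard, 7 short-query) anchor ungapped extension
#'     along the diagonal; the bit score is twice the number of matched
#'     bases in the best segment and the e-value is the Karlin-Altschul
#'     form \eqn{E = m n 2^{-S}} with m the query length and n the total
#'     database length. Searches the given strand only (the external
#'     backend also searches the reverse complement). Only ordering and
#'     thresholding semantics matter downstream, which this backend
#'     preserves.}
#' }
#' \code{"auto"} uses blastn when it is on the PATH, else the internal
#' backend.
#'
#' @param queries,targets named \link[Biostrings]{DNAStringSet}s.
#' @param mode \code{"standard"} or \code{"short_query"}.
#' @param e_cutoff keep hits with e-value at or below this.
#' @param backend \code{"auto"}, \code{"blast"} or \code{"internal"}.
#' @return data.frame (query_id, target_id, bit_score, e_value) sorted by
#'   query, then bit score descending, e-value ascending, target ID.
#' @export
ph_search <- function(queries, targets, mode = c("standard", "short_query"),
                      e_cutoff = 10, backend = c("auto", "blast",
                                                 "internal")) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (length(queries) == 0L || length(targets) == 0L)
    stop("empty query or target collection")
  if (backend == "auto")
    backend <- if (has_blast()) "blast" else "internal"
  hits <- switch(backend,
    blast = blast_search(queries, targets, mode, e_cutoff),
    internal = internal_search(queries, targets, mode, e_cutoff))
  hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  # keep e-values strictly positive (blastn prints 0 for overwhelming hits)
  hits$e_value <- pmax(hits$e_value, 1e-300)
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value,
               hits$target_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @keywords internal
has_blast <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

#' @keywords internal
empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             bit_score = numeric(), e_value = numeric(),
             stringsAsFactors = FALSE)
}

#' @keywords internal
blast_search <- function(queries, targets, mode, e_cutoff) {
  if (!has_blast()) stop("blastn/makeblastdb not found on PATH")
  wd <- tempfile("blast")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  qf <- file.path(wd, "q.fasta"); tf <- file.path(wd, "t.fasta")
  Biostrings::writeXStringSet(queries, qf)
  Biostrings::writeXStringSet(targets, tf)
  db <- file.path(wd, "db")
  st <- system2("makeblastdb", c("-in", tf, "-dbtype", "nucl",
                                 "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed")
  out <- file.path(wd, "hits.tsv")
  task <- if (mode == "short_query") "blastn-short" else "blastn"
  st <- system2("blastn",
                c("-task", task, "-query", qf, "-db", db,
                  "-evalue", format(e_cutoff, scientific = TRUE),
                  "-outfmt", shQuote("6 qseqid sseqid bitscore evalue"),
                  "-num_threads", "1", "-dust", "no",
                  "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastn failed")
  if (file.size(out) == 0L) return(empty_hits())
  tab <- read.table(out, sep = "\t", col.names = c("query_id",
                    "target_id", "bit_score", "e_value"),
                    colClasses = c("character", "character", "numeric",
                                   "numeric"))
  tab
}

# ---- internal exact-seed fallback aligner ----------------------------

# Encode a sequence as an integer vector (A=1,C=2,G=3,T=4, N=0).
#' @keywords internal
seq_ints <- function(s) {
  match(strsplit(as.character(s), "")[[1]],
        c("A", "C", "G", "T"), nomatch = 0L)
}

# Positions of every word of width w as integers (base-4 packing);
# words containing N get NA.
#' @keywords internal
word_codes <- function(v, w) {
  L <- length(v)
  if (L < w) return(integer(0))
  n <- L - w + 1L
  code <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    b <- v[j:(j + n - 1L)]
    bad <- bad | b == 0L
    code <- code * 4 + (b - 1L)
  }
  code[bad] <- NA_real_
  code
}

#' @keywords internal
internal_search <- function(queries, targets, mode, e_cutoff) {
  w <- if (mode == "short_query") 7L else 11L
  tvecs <- lapply(seq_along(targets),
                  function(i) seq_ints(targets[[i]]))
  names(tvecs) <- names(targets)
  twords <- lapply(tvecs, word_codes, w = w)
  dblen <- sum(lengths(tvecs))
  rows <- list()
  for (qi in seq_along(queries)) {
    qv <- seq_ints(queries[[qi]])
    qw <- word_codes(qv, w)
    if (!length(qw)) next
    for (ti in seq_along(tvecs)) {
      hit <- align_pair(qv, qw, tvecs[[ti]], twords[[ti]], w, dblen)
      if (!is.null(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = names(queries)[qi], target_id = names(tvecs)[ti],
          bit_score = hit["bit"], e_value = hit["e"],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Best ungapped alignment between one query and one target: shared seed
# words define candidate diagonals; on each diagonal the best-scoring
# segment (match +2 / mismatch -3, Kadane scan) that still contains an
# intact seed word is kept. Returns c(bit, e) or NULL.
#' @keywords internal
align_pair <- function(qv, qw, tv, tw, w, dblen) {
  shared <- intersect(qw[!is.na(qw)], tw[!is.na(tw)])
  if (!length(shared)) return(NULL)
  qpos <- which(qw %in% shared)
  # diagonals (qpos - tpos) holding at least one shared word
  diags <- unique(unlist(lapply(qpos, function(p) {
    p - which(tw == qw[p])
  })))
  best_bit <- -Inf
  for (d in diags) {
    # overlap of query i and target i-d
    i0 <- max(1L, 1L + d); i1 <- min(length(qv), length(tv) + d)
    if (i1 - i0 + 1L < w) next
    qs <- qv[i0:i1]; ts <- tv[(i0 - d):(i1 - d)]
    m <- qs == ts & qs != 0L
    sc <- ifelse(m, 2, -3)
    # Kadane with segment tracking
    cur <- 0; cur_start <- 1L
    best <- -Inf; b0 <- 1L; b1 <- 1L
    for (j in seq_along(sc)) {
      if (cur <= 0) { cur <- 0; cur_start <- j }
      cur <- cur + sc[j]
      if (cur > best) { best <- cur; b0 <- cur_start; b1 <- j }
    }
    if (best <= 0) next
    seg <- m[b0:b1]
    # require an intact seed word inside the segment
    r <- rle(seg)
    if (!any(r$values & r$lengths >= w)) next
    bit <- 2 * sum(seg)
    if (bit > best_bit) best_bit <- bit
  }
  if (!is.finite(best_bit)) return(NULL)
  e <- length(qv) * dblen * 2^(-best_bit)
  c(bit = best_bit, e = e)
}
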