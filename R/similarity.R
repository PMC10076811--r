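# Top hit among a hit table: max bit score, then min e-value, then
# lexicographically smallest target ID. Deterministic total order.
#' @keywords internal
top_hit <- function(hits) {
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$bit_score, hits$e_value, hits$target_id)
  hits[ord[1L], , drop = FALSE]
}

#' @keywords internal
alignment_prediction <- function(phage_id, host_id, e_value, method) {
  structure(list(phage_id = phage_id,
                 predicted_host_id = host_id,
                 e_value = e_value,
                 method = method),
            class = "alignment_prediction")
}

#' @export
print.alignment_prediction <- function(x, ...) {
  cat(sprintf("[%s] %s -> %s (e = %s)\n", x$method, x$phage_id,
              if (is.na(x$predicted_host_id)) "no-prediction"
              else x$predicted_host_id,
              format(x$e_value)))
  invisible(x)
}

#' Predict a host via similarity to reference phages
#'
#' The query phage genome is searched against the reference phages whose
#' interacting hosts are known; the host of the top hit is assigned when
#' the hit's e-value is at or below the cutoff, otherwise no prediction
#' is made. Ties on bit score break by e-value, then by smaller phage
#' ID.
#'
#' @param phage a single-record named \link[Biostrings]{DNAStringSet}
#'   (the query phage).
#' @param bundle a \code{"ref_bundle"}.
#' @param e_cutoff e-value threshold (cascade default 1e-10).
#' @param backend see \code{\link{ph_search}}.
#' @param hits optional precomputed hit table for this phage against
#'   \code{bundle$phages} (to reuse one search across cutoffs).
#' @return an \code{"alignment_prediction"} with method
#'   \code{"blast_phage"}; \code{predicted_host_id} is \code{NA} on a
#'   miss.
#' @export
blast_phage_predict <- function(phage, bundle, e_cutoff = 1e-10,
                                backend = "auto", hits = NULL) {
  stopifnot(length(phage) == 1L)
  if (is.null(hits))
    hits <- ph_search(phage, bundle$phages, "standard", e_cutoff,
                      backend)
  hits <- hits[hits$e_value <= e_cutoff &
                 hits$query_id == names(phage), , drop = FALSE]
  th <- top_hit(hits)
  if (is.null(th))
    return(alignment_prediction(names(phage), NA_character_, NA_real_,
                                "blast_phage"))
  alignment_prediction(names(phage),
                       training_host(bundle, th$target_id),
                       th$e_value, "blast_phage")
}

#' Predict a host via direct phage-vs-host similarity
#'
#' The query phage genome is searched against the M reference host
#' genomes; the top-hit host itself is assigned when the e-value passes
#' the cutoff. Picks up prophage-like shared segments between phage and
#' host genomes.
#'
#' @inheritParams blast_phage_predict
#' @param e_cutoff e-value threshold (cascade default 1e-20).
#' @return an \code{"alignment_prediction"} with method
#'   \code{"blast_host"}.
#' @export
blast_host_predict <- function(phage, bundle, e_cutoff = 1e-20,
                               backend = "auto", hits = NULL) {
  stopifnot(length(phage) == 1L)
  if (is.null(hits))
    hits <- ph_search(phage, bundle$hosts, "standard", e_cutoff, backend)
  hits <- hits[hits$e_value <= e_cutoff &
                 hits$query_id == names(phage), , drop = FALSE]
  th <- top_hit(hits)
  if (is.null(th))
    return(alignment_prediction(names(phage), NA_character_, NA_real_,
                                "blast_host"))
  alignment_prediction(names(phage), th$target_id, th$e_value,
                       "blast_host")
}

#' Build a similarity matrix (best bit score per pair)
#'
#' Three kinds are used by the hybrid score: \code{"phage_phage"}
#' (queries vs reference phages), \code{"phage_host"} (queries vs
#' reference hosts) and \code{"host_host"} (reference hosts vs
#' themselves). The value is the best bit score over all hits for the
#' pair; 0 when there is no hit.
#'
#' @param kind one of \code{"phage_phage"}, \code{"phage_host"},
#'   \code{"host_host"}.
#' @param bundle a \code{"ref_bundle"} supplying the target collection.
#' @param queries query \link[Biostrings]{DNAStringSet}; defaults to the
#'   appropriate bundle collection for \code{"host_host"}.
#' @param e_cutoff permissive hit threshold for matrix construction
#'   (default 10, as similarity scores feed a weighted sum rather than a
#'   decision threshold).
#' @param backend see \code{\link{ph_search}}.
#' @return object of class \code{"sim_matrix"}: numeric matrix (rows =
#'   query IDs, cols = target IDs) with attributes \code{kind} and
#'   \code{normalized = FALSE}.
#' @export
build_similarity_matrix <- function(kind = c("phage_phage", "phage_host",
                                             "host_host"),
                                    bundle, queries = NULL,
                                    e_cutoff = 10, backend = "auto") {
  kind <- match.arg(kind)
  targets <- switch(kind,
    phage_phage = bundle$phages,
    phage_host = bundle$hosts,
    host_host = bundle$hosts)
  if (is.null(queries))
    queries <- if (kind == "host_host") bundle$hosts else bundle$phages
  hits <- ph_search(queries, targets, "standard", e_cutoff, backend)
  m <- matrix(0, nrow = length(queries), ncol = length(targets),
              dimnames = list(names(queries), names(targets)))
  if (nrow(hits)) {
    best <- aggregate(bit_score ~ query_id + target_id, data = hits,
                      FUN = max)
    m[cbind(best$query_id, best$target_id)] <- best$bit_score
  }
  structure(m, kind = kind, normalized = FALSE, class = "sim_matrix")
}

#' Row max-normalize a similarity matrix
#'
#' Each row is divided by its maximum so the best target scores 1;
#' all-zero rows stay zero. Raw bit scores grow with genome length and
#' would swamp the probability terms of the hybrid score, which mixes
#' quantities on [0,1].
#'
#' @param m a \code{"sim_matrix"} (or plain matrix).
#' @return the normalized \code{"sim_matrix"} (\code{normalized = TRUE}).
#' @export
normalize_similarity <- function(m) {
  if (isTRUE(attr(m, "normalized"))) return(m)
  mx <- apply(m, 1L, max)
  mx[mx == 0] <- 1
  out <- m / mx
  attributes(out) <- attributes(m)
  attr(out, "normalized") <- TRUE
  out
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("similarity matrix [%s] %d x %d (%snormalized)\n",
              attr(x, "kind"), nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "" else "not "))
  invisible(x)
}

#' Persist / load a similarity matrix as TSV
#'
#' @param m a \code{"sim_matrix"}.
#' @param path TSV path (row and column headers kept).
#' @return \code{path} (write), or the \code{"sim_matrix"} (read).
#' @export
write_similarity_matrix <- function(m, path) {
  hdr <- paste(c(paste0("#kind=", attr(m, "kind")),
                 paste0("#normalized=", isTRUE(attr(m, "normalized")))),
               collapse = "\n")
  mm <- m
  attributes(mm) <- list(dim = dim(m), dimnames = dimnames(m))
  con <- file(path, "w")
  writeLines(hdr, con)
  write.table(data.frame(id = rownames(mm), mm, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  kind <- sub("^#kind=", "", hdr[1L])
  normalized <- identical(sub("^#normalized=", "", hdr[2L]), "TRUE")
  tab <- read.table(path, header = TRUE, sep = "\t", skip = 2L,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  structure(m, kind = kind, normalized = normalized,
            class = "sim_matrix")
}
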