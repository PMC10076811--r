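#' Is a prediction correct at a taxonomic rank?
#'
#' A strain-level call counts as correct at rank r when the predicted
#' and true hosts carry the same known name at that rank. An unknown
#' name (the reserved \code{"NA"} token) on either side scores as
#' incorrect -- conservative, never crediting an unknown-vs-unknown
#' match.
#'
#' @param predicted,truth host IDs (vectors recycle elementwise).
#' @param rank one of strain, species, genus, family, order, class,
#'   phylum.
#' @param taxonomy taxonomy data.frame.
#' @return logical vector.
#' @export
correct_at_rank <- function(predicted, truth, rank, taxonomy) {
  p <- host_rank(taxonomy, predicted, rank)
  t <- host_rank(taxonomy, truth, rank)
  p == t & p != NA_TOKEN & t != NA_TOKEN
}

#' Score staged predictions at the five taxonomic ranks
#'
#' Per rank: accuracy = 100 * correct / total test samples; probability
#' of correct prediction (PCP) = 100 * correct / predictions made;
#' coverage = 100 * predictions made / total. A no-prediction counts in
#' the accuracy denominator but not in PCP's; with zero predictions PCP
#' is NA. accuracy = pcp * coverage / 100 by construction.
#'
#' @param predictions a \code{"staged_predictions"} data.frame (or any
#'   data.frame with phage_id, host_id).
#' @param truth interaction data.frame (phage_id, host_id) with the true
#'   hosts; every prediction's phage must appear here.
#' @param taxonomy taxonomy data.frame.
#' @param ranks ranks to score (default genus..phylum).
#' @return data.frame, one row per rank: rank, n_total, n_predicted,
#'   n_correct, accuracy, pcp, coverage.
#' @export
evaluate_predictions <- function(predictions, truth, taxonomy,
                                 ranks = SCORED_RANKS) {
  missing <- setdiff(predictions$phage_id, truth$phage_id)
  if (length(missing))
    stop("phage missing from truth: ", paste(missing, collapse = ", "))
  true_host <- truth$host_id[match(predictions$phage_id,
                                   truth$phage_id)]
  called <- !is.na(predictions$host_id)
  n_total <- nrow(predictions)
  n_predicted <- sum(called)
  rows <- lapply(ranks, function(r) {
    n_correct <- if (n_predicted)
      sum(correct_at_rank(predictions$host_id[called],
                          true_host[called], r, taxonomy))
    else 0L
    data.frame(rank = r, n_total = n_total,
               n_predicted = n_predicted, n_correct = n_correct,
               accuracy = 100 * n_correct / n_total,
               pcp = if (n_predicted) 100 * n_correct / n_predicted
                     else NA_real_,
               coverage = 100 * n_predicted / n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ranked_results", "data.frame")
  out
}

#' @export
print.ranked_results <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("accuracy", "pcp", "coverage"))
    y[[col]] <- round(y[[col]], 1)    # tables report one decimal
  print(y, row.names = FALSE)
  invisible(x)
}

#' Threshold sweep for one alignment-based predictor
#'
#' Re-thresholds a single predictor (phage-phage, phage-host or CRISPR)
#' over a descending list of e-values and scores each operating point at
#' every rank. One permissive search is reused across cutoffs, so the
#' sweep reflects pure monotone filtering: coverage never increases as
#' the e-value tightens.
#'
#' @param method \code{"blast_phage"}, \code{"blast_host"} or
#'   \code{"crispr"}.
#' @param e_values numeric vector of thresholds, sorted descending.
#' @param phages query \link[Biostrings]{DNAStringSet}.
#' @param bundle a \code{"ref_bundle"}.
#' @param truth interaction data.frame with the true hosts.
#' @param spacer_db a \code{"spacer_db"} (required for
#'   \code{"crispr"}).
#' @param backend see \code{\link{ph_search}}.
#' @return data.frame: e_value x rank rows with the
#'   \code{\link{evaluate_predictions}} columns.
#' @export
threshold_sweep <- function(method = c("blast_phage", "blast_host",
                                       "crispr"),
                            e_values, phages, bundle, truth,
                            spacer_db = NULL, backend = "auto") {
  method <- match.arg(method)
  if (is.unsorted(rev(e_values)))
    stop("e_values must be sorted descending")
  e_max <- max(e_values)
  hits <- switch(method,
    blast_phage = ph_search(phages, bundle$phages, "standard", e_max,
                            backend),
    blast_host = ph_search(phages, bundle$hosts, "standard", e_max,
                           backend),
    crispr = {
      if (is.null(spacer_db)) stop("spacer_db required")
      tg <- Biostrings::DNAStringSet(spacer_db$spacer_seq)
      names(tg) <- spacer_db$spacer_id
      h <- ph_search(phages, tg, "short_query", e_max, backend)
      if (nrow(h))
        h$target_id <- spacer_db$host_id[match(h$target_id,
                                               spacer_db$spacer_id)]
      h
    })
  out <- NULL
  for (e in e_values) {
    sub <- hits[hits$e_value <= e, , drop = FALSE]
    pred <- data.frame(phage_id = names(phages),
                       host_id = NA_character_,
                       stringsAsFactors = FALSE)
    for (i in seq_along(phages)) {
      th <- top_hit(sub[sub$query_id == names(phages)[i], ,
                        drop = FALSE])
      if (is.null(th)) next
      pred$host_id[i] <- if (method == "blast_phage")
        training_host(bundle, th$target_id) else th$target_id
    }
    res <- evaluate_predictions(pred, truth, bundle$taxonomy)
    res <- cbind(e_value = e, method = method,
                 as.data.frame(res))
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}
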