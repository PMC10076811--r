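#' Cascade configuration
#'
#' Thresholds of the staged decision cascade. Defaults are the operating
#' point of the full ensemble: phage-phage alignment at e <= 1e-10,
#' phage-host at e <= 1e-20, hybrid call when the top score reaches 0.6,
#' CRISPR spacer match at e <= 1e-2. \code{force_call} makes the hybrid
#' argmax the answer of last resort instead of a no-prediction.
#'
#' @param e_blast_phage,e_blast_host,e_crispr e-value thresholds (> 0).
#' @param p_hybrid hybrid score threshold in [0,1].
#' @param force_call logical.
#' @return object of class \code{"cascade_config"}.
#' @export
cascade_config <- function(e_blast_phage = 1e-10, e_blast_host = 1e-20,
                           e_crispr = 1e-2, p_hybrid = 0.6,
                           force_call = FALSE) {
  stopifnot(e_blast_phage > 0, e_blast_host > 0, e_crispr > 0,
            p_hybrid >= 0, p_hybrid <= 1)
  structure(list(e_blast_phage = e_blast_phage,
                 e_blast_host = e_blast_host,
                 e_crispr = e_crispr, p_hybrid = p_hybrid,
                 force_call = isTRUE(force_call)),
            class = "cascade_config")
}

#' Fit the full host-prediction ensemble
#'
#' The one "fit" of the package: builds every asset the staged cascade
#' consults against a fixed reference bundle -- the k-mer host
#' classifier, the host-host similarity matrix, the CRISPR spacer
#' database, and the hybrid weights (fixed, or tuned by grid search on
#' the training interactions). \code{\link{predict.host_ensemble}}
#' dispatches the three application modes.
#'
#' @param bundle a \code{"ref_bundle"}.
#' @param algorithm base classifier (see
#'   \code{\link{train_host_classifier}}); default \code{"lr"}.
#' @param k k-mer length for the classifier features.
#' @param weights a \code{"hybrid_weights"}; ignored when
#'   \code{tune_weights = TRUE}.
#' @param cascade a \code{"cascade_config"}.
#' @param crispr CRISPR detection parameters
#'   (\code{\link{crispr_params}}).
#' @param tune_weights grid-search alpha/gamma on the training
#'   interactions instead of using \code{weights}.
#' @param seed integer seed for classifier training.
#' @param backend alignment backend (see \code{\link{ph_search}}).
#' @return object of class \code{"host_ensemble"}.
#' @export
host_ensemble <- function(bundle, algorithm = "lr", k = 6,
                          weights = hybrid_weights(),
                          cascade = cascade_config(),
                          crispr = crispr_params(),
                          tune_weights = FALSE, seed = 1L,
                          backend = "auto") {
  stopifnot(inherits(bundle, "ref_bundle"))
  model <- train_host_classifier(bundle, algorithm, k, seed)
  sim_hh <- build_similarity_matrix("host_host", bundle,
                                    backend = backend)
  spacer_db <- build_spacer_db(bundle, crispr)
  if (tune_weights) {
    sim_pp <- build_similarity_matrix("phage_phage", bundle,
                                      backend = backend)
    sim_ph <- build_similarity_matrix("phage_host", bundle,
                                      backend = backend)
    weights <- grid_search_weights(bundle, model,
                                   list(pp = sim_pp, ph = sim_ph,
                                        hh = sim_hh))
  }
  structure(list(bundle = bundle, model = model, sim_hh = sim_hh,
                 spacer_db = spacer_db, weights = weights,
                 cascade = cascade, crispr = crispr,
                 seed = as.integer(seed), backend = backend),
            class = "host_ensemble")
}

#' @export
print.host_ensemble <- function(x, ...) {
  cat("Staged host-prediction ensemble\n")
  cat(sprintf("  reference: %d phages, %d hosts, %d training pairs\n",
              length(x$bundle$phages), length(x$bundle$hosts),
              nrow(x$bundle$training)))
  cat(sprintf("  base model: %s (k = %d)\n", x$model$algorithm,
              x$model$k))
  cat(sprintf("  hybrid weights: alpha = %g, gamma = %g\n",
              x$weights$alpha, x$weights$gamma))
  cat(sprintf("  spacers in CRISPR database: %d\n", nrow(x$spacer_db)))
  cat(sprintf(
    "  cascade: phage-sim e<=%g -> host-sim e<=%g -> hybrid >=%g -> crispr e<=%g%s\n",
    x$cascade$e_blast_phage, x$cascade$e_blast_host,
    x$cascade$p_hybrid, x$cascade$e_crispr,
    if (x$cascade$force_call) " (force call)" else ""))
  invisible(x)
}

#' @export
summary.host_ensemble <- function(object, ...) {
  print(object)
  cat("\nHost genera represented:",
      paste(sort(unique(host_rank(object$bundle,
                                  object$bundle$host_ids, "genus"))),
            collapse = ", "), "\n")
  invisible(object)
}

#' Staged host prediction for query phages
#'
#' Stages are tried strictly in order: (1) similarity to reference
#' phages, (2) similarity to reference hosts, (3) hybrid score, (4)
#' CRISPR spacers. The first stage passing its threshold supplies the
#' call; a phage failing all four gets a no-prediction (or the hybrid
#' argmax when \code{force_call} is set). The score column carries the
#' decisive e-value for alignment stages and the top hybrid score for
#' the hybrid stage.
#'
#' @param object a \code{"host_ensemble"}.
#' @param phages named \link[Biostrings]{DNAStringSet} of query phage
#'   genomes.
#' @param cascade optional \code{"cascade_config"} overriding the fitted
#'   one.
#' @return object of class \code{"staged_predictions"}: data.frame with
#'   columns phage_id, host_id (NA for no-prediction), stage (one of
#'   blast_phage, blast_host, hybrid, crispr, none), score.
#' @export
predict_hosts <- function(object, phages, cascade = NULL) {
  stopifnot(inherits(object, "host_ensemble"))
  cfg <- if (is.null(cascade)) object$cascade else cascade
  bundle <- object$bundle
  backend <- object$backend
  # one permissive search per target set serves both the alignment
  # stages and the similarity rows of the hybrid stage
  hits_pp <- ph_search(phages, bundle$phages, "standard", 10, backend)
  hits_ph <- ph_search(phages, bundle$hosts, "standard", 10, backend)
  sim_pp <- hits_to_matrix(hits_pp, names(phages),
                           names(bundle$phages), "phage_phage")
  sim_ph <- hits_to_matrix(hits_ph, names(phages),
                           names(bundle$hosts), "phage_host")
  sims <- list(pp = sim_pp, ph = sim_ph, hh = object$sim_hh)
  out <- data.frame(phage_id = names(phages),
                    host_id = NA_character_, stage = "none",
                    score = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(phages)) {
    q <- phages[i]
    p1 <- blast_phage_predict(q, bundle, cfg$e_blast_phage,
                              hits = hits_pp)
    if (!is.na(p1$predicted_host_id)) {
      out[i, c("host_id", "stage")] <- c(p1$predicted_host_id,
                                         "blast_phage")
      out$score[i] <- p1$e_value
      next
    }
    p2 <- blast_host_predict(q, bundle, cfg$e_blast_host,
                             hits = hits_ph)
    if (!is.na(p2$predicted_host_id)) {
      out[i, c("host_id", "stage")] <- c(p2$predicted_host_id,
                                         "blast_host")
      out$score[i] <- p2$e_value
      next
    }
    hs <- hybrid_score(q, object$model, sims, object$weights, bundle)
    if (hs$argmax_score >= cfg$p_hybrid) {
      out[i, c("host_id", "stage")] <- c(hs$argmax_host, "hybrid")
      out$score[i] <- hs$argmax_score
      next
    }
    p4 <- crispr_predict(q, object$spacer_db, cfg$e_crispr,
                         backend = backend)
    if (!is.na(p4$predicted_host_id)) {
      out[i, c("host_id", "stage")] <- c(p4$predicted_host_id,
                                         "crispr")
      out$score[i] <- p4$e_value
      next
    }
    if (cfg$force_call) {
      out[i, c("host_id", "stage")] <- c(hs$argmax_host, "hybrid")
      out$score[i] <- hs$argmax_score
    }
  }
  class(out) <- c("staged_predictions", "data.frame")
  out
}

# Best-bit-score matrix from a hit table over fixed row/col ID sets.
#' @keywords internal
hits_to_matrix <- function(hits, row_ids, col_ids, kind) {
  m <- matrix(0, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  if (nrow(hits)) {
    best <- aggregate(bit_score ~ query_id + target_id, data = hits,
                      FUN = max)
    m[cbind(best$query_id, best$target_id)] <- best$bit_score
  }
  structure(m, kind = kind, normalized = FALSE, class = "sim_matrix")
}

#' @export
predict.host_ensemble <- function(object, phages,
                                  type = c("host", "interaction",
                                           "phage_for_host"),
                                  bacterium = NULL, ...) {
  type <- match.arg(type)
  switch(type,
    host = predict_hosts(object, phages, ...),
    interaction = predict_interaction(object, phages, bacterium, ...),
    phage_for_host = predict_phage_for_host(object$bundle,
                                            bacterium = bacterium,
                                            backend = object$backend,
                                            ...))
}

#' Does a given phage-bacterium pair interact?
#'
#' Predicts the query phage's host through the cascade, then asks
#' whether the query bacterium is (or closely aligns to) that reference
#' host: yes when the bacterium is the predicted host itself or aligns
#' to it with e-value at or below \code{e_host_match}.
#'
#' @param object a \code{"host_ensemble"}.
#' @param phage single-record named \link[Biostrings]{DNAStringSet}.
#' @param bacterium single-record named \link[Biostrings]{DNAStringSet}.
#' @param e_host_match e-value threshold for the bacterium-vs-predicted
#'   host alignment (default 1e-10).
#' @return list with \code{interacting} (logical),
#'   \code{predicted_host_id}, \code{evidence} (character).
#' @export
predict_interaction <- function(object, phage, bacterium,
                                e_host_match = 1e-10) {
  stopifnot(length(phage) == 1L, length(bacterium) == 1L)
  pred <- predict_hosts(object, phage)
  host_id <- pred$host_id[1L]
  if (is.na(host_id))
    return(list(interacting = FALSE, predicted_host_id = NA_character_,
                evidence = "no host call"))
  ref <- object$bundle$hosts[host_id]
  if (identical(names(bacterium), host_id) ||
      identical(as.character(bacterium[[1]]), as.character(ref[[1]])))
    return(list(interacting = TRUE, predicted_host_id = host_id,
                evidence = "query bacterium is the predicted host"))
  hits <- ph_search(bacterium, ref, "standard", e_host_match,
                    object$backend)
  if (nrow(hits) > 0L)
    list(interacting = TRUE, predicted_host_id = host_id,
         evidence = sprintf("aligns to predicted host (e = %.3g)",
                            hits$e_value[1L]))
  else
    list(interacting = FALSE, predicted_host_id = host_id,
         evidence = "no alignment to predicted host at threshold")
}

#' Suggest a phage for a query bacterium
#'
#' The bacterium genome is aligned against the reference host genomes;
#' the training phage paired with the top-hit host is returned. When the
#' top-hit host pairs with several training phages, the
#' lexicographically smallest phage ID wins. No hit at the threshold
#' yields no suggestion.
#'
#' @param bundle a \code{"ref_bundle"}.
#' @param bacterium single-record named \link[Biostrings]{DNAStringSet}.
#' @param e_cutoff e-value threshold (default 1e-10).
#' @param backend see \code{\link{ph_search}}.
#' @return list with \code{phage_id} (NA when none) and
#'   \code{via_host_id}.
#' @export
predict_phage_for_host <- function(bundle, bacterium, e_cutoff = 1e-10,
                                   backend = "auto") {
  stopifnot(length(bacterium) == 1L)
  hits <- ph_search(bacterium, bundle$hosts, "standard", e_cutoff,
                    backend)
  th <- top_hit(hits)
  if (is.null(th))
    return(list(phage_id = NA_character_,
                via_host_id = NA_character_))
  cand <- bundle$training$phage_id[bundle$training$host_id ==
                                     th$target_id]
  if (!length(cand))
    return(list(phage_id = NA_character_, via_host_id = th$target_id))
  list(phage_id = sort(cand)[1L], via_host_id = th$target_id)
}

#' Write staged predictions as TSV
#'
#' Stable column order: phage_id, host_id, stage, score.
#'
#' @param predictions a \code{"staged_predictions"} data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- as.data.frame(predictions)[, c("phage_id", "host_id",
                                        "stage", "score")]
  out$score <- ifelse(is.na(out$score), "NA",
                      formatC(out$score, format = "g", digits = 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
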