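#' Hybrid-score weighting parameters
#'
#' \code{alpha} weighs host-host vs phage-host similarity inside the
#' similarity term; \code{gamma} weighs the similarity term against the
#' base-model probabilities. Both live on [0,1] and are found by grid
#' search (step 0.1) during cross-validation; on the study's data the
#' best performance was at alpha = 0.9, gamma = 0.6, which are the
#' defaults here.
#'
#' @param alpha,gamma reals in [0,1].
#' @return object of class \code{"hybrid_weights"}.
#' @export
hybrid_weights <- function(alpha = 0.9, gamma = 0.6) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  structure(list(alpha = alpha, gamma = gamma),
            class = "hybrid_weights")
}

#' @export
print.hybrid_weights <- function(x, ...) {
  cat(sprintf("hybrid weights: alpha = %g, gamma = %g\n",
              x$alpha, x$gamma))
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  grid-search CV accuracy at %s rank: %.1f%%\n",
                x$rank, x$cv_accuracy))
  invisible(x)
}

#' Support host of a query phage
#'
#' The host (in training) of the most similar reference phage according
#' to the phage-phage similarity row. Its host-host similarity row
#' enters the hybrid score: hosts similar to the support host are
#' plausible hosts for the query. Ties break to the lexicographically
#' smaller phage ID; an all-zero row yields no support host (the
#' host-host term then contributes a zero vector).
#'
#' @param phage a single-record named \link[Biostrings]{DNAStringSet} or
#'   a phage ID present among the rows of \code{sim_pp}.
#' @param sim_pp a \code{"sim_matrix"} of kind phage_phage whose columns
#'   are the bundle's training phages.
#' @param bundle a \code{"ref_bundle"}.
#' @return a host ID, or \code{NA_character_}.
#' @export
support_host <- function(phage, sim_pp, bundle) {
  id <- if (is.character(phage)) phage else names(phage)
  if (!id %in% rownames(sim_pp)) stop("no phage-phage row for ", id)
  row <- sim_pp[id, ]
  if (all(row == 0)) return(NA_character_)
  cand <- colnames(sim_pp)[row == max(row)]
  best_phage <- sort(cand)[1L]
  training_host(bundle, best_phage)
}

# Core score: one query's per-host vector from its base probabilities,
# its normalized phage-host similarity row, and the normalized host-host
# row of the support host (zeros when there is none).
#' @keywords internal
combine_scores <- function(prb, simph_row, simhh_row, alpha, gamma,
                           form = c("convex", "exponent")) {
  form <- match.arg(form)
  if (form == "convex") {
    (1 - gamma) * prb +
      gamma * ((1 - alpha) * simph_row + alpha * simhh_row)
  } else {
    # alternative reading of the combination as exponents
    prb^(1 - gamma) + simph_row^(1 - alpha) + simhh_row^(alpha * gamma)
  }
}

#' Hybrid per-host score for a query phage
#'
#' Mixes the base classifier's probability vector with two similarity
#' rows into the final per-host score
#' \deqn{Pr_o = (1-\gamma) Pr_b + \gamma [(1-\alpha)\,SIM_{PH}(v_q, H)
#'       + \alpha\, SIM_{HH}(h_s, H)]}
#' where \eqn{v_q} is the query, H the ordered reference hosts, and
#' \eqn{h_s} the support host (see \code{\link{support_host}}). SIM rows
#' are max-normalized to [0,1] before mixing so all three terms are
#' commensurate; with convex weights the scores stay in [0,1]. The
#' predicted host is the argmax. An alternative exponent reading of the
#' combination is available as \code{form = "exponent"}; the convex
#' combination is the default and the one whose scores a probability
#' threshold can be applied to.
#'
#' @param phage single-record named \link[Biostrings]{DNAStringSet}.
#' @param model a \code{"host_classifier"}.
#' @param sims list with elements \code{pp}, \code{ph}, \code{hh}:
#'   similarity matrices whose rows cover the query (pp, ph) and the
#'   reference hosts (hh).
#' @param weights a \code{"hybrid_weights"}.
#' @param bundle a \code{"ref_bundle"} (host order must match the
#'   model).
#' @param form \code{"convex"} (default) or \code{"exponent"}.
#' @param prb optional precomputed base-probability vector for the
#'   query.
#' @return object of class \code{"hybrid_score"}: list with
#'   \code{phage_id}, \code{pro} (named per-host vector),
#'   \code{support_host}, \code{argmax_host}, \code{argmax_score}.
#' @export
hybrid_score <- function(phage, model, sims, weights, bundle,
                         form = c("convex", "exponent"), prb = NULL) {
  form <- match.arg(form)
  id <- names(phage)
  if (!identical(bundle$host_checksum, model$host_checksum))
    stop("host order checksum mismatch between model and bundle")
  if (is.null(prb)) prb <- predict_host_proba(model, phage)
  M <- length(bundle$host_ids)
  ph <- normalize_similarity(sims$ph)
  hh <- normalize_similarity(sims$hh)
  if (!identical(colnames(ph), bundle$host_ids) ||
      !identical(colnames(hh), bundle$host_ids))
    stop("similarity matrix host order does not match the bundle")
  hs <- support_host(id, sims$pp, bundle)
  simph_row <- ph[id, ]
  simhh_row <- if (is.na(hs)) setNames(numeric(M), bundle$host_ids)
               else hh[hs, ]
  pro <- combine_scores(prb, simph_row, simhh_row,
                        weights$alpha, weights$gamma, form)
  best <- which.max(pro)
  structure(list(phage_id = id, pro = pro, support_host = hs,
                 argmax_host = names(pro)[best],
                 argmax_score = unname(pro[best])),
            class = "hybrid_score")
}

#' @export
print.hybrid_score <- function(x, ...) {
  cat(sprintf("hybrid score %s -> %s (%.3f; support host %s)\n",
              x$phage_id, x$argmax_host, x$argmax_score,
              if (is.na(x$support_host)) "none" else x$support_host))
  invisible(x)
}

#' Grid search for the hybrid weights (matrix form)
#'
#' Exhaustive search of (alpha, gamma) on [0,1]^2 at \code{grid_step},
#' scoring rank-level accuracy of the hybrid argmax over a set of
#' queries given precomputed inputs. Ties break to the smaller gamma,
#' then the smaller alpha.
#'
#' @param prb matrix (queries x hosts) of base-model probabilities.
#' @param sim_ph matrix (queries x hosts), max-normalized rows.
#' @param sim_hh_rows matrix (queries x hosts): for each query, the
#'   host-host similarity row of its support host (zeros when none).
#' @param truth_hosts character vector of true host IDs per query.
#' @param taxonomy taxonomy data.frame.
#' @param rank taxonomic rank at which accuracy is scored.
#' @param grid_step grid step; must divide 1 evenly.
#' @param form see \code{\link{hybrid_score}}.
#' @return a \code{"hybrid_weights"} with the full grid as attribute
#'   element \code{grid} (alpha, gamma, accuracy) and \code{cv_accuracy}.
#' @export
weight_grid_search <- function(prb, sim_ph, sim_hh_rows, truth_hosts,
                               taxonomy, rank = "genus",
                               grid_step = 0.1,
                               form = c("convex", "exponent")) {
  form <- match.arg(form)
  steps <- round(1 / grid_step)
  if (abs(steps * grid_step - 1) > 1e-9)
    stop("grid_step must divide 1 evenly")
  vals <- seq(0, 1, length.out = steps + 1L)
  hosts <- colnames(prb)
  truth_rank <- host_rank(taxonomy, truth_hosts, rank)
  host_ranks <- host_rank(taxonomy, hosts, rank)
  grid <- expand.grid(alpha = vals, gamma = vals,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  best <- NULL
  for (gi in seq_along(vals)) {        # gamma ascending (outer)
    for (ai in seq_along(vals)) {      # alpha ascending (inner)
      a <- vals[ai]; g <- vals[gi]
      # element-wise on matrices: every row is one query's combination
      pro <- combine_scores(prb, sim_ph, sim_hh_rows, a, g, form)
      pred <- hosts[max.col(pro, ties.method = "first")]
      pred_rank <- host_ranks[match(pred, hosts)]
      acc <- 100 * mean(pred_rank == truth_rank &
                          pred_rank != NA_TOKEN)
      grid$accuracy[grid$alpha == a & grid$gamma == g] <- acc
      if (is.null(best) || acc > best$acc + 1e-12)
        best <- list(alpha = a, gamma = g, acc = acc)
    }
  }
  w <- hybrid_weights(best$alpha, best$gamma)
  w$cv_accuracy <- best$acc
  w$rank <- rank
  w$grid <- grid
  w
}

#' Grid search for the hybrid weights on a bundle's training set
#'
#' Leave-one-out over the training interactions: each training phage is
#' scored with its own column removed from the phage-phage similarity
#' row (so the support host cannot come from a self-match). The
#' (alpha, gamma) pair maximizing accuracy at the given rank is
#' returned; ties break to smaller gamma then smaller alpha.
#'
#' @param bundle a \code{"ref_bundle"}.
#' @param model a \code{"host_classifier"} trained on the bundle.
#' @param sims list with \code{pp} (training phages vs training phages),
#'   \code{ph} (training phages vs hosts) and \code{hh} (hosts vs
#'   hosts) similarity matrices.
#' @param grid_step grid step (default 0.1: an 11 x 11 grid).
#' @param rank rank for the CV accuracy (default \code{"genus"}).
#' @param form see \code{\link{hybrid_score}}.
#' @return a \code{"hybrid_weights"}; element \code{grid} holds the full
#'   accuracy table for audit.
#' @export
grid_search_weights <- function(bundle, model, sims, grid_step = 0.1,
                                rank = "genus",
                                form = c("convex", "exponent")) {
  form <- match.arg(form)
  ids <- bundle$training$phage_id
  hosts <- bundle$host_ids
  prb <- t(vapply(ids, function(id)
    predict_host_proba(model, bundle$phages[id]), numeric(length(hosts))))
  ph <- normalize_similarity(sims$ph)[ids, hosts, drop = FALSE]
  hh <- normalize_similarity(sims$hh)
  pp <- sims$pp
  sim_hh_rows <- matrix(0, length(ids), length(hosts),
                        dimnames = list(ids, hosts))
  for (i in seq_along(ids)) {
    row <- pp[ids[i], ]
    row[colnames(pp) == ids[i]] <- 0      # leave-one-out: no self-match
    if (any(row > 0)) {
      best_phage <- sort(colnames(pp)[row == max(row)])[1L]
      sim_hh_rows[i, ] <- hh[training_host(bundle, best_phage), ]
    }
  }
  weight_grid_search(prb, ph, sim_hh_rows,
                     training_host(bundle, ids), bundle$taxonomy,
                     rank = rank, grid_step = grid_step, form = form)
}

#' Persist grid-search results
#'
#' Selected weights as JSON and the full accuracy grid as TSV.
#'
#' @param w a \code{"hybrid_weights"} from a grid search.
#' @param json_path,tsv_path output paths.
#' @return invisibly, the paths.
#' @export
write_weights <- function(w, json_path, tsv_path = NULL) {
  jsonlite::write_json(list(alpha = w$alpha, gamma = w$gamma,
                            rank = w$rank,
                            cv_accuracy = w$cv_accuracy),
                       json_path, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(tsv_path) && !is.null(w$grid))
    write.table(w$grid, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
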