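CLASSIFIER_ALGOS <- c("lr", "svm", "knn", "mlp", "rf", "xgb", "gnb",
                      "dt")

#' Train a multi-class host classifier on k-mer features
#'
#' Maps a phage's modified k-mer frequency vector to a probability
#' distribution over the M reference hosts. The class label is the host
#' strain ID of the training interaction (rank-level calls are obtained
#' afterwards by aggregating the strain-level call through the
#' taxonomy). Eight algorithms share the surface; multinomial
#' ridge-penalised logistic regression (\code{"lr"}) is the default base
#' model. Hyperparameters are library defaults with a fixed seed; the
#' exact settings are recorded in the returned object.
#'
#' @param bundle a \code{"ref_bundle"}; every training phage must map to
#'   one of its hosts.
#' @param algorithm one of \code{"lr"} (multinomial logistic
#'   regression), \code{"svm"} (linear SVM), \code{"knn"},
#'   \code{"mlp"}, \code{"rf"} (random forest), \code{"xgb"} (gradient
#'   boosting), \code{"gnb"} (Gaussian naive Bayes), \code{"dt"}
#'   (decision tree).
#' @param k k-mer length for the features (default 6).
#' @param seed integer seed; training is deterministic given the seed.
#' @return object of class \code{"host_classifier"} with elements
#'   \code{algorithm}, \code{k}, \code{host_ids}, \code{host_checksum},
#'   \code{classes}, \code{fit}, \code{seed}.
#' @export
train_host_classifier <- function(bundle, algorithm = "lr", k = 6,
                                  seed = 1L) {
  algorithm <- match.arg(algorithm, CLASSIFIER_ALGOS)
  ids <- bundle$training$phage_id
  lab <- bundle$training$host_id
  if (!all(lab %in% bundle$host_ids))
    stop("training host outside the reference host set")
  x <- kmer_feature_matrix(bundle$phages[ids], k)
  classes <- sort(unique(lab))
  y <- factor(lab, levels = classes)
  fit <- if (length(classes) < 2L) {
    list(type = "constant", class = classes)
  } else {
    set.seed(seed)
    fit_algo(algorithm, x, y)
  }
  structure(list(algorithm = algorithm, k = k,
                 host_ids = bundle$host_ids,
                 host_checksum = bundle$host_checksum,
                 classes = classes, fit = fit, seed = as.integer(seed)),
            class = "host_classifier")
}

#' @keywords internal
fit_algo <- function(algorithm, x, y) {
  switch(algorithm,
    lr = {
      # the multinomial ridge path needs >= 2 observations per class;
      # duplicating a singleton leaves its fitted optimum unchanged up
      # to observation weighting (common with strain-level labels)
      tab <- table(y)
      if (any(tab < 2L)) {
        add <- which(y %in% names(tab)[tab < 2L])
        x <- rbind(x, x[add, , drop = FALSE])
        y <- factor(c(as.character(y), as.character(y)[add]),
                    levels = levels(y))
      }
      list(type = "glmnet",
           fit = glmnet::glmnet(x, y, family = "multinomial",
                                alpha = 0, lambda = 1e-3))
    },
    dt = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      list(type = "rpart", fit = rpart::rpart(.y ~ ., data = df,
                                              method = "class"))
    },
    gnb = list(type = "naiveBayes", fit = e1071::naiveBayes(x, y)),
    rf = list(type = "randomForest",
              fit = randomForest::randomForest(x, y, ntree = 200)),
    svm = list(type = "svm",
               fit = e1071::svm(x, y, kernel = "linear", scale = FALSE,
                                decision.values = TRUE)),
    xgb = list(type = "xgboost", levels = levels(y),
               fit = xgboost::xgboost(x, y, nrounds = 30,
                                      verbosity = 0, nthread = 1)),
    knn = list(type = "knn", x = x, y = y,
               k_nn = min(5L, nrow(x))),
    mlp = list(type = "nnet",
               fit = nnet::nnet(x, nnet::class.ind(y), size = 8,
                                softmax = TRUE, MaxNWts = 1e6,
                                maxit = 200, trace = FALSE)))
}

#' @export
print.host_classifier <- function(x, ...) {
  cat(sprintf(
    "host classifier [%s]: k = %d, %d classes over %d hosts\n",
    x$algorithm, x$k, length(x$classes), length(x$host_ids)))
  invisible(x)
}

# Class-probability matrix (rows = samples, cols = model classes) from a
# fitted algorithm. Margin-based classifiers without native
# probabilities (linear SVM) are calibrated by a softmax over per-class
# decision values so that every algorithm emits a simplex vector.
#' @keywords internal
algo_proba <- function(fit, classes, x) {
  p <- switch(fit$type,
    glmnet = {
      pr <- predict(fit$fit, x, type = "response")
      pr[, , 1, drop = FALSE][, , 1]
    },
    rpart = predict(fit$fit,
                    data.frame(x, check.names = FALSE),
                    type = "prob"),
    naiveBayes = predict(fit$fit, x, type = "raw"),
    randomForest = predict(fit$fit, x, type = "prob"),
    svm = {
      dv <- attr(predict(fit$fit, x, decision.values = TRUE),
                 "decision.values")
      svm_vote_proba(dv, classes, nrow(x))
    },
    xgboost = predict(fit$fit, x, type = "response"),
    knn = knn_proba(fit, x),
    nnet = predict(fit$fit, x))
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(x))
  if (is.null(colnames(p))) colnames(p) <- classes
  p <- p[, classes, drop = FALSE]
  p / rowSums(p)
}

# One-vs-one decision values -> per-class aggregated score -> softmax.
#' @keywords internal
svm_vote_proba <- function(dv, classes, n) {
  score <- matrix(0, nrow = n, ncol = length(classes),
                  dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    score[, a] <- score[, a] + dv[, j]
    score[, b] <- score[, b] - dv[, j]
  }
  sm <- exp(score - apply(score, 1L, max))
  sm / rowSums(sm)
}

# Distance-weighted class proportions among the k nearest training rows.
#' @keywords internal
knn_proba <- function(fit, x) {
  out <- matrix(0, nrow = nrow(x), ncol = nlevels(fit$y),
                dimnames = list(rownames(x), levels(fit$y)))
  for (i in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(fit$x) - x[i, ])^2))
    nb <- order(d, fit$y)[seq_len(fit$k_nn)]
    tab <- table(fit$y[nb])
    out[i, names(tab)] <- as.numeric(tab) / fit$k_nn
  }
  out
}

#' Per-host probability vector for a phage
#'
#' Output indexes the bundle's fixed host order; hosts that never occur
#' in training receive probability 0. Entries sum to 1.
#'
#' @param model a \code{"host_classifier"}.
#' @param phage single-record named \link[Biostrings]{DNAStringSet}.
#' @param bundle optional \code{"ref_bundle"}; when given, its host
#'   order checksum must match the one the model was trained against.
#' @return named numeric vector of length M (the reference hosts).
#' @export
predict_host_proba <- function(model, phage, bundle = NULL) {
  stopifnot(inherits(model, "host_classifier"), length(phage) == 1L)
  if (!is.null(bundle) &&
      !identical(bundle$host_checksum, model$host_checksum))
    stop("host order checksum mismatch between model and bundle")
  out <- setNames(numeric(length(model$host_ids)), model$host_ids)
  if (identical(model$fit$type, "constant")) {
    out[model$fit$class] <- 1
    return(out)
  }
  x <- matrix(as.numeric(modified_frequency(phage[[1]], model$k)),
              nrow = 1,
              dimnames = list(names(phage), kmer_alphabet(model$k)))
  p <- algo_proba(model$fit, model$classes, x)
  out[colnames(p)] <- p[1, ]
  out
}

#' Save / load a trained classifier
#'
#' Binary model file plus a JSON manifest recording the algorithm, k,
#' seed and the host-order checksum.
#'
#' @param model a \code{"host_classifier"}.
#' @param path path to the model file; the manifest is written next to
#'   it as \code{<path>.json}.
#' @return \code{path} (save) or the model (load).
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(format_version = 1L, algorithm = model$algorithm,
         k = model$k, seed = model$seed,
         host_checksum = model$host_checksum,
         n_classes = length(model$classes)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"))
  model <- readRDS(path)
  if (!identical(man$host_checksum, model$host_checksum))
    stop("manifest/model checksum mismatch")
  model
}
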