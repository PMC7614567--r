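#' Select candidate orthogonal mutants by the quadrant threshold scan
#'
#' Scans the 45-degree line through the mean of the
#' (`d_inter_astar_b`, `d_inter_a_bstar`) cloud, from high values downward,
#' for the threshold pair `(e1, e2) = (mean_x + t, mean_y + t)` at which the
#' retained fraction (candidates with `d_inter_astar_b > e1` AND
#' `d_inter_a_bstar > e2`, strictly) first reaches the target fraction `F`.
#' Candidates lying exactly on a threshold are excluded. High cross-talk
#' scores mean unfavourable chimera interactions, i.e. predicted insulation
#' from the native partners.
#'
#' @param repertoire An `ois_repertoire` (or any tibble with the two
#'   cross-talk score columns).
#' @param fraction Target fraction `F` in `[0, 1]` (`0` selects nothing,
#'   `1` everything with thresholds at `-Inf`).
#' @return An `ois_selection`: list with `thresholds` (`e1`, `e2`),
#'   `target_fraction`, `achieved_fraction`, the selected subset (`selected`)
#'   and the scan centre (`center`).
#' @export
select_orthogonal <- function(repertoire, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (nrow(repertoire) == 0L) stop("empty repertoire", call. = FALSE)
  x <- repertoire$d_inter_astar_b
  y <- repertoire$d_inter_a_bstar
  stopifnot(!is.null(x), !is.null(y))
  mx <- mean(x); my <- mean(y)
  u <- pmin(x - mx, y - my)
  n <- length(u)
  m <- ceiling(fraction * n)
  if (m == 0L) {
    t_star <- Inf
  } else if (m == n) {
    t_star <- -Inf
  } else {
    vals <- sort(unique(u), decreasing = TRUE)
    counts <- vapply(vals, function(v) sum(u > v), integer(1))
    hit <- which(counts >= m)
    t_star <- if (length(hit)) vals[hit[1]] else -Inf
  }
  sel <- u > t_star
  structure(
    list(thresholds = c(e1 = mx + t_star, e2 = my + t_star),
         target_fraction = fraction,
         achieved_fraction = mean(sel),
         center = c(mean_astar_b = mx, mean_a_bstar = my),
         selected = tibble::as_tibble(repertoire)[sel, , drop = FALSE]),
    class = "ois_selection"
  )
}

#' @exportS3Method base::print
print.ois_selection <- function(x, ...) {
  cat("<ois_selection> ", nrow(x$selected), " candidates retained (",
      "target F = ", x$target_fraction, ", achieved = ",
      signif(x$achieved_fraction, 4), ")\n",
      "thresholds: e1 = ", signif(x$thresholds[["e1"]], 4),
      ", e2 = ", signif(x$thresholds[["e2"]], 4), "\n", sep = "")
  invisible(x)
}

#' Five-score feature vectors for labeled mutant pairs
#'
#' Builds, for each labeled mutant pair, the feature vector
#' `(dE_intra(A*), dE_intra(B*), dE_inter(A*,B*), dE_inter(A*,B),
#' dE_inter(A,B*))` used by the orthogonal-vs-promiscuous classifier.
#'
#' @param model A [potts_model()].
#' @param wildtype Wild-type pair `(A, B)`.
#' @param mutants Tibble with columns `mutant_a`, `mutant_b`, `label`
#'   (values `"orthogonal"` or `"promiscuous"`).
#' @return Tibble with the five feature columns plus `label`.
#' @export
build_feature_vectors <- function(model, wildtype, mutants) {
  stopifnot(all(c("mutant_a", "mutant_b", "label") %in% names(mutants)),
            all(mutants$label %in% c("orthogonal", "promiscuous")))
  sc <- score_pairs(model, wildtype, mutants)
  dplyr::bind_cols(sc, tibble::tibble(label = mutants$label))
}

feature_cols <- c("d_intra_a", "d_intra_b", "d_inter_cognate",
                  "d_inter_astar_b", "d_inter_a_bstar")

#' Repeated random-split logistic-regression evaluation
#'
#' Fits an L2-regularized logistic regression (regularization constant
#' `reg_c`, intercept unpenalized; implemented as ridge-penalized logistic
#' regression with penalty `1/(n * reg_c)`) on repeated random train/test
#' splits, and averages accuracy, AUC and the confusion matrix over the test
#' sets. The positive class for the AUC is `"promiscuous"`. AUC is averaged
#' over splits whose test set contains both classes.
#'
#' @param features Tibble from [build_feature_vectors()] (five feature
#'   columns plus `label`).
#' @param n_repeats Number of random splits (reference protocol: 100).
#' @param train_n,test_n Training and test set sizes (reference: 31 and 10).
#' @param reg_c Regularization constant `C`.
#' @param standardize Standardize features before fitting (default FALSE).
#' @param seed Integer seed for the splits.
#' @return An `ois_classifier_report`: mean accuracy, mean AUC, mean
#'   row-normalized confusion matrix, per-feature coefficient means and SDs.
#' @export
evaluate_classifier <- function(features, n_repeats = 100L, train_n = 31L,
                                test_n = 10L, reg_c = 1, standardize = FALSE,
                                seed = 1L) {
  stopifnot(all(c(feature_cols, "label") %in% names(features)))
  lab <- factor(features$label, levels = c("orthogonal", "promiscuous"))
  if (nlevels(droplevels(lab)) < 2L) {
    stop("both classes must be present to train a classifier", call. = FALSE)
  }
  n <- nrow(features)
  if (train_n + test_n > n) {
    stop("train_n + test_n exceeds the dataset size (", n, ")", call. = FALSE)
  }
  X <- as.matrix(features[, feature_cols])
  acc <- auc <- rep(NA_real_, n_repeats)
  conf <- matrix(0, 2, 2,
                 dimnames = list(true = levels(lab), pred = levels(lab)))
  conf_n <- 0L
  coefs <- matrix(NA_real_, n_repeats, length(feature_cols),
                  dimnames = list(NULL, feature_cols))
  with_local_seed(seed, {
    for (r in seq_len(n_repeats)) {
      repeat {
        idx <- sample.int(n, train_n + test_n)
        tr <- idx[seq_len(train_n)]
        te <- idx[train_n + seq_len(test_n)]
        if (nlevels(droplevels(lab[tr])) == 2L) break
      }
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], lab[tr],
                            family = "binomial", alpha = 0,
                            lambda = 1 / (train_n * reg_c),
                            standardize = standardize)
      coefs[r, ] <- as.numeric(stats::coef(fit))[-1]
      p <- as.numeric(stats::predict(fit, X[te, , drop = FALSE],
                                     type = "response"))
      pred <- factor(ifelse(p > 0.5, "promiscuous", "orthogonal"),
                     levels = levels(lab))
      acc[r] <- mean(pred == lab[te])
      tab <- table(lab[te], pred)
      rs <- rowSums(tab)
      if (all(rs > 0)) {
        conf <- conf + tab / rs
        conf_n <- conf_n + 1L
      }
      if (nlevels(droplevels(lab[te])) == 2L) {
        auc[r] <- as.numeric(pROC::auc(pROC::roc(
          lab[te], p, levels = c("orthogonal", "promiscuous"),
          direction = "<", quiet = TRUE)))
      }
    }
  })
  structure(
    list(accuracy = mean(acc),
         auc = mean(auc, na.rm = TRUE),
         confusion = matrix(conf / max(conf_n, 1L), 2L, 2L,
                            dimnames = dimnames(conf)),
         coefficients = tibble::tibble(
           term = feature_cols,
           estimate = colMeans(coefs),
           std_error = apply(coefs, 2, stats::sd)),
         n_repeats = n_repeats,
         per_split = tibble::tibble(split = seq_len(n_repeats),
                                    accuracy = acc, auc = auc)),
    class = "ois_classifier_report"
  )
}

#' @exportS3Method base::print
print.ois_classifier_report <- function(x, ...) {
  cat("<ois_classifier_report> ", x$n_repeats, " random splits\n",
      "mean accuracy: ", signif(x$accuracy, 4),
      "   mean AUC: ", signif(x$auc, 4), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
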