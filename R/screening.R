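## Sequence-encoded affinity screening: Conjoint-Triad features, dataset
## splitting, regression metrics and variant ranking. Model fitting lives
## in models.R.

## The standard 7-class physicochemical grouping used by the Conjoint
## Triad method (electrostatics + side-chain volume).
CT_CLASS <- c(A = 1L, G = 1L, V = 1L,
              I = 2L, L = 2L, F = 2L, P = 2L,
              Y = 3L, M = 3L, T = 3L, S = 3L,
              H = 4L, N = 4L, Q = 4L, W = 4L,
              R = 5L, K = 5L,
              D = 6L, E = 6L,
              C = 7L)

#' Conjoint-Triad encoding of a peptide or protein sequence
#'
#' Maps each residue to one of 7 physicochemical classes and counts every
#' overlapping window of three classes into a 343-bin vector (bin index
#' `c1*49 + c2*7 + c3` in zero-based form). `"frequency"` normalisation
#' divides by the number of windows (`L - 2`) so vectors are comparable
#' across lengths; `"count"` keeps raw window counts.
#'
#' @param seq sequence string, length >= 3, standard 20 letters.
#' @param normalize `"frequency"` (default) or `"count"`.
#' @return numeric vector of 343 bins.
#' @export
conjoint_triad <- function(seq, normalize = c("frequency", "count")) {
  normalize <- match.arg(normalize)
  letters <- validate_sequence(seq, "sequence")
  L <- length(letters)
  if (L < 3) stop("sequence must have length >= 3 for triad encoding")
  cls <- unname(CT_CLASS[letters])
  c1 <- cls[1:(L - 2)]; c2 <- cls[2:(L - 1)]; c3 <- cls[3:L]
  idx <- (c1 - 1L) * 49L + (c2 - 1L) * 7L + c3
  bins <- tabulate(idx, nbins = 343)
  if (normalize == "frequency") bins <- bins / (L - 2)
  as.numeric(bins)
}

#' Encode a peptide-target pair
#'
#' Concatenates the peptide's and the target's 343-bin triad vectors into a
#' 686-value feature vector.
#'
#' @param peptide,target sequence strings, each length >= 3.
#' @inheritParams conjoint_triad
#' @return numeric vector of 686 features.
#' @export
encode_pair <- function(peptide, target, normalize = "frequency") {
  c(conjoint_triad(peptide, normalize), conjoint_triad(target, normalize))
}

#' Encode many peptide-target pairs into a feature matrix
#'
#' @param peptides character vector of peptide sequences.
#' @param targets single target sequence or one per peptide.
#' @inheritParams conjoint_triad
#' @return matrix with one row per pair, 686 columns.
#' @export
encode_pairs <- function(peptides, targets, normalize = "frequency") {
  targets <- rep_len(targets, length(peptides))
  t(mapply(function(p, t) encode_pair(p, t, normalize), peptides, targets))
}

#' Shuffle-split an affinity dataset
#'
#' @param records data.frame with at least columns `peptide_seq`,
#'   `target_seq`, `affinity` (>= 5 rows).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer RNG seed; the split is reproducible for a fixed
#'   seed.
#' @return `list(train =, test =)` of disjoint, exhaustive subsets;
#'   `|train| = round(train_fraction * n)`.
#' @export
split_dataset <- function(records, train_fraction = 0.8, seed = 42) {
  if (nrow(records) < 5) stop("need at least 5 records to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  perm <- withr_seed(seed, sample.int(nrow(records)))
  n_train <- round(train_fraction * nrow(records))
  list(train = records[perm[seq_len(n_train)], , drop = FALSE],
       test = records[perm[-seq_len(n_train)], , drop = FALSE])
}

## Evaluate `expr` under a local RNG seed without disturbing the caller's
## RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Regression-quality metrics
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return list with `r2` (`1 - SS_res/SS_tot`), `mse`, `mae`, `pearson`.
#'   Zero-variance `y` makes `r2`/`pearson` `NaN` with a warning.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - yhat)^2)
  if (ss_tot == 0) {
    warning("zero-variance response: R^2 and Pearson undefined")
    r2 <- NaN
    pearson <- NaN
  } else {
    r2 <- 1 - ss_res / ss_tot
    pearson <- if (stats::sd(yhat) == 0) NaN else stats::cor(y, yhat)
  }
  list(r2 = r2, mse = mean((y - yhat)^2), mae = mean(abs(y - yhat)),
       pearson = pearson)
}

#' Train/test metrics report for a fitted model
#'
#' @param model a fitted `affinity_model`.
#' @param X_train,y_train training features and affinities.
#' @param X_test,y_test test features and affinities.
#' @return a `metrics_report` with `$train` and `$test` metric lists.
#' @export
evaluate_model <- function(model, X_train, y_train, X_test, y_test) {
  if (length(y_test) == 0) stop("empty test set")
  rep <- list(train = regression_metrics(y_train, predict(model, X_train)),
              test = regression_metrics(y_test, predict(model, X_test)),
              kind = model$kind)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s\n", x$kind))
  for (split in c("train", "test")) {
    m <- x[[split]]
    cat(sprintf("  %-5s R2=%.4f MSE=%.4f MAE=%.4f r=%.4f\n", split,
                m$r2, m$mse, m$mae, m$pearson))
  }
  invisible(x)
}

#' Rank mutant-library variants by predicted affinity
#'
#' Predicts an affinity for every variant paired with the target and sorts
#' ascending (most negative = strongest binder first); ties keep library
#' order; the list is truncated to `k` rows.
#'
#' @param model fitted `affinity_model`.
#' @param library a `mutant_library`.
#' @param target target sequence used for pairing.
#' @param k number of top variants to return.
#' @inheritParams conjoint_triad
#' @return data.frame with `name`, `sequence`, `predicted`, best first.
#' @export
rank_variants <- function(model, library, target, k = 20,
                          normalize = "frequency") {
  if (!is.numeric(k) || k <= 0) stop("k must be a positive integer")
  if (nrow(library) == 0) stop("empty mutant library")
  X <- encode_pairs(library$sequence, target, normalize)
  pred <- predict(model, X)
  ord <- order(pred, seq_along(pred))  # stable: ties keep library order
  out <- data.frame(name = library$name[ord], sequence = library$sequence[ord],
                    predicted = pred[ord], stringsAsFactors = FALSE)
  utils::head(out, min(as.integer(k), nrow(out)))
}
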