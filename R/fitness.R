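#' Fitness-evaluation parameters
#'
#' The objective rewards mean validation accuracy and, once that accuracy
#' exceeds the expectation threshold `d`, adds a parsimony bonus
#' `omega_f / n_selected` so that among near-perfect subsets the smaller
#' one wins.  Defaults follow the published protocol: `omega_f = 1`,
#' `d = 0.98`, 20 random 75/25 splits.
#'
#' @param omega_f Nonnegative feature-selection cost weight.
#' @param d Expected-accuracy threshold in (0, 1].
#' @param n_splits Number of random train/test splits (>= 1).
#' @param train_fraction Fraction of each class placed in training, in (0,1).
#' @return A `fitness_params` object.
#' @export
fitness_params <- function(omega_f = 1, d = 0.98, n_splits = 20L,
                           train_fraction = 0.75) {
  if (omega_f < 0) stop("omega_f must be nonnegative")
  if (!(d > 0 && d <= 1)) stop("d must be in (0, 1]")
  if (n_splits < 1L) stop("n_splits must be >= 1")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  structure(list(omega_f = omega_f, d = d, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction),
            class = "fitness_params")
}

#' Stratified random train/test split
#'
#' Each class contributes `ceiling(train_fraction * n_c)` samples to the
#' training set (never fewer than one), drawn uniformly without
#' replacement; the remainder go to test.  Stratification is a deliberate
#' strengthening of plain random splitting: with as few as 8 samples in a
#' class, an unstratified 25% draw can leave a class entirely out of
#' training, making the classifier undefined for it.
#'
#' @param dataset An `expression_dataset` (labeled).
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with integer vectors `train` and `test` partitioning
#'   `seq_len(n_samples(dataset))`.
#' @export
random_split <- function(dataset, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  labels <- dataset$labels
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 samples cannot be split: ",
         paste(small, collapse = ", "))
  train <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      k <- max(1L, ceiling(train_fraction * length(idx)))
      train <- c(train, sort(sample(idx, k)))
    }
  })
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  if (length(test) == 0L)
    stop("split left the test set empty; reduce train_fraction or add samples")
  list(train = train, test = test)
}

#' Overall classification accuracy
#'
#' The ratio of correctly classified samples to the total number of
#' samples.
#'
#' @param predicted,truth Equal-length nonempty label vectors.
#' @return Scalar in \[0, 1\].
#' @export
overall_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(truth) == 0L)
    stop("empty label vector")
  if (length(predicted) != length(truth))
    stop("length mismatch: ", length(predicted), " predictions vs ",
         length(truth), " truths")
  mean(as.character(predicted) == as.character(truth))
}

#' Subset-size-penalised fitness
#'
#' `f = mean_accuracy + omega_f / n_selected` when `mean_accuracy > d`
#' (strict), and `f = mean_accuracy` otherwise.  The denominator is the
#' number of 1-bits in the chromosome, so at equal accuracy above the
#' threshold a smaller gene set scores strictly higher.
#'
#' @param mean_accuracy Scalar in \[0, 1\].
#' @param n_selected Number of selected genes (>= 1).
#' @param params A `fitness_params` object.
#' @return Scalar fitness value.
#' @export
eq1_fitness <- function(mean_accuracy, n_selected, params = fitness_params()) {
  if (n_selected < 1L)
    stop("n_selected must be >= 1 (the fitness divides by the bit count)")
  if (mean_accuracy < 0 || mean_accuracy > 1)
    stop("mean_accuracy must lie in [0, 1]")
  if (mean_accuracy > params$d)
    mean_accuracy + params$omega_f / n_selected
  else
    mean_accuracy
}

#' Evaluate a gene subset by repeated split-train-test
#'
#' Restricts the expression matrix to the genes the chromosome selects,
#' then for each of `n_splits` seeded stratified splits trains a fresh ELM
#' (new random hidden layer per split, averaging over initialisation
#' noise) on the training part and records overall accuracy on the test
#' part.  The fitness is the size-penalised value of the mean accuracy.
#'
#' @param dataset A labeled `expression_dataset`.
#' @param chromosome Binary 0/1 vector of length `n_genes(dataset)` with at
#'   least one bit set, or an integer vector of selected gene indices.
#' @param params A `fitness_params` object.
#' @param elm List of classifier settings: `n_hidden` (default
#'   `min(n_train, 100)`), `activation`.
#' @param seed Integer seed; together with the dataset and chromosome it
#'   determines the result bit-for-bit.
#' @return A `fitness_result`: `mean_accuracy`, `n_selected`, `fitness`,
#'   `per_split_accuracies`.
#' @export
evaluate_subset <- function(dataset, chromosome, params = fitness_params(),
                            elm = list(), seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sel <- chromosome_to_indices(chromosome, n_genes(dataset))
  Xall <- t(dataset$matrix[sel, , drop = FALSE]) # samples x selected genes
  labels <- dataset$labels
  acts <- numeric(params$n_splits)
  for (s in seq_len(params$n_splits)) {
    sp <- random_split(dataset, params$train_fraction,
                       seed = derive_seed(seed, 1L, s))
    m <- train_elm(Xall[sp$train, , drop = FALSE], labels[sp$train],
                   n_hidden = elm$n_hidden %||% NULL,
                   activation = elm$activation %||% "sigmoid",
                   seed = derive_seed(seed, 2L, s))
    acts[s] <- overall_accuracy(predict_elm(m, Xall[sp$test, , drop = FALSE]),
                                labels[sp$test])
  }
  out <- fitness_result(mean(acts), length(sel), acts, params)
  attr(out, "seed") <- as.integer(seed) # echoed so any cached result can be replayed
  out
}

fitness_result <- function(mean_accuracy, n_selected, per_split, params) {
  structure(list(mean_accuracy = mean_accuracy,
                 n_selected = as.integer(n_selected),
                 fitness = eq1_fitness(mean_accuracy, n_selected, params),
                 per_split_accuracies = per_split),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result> fitness %.4f (mean accuracy %.4f over %d splits, %d genes)\n",
              x$fitness, x$mean_accuracy, length(x$per_split_accuracies),
              x$n_selected))
  invisible(x)
}

# Accept either a full-length 0/1 vector or a plain index vector; always
# return sorted unique 1-based gene indices with >= 1 entry.
chromosome_to_indices <- function(chromosome, n_genes) {
  chromosome <- as.integer(chromosome)
  if (length(chromosome) == n_genes && all(chromosome %in% c(0L, 1L))) {
    sel <- which(chromosome == 1L)
  } else if (all(chromosome >= 1L & chromosome <= n_genes)) {
    sel <- sort(unique(chromosome))
  } else {
    stop("chromosome must be a 0/1 vector of length ", n_genes,
         " or a vector of gene indices in 1..", n_genes)
  }
  if (length(sel) == 0L)
    stop("chromosome selects no genes (all-zero); the fitness divides by ",
         "the selected-gene count")
  sel
}
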