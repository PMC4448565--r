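#' Specification of a synthetic multi-class expression dataset
#'
#' The generator emulates the regime of multi-class tumour compendia: many
#' features of which only a handful are class-discriminative, few samples
#' per class, and optional class imbalance.  Each informative gene gets a
#' random binary class pattern (some classes at a high mean, the rest at a
#' low mean, the two levels `effect_size * noise_sd` apart), so different
#' informative genes separate different class subsets; noise genes share
#' one mean across all classes.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Integer vector of per-class sample counts
#'   (recycled to `n_classes`); each must be >= 2.
#' @param n_informative Number of planted discriminative genes (>= 1).
#' @param n_noise Number of noise genes (>= 0).
#' @param effect_size Class-mean separation in units of `noise_sd`.
#' @param noise_sd Within-class standard deviation (> 0).
#' @param log_normal If `TRUE`, exponentiate the simulated values, giving
#'   the right-skewed marginals typical of raw intensity data.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_classes = 4L, samples_per_class = 15L,
                           n_informative = 10L, n_noise = 490L,
                           effect_size = 5, noise_sd = 1,
                           log_normal = FALSE, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (any(samples_per_class < 2L))
    stop("every class needs >= 2 samples")
  if (n_informative < 1L) stop("n_informative must be >= 1")
  if (n_noise < 0L) stop("n_noise must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  structure(list(n_classes = n_classes,
                 samples_per_class = samples_per_class,
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size, noise_sd = noise_sd,
                 log_normal = isTRUE(log_normal),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with planted structure
#'
#' @param spec A `synthetic_spec`.
#' @return List with `dataset` (an `expression_dataset`; gene order is
#'   shuffled so informative genes are not positionally clustered) and
#'   `truth` (a `planted_truth`: `informative_gene_ids` and the
#'   `class_mean_matrix`, `n_informative` x `n_classes`).
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_classes = 3, n_noise = 50,
#'                                        seed = 7))
#' sim$dataset
#' sim$truth$informative_gene_ids
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_genes <- spec$n_informative + spec$n_noise
  n_total <- sum(spec$samples_per_class)
  class_names <- paste0("class", seq_len(spec$n_classes))
  labels <- rep(class_names, times = spec$samples_per_class)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  out <- with_seed(spec$seed, {
    sep <- spec$effect_size * spec$noise_sd
    # random non-constant high/low class pattern per informative gene
    mu <- matrix(0, spec$n_informative, spec$n_classes,
                 dimnames = list(NULL, class_names))
    for (g in seq_len(spec$n_informative)) {
      repeat {
        pat <- stats::rbinom(spec$n_classes, 1L, 0.5)
        if (spec$effect_size == 0 || length(unique(pat)) > 1L) break
      }
      mu[g, ] <- pat * sep
    }
    X <- matrix(stats::rnorm(n_genes * n_total, sd = spec$noise_sd),
                nrow = n_genes)
    for (g in seq_len(spec$n_informative))
      X[g, ] <- X[g, ] + mu[g, match(labels, class_names)]
    perm <- sample.int(n_genes)
    list(X = X[perm, , drop = FALSE], ids = gene_ids,
         informative = gene_ids[order(perm)[seq_len(spec$n_informative)]],
         mu = mu)
  })
  X <- out$X
  if (spec$log_normal) X <- exp(X)
  rownames(X) <- out$ids
  colnames(X) <- sprintf("S%04d", seq_len(n_total))
  truth <- structure(list(informative_gene_ids = out$informative,
                          class_mean_matrix = out$mu),
                     class = "planted_truth")
  list(dataset = expression_dataset(X, out$ids, labels), truth = truth)
}

#' Precision and recall of a gene selection against the planted truth
#'
#' @param selected Nonempty vector of selected gene identifiers.
#' @param truth A `planted_truth`.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
recovery_score <- function(selected, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  selected <- unique(as.character(selected))
  if (length(selected) == 0L) stop("empty selection")
  hit <- sum(selected %in% truth$informative_gene_ids)
  c(precision = hit / length(selected),
    recall = hit / length(truth$informative_gene_ids))
}
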