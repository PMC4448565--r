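# Shared fixtures, all generated in code.

# Hand-built hidden layer with known weights (bypasses the random draw).
make_hidden <- function(V, b, activation = "sigmoid") {
  structure(list(n_hidden = nrow(V), input_weights = V, bias = b,
                 activation = activation),
            class = "hidden_layer_params")
}

# Tiny linearly separable multi-class set: class c centred at
# radius * (cos, sin) of angle 2*pi*c/k, well beyond the unit noise.
separable_points <- function(n_per_class = 10, k = 3, radius = 6,
                             seed = 1) {
  withr::with_seed(seed, {
    ang <- 2 * pi * seq_len(k) / k
    X <- do.call(rbind, lapply(seq_len(k), function(c)
      cbind(radius * cos(ang[c]) + rnorm(n_per_class),
            radius * sin(ang[c]) + rnorm(n_per_class))))
    list(X = X, y = rep(LETTERS[seq_len(k)], each = n_per_class))
  })
}

# Small labeled expression dataset wrapping separable samples: two
# informative rows (the coordinates) plus pure-noise rows.
separable_dataset <- function(n_per_class = 8, k = 2, n_noise_genes = 3,
                              seed = 1) {
  pts <- separable_points(n_per_class, k, seed = seed)
  M <- rbind(t(pts$X),
             matrix(withr::with_seed(seed + 1,
                                     rnorm(n_noise_genes * nrow(pts$X))),
                    nrow = n_noise_genes))
  rownames(M) <- paste0("g", seq_len(nrow(M)))
  colnames(M) <- paste0("s", seq_len(ncol(M)))
  expression_dataset(M, labels = pts$y)
}

# Deterministic small synthetic world reused across tests.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_spec(
        n_classes = 4, samples_per_class = 15, n_informative = 10,
        n_noise = 490, effect_size = 5, seed = 42))
    cache
  }
})

informative_bits <- function(sim) {
  as.integer(sim$dataset$gene_ids %in% sim$truth$informative_gene_ids)
}
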