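# Small fixtures shared across test files; everything is generated in code.

# A tiny backbone for fast CPU tests: 32x32 input, ~6k parameters.
tiny_arch <- function(input_size = 32, embedding = 32) {
  arch <- dissimspace:::new_architecture(
    99L,
    list(dissimspace:::conv_l(5, 8, stride = 2),
         dissimspace:::pool_l(2),
         dissimspace:::conv_l(3, 8),
         dissimspace:::relu_l(),
         dissimspace:::fc_l(embedding)),
    embedding, input_size = input_size, name = "tiny_test_net")
  arch
}

tiny_dataset <- function(classes = 2, per_class = 12, side = 32,
                         separation = 2, noise_sd = 0.3, seed = 42) {
  synth_images(classes = classes, per_class = per_class, side = side,
               separation = separation, noise_sd = noise_sd, seed = seed)
}

random_image <- function(side = 16) matrix(runif(side * side), side, side)

# Brute-force plug-in MI oracle: joint table by double loop over bins.
mi_oracle <- function(a, b, bins) {
  ia <- dissimspace:::bin_index(a, bins)
  ib <- dissimspace:::bin_index(b, bins)
  n <- length(a)
  total <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      pij <- sum(ia == i & ib == j) / n
      if (pij > 0) {
        total <- total + pij * log(pij / ((sum(ia == i) / n) * (sum(ib == j) / n)))
      }
    }
  }
  total
}

# Brute-force AUC oracle: count positive/negative pairs, ties half credit.
auc_oracle <- function(s, positive) {
  pos <- s[positive]; neg <- s[!positive]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}
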