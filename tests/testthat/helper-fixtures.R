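# Shared fixtures, built in code at test time.

standard_residues <- function() unname(unlist(residue_groups()))

random_standard_sequence <- function(len) {
  paste(sample(standard_residues(), len, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# Two well-separated Gaussian clouds over the nine attributes; positives are
# short, positively charged. All columns vary so every algorithm family
# (including naive Bayes) can be fit.
toy_separable_dataset <- function(n_per_class = 25, seed = 42,
                                  task = "RP_vs_NRP",
                                  species = "toy") {
  set.seed(seed)
  mk <- function(n, pos_mean, len_mean) {
    data.frame(
      aromatic           = rnorm(n, 0.05, 0.01),
      negatively_charged = rnorm(n, 0.10, 0.01),
      nonpolar_aliphatic = rnorm(n, 0.35, 0.02),
      polar_uncharged    = rnorm(n, 0.25, 0.02),
      positively_charged = rnorm(n, pos_mean, 0.015),
      hydrophobicity     = rnorm(n, -0.8, 0.1),
      molecular_mass     = rnorm(n, 130, 2),
      volume             = rnorm(n, 135, 2),
      length             = round(rnorm(n, len_mean, 15)))
  }
  neg_class <- if (task == "RP_vs_NRP") "NRP" else "HP"
  labeled_dataset(
    species, task,
    features = rbind(mk(n_per_class, 0.30, 150), mk(n_per_class, 0.12, 450)),
    class_name = c(rep("RP", n_per_class), rep(neg_class, n_per_class)),
    seed = seed)
}

# Minimal 8-instance, 4/4 two-class dataset for leave-one-out equivalence.
toy_eight_dataset <- function() {
  feats <- data.frame(
    aromatic           = c(.04, .05, .06, .05, .05, .04, .06, .05),
    negatively_charged = c(.10, .11, .09, .10, .10, .11, .09, .10),
    nonpolar_aliphatic = c(.34, .35, .36, .35, .35, .34, .36, .35),
    polar_uncharged    = c(.24, .25, .26, .25, .25, .24, .26, .25),
    positively_charged = c(.30, .31, .29, .32, .12, .13, .11, .14),
    hydrophobicity     = c(-1.1, -1.0, -1.2, -1.0, -0.4, -0.5, -0.3, -0.5),
    molecular_mass     = c(129, 130, 128, 131, 131, 132, 130, 133),
    volume             = c(134, 135, 133, 136, 133, 134, 132, 135),
    length             = c(140, 150, 160, 145, 420, 450, 480, 430))
  labeled_dataset("toy8", "RP_vs_NRP", feats,
                  c(rep("RP", 4), rep("NRP", 4)))
}

# Independent mutual-information oracle: I(bin; class) from the joint count
# table, via H(X) + H(Y) - H(X, Y).
mi_oracle <- function(bins, labels) {
  joint <- table(bins, labels)
  h <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  h(rowSums(joint)) + h(colSums(joint)) - h(joint)
}

# A small cached benchmark + registry so pipeline tests do not refit models
# in every block.
cached_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(bench = default_benchmark(seed = 1))
      cache$registry <<- build_registry(cache$bench, seed = 11)
    }
    cache
  }
})
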