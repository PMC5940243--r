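# Shared fixtures and independent oracles, built in code.

# A tiny hand-written record set covering all demographic branches.
tiny_records <- function() {
  emr_records(
    patient_id = c("p1", "p2", "p3", "p4"),
    class_label = c("Black", "White", "Hispanic", "Other"),
    age_years = c(45, 30, 45, 62),
    gender = c("female", "male", "unknown", "trans"),
    icd9_codes = list(c("401.9", "789.00"), "401.9", character(), c("250.00", "V72.6"))
  )
}

# Write records in the text dialect to a temp file and return the path.
tiny_emr_file <- function(records = tiny_records()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_emr_file(records, path)
  path
}

# Brute-force AUC by all-pairs concordance counting (ties = 1/2).
brute_force_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Small untrained network with reproducible weights for DeepLIFT checks.
toy_model <- function(input_dim = 10, hidden = c(6, 5), activation = "prelu",
                      alpha0 = 0.25, seed = 1, n_classes = 4) {
  build_mlp(network_spec(input_dim, hidden, activation, dropout_rate = 0,
                         n_classes = n_classes, prelu_alpha_init = alpha0),
            seed = seed)
}

# Effective weight matrix of an identity-activation (alpha = 1) network:
# the product of the layer weight matrices. Bias terms cancel in
# difference-from-reference space.
effective_weights <- function(model) {
  Reduce(`%*%`, lapply(model$layers, `[[`, "W"))
}

# A linearly separable 4-class cohort: two binary marker features whose
# joint pattern determines the class exactly.
separable_xy <- function(n = 500, n_noise = 3, seed = 1) {
  withr::with_seed(seed, {
    cls <- sample.int(4, n, replace = TRUE)
    X <- cbind(as.numeric(cls %in% c(2, 4)), as.numeric(cls %in% c(3, 4)),
               matrix(rbinom(n * n_noise, 1, 0.1), n, n_noise))
    list(X = X, y = cls)
  })
}
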