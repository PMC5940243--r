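# DeepLIFT feature-to-class contribution scores for the trained MLP,
# implemented from first principles with the rescale rule.
#
# Each output-node difference from its reference value, delta_t, is
# decomposed over input features so that sum_i C[i, t] = delta_t
# (summation-to-delta). Multipliers chain backwards through the network:
# affine layers use the linear rule (a weight w propagates w * delta_x),
# and rectifier nonlinearities use the rescale rule (multiplier =
# delta_out / delta_in relative to reference, falling back to the
# activation's derivative at the reference when |delta_in| is tiny).
# The input reference is the all-zeros vector — the natural "no observed
# disease, no demographics" baseline for sparse binary encodings — and
# hidden/output references are its forward pass.

#' Compute layer-wise reference activations
#'
#' Propagates the reference input (all zeros by default) through the model,
#' recording pre- and post-activation values at every layer.
#'
#' @param model a trained `mlp_model`
#' @param input_reference optional custom reference vector of length
#'   `input_dim` (e.g. population disease incidences); defaults to zeros
#' @return a `deeplift_refs` object with per-layer `z` and `a`, plus the
#'   reference `logits` and `probs`
#' @export
compute_references <- function(model, input_reference = NULL) {
  x0 <- input_reference %||% numeric(model$spec$input_dim)
  if (length(x0) != model$spec$input_dim)
    stop_("input_reference must have length ", model$spec$input_dim)
  fw <- mlp_forward(model, matrix(x0, nrow = 1))
  structure(list(input = x0,
                 z = lapply(fw$z, as.numeric),
                 a = lapply(fw$a, as.numeric),
                 logits = as.numeric(fw$logits),
                 probs = as.numeric(fw$probs)),
            class = "deeplift_refs")
}

# Rescale-rule multiplier matrices from the input to each target node, for
# one sample. Shared by deeplift_sample() and the batch aggregator.
deeplift_multipliers <- function(model, refs, fw_row, target_layer, eps = 1e-7) {
  L <- length(model$layers)
  C_dim <- model$spec$n_classes
  M <- diag(C_dim)
  delta_logits <- as.numeric(fw_row$logits) - refs$logits
  if (target_layer == "probabilities") {
    dp <- as.numeric(fw_row$probs) - refs$probs
    m_soft <- ifelse(abs(delta_logits) > eps, dp / delta_logits,
                     refs$probs * (1 - refs$probs))
    M <- diag(m_soft, nrow = C_dim)
  }
  for (l in L:1) {
    M <- model$layers[[l]]$W %*% M           # linear rule through layer l
    if (l > 1) {                             # rescale rule through activation l-1
      zs <- as.numeric(fw_row$z[[l - 1]]); zr <- refs$z[[l - 1]]
      as_ <- as.numeric(fw_row$a[[l]]); ar <- refs$a[[l]]
      dz <- zs - zr
      alpha <- model$layers[[l - 1]]$alpha
      m_act <- ifelse(abs(dz) > eps, (as_ - ar) / dz,
                      ifelse(zr > 0, 1, alpha))
      if (any(!is.finite(m_act)))
        stop_("non-finite rescale multiplier at hidden layer ", l - 1)
      M <- m_act * M
    }
  }
  list(M = M,
       delta = if (target_layer == "probabilities")
         as.numeric(fw_row$probs) - refs$probs else delta_logits)
}

#' DeepLIFT contribution scores for a single patient
#'
#' Decomposes each class output's difference-from-reference into per-feature
#' contributions `C[i, t]` obeying summation-to-delta. Scores target the
#' pre-softmax logits by default; `target_layer = "probabilities"` rescales
#' each class column so the decomposition holds on the probability scale.
#'
#' @param model a trained `mlp_model`
#' @param refs references from [compute_references()]
#' @param x binary input row of length `input_dim`
#' @param target_layer `"logits"` (default) or `"probabilities"`
#' @param eps rescale-rule degeneracy threshold on |delta input|
#' @return a `sample_contribution`: matrix `C` (features x classes) and the
#'   per-class `delta`
#' @export
deeplift_sample <- function(model, refs, x, target_layer = c("logits", "probabilities"),
                            eps = 1e-7) {
  target_layer <- match.arg(target_layer)
  x <- as.numeric(x)
  if (length(x) != model$spec$input_dim)
    stop_("sample has length ", length(x), " but input_dim is ", model$spec$input_dim)
  fw <- mlp_forward(model, matrix(x, nrow = 1))
  mu <- deeplift_multipliers(model, refs, fw, target_layer, eps)
  C <- (x - refs$input) * mu$M
  C <- as.matrix(C)
  delta <- mu$delta
  if (model$spec$n_classes == length(RE_CLASSES)) {
    colnames(C) <- RE_CLASSES
    names(delta) <- RE_CLASSES
  }
  structure(list(C = C, delta = delta, target_layer = target_layer),
            class = "sample_contribution")
}

#' Aggregate DeepLIFT scores over samples (and experiments)
#'
#' Element-wise sum of per-sample contribution matrices, optionally on top
#' of a previous aggregate — used to sum scores across all test samples of a
#' fold and then across the k cross-validation experiments.
#'
#' @param samples list of `sample_contribution`s (or bare matrices)
#' @param previous optional `contribution_matrix` to accumulate onto
#' @return a `contribution_matrix` with `scores` (features x classes) and
#'   `sample_count`
#' @export
aggregate_contributions <- function(samples, previous = NULL) {
  mats <- lapply(samples, function(s) if (inherits(s, "sample_contribution")) s$C else s)
  scores <- NULL; count <- 0L
  if (!is.null(previous)) {
    stopifnot(inherits(previous, "contribution_matrix"))
    scores <- previous$scores; count <- previous$sample_count
  }
  for (m in mats) {
    if (is.null(scores)) scores <- m * 0
    if (!identical(dim(scores), dim(m))) stop_("contribution shape mismatch")
    scores <- scores + m
    count <- count + 1L
  }
  if (is.null(scores)) stop_("nothing to aggregate: empty sample list and no previous matrix")
  structure(list(scores = scores, sample_count = count),
            class = "contribution_matrix")
}

#' Aggregate DeepLIFT scores for a whole batch of samples
#'
#' Computes per-sample contributions and their running sum without storing
#' each sample's matrix; the workhorse behind fold-level interpretation.
#'
#' @param model a trained `mlp_model`
#' @param X matrix or `encoded_batch` of samples to explain
#' @param refs optional precomputed references
#' @param target_layer `"logits"` or `"probabilities"`
#' @param check_tol if non-NULL, verify summation-to-delta for every sample
#'   at this relative tolerance and error on violation
#' @return a `contribution_matrix`
#' @export
deeplift_scores <- function(model, X, refs = NULL,
                            target_layer = c("logits", "probabilities"),
                            check_tol = NULL) {
  target_layer <- match.arg(target_layer)
  if (inherits(X, "encoded_batch")) X <- X$matrix
  X <- as.matrix(X)
  refs <- refs %||% compute_references(model)
  fw <- mlp_forward(model, X)
  n <- nrow(X)
  scores <- matrix(0, model$spec$input_dim, model$spec$n_classes)
  for (i in seq_len(n)) {
    row <- list(z = lapply(fw$z, function(m) m[i, ]),
                a = lapply(fw$a, function(m) m[i, ]),
                logits = fw$logits[i, ], probs = fw$probs[i, ])
    mu <- deeplift_multipliers(model, refs, row, target_layer)
    C <- (X[i, ] - refs$input) * mu$M
    if (!is.null(check_tol)) {
      err <- abs(colSums(C) - mu$delta) / pmax(abs(mu$delta), 1e-8)
      if (any(err > check_tol))
        stop_("summation-to-delta violated for sample ", i,
              " (max relative error ", format(max(err)), ")")
    }
    scores <- scores + C
  }
  rownames(scores) <- colnames(X) %||% paste0("f", seq_len(nrow(scores)))
  if (model$spec$n_classes == length(RE_CLASSES)) colnames(scores) <- RE_CLASSES
  structure(list(scores = as.matrix(scores), sample_count = n),
            class = "contribution_matrix")
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat("DeepLIFT contribution matrix:", nrow(x$scores), "features x",
      ncol(x$scores), "classes, aggregated over", x$sample_count, "samples\n")
  invisible(x)
}

#' Descending class ordering for one feature
#'
#' Sorts the four classes from the most positive to the most negative
#' contribution score. Ties are broken by the canonical class order
#' (Other, White, Hispanic, Black) for determinism.
#'
#' @param feature_name the feature being ordered
#' @param scores numeric 4-vector of scores, in canonical class order (or
#'   named by class)
#' @return a `class_ordering` with `classes` (descending) and the matching
#'   `scores`
#' @export
class_ordering <- function(feature_name, scores) {
  if (!is.null(names(scores))) scores <- scores[RE_CLASSES]
  scores <- as.numeric(scores)
  if (length(scores) != length(RE_CLASSES) || any(!is.finite(scores)))
    stop_("scores must be ", length(RE_CLASSES), " finite values")
  ord <- order(-scores)  # stable: ties keep canonical class order
  structure(list(feature_name = feature_name,
                 classes = RE_CLASSES[ord], scores = scores[ord]),
            class = "class_ordering")
}

#' @export
print.class_ordering <- function(x, ...) {
  cat(x$feature_name, "->",
      paste(sprintf("%s (%s)", x$classes, format(x$scores, trim = TRUE)),
            collapse = " > "), "\n")
  invisible(x)
}

#' Frequency-based class ordering for one feature
#'
#' The non-model counterpart of a DeepLIFT ordering: classes sorted by the
#' number of labeled samples in each class exhibiting the feature, with
#' mean-centered counts as scores.
#'
#' @param batch a labeled `encoded_batch`
#' @param feature feature name present in the batch's vocabulary
#' @return a `class_ordering`; the raw per-class counts are attached as
#'   attribute `"counts"`
#' @export
frequency_ordering <- function(batch, feature) {
  j <- batch$vocab$index_of[feature]
  if (is.na(j)) stop_("unknown feature: ", feature)
  present <- as.numeric(batch$matrix[, j])
  lab <- batch$labels
  counts <- vapply(seq_along(RE_CLASSES),
                   function(k) sum(present[!is.na(lab) & lab == k]), 0)
  names(counts) <- RE_CLASSES
  out <- class_ordering(feature, counts - mean(counts))
  attr(out, "counts") <- counts
  out
}

#' Rank features by the range of their class scores
#'
#' A feature whose scores spread widely across classes discriminates between
#' them; range = max(scores) - min(scores). Ties are broken by feature name.
#'
#' @param matrix a `contribution_matrix`
#' @param top_k how many features to return (clamped to the feature count)
#' @return data frame with `feature` and `range`, descending
#' @export
rank_features_by_range <- function(matrix, top_k = 10) {
  stopifnot(top_k >= 1)
  s <- matrix$scores
  rng <- apply(s, 1, max) - apply(s, 1, min)
  ord <- order(-rng, rownames(s), method = "radix")
  top <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(feature = rownames(s)[top], range = rng[top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate class orderings for every feature
#'
#' One row per feature with classes in descending-score order and the
#' corresponding scores, sorted by score range (descending, ties by name).
#'
#' @param matrix a `contribution_matrix`
#' @param descriptions optional named character map feature -> description
#' @param top_k optional cap on the number of rows
#' @return data frame with columns `feature`, `description`, `class_1..4`,
#'   `score_1..4`, `range`
#' @export
orderings_table <- function(matrix, descriptions = NULL, top_k = NULL) {
  s <- matrix$scores
  ranked <- rank_features_by_range(matrix, top_k %||% nrow(s))
  rows <- lapply(seq_len(nrow(ranked)), function(r) {
    f <- ranked$feature[r]
    o <- class_ordering(f, s[f, ])
    data.frame(feature = f,
               description = unname(descriptions[f] %||% NA_character_),
               class_1 = o$classes[1], class_2 = o$classes[2],
               class_3 = o$classes[3], class_4 = o$classes[4],
               score_1 = o$scores[1], score_2 = o$scores[2],
               score_3 = o$scores[3], score_4 = o$scores[4],
               range = ranked$range[r], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export class orderings as TSV
#' @param matrix a `contribution_matrix`
#' @param path output path
#' @param descriptions optional named map feature -> description
#' @param top_k optional row cap
#' @export
export_orderings <- function(matrix, path, descriptions = NULL, top_k = NULL) {
  tab <- orderings_table(matrix, descriptions, top_k)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an orderings TSV written by [export_orderings()]
#' @param path file path
#' @return data frame in the [orderings_table()] layout
#' @export
read_orderings <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "", colClasses = c(feature = "character"))
}
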