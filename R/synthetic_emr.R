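# Synthetic EMR cohorts with known class-conditional feature structure.
#
# The generator emulates the structure of a de-identified EMR extract: four
# mutually exclusive race/ethnicity classes with unbalanced priors, sparse
# binary ICD9-like disease features, integer ages and quinary gender. Marker
# features are Bernoulli with an elevated prevalence in one target class;
# background features share one prevalence across classes; age and gender
# carry no class signal. Because features are conditionally independent
# given class, both the Bayes-optimal accuracy and the ground-truth
# feature-to-class associations are known exactly, which is what makes model
# training and DeepLIFT interpretation testable without private patient data.
#
# An optional interaction mode plants feature *pairs* whose agreement
# (both present or both absent) is informative for a class while each
# feature's marginal prevalence is 0.5 in every class — a signal invisible
# to a main-effects linear model but learnable by an MLP.

DEFAULT_PRIORS <- c(Other = 0.532, White = 0.187, Hispanic = 0.155, Black = 0.126)

#' Default planted-marker table: two markers per class
#'
#' @param prev_in marker prevalence within the target class
#' @param prev_out marker prevalence in the other classes
#' @param n_per_class markers planted per class
#' @return data frame with columns `feature`, `target_class`,
#'   `prevalence_in_target`, `prevalence_elsewhere`
#' @export
default_markers <- function(prev_in = 0.6, prev_out = 0.05, n_per_class = 2) {
  pool <- c("401.9", "250.00", "282.60", "042", "070.32", "493.90",
            "290.0", "088.81", "285.9", "571.5", "696.1", "733.00")
  k <- 4 * n_per_class
  if (k > length(pool)) stop_("at most ", length(pool) / 4, " markers per class")
  data.frame(feature = pool[seq_len(k)],
             target_class = rep(RE_CLASSES, each = n_per_class),
             prevalence_in_target = prev_in,
             prevalence_elsewhere = prev_out,
             stringsAsFactors = FALSE)
}

#' Specify a synthetic EMR cohort
#'
#' @param n_patients cohort size
#' @param n_background_features number of uninformative ICD9-like features
#'   (same Bernoulli prevalence in every class)
#' @param class_priors probability 4-vector over `RE_CLASSES` (sums to 1);
#'   defaults mirror a large two-city EMR composition
#' @param markers data frame as from [default_markers()]; may be NULL
#' @param interactions optional data frame with columns `feature_a`,
#'   `feature_b`, `target_class`, `concordance_in_target`,
#'   `concordance_elsewhere`: the pair agrees (11 or 00) with the
#'   class-conditional concordance probability, and each member has marginal
#'   prevalence 0.5 everywhere
#' @param background_prevalence baseline Bernoulli rate for background features
#' @param age_distribution data frame `age`, `prob`; default is a discretized
#'   bell over ages 18-90 (mean 45, sd 16), identical across classes
#' @param gender_distribution named probability vector over `GENDER_LEVELS`
#' @param seed integer seed; the cohort is a pure function of the spec
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n_patients,
                        n_background_features = 100,
                        class_priors = DEFAULT_PRIORS,
                        markers = default_markers(),
                        interactions = NULL,
                        background_prevalence = 0.05,
                        age_distribution = NULL,
                        gender_distribution = c(male = 0.46, female = 0.50,
                                                trans = 0.005, other = 0.005,
                                                unknown = 0.03),
                        seed = 1) {
  stopifnot(n_patients >= 1, n_background_features >= 0)
  class_priors <- unname(class_priors)
  if (length(class_priors) != 4 || abs(sum(class_priors) - 1) > 1e-8 || any(class_priors < 0))
    stop_("class_priors must be 4 non-negative probabilities summing to 1")
  if (!is.null(markers) && nrow(markers) > 0) {
    stopifnot(all(markers$target_class %in% RE_CLASSES))
    if (any(markers$prevalence_in_target < 0 | markers$prevalence_in_target > 1) ||
        any(markers$prevalence_elsewhere < 0 | markers$prevalence_elsewhere > 1))
      stop_("marker prevalences must lie in [0, 1]")
    if (any(markers$prevalence_in_target <= markers$prevalence_elsewhere))
      stop_("each marker needs prevalence_in_target > prevalence_elsewhere")
    if (anyDuplicated(markers$feature)) stop_("duplicate marker feature names")
  }
  if (!is.null(interactions) && nrow(interactions) > 0) {
    stopifnot(all(interactions$target_class %in% RE_CLASSES),
              all(c("feature_a", "feature_b") %in% names(interactions)))
    if (any(interactions$concordance_in_target <= interactions$concordance_elsewhere))
      stop_("each interaction needs concordance_in_target > concordance_elsewhere")
  }
  if (background_prevalence < 0 || background_prevalence > 1)
    stop_("background_prevalence must lie in [0, 1]")
  if (is.null(age_distribution)) {
    ages <- 18:90
    w <- stats::dnorm(ages, mean = 45, sd = 16)
    age_distribution <- data.frame(age = ages, prob = w / sum(w))
  }
  gender_distribution <- gender_distribution[GENDER_LEVELS]
  if (anyNA(gender_distribution) || abs(sum(gender_distribution) - 1) > 1e-8)
    stop_("gender_distribution must cover the five gender levels and sum to 1")
  structure(list(n_patients = as.integer(n_patients),
                 n_background_features = as.integer(n_background_features),
                 class_priors = class_priors,
                 markers = markers, interactions = interactions,
                 background_prevalence = background_prevalence,
                 age_distribution = age_distribution,
                 gender_distribution = gender_distribution,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

background_feature_names <- function(n) {
  if (n == 0) return(character())
  sprintf("%03d.%d", 700 + (seq_len(n) - 1) %/% 10, (seq_len(n) - 1) %% 10)
}

#' Generate a synthetic EMR cohort
#'
#' Draws each patient's class from the priors, then each feature
#' independently with its class-conditional prevalence. Identical specs
#' (including seed) yield identical cohorts.
#'
#' @param spec a `cohort_spec`
#' @return list with `records` (an `emr_records` data frame) and `markers`
#'   (ground-truth marker table, including interaction rows if any)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  withr::with_seed(spec$seed, {
    cls <- sample(RE_CLASSES, n, replace = TRUE, prob = spec$class_priors)
    age <- sample(spec$age_distribution$age, n, replace = TRUE,
                  prob = spec$age_distribution$prob)
    gender <- sample(GENDER_LEVELS, n, replace = TRUE, prob = spec$gender_distribution)
    per_patient <- vector("list", n)
    add_feature <- function(name, present) {
      idx <- which(present == 1)
      for (i in idx) per_patient[[i]] <<- c(per_patient[[i]], name)
    }
    if (!is.null(spec$markers) && nrow(spec$markers) > 0) {
      for (r in seq_len(nrow(spec$markers))) {
        m <- spec$markers[r, ]
        p <- ifelse(cls == m$target_class, m$prevalence_in_target, m$prevalence_elsewhere)
        add_feature(m$feature, stats::rbinom(n, 1, p))
      }
    }
    if (!is.null(spec$interactions) && nrow(spec$interactions) > 0) {
      for (r in seq_len(nrow(spec$interactions))) {
        it <- spec$interactions[r, ]
        p_conc <- ifelse(cls == it$target_class, it$concordance_in_target,
                         it$concordance_elsewhere)
        conc <- stats::rbinom(n, 1, p_conc)
        high <- stats::rbinom(n, 1, 0.5)
        a <- high
        b <- ifelse(conc == 1, high, 1 - high)
        add_feature(it$feature_a, a)
        add_feature(it$feature_b, b)
      }
    }
    for (f in background_feature_names(spec$n_background_features)) {
      add_feature(f, stats::rbinom(n, 1, spec$background_prevalence))
    }
  })
  per_patient <- lapply(per_patient, function(x) x %||% character())
  records <- emr_records(sprintf("p%06d", seq_len(n)), cls, age, gender, per_patient)
  truth <- spec$markers
  if (!is.null(spec$interactions) && nrow(spec$interactions) > 0) {
    inter <- data.frame(
      feature = paste(spec$interactions$feature_a, spec$interactions$feature_b, sep = "+"),
      target_class = spec$interactions$target_class,
      prevalence_in_target = spec$interactions$concordance_in_target,
      prevalence_elsewhere = spec$interactions$concordance_elsewhere,
      stringsAsFactors = FALSE)
    truth <- rbind(truth, inter)
  }
  list(records = records, markers = truth)
}

#' Exact Bayes-optimal accuracy under the generative model
#'
#' Enumerates all joint presence patterns of the informative bits (marker
#' features, plus one concordance bit per interaction pair) and returns the
#' accuracy of the classifier that picks the maximum-posterior class for each
#' pattern. Background features, age and gender are class-independent and
#' contribute nothing. This is an analytic ceiling: no classifier's expected
#' accuracy on a cohort drawn from `spec` can exceed it.
#'
#' @param spec a `cohort_spec` with at most 20 informative bits
#' @return the Bayes accuracy as a probability
#' @export
bayes_optimal_accuracy <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p_in <- c(if (!is.null(spec$markers)) spec$markers$prevalence_in_target,
            if (!is.null(spec$interactions)) spec$interactions$concordance_in_target)
  p_out <- c(if (!is.null(spec$markers)) spec$markers$prevalence_elsewhere,
             if (!is.null(spec$interactions)) spec$interactions$concordance_elsewhere)
  target <- c(if (!is.null(spec$markers)) spec$markers$target_class,
              if (!is.null(spec$interactions)) spec$interactions$target_class)
  m <- length(p_in)
  if (m == 0) return(max(spec$class_priors))
  if (m > 20) stop_("pattern enumeration infeasible beyond 20 informative bits")
  patterns <- as.matrix(expand.grid(rep(list(0:1), m)))
  acc <- 0
  for (r in seq_len(nrow(patterns))) {
    bits <- patterns[r, ]
    lik <- vapply(RE_CLASSES, function(cl) {
      p <- ifelse(target == cl, p_in, p_out)
      prod(ifelse(bits == 1, p, 1 - p))
    }, 0)
    joint <- spec$class_priors * lik
    acc <- acc + max(joint)
  }
  acc
}

#' Write a cohort's ground-truth marker table as TSV
#' @param markers marker table from [generate_cohort()]
#' @param path output path
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
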