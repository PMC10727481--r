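#' Equal-frequency discretization
#'
#' Bins a continuous vector into `n_bins` bins of as-equal-as-possible size
#' (counts differ by at most one), with ties broken by value order. Vectors
#' with at most `n_bins` distinct values are treated as already discrete and
#' mapped to their value ranks; a constant vector falls into a single bin.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer bin labels in `1..n_bins`.
#' @export
#' @examples
#' discretize(1:10, 2)
discretize <- function(x, n_bins = 3) {
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) return(match(x, ux))
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

#' Class-entropy-minimising binary discretization
#'
#' Splits a continuous feature at the cut point (midpoint between adjacent
#' sorted values) that minimises the conditional class entropy
#' \eqn{H(Y \mid X > t)}, i.e. the single most class-informative threshold.
#' This supervised binning is what makes a high symmetrical-uncertainty
#' threshold operative: under equal-frequency binning the SU between a
#' k-binned feature and a binary class is bounded by
#' \eqn{2 H(Y) / (\log_2 k + H(Y)) < 0.9} for any realistically unbalanced
#' class, so a 0.9 selection rule could never fire (see the package
#' vignette). Features with few distinct values are left as-is.
#'
#' @param x Numeric feature.
#' @param y Class labels (factor or vector).
#' @param max_distinct Features with at most this many distinct values are
#'   treated as already discrete.
#' @return Integer labels (1 = below the cut, 2 = above).
#' @export
entropy_discretize <- function(x, y, max_distinct = 3) {
  ux <- sort(unique(x))
  if (length(ux) <= max_distinct) return(match(x, ux))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  n <- length(x)
  cond_H <- vapply(cuts, function(t) {
    hi <- x > t
    p_hi <- mean(hi)
    p_hi * shannon_entropy(prop.table(table(y[hi]))) +
      (1 - p_hi) * shannon_entropy(prop.table(table(y[!hi])))
  }, numeric(1))
  best <- cuts[which.min(cond_H)]
  as.integer(x > best) + 1L
}

#' Symmetrical uncertainty between two discrete variables
#'
#' \deqn{SU(X, Y) = \frac{2\,IG(X; Y)}{H(X) + H(Y)},}
#' the information gain \eqn{IG = H(X) + H(Y) - H(X, Y)} normalised into
#' \eqn{[0, 1]}; entropies are Shannon entropies (base 2) of the empirical
#' frequencies. SU is symmetric, equals 1 when either variable determines
#' the other, 0 when they are empirically independent, and is defined as 0
#' when both variables are constant (\eqn{H(X) + H(Y) = 0}).
#'
#' @param x,y Discrete label vectors of equal length (>= 2).
#' @return SU value in `[0, 1]`.
#' @export
#' @examples
#' symmetrical_uncertainty(rep(1:2, each = 5), rep(c("a", "b"), each = 5))
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal lengths", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  n <- length(x)
  hx <- shannon_entropy(tabulate(match(x, unique(x))) / n)
  hy <- shannon_entropy(tabulate(match(y, unique(y))) / n)
  if (hx + hy == 0) return(0)
  joint <- paste(match(x, unique(x)), match(y, unique(y)))
  hxy <- shannon_entropy(tabulate(match(joint, unique(joint))) / n)
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

#' Correlation-based feature selection via symmetrical uncertainty
#'
#' Ranks every feature by its symmetrical uncertainty (SU) with the class
#' and selects the relevant, non-redundant subset: a feature is kept when
#' its SU with the class exceeds `threshold` *and* exceeds its SU with other
#' features. Two redundancy readings are provided:
#' \describe{
#'   \item{`mode = "all"` (default)}{the literal rule — the feature's
#'     class-SU must strictly exceed its SU with *every* other feature.
#'     Note the documented consequence: two near-duplicate features that are
#'     both perfectly class-aligned eliminate each other.}
#'   \item{`mode = "fcbf"`}{sequential fast-correlation-based filtering —
#'     walk the class-SU ranking from the top, keep a feature unless some
#'     already-kept feature g has \eqn{SU(f, g) \ge SU(f, class)}.}
#' }
#' Features are discretized before any SU computation:
#' `discretization = "entropy"` (default) uses the class-entropy-minimising
#' binary split of [entropy_discretize()]; `"frequency"` uses equal-frequency
#' bins ([discretize()]). Integer-valued features with few distinct values
#' (e.g. clinical scores) are used as-is in both modes.
#'
#' @param table Feature table (data frame); its feature columns are all
#'   columns except `patient_id` and `label`.
#' @param labels Class labels; taken from `table$label` when omitted.
#' @param threshold SU-to-class selection threshold (default 0.9).
#' @param n_bins Bins for frequency discretization / `max_distinct` for the
#'   entropy split.
#' @param discretization `"entropy"` or `"frequency"`.
#' @param mode `"all"` (literal pairwise rule) or `"fcbf"`.
#' @return An object of class `cfs_selection`: list with `scores` (named
#'   class-SU, descending), `matrix` (pairwise feature SU), `selected`
#'   (character, ordered by descending class-SU), `threshold`, `mode`,
#'   `discretization`. An empty selection is returned with a warning;
#'   downstream callers fall back to all features.
#' @export
#' @examples
#' y <- rep(c("a", "b"), each = 10)
#' tab <- data.frame(good = as.numeric(y == "a") + rnorm(20, 0, 0.01),
#'                   noise = rnorm(20), label = y)
#' cfs_select(tab, threshold = 0.9)$selected
cfs_select <- function(table, labels = NULL, threshold = 0.9, n_bins = 3,
                       discretization = c("entropy", "frequency"),
                       mode = c("all", "fcbf")) {
  discretization <- match.arg(discretization)
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- table$label
  feats <- feature_names(table)
  if (length(feats) < 2) stop("need at least 2 features", call. = FALSE)

  disc <- lapply(table[feats], function(x) {
    switch(discretization,
      entropy = entropy_discretize(x, labels, max_distinct = n_bins),
      frequency = discretize(x, n_bins))
  })
  su_class <- vapply(disc, symmetrical_uncertainty, numeric(1), y = labels)
  p <- length(feats)
  su_mat <- diag(1, p)
  dimnames(su_mat) <- list(feats, feats)
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      su_mat[i, j] <- su_mat[j, i] <-
        symmetrical_uncertainty(disc[[i]], disc[[j]])
    }
  }

  ord <- order(-su_class)  # ties keep column order
  if (mode == "all") {
    keep <- vapply(seq_len(p), function(i) {
      su_class[i] > threshold && all(su_class[i] > su_mat[i, -i])
    }, logical(1))
    selected <- feats[ord][keep[ord]]
  } else {
    selected <- character(0)
    for (i in ord) {
      if (su_class[i] <= threshold) next
      redundant <- any(su_mat[i, selected] >= su_class[i])
      if (!redundant) selected <- c(selected, feats[i])
    }
  }
  if (!length(selected)) {
    warning("no feature passed the selection rule (threshold ", threshold,
            "); callers fall back to all features", call. = FALSE)
  }
  structure(list(scores = sort(su_class, decreasing = TRUE),
                 matrix = su_mat, selected = selected,
                 threshold = threshold, mode = mode,
                 discretization = discretization),
            class = "cfs_selection")
}

#' @export
print.cfs_selection <- function(x, ...) {
  cat("<cfs_selection> threshold", x$threshold, "| mode", x$mode,
      "| discretization", x$discretization, "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  top <- utils::head(x$scores, 5)
  cat("  top SU-to-class:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
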