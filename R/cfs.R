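## ---- entropy helpers (log base 2) -------------------------------------

entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Supervised entropy-based discretization (MDL stopping rule)
#'
#' Recursive binary splitting of a numeric feature: each split minimises
#' the class-entropy of the partition and is accepted only when its
#' information gain passes the minimum-description-length criterion
#' (Fayyad & Irani). Features for which no split is accepted collapse to a
#' single bin and carry no class information.
#'
#' @param x Numeric vector.
#' @param y Class factor of the same length.
#' @return Integer vector of bin codes, with the cut points in the
#'   `breaks` attribute.
#' @export
mdl_discretize <- function(x, y) {
  stopifnot(length(x) == length(y))
  y <- droplevels(as.factor(y))
  ord <- order(x)
  xs <- x[ord]
  yi <- as.integer(y)[ord]
  k_all <- nlevels(y)
  cuts <- numeric(0)

  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return()
    seg_y <- yi[lo:hi]
    seg_x <- xs[lo:hi]
    cnt <- tabulate(seg_y, k_all)
    ent_s <- entropy_counts(cnt)
    if (ent_s == 0) return()
    ## cumulative class counts for O(1) entropy at each candidate
    cum <- vapply(seq_len(k_all), function(c) cumsum(seg_y == c), numeric(n))
    cand <- which(seg_x[-n] < seg_x[-1])  # splits between distinct values
    if (length(cand) == 0) return()
    best_i <- NA_integer_
    best_e <- Inf
    for (i in cand) {
      c1 <- cum[i, ]
      c2 <- cnt - c1
      e <- (i * entropy_counts(c1) + (n - i) * entropy_counts(c2)) / n
      if (e < best_e) {
        best_e <- e
        best_i <- i
      }
    }
    c1 <- cum[best_i, ]
    c2 <- cnt - c1
    gain <- ent_s - best_e
    k <- sum(cnt > 0)
    k1 <- sum(c1 > 0)
    k2 <- sum(c2 > 0)
    delta <- log2(3^k - 2) -
      (k * ent_s - k1 * entropy_counts(c1) - k2 * entropy_counts(c2))
    if (gain <= (log2(n - 1) + delta) / n) return()
    cuts <<- c(cuts, (seg_x[best_i] + seg_x[best_i + 1L]) / 2)
    recurse(lo, lo + best_i - 1L)
    recurse(lo + best_i, hi)
  }
  recurse(1L, length(xs))
  breaks <- sort(cuts)
  codes <- findInterval(x, breaks) + 1L
  attr(codes, "breaks") <- breaks
  codes
}

#' Symmetrical uncertainty between two discrete variables
#'
#' `2 * IG(a; b) / (H(a) + H(b))`, a normalised mutual information in
#' `[0, 1]`; 0 when either variable is constant.
#'
#' @param a,b Discrete vectors (factors or integer codes) of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(a, b) {
  tab <- table(a, b)
  h_a <- entropy_counts(rowSums(tab))
  h_b <- entropy_counts(colSums(tab))
  if (h_a + h_b == 0) return(0)
  h_ab <- entropy_counts(as.numeric(tab))
  ig <- h_a + h_b - h_ab
  max(0, 2 * ig / (h_a + h_b))
}

#' CFS merit of a feature subset
#'
#' Hall's correlation-based merit
#' `k * rcf / sqrt(k + k * (k - 1) * rff)`, where `rcf` is the mean
#' feature-class correlation of the subset and `rff` the mean pairwise
#' feature-feature correlation (both measured as symmetrical uncertainty):
#' relevance rewarded, redundancy penalised.
#'
#' @param subset Integer or logical index into `su_cf`.
#' @param su_cf Numeric vector of feature-class correlations.
#' @param su_ff Symmetric matrix of feature-feature correlations.
#' @return Scalar merit; 0 for an empty subset.
#' @export
cfs_merit <- function(subset, su_cf, su_ff) {
  idx <- if (is.logical(subset)) which(subset) else as.integer(subset)
  k <- length(idx)
  if (k == 0) return(0)
  rcf <- mean(su_cf[idx])
  if (k == 1) return(rcf)
  rff <- mean(su_ff[idx, idx][upper.tri(diag(k))])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

## discretize every feature and build the SU structures once
cfs_correlations <- function(table, features, label) {
  disc <- purrr::map(features, function(f) mdl_discretize(table[[f]], label))
  names(disc) <- features
  su_cf <- vapply(disc, symmetrical_uncertainty, numeric(1), b = label)
  p <- length(features)
  su_ff <- diag(1, p)
  if (p > 1) {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        su_ff[i, j] <- su_ff[j, i] <- symmetrical_uncertainty(disc[[i]], disc[[j]])
      }
    }
  }
  dimnames(su_ff) <- list(features, features)
  list(su_cf = su_cf, su_ff = su_ff)
}

#' Correlation-based feature selection with best-first search
#'
#' Numeric features are first discretized with the supervised MDL method
#' ([mdl_discretize()]); feature-class and feature-feature correlations are
#' symmetrical uncertainties on the discretized codes. A forward best-first
#' search over subsets maximises the CFS merit ([cfs_merit()]) and stops
#' after `max_stale` consecutive expansions without improvement. Constant
#' features are excluded before the search.
#'
#' @param table Feature table with a `label` column.
#' @param features Candidate feature columns; default [feature_columns()].
#' @param label_col Name of the class column, default `"label"`.
#' @param max_stale Stale-expansion stopping limit, default 5.
#' @return Tibble of the selected features (`feature`, `su_class`), in
#'   decreasing feature-class correlation, with the achieved `merit` and
#'   the correlation structures as attributes.
#' @export
#' @examples
#' tab <- synth_cohort_table(2, seed = 3)
#' cfs_select(tab)
cfs_select <- function(table, features = NULL, label_col = "label",
                       max_stale = 5) {
  if (is.null(features)) features <- feature_columns(table)
  label <- droplevels(as.factor(table[[label_col]]))
  keep <- vapply(features, function(f) {
    v <- table[[f]]
    is.numeric(v) && length(unique(v)) > 1
  }, logical(1))
  features <- features[keep]
  if (length(features) < 2) {
    stop("need at least 2 non-constant numeric features", call. = FALSE)
  }
  cors <- cfs_correlations(table, features, label)
  su_cf <- cors$su_cf
  su_ff <- cors$su_ff
  p <- length(features)

  key_of <- function(idx) paste0("s", paste(sort(idx), collapse = ","))
  ## open list holds subsets not yet expanded, keyed to avoid revisits
  open <- list(list(idx = integer(0), merit = 0))
  seen <- new.env(parent = emptyenv())
  assign(key_of(integer(0)), TRUE, envir = seen)
  best <- list(idx = integer(0), merit = 0)
  stale <- 0L
  while (length(open) > 0 && stale < max_stale) {
    merits <- vapply(open, function(s) s$merit, numeric(1))
    i_best <- which.max(merits)
    node <- open[[i_best]]
    open[[i_best]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$idx)) {
      idx <- c(node$idx, f)
      key <- key_of(idx)
      if (exists(key, envir = seen)) next
      assign(key, TRUE, envir = seen)
      m <- cfs_merit(idx, su_cf, su_ff)
      open[[length(open) + 1L]] <- list(idx = idx, merit = m)
      if (m > best$merit + 1e-12) {
        best <- list(idx = idx, merit = m)
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }

  sel <- best$idx[order(su_cf[best$idx], decreasing = TRUE)]
  out <- tibble::tibble(feature = features[sel], su_class = unname(su_cf[sel]))
  attr(out, "merit") <- best$merit
  attr(out, "su_cf") <- su_cf
  attr(out, "su_ff") <- su_ff
  out
}
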