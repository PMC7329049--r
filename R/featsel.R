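#' Varimax-rotated PCA of an acoustic feature table
#'
#' Rows with missing values are dropped listwise (count reported via a
#' message), features are standardized, and the correlation matrix is
#' eigendecomposed (features have incommensurable units, so the correlation
#' rather than covariance matrix is used). Components whose variance fraction
#' exceeds `retain_rule$var_frac` are retained (at least
#' `retain_rule$min_retain`, with a warning if the rule alone retains fewer),
#' and the retained loadings are varimax-rotated with Kaiser normalization.
#' An orthogonal rotation redistributes but preserves the total retained
#' variance and each feature's communality.
#'
#' @param x Numeric data frame or matrix (stimuli x features); non-feature
#'   columns such as `stimulus_id` are ignored.
#' @param retain_rule List with `var_frac` (default 0.10) and `min_retain`
#'   (default 1).
#' @return Object of class `pca_varimax`: `loadings` (rotated, features x
#'   retained components), `unrotated`, `variance_explained` (per rotated
#'   component, fractions), `variance_unrotated`, `retained`, `rotation`,
#'   `n_used`, `n_dropped`.
#' @export
pca_varimax <- function(x, retain_rule = list(var_frac = 0.10, min_retain = 1)) {
  x <- as.data.frame(x)
  x <- x[vapply(x, is.numeric, TRUE)]
  cc <- complete.cases(x)
  n_dropped <- sum(!cc)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 complete rows")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(names(x)[sds == 0], collapse = ", "))
  }
  if (n_dropped > 0) message(n_dropped, " incomplete row(s) dropped before PCA")

  R <- cor(as.matrix(x))
  eig <- eigen(R, symmetric = TRUE)
  p <- ncol(x)
  frac <- eig$values / p
  var_frac <- retain_rule$var_frac %||% 0.10
  min_retain <- retain_rule$min_retain %||% 1
  retained <- which(frac > var_frac)
  if (length(retained) < min_retain) {
    warning("only ", length(retained), " component(s) exceed ",
            round(100 * var_frac), "% variance; retaining the top ",
            min_retain, " by the retention floor")
    retained <- seq_len(min_retain)
  }
  L <- eig$vectors[, retained, drop = FALSE] %*%
    diag(sqrt(eig$values[retained]), length(retained))
  # eigenvectors are sign-indeterminate; fix each column so its largest
  # absolute loading is positive, making the output order-invariant
  fix_signs <- function(m) {
    s <- apply(m, 2, function(cl) sign(cl[which.max(abs(cl))]))
    sweep(m, 2, ifelse(s == 0, 1, s), "*")
  }
  L <- fix_signs(L)
  dimnames(L) <- list(names(x), paste0("PC", retained))
  if (length(retained) > 1) {
    rot <- varimax(L, normalize = TRUE, eps = 1e-6)
    Lr <- fix_signs(L %*% rot$rotmat)
    dimnames(Lr) <- dimnames(L)
  } else {
    rot <- NULL
    Lr <- L
  }
  structure(list(
    loadings = Lr, unrotated = L,
    variance_explained = colSums(Lr^2) / p,
    variance_unrotated = frac[retained],
    retained = retained,
    rotation = if (is.null(rot)) diag(1) else rot$rotmat,
    n_used = nrow(x), n_dropped = n_dropped), class = "pca_varimax")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from the least-squares regression
#' of feature `j` on the other features of `subset`. A perfectly collinear
#' feature is reported as `Inf` rather than raising an error.
#'
#' @param x Feature table (data frame or matrix).
#' @param subset Character vector of feature names (default: all numeric
#'   columns).
#' @return Named numeric vector of VIFs with attribute `subset`.
#' @export
vif <- function(x, subset = NULL) {
  x <- as.data.frame(x)
  x <- x[vapply(x, is.numeric, TRUE)]
  if (!is.null(subset)) {
    missing_cols <- setdiff(subset, names(x))
    if (length(missing_cols) > 0)
      stop("features not in table: ", paste(missing_cols, collapse = ", "))
    x <- x[subset]
  }
  if (ncol(x) < 2) stop("subset needs at least 2 features")
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) <= ncol(x)) stop("need more rows than features")
  out <- vapply(names(x), function(j) {
    fit <- lm(as.formula(paste0("`", j, "` ~ .")), data = x)
    r2 <- summary(fit)$r.squared
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  attr(out, "subset") <- names(x)
  out
}

#' Select modelling features from the PCA and VIF diagnostics
#'
#' The default `"paper"` policy returns the canonical six-feature set (SCoG,
#' duration, f0 mean, f0 s.d., HNR mean, HNR max). The generic
#' `"loading-vif"` policy walks the retained components round-robin in order
#' of absolute loading and greedily adds each component's strongest unused
#' feature whenever the within-set VIF stays below `vif_threshold`.
#'
#' @param pca A [pca_varimax()] fit (required for the generic policy).
#' @param feature_table The feature table the PCA was fit on (required for
#'   the generic policy, to compute within-set VIFs).
#' @param policy `"paper"` or `"loading-vif"`.
#' @param vif_threshold Maximum within-set VIF (default 5).
#' @param max_features Upper bound on the selected set size.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(pca = NULL, feature_table = NULL,
                            policy = c("paper", "loading-vif"),
                            vif_threshold = 5, max_features = 6) {
  policy <- match.arg(policy)
  if (policy == "paper") {
    return(the_six_features)
  }
  if (is.null(pca) || is.null(feature_table))
    stop("the loading-vif policy needs both a pca_varimax fit and the feature table")
  L <- abs(pca$loadings)
  selected <- character(0)
  # candidate queues per component, strongest loading first
  queues <- lapply(seq_len(ncol(L)), function(j) rownames(L)[order(-L[, j])])
  progressed <- TRUE
  while (length(selected) < max_features && progressed) {
    progressed <- FALSE
    for (j in seq_along(queues)) {
      queues[[j]] <- setdiff(queues[[j]], selected)
      for (cand in queues[[j]]) {
        trial <- c(selected, cand)
        ok <- length(trial) < 2 ||
          all(is.finite(v <- vif(feature_table, trial))) && max(v) < vif_threshold
        if (ok) {
          selected <- trial
          progressed <- TRUE
          break
        }
      }
      if (length(selected) >= max_features) break
    }
  }
  if (length(selected) == 0)
    stop("no feature satisfies the VIF threshold ", vif_threshold)
  selected
}
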