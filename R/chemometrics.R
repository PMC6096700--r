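#' Principal component model of a spectra matrix
#'
#' @slot center numeric, mean spectrum removed before projection.
#' @slot loadings matrix (variables x components), orthonormal columns.
#' @slot explained numeric, per-component fraction of total variance,
#'   non-increasing.
#' @slot nComponents integer, retained components.
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 explained = "numeric", nComponents = "integer"))

#' @describeIn PCAModel-class summary.
#' @param object a `PCAModel`.
#' @export
setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components, %.1f%% of variance\n",
              object@nComponents,
              100 * sum(object@explained[seq_len(object@nComponents)])))
  invisible(NULL)
})

#' Canonical variate model (PCA subspace + canonical directions)
#'
#' @slot pca the [PCAModel-class] feeding the canonical space, or `NULL`
#'   when fitted directly on scores.
#' @slot vectors matrix (score dimensions x canonical variates), unit-norm
#'   generalized eigenvectors of between- vs within-class scatter, sorted by
#'   decreasing eigenvalue.
#' @slot lambda numeric, generalized eigenvalues (between/within variance
#'   ratios), non-negative.
#' @slot centroids matrix (classes x canonical variates) of class means in
#'   canonical space.
#' @slot ridge numeric, ridge term added to the within-class scatter.
#' @slot classes character, class names (row order of `centroids`).
#' @slot grid numeric, wavenumber axis the model expects (may be empty).
#' @export
setClass("CVAModel",
  representation(pca = "ANY", vectors = "matrix", lambda = "numeric",
                 centroids = "matrix", ridge = "numeric",
                 classes = "character", grid = "numeric"))

#' @describeIn CVAModel-class summary.
#' @param object a `CVAModel`.
#' @export
setMethod("show", "CVAModel", function(object) {
  cat(sprintf("CVAModel: %d classes (%s), %d canonical variates\n",
              length(object@classes),
              paste(object@classes, collapse = ", "), ncol(object@vectors)))
  cat("eigenvalues:", paste(sprintf("%.4g", object@lambda), collapse = ", "),
      "\n")
  invisible(NULL)
})

#' Cross-validation report (per-fold, per-class percent correct)
#'
#' @slot percentCorrect matrix, folds x classes, percent of test spectra of
#'   each class correctly classified in each fold.
#' @slot confusion list of per-fold confusion matrices (truth x prediction).
#' @slot folds integer vector, test-fold assignment of every spectrum.
#' @slot seed integer seed that generated the fold assignment.
#' @slot k integer, number of folds.
#' @export
setClass("CVReport",
  representation(percentCorrect = "matrix", confusion = "list",
                 folds = "integer", seed = "numeric", k = "integer"))

#' @describeIn CVReport-class render the per-fold table with per-class range
#'   and mean.
#' @param object a `CVReport`.
#' @export
setMethod("show", "CVReport", function(object) {
  pc <- object@percentCorrect
  cat(sprintf("%d-fold cross-validation (seed %g)\n", object@k, object@seed))
  cat("% correctly classified\n")
  print(data.frame(k = seq_len(nrow(pc)), round(pc), check.names = FALSE),
        row.names = FALSE)
  rng <- apply(pc, 2, range)
  cat("Range (%):", paste(sprintf("%s %.0f-%.0f", colnames(pc), rng[1, ],
                                  rng[2, ]), collapse = "; "), "\n")
  cat("Mean (%): ", paste(sprintf("%s %.0f", colnames(pc),
                                  colMeans(pc)), collapse = "; "), "\n")
  invisible(NULL)
})

#' Per-class summary of a cross-validation report
#'
#' @param report a [CVReport-class].
#' @return data.frame with one row per class: `class`, `min`, `max`, `mean`
#'   percent correctly classified across folds.
#' @export
cvSummary <- function(report) {
  pc <- report@percentCorrect
  data.frame(class = colnames(pc), min = unname(apply(pc, 2, min)),
             max = unname(apply(pc, 2, max)), mean = unname(colMeans(pc)),
             row.names = NULL)
}

#' Fit a mean-centred principal component model
#'
#' @param m numeric matrix, observations in rows (spectra), variables in
#'   columns (wavenumbers); or an [IRSpectra-class], which is transposed
#'   internally.
#' @param varianceTarget retain the smallest number of components whose
#'   cumulative explained variance fraction reaches this value (in `(0, 1]`),
#'   subject to `cap`.
#' @param nComponents retain exactly this many components (overrides
#'   `varianceTarget`).
#' @param cap hard ceiling on the component count used with
#'   `varianceTarget` (default 21).
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(m, varianceTarget = 0.95, nComponents = NULL, cap = 21) {
  if (is(m, "IRSpectra")) m <- t(absorbance(m))
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 spectra")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  sv <- svd(mc)
  ev <- sv$d^2
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  explained <- ev / sum(ev)
  if (!is.null(nComponents)) {
    k <- min(nComponents, rank)
  } else {
    if (varianceTarget <= 0 || varianceTarget > 1)
      stop("varianceTarget must be in (0, 1]")
    k <- which(cumsum(explained) >= varianceTarget - 1e-12)[1]
    if (is.na(k)) k <- rank
    k <- min(k, cap, rank)
  }
  new("PCAModel", center = ctr,
      loadings = sv$v[, seq_len(k), drop = FALSE],
      explained = explained, nComponents = as.integer(k))
}

#' Project spectra into a PCA score space
#'
#' @param model a [PCAModel-class].
#' @param m matrix (observations x variables) or [IRSpectra-class].
#' @return score matrix (observations x components).
#' @export
pcaScores <- function(model, m) {
  if (is(m, "IRSpectra")) m <- t(absorbance(m))
  sweep(as.matrix(m), 2, model@center) %*% model@loadings
}

## scatter matrices: Sb (between, weighted by class size) and Sw (within,
## pooled sums of squares)
.scatter <- function(s, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  d <- ncol(s)
  gm <- colMeans(s)
  Sb <- matrix(0, d, d); Sw <- matrix(0, d, d)
  centroids <- matrix(0, length(classes), d,
                      dimnames = list(classes, NULL))
  for (g in classes) {
    rows <- s[labels == g, , drop = FALSE]
    mg <- colMeans(rows)
    centroids[g, ] <- mg
    Sb <- Sb + nrow(rows) * tcrossprod(mg - gm)
    cw <- sweep(rows, 2, mg)
    Sw <- Sw + crossprod(cw)
  }
  list(Sb = Sb, Sw = Sw, classes = classes, centroids = centroids)
}

#' Canonical variate analysis on score rows
#'
#' Solves the generalized eigenproblem
#' \deqn{S_b v = \lambda (S_w + ridge \cdot I) v}
#' for the between-class (\eqn{S_b}) and pooled within-class (\eqn{S_w})
#' scatter of the rows of `scores`, via a Cholesky whitening of the
#' regularised within-class scatter followed by a symmetric
#' eigendecomposition. At most `classes - 1` canonical vectors exist; they
#' are returned unit-norm, sorted by decreasing \eqn{\lambda}, signs fixed so
#' each vector's largest-magnitude entry is positive.
#'
#' @param scores numeric matrix, observations x dimensions (typically PCA
#'   scores).
#' @param labels class label per row; at least 2 classes with >= 2 members.
#' @param ridge ridge added to the within-class scatter diagonal; default
#'   `1e-8 * trace(Sw) / ncol(scores)`. Must be > 0 when the within-class
#'   scatter is singular (more dimensions than `rows - classes`).
#' @return a [CVAModel-class] (with empty `pca` and `grid`).
#' @export
fitCVA <- function(scores, labels, ridge = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (nrow(scores) != length(labels)) stop("one label per score row required")
  tab <- table(labels)
  if (length(tab) < 2) stop("single class: canonical variate analysis needs ",
                            ">= 2 classes")
  if (any(tab < 2)) stop("every class needs >= 2 members")
  d <- ncol(scores)
  sc <- .scatter(scores, labels)
  if (is.null(ridge)) ridge <- 1e-8 * sum(diag(sc$Sw)) / d
  if (d > nrow(scores) - length(tab) && ridge <= 0)
    stop("singular within-class scatter; increase ridge or use fewer ",
         "components")
  W <- sc$Sw + ridge * diag(d)
  L <- t(chol(W))
  M <- forwardsolve(L, t(forwardsolve(L, sc$Sb)))
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  ncv <- min(length(tab) - 1L, d)
  V <- backsolve(t(L), eig$vectors[, seq_len(ncv), drop = FALSE])
  V <- apply(V, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  V <- matrix(V, nrow = d)
  lambda <- pmax(eig$values[seq_len(ncv)], 0)
  new("CVAModel", pca = NULL, vectors = V, lambda = lambda,
      centroids = sc$centroids %*% V, ridge = ridge,
      classes = sc$classes, grid = numeric())
}

#' Fit the full PCA + CVA classification model on spectra
#'
#' Compresses the spectra by mean-centred PCA (see [fitPCA()]) and fits
#' canonical variates on the scores (see [fitCVA()]).
#'
#' @param x an [IRSpectra-class]; spectra are the observations.
#' @param labels class label per spectrum.
#' @param varianceTarget,nComponents,cap passed to [fitPCA()].
#' @param ridge passed to [fitCVA()].
#' @return a [CVAModel-class] carrying its `pca` and the wavenumber `grid`.
#' @export
fitCVAModel <- function(x, labels, varianceTarget = 0.95, nComponents = NULL,
                        cap = 21, ridge = NULL) {
  pca <- fitPCA(x, varianceTarget = varianceTarget,
                nComponents = nComponents, cap = cap)
  model <- fitCVA(pcaScores(pca, x), labels, ridge = ridge)
  model@pca <- pca
  model@grid <- wavenumbers(x)
  model
}

#' Canonical coordinates of spectra under a fitted model
#'
#' @param model a [CVAModel-class] fitted with [fitCVAModel()].
#' @param x an [IRSpectra-class] on the model's grid.
#' @return matrix, spectra x canonical variates (columns `CV1`, `CV2`, ...).
#' @export
cvaScores <- function(model, x) {
  if (length(model@grid) &&
      !isTRUE(all.equal(model@grid, wavenumbers(x))))
    stop("grid mismatch: spectra are not on the model's wavenumber axis")
  cc <- pcaScores(model@pca, x) %*% model@vectors
  colnames(cc) <- paste0("CV", seq_len(ncol(cc)))
  rownames(cc) <- spectrumInfo(x)$id
  cc
}

#' Classify spectra by nearest class centroid in canonical space
#'
#' Projects through the model's PCA and canonical vectors, then assigns each
#' spectrum to the class whose centroid is nearest in Euclidean distance.
#' Exact ties go to the lexicographically first class name and are flagged.
#'
#' @param model a [CVAModel-class] from [fitCVAModel()].
#' @param x an [IRSpectra-class] on the model's grid.
#' @return data.frame: `id`, assigned `label`, logical `tie`, canonical
#'   coordinates (`CV1`, ...) and one distance column per class
#'   (`dist_<class>`).
#' @export
classifySpectra <- function(model, x) {
  cc <- cvaScores(model, x)
  D <- vapply(seq_along(model@classes), function(g)
    sqrt(rowSums(sweep(cc, 2, model@centroids[g, ])^2)),
    numeric(nrow(cc)))
  D <- matrix(D, nrow = nrow(cc),
              dimnames = list(NULL, paste0("dist_", model@classes)))
  ## classes are stored sorted: the first index among the tied set is the
  ## lexicographically first class
  tied <- apply(D, 1, function(r) which(r - min(r) < 1e-9 * (1 + min(r))),
                simplify = FALSE)
  best <- vapply(tied, min, integer(1))
  tie <- lengths(tied) > 1
  out <- data.frame(id = rownames(cc), label = model@classes[best],
                    tie = tie, row.names = NULL)
  cbind(out, as.data.frame(cc), as.data.frame(D))
}

## fold assignment without disturbing the caller's RNG stream
.stratifiedFolds <- function(labels, k, seed) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("stratification error: class '",
         names(tab)[which.min(tab)], "' has fewer than k = ", k, " members")
  folds <- integer(length(labels))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (g in names(tab)) {
    idx <- which(labels == g)
    folds[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  folds
}

#' Stratified k-fold cross-validated classification
#'
#' Splits the spectra into `k` stratified folds (seeded, recorded), and for
#' each fold fits the PCA and the canonical variate model on the training
#' rows only, then projects the held-out fold in for nearest-centroid
#' classification — the test data never influence the subspace, so the
#' estimate is leakage-free. A whole-data PCA variant is available for
#' comparison via `wholeDataPCA = TRUE` (it leaks the test rows into the
#' subspace and is not the shipped default).
#'
#' @param x an [IRSpectra-class].
#' @param labels class label per spectrum.
#' @param k number of folds (default 5); every class needs >= k members.
#' @param seed integer controlling the fold assignment.
#' @param varianceTarget,nComponents,cap,ridge model settings per fold, as in
#'   [fitCVAModel()].
#' @param wholeDataPCA logical; fit the PCA once on all spectra (leaky
#'   comparison variant).
#' @return a [CVReport-class].
#' @export
kfoldCrossValidate <- function(x, labels, k = 5, seed = 1,
                               varianceTarget = 0.95, nComponents = NULL,
                               cap = 21, ridge = NULL,
                               wholeDataPCA = FALSE) {
  if (k < 2) stop("k must be >= 2")
  labels <- as.character(labels)
  folds <- .stratifiedFolds(labels, k, seed)
  classes <- sort(unique(labels))
  pc <- matrix(NA_real_, k, length(classes),
               dimnames = list(NULL, classes))
  confusion <- vector("list", k)
  globalPCA <- if (wholeDataPCA)
    fitPCA(x, varianceTarget = varianceTarget, nComponents = nComponents,
           cap = cap) else NULL
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (wholeDataPCA) {
      scores <- pcaScores(globalPCA, x)
      model <- fitCVA(scores[tr, , drop = FALSE], labels[tr], ridge = ridge)
      cc <- scores[te, , drop = FALSE] %*% model@vectors
      D <- vapply(seq_along(model@classes), function(g)
        sqrt(rowSums(sweep(cc, 2, model@centroids[g, ])^2)),
        numeric(nrow(cc)))
      pred <- model@classes[apply(matrix(D, nrow = nrow(cc)), 1, which.min)]
    } else {
      model <- fitCVAModel(x[, tr], labels[tr],
                           varianceTarget = varianceTarget,
                           nComponents = nComponents, cap = cap,
                           ridge = ridge)
      pred <- classifySpectra(model, x[, te])$label
    }
    truth <- labels[te]
    confusion[[f]] <- table(truth = factor(truth, classes),
                            prediction = factor(pred, classes))
    for (g in classes)
      pc[f, g] <- 100 * mean(pred[truth == g] == g)
  }
  new("CVReport", percentCorrect = pc, confusion = confusion,
      folds = folds, seed = seed, k = as.integer(k))
}
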