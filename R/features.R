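#' Non-dimensional spatio-temporal parameters
#'
#' Scales walking speed and step length by leg length (and gravity, for
#' speed) to remove body-size effects: speed maps to `v / sqrt(g * L)` and
#' step length to `s / L`.
#'
#' @param value Raw measurement: speed in m/s or step length in m. Vectorized.
#' @param kind `"speed"` or `"step_length"`.
#' @param leg_length Leg length in meters, strictly positive.
#' @param g Gravitational acceleration in m/s^2.
#' @return Dimensionless value(s).
#' @export
#' @examples
#' nondimensionalize(1.2, "speed", leg_length = 0.75)
nondimensionalize <- function(value, kind = c("speed", "step_length"),
                              leg_length, g = 9.81) {
  kind <- match.arg(kind)
  if (any(!is.finite(leg_length)) || any(leg_length <= 0)) {
    stop("leg_length must be strictly positive")
  }
  switch(kind,
         speed = value / sqrt(g * leg_length),
         step_length = value / leg_length)
}

#' Column-mean imputation
#'
#' Replaces each missing entry by the mean of its column's observed entries;
#' observed entries are unchanged, so column means are preserved exactly.
#'
#' @param x Numeric matrix or data frame with possible `NA` entries.
#' @return Object of the same shape with no missing entries.
#' @export
mean_impute <- function(x) {
  m <- as.matrix(x)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop("column(s) entirely missing, cannot impute: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- mean(m[!miss, j])
  }
  if (is.data.frame(x)) as.data.frame(m) else m
}

#' Condense joint-level exam items into a summary score
#'
#' Physical-exam measurements of one modality (manual muscle strength,
#' selective motor control, or spasticity) are noisy but correlated across
#' joints. This operator condenses them into a single per-limb score by an
#' iterative rank-1 principal-component scheme that also imputes missing
#' cells: mean-impute, standardize columns, take the first principal
#' component, re-impute missing cells from the rank-1 reconstruction, and
#' repeat until the scores change by less than `tolerance`.
#'
#' Scores are standardized to mean 0, SD 1 on the fitting set. The loading
#' vector has unit norm and its sign is fixed so that the loading sum is
#' positive, making higher scores mean more strength / more selective
#' control; spasticity items are negated before scoring so that higher
#' scores mean less spasticity.
#'
#' @param items Numeric matrix or data frame, limbs x items, possibly with
#'   missing entries; at least 2 columns, each with at least 2 observed
#'   values.
#' @param modality `"strength"`, `"smc"` or `"spasticity"`.
#' @param max_iterations Iteration cap for the impute/score loop.
#' @param tolerance Convergence threshold on the maximum absolute change in
#'   standardized scores.
#' @return A list of class `semls_summary_score`: `score` (length-n,
#'   mean 0 / SD 1), `loadings` (unit norm, named by item), `modality`,
#'   `iterations`, `converged`. Non-convergence returns the last iterate
#'   with a warning.
#' @export
summary_score <- function(items, modality = c("strength", "smc", "spasticity"),
                          max_iterations = 100, tolerance = 1e-8) {
  modality <- match.arg(modality)
  m <- as.matrix(items)
  if (ncol(m) < 2) stop("need at least 2 item columns")
  if (any(colSums(!is.na(m)) < 2)) {
    stop("each item column needs at least 2 observed values")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("item_", seq_len(ncol(m)))
  if (modality == "spasticity") m <- -m

  missing <- is.na(m)
  filled <- mean_impute(m)
  score <- rep(0, nrow(m))
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    mu <- colMeans(filled)
    sds <- apply(filled, 2, stats::sd)
    sds[sds == 0] <- 1
    z <- scale(filled, center = mu, scale = sds)
    sv <- svd(z, nu = 1, nv = 1)
    v <- drop(sv$v)
    raw <- drop(z %*% v)
    if (sum(v) < 0) {
      v <- -v
      raw <- -raw
    }
    new_score <- as.vector(scale(raw))
    # rank-1 reconstruction back on natural scale fills the missing cells
    recon <- sweep(sweep(sv$u %*% (sv$d[1] * t(sv$v)), 2, sds, "*"), 2, mu, "+")
    filled[missing] <- recon[missing]
    if (max(abs(new_score - score)) < tolerance) {
      score <- new_score
      converged <- TRUE
      break
    }
    score <- new_score
  }
  if (!converged) {
    warning("summary_score did not converge in ", max_iterations,
            " iterations; returning last iterate")
  }
  structure(
    list(score = score, loadings = stats::setNames(v, colnames(m)),
         modality = modality, iterations = iterations, converged = converged),
    class = "semls_summary_score"
  )
}
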