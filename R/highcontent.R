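# High-content screen normalization and knockdown phenotype profiles.
#
# A screen table is a long-form data.frame with columns
# knockdown / plate / replicate / feature / value: one measured feature
# value per (knockdown, replicate) well. Z-scores are computed within
# each (plate, feature) group to remove plate-level batch effects, then
# replicates are averaged into one phenotype profile per knockdown.

validate_screen_table <- function(table) {
  needed <- c("knockdown", "plate", "replicate", "feature", "value")
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop_config("screen table is missing column(s): %s",
                paste(missing, collapse = ", "))
  if (!all(is.finite(table$value)))
    stop_config("screen table contains non-finite values")
  key <- paste(table$knockdown, table$plate, table$replicate, table$feature,
               sep = "\r")
  if (anyDuplicated(key))
    stop_config("duplicate (knockdown, plate, replicate, feature) keys in screen table")
  invisible(table)
}

#' Z-score screen values within each (plate, feature) group
#'
#' Centers and scales every value by the mean and sample standard
#' deviation (ddof = 1) of its (plate, feature) group, the per-plate
#' normalization used for plate-structured siRNA screens. Groups with
#' fewer than two distinct values cannot be scaled and raise an error
#' naming the offending groups rather than silently producing NaN.
#'
#' @param table long-form screen data.frame with columns
#'   `knockdown`, `plate`, `replicate`, `feature`, `value`
#' @return the same table with `value` replaced by the per-(plate,
#'   feature) Z-score. Idempotent up to numerical tolerance.
#' @examples
#' tab <- data.frame(knockdown = c("A", "B", "C"), plate = "P1",
#'                   replicate = 1, feature = "f", value = c(1, 2, 3))
#' zscore_by_plate(tab)$value  # -1 0 1
#' @export
zscore_by_plate <- function(table) {
  validate_screen_table(table)
  grp <- interaction(table$plate, table$feature, drop = TRUE, sep = " / ")
  n <- tapply(table$value, grp, function(v) length(unique(v)))
  sds <- tapply(table$value, grp, stats::sd)
  bad <- names(n)[n < 2L | sds == 0]
  if (length(bad))
    stop_config("zero-variance (plate / feature) group(s): %s",
                paste(bad, collapse = ", "))
  mu <- tapply(table$value, grp, mean)
  idx <- as.character(grp)
  table$value <- as.numeric((table$value - mu[idx]) / sds[idx])
  table
}

#' Average replicate Z-scores into per-knockdown phenotype profiles
#'
#' For each knockdown and feature, takes the arithmetic mean of the
#' (already Z-scored) values over replicates. A replicate missing one
#' (knockdown, feature) measurement is simply skipped in that mean; a
#' feature with no measurement at all for a knockdown is an error.
#' Knockdowns supported by fewer than `min_replicates` replicates on
#' any feature are excluded and reported via a message.
#'
#' @param table Z-scored screen table (see [zscore_by_plate()])
#' @param min_replicates minimum replicates per feature to keep a
#'   knockdown (default 2)
#' @return an object of class `phenotype_profiles`: list with `z`
#'   (knockdown x feature matrix of averaged Z-scores),
#'   `n_replicates_used` (named integer, the minimum per-feature
#'   replicate count per knockdown) and `excluded` (character)
#' @export
aggregate_replicates <- function(table, min_replicates = 2L) {
  if (!nrow(table)) stop_config("empty screen table")
  validate_screen_table(table)
  kd <- factor(table$knockdown)
  ft <- factor(table$feature)
  z <- tapply(table$value, list(kd, ft), mean)
  n <- tapply(table$value, list(kd, ft), length)
  n[is.na(n)] <- 0L
  if (any(n == 0)) {
    miss <- which(n == 0, arr.ind = TRUE)
    stop_config("feature(s) fully missing for knockdown(s): %s",
                paste(unique(sprintf("%s/%s", rownames(n)[miss[, 1]],
                                     colnames(n)[miss[, 2]])), collapse = ", "))
  }
  n_used <- apply(n, 1, min)
  keep <- n_used >= min_replicates
  if (any(!keep))
    message("excluding knockdown(s) with < ", min_replicates,
            " replicates: ", paste(rownames(z)[!keep], collapse = ", "))
  structure(list(z = z[keep, , drop = FALSE],
                 n_replicates_used = as.integer(n_used[keep]) |>
                   stats::setNames(rownames(z)[keep]),
                 excluded = rownames(z)[!keep]),
            class = "phenotype_profiles")
}

#' @export
print.phenotype_profiles <- function(x, ...) {
  cat(sprintf("phenotype_profiles: %d knockdowns x %d features\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

profile_matrix <- function(profiles) {
  if (inherits(profiles, "phenotype_profiles")) profiles$z
  else as.matrix(profiles)
}

#' Rank knockdowns by one averaged screen feature
#'
#' Orders knockdowns by their replicate-averaged Z-score on the named
#' feature, ascending (the strongest negative phenotype, e.g. fewest
#' colonies, first). Ties are broken lexicographically by knockdown
#' name so the ranking is deterministic.
#'
#' @param profiles `phenotype_profiles` (or knockdown x feature matrix)
#' @param feature feature label to rank on
#' @return data.frame with columns `knockdown`, `score`, best (lowest)
#'   score first
#' @export
rank_hits <- function(profiles, feature) {
  z <- profile_matrix(profiles)
  if (!feature %in% colnames(z))
    stop_config("unknown feature: %s", feature)
  score <- z[, feature]
  ord <- order(score, rownames(z))
  data.frame(knockdown = rownames(z)[ord], score = unname(score[ord]))
}

#' Knockdown-to-knockdown Pearson correlation of phenotype profiles
#'
#' Computes all pairwise Pearson correlations between knockdown
#' phenotype profiles over the feature axis, optionally restricted to a
#' selected feature subset (screens typically correlate on a curated
#' feature panel; the default uses all features).
#'
#' @param profiles `phenotype_profiles` (or knockdown x feature matrix)
#' @param features optional character vector of feature labels
#' @return symmetric correlation matrix with unit diagonal, knockdowns
#'   as dimnames
#' @export
phenotype_correlation <- function(profiles, features = NULL) {
  z <- profile_matrix(profiles)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(z))
    if (length(missing))
      stop_config("unknown feature(s): %s", paste(missing, collapse = ", "))
    z <- z[, features, drop = FALSE]
  }
  if (ncol(z) < 3L)
    stop_config("need >= 3 features to correlate profiles (have %d)", ncol(z))
  sds <- apply(z, 1, stats::sd)
  if (any(sds == 0))
    stop_config("zero-variance profile for knockdown(s): %s",
                paste(rownames(z)[sds == 0], collapse = ", "))
  r <- stats::cor(t(z))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must vary
#' @return list with `slope`, `intercept` and `r_squared`
#'   (the squared Pearson correlation of x and y)
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y differ in length")
  if (length(x) < 3L) stop_config("need >= 3 points")
  if (stats::var(x) == 0) stop_config("x has zero variance")
  fit <- stats::lm.fit(cbind(intercept = 1, x = x), y)
  list(slope = unname(fit$coefficients["x"]),
       intercept = unname(fit$coefficients["intercept"]),
       r_squared = if (stats::var(y) == 0) 0 else stats::cor(x, y)^2)
}

#' Read / write long-form screen tables
#'
#' Tab-separated, header `knockdown plate replicate feature value`.
#' @param path file path
#' @return `read_screen_table`: validated data.frame
#' @export
read_screen_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_screen_table(tab)
  tab
}

#' @rdname read_screen_table
#' @param table screen data.frame
#' @export
write_screen_table <- function(table, path) {
  validate_screen_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
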