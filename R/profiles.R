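#' Structural profiles
#'
#' A structural profile is a tibble with one row per residue of one
#' subunit (or of the whole model), keyed like the model (subunit,
#' seq_num, icode, aa) with the per-residue quantity in `value`. The
#' `kind` attribute records what the values are: `"wcn_raw"` (weighted
#' contact number, the reciprocal packing density), `"cdist_raw"`
#' (centroid distance in Angstrom) or `"normalized"` (dimensionless
#' z-scores).
#'
#' @name structural-profiles
NULL

new_profile <- function(keys, values, kind, context) {
  out <- tibble(subunit = keys$subunit, seq_num = keys$seq_num,
                icode = keys$icode, aa = keys$aa, value = values)
  structure(out, class = c("capsid_profile", class(as_tibble(out))),
            kind = kind, context = context)
}

#' @export
print.capsid_profile <- function(x, ...) {
  cat(sprintf("<capsid_profile> kind=%s, %d residues | %s\n",
              attr(x, "kind") %||% "?", nrow(x), attr(x, "context") %||% ""))
  NextMethod()
  invisible(x)
}

# Squared distances from each of rows (subset) to every residue, summed
# as inverse squares. Blocked so a 6000-residue capsid never materialises
# more than block x N doubles. Uses the expansion
# |a-b|^2 = |a|^2 + |b|^2 - 2 a.b.
inv_sq_sums <- function(X, rows, block = 2048L, tol = 1e-6) {
  N <- nrow(X)
  rs <- rowSums(X * X)
  out <- numeric(length(rows))
  for (start in seq(1, length(rows), by = block)) {
    idx <- rows[start:min(start + block - 1L, length(rows))]
    D2 <- outer(rs[idx], rs, "+") - 2 * X[idx, , drop = FALSE] %*% t(X)
    D2[cbind(seq_along(idx), idx)] <- Inf
    near <- which(D2 < tol^2, arr.ind = TRUE)
    if (nrow(near) > 0) {
      i <- idx[near[1, 1]]; j <- near[1, 2]
      abort(paste0("coincident C-alpha pair (r < ", tol, " A): residues ",
                   i, " and ", j,
                   "; the inverse-square sum is singular there"),
            class = "capsidprof_degenerate_error",
            residues = c(i, j))
    }
    out[start:(start + length(idx) - 1L)] <- rowSums(1 / D2)
  }
  out
}

#' Weighted contact number (packing density) profile
#'
#' For every residue i of the requested subunit, the packing density is
#' \deqn{n_i = \sum_{j \ne i} 1/r_{ij}^2}
#' with the sum running over all residues of the whole model -- there is
#' no cutoff radius and no neighbour truncation, so a residue's packing
#' includes contributions from its own subunit and from every other
#' subunit of the capsid. The profile value is the weighted contact
#' number, the reciprocal \eqn{w_i = 1/n_i}: small w means densely
#' packed, large w means loosely packed.
#'
#' @param model a C-alpha model (whole capsid for capsid work: expand the
#'   assembly first).
#' @param subunit subunit id to report, or `"all"` for every residue.
#' @return a structural profile tibble (kind `"wcn_raw"`).
#' @examples
#' m <- make_shell_capsid(n_subunits = 4, residues_per_subunit = 25,
#'                        radii = 30, radial_jitter_sd = 1, seed = 1)
#' wcn_profile(m, subunit = "A")
#' @export
wcn_profile <- function(model, subunit = "all") {
  model <- as_calpha_model(model, source = attr(model, "source"))
  if (nrow(model) < 2) {
    abort("weighted contact number needs at least 2 residues",
          class = "capsidprof_input_error")
  }
  rows <- subunit_rows(model, subunit)
  n <- inv_sq_sums(coord_matrix(model), rows)
  new_profile(model[rows, ], 1 / n, kind = "wcn_raw",
              context = sprintf("whole model of %d residues, %d subunit(s)",
                                nrow(model), length(model_subunits(model))))
}

#' Centroid-distance profile
#'
#' The centroid distance (c-distance) of a residue is the Euclidean
#' distance from its Calpha to the centroid of the model, the unweighted
#' mean of all Calpha positions. For a capsid the centroid is computed
#' over the whole particle, so the profile is a radial coordinate:
#' residues near the inner surface score low, surface loops score high.
#'
#' @inheritParams wcn_profile
#' @return a structural profile tibble (kind `"cdist_raw"`, Angstrom).
#' @export
cdistance_profile <- function(model, subunit = "all") {
  model <- as_calpha_model(model, source = attr(model, "source"))
  rows <- subunit_rows(model, subunit)
  X <- coord_matrix(model)
  centroid <- colMeans(X)
  d <- sqrt(rowSums(sweep(X[rows, , drop = FALSE], 2, centroid)^2))
  new_profile(model[rows, ], d, kind = "cdist_raw",
              context = sprintf("centroid over %d residues", nrow(model)))
}

# z-scores with the population standard deviation (divisor N).
z_norm <- function(x, what = "profile") {
  if (length(x) < 2) {
    abort(paste0("cannot normalize a ", what, " of length < 2"),
          class = "capsidprof_input_error")
  }
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12 * abs(m) + 1e-300) {
    abort(paste0("constant ", what, ": standard deviation is zero, ",
                 "z-scores are undefined"),
          class = "capsidprof_degenerate_error")
  }
  (x - m) / s
}

#' Normalize a profile to z-scores
#'
#' Shifts and scales the profile so its mean is 0 and its standard
#' deviation is 1 (population convention, divisor N). Applied to a WCN
#' profile this yields z_w, applied to a c-distance profile z_r; both
#' models are compared to conservation on this common dimensionless
#' scale. Idempotent. Constant profiles (e.g. c-distances of an ideal
#' sphere) raise a degenerate-profile error rather than dividing by zero.
#'
#' @param profile a structural profile tibble with a `value` column.
#' @return the profile with `value` replaced by z-scores (kind
#'   `"normalized"`); key order preserved.
#' @export
normalize_profile <- function(profile) {
  if (!"value" %in% names(profile)) {
    abort("profile must have a `value` column", class = "capsidprof_input_error")
  }
  out <- profile
  out$value <- z_norm(profile$value)
  attr(out, "base_kind") <- attr(profile, "kind")
  attr(out, "kind") <- "normalized"
  out
}

#' Sliding-window smoothing
#'
#' Replaces each value by the unweighted mean of the values in a centred
#' index window along the chain, shrinking the window at both ends (the
#' first residue of a window-5 smooth averages positions 1..3). Window 1
#' is the identity. Used to denoise sequence-conservation profiles before
#' comparison; structural profiles can be smoothed the same way for
#' visual comparison.
#'
#' @param profile a profile tibble with a `value` column, or a
#'   conservation profile with a `score` column.
#' @param window odd positive integer window width (default 5).
#' @return the profile with the smoothed column.
#' @export
smooth_profile <- function(profile, window = 5) {
  col <- if ("value" %in% names(profile)) "value"
         else if ("score" %in% names(profile)) "score"
         else abort("profile must have a `value` or `score` column",
                    class = "capsidprof_input_error")
  if (length(window) != 1 || is.na(window) || window < 1 ||
      window != as.integer(window) || window %% 2 == 0) {
    abort("`window` must be an odd positive integer",
          class = "capsidprof_input_error")
  }
  if (window > nrow(profile)) {
    abort("`window` exceeds profile length", class = "capsidprof_input_error")
  }
  out <- profile
  out[[col]] <- as.numeric(zoo::rollapply(profile[[col]], width = window,
                                          FUN = mean, partial = TRUE,
                                          align = "center"))
  out
}
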