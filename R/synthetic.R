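# Run code with a private RNG stream; caller's RNG state is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic golden-angle (Fibonacci) spiral: point i of n sits at
#' height z = 1 - (2i-1)/n and longitude (i-1) times the golden angle,
#' giving an even ~4*pi/n steradian per point without randomness.
#'
#' @param n number of points.
#' @return an n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- (i - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Nudge a direction set so its mean is numerically zero while keeping
# every row on the unit sphere: a jitter-free shell then has its
# centroid at the sphere center and every c-distance exactly equal to
# the radius. The fixed-point iteration contracts the mean by ~1/3 per
# step (the direction covariance of a near-uniform set is ~I/3).
balance_directions <- function(dirs, tol = 1e-13, max_iter = 300) {
  if (nrow(dirs) < 4) return(dirs)   # too few points to balance on a sphere
  for (it in seq_len(max_iter)) {
    m <- colMeans(dirs)
    if (max(abs(m)) < tol) break
    shifted <- sweep(dirs, 2, m)
    dirs <- shifted / sqrt(rowSums(shifted^2))
  }
  dirs
}

# Rows involved in a pair closer than min_sep (blocked O(N^2) scan).
too_close_rows <- function(X, min_sep, block = 2048L) {
  N <- nrow(X)
  rs <- rowSums(X * X)
  bad <- logical(N)
  for (start in seq(1, N, by = block)) {
    idx <- start:min(start + block - 1L, N)
    D2 <- outer(rs[idx], rs, "+") - 2 * X[idx, , drop = FALSE] %*% t(X)
    D2[cbind(seq_along(idx), idx)] <- Inf
    bad[idx] <- bad[idx] | (row_mins(D2) < min_sep^2)
  }
  which(bad)
}

row_mins <- function(M) do.call(pmin, as.data.frame(M))

#' Generate a capsid-like spherical shell model
#'
#' Places `n_subunits * residues_per_subunit` Calpha points
#' quasi-uniformly on one or more concentric spherical shells
#' (deterministic Fibonacci spiral per shell), applies Gaussian radial
#' jitter, and partitions the points into contiguous subunit "chains".
#' This emulates what the structural models see in a real capsid -- a
#' roughly spherical multi-subunit shell with radial depth variation --
#' while having analytic ground truth; it does not emulate protein fold
#' geometry, icosahedral T-number lattices or realistic sequences.
#'
#' Points closer than `min_sep` (which would ill-condition the
#' inverse-square packing sum) get their jitter redrawn, up to
#' `max_retries` rounds; an infeasibly dense specification errors out.
#'
#' @param n_subunits number of chains.
#' @param residues_per_subunit residues per chain.
#' @param radii shell radii in Angstrom, strictly increasing. Points are
#'   split as evenly as possible across shells.
#' @param radial_jitter_sd standard deviation (Angstrom) of Gaussian
#'   jitter applied along the radial direction. Default 0.
#' @param seed integer seed; the same spec and seed give identical
#'   coordinates.
#' @param min_sep minimal allowed inter-point distance in Angstrom
#'   (default 1.0).
#' @param max_retries jitter-resampling rounds before giving up.
#' @return a `calpha_model`; subunit ids are single characters (A-Z,
#'   a-z, 0-9) while they last, then `c<index>`.
#' @examples
#' make_shell_capsid(n_subunits = 3, residues_per_subunit = 40,
#'                   radii = c(45, 50), radial_jitter_sd = 1, seed = 42)
#' @export
make_shell_capsid <- function(n_subunits, residues_per_subunit, radii,
                              radial_jitter_sd = 0, seed = 1,
                              min_sep = 1.0, max_retries = 50) {
  stopifnot(n_subunits >= 1, residues_per_subunit >= 1)
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    abort("`radii` must be strictly positive and increasing",
          class = "capsidprof_input_error")
  }
  if (radial_jitter_sd < 0) {
    abort("`radial_jitter_sd` must be >= 0", class = "capsidprof_input_error")
  }
  total <- n_subunits * residues_per_subunit
  n_shell <- rep(total %/% length(radii), length(radii))
  extra <- total %% length(radii)
  if (extra > 0) n_shell[seq_len(extra)] <- n_shell[seq_len(extra)] + 1

  dirs <- do.call(rbind, lapply(seq_along(radii), function(s)
    balance_directions(fibonacci_sphere(n_shell[s]))))
  base_r <- rep(radii, n_shell)

  X <- with_seed(seed, {
    r <- base_r + rnorm(total, 0, radial_jitter_sd)
    P <- dirs * r
    tries <- 0
    repeat {
      bad <- too_close_rows(P, min_sep)
      if (length(bad) == 0) break
      tries <- tries + 1
      if (tries > max_retries) {
        abort(paste0("cannot satisfy the ", min_sep, " A minimum separation ",
                     "(", length(bad), " residue(s) still clash after ",
                     max_retries, " resampling rounds); the shell is too dense"),
              class = "capsidprof_generation_error")
      }
      r_new <- base_r[bad] + rnorm(length(bad), 0, max(radial_jitter_sd,
                                                       0.25 * min_sep))
      P[bad, ] <- dirs[bad, , drop = FALSE] * r_new
    }
    P
  })

  sub_ids <- if (n_subunits <= length(CHAIN_ALPHABET))
    CHAIN_ALPHABET[seq_len(n_subunits)]
  else paste0("c", seq_len(n_subunits))
  aa_cycle <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  as_calpha_model(
    tibble(subunit = rep(sub_ids, each = residues_per_subunit),
           chain = rep(CHAIN_ALPHABET[(seq_len(n_subunits) - 1) %%
                                        length(CHAIN_ALPHABET) + 1],
                       each = residues_per_subunit),
           seq_num = rep(seq_len(residues_per_subunit), n_subunits),
           icode = "",
           aa = rep(aa_cycle[(seq_len(residues_per_subunit) - 1) %% 20 + 1],
                    n_subunits),
           x = X[, 1], y = X[, 2], z = X[, 3]),
    source = sprintf("synthetic shell capsid (%d x %d, radii %s, jitter %g, seed %d)",
                     n_subunits, residues_per_subunit,
                     paste(radii, collapse = ","), radial_jitter_sd, seed))
}

#' Synthetic conservation scores with known ground truth
#'
#' Generates per-site conservation scores as a stated linear function of
#' a structural z-profile plus Gaussian noise:
#' `score_i = slope * z_i + e_i`, `e_i ~ N(0, noise_sd^2)`. Because the
#' basis z-profile has unit variance, the population correlation between
#' the scores and the basis is `slope / sqrt(slope^2 + noise_sd^2)` --
#' for slope 1 this is `1 / sqrt(1 + noise_sd^2)`, so a target
#' correlation rho is dialled in with [noise_sd_for_rho()].
#'
#' @param model a C-alpha model (typically from [make_shell_capsid()]).
#' @param subunit subunit whose residues become sites.
#' @param basis `"wcn"` or `"cdist"`: which structural z-profile (in
#'   whole-model context) drives the scores.
#' @param slope linear coefficient (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer seed for the noise.
#' @return a conservation profile tibble (positions = residue numbers of
#'   the subunit).
#' @export
make_conservation <- function(model, subunit, basis = c("wcn", "cdist"),
                              slope = 1, noise_sd = 0, seed = 1) {
  basis <- match.arg(basis)
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0", class = "capsidprof_input_error")
  }
  prof <- if (basis == "wcn") wcn_profile(model, subunit)
          else cdistance_profile(model, subunit)
  z <- normalize_profile(prof)
  eps <- with_seed(seed, rnorm(nrow(z), 0, noise_sd))
  new_conservation(pos = z$seq_num, aa = z$aa,
                   score = slope * z$value + eps,
                   source = sprintf("synthetic (%s basis, slope %g, noise %g, seed %d)",
                                    basis, slope, noise_sd, seed))
}

#' Noise level for a target structure-conservation correlation
#'
#' Inverts the attenuation formula `rho = 1 / sqrt(1 + sigma^2)` of
#' [make_conservation()] (slope 1, unit-variance basis): returns the
#' `noise_sd` giving population correlation `rho`.
#'
#' @param rho target correlation in (0, 1\].
#' @return the corresponding `noise_sd`.
#' @export
noise_sd_for_rho <- function(rho) {
  stopifnot(rho > 0, rho <= 1)
  sqrt(1 / rho^2 - 1)
}
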